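# Independent brute-force oracles used to constrain the implementation.

# Transitive-closure components of credible sets, O(n^2) pairwise overlap +
# Warshall closure. `sets`: data.frame cs_id, group_id, variant_id (long).
# Returns a canonical partition: list of sorted cs_id vectors, sorted by first
# member.
oracle_components <- function(sets) {
  ids <- unique(sets$cs_id)
  n <- length(ids)
  vars <- lapply(ids, function(i) sets$variant_id[sets$cs_id == i])
  grp <- vapply(ids, function(i) sets$group_id[sets$cs_id == i][1], character(1))
  adj <- diag(n) > 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && grp[i] == grp[j] && length(intersect(vars[[i]], vars[[j]])) > 0)
      adj[i, j] <- adj[j, i] <- TRUE
  }
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (adj[i, k] && adj[k, j]) adj[i, j] <- TRUE
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (seen[i]) next
    member <- which(adj[i, ])
    seen[member] <- TRUE
    comps[[length(comps) + 1L]] <- sort(ids[member])
  }
  comps[order(vapply(comps, `[`, "", 1))]
}

canonical_partition <- function(components_df) {
  comps <- split(components_df$cs_id, components_df$component_id)
  comps <- lapply(comps, sort)
  unname(comps[order(vapply(comps, `[`, "", 1))])
}

# Literal Benjamini-Hochberg step-up: q_(i) = min_{j >= i} m * p_(j) / j.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * p[o[j]] / j)
    q[o[i]] <- min(best, 1)
  }
  q
}

# Coloc posteriors by enumerating all Q^2 causal-variant configurations from
# exponentiated Bayes factors and per-variant priors.
oracle_coloc <- function(l1, l2, p1 = 1e-4, p2 = 1e-4, p12 = 5e-6) {
  bf1 <- exp(l1); bf2 <- exp(l2)
  L0 <- 1
  L1 <- sum(p1 * bf1)
  L2 <- sum(p2 * bf2)
  L3 <- 0
  for (i in seq_along(bf1)) for (j in seq_along(bf2))
    if (i != j) L3 <- L3 + p1 * p2 * bf1[i] * bf2[j]
  L4 <- sum(p12 * bf1 * bf2)
  L <- c(L0, L1, L2, L3, L4)
  L / sum(L)
}

# Random long-format credible-set instance for the components oracle.
random_cs_instance <- function(n_sets, n_groups = 2, pool = 12) {
  rows <- lapply(seq_len(n_sets), function(i) {
    vids <- sample(sprintf("chr9_%d_A_G", seq_len(pool)), sample(1:4, 1))
    data.frame(cs_id = sprintf("cs%02d", i),
               trait_id = sprintf("tr%02d", i),
               group_id = sprintf("g%d", sample.int(n_groups, 1)),
               variant_id = vids,
               pip = runif(length(vids)),
               z = runif(length(vids), 3.5, 8),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Random exon structure on one chromosome: sorted, disjoint.
random_exon_structure <- function(max_exons = 20) {
  n <- sample.int(max_exons, 1)
  lens <- sample(30:400, n, replace = TRUE)
  gaps <- if (n > 1) sample(1:5000, n - 1, replace = TRUE) else integer(0)
  starts <- 1000 + cumsum(c(0, lens[-n] + gaps))
  gintervals("chr5", starts, starts + lens)
}
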