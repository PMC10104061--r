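logsumexp <- function(x) {
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Signal-level log Bayes factor vector
#'
#' One fine-mapped signal's per-variant evidence: natural-log Bayes factors
#' aligned to variant IDs in canonical `chr_pos_ref_alt` form.
#'
#' @param signal_id identifier
#' @param variant_ids character vector
#' @param lbf finite numeric vector, same length
#' @return a `signal_lbf` object
#' @export
signal_lbf <- function(signal_id, variant_ids, lbf) {
  stopifnot(length(variant_ids) == length(lbf))
  if (any(!is.finite(lbf))) stop("log Bayes factors must be finite")
  if (anyDuplicated(variant_ids)) stop("duplicate variant IDs in signal ", signal_id)
  structure(list(signal_id = signal_id,
                 variant_ids = as.character(variant_ids),
                 lbf = as.numeric(lbf)),
            class = "signal_lbf")
}

#' Colocalisation posteriors for a pair of fine-mapped signals
#'
#' Computes PP0-PP4 — the posteriors of the five colocalisation hypotheses
#' (H0 neither trait associated ... H4 both associated through a shared
#' causal variant) — for two signals from their per-variant log Bayes
#' factors, on the intersection of their variant grids. With aligned LBF
#' vectors l1, l2 over Q shared variants and per-variant priors p1, p2, p12,
#' the five log-scores are
#' \deqn{S0 = 0,\quad S1 = \mathrm{lse}(l_1) + \log p_1,\quad
#'       S2 = \mathrm{lse}(l_2) + \log p_2,}
#' \deqn{S4 = \mathrm{lse}(l_1 + l_2) + \log p_{12},\quad
#'       S3 = \log\left(e^{\mathrm{lse}(l_1)+\mathrm{lse}(l_2)} -
#'            e^{\mathrm{lse}(l_1+l_2)}\right) + \log(p_1 p_2),}
#' where lse is log-sum-exp over variants (the S3 subtraction removes the
#' same-variant configurations from the two-distinct-variants hypothesis).
#' Posteriors are the softmax of S0..S4. Variants are matched by exact ID;
#' mismatches drop out of the intersection.
#'
#' @param a,b [signal_lbf()] objects
#' @param p1,p2 per-variant prior probability of association with trait 1 / 2
#'   (default 1e-4)
#' @param p12 per-variant prior probability of association with both
#'   (default 5e-6)
#' @return a `coloc_result`: `pp0..pp4` (summing to 1), `n_shared_variants`,
#'   the priors, the two signal IDs, and `low_overlap` (TRUE when fewer than
#'   10 shared variants)
#' @export
coloc_pair <- function(a, b, p1 = 1e-4, p2 = 1e-4, p12 = 5e-6) {
  stopifnot(inherits(a, "signal_lbf"), inherits(b, "signal_lbf"))
  if (any(c(p1, p2, p12) <= 0) || any(c(p1, p2, p12) >= 1))
    stop("priors must lie in (0, 1)")
  shared <- intersect(a$variant_ids, b$variant_ids)
  if (length(shared) == 0L)
    stop(sprintf("signals %s and %s share no variants", a$signal_id, b$signal_id))
  l1 <- a$lbf[match(shared, a$variant_ids)]
  l2 <- b$lbf[match(shared, b$variant_ids)]

  lse1 <- logsumexp(l1)
  lse2 <- logsumexp(l2)
  lse12 <- logsumexp(l1 + l2)
  s0 <- 0
  s1 <- lse1 + log(p1)
  s2 <- lse2 + log(p2)
  s4 <- lse12 + log(p12)
  # sum over distinct-variant pairs = full cross sum minus the diagonal
  if (lse12 >= lse1 + lse2 - 1e-12) {
    s3 <- -Inf                              # degenerate (e.g. Q = 1): no off-diagonal mass
  } else {
    s3 <- lse1 + lse2 + log1p(-exp(lse12 - (lse1 + lse2))) + log(p1) + log(p2)
  }
  s <- c(s0, s1, s2, s3, s4)
  pp <- exp(s - logsumexp(s))
  pp <- pp / sum(pp)
  structure(list(signal_a = a$signal_id, signal_b = b$signal_id,
                 pp0 = pp[1], pp1 = pp[2], pp2 = pp[3], pp3 = pp[4], pp4 = pp[5],
                 n_shared_variants = length(shared),
                 priors = c(p1 = p1, p2 = p2, p12 = p12),
                 low_overlap = length(shared) < 10L),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc %s x %s (Q = %d%s)\n", x$signal_a, x$signal_b,
              x$n_shared_variants, if (x$low_overlap) ", low overlap" else ""))
  cat(sprintf("  PP0 %.3f  PP1 %.3f  PP2 %.3f  PP3 %.3f  PP4 %.3f\n",
              x$pp0, x$pp1, x$pp2, x$pp3, x$pp4))
  invisible(x)
}

#' All-pairs signal colocalisation
#'
#' Runs [coloc_pair()] over the Cartesian product of two signal lists
#' (e.g. GWAS signals x QTL signals at a locus), capping each side at
#' `max_signals_per_locus` signals, and flags pairs with PP4 strictly above
#' `pp4_threshold`. Pairs with no shared variants are skipped and counted.
#'
#' @param gwas_signals,qtl_signals lists of [signal_lbf()]
#' @param pp4_threshold pass threshold on PP4 (strict `>`, default 0.9)
#' @param max_signals_per_locus per-side cap (default 10); extra signals are
#'   dropped with a message
#' @inheritParams coloc_pair
#' @return `data.frame`: gwas_signal, qtl_signal, nsnps, pp0..pp4, pass;
#'   attribute `n_skipped` counts non-overlapping pairs
#' @export
coloc_all_pairs <- function(gwas_signals, qtl_signals, pp4_threshold = 0.9,
                            max_signals_per_locus = 10,
                            p1 = 1e-4, p2 = 1e-4, p12 = 5e-6) {
  stopifnot(length(gwas_signals) > 0, length(qtl_signals) > 0)
  cap <- function(sig, side) {
    if (length(sig) > max_signals_per_locus) {
      message(sprintf("%s side: %d signals, keeping first %d",
                      side, length(sig), max_signals_per_locus))
      sig[seq_len(max_signals_per_locus)]
    } else sig
  }
  gwas_signals <- cap(gwas_signals, "GWAS")
  qtl_signals <- cap(qtl_signals, "QTL")
  rows <- list()
  n_skipped <- 0L
  for (ga in gwas_signals) for (qa in qtl_signals) {
    if (length(intersect(ga$variant_ids, qa$variant_ids)) == 0L) {
      n_skipped <- n_skipped + 1L
      next
    }
    r <- coloc_pair(ga, qa, p1 = p1, p2 = p2, p12 = p12)
    rows[[length(rows) + 1L]] <- data.frame(
      gwas_signal = r$signal_a, qtl_signal = r$signal_b,
      nsnps = r$n_shared_variants,
      pp0 = r$pp0, pp1 = r$pp1, pp2 = r$pp2, pp3 = r$pp3, pp4 = r$pp4,
      pass = r$pp4 > pp4_threshold, stringsAsFactors = FALSE)
  }
  if (n_skipped > 0)
    message(n_skipped, " pair(s) skipped: no shared variants")
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gwas_signal = character(), qtl_signal = character(),
               nsnps = integer(), pp0 = numeric(), pp1 = numeric(),
               pp2 = numeric(), pp3 = numeric(), pp4 = numeric(),
               pass = logical())
  attr(out, "n_skipped") <- n_skipped
  out
}
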