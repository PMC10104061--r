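#' Credible-set tables
#'
#' Fine-mapped credible sets are handled as a long-format `data.frame` with
#' one row per (credible set, variant): columns `cs_id`, `trait_id`,
#' `group_id`, `variant_id`, `pip`, `z`. One credible set represents one
#' independent genetic signal for one molecular trait; `group_id` is the
#' unit within which signals are deduplicated (gene for exon/transcript
#' traits, splice cluster for junction traits).
#'
#' @param df candidate `data.frame`
#' @return the validated `data.frame` (invisibly on error-free input)
#' @export
validate_credible_sets <- function(df) {
  need <- c("cs_id", "trait_id", "group_id", "variant_id", "pip", "z")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("credible-set table missing column(s): ", paste(missing_cols, collapse = ", "))
  if (any(is.na(df$z))) {
    bad <- unique(df$cs_id[is.na(df$z)])
    stop("missing z-scores for credible set(s): ", paste(bad, collapse = ", "))
  }
  if (any(df$pip < 0 | df$pip > 1, na.rm = TRUE)) stop("PIPs must lie in [0, 1]")
  invisible(df)
}

#' QC-filter credible sets
#'
#' Drops a credible set if its maximum absolute z-score is lower than
#' `z_min` or its size is bigger than `size_max` variants. Both comparisons
#' are strict, so boundary sets (max |z| exactly 3, exactly 200 variants)
#' are kept.
#'
#' @param cs_df long-format credible-set table (see [validate_credible_sets()])
#' @param z_min minimum tolerated max |z| (default 3)
#' @param size_max maximum tolerated set size in variants (default 200)
#' @return list: `kept` (filtered table) and `dropped` (`data.frame` of
#'   cs_id, reason, max_abs_z, size)
#' @export
qc_credible_sets <- function(cs_df, z_min = 3, size_max = 200) {
  validate_credible_sets(cs_df)
  max_z <- tapply(abs(cs_df$z), cs_df$cs_id, max)
  size <- tapply(cs_df$variant_id, cs_df$cs_id, length)
  ids <- names(max_z)
  low_z <- max_z < z_min
  too_big <- size[ids] > size_max
  reason <- ifelse(low_z & too_big, "low_z;too_large",
                   ifelse(low_z, "low_z", ifelse(too_big, "too_large", NA)))
  dropped <- data.frame(cs_id = ids, reason = reason,
                        max_abs_z = as.numeric(max_z),
                        size = as.integer(size[ids]),
                        stringsAsFactors = FALSE)
  dropped <- dropped[!is.na(dropped$reason), , drop = FALSE]
  rownames(dropped) <- NULL
  list(kept = cs_df[!(cs_df$cs_id %in% dropped$cs_id), , drop = FALSE],
       dropped = dropped)
}

#' Connected components of credible sets
#'
#' Two credible sets are linked when they belong to the same group and share
#' at least one variant; components are the transitive closure of that
#' relation, each component representing one independent genetic signal.
#'
#' @param cs_df QC-passing credible-set table
#' @return `data.frame`: `cs_id`, `group_id`, `component_id` — a partition of
#'   the input credible sets
#' @export
build_components <- function(cs_df) {
  validate_credible_sets(cs_df)
  sets <- unique(cs_df[c("cs_id", "group_id")])
  if (nrow(sets) == 0L)
    return(data.frame(cs_id = character(), group_id = character(),
                      component_id = character(), stringsAsFactors = FALSE))
  # edges: within each (group, variant), link all sets carrying that variant
  key <- paste(cs_df$group_id, cs_df$variant_id, sep = "\r")
  by_var <- split(cs_df$cs_id, key)
  edges <- lapply(by_var, function(ids) {
    ids <- unique(ids)
    if (length(ids) < 2L) return(NULL)
    cbind(ids[1], ids[-1])                  # star suffices for connectivity
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(sets$cs_id)
  if (!is.null(edges)) g <- g + igraph::edges(t(edges))
  memb <- igraph::components(g)$membership
  comp <- memb[sets$cs_id]
  # stable, human-readable component ids: group_id + index of first member
  first_of <- tapply(seq_len(nrow(sets)), comp, min)
  ord_id <- rank(first_of)
  data.frame(cs_id = sets$cs_id, group_id = sets$group_id,
             component_id = paste0(sets$group_id, "_c", ord_id[as.character(comp)]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select the representative trait per component
#'
#' For each connected component, keeps the molecular trait with the highest
#' posterior inclusion probability. `pip_rule = "max"` scores a trait by its
#' single best variant PIP over its member credible sets; `"sum"` scores by
#' the summed PIP. Exact ties break to the lexicographically smallest
#' trait ID.
#'
#' @param cs_df QC-passing credible-set table
#' @param components output of [build_components()] on the same table
#' @param pip_rule `"max"` (default) or `"sum"`
#' @return `data.frame`: component_id, group_id, n_sets, member_cs_ids
#'   (semicolon-joined), selected_trait_id, selected_pip
#' @export
select_representative_traits <- function(cs_df, components, pip_rule = c("max", "sum")) {
  pip_rule <- match.arg(pip_rule)
  if (nrow(components) == 0L) stop("empty component list")
  df <- merge(cs_df, components[c("cs_id", "component_id")], by = "cs_id")
  agg_fun <- if (pip_rule == "max") max else sum
  score <- stats::aggregate(pip ~ component_id + trait_id, data = df, FUN = agg_fun)
  # per component: highest score, ties to smallest trait_id
  score <- score[order(score$component_id, -score$pip, score$trait_id), ]
  sel <- score[!duplicated(score$component_id), ]
  members <- stats::aggregate(cs_id ~ component_id, data = unique(df[c("cs_id", "component_id")]),
                              FUN = function(x) paste(sort(x), collapse = ";"))
  grp <- unique(components[c("component_id", "group_id")])
  n_sets <- stats::aggregate(cs_id ~ component_id,
                             data = unique(df[c("cs_id", "component_id")]), FUN = length)
  out <- Reduce(function(a, b) merge(a, b, by = "component_id"),
                list(grp,
                     stats::setNames(n_sets, c("component_id", "n_sets")),
                     stats::setNames(members, c("component_id", "member_cs_ids")),
                     stats::setNames(sel[c("component_id", "trait_id", "pip")],
                                     c("component_id", "selected_trait_id", "selected_pip"))))
  out[order(out$component_id), ]
}

#' Filter summary statistics to the selected traits
#'
#' Keeps only rows whose molecular trait was selected as the representative
#' of a connected component in its group — the filtering that shrinks
#' transcript-level summary statistics by an order of magnitude while
#' retaining one trait per independent signal.
#'
#' @param stats_df summary-statistic `data.frame` with at least `trait_id`
#'   and `group_id` columns
#' @param selections output of [select_representative_traits()]
#' @return list: `stats` (filtered rows), `report` (n_input, n_output,
#'   reduction — the fraction of rows removed)
#' @export
filter_summary_stats <- function(stats_df, selections) {
  stopifnot(all(c("trait_id", "group_id") %in% names(stats_df)))
  unknown <- setdiff(selections$group_id, stats_df$group_id)
  if (length(unknown))
    warning("selection(s) reference group(s) absent from summary statistics: ",
            paste(utils::head(unknown, 5), collapse = ", "))
  keep_key <- unique(paste(selections$group_id, selections$selected_trait_id, sep = "\r"))
  keep <- paste(stats_df$group_id, stats_df$trait_id, sep = "\r") %in% keep_key
  out <- stats_df[keep, , drop = FALSE]
  list(stats = out,
       report = list(n_input = nrow(stats_df), n_output = nrow(out),
                     reduction = if (nrow(stats_df) > 0) 1 - nrow(out) / nrow(stats_df) else 0))
}

#' Full credible-set filtering pipeline
#'
#' QC -> connected components -> representative-trait selection -> summary
#' statistics filtering, with the invariant checks (partition of QC-passing
#' sets; every retained trait is the PIP argmax of its component) asserted
#' on every run.
#'
#' @param cs_df long-format credible-set table
#' @param stats_df summary statistics with `trait_id`, `group_id`
#' @inheritParams qc_credible_sets
#' @inheritParams select_representative_traits
#' @return list: `selections`, `stats`, `report`, `dropped`, `components`
#' @export
credfilter_pipeline <- function(cs_df, stats_df, z_min = 3, size_max = 200,
                                pip_rule = "max") {
  qc <- qc_credible_sets(cs_df, z_min = z_min, size_max = size_max)
  comp <- build_components(qc$kept)
  stopifnot(setequal(comp$cs_id, unique(qc$kept$cs_id)))  # partition check
  sel <- select_representative_traits(qc$kept, comp, pip_rule = pip_rule)
  filt <- filter_summary_stats(stats_df, sel)
  list(selections = sel, stats = filt$stats, report = filt$report,
       dropped = qc$dropped, components = comp)
}
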