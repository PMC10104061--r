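#' Usage ratios within trait groups
#'
#' Converts absolute expression estimates (e.g. transcript TPMs) into usage
#' ratios: each trait's value divided by the summed expression of all traits
#' in the same group (gene or splice cluster) in that sample. Where a group
#' sums to zero in a sample the ratio is undefined and emitted as `NA` —
#' zero would falsely assert absence of usage.
#'
#' @param values non-negative trait x sample matrix (rownames = trait IDs)
#' @param grouping named character vector trait -> group ID, covering every row
#' @return matrix of usage ratios; within-group column sums are 1 where defined
#' @export
usage_matrix <- function(values, grouping) {
  stopifnot(is.matrix(values), !is.null(rownames(values)))
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  if (!all(rownames(values) %in% names(grouping)))
    stop("grouping missing for trait(s): ",
         paste(setdiff(rownames(values), names(grouping)), collapse = ", "))
  grp <- grouping[rownames(values)]
  out <- values
  n_undef <- 0L
  for (g in unique(grp)) {
    rows <- which(grp == g)
    sums <- colSums(values[rows, , drop = FALSE])
    zero <- !is.na(sums) & sums == 0
    denom <- ifelse(zero, NA_real_, sums)
    out[rows, ] <- sweep(values[rows, , drop = FALSE], 2, denom, "/")
    n_undef <- n_undef + sum(zero)
  }
  if (n_undef > 0)
    message(n_undef, " group/sample combination(s) had zero total expression; usages set to NA")
  out
}

#' Rank-based inverse normal transform
#'
#' Maps values to standard-normal quantiles via
#' `qnorm((rank - 0.5) / n)` with average ranks for ties, the standard
#' normalisation applied to molecular trait values before QTL mapping.
#' Missing values stay missing and do not count towards `n`. If all values
#' are identical they all share the average rank and transform to 0.
#'
#' @param x numeric vector (NAs allowed)
#' @return transformed vector, same length and NA pattern
#' @export
inverse_normal <- function(x) {
  out <- rep(NA_real_, length(x))
  obs <- !is.na(x)
  n <- sum(obs)
  if (n == 0L) return(out)
  if (n == 1L) { out[obs] <- 0; return(out) }
  r <- rank(x[obs], ties.method = "average")
  out[obs] <- stats::qnorm((r - 0.5) / n)
  out
}

# design matrix [1, covariates] with rank check; covariates: n x k or NULL
build_design <- function(n, covariates) {
  if (is.null(covariates)) return(matrix(1, n, 1, dimnames = list(NULL, "intercept")))
  covariates <- as.matrix(covariates)
  stopifnot(nrow(covariates) == n)
  X <- cbind(intercept = 1, covariates)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_cols <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(drop_cols, collapse = ", "))
  }
  X
}

#' Regress covariates out of a trait matrix
#'
#' Replaces each trait (row) by its OLS residuals against an intercept plus
#' the supplied covariates — the step that removes expression and genotype
#' principal components before fine mapping. Residuals are orthogonal to the
#' covariates by construction.
#'
#' @param y_matrix trait x sample numeric matrix
#' @param covariates sample x k numeric matrix (or `NULL` for mean-centring)
#' @return residual matrix with the same dimensions
#' @export
regress_out_covariates <- function(y_matrix, covariates = NULL) {
  y_matrix <- as.matrix(y_matrix)
  n <- ncol(y_matrix)
  X <- build_design(n, covariates)
  if (ncol(X) >= n) stop("need more samples than covariates")
  qrX <- qr(X)
  # residual of each row: y - X (X'X)^-1 X' y, via one QR for all traits
  t(qr.resid(qrX, t(y_matrix)))
}

#' Exon-level QTL effect sizes
#'
#' Per exon (or any molecular trait), fits ordinary least squares of the
#' trait value on variant dosage plus optional covariates and an intercept,
#' and reports the dosage coefficient: effect per copy of the alternative
#' allele with standard error, Student-t 95% confidence interval
#' (`n - k - 2` df) and nominal p-value. Benjamini-Hochberg q-values are
#' computed across the exons supplied (the displayed gene), and
#' `fdr_significant` flags `q <= fdr`.
#'
#' @param exon_matrix exon x sample matrix (rownames = exon IDs)
#' @param dosage sample dosage vector, aligned to columns; variance must be > 0
#' @param covariates sample x k matrix or `NULL`
#' @param exons optional exon interval `data.frame` (row per exon) carried
#'   into the output for plotting
#' @param alpha confidence level complement for the CI (default 0.05 -> 95% CI)
#' @param fdr FDR threshold for the significance flag (default 0.01)
#' @param int apply [inverse_normal()] to each exon row before fitting
#' @return `data.frame`: exon_id, beta, se, ci_low, ci_high, p, q, fdr_significant
#'   (+ chrom/start/end when `exons` given)
#' @export
exon_effects <- function(exon_matrix, dosage, covariates = NULL, exons = NULL,
                         alpha = 0.05, fdr = 0.01, int = FALSE) {
  exon_matrix <- as.matrix(exon_matrix)
  n <- ncol(exon_matrix)
  stopifnot(length(dosage) == n)
  if (stats::var(dosage) == 0) stop("monomorphic variant: zero dosage variance")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n < k + 3L) stop("need at least k + 3 samples")
  if (int) exon_matrix <- t(apply(exon_matrix, 1, inverse_normal))

  X <- cbind(build_design(n, covariates), dosage = dosage)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("dosage collinear with covariates")
  Y <- t(exon_matrix)                       # n x m
  coefs <- qr.coef(qrX, Y)                  # p x m
  res <- qr.resid(qrX, Y)
  df <- n - ncol(X)                         # n - k - 2
  sigma2 <- colSums(res^2) / df
  XtX_inv <- chol2inv(chol(crossprod(X)))
  v_dosage <- XtX_inv[ncol(X), ncol(X)]
  beta <- coefs["dosage", ]
  se <- sqrt(pmax(sigma2 * v_dosage, 0))
  tstat <- ifelse(se > 0, beta / se, ifelse(beta == 0, 0, Inf * sign(beta)))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  tcrit <- stats::qt(1 - alpha / 2, df = df)
  q <- bh_fdr(p)
  out <- data.frame(exon_id = rownames(exon_matrix),
                    beta = beta, se = se,
                    ci_low = beta - tcrit * se, ci_high = beta + tcrit * se,
                    p = p, q = q, fdr_significant = q <= fdr,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(exons)) {
    stopifnot(nrow(exons) == nrow(out))
    out <- cbind(out[1], exons[c("chrom", "start", "end")], out[-1])
  }
  out
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false discovery rate adjustment (delegates to
#' [stats::p.adjust()] with `method = "BH"`).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`
#' @return q-values, same length
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Filter traits by cis-window variant support
#'
#' Drops molecular traits with fewer than `min_variants` genetic variants in
#' their cis window (default +/- 1 Mb around the gene start, 5 variants),
#' the batch-mapping exclusion rule for regions of poor genotyping coverage.
#'
#' @param trait_pos `data.frame` with `trait_id`, `chrom`, `start` (gene start, 0-based)
#' @param variant_pos `data.frame` with `chrom`, `pos` (0-based) of available variants
#' @param cis_window half-width of the cis window in bp (default 1e6)
#' @param min_variants minimum variants required (default 5)
#' @return `trait_pos` rows that pass, with an `n_cis_variants` column
#' @export
filter_traits_by_cis_variants <- function(trait_pos, variant_pos,
                                          cis_window = 1e6, min_variants = 5) {
  n_cis <- vapply(seq_len(nrow(trait_pos)), function(i) {
    sum(variant_pos$chrom == trait_pos$chrom[i] &
          abs(variant_pos$pos - trait_pos$start[i]) <= cis_window)
  }, integer(1))
  out <- trait_pos[n_cis >= min_variants, , drop = FALSE]
  out$n_cis_variants <- n_cis[n_cis >= min_variants]
  out
}
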