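#' Blank-based contaminant filtering
#'
#' Retains a feature iff its median intensity across samples is at least
#' \code{fold} times its median intensity across blank runs. The boundary
#' follows the "less than \code{fold}-fold higher are excluded" convention,
#' so a feature at exactly \code{fold} times the blank median is kept.
#' Features with a blank median of zero are always kept.
#'
#' @param features \code{feature_table} in raw view.
#' @param blanks numeric matrix (same feature ids as rows) of blank-run
#'   intensities, or a \code{feature_table}.
#' @param fold fold-change threshold (> 0), default 20.
#' @return list with \code{features} (filtered \code{feature_table}) and
#'   \code{report} (data.frame: feature_id, sample_median, blank_median,
#'   fold, kept).
#' @export
blank_subtract <- function(features, blanks, fold = 20) {
  stopifnot_view(features, "raw")
  if (fold <= 0) stop("fold threshold must be positive")
  shared <- intersect(rownames(features), rownames(blanks))
  if (length(shared) == 0L) {
    stop("no shared feature ids between samples and blanks")
  }
  f <- as_ft_matrix(features)
  b <- as.matrix(blanks)[shared, , drop = FALSE]
  med_s <- apply(f, 1L, stats::median)
  med_b <- stats::setNames(rep(0, nrow(f)), rownames(f))
  med_b[shared] <- apply(b, 1L, stats::median)
  ratio <- ifelse(med_b > 0, med_s / med_b, Inf)
  kept <- med_b == 0 | med_s >= fold * med_b
  report <- data.frame(feature_id = rownames(f),
                       sample_median = med_s,
                       blank_median = med_b,
                       fold = ratio,
                       kept = kept,
                       row.names = NULL, stringsAsFactors = FALSE)
  list(features = feature_table(f[kept, , drop = FALSE], "raw"),
       report = report)
}

#' Total-intensity normalization
#'
#' Divides each sample (column) by its total intensity over all annotated
#' lipids, giving per-sample proportions that sum to 1.
#'
#' @param features \code{feature_table} in raw view.
#' @return \code{feature_table} in relative view.
#' @export
normalize_total <- function(features) {
  stopifnot_view(features, "raw")
  f <- as_ft_matrix(features)
  tot <- colSums(f)
  if (any(tot <= 0)) {
    stop("sample(s) with zero total intensity: ",
         paste(colnames(f)[tot <= 0], collapse = ", "))
  }
  feature_table(sweep(f, 2L, tot, "/"), "relative")
}

#' Centered log-ratio transform
#'
#' \eqn{clr_i = \ln(x_i / g(x))} per sample, with \eqn{g} the geometric mean
#' over features. Zeros are first replaced multiplicatively: zeros in a
#' sample become \eqn{\delta} = \code{delta_frac} times that sample's
#' smallest nonzero proportion and the nonzero proportions are rescaled so
#' the sample still sums to 1. Each output column sums to 0 by construction.
#'
#' @param features \code{feature_table} in relative view.
#' @param delta_frac zero-replacement value as a fraction of the smallest
#'   nonzero proportion in the sample (default 0.5).
#' @return \code{feature_table} in clr view.
#' @export
clr_transform <- function(features, delta_frac = 0.5) {
  stopifnot_view(features, "relative")
  f <- as_ft_matrix(features)
  if (any(f < 0)) stop("relative intensities must be non-negative")
  out <- apply(f, 2L, function(x) {
    zero <- x == 0
    if (any(zero)) {
      if (all(zero)) stop("clr undefined for an all-zero sample")
      delta <- delta_frac * min(x[!zero])
      x[zero] <- delta
      x[!zero] <- x[!zero] * (1 - sum(zero) * delta)
    }
    lx <- log(x)
    lx - mean(lx)
  })
  dimnames(out) <- dimnames(f)
  feature_table(out, "clr")
}
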