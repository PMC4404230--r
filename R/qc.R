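#' Derivative log ratio spread (DLRS)
#'
#' Robust per-sample noise measure used to flag noisy arrays: the spread of
#' first differences of the LRR profile, taken only between consecutive
#' markers on the same chromosome, divided by sqrt(2) (a difference of two
#' independent noise terms has variance 2 sigma^2). Spread is estimated
#' robustly as IQR / 1.349, the normal-consistent interquartile estimator,
#' so single CNV breakpoints barely move it. DLRS is invariant to adding a
#' constant to the whole profile or to any per-chromosome constant.
#'
#' @param lrr numeric LRR vector aligned to `map`.
#' @param map a [marker_map()] (defines chromosome runs and order).
#' @return non-negative scalar; approaches the marker-level noise SD for
#'   i.i.d. Gaussian noise.
#' @export
dlrs <- function(lrr, map) {
  stopifnot(length(lrr) == nrow(map))
  if (length(lrr) < 2L) stop("dlrs needs at least 2 markers")
  d <- unlist(lapply(
    split(lrr, factor(map$chromosome, levels = unique(map$chromosome))),
    diff
  ), use.names = FALSE)
  d <- d[is.finite(d)]
  if (length(d) == 0L) stop("no finite consecutive-marker differences")
  (IQR(d) / 1.349) / sqrt(2)
}

#' Genomic wave factor
#'
#' GC-correlated low-frequency intensity waves are a standard array artifact.
#' The wave factor is the least-squares slope of LRR on centered GC fraction;
#' a wave-free sample has a factor near 0. Samples whose absolute factor
#' exceeds a threshold are flagged wavy in [qc_report()].
#'
#' @param lrr numeric LRR vector aligned to `map`.
#' @param map a [marker_map()] providing `gc` per marker.
#' @return signed regression slope (LRR units per unit GC fraction).
#' @export
wave_factor <- function(lrr, map) {
  stopifnot(length(lrr) == nrow(map))
  gc_c <- map$gc - mean(map$gc)
  ok <- is.finite(lrr)
  ss <- sum(gc_c[ok]^2)
  if (ss == 0) stop("zero GC variance: wave factor undefined")
  sum(gc_c[ok] * (lrr[ok] - mean(lrr[ok]))) / ss
}

#' PCA batch-stratification check
#'
#' Principal component analysis of the sample x marker LRR matrix
#' (marker-centered, unscaled; zero-variance markers dropped), followed by a
#' two-sided rank-sum test of PC1 scores between batch labels (Kruskal-Wallis
#' for more than two batches). The cohort is called "stratified" when
#' p < 0.05, mirroring the use of PCA to detect genotyping-date batch
#' effects.
#'
#' @param lrr sample x marker matrix (>= 3 samples).
#' @param batch batch label per sample.
#' @param k number of principal coordinates to report (>= 2).
#' @param alpha significance level for the verdict.
#' @return list: `scores` (samples x k), `statistic`, `p_value`, `verdict`
#'   (`"stratified"`, `"not_stratified"`, or `"not_applicable"` for a single
#'   batch).
#' @export
pca_batch_check <- function(lrr, batch, k = 2L, alpha = 0.05) {
  stopifnot(nrow(lrr) >= 3L, length(batch) == nrow(lrr), k >= 2L)
  v <- apply(lrr, 2L, var)
  x <- lrr[, v > 0, drop = FALSE]
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]

  batch <- as.character(batch)
  if (length(unique(batch)) < 2L) {
    return(list(scores = scores, statistic = NA_real_, p_value = NA_real_,
                verdict = "not_applicable"))
  }
  if (length(unique(batch)) == 2L) {
    groups <- split(scores[, 1L], batch)
    ht <- suppressWarnings(wilcox.test(groups[[1L]], groups[[2L]],
                                       alternative = "two.sided"))
  } else {
    ht <- kruskal.test(scores[, 1L], factor(batch))
  }
  list(
    scores = scores,
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    verdict = if (ht$p.value < alpha) "stratified" else "not_stratified"
  )
}

#' Drop X/Y markers from a cohort matrix
#'
#' Sex-chromosome intensities are confounded by sample sex and are excluded
#' before CNV analysis. The sample set is unchanged.
#'
#' @param lrr sample x marker matrix aligned to `map`.
#' @param map a [marker_map()].
#' @return list with filtered `lrr` and `map`.
#' @export
exclude_sex_chromosomes <- function(lrr, map) {
  keep <- !is_sex_chrom(map$chromosome)
  if (!any(keep)) warning("all markers are on sex chromosomes; result is empty")
  map2 <- map[keep, , drop = FALSE]
  rownames(map2) <- NULL
  list(lrr = lrr[, keep, drop = FALSE], map = map2)
}

#' Sample-level QC report
#'
#' Computes DLRS and wave factor per sample, flags outliers, and runs the
#' PCA batch check. Noise flagging is cohort-relative
#' (`dlrs > median + 3 IQR` of the cohort DLRS values, a scale-free robust
#' outlier rule); wave flagging uses an absolute slope threshold.
#'
#' @param lrr sample x marker matrix.
#' @param map a [marker_map()].
#' @param batch batch label per sample (optional; row order of `lrr`).
#' @param wave_threshold absolute wave-factor threshold for the `wavy` flag.
#' @param dlrs_iqr_mult multiplier of the cohort IQR for the `noisy` flag.
#' @return list: `samples` (data.frame with `sample_id`, `dlrs`,
#'   `wave_factor`, `noisy`, `wavy`, `pc1`, `pc2`), `batch_test` (the
#'   [pca_batch_check()] result, or `NULL` when `batch` is missing).
#' @export
qc_report <- function(lrr, map, batch = NULL,
                      wave_threshold = 0.05, dlrs_iqr_mult = 3) {
  d <- apply(lrr, 1L, dlrs, map = map)
  wf <- apply(lrr, 1L, wave_factor, map = map)
  noisy <- d > median(d) + dlrs_iqr_mult * IQR(d)
  wavy <- abs(wf) > wave_threshold

  bt <- NULL
  pc <- matrix(NA_real_, nrow(lrr), 2L)
  if (!is.null(batch)) {
    bt <- pca_batch_check(lrr, batch)
    pc <- bt$scores[, 1:2, drop = FALSE]
  }
  out <- data.frame(
    sample_id = rownames(lrr) %||% as.character(seq_len(nrow(lrr))),
    dlrs = unname(d), wave_factor = unname(wf),
    noisy = unname(noisy), wavy = unname(wavy),
    pc1 = unname(pc[, 1L]), pc2 = unname(pc[, min(2L, ncol(pc))]),
    stringsAsFactors = FALSE
  )
  list(samples = out, batch_test = bt)
}
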