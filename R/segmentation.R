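#' Segmentation parameters
#'
#' Operational parameters of the copy-number segmentation: the maximum
#' pairwise p-value between adjacent segments (segments whose means do not
#' differ at this level are merged during pruning), the minimum number of
#' markers per segment, the segment-mean calling thresholds (< -0.15 for a
#' loss, > 0.1 for a gain), and a cap on the number of segments fitted per
#' chromosome (bounds the dynamic-programming cost).
#'
#' @param max_pairwise_p adjacent-segment significance level, in (0, 1).
#' @param min_markers minimum markers per segment (>= 1). With
#'   `min_markers = 1`, single-marker segments are retained by the pruning
#'   degenerate-case convention, so isolated extreme markers become calls;
#'   `min_markers = 3` (the default) requires multi-marker support.
#' @param loss_threshold,gain_threshold segment-mean calling thresholds.
#' @param max_segments_per_chromosome upper bound for the fitted number of
#'   segments.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(max_pairwise_p = 0.005,
                                min_markers = 3L,
                                loss_threshold = -0.15,
                                gain_threshold = 0.1,
                                max_segments_per_chromosome = 20L) {
  stopifnot(
    max_pairwise_p > 0, max_pairwise_p < 1,
    min_markers >= 1L,
    loss_threshold < 0, gain_threshold > 0,
    max_segments_per_chromosome >= 1L
  )
  structure(
    list(max_pairwise_p = max_pairwise_p,
         min_markers = as.integer(min_markers),
         loss_threshold = loss_threshold,
         gain_threshold = gain_threshold,
         max_segments_per_chromosome = as.integer(max_segments_per_chromosome)),
    class = "segmentation_params"
  )
}

# Exact least-squares segmentation by dynamic programming.
#
# CS1/CS2: nseries x (n+1) cumulative sums of the series and their squares
# (first column 0). Returns, for each k in 1..kmax, the optimal within-
# segment residual sum of squares (summed over series) and the cut-points
# achieving it, under a minimum segment length mm. Cost of segment (j+1..t)
# is sum_s [ S2_s(t)-S2_s(j) - (S1_s(t)-S1_s(j))^2 / (t-j) ].
.dp_segment <- function(CS1, CS2, kmax, mm) {
  n <- ncol(CS1) - 1L
  ns <- nrow(CS1)
  stopifnot(kmax >= 1L, mm >= 1L, kmax * mm <= n)

  segcost <- function(j, t) {
    # j: integer vector of left boundaries (0-based), t: scalar right end
    len <- t - j
    d1 <- CS1[, t + 1L] - CS1[, j + 1L, drop = FALSE]
    d2 <- CS2[, t + 1L] - CS2[, j + 1L, drop = FALSE]
    if (ns == 1L) {
      as.numeric(d2 - d1^2 / len)
    } else {
      colSums(d2 - d1^2 / matrix(len, ns, length(j), byrow = TRUE))
    }
  }

  FF <- matrix(Inf, kmax, n)          # FF[k, t]: best RSS for x[1..t], k segments
  BB <- matrix(NA_integer_, kmax, n)  # argmin boundary
  t1 <- mm:n
  if (ns == 1L) {
    FF[1L, t1] <- CS2[1L, t1 + 1L] - CS1[1L, t1 + 1L]^2 / t1
  } else {
    FF[1L, t1] <- colSums(CS2[, t1 + 1L, drop = FALSE] -
      CS1[, t1 + 1L, drop = FALSE]^2 / matrix(t1, ns, length(t1), byrow = TRUE))
  }
  if (kmax >= 2L) {
    for (k in 2L:kmax) {
      for (t in seq.int(k * mm, n)) {
        j <- seq.int((k - 1L) * mm, t - mm)
        vals <- FF[k - 1L, j] + segcost(j, t)
        best <- which.min(vals)
        FF[k, t] <- vals[best]
        BB[k, t] <- j[best]
      }
    }
  }

  backtrack <- function(k) {
    if (k == 1L) return(integer(0))
    cuts <- integer(k - 1L)
    t <- n
    for (kk in k:2L) {
      t <- BB[kk, t]
      cuts[kk - 1L] <- t
    }
    cuts
  }
  list(rss = FF[, n], cuts = lapply(seq_len(kmax), backtrack))
}

# Default model selection over the DP's candidate segment counts.
# An (essentially) zero residual is matched by the smallest k achieving it
# (noiseless signals get their exact number of segments); otherwise k
# minimizes the Gaussian BIC, N log(RSS_k / N) + ppseg * k * log(N), where
# ppseg counts the parameters added per extra segment (one mean per series
# plus the boundary). Spurious cut-points that survive the penalty are
# left for the pairwise-p pruning to remove.
.select_k <- function(rss, n_obs, ppseg, scale) {
  tol <- 1e-10 * max(scale, 1)
  if (min(rss) <= tol) return(min(which(rss <= min(rss) + tol)))
  k <- seq_along(rss)
  crit <- n_obs * log(rss / n_obs) + ppseg * k * log(n_obs)
  which.min(crit)
}

#' Optimal least-squares segmentation of one LRR series
#'
#' Exact (non-heuristic) segmentation of a single-chromosome series by
#' dynamic programming: for a given number of segments k, the returned
#' cut-points minimize the within-segment sum of squared deviations over all
#' possible placements, subject to the minimum segment length. When
#' `n_segments` is `NULL`, the number of segments is chosen by Gaussian BIC
#' over the candidate values up to `max_segments_per_chromosome` (a constant
#' series yields no cut-points, a noiseless step exactly one); cut-points
#' whose adjacent means do not differ significantly are then removed by
#' [prune_cutpoints()].
#'
#' A cut-point i means a boundary between positions i and i+1 (1-based).
#'
#' @param x finite numeric series (one chromosome).
#' @param params a [segmentation_params()].
#' @param n_segments fit exactly this many segments (must be feasible), or
#'   `NULL` for the default choice above.
#' @return integer vector of cut-points, with attributes `rss` (achieved
#'   residual sum of squares) and `k` (number of segments).
#' @export
optimal_segment <- function(x, params = segmentation_params(),
                            n_segments = NULL) {
  if (any(!is.finite(x))) stop("series must be finite")
  n <- length(x)
  mm <- params$min_markers
  if (n < mm) stop("series shorter than min_markers")
  kmax <- min(params$max_segments_per_chromosome, n %/% mm)
  if (!is.null(n_segments)) {
    if (n_segments < 1L || n_segments * mm > n) {
      stop("infeasible n_segments for this series length and min_markers")
    }
    kmax <- as.integer(n_segments)
  }
  CS1 <- matrix(c(0, cumsum(x)), 1L)
  CS2 <- matrix(c(0, cumsum(x^2)), 1L)
  dp <- .dp_segment(CS1, CS2, kmax, mm)
  k <- if (is.null(n_segments)) {
    .select_k(dp$rss, n_obs = n, ppseg = 2, scale = sum(x^2))
  } else {
    kmax
  }
  structure(dp$cuts[[k]], rss = dp$rss[k], k = k)
}

# Pooled-variance two-sample t-test p-value between two adjacent segments.
# Degenerate convention (needed for noiseless data and singleton segments):
# when the pooled within-segment variance is zero, p = 0 if the means
# differ and p = 1 if they are equal.
.pairwise_segment_p <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  m1 <- mean(x1); m2 <- mean(x2)
  ss <- sum((x1 - m1)^2) + sum((x2 - m2)^2)
  scale <- max(abs(c(x1, x2)), 1)
  if (ss <= (1e-10 * scale)^2 * (n1 + n2)) {
    return(if (abs(m1 - m2) <= 1e-10 * scale) 1 else 0)
  }
  df <- n1 + n2 - 2L  # ss > 0 implies n1 + n2 >= 3, so df >= 1
  tt <- (m1 - m2) / sqrt(ss / df * (1 / n1 + 1 / n2))
  2 * pt(-abs(tt), df)
}

#' Prune cut-points by adjacent-segment significance
#'
#' Backward elimination: while the largest pooled-variance t-test p-value
#' between any pair of adjacent segments exceeds `max_pairwise_p`, the
#' cut-point between that pair is removed and segment means are recomputed.
#' On exit every retained adjacent pair differs at p <= `max_pairwise_p`.
#'
#' @param x the series that was segmented (for the multivariate path, the
#'   cross-sample mean profile).
#' @param cuts integer cut-points (boundary after position i).
#' @param params a [segmentation_params()].
#' @return pruned integer cut-point vector (possibly empty).
#' @export
prune_cutpoints <- function(x, cuts, params = segmentation_params()) {
  n <- length(x)
  cuts <- sort(unique(as.integer(cuts)))
  if (any(cuts < 1L | cuts >= n)) stop("cut-points out of range")
  alpha <- params$max_pairwise_p
  while (length(cuts) > 0L) {
    bounds <- c(0L, cuts, n)
    p <- vapply(seq_along(cuts), function(i) {
      .pairwise_segment_p(x[(bounds[i] + 1L):bounds[i + 1L]],
                          x[(bounds[i + 1L] + 1L):bounds[i + 2L]])
    }, numeric(1))
    worst <- which.max(p)
    if (p[worst] > alpha) cuts <- cuts[-worst] else break
  }
  cuts
}

# Segment table from a series and its cut-points: one row per segment with
# marker index range, per-segment mean, and threshold status.
.segment_table <- function(x, cuts, params) {
  bounds <- c(0L, sort(cuts), length(x))
  first <- bounds[-length(bounds)] + 1L
  last <- bounds[-1L]
  means <- vapply(seq_along(first),
                  function(i) mean(x[first[i]:last[i]]), numeric(1))
  data.frame(
    first_marker = first, last_marker = last,
    n_markers = last - first + 1L,
    mean_lrr = means,
    status = ifelse(means < params$loss_threshold, "loss",
                    ifelse(means > params$gain_threshold, "gain", "neutral")),
    stringsAsFactors = FALSE
  )
}

#' Call copy-number segments by mean thresholds
#'
#' Applies the calling filter to a segmented series: a segment is a loss
#' when its mean is below `loss_threshold`, a gain when above
#' `gain_threshold`, neutral otherwise. Only non-neutral segments with at
#' least `min_markers` markers are emitted.
#'
#' @param x numeric series (one chromosome).
#' @param cuts integer cut-points (typically from [optimal_segment()] then
#'   [prune_cutpoints()]).
#' @param params a [segmentation_params()].
#' @return data.frame of calls: `first_marker`, `last_marker`, `n_markers`,
#'   `mean_lrr`, `status` (`"loss"`/`"gain"`).
#' @export
call_segments <- function(x, cuts, params = segmentation_params()) {
  seg <- .segment_table(x, cuts, params)
  seg[seg$status != "neutral" & seg$n_markers >= params$min_markers, ,
      drop = FALSE]
}

# Run segment -> prune -> call on one chromosome of one sample; returns
# calls with genomic coordinates attached.
.univariate_chrom_calls <- function(x, map_chr, params) {
  if (length(x) < params$min_markers) return(NULL)
  cuts <- optimal_segment(x, params)
  cuts <- prune_cutpoints(x, cuts, params)
  calls <- call_segments(x, cuts, params)
  if (nrow(calls) == 0L) return(NULL)
  calls$chromosome <- map_chr$chromosome[1L]
  calls$start_bp <- map_chr$position[calls$first_marker]
  calls$end_bp <- map_chr$position[calls$last_marker]
  calls
}

#' Univariate (per-sample) CNV calling
#'
#' Scans each sample separately: every chromosome of every sample is
#' segmented by [optimal_segment()], pruned by [prune_cutpoints()], and
#' called by [call_segments()].
#'
#' @param lrr sample x marker matrix aligned to `map`.
#' @param map a [marker_map()].
#' @param params a [segmentation_params()].
#' @return data.frame of CNV calls: `sample_id`, `chromosome`, `start_bp`,
#'   `end_bp`, `n_markers`, `mean_lrr`, `status`.
#' @export
univariate_calls <- function(lrr, map, params = segmentation_params()) {
  stopifnot(ncol(lrr) == nrow(map))
  chroms <- unique(map$chromosome)
  out <- list()
  for (s in seq_len(nrow(lrr))) {
    sid <- rownames(lrr)[s] %||% as.character(s)
    for (ch in chroms) {
      idx <- which(map$chromosome == ch)
      calls <- .univariate_chrom_calls(lrr[s, idx], map[idx, , drop = FALSE],
                                       params)
      if (!is.null(calls)) {
        calls$sample_id <- sid
        out[[length(out) + 1L]] <- calls
      }
    }
  }
  cols <- c("sample_id", "chromosome", "start_bp", "end_bp",
            "first_marker", "last_marker", "n_markers", "mean_lrr", "status")
  if (length(out) == 0L) {
    return(stats::setNames(
      data.frame(character(), character(), integer(), integer(), integer(),
                 integer(), integer(), numeric(), character(),
                 stringsAsFactors = FALSE), cols))
  }
  res <- do.call(rbind, out)[, cols]
  rownames(res) <- NULL
  res
}

#' Multivariate (joint) segmentation of a sample group
#'
#' Segments all samples of a group simultaneously with common cut-points:
#' the dynamic program minimizes the sum over samples of the within-segment
#' residual sum of squares, pruning is applied to the cross-sample mean
#' profile, and a segment becomes a group call only when it is present in
#' all samples — operationalized as every sample's segment mean lying beyond
#' the same calling threshold (all below `loss_threshold`, or all above
#' `gain_threshold`). A single-sample group reduces exactly to the
#' univariate path.
#'
#' @param lrr matrix restricted to the group's samples (rows) over `map`.
#' @param map a [marker_map()].
#' @param params a [segmentation_params()].
#' @return data.frame of group calls: `chromosome`, `start_bp`, `end_bp`,
#'   `n_markers`, `mean_lrr` (mean of per-sample means), `status`,
#'   `sample_ids` (comma-joined group members).
#' @export
multivariate_segment <- function(lrr, map, params = segmentation_params()) {
  if (is.null(dim(lrr))) lrr <- matrix(lrr, nrow = 1L)
  if (nrow(lrr) == 0L) stop("empty sample group")
  stopifnot(ncol(lrr) == nrow(map))
  mm <- params$min_markers
  ids <- rownames(lrr) %||% as.character(seq_len(nrow(lrr)))

  out <- list()
  for (ch in unique(map$chromosome)) {
    idx <- which(map$chromosome == ch)
    n <- length(idx)
    if (n < mm) next
    X <- lrr[, idx, drop = FALSE]
    CS1 <- cbind(0, t(apply(X, 1L, cumsum)))
    CS2 <- cbind(0, t(apply(X^2, 1L, cumsum)))
    kmax <- min(params$max_segments_per_chromosome, n %/% mm)
    dp <- .dp_segment(CS1, CS2, kmax, mm)
    k <- .select_k(dp$rss, n_obs = nrow(X) * n, ppseg = nrow(X) + 1,
                   scale = sum(X^2))
    profile <- colMeans(X)
    cuts <- prune_cutpoints(profile, dp$cuts[[k]], params)

    seg <- .segment_table(profile, cuts, params)
    for (i in seq_len(nrow(seg))) {
      if (seg$n_markers[i] < mm) next
      rng <- seg$first_marker[i]:seg$last_marker[i]
      smeans <- rowMeans(X[, rng, drop = FALSE])
      status <- if (all(smeans < params$loss_threshold)) "loss"
                else if (all(smeans > params$gain_threshold)) "gain"
                else "neutral"
      if (status == "neutral") next
      out[[length(out) + 1L]] <- data.frame(
        chromosome = ch,
        start_bp = map$position[idx[seg$first_marker[i]]],
        end_bp = map$position[idx[seg$last_marker[i]]],
        n_markers = seg$n_markers[i],
        mean_lrr = mean(smeans),
        status = status,
        sample_ids = paste(ids, collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chromosome = character(), start_bp = integer(),
                      end_bp = integer(), n_markers = integer(),
                      mean_lrr = numeric(), status = character(),
                      sample_ids = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Group-specific multivariate calls
#'
#' Runs [multivariate_segment()] on the high group, the low group, and the
#' pooled sample set. A call from one group's run is accepted as
#' group-specific only if it overlaps (by >= 1 bp) no same-status call from
#' the other group's run and no call at all from the pooled run — i.e. the
#' event is present in one phenotype group but neither in the other group
#' nor in all samples together. An event present in both groups with
#' opposite copy-number status is retained from both runs (there is no
#' threshold-consistent pooled call for it); it is later labelled as an
#' opposite-status region by [cnvr_catalogue()].
#'
#' @param lrr full sample x marker matrix.
#' @param groups list with character vectors `high` and `low` of sample ids
#'   (row names of `lrr`); both must be non-empty.
#' @param map a [marker_map()].
#' @param params a [segmentation_params()].
#' @return data.frame as [multivariate_segment()] plus a `group` column
#'   (`"high"`/`"low"`).
#' @export
group_specific_multivariate <- function(lrr, groups, map,
                                        params = segmentation_params()) {
  stopifnot(length(groups$high) > 0L, length(groups$low) > 0L)
  run <- function(ids) multivariate_segment(lrr[ids, , drop = FALSE], map, params)
  calls_h <- run(groups$high)
  calls_l <- run(groups$low)
  calls_all <- run(c(groups$high, groups$low))

  accept <- function(calls, other_group, pooled) {
    if (nrow(calls) == 0L) return(calls)
    keep <- rep(TRUE, nrow(calls))
    if (nrow(other_group) > 0L) {
      hits <- overlaps(calls, other_group)
      same <- calls$status[S4Vectors::queryHits(hits)] ==
        other_group$status[S4Vectors::subjectHits(hits)]
      keep[unique(S4Vectors::queryHits(hits)[same])] <- FALSE
    }
    if (nrow(pooled) > 0L) {
      hits <- overlaps(calls, pooled)
      keep[unique(S4Vectors::queryHits(hits))] <- FALSE
    }
    calls[keep, , drop = FALSE]
  }
  acc_h <- accept(calls_h, calls_l, calls_all)
  acc_l <- accept(calls_l, calls_h, calls_all)
  res <- rbind(
    if (nrow(acc_h)) cbind(acc_h, group = "high", stringsAsFactors = FALSE),
    if (nrow(acc_l)) cbind(acc_l, group = "low", stringsAsFactors = FALSE)
  )
  if (is.null(res)) {
    res <- data.frame(chromosome = character(), start_bp = integer(),
                      end_bp = integer(), n_markers = integer(),
                      mean_lrr = numeric(), status = character(),
                      sample_ids = character(), group = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}
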