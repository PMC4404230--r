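p1 <- segmentation_params(min_markers = 1L)
p3 <- segmentation_params()  # min_markers 3

test_that("optimal_segment solves noiseless and constant series exactly", {
  cuts <- optimal_segment(c(0, 0, 0, -1, -1, -1), p1)
  expect_identical(as.integer(cuts), 3L)
  expect_equal(attr(cuts, "rss"), 0)

  expect_length(optimal_segment(rep(0.4, 12), p1), 0)
  expect_length(optimal_segment(rep(0.4, 12), p3), 0)

  expect_error(optimal_segment(c(1, 2), p3), "shorter than min_markers")
  expect_error(optimal_segment(c(1, NA, 3), p1), "finite")
  expect_error(optimal_segment(rnorm(10), p1, n_segments = 11), "infeasible")
})

test_that("DP achieves the exhaustive-enumeration optimum (oracle)", {
  set.seed(42)
  for (case in 1:40) {
    n <- sample(6:20, 1)
    x <- rnorm(n)
    for (k in 2:4) {
      if (k > n) next
      cuts <- optimal_segment(x, p1, n_segments = k)
      expect_equal(attr(cuts, "rss"), brute_force_rss(x, k),
                   tolerance = 1e-9,
                   label = sprintf("case %d (n=%d, k=%d)", case, n, k))
    }
  }
})

test_that("DP respects min_markers", {
  set.seed(5)
  x <- rnorm(15)
  cuts <- optimal_segment(x, p3, n_segments = 4)
  lens <- diff(c(0, cuts, 15))
  expect_true(all(lens >= 3))
  expect_equal(attr(cuts, "rss"), brute_force_rss(x, 4, min_markers = 3),
               tolerance = 1e-9)
})

test_that("prune_cutpoints merges equal segments and keeps clean steps", {
  # equal adjacent values: p = 1, cut removed
  expect_length(prune_cutpoints(rep(0.2, 10), 5L, p1), 0)
  # zero variance, different means: p = 0, cut retained
  expect_identical(prune_cutpoints(c(0, 0, 0, -1, -1, -1), 3L, p1), 3L)
  # the same step buried among spurious cuts survives alone
  expect_identical(prune_cutpoints(c(0, 0, 0, -1, -1, -1), c(1L, 2L, 3L, 4L, 5L), p1), 3L)
  expect_error(prune_cutpoints(rnorm(5), 7L, p1), "out of range")
})

test_that("pruning matches an independent backward-elimination oracle", {
  for (seed in 1:50) {
    set.seed(seed)
    x <- rnorm(60)
    got <- prune_cutpoints(x, c(15L, 30L, 45L), p3)
    want <- oracle_prune(x, c(15L, 30L, 45L), 0.005)
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("call_segments applies the mean and length filters", {
  # mean -0.2 over 3 markers with min_markers 3: loss call
  calls <- call_segments(c(rep(0, 5), rep(-0.2, 3)), 5L, p3)
  expect_identical(calls$status, "loss")
  expect_identical(calls$n_markers, 3L)
  # mean 0.05: neutral, no call
  expect_identical(nrow(call_segments(rep(0.05, 6), integer(0), p3)), 0L)
  # mean 0.12 but only 2 markers: too short under min_markers 3
  calls <- call_segments(c(rep(0, 6), rep(0.12, 2)), 6L, p3)
  expect_identical(nrow(calls), 0L)
})

test_that("pruning is monotone in alpha and calls are monotone in thresholds", {
  set.seed(77)
  x <- rnorm(80, 0, 0.1)
  x[21:32] <- x[21:32] - 0.4
  cuts <- optimal_segment(x, p3)
  strict <- prune_cutpoints(x, cuts, segmentation_params(max_pairwise_p = 1e-4))
  loose <- prune_cutpoints(x, cuts, segmentation_params(max_pairwise_p = 0.05))
  expect_true(all(strict %in% loose))

  wide <- segmentation_params(loss_threshold = -0.35, gain_threshold = 0.3)
  expect_lte(nrow(call_segments(x, prune_cutpoints(x, cuts, wide), wide)),
             nrow(call_segments(x, prune_cutpoints(x, cuts, p3), p3)))
})

test_that("adding a constant shifts calls only through the thresholds", {
  set.seed(12)
  x <- rnorm(100, 0, 0.1)
  x[41:55] <- x[41:55] - 0.45
  c0 <- prune_cutpoints(x, optimal_segment(x, p3), p3)
  c1 <- prune_cutpoints(x + 0, optimal_segment(x + 0, p3), p3)
  expect_identical(c0, c1)
  calls <- call_segments(x, c0, p3)
  expect_identical(calls$status, "loss")
})

test_that("multivariate segmentation requires the event in every sample", {
  map <- make_map(60)
  set.seed(31)
  make_group <- function(n_carriers, n_samples = 5L) {
    lrr <- matrix(rnorm(n_samples * 60, 0, 0.1), n_samples, 60,
                  dimnames = list(paste0("s", seq_len(n_samples)), map$marker_id))
    if (n_carriers > 0) {
      lrr[seq_len(n_carriers), 21:35] <- lrr[seq_len(n_carriers), 21:35] - 0.45
    }
    lrr
  }
  # implanted in all 5 -> one group loss call spanning the implant +/- 2 markers
  calls <- multivariate_segment(make_group(5L), map, p3)
  loss <- calls[calls$status == "loss", ]
  expect_identical(nrow(loss), 1L)
  expect_lte(abs(loss$start_bp / 1000 - 21), 2)
  expect_lte(abs(loss$end_bp / 1000 - 35), 2)

  # implanted in 3 of 5 -> not "present in all samples", no group call
  calls <- multivariate_segment(make_group(3L), map, p3)
  expect_identical(nrow(calls[calls$status == "loss", ]), 0L)

  expect_error(multivariate_segment(matrix(0, 0, 60), map, p3), "empty")
})

test_that("a single-sample group reproduces the univariate result", {
  map <- make_map(80)
  set.seed(8)
  x <- rnorm(80, 0, 0.1)
  x[31:45] <- x[31:45] + 0.3
  uni <- univariate_calls(matrix(x, 1, dimnames = list("s1", map$marker_id)),
                          map, p3)
  multi <- multivariate_segment(matrix(x, 1, dimnames = list("s1", map$marker_id)),
                                map, p3)
  expect_identical(nrow(multi), nrow(uni))
  expect_identical(multi$start_bp, uni$start_bp)
  expect_identical(multi$end_bp, uni$end_bp)
  expect_identical(multi$status, uni$status)
})

test_that("group-specific multivariate logic accepts and rejects correctly", {
  map <- make_map(60)
  ids_h <- paste0("H", 1:4); ids_l <- paste0("L", 1:4)
  groups <- list(high = ids_h, low = ids_l)
  base <- function(seed) {
    set.seed(seed)
    matrix(rnorm(8 * 60, 0, 0.05), 8, 60,
           dimnames = list(c(ids_h, ids_l), map$marker_id))
  }
  # event in all low samples only -> accepted as low-specific
  lrr <- base(1); lrr[ids_l, 11:25] <- lrr[ids_l, 11:25] - 0.45
  calls <- group_specific_multivariate(lrr, groups, map, p3)
  expect_identical(unique(calls$group), "low")
  expect_identical(unique(calls$status), "loss")

  # event in every sample of both groups -> rejected via the pooled run
  lrr <- base(2); lrr[, 11:25] <- lrr[, 11:25] - 0.45
  calls <- group_specific_multivariate(lrr, groups, map, p3)
  expect_identical(nrow(calls), 0L)

  # opposite statuses in the two groups -> both retained
  lrr <- base(3)
  lrr[ids_l, 11:25] <- lrr[ids_l, 11:25] + 0.3
  lrr[ids_h, 11:25] <- lrr[ids_h, 11:25] - 0.45
  calls <- group_specific_multivariate(lrr, groups, map, p3)
  expect_setequal(calls$group, c("high", "low"))
  expect_setequal(calls$status, c("loss", "gain"))
})
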