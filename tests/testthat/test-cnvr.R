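mk_calls <- function(start, end, chromosome = "1", status = "loss",
                     group = "low", sample_id = paste0("s", seq_along(start))) {
  data.frame(chromosome = chromosome, start_bp = start, end_bp = end,
             status = status, group = group, sample_id = sample_id,
             stringsAsFactors = FALSE)
}

test_that("merge_calls takes the union of overlapping intervals only", {
  m <- merge_calls(mk_calls(c(100L, 150L), c(200L, 300L)))
  expect_identical(nrow(m), 1L)
  expect_identical(m$start_bp, 100L)
  expect_identical(m$end_bp, 300L)

  # abutting 1-based inclusive intervals do not overlap
  m <- merge_calls(mk_calls(c(100L, 201L), c(200L, 300L)))
  expect_identical(nrow(m), 2L)

  # different chromosomes never merge
  m <- merge_calls(mk_calls(c(100L, 100L), c(200L, 200L),
                            chromosome = c("1", "2")))
  expect_identical(nrow(m), 2L)
})

test_that("merge_calls is order-invariant and idempotent", {
  set.seed(19)
  for (rep in 1:10) {
    start <- sample.int(1000, 10)
    calls <- mk_calls(start, start + sample.int(300, 10),
                      chromosome = sample(c("1", "2"), 10, replace = TRUE))
    a <- merge_calls(calls)
    b <- merge_calls(calls[sample(nrow(calls)), ])
    expect_identical(a[c("chromosome", "start_bp", "end_bp")],
                     b[c("chromosome", "start_bp", "end_bp")])
    # idempotence: merging the merged regions changes nothing
    again <- merge_calls(data.frame(chromosome = a$chromosome,
                                    start_bp = a$start_bp, end_bp = a$end_bp))
    expect_identical(a[c("chromosome", "start_bp", "end_bp")],
                     again[c("chromosome", "start_bp", "end_bp")])
    # union length never exceeds summed member lengths
    expect_lte(sum(a$end_bp - a$start_bp + 1),
               sum(calls$end_bp - calls$start_bp + 1))
  }
})

test_that("classify_specificity implements the H/L/HL-opposite rule", {
  expect_identical(classify_specificity(rep("loss", 4), rep("low", 4)),
                   list(specificity = "L", status = "loss"))
  expect_identical(classify_specificity(c("gain", "loss"), c("low", "high")),
                   list(specificity = "HL_opposite", status = "both"))
  # same status in both groups: non-specific
  expect_identical(classify_specificity(c("loss", "loss"), c("low", "high")),
                   list(specificity = "none", status = "loss"))
  # mixed status within a group blocks the opposite label
  expect_identical(
    classify_specificity(c("loss", "gain", "loss"), c("low", "low", "high")),
    list(specificity = "none", status = "both"))
  expect_error(classify_specificity("loss", "validation"), "unknown group")
})

test_that("cnvr_catalogue names regions deterministically in genome order", {
  calls <- rbind(
    mk_calls(c(500L, 600L), c(700L, 800L), chromosome = "2",
             status = "gain", group = "high", sample_id = c("h1", "h2")),
    mk_calls(100L, 200L, chromosome = "1", sample_id = "l1"))
  ctg <- cnvr_catalogue(calls)
  expect_identical(ctg$name, c("CNVR1L", "CNVR2H"))
  expect_identical(ctg$carriers_high, c("", "h1,h2"))
  expect_identical(ctg$length_bp, c(101L, 301L))
  # identical input reproduces identical names
  expect_identical(cnvr_catalogue(calls), ctg)
})

test_that("summarize_cnvrs computes coverage arithmetic", {
  calls <- mk_calls(c(1e6L, 5e6L), c(1999999L, 5999999L), chromosome = "2",
                    sample_id = c("a", "b"))
  ctg <- cnvr_catalogue(calls)
  s <- summarize_cnvrs(ctg, 100e6)
  expect_identical(s$n_cnvrs, 2L)
  expect_equal(s$genome_fraction, 0.02)
  expect_identical(s$by_chromosome$n[s$by_chromosome$chromosome == "2"], 2L)

  empty <- summarize_cnvrs(cnvr_catalogue(
    data.frame(chromosome = character(0), start_bp = integer(0),
               end_bp = integer(0), status = character(0),
               group = character(0), sample_id = character(0))), 1e6)
  expect_identical(empty$n_cnvrs, 0L)
  expect_equal(empty$genome_fraction, 0)
  expect_true(all(empty$by_status == 0L))
})

test_that("validate_cohort detects complete separation and handles edge cases", {
  map <- make_map(10)
  high <- paste0("vh", 1:9); low <- paste0("vl", 1:8)
  lrr <- make_lrr(c(high, low), map)
  # distinct within-group values so the exact (tie-free) test applies
  for (i in seq_along(high)) lrr[high[i], ] <- i * 1e-6
  for (i in seq_along(low)) lrr[low[i], ] <- -0.4 + i * 1e-6
  cnvrs <- cnvr_catalogue(mk_calls(1000L, 10000L, sample_id = "l1"))
  v <- validate_cohort(lrr, map, list(high = high, low = low), cnvrs)
  # exact two-sided Mann-Whitney floor under complete separation at 9 vs 8
  expect_equal(v$p_value, 2 / choose(17, 8), tolerance = 1e-10)
  expect_true(v$replicated)
  expect_true(v$present)

  # n = 1 vs 1 can never reach p < 0.05
  v2 <- validate_cohort(lrr[c("vh1", "vl1"), ], map,
                        list(high = "vh1", low = "vl1"), cnvrs)
  expect_false(v2$replicated)
  expect_gte(v2$p_value, 0.05)

  # region covering no markers of the validation map: not testable
  far <- cnvr_catalogue(mk_calls(900000L, 950000L, sample_id = "l1"))
  v3 <- validate_cohort(lrr, map, list(high = high, low = low), far)
  expect_false(v3$testable)
  expect_true(is.na(v3$p_value))
})
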