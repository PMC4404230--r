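mk_cnvrs <- function(start, end, chromosome = "1") {
  calls <- data.frame(chromosome = chromosome, start_bp = start, end_bp = end,
                      status = "loss", group = "low",
                      sample_id = paste0("s", seq_along(start)),
                      stringsAsFactors = FALSE)
  cnvr_catalogue(calls)
}

mk_track <- function(start, end, chromosome = "1", label = "trait",
                     kind = "qtl", id = paste0("r", seq_along(start))) {
  interval_track(data.frame(chromosome = chromosome, start_bp = start,
                            end_bp = end, id = id, label = label,
                            stringsAsFactors = FALSE), kind)
}

test_that("overlap_track reports exactly the >=1 bp intersections", {
  cnvrs <- mk_cnvrs(100L, 300L)
  expect_identical(nrow(overlap_track(cnvrs, mk_track(250L, 400L))), 1L)
  expect_identical(nrow(overlap_track(mk_cnvrs(100L, 200L),
                                      mk_track(300L, 400L, kind = "gene"))), 0L)
})

test_that("overlap_track equals a quadratic brute-force scan", {
  set.seed(23)
  s1 <- sample.int(5000, 35)
  cnvrs <- mk_cnvrs(s1, s1 + sample.int(200, 35),
                    chromosome = sample(c("1", "2", "3"), 35, replace = TRUE))
  s2 <- sample.int(5000, 500)
  track <- mk_track(s2, s2 + sample.int(400, 500, replace = TRUE),
                    chromosome = sample(c("1", "2", "3"), 500, replace = TRUE))
  got <- overlap_track(cnvrs, track)
  brute <- 0L
  for (i in seq_len(nrow(cnvrs))) {
    for (j in seq_len(nrow(track))) {
      if (cnvrs$chromosome[i] == track$chromosome[j] &&
          cnvrs$start_bp[i] <= track$end_bp[j] &&
          cnvrs$end_bp[i] >= track$start_bp[j]) brute <- brute + 1L
    }
  }
  expect_identical(nrow(got), brute)
  expect_identical(anyDuplicated(paste(got$name, got$id)), 0L)
})

test_that("qtl_enrichment reproduces the closed-form Yates chi-square", {
  # construct QTL records yielding the 2x2 table [[20,10],[10,20]]
  cnvrs <- mk_cnvrs(1L, 10000L)
  qtl <- mk_track(
    start = c(rep(100L, 20), rep(50000L, 10), rep(200L, 10), rep(60000L, 20)),
    end = c(rep(900L, 20), rep(50900L, 10), rep(990L, 10), rep(60900L, 20)),
    label = rep(c("litter size", "litter size", "growth", "growth"),
                c(20, 10, 10, 20)))
  res <- qtl_enrichment(cnvrs, qtl)
  expect_true(res$testable)
  expect_identical(as.vector(res$table), c(20L, 10L, 10L, 20L))
  expect_equal(res$statistic, 5.4, tolerance = 1e-9)
  expect_equal(res$p_value, 0.02013675, tolerance = 1e-6)

  # identical rows: no association
  qtl0 <- mk_track(start = rep(c(100L, 50000L), 10),
                   end = rep(c(900L, 50900L), 10),
                   label = rep(c("litter size", "growth"), each = 10))
  res0 <- qtl_enrichment(cnvrs, qtl0)
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 1)

  # zero margin: not testable
  resna <- qtl_enrichment(cnvrs, mk_track(100L, 900L, label = "litter size"))
  expect_false(resna$testable)
})

test_that("pathway_enrichment matches the hypergeometric pmf-summation oracle", {
  # N = 1000, n = 50, C = 100, O = 10
  ref <- sprintf("g%04d", 1:1000)
  categories <- list(cat = ref[1:100])
  gene_set <- c(ref[1:10], ref[101:140])  # 10 in category, 40 out
  rows <- pathway_enrichment(gene_set, categories, ref)
  expect_identical(rows$C, 100L)
  expect_identical(rows$O, 10L)
  expect_equal(rows$E, 5)
  expect_equal(rows$R, 2)
  # oracle: explicit pmf summation over the upper tail
  pmf_sum <- sum(choose(100, 10:50) * choose(900, 50 - (10:50)) / choose(1000, 50))
  expect_equal(rows$rawP, pmf_sum, tolerance = 1e-12)

  # O = 0: ratio 0, rawP = 1
  rows0 <- pathway_enrichment(ref[200:210], list(cat = ref[1:50]), ref)
  expect_identical(rows0$O, 0L)
  expect_equal(rows0$R, 0)
  expect_equal(rows0$rawP, 1)
})

test_that("pathway_enrichment adjusts with BH and validates inputs", {
  ref <- sprintf("g%03d", 1:200)
  cats <- list(a = ref[1:20], b = ref[21:60], c = ref[61:160])
  gene_set <- ref[c(1:10, 25:28, 61:63)]
  rows <- pathway_enrichment(gene_set, cats, ref)
  # BH: monotone over the rawP ranking, bounded by 1, never below rawP
  ord <- order(rows$rawP)
  expect_true(all(diff(rows$adjP[ord]) >= -1e-12))
  expect_true(all(rows$adjP <= 1))
  expect_true(all(rows$adjP >= rows$rawP - 1e-12))
  expect_equal(rows$adjP, p.adjust(rows$rawP, "BH"))

  expect_warning(
    pathway_enrichment(ref[1:5], list(a = c(ref[1:5], "alien")), ref),
    "outside the reference")
  expect_error(pathway_enrichment(c(ref, "zz"), list(a = ref[1:5]), ref),
               "subset")
  expect_error(pathway_enrichment(ref[1:10], list(a = ref[1:5]), 5),
               "larger than the reference")

  # degenerate full-coverage case: gene set = reference
  full <- pathway_enrichment(ref, cats, ref)
  expect_true(all(full$O == full$C))
  expect_true(all(full$rawP == 1))
})

test_that("report_gene_mirna_content lists content and keeps empty rows", {
  cnvrs <- mk_cnvrs(c(100L, 5000L), c(1000L, 6000L))
  genes <- mk_track(c(150L, 800L), c(300L, 950L), kind = "gene",
                    label = c("GENE1", "GENE2"))
  mirna <- mk_track(200L, 250L, kind = "mirna", label = "miR-21")
  out <- report_gene_mirna_content(cnvrs, genes, mirna)
  expect_identical(out$genes[1], "GENE1,GENE2")
  expect_identical(out$mirnas[1], "miR-21")
  expect_identical(out$genes[2], "")     # annotation-free CNVR retained
  expect_identical(out$status_label[1], "DEL")

  # an opposite-status region is displayed as GAIN/DEL
  calls <- data.frame(chromosome = "1", start_bp = c(100L, 150L),
                      end_bp = c(1000L, 900L), status = c("loss", "gain"),
                      group = c("high", "low"), sample_id = c("h1", "l1"),
                      stringsAsFactors = FALSE)
  hl <- report_gene_mirna_content(cnvr_catalogue(calls), genes, mirna)
  expect_identical(hl$specificity, "HL_opposite")
  expect_identical(hl$status_label, "GAIN/DEL")
})
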