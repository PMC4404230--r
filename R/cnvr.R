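#' Merge CNV calls into CNV regions
#'
#' The transitive closure of >= 1 bp overlap on the same chromosome: calls
#' that overlap (directly or through a chain of overlapping calls) are
#' merged into one CNV region (CNVR) whose extent is the union of the member
#' intervals. Abutting intervals (end + 1 == start under 1-based inclusive
#' coordinates) are NOT merged. The result is independent of input order and
#' idempotent.
#'
#' @param calls data.frame with at least `chromosome`, `start_bp`, `end_bp`
#'   columns (e.g. from [univariate_calls()] or
#'   [group_specific_multivariate()]).
#' @return data.frame of regions: `chromosome`, `start_bp`, `end_bp`,
#'   `n_calls`, and a list-column `members` holding the row indices of
#'   `calls` belonging to each region; sorted by genome order.
#' @export
merge_calls <- function(calls) {
  if (nrow(calls) == 0L) {
    out <- data.frame(chromosome = character(), start_bp = integer(),
                      end_bp = integer(), n_calls = integer(),
                      stringsAsFactors = FALSE)
    out$members <- list()
    return(out)
  }
  gr <- intervals_to_granges(calls)
  # min.gapwidth = 0 merges only truly overlapping ranges, not abutting ones
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  hits <- GenomicRanges::findOverlaps(gr, red)
  region_of <- S4Vectors::subjectHits(hits)[order(S4Vectors::queryHits(hits))]

  out <- data.frame(
    chromosome = as.character(GenomicRanges::seqnames(red)),
    start_bp = GenomicRanges::start(red),
    end_bp = GenomicRanges::end(red),
    stringsAsFactors = FALSE
  )
  out$members <- split(seq_len(nrow(calls)), region_of)[as.character(seq_len(nrow(out)))]
  out$n_calls <- lengths(out$members)
  ord <- order(chrom_rank(out$chromosome), out$start_bp)
  out <- out[ord, c("chromosome", "start_bp", "end_bp", "n_calls", "members")]
  rownames(out) <- NULL
  out
}

#' Classify the group specificity and status of one region
#'
#' Given the statuses and phenotype groups of a region's member calls:
#' specificity is `"H"` when all carriers are from the high group, `"L"`
#' when all are low, `"HL_opposite"` when both groups are present with
#' strictly opposite statuses (one group all-loss, the other all-gain), and
#' `"none"` otherwise (present in both groups with the same or mixed
#' status; such regions are excluded from the H/L marker lists). Status is
#' `"loss"`, `"gain"`, or `"both"`.
#'
#' @param statuses character vector (`"loss"`/`"gain"`) of member calls.
#' @param groups character vector (`"high"`/`"low"`) of member calls.
#' @return list with `specificity` and `status`.
#' @export
classify_specificity <- function(statuses, groups) {
  stopifnot(length(statuses) == length(groups), length(statuses) > 0L)
  if (!all(groups %in% c("high", "low"))) {
    stop("carrier with unknown group: ",
         paste(setdiff(groups, c("high", "low")), collapse = ", "))
  }
  status <- if (all(statuses == "loss")) "loss"
            else if (all(statuses == "gain")) "gain"
            else "both"
  gset <- unique(groups)
  specificity <- if (identical(gset, "high")) "H"
    else if (identical(gset, "low")) "L"
    else {
      st_h <- unique(statuses[groups == "high"])
      st_l <- unique(statuses[groups == "low"])
      if (length(st_h) == 1L && length(st_l) == 1L && st_h != st_l) {
        "HL_opposite"
      } else {
        "none"
      }
    }
  list(specificity = specificity, status = status)
}

#' Build the CNVR catalogue from CNV calls
#'
#' Merges calls into regions ([merge_calls()]), classifies each region's
#' group specificity and gain/loss status ([classify_specificity()]), and
#' assigns stable names: regions are numbered in ascending
#' (chromosome, start) order and suffixed `H`, `L`, or `HL` (opposite-status
#' regions); non-specific regions carry no suffix.
#'
#' @param calls data.frame with `chromosome`, `start_bp`, `end_bp`,
#'   `status`, `group` and either `sample_id` (univariate calls) or
#'   `sample_ids` (comma-joined, multivariate calls).
#' @return data.frame: `name`, `chromosome`, `start_bp`, `end_bp`,
#'   `length_bp`, `specificity`, `status`, `n_calls`, `carriers_high`,
#'   `carriers_low` (comma-joined carrier ids per group).
#' @export
cnvr_catalogue <- function(calls) {
  if (nrow(calls) == 0L) {
    return(data.frame(name = character(), chromosome = character(),
                      start_bp = integer(), end_bp = integer(),
                      length_bp = integer(), specificity = character(),
                      status = character(), n_calls = integer(),
                      carriers_high = character(), carriers_low = character(),
                      stringsAsFactors = FALSE))
  }
  if (is.null(calls$group)) stop("calls must carry a 'group' column")
  carrier_col <- if (!is.null(calls$sample_ids)) calls$sample_ids else calls$sample_id
  if (is.null(carrier_col)) stop("calls must carry sample_id or sample_ids")

  regions <- merge_calls(calls)
  n <- nrow(regions)
  spec <- character(n); status <- character(n)
  ch <- character(n); cl <- character(n)
  for (i in seq_len(n)) {
    m <- regions$members[[i]]
    cls <- classify_specificity(calls$status[m], calls$group[m])
    spec[i] <- cls$specificity
    status[i] <- cls$status
    carriers <- strsplit(carrier_col[m], ",", fixed = TRUE)
    ch[i] <- paste(sort(unique(unlist(carriers[calls$group[m] == "high"]))),
                   collapse = ",")
    cl[i] <- paste(sort(unique(unlist(carriers[calls$group[m] == "low"]))),
                   collapse = ",")
  }
  suffix <- c(H = "H", L = "L", HL_opposite = "HL", none = "")[spec]
  data.frame(
    name = paste0("CNVR", seq_len(n), suffix),
    chromosome = regions$chromosome,
    start_bp = regions$start_bp,
    end_bp = regions$end_bp,
    length_bp = regions$end_bp - regions$start_bp + 1L,
    specificity = spec,
    status = status,
    n_calls = regions$n_calls,
    carriers_high = ch,
    carriers_low = cl,
    stringsAsFactors = FALSE
  )
}

#' Summarize a CNVR catalogue
#'
#' Per-chromosome counts and covered bp, counts by specificity and status,
#' total CNVR length and the fraction of the genome covered.
#'
#' @param cnvrs a [cnvr_catalogue()] data.frame.
#' @param genome_length_bp total genome length (> 0); e.g. 2.8e9 for the
#'   2800 Mb porcine genome.
#' @return list of class `cnvr_summary`: `n_cnvrs`, `total_length_bp`,
#'   `genome_fraction`, `by_chromosome` (data.frame), `by_specificity`,
#'   `by_status` (named counts).
#' @export
summarize_cnvrs <- function(cnvrs, genome_length_bp) {
  stopifnot(genome_length_bp > 0)
  total <- sum(as.numeric(cnvrs$length_bp))
  by_chrom <- if (nrow(cnvrs) == 0L) {
    data.frame(chromosome = character(), n = integer(), covered_bp = numeric(),
               stringsAsFactors = FALSE)
  } else {
    agg <- aggregate(cbind(n = rep(1L, nrow(cnvrs)),
                           covered_bp = cnvrs$length_bp) ~ chromosome,
                     data = cnvrs, FUN = sum)
    agg[order(chrom_rank(agg$chromosome)), , drop = FALSE]
  }
  count_levels <- function(x, levels) {
    out <- stats::setNames(integer(length(levels)), levels)
    tab <- table(factor(x, levels = levels))
    out[names(tab)] <- as.integer(tab)
    out
  }
  structure(list(
    n_cnvrs = nrow(cnvrs),
    total_length_bp = total,
    genome_fraction = total / genome_length_bp,
    by_chromosome = by_chrom,
    by_specificity = count_levels(cnvrs$specificity,
                                  c("H", "L", "HL_opposite", "none")),
    by_status = count_levels(cnvrs$status, c("loss", "gain", "both"))
  ), class = "cnvr_summary")
}

#' @export
print.cnvr_summary <- function(x, ...) {
  cat(sprintf("%d CNVRs, total %.2f Mb (%.2f%% of genome)\n",
              x$n_cnvrs, x$total_length_bp / 1e6, 100 * x$genome_fraction))
  cat("specificity:", paste(names(x$by_specificity), x$by_specificity,
                            sep = "=", collapse = " "), "\n")
  cat("status:     ", paste(names(x$by_status), x$by_status,
                            sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Test CNVRs in an independent validation cohort
#'
#' For each CNVR, computes every validation sample's mean LRR across the
#' region's markers and compares the high- and low-group distributions with
#' a two-sided Mann-Whitney U test. A region is "replicated" when p < 0.05,
#' and "present" when at least one validation sample re-calls a non-neutral
#' status by the mean thresholds. Regions covering no marker of the
#' validation map are reported as not testable.
#'
#' @param lrr validation sample x marker matrix.
#' @param map validation [marker_map()].
#' @param groups list with character vectors `high` and `low` of validation
#'   sample ids (must be disjoint from the discovery cohort).
#' @param cnvrs a [cnvr_catalogue()] data.frame.
#' @param params a [segmentation_params()] (for the calling thresholds).
#' @param alpha significance level for replication.
#' @return data.frame: `name`, `n_markers`, `p_value`, `replicated`,
#'   `present`, `testable`.
#' @export
validate_cohort <- function(lrr, map, groups, cnvrs,
                            params = segmentation_params(), alpha = 0.05) {
  stopifnot(all(c(groups$high, groups$low) %in% rownames(lrr)))
  n <- nrow(cnvrs)
  p <- rep(NA_real_, n); nm <- integer(n)
  present <- rep(NA, n); testable <- rep(FALSE, n)
  for (i in seq_len(n)) {
    idx <- which(map$chromosome == cnvrs$chromosome[i] &
                 map$position >= cnvrs$start_bp[i] &
                 map$position <= cnvrs$end_bp[i])
    nm[i] <- length(idx)
    if (length(idx) == 0L) next
    testable[i] <- TRUE
    mh <- rowMeans(lrr[groups$high, idx, drop = FALSE])
    ml <- rowMeans(lrr[groups$low, idx, drop = FALSE])
    p[i] <- suppressWarnings(
      wilcox.test(mh, ml, alternative = "two.sided")$p.value)
    all_means <- c(mh, ml)
    present[i] <- any(all_means < params$loss_threshold |
                      all_means > params$gain_threshold)
  }
  data.frame(
    name = cnvrs$name, n_markers = nm, p_value = p,
    replicated = !is.na(p) & p < alpha,
    present = present, testable = testable,
    stringsAsFactors = FALSE
  )
}

#' Write a CNVR catalogue as TSV and BED
#'
#' @param cnvrs a [cnvr_catalogue()] data.frame.
#' @param tsv,bed output paths (`NULL` to skip either).
#' @return invisibly, the catalogue.
#' @export
write_cnvrs <- function(cnvrs, tsv = NULL, bed = NULL) {
  if (!is.null(tsv)) {
    write.table(cnvrs, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(bed)) {
    bed_df <- data.frame(chrom = cnvrs$chromosome,
                         start = cnvrs$start_bp - 1L,
                         end = cnvrs$end_bp,
                         name = cnvrs$name)
    write.table(bed_df, bed, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(cnvrs)
}
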