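#' Overlap CNVRs with an interval track
#'
#' Reports every (CNVR, track record) pair sharing >= 1 bp on the same
#' chromosome, each pair once, in deterministic (CNVR, record) order.
#'
#' @param cnvrs a [cnvr_catalogue()] data.frame.
#' @param track an [interval_track()].
#' @return data.frame: `name` (CNVR), `id`, `label` (track record).
#' @export
overlap_track <- function(cnvrs, track) {
  empty <- data.frame(name = character(), id = character(),
                      label = character(), stringsAsFactors = FALSE)
  if (nrow(cnvrs) == 0L || nrow(track) == 0L) return(empty)
  hits <- overlaps(cnvrs, track)
  if (length(hits) == 0L) return(empty)
  q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
  ord <- order(q, s)
  data.frame(name = cnvrs$name[q[ord]],
             id = as.character(track$id[s[ord]]),
             label = as.character(track$label[s[ord]]),
             stringsAsFactors = FALSE)
}

#' Reproduction-QTL enrichment within CNVRs (Yates chi-square)
#'
#' Builds a 2x2 table of QTL records — class (reproduction vs other) by
#' overlap with any CNVR (yes/no) — and tests it with the
#' continuity-corrected (Yates) chi-square on 1 df. The counting unit is the
#' QTL record, not the trait or covered bp.
#'
#' @param cnvrs a [cnvr_catalogue()] data.frame.
#' @param qtl_track an [interval_track()] of QTL records; reproduction
#'   membership is taken from a logical `is_reproduction` column if present,
#'   otherwise from `label` membership in `reproduction_categories`.
#' @param reproduction_categories trait categories counted as reproduction
#'   QTLs (defaults to the Animal QTLdb reproduction classes).
#' @return list of class `qtl_enrichment`: `table` (2x2), `statistic`,
#'   `p_value`, `testable` (`FALSE` with `NA` statistics when a margin is
#'   zero).
#' @export
qtl_enrichment <- function(cnvrs, qtl_track,
                           reproduction_categories = c(
                             "endocrine", "litter size",
                             "reproductive organ", "reproductive trait")) {
  is_repro <- if (!is.null(qtl_track$is_reproduction)) {
    as.logical(qtl_track$is_reproduction)
  } else {
    tolower(as.character(qtl_track$label)) %in% tolower(reproduction_categories)
  }
  overlapping <- rep(FALSE, nrow(qtl_track))
  if (nrow(cnvrs) > 0L && nrow(qtl_track) > 0L) {
    hits <- overlaps(qtl_track, cnvrs)
    overlapping[unique(S4Vectors::queryHits(hits))] <- TRUE
  }
  tab <- table(
    class = factor(ifelse(is_repro, "reproduction", "other"),
                   levels = c("reproduction", "other")),
    in_cnvr = factor(ifelse(overlapping, "yes", "no"),
                     levels = c("yes", "no"))
  )
  if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    return(structure(list(table = tab, statistic = NA_real_,
                          p_value = NA_real_, testable = FALSE),
                     class = "qtl_enrichment"))
  }
  ht <- suppressWarnings(chisq.test(tab, correct = TRUE))
  structure(list(table = tab, statistic = unname(ht$statistic),
                 p_value = ht$p.value, testable = TRUE),
            class = "qtl_enrichment")
}

#' @export
print.qtl_enrichment <- function(x, ...) {
  print(x$table)
  if (x$testable) {
    cat(sprintf("Yates chi-square = %.4g, df = 1, p = %.4g\n",
                x$statistic, x$p_value))
  } else {
    cat("not testable (zero margin)\n")
  }
  invisible(x)
}

#' Hypergeometric gene-set enrichment over local category tables
#'
#' For each category: C = number of reference genes in the category, O =
#' observed members of the gene set in the category, E = C n / N the
#' expected count for a gene set of size n against a reference of size N,
#' R = O / E the enrichment ratio, rawP = upper-tail hypergeometric
#' probability P(X >= O), and adjP = Benjamini-Hochberg adjusted p across
#' the tested categories. Rows are sorted by adjP, then rawP.
#'
#' @param gene_set character vector of gene ids (must lie in the reference).
#' @param categories named list of gene-id vectors (e.g. from [read_gmt()]).
#' @param reference either the full reference gene-id vector, or a single
#'   integer giving the reference size N (in which case categories are
#'   assumed to lie within the reference).
#' @return data.frame: `category_id`, `category_name`, `C`, `O`, `E`, `R`,
#'   `rawP`, `adjP`.
#' @export
pathway_enrichment <- function(gene_set, categories, reference) {
  if (length(categories) == 0L) stop("categories must be non-empty")
  gene_set <- unique(gene_set)
  if (length(reference) == 1L && is.numeric(reference)) {
    N <- as.integer(reference)
  } else {
    reference <- unique(as.character(reference))
    N <- length(reference)
    if (!all(gene_set %in% reference)) {
      stop("gene_set must be a subset of the reference")
    }
    trimmed <- lapply(categories, intersect, reference)
    dropped <- sum(lengths(categories) - lengths(trimmed))
    if (dropped > 0L) {
      warning(dropped, " category gene(s) outside the reference dropped")
    }
    categories <- trimmed
  }
  n <- length(gene_set)
  if (n > N) stop("gene set larger than the reference")

  cname <- attr(categories, "category_name") %||%
    stats::setNames(names(categories), names(categories))
  C <- lengths(lapply(categories, unique))
  O <- vapply(categories, function(g) length(intersect(unique(g), gene_set)),
              integer(1))
  E <- C * n / N
  out <- data.frame(
    category_id = names(categories),
    category_name = unname(cname[names(categories)]),
    C = unname(C), O = unname(O), E = unname(E),
    R = unname(ifelse(E > 0, O / E, NA_real_)),
    rawP = unname(phyper(O - 1L, C, N - C, n, lower.tail = FALSE)),
    stringsAsFactors = FALSE
  )
  out$adjP <- p.adjust(out$rawP, method = "BH")
  out <- out[order(out$adjP, out$rawP), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate CNVRs with their gene and miRNA content
#'
#' Per CNVR, lists the overlapping gene and miRNA ids and carries the
#' specificity and status through, with a display label in the gain/loss
#' vocabulary (`GAIN`, `DEL`, `GAIN/DEL` for opposite-status regions).
#'
#' @param cnvrs a [cnvr_catalogue()] data.frame.
#' @param gene_track,mirna_track [interval_track()]s (either may be `NULL`).
#' @return `cnvrs` with added `genes` and `mirnas` columns (comma-joined
#'   labels, empty string when none) and `status_label`.
#' @export
report_gene_mirna_content <- function(cnvrs, gene_track = NULL,
                                      mirna_track = NULL) {
  join <- function(track) {
    if (is.null(track) || nrow(cnvrs) == 0L) return(character(nrow(cnvrs)))
    ov <- overlap_track(cnvrs, track)
    hits <- split(ov$label, factor(ov$name, levels = cnvrs$name))
    vapply(hits, function(x) paste(unique(x), collapse = ","), "")
  }
  cnvrs$genes <- unname(join(gene_track))
  cnvrs$mirnas <- unname(join(mirna_track))
  cnvrs$status_label <- c(loss = "DEL", gain = "GAIN",
                          both = "GAIN/DEL")[cnvrs$status]
  cnvrs
}
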