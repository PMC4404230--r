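#' Write a cohort to plain-text files
#'
#' Writes `lrr.tsv` (wide matrix: `sample_id` column then one column per
#' marker), `map.tsv` (`marker_id`, `chromosome`, `position`, `gc`),
#' `samples.tsv`, and — when ground truth is present — `truth.bed`
#' (0-based half-open BED, `name` = `copy_state;carrier1,carrier2,...`).
#' Numeric values are written at full precision so the round trip through
#' [read_cohort()] is exact to >= 6 significant digits.
#'
#' @param cohort a `cnv_cohort` (see [simulate_cohort()]).
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cnv_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)

  lrr_df <- data.frame(sample_id = rownames(cohort$lrr),
                       cohort$lrr, check.names = FALSE,
                       stringsAsFactors = FALSE)
  write.table(lrr_df, file.path(dir, "lrr.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(cohort$map), file.path(dir, "map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$samples, file.path(dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$truth) && nrow(cohort$truth) > 0L) {
    bed <- data.frame(
      chrom = cohort$truth$chromosome,
      start = cohort$truth$start_bp - 1L,  # BED is 0-based half-open
      end = cohort$truth$end_bp,
      name = paste0(cohort$truth$copy_state, ";",
                    vapply(cohort$truth$carriers, paste, "", collapse = ","))
    )
    write.table(bed, file.path(dir, "truth.bed"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' Read a log R ratio matrix
#'
#' Accepts either the wide format written by [write_cohort()] (first column
#' `sample_id`, one column per marker) or a GenomeStudio-final-report-like
#' long format with columns `Sample ID`, `SNP Name`, `Log R Ratio` (matched
#' case- and punctuation-insensitively).
#'
#' @param path TSV file.
#' @return numeric matrix, samples in rows, markers in columns.
#' @export
read_lrr <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  norm <- tolower(gsub("[^a-z]", "", tolower(names(df))))
  long_cols <- match(c("sampleid", "snpname", "logrratio"), norm)
  if (!anyNA(long_cols)) {
    samples <- unique(df[[long_cols[1]]])
    markers <- unique(df[[long_cols[2]]])
    lrr <- matrix(NA_real_, length(samples), length(markers),
                  dimnames = list(samples, markers))
    lrr[cbind(match(df[[long_cols[1]]], samples),
              match(df[[long_cols[2]]], markers))] <- df[[long_cols[3]]]
    return(lrr)
  }
  if (names(df)[1] != "sample_id") {
    stop("malformed LRR header: expected 'sample_id' or GenomeStudio long format")
  }
  lrr <- as.matrix(df[, -1, drop = FALSE])
  rownames(lrr) <- df$sample_id
  lrr
}

#' Read a cohort written by [write_cohort()]
#'
#' Markers that arrive out of genome order are re-sorted by
#' (chromosome, position) with a warning; the LRR columns are permuted to
#' match. Errors on marker/sample mismatches between the files.
#'
#' @param dir directory containing `lrr.tsv`, `map.tsv`, `samples.tsv` and
#'   optionally `truth.bed`.
#' @return a `cnv_cohort` list.
#' @export
read_cohort <- function(dir) {
  map_df <- read.delim(file.path(dir, "map.tsv"), stringsAsFactors = FALSE)
  ord <- order(chrom_rank(map_df$chromosome), map_df$position)
  if (!identical(ord, seq_len(nrow(map_df)))) {
    warning("marker map not in genome order; re-sorting by (chromosome, position)")
  }
  map <- marker_map(map_df$marker_id, map_df$chromosome,
                    map_df$position, map_df$gc)

  lrr <- read_lrr(file.path(dir, "lrr.tsv"))
  if (!setequal(colnames(lrr), map$marker_id)) {
    stop("marker mismatch between lrr.tsv and map.tsv")
  }
  lrr <- lrr[, map$marker_id, drop = FALSE]

  samples <- read.delim(file.path(dir, "samples.tsv"), stringsAsFactors = FALSE)
  if (!setequal(samples$sample_id, rownames(lrr))) {
    stop("sample mismatch between lrr.tsv and samples.tsv")
  }
  lrr <- lrr[samples$sample_id, , drop = FALSE]

  truth <- NULL
  bed_path <- file.path(dir, "truth.bed")
  if (file.exists(bed_path)) {
    bed <- read.delim(bed_path, header = FALSE, stringsAsFactors = FALSE)
    parts <- strsplit(bed$V4, ";", fixed = TRUE)
    truth <- truth_cnv(
      chromosome = bed$V1,
      start_bp = bed$V2 + 1L,  # back to 1-based inclusive
      end_bp = bed$V3,
      copy_state = vapply(parts, `[`, "", 1L),
      design_role = rep("shared", nrow(bed)),
      carriers = lapply(parts, function(p) strsplit(p[2], ",", fixed = TRUE)[[1]])
    )
    truth$design_role <- NA_character_  # role is not encoded in BED
  }

  structure(list(lrr = lrr, samples = samples, map = map, truth = truth),
            class = "cnv_cohort")
}

#' Read a BED-like interval track (QTL, gene or miRNA annotations)
#'
#' Expects a TSV with columns `chromosome`, `start_bp`, `end_bp`, `id`,
#' `label` (PigQTLdb-export style; `label` holds the trait name, gene symbol
#' or miRNA name).
#'
#' @param path TSV file with header.
#' @param kind one of `"qtl"`, `"gene"`, `"mirna"`.
#' @return data.frame of class `interval_track`.
#' @export
read_track <- function(path, kind = c("qtl", "gene", "mirna")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  interval_track(df, kind = match.arg(kind))
}

#' Validate an interval track
#'
#' @param df data.frame with `chromosome`, `start_bp`, `end_bp`, `id`,
#'   `label` columns.
#' @param kind track kind.
#' @return `df` with class `interval_track` and a `kind` attribute.
#' @export
interval_track <- function(df, kind = c("qtl", "gene", "mirna")) {
  kind <- match.arg(kind)
  need <- c("chromosome", "start_bp", "end_bp", "id", "label")
  if (!all(need %in% names(df))) {
    stop("track must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$start_bp > df$end_bp)) stop("track has start_bp > end_bp")
  if (anyDuplicated(df$id)) stop("track ids must be unique")
  attr(df, "kind") <- kind
  class(df) <- unique(c("interval_track", class(df)))
  df
}

#' Read a GMT-like category table
#'
#' One category per line: `category_id<TAB>category_name<TAB>gene1<TAB>...`.
#'
#' @param path GMT file.
#' @return named list of gene-id vectors; category names are kept in the
#'   `category_name` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  cats <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(cats) <- vapply(parts, `[`, "", 1L)
  attr(cats, "category_name") <- stats::setNames(
    vapply(parts, `[`, "", 2L), names(cats))
  cats
}
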