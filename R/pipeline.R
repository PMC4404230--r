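#' Run the end-to-end CNV discovery pipeline
#'
#' Orchestrates the whole analysis from one seeded configuration:
#' sex-chromosome exclusion, sample QC, the univariate path (per-sample
#' segment, prune, call), the multivariate path (per batch cluster, per
#' phenotype group, with pooled-run exclusion), merging of all calls into
#' the final CNVR catalogue with specificity labels, summary statistics,
#' optional track annotation, and optional validation against an
#' independent cohort. Identical configuration and seed reproduce every
#' output byte for byte.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognized entries:
#'   \describe{
#'     \item{cohort}{a `cnv_cohort` object, or a directory for
#'       [read_cohort()]. When absent, a cohort is simulated from
#'       `simulate` (a list of [simulate_cohort()] arguments; a
#'       [simulate_marker_map()] map is built from `simulate$map_args`
#'       unless `simulate$map` is given).}
#'     \item{validation}{optional: a `cnv_cohort` or directory for the
#'       independent validation cohort, or a list of [simulate_cohort()]
#'       arguments under `validation$simulate`.}
#'     \item{params}{list of [segmentation_params()] arguments.}
#'     \item{genome_length_bp}{genome size for [summarize_cnvrs()]
#'       (default 2.8e9).}
#'     \item{qtl_track, gene_track, mirna_track}{optional
#'       [interval_track()]s or TSV paths for [read_track()].}
#'     \item{seed}{master seed for every source of randomness.}
#'     \item{out_dir}{optional output directory; when set, the CNVR table
#'       and BED, QC report, call tables, validation report and a JSON
#'       manifest are written there. On any stage failure partial outputs
#'       are removed.}
#'   }
#' @return list of class `cnv_discovery`: `cohort`, `qc`, `calls_univariate`,
#'   `calls_multivariate`, `catalogue`, `summary`, `annotation` (or `NULL`),
#'   `validation` (or `NULL`), `manifest`.
#' @export
run_discovery <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir
  written <- character(0)
  stage_name <- "configuration"
  on_fail <- function(e) {
    if (length(written)) unlink(written)
    stop("stage '", stage_name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  withCallingHandlers(
    expr = {
      stage_name <- "load_cohort"
      cohort <- .resolve_cohort(config$cohort, config$simulate, seed)

      stage_name <- "exclude_sex_chromosomes"
      aut <- exclude_sex_chromosomes(cohort$lrr, cohort$map)

      stage_name <- "qc"
      qc <- qc_report(aut$lrr, aut$map, batch = cohort$samples$batch)

      stage_name <- "segmentation_params"
      params <- do.call(segmentation_params, config$params %||% list())

      # mean-threshold calling is not shift-invariant, so per-sample
      # additive offsets (batch effects) are removed by median centering
      # before segmentation; QC above sees the raw signal
      stage_name <- "center_samples"
      if (config[["center_samples"]] %||% TRUE) {
        aut$lrr <- aut$lrr - apply(aut$lrr, 1L, stats::median)
      }

      stage_name <- "univariate_segmentation"
      uni <- univariate_calls(aut$lrr, aut$map, params)
      grp <- .group_of(cohort$samples)
      uni$group <- unname(grp[uni$sample_id])

      stage_name <- "multivariate_segmentation"
      multi <- .multivariate_by_batch(aut$lrr, aut$map, cohort$samples,
                                      grp, params)

      stage_name <- "cnvr_catalogue"
      all_calls <- .stack_calls(uni, multi)
      catalogue <- cnvr_catalogue(all_calls)

      stage_name <- "summary"
      summary <- summarize_cnvrs(catalogue, config$genome_length_bp %||% 2.8e9)

      stage_name <- "annotation"
      annotation <- .run_annotation(catalogue, config)

      stage_name <- "validation"
      validation <- NULL
      if (!is.null(config$validation)) {
        vc <- .resolve_cohort(config$validation,
                              config$validation$simulate, seed + 1L)
        vaut <- exclude_sex_chromosomes(vc$lrr, vc$map)
        vgrp <- .group_of(vc$samples)
        validation <- validate_cohort(
          vaut$lrr, vaut$map,
          groups = list(high = vc$samples$sample_id[vgrp[vc$samples$sample_id] == "high"],
                        low = vc$samples$sample_id[vgrp[vc$samples$sample_id] == "low"]),
          cnvrs = catalogue, params = params
        )
      }

      stage_name <- "write_outputs"
      manifest <- list(
        package = "extremecnv",
        version = as.character(utils::packageVersion("extremecnv")),
        seed = seed,
        params = unclass(params),
        genome_length_bp = config$genome_length_bp %||% 2.8e9,
        counts = list(
          samples = nrow(cohort$samples),
          markers = nrow(aut$map),
          calls_univariate = nrow(uni),
          calls_multivariate = nrow(multi),
          cnvrs = nrow(catalogue),
          by_specificity = as.list(summary$by_specificity)
        )
      )
      if (!is.null(out_dir)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        wt <- function(x, name) {
          path <- file.path(out_dir, name)
          write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
          written <<- c(written, path)
          path
        }
        wt(qc$samples, "qc_report.tsv")
        wt(uni, "calls_univariate.tsv")
        wt(multi, "calls_multivariate.tsv")
        wt(catalogue, "cnvr.tsv")
        bed_path <- file.path(out_dir, "cnvr.bed")
        write_cnvrs(catalogue, bed = bed_path)
        written <- c(written, bed_path)
        if (!is.null(validation)) wt(validation, "validation.tsv")
        if (!is.null(annotation)) wt(annotation$cnvrs, "annotation.tsv")
        manifest_path <- file.path(out_dir, "manifest.json")
        jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                             pretty = TRUE, digits = NA)
        written <- c(written, manifest_path)
      }

      structure(list(
        cohort = cohort, qc = qc,
        calls_univariate = uni, calls_multivariate = multi,
        catalogue = catalogue, summary = summary,
        annotation = annotation, validation = validation,
        manifest = manifest
      ), class = "cnv_discovery")
    },
    error = on_fail
  )
}

# map arbitrary group labels onto high/low (validation_high -> high etc.)
.group_of <- function(samples) {
  g <- tolower(samples$group)
  out <- ifelse(grepl("high", g), "high", ifelse(grepl("low", g), "low", g))
  stats::setNames(out, samples$sample_id)
}

.resolve_cohort <- function(cohort, simulate_args, seed) {
  if (inherits(cohort, "cnv_cohort")) return(cohort)
  if (is.character(cohort) && length(cohort) == 1L && dir.exists(cohort)) {
    return(read_cohort(cohort))
  }
  if (is.list(cohort) && !is.null(cohort[["simulate"]])) {
    simulate_args <- cohort[["simulate"]]
  }
  if (is.null(simulate_args)) stop("no cohort given and nothing to simulate")
  args <- simulate_args
  args$seed <- args[["seed"]] %||% seed
  if (is.null(args[["map"]])) {
    set.seed(as.integer(args$seed))  # map GC draws must reproduce too
    args$map <- do.call(simulate_marker_map, args[["map_args"]] %||% list())
  }
  args[["map_args"]] <- NULL
  if (!is.null(args[["design"]]) && !inherits(args[["design"]], "truth_cnv")) {
    args$design <- do.call(truth_cnv, args[["design"]])
  }
  do.call(simulate_cohort, args)
}

# multivariate path: the batch clusters found by PCA are segmented
# separately so batch shifts cannot masquerade as common segments
.multivariate_by_batch <- function(lrr, map, samples, grp, params) {
  out <- list()
  for (b in unique(samples$batch)) {
    ids <- samples$sample_id[samples$batch == b]
    groups <- list(high = ids[grp[ids] == "high"],
                   low = ids[grp[ids] == "low"])
    if (length(groups$high) == 0L || length(groups$low) == 0L) next
    calls <- group_specific_multivariate(lrr[ids, , drop = FALSE], groups,
                                         map, params)
    if (nrow(calls) > 0L) {
      calls$batch <- b
      out[[length(out) + 1L]] <- calls
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chromosome = character(), start_bp = integer(),
                      end_bp = integer(), n_markers = integer(),
                      mean_lrr = numeric(), status = character(),
                      sample_ids = character(), group = character(),
                      batch = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# concatenate univariate and multivariate calls on the shared columns
.stack_calls <- function(uni, multi) {
  cols <- c("chromosome", "start_bp", "end_bp", "n_markers", "mean_lrr",
            "status", "group", "sample_ids")
  u <- uni
  if (nrow(u) > 0L) u$sample_ids <- u$sample_id
  u <- u[, intersect(cols, names(u)), drop = FALSE]
  m <- multi[, intersect(cols, names(multi)), drop = FALSE]
  out <- rbind(u[, cols[cols %in% names(u)], drop = FALSE],
               m[, cols[cols %in% names(m)], drop = FALSE])
  rownames(out) <- NULL
  out
}

.run_annotation <- function(catalogue, config) {
  get_track <- function(x, kind) {
    if (is.null(x)) return(NULL)
    if (is.character(x)) read_track(x, kind) else interval_track(x, kind)
  }
  qtl <- get_track(config$qtl_track, "qtl")
  genes <- get_track(config$gene_track, "gene")
  mirna <- get_track(config$mirna_track, "mirna")
  if (is.null(qtl) && is.null(genes) && is.null(mirna)) return(NULL)
  list(
    cnvrs = report_gene_mirna_content(catalogue, genes, mirna),
    qtl_overlap = if (!is.null(qtl)) overlap_track(catalogue, qtl),
    qtl_enrichment = if (!is.null(qtl)) qtl_enrichment(catalogue, qtl)
  )
}

#' @export
print.cnv_discovery <- function(x, ...) {
  cat("CNV discovery run (seed ", x$manifest$seed, ")\n", sep = "")
  print(x$summary)
  invisible(x)
}
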