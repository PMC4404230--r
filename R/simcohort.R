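#' Construct and validate a marker map
#'
#' A marker map describes the genomic context of every array probe: its
#' identifier, chromosome, 1-based bp position and the GC fraction of a fixed
#' window around it (used by the genomic-wave model). Markers are sorted by
#' (chromosome, position); positions must be unique within a chromosome and
#' GC fractions must lie in \[0, 1\].
#'
#' @param marker_id character vector of unique probe identifiers.
#' @param chromosome chromosome label per marker (autosome names; X/Y are
#'   allowed but flagged downstream).
#' @param position integer bp position (1-based).
#' @param gc GC fraction in \[0, 1\].
#' @return A `data.frame` of class `marker_map` with columns
#'   `marker_id`, `chromosome`, `position`, `gc`, sorted by genome order.
#' @export
marker_map <- function(marker_id, chromosome, position, gc) {
  if (anyDuplicated(marker_id)) stop("marker ids must be unique")
  if (any(!is.finite(gc)) || any(gc < 0 | gc > 1)) {
    stop("gc must be a fraction in [0, 1]")
  }
  map <- data.frame(
    marker_id = as.character(marker_id),
    chromosome = as.character(chromosome),
    position = as.integer(position),
    gc = as.numeric(gc),
    stringsAsFactors = FALSE
  )
  ord <- order(chrom_rank(map$chromosome), map$position)
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  dup <- stats::ave(map$position, map$chromosome, FUN = anyDuplicated)
  if (any(dup > 0)) stop("positions must be unique within a chromosome")
  class(map) <- c("marker_map", "data.frame")
  map
}

#' Simulate a regularly spaced marker map
#'
#' Generates `n_per_chrom` markers on each requested chromosome at a fixed
#' spacing, with per-marker GC fractions drawn from a Beta distribution
#' centred near the genome-typical 0.41.
#'
#' @param chromosomes chromosome labels (default `"1"`..`"18"`, the porcine
#'   autosomes).
#' @param n_per_chrom markers per chromosome.
#' @param spacing_bp distance between adjacent markers in bp.
#' @param gc_shape1,gc_shape2 Beta parameters of the GC distribution.
#' @return A [marker_map()].
#' @export
simulate_marker_map <- function(chromosomes = as.character(1:18),
                                n_per_chrom = 200L,
                                spacing_bp = 50000L,
                                gc_shape1 = 12, gc_shape2 = 17) {
  n <- length(chromosomes) * n_per_chrom
  marker_map(
    marker_id = sprintf("SNP%05d", seq_len(n)),
    chromosome = rep(chromosomes, each = n_per_chrom),
    position = rep(seq_len(n_per_chrom) * spacing_bp, length(chromosomes)),
    gc = rbeta(n, gc_shape1, gc_shape2)
  )
}

#' Select the extreme tails of a phenotype distribution
#'
#' Implements the extreme-group / selective-genotyping sampling rule: from a
#' vector of phenotype values (here, direct boar effect on litter size, DBE)
#' it returns the indices of the lowest and highest `floor(n * tail_fraction)`
#' values. Ties are broken by original index order (stable sort), so the
#' result is deterministic.
#'
#' @param values finite numeric phenotype values.
#' @param tail_fraction fraction of each tail to select, in (0, 0.5).
#' @return list with integer index vectors `low` and `high` (disjoint).
#' @examples
#' select_extremes(c(5, 1, 9, 3, 7, 2, 8, 4, 6, 10), tail_fraction = 0.2)
#' @export
select_extremes <- function(values, tail_fraction = 0.1) {
  if (length(values) == 0L) stop("empty phenotype vector")
  if (any(!is.finite(values))) stop("phenotype values must be finite")
  if (!is.numeric(tail_fraction) || tail_fraction <= 0 || tail_fraction >= 0.5) {
    stop("tail_fraction must be in (0, 0.5)")
  }
  k <- floor(length(values) * tail_fraction)
  ord <- order(values)  # stable: ties keep original index order
  list(low = sort(head(ord, k)), high = sort(tail(ord, k)))
}

#' Define a set of ground-truth CNVs for simulation
#'
#' @param chromosome,start_bp,end_bp event interval (1-based inclusive).
#' @param copy_state `"loss"` or `"gain"`.
#' @param design_role one of `"group_specific_high"`, `"group_specific_low"`,
#'   `"shared"`, `"private"`; determines which samples carry the event when
#'   `carriers` is not given explicitly.
#' @param carriers optional list of character vectors of carrier sample ids
#'   (filled in by [simulate_cohort()] from `design_role` when `NA`).
#' @return data.frame of class `truth_cnv`.
#' @export
truth_cnv <- function(chromosome, start_bp, end_bp, copy_state, design_role,
                      carriers = NULL) {
  stopifnot(all(start_bp <= end_bp))
  if (!all(copy_state %in% c("loss", "gain"))) stop("copy_state must be loss/gain")
  roles <- c("group_specific_high", "group_specific_low", "shared", "private")
  if (!all(design_role %in% roles)) {
    stop("design_role must be one of: ", paste(roles, collapse = ", "))
  }
  df <- data.frame(
    chromosome = as.character(chromosome),
    start_bp = as.integer(start_bp),
    end_bp = as.integer(end_bp),
    copy_state = copy_state,
    design_role = design_role,
    stringsAsFactors = FALSE
  )
  df$carriers <- carriers %||% replicate(nrow(df), NA_character_, simplify = FALSE)
  class(df) <- c("truth_cnv", "data.frame")
  df
}

#' Study-scale ground-truth design: 14 high- and 19 low-specific regions
#'
#' A designed set of implanted group-specific CNVs at the scale of the
#' targeted study: 33 regions (14 carried by every high-group sample, 19 by
#' every low-group sample, losses outnumbering gains roughly 4:1) spread
#' over 17 autosomes, each spanning `implant_markers` consecutive markers.
#' Intended for the map produced by
#' `simulate_marker_map(chromosomes = as.character(1:17), n_per_chrom, spacing_bp)`
#' with `n_per_chrom >= 110 + implant_markers`.
#'
#' @param spacing_bp marker spacing of the target map.
#' @param implant_markers markers per implanted region.
#' @return a [truth_cnv()] design.
#' @export
study_design <- function(spacing_bp = 50000L, implant_markers = 12L) {
  # two well-separated slots per chromosome, first 17 used for high-specific,
  # next 19 for low-specific
  slots <- data.frame(
    chromosome = rep(as.character(1:17), 2L),
    first_marker = rep(c(30L, 95L), each = 17L)
  )[seq_len(33L), ]
  role <- rep(c("group_specific_high", "group_specific_low"), c(14L, 19L))
  state <- c(rep(c("loss", "gain"), c(11L, 3L)),   # high: 11 losses, 3 gains
             rep(c("loss", "gain"), c(15L, 4L)))   # low: 15 losses, 4 gains
  truth_cnv(
    chromosome = slots$chromosome,
    start_bp = slots$first_marker * spacing_bp,
    end_bp = (slots$first_marker + implant_markers - 1L) * spacing_bp,
    copy_state = state,
    design_role = role
  )
}

#' Simulate an extreme-group SNP-array cohort with known ground truth
#'
#' Generates per-sample log R ratio (LRR) vectors over a marker map under an
#' additive signal model: at marker m of sample s in batch b,
#' \deqn{LRR_{s,m} = \delta_{s,m} + w_b (gc_m - \bar{gc}) + \beta_b +
#'   \epsilon_{s,m},\quad \epsilon \sim N(0, \sigma^2)}
#' where \eqn{\delta} is the copy-state shift (`loss_shift` / `gain_shift`
#' inside a truth CNV carried by s, else 0), \eqn{w_b} a per-batch
#' GC-wave slope, and \eqn{\beta_b} a per-batch additive intensity shift.
#'
#' Defaults emulate the study design this package targets: 11 high- and 10
#' low-fertility boars drawn from the opposite 10% tails of the DBE (direct
#' boar effect on litter size) distribution, with group DBE means/SDs of
#' 2.83 +/- 0.61 and -2.72 +/- 0.79 piglets, genotyped in two batches.
#' One-copy shifts default to -0.45 (loss) and +0.30 (gain), both beyond the
#' -0.15/+0.1 calling thresholds.
#'
#' @param map a [marker_map()].
#' @param design a [truth_cnv()] data.frame, or `NULL` for no events.
#' @param n_high,n_low group sizes.
#' @param noise_sd marker-level Gaussian noise SD (LRR units).
#' @param wave_slope named numeric, GC-wave slope per batch.
#' @param batch_shift named numeric, additive LRR shift per batch; its names
#'   define the batch labels, samples are assigned round-robin within group.
#' @param loss_shift,gain_shift LRR shift of implanted losses/gains; must
#'   satisfy `loss_shift < -0.15` and `gain_shift > 0.1` so implants are
#'   callable under the default thresholds.
#' @param dbe_mean,dbe_sd named numeric (`high`, `low`): phenotype model per
#'   group.
#' @param group_labels length-2 character: labels stored for the high and low
#'   group (use `c("validation_high", "validation_low")` for a validation
#'   cohort).
#' @param breeds breed labels sampled uniformly per animal.
#' @param seed integer seed; identical seeds give bitwise-identical cohorts.
#' @return list of class `cnv_cohort`: `lrr` (sample x marker matrix),
#'   `samples` (sample table), `map`, `truth` (carriers filled in).
#' @export
simulate_cohort <- function(map,
                            design = NULL,
                            n_high = 11L, n_low = 10L,
                            noise_sd = 0.10,
                            wave_slope = c(B1 = 0.02, B2 = 0.02),
                            batch_shift = c(B1 = 0, B2 = 0.05),
                            loss_shift = -0.45, gain_shift = 0.30,
                            dbe_mean = c(high = 2.83, low = -2.72),
                            dbe_sd = c(high = 0.61, low = 0.79),
                            group_labels = c("high", "low"),
                            breeds = c("Yorkshire", "Landrace", "Duroc"),
                            seed = 1L) {
  stopifnot(inherits(map, "marker_map"))
  if (!(loss_shift < -0.15 && gain_shift > 0.1)) {
    stop("shifts must satisfy loss_shift < -0.15 and gain_shift > 0.1")
  }
  if (is.null(names(batch_shift)) || is.null(names(wave_slope)) ||
      !identical(sort(names(batch_shift)), sort(names(wave_slope)))) {
    stop("batch_shift and wave_slope must share batch names")
  }
  set.seed(as.integer(seed))

  batches <- names(batch_shift)
  n <- n_high + n_low
  ids <- c(sprintf("H%02d", seq_len(n_high)), sprintf("L%02d", seq_len(n_low)))
  samples <- data.frame(
    sample_id = ids,
    dbe = c(rnorm(n_high, dbe_mean[["high"]], dbe_sd[["high"]]),
            rnorm(n_low, dbe_mean[["low"]], dbe_sd[["low"]])),
    group = rep(group_labels, c(n_high, n_low)),
    breed = sample(breeds, n, replace = TRUE),
    batch = c(rep_len(batches, n_high), rep_len(batches, n_low)),
    stringsAsFactors = FALSE
  )

  m <- nrow(map)
  gc_c <- map$gc - mean(map$gc)
  lrr <- matrix(rnorm(n * m, 0, noise_sd), nrow = n, ncol = m,
                dimnames = list(ids, map$marker_id))
  for (s in seq_len(n)) {
    b <- samples$batch[s]
    lrr[s, ] <- lrr[s, ] + wave_slope[[b]] * gc_c + batch_shift[[b]]
  }

  truth <- design
  if (!is.null(truth) && nrow(truth) > 0L) {
    stopifnot(inherits(truth, "truth_cnv"))
    high_ids <- ids[seq_len(n_high)]
    low_ids <- ids[n_high + seq_len(n_low)]
    for (i in seq_len(nrow(truth))) {
      idx <- which(map$chromosome == truth$chromosome[i] &
                   map$position >= truth$start_bp[i] &
                   map$position <= truth$end_bp[i])
      if (length(idx) == 0L) {
        stop("truth CNV ", i, " covers zero markers")
      }
      carriers <- truth$carriers[[i]]
      if (length(carriers) == 1L && is.na(carriers)) {
        carriers <- switch(truth$design_role[i],
          group_specific_high = high_ids,
          group_specific_low = low_ids,
          shared = ids,
          private = sample(ids, 1L)
        )
        truth$carriers[[i]] <- carriers
      }
      if (!all(carriers %in% ids)) {
        stop("unknown carrier id in truth CNV ", i)
      }
      shift <- if (truth$copy_state[i] == "loss") loss_shift else gain_shift
      lrr[carriers, idx] <- lrr[carriers, idx] + shift
    }
  }

  structure(
    list(lrr = lrr, samples = samples, map = map, truth = truth),
    class = "cnv_cohort"
  )
}

#' @export
print.cnv_cohort <- function(x, ...) {
  cat(sprintf(
    "cnv_cohort: %d samples x %d markers on %d chromosomes; %d truth CNVs\n",
    nrow(x$lrr), ncol(x$lrr), length(unique(x$map$chromosome)),
    if (is.null(x$truth)) 0L else nrow(x$truth)
  ))
  invisible(x)
}
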