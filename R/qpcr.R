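#' Amplification efficiency from a qPCR curve
#'
#' Per-well efficiency estimation in the window-of-linearity style: the
#' baseline (mean fluorescence of the first `baseline_cycles` cycles) is
#' subtracted, then log10(fluorescence) is regressed on cycle over every
#' sliding window of 4-6 cycles with all-positive signal, and the window
#' with the highest R-squared is taken as the exponential phase. The
#' efficiency is the per-cycle fold change, `10^slope` (2.0 for perfect
#' doubling). When no window reaches `min_r2` the curve has no detectable
#' exponential phase and a `qpcr_not_estimable` error is signalled.
#'
#' @param fluorescence numeric fluorescence series, one value per cycle.
#' @param cycles cycle numbers (defaults to 1..length).
#' @param window_widths candidate window widths in cycles.
#' @param baseline_cycles number of leading cycles averaged as baseline.
#' @param min_r2 minimum R-squared for an acceptable window.
#' @return efficiency (fold change per cycle), with attributes `window`
#'   (cycle indices used) and `r_squared`.
#' @export
qpcr_efficiency <- function(fluorescence, cycles = seq_along(fluorescence),
                            window_widths = 4:6, baseline_cycles = 3L,
                            min_r2 = 0.99) {
  stopifnot(length(fluorescence) == length(cycles))
  if (length(fluorescence) < 10L) stop("curve must have at least 10 cycles")
  if (any(!is.finite(fluorescence))) stop("fluorescence must be finite")
  y <- fluorescence - mean(fluorescence[seq_len(baseline_cycles)])

  best <- list(r2 = -Inf)
  n <- length(y)
  for (w in window_widths) {
    for (i in seq_len(n - w + 1L)) {
      idx <- i:(i + w - 1L)
      yy <- y[idx]
      if (any(yy <= 0)) next
      ly <- log10(yy)
      cc <- cycles[idx]
      fit_slope <- cov(cc, ly) / var(cc)
      res <- ly - mean(ly) - fit_slope * (cc - mean(cc))
      tss <- sum((ly - mean(ly))^2)
      r2 <- if (tss > 0) 1 - sum(res^2) / tss else 0
      if (r2 > best$r2) best <- list(r2 = r2, slope = fit_slope, idx = idx)
    }
  }
  if (!is.finite(best$r2) || best$r2 < min_r2) {
    stop2("no amplification window with sufficient linearity: efficiency not estimable",
          "qpcr_not_estimable")
  }
  eff <- 10^best$slope
  if (eff <= 1 || eff > 2.2) {
    warning(sprintf("efficiency %.3f outside the plausible (1, 2.2] range", eff))
  }
  structure(eff, window = best$idx, r_squared = best$r2)
}

#' Per-locus efficiencies from a table of amplification curves
#'
#' Computes one efficiency per well with [qpcr_efficiency()] and averages
#' within locus (wells whose curves are not estimable are dropped with a
#' warning).
#'
#' @param curves long-format data.frame with columns `well`, `sample`,
#'   `locus`, `cycle`, `fluorescence`.
#' @param ... passed to [qpcr_efficiency()].
#' @return data.frame: `locus`, `efficiency` (mean over wells), `n_wells`.
#' @export
locus_efficiencies <- function(curves, ...) {
  need <- c("well", "sample", "locus", "cycle", "fluorescence")
  if (!all(need %in% names(curves))) {
    stop("curves must have columns: ", paste(need, collapse = ", "))
  }
  by_well <- split(curves, curves$well)
  eff <- lapply(by_well, function(cw) {
    cw <- cw[order(cw$cycle), ]
    e <- tryCatch(as.numeric(qpcr_efficiency(cw$fluorescence, cw$cycle, ...)),
                  qpcr_not_estimable = function(e) NA_real_)
    data.frame(locus = cw$locus[1L], efficiency = e, stringsAsFactors = FALSE)
  })
  eff <- do.call(rbind, eff)
  if (anyNA(eff$efficiency)) {
    warning(sum(is.na(eff$efficiency)), " well(s) not estimable, dropped")
    eff <- eff[!is.na(eff$efficiency), , drop = FALSE]
  }
  out <- aggregate(efficiency ~ locus, data = eff, FUN = mean)
  out$n_wells <- as.integer(table(eff$locus)[out$locus])
  out
}

#' Aggregate triplicate Ct values
#'
#' Mean and SD of replicate Ct measurements per (sample, locus); wells are
#' flagged when the replicate SD exceeds `sd_flag` cycles.
#'
#' @param measurements data.frame with `sample_id`, `locus`, `ct`.
#' @param sd_flag replicate-SD threshold in cycles.
#' @return data.frame: `sample_id`, `locus`, `ct` (mean), `ct_sd`,
#'   `n_replicates`, `flagged`.
#' @export
aggregate_ct <- function(measurements, sd_flag = 0.5) {
  agg <- aggregate(ct ~ sample_id + locus, data = measurements,
                   FUN = function(x) c(mean = mean(x), sd = sd(x), n = length(x)))
  out <- data.frame(sample_id = agg$sample_id, locus = agg$locus,
                    ct = agg$ct[, "mean"], ct_sd = agg$ct[, "sd"],
                    n_replicates = as.integer(agg$ct[, "n"]),
                    stringsAsFactors = FALSE)
  out$flagged <- !is.na(out$ct_sd) & out$ct_sd > sd_flag
  out
}

#' Efficiency-corrected relative quantification (Pfaffl ratio)
#'
#' \deqn{ratio = E_{target}^{\Delta Ct_{target}} / E_{ref}^{\Delta Ct_{ref}}}
#' with \eqn{\Delta Ct = Ct(control) - Ct(sample)} for each locus. With both
#' efficiencies equal to 2 this reduces to the familiar
#' \eqn{2^{\Delta Ct_{target} - \Delta Ct_{ref}}} (delta-delta-Ct) identity.
#' A two-copy (normal) locus gives ratio ~ 1; a heterozygous deletion ~ 0.5;
#' a one-copy gain ~ 1.5.
#'
#' @param e_target,e_ref amplification efficiencies (> 1; warned when
#'   outside (1, 2.2]).
#' @param dct_target,dct_ref Ct(control) - Ct(sample) for the target and
#'   reference locus.
#' @return relative quantity (vectorized).
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  if (any(e_target <= 0) || any(e_ref <= 0)) {
    stop("efficiencies must be positive")
  }
  if (any(e_target <= 1 | e_target > 2.2) || any(e_ref <= 1 | e_ref > 2.2)) {
    warning("efficiency outside the plausible (1, 2.2] range")
  }
  e_target^dct_target / e_ref^dct_ref
}

#' Classify a qPCR relative quantity as loss/normal/gain
#'
#' Bounds default midway between the expected two-copy ratio (1.0) and the
#' one-copy (0.5) / three-copy (1.5) ratios.
#'
#' @param ratio positive relative quantity (vectorized).
#' @param lower,upper classification bounds.
#' @return character vector in `{"loss", "normal", "gain"}`.
#' @export
classify_qpcr <- function(ratio, lower = 0.75, upper = 1.25) {
  if (any(ratio <= 0)) stop("ratio must be positive")
  ifelse(ratio < lower, "loss", ifelse(ratio > upper, "gain", "normal"))
}

#' Expected Ct for a given copy number
#'
#' Utility for concordance harnesses: under efficiency `e`, a locus at
#' `copy` copies (2 = normal) amplifies from copy/2 times the control
#' template, shifting Ct by `-log(copy/2) / log(e)` relative to the control
#' Ct. Feeding the resulting Ct values through [pfaffl_ratio()] returns
#' exactly copy/2 for a perfectly efficient reference.
#'
#' @param copy copy number (2 = diploid normal).
#' @param e amplification efficiency.
#' @param ct_control control-sample Ct at two copies.
#' @return simulated Ct value(s).
#' @export
expected_ct <- function(copy, e, ct_control = 25) {
  stopifnot(all(copy > 0), all(e > 1))
  ct_control - log(copy / 2) / log(e)
}
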