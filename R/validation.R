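#' Percent signal reduction of an assay control
#'
#' Quantifies selectivity and immunodepletion effectivity: the control
#' (e.g. capture control, autofluorescence control, cross-reactivity
#' control, or an immunodepleted aliquot) is expressed as percent
#' remaining signal relative to the standard assay setup (or non-depleted
#' sample), and the signal reduction is its complement.
#'
#' @param reference `sample_readout` (or single numeric mean) of the
#'   reference setup; must be positive.
#' @param control `sample_readout` (or numeric) of the control setup.
#' @return A list of class `control_comparison`: `remaining_percent`,
#'   `signal_reduction_percent`, `reference_mean`, `control_mean`.
#' @examples
#' percent_signal_reduction(1000, 250)$signal_reduction_percent  # 75
#' @export
percent_signal_reduction <- function(reference, control) {
  ref <- if (inherits(reference, "sample_readout")) reference$mean
         else as.numeric(reference)
  ctl <- if (inherits(control, "sample_readout")) control$mean
         else as.numeric(control)
  if (!is.finite(ref) || ref <= 0)
    stop("reference mean must be positive for percent signal reduction",
         call. = FALSE)
  remaining <- 100 * ctl / ref
  structure(list(
    reference_mean = ref, control_mean = ctl,
    remaining_percent = remaining,
    signal_reduction_percent = 100 - remaining
  ), class = "control_comparison")
}

#' Dilution linearity of a blank-corrected dilution series
#'
#' Computes percent dilution linearity per point relative to the
#' least-diluted anchor: at dilution factor `f_i` with blank-corrected
#' readout `y_i`, linearity_i = 100 * (y_i * f_i / f_0) / y_0. A series
#' passes when every point (and the mean over the non-anchor points)
#' falls inside the inclusive tolerance band, 80-120% by default.
#'
#' @param dilution_factor strictly increasing numeric vector (the anchor
#'   is the first, least-diluted point).
#' @param readout blank-corrected readouts at each factor; the anchor
#'   readout must be positive.
#' @param tolerance length-2 numeric, inclusive percent bounds.
#' @return A list of class `dilution_series`: `table` (per-point
#'   linearity and pass flags), `mean_linearity`, `pass`.
#' @export
dilution_linearity <- function(dilution_factor, readout,
                               tolerance = c(80, 120)) {
  if (length(dilution_factor) < 2)
    stop_param("need >= 2 dilution points")
  if (length(dilution_factor) != length(readout))
    stop_param("factor/readout length mismatch")
  if (is.unsorted(dilution_factor, strictly = TRUE))
    stop_param("dilution factors must be strictly increasing")
  if (!is.finite(readout[1]) || readout[1] <= 0)
    stop("anchor readout must be positive: series invalid", call. = FALSE)
  lin <- 100 * (readout * dilution_factor / dilution_factor[1]) /
    readout[1]
  point_pass <- lin >= tolerance[1] & lin <= tolerance[2]
  mean_lin <- mean(lin[-1])
  structure(list(
    table = data.frame(dilution_factor = dilution_factor,
                       readout = readout,
                       linearity_percent = lin,
                       pass = point_pass),
    mean_linearity = mean_lin,
    tolerance = tolerance,
    pass = all(point_pass[-1]) &&
      mean_lin >= tolerance[1] && mean_lin <= tolerance[2]
  ), class = "dilution_series")
}

#' Percent spike recovery
#'
#' Recovery of a known spike from a complex matrix:
#' `100 * measured_net / nominal_spike`, where `measured_net` is the
#' spiked-sample reading minus the unspiked reading (any concentration
#' unit, used consistently). Negative net readings (over-subtraction)
#' are reported as-is with a flag.
#'
#' @param measured_net net measured spike (spiked minus unspiked).
#' @param nominal_spike nominal spiked amount (> 0).
#' @return Numeric percent recovery with attribute `over_subtracted`.
#' @examples
#' spike_recovery(37.0, 45)  # ~82.2%
#' @export
spike_recovery <- function(measured_net, nominal_spike) {
  if (nominal_spike <= 0) stop_param("nominal_spike must be > 0")
  rec <- 100 * measured_net / nominal_spike
  attr(rec, "over_subtracted") <- measured_net < 0
  rec
}

#' Stability check against a baseline
#'
#' Normalizes a stressed condition (freeze-thaw cycle, transport
#' temperature/time) to its baseline readout and applies the inclusive
#' +/- `tolerance`% acceptance band (75-125% by default).
#'
#' @param baseline `sample_readout` or numeric baseline mean (> 0).
#' @param condition `sample_readout` or numeric condition mean.
#' @param condition_label free-text condition description.
#' @param tolerance half-width of the acceptance band in percent
#'   (default 25).
#' @return A list of class `stability_result`: `condition`,
#'   `normalized_percent`, `within_tolerance`.
#' @export
stability_check <- function(baseline, condition,
                            condition_label = NA_character_,
                            tolerance = 25) {
  base <- if (inherits(baseline, "sample_readout")) baseline$mean
          else as.numeric(baseline)
  cond <- if (inherits(condition, "sample_readout")) condition$mean
          else as.numeric(condition)
  if (!is.finite(base) || base <= 0)
    stop("baseline mean must be positive", call. = FALSE)
  norm <- 100 * cond / base
  structure(list(
    condition = condition_label,
    normalized_percent = norm,
    tolerance = tolerance,
    within_tolerance = norm >= 100 - tolerance & norm <= 100 + tolerance
  ), class = "stability_result")
}

#' Inter-assay agreement of paired runs
#'
#' Spearman rank correlation between two independent measurements of the
#' same samples, with the acceptance gate rho > 0.9 for low inter-assay
#' variability. Ties are handled by midranks; the p-value is exact by
#' permutation for fewer than 10 pairs without ties and uses the
#' t-approximation otherwise (via [stats::cor.test()]).
#'
#' @param run1,run2 numeric readout vectors of equal length (>= 5 pairs).
#' @param rho_gate acceptance threshold on rho (default 0.9).
#' @return A list of class `agreement_result`: `spearman_rho`,
#'   `p_value`, `n`, `pass`.
#' @export
inter_assay_agreement <- function(run1, run2, rho_gate = 0.9) {
  keep <- is.finite(run1) & is.finite(run2)
  run1 <- run1[keep]; run2 <- run2[keep]
  if (length(run1) < 5) stop_param("need >= 5 paired samples")
  if (length(unique(run1)) < 2 || length(unique(run2)) < 2)
    stop("constant run: Spearman correlation undefined", call. = FALSE)
  ct <- suppressWarnings(cor.test(run1, run2, method = "spearman"))
  structure(list(
    spearman_rho = unname(ct$estimate),
    p_value = ct$p.value,
    n = length(run1),
    rho_gate = rho_gate,
    pass = unname(ct$estimate) > rho_gate
  ), class = "agreement_result")
}

#' Assemble a validation report table
#'
#' Collects heterogeneous validation results (control comparisons,
#' dilution series, stability checks, agreement results, spike
#' recoveries) into one metric-per-row pass/fail table suitable for CSV
#' export.
#'
#' @param ... named validation result objects.
#' @return A `data.frame` with columns `metric`, `value`, `pass`.
#' @export
validation_report <- function(...) {
  items <- list(...)
  rows <- lapply(names(items), function(nm) {
    x <- items[[nm]]
    if (inherits(x, "control_comparison"))
      data.frame(metric = nm, value = x$signal_reduction_percent,
                 pass = NA)
    else if (inherits(x, "dilution_series"))
      data.frame(metric = nm, value = x$mean_linearity, pass = x$pass)
    else if (inherits(x, "stability_result"))
      data.frame(metric = nm, value = x$normalized_percent,
                 pass = x$within_tolerance)
    else if (inherits(x, "agreement_result"))
      data.frame(metric = nm, value = x$spearman_rho, pass = x$pass)
    else data.frame(metric = nm, value = as.numeric(x), pass = NA)
  })
  do.call(rbind, rows)
}
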