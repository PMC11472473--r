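#' Select calibration points by blank comparison and linear range
#'
#' Applies the two inclusion rules for calibration standards: (i) the
#' standard's replicate pixel counts must significantly exceed the
#' blank-control replicates by a one-sided Mann-Whitney U test at
#' `alpha` (exact distribution when both groups have at most 8
#' replicates and no ties, normal approximation otherwise), and (ii) the
#' point must lie in the linear range. Linear range is assessed by
#' iterative trimming from the top: the highest remaining concentration
#' is dropped while its relative residual from a weighted refit on the
#' points below it exceeds `max_rel_residual`, capturing saturation
#' roll-off.
#'
#' @param standards list of `sample_readout` objects (or a data.frame
#'   with columns `nominal_concentration_fM` and `mean` plus a
#'   `replicates` list-column), sorted by increasing concentration.
#' @param concentrations nominal concentrations (fM) when `standards` is
#'   a list of readouts.
#' @param bc_replicates numeric vector of blank-control replicate pixel
#'   counts (>= 4).
#' @param alpha one-sided significance level (default 0.05).
#' @param max_rel_residual linear-range tolerance on the relative
#'   residual (default 0.20).
#' @return A `data.frame` of class `calibration_points` with one row per
#'   standard: `nominal_concentration_fM`, `mean_pixel_count`,
#'   `inclusion_pvalue`, `significant`, `in_linear_range`, `included`.
#' @export
select_calibration_points <- function(standards, concentrations = NULL,
                                      bc_replicates, alpha = 0.05,
                                      max_rel_residual = 0.20) {
  if (length(bc_replicates) < 4)
    stop_param("need >= 4 blank-control replicate readouts")
  if (is.data.frame(standards)) {
    conc <- standards$nominal_concentration_fM
    reps <- standards$replicates
    means <- standards$mean
  } else {
    conc <- concentrations
    reps <- lapply(standards, `[[`, "replicate_pixel_counts")
    means <- vapply(standards, `[[`, numeric(1), "mean")
  }
  if (is.null(conc) || length(conc) != length(reps))
    stop_param("concentrations must match the standards")
  if (is.unsorted(conc, strictly = TRUE))
    stop_param("standards must be sorted by strictly increasing concentration")
  pvals <- vapply(seq_along(reps), function(i) {
    x <- reps[[i]]
    if (length(x) < 2) return(NA_real_)
    exact <- length(x) <= 8 && length(bc_replicates) <= 8 &&
      !anyDuplicated(c(x, bc_replicates))
    suppressWarnings(
      wilcox.test(x, bc_replicates, alternative = "greater",
                  exact = exact)$p.value)
  }, numeric(1))
  significant <- !is.na(pvals) & pvals < alpha
  in_range <- linear_range_flags(conc, means, significant,
                                 max_rel_residual)
  out <- data.frame(
    nominal_concentration_fM = conc,
    mean_pixel_count = means,
    inclusion_pvalue = pvals,
    significant = significant,
    in_linear_range = in_range,
    included = significant & in_range)
  if (!any(out$included))
    stop("no calibration point passes inclusion: cannot calibrate",
         call. = FALSE)
  class(out) <- c("calibration_points", "data.frame")
  out
}

# Iterative top-trimming linear-range rule. Points not significant are
# ignored; among significant points, the highest concentration is dropped
# while its relative residual from a 1/y-weighted refit on the remaining
# points exceeds the tolerance. Needs >= 3 significant points to trim.
linear_range_flags <- function(conc, means, significant,
                               max_rel_residual = 0.20) {
  in_range <- rep(TRUE, length(conc))
  idx <- which(significant & means > 0)
  while (length(idx) >= 3) {
    top <- idx[length(idx)]
    rest <- idx[-length(idx)]
    fit <- lm(means[rest] ~ conc[rest], weights = 1 / means[rest])
    pred <- coef(fit)[1] + coef(fit)[2] * conc[top]
    if (is.finite(pred) && pred > 0 &&
        abs(means[top] - pred) / pred > max_rel_residual) {
      in_range[top] <- FALSE
      idx <- rest
    } else break
  }
  in_range
}

#' Fit the pixel-count calibration curve
#'
#' Weighted linear regression of mean pixel count on nominal standard
#' concentration, with weights `1/readout` (the observed mean pixel count
#' per point), as used to convert the assay's pixel counts into molar
#' particle concentrations. Only included points enter the fit; points
#' with non-positive mean readout are unweightable and excluded.
#'
#' @param points a `calibration_points` table (from
#'   [select_calibration_points()]) or a data.frame with columns
#'   `nominal_concentration_fM` and `mean_pixel_count` (an `included`
#'   column is honoured when present).
#' @param alpha significance level recorded with the curve.
#' @return An object of class `sfida_calibration` with components
#'   `slope` (pixel count per fM), `intercept` (pixel count), `r_squared`,
#'   `points`, `n_points`, `alpha`.
#' @seealso [pixel_to_concentration()], [compute_lod()]
#' @examples
#' pts <- data.frame(nominal_concentration_fM = c(1, 2, 4),
#'                   mean_pixel_count = c(10, 20, 40))
#' fit <- fit_calibration(pts)
#' coef(fit)
#' @export
fit_calibration <- function(points, alpha = 0.05) {
  inc <- if (!is.null(points$included)) points$included else
    rep(TRUE, nrow(points))
  inc <- inc & points$mean_pixel_count > 0
  x <- points$nominal_concentration_fM[inc]
  y <- points$mean_pixel_count[inc]
  if (length(x) < 2) stop("need >= 2 included calibration points",
                          call. = FALSE)
  if (length(unique(x)) < 2)
    stop("singular calibration design: all concentrations equal",
         call. = FALSE)
  fit <- lm(y ~ x, weights = 1 / y)
  structure(list(
    slope = unname(coef(fit)[2]),
    intercept = unname(coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit)$r.squared),
    points = points,
    n_points = length(x),
    alpha = alpha,
    lm = fit
  ), class = "sfida_calibration")
}

#' @export
print.sfida_calibration <- function(x, ...) {
  cat("sFIDA calibration curve (weighted least squares, weights 1/readout)\n")
  cat(sprintf("  pixel count = %.4g + %.4g * [fM]   (r^2 = %.4f, %d points)\n",
              x$intercept, x$slope, x$r_squared, x$n_points))
  if (!is.null(x$lod))
    cat(sprintf("  LoD: %.1f pixel counts = %.3g fM\n",
                x$lod$lod_pixel, x$lod$lod_fM))
  invisible(x)
}

#' @export
coef.sfida_calibration <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Predict method for calibration curves
#'
#' @param object an `sfida_calibration` fit.
#' @param newdata numeric vector: pixel counts when
#'   `type = "concentration"` (the inverse, default), concentrations in
#'   fM when `type = "pixel_count"`.
#' @param type direction of the prediction.
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.sfida_calibration <- function(object, newdata,
                                      type = c("concentration",
                                               "pixel_count"), ...) {
  type <- match.arg(type)
  if (type == "pixel_count")
    return(object$intercept + object$slope * newdata)
  pixel_to_concentration(newdata, object, clamp = FALSE)
}

#' @export
plot.sfida_calibration <- function(x, ...) {
  pts <- x$points
  plot(pts$nominal_concentration_fM, pts$mean_pixel_count, log = "xy",
       xlab = "nominal concentration [fM]", ylab = "pixel count",
       pch = ifelse(pts$included %||% TRUE, 19, 1), ...)
  cc <- exp(seq(log(max(min(pts$nominal_concentration_fM), 1e-3)),
                log(max(pts$nominal_concentration_fM)), length.out = 50))
  lines(cc, pmax(x$intercept + x$slope * cc, 1e-9), col = 2)
  invisible(x)
}

#' Convert pixel counts to molar particle concentration
#'
#' Inverts the calibration line: `(pixel_count - intercept) / slope`.
#' Negative concentrations (readouts below the fitted blank level) are
#' clamped to 0 and flagged via the `below_blank` attribute.
#'
#' @param pixel_count numeric vector of sample pixel counts.
#' @param curve an `sfida_calibration` fit.
#' @param clamp clamp negative values to zero (default TRUE).
#' @return Numeric vector of concentrations (fM) with attribute
#'   `below_blank` (logical vector).
#' @export
pixel_to_concentration <- function(pixel_count, curve, clamp = TRUE) {
  if (curve$slope <= 0)
    stop("invalid calibration: slope must be > 0", call. = FALSE)
  conc <- (pixel_count - curve$intercept) / curve$slope
  below <- conc < 0
  if (clamp) conc[below] <- 0
  attr(conc, "below_blank") <- below
  conc
}

#' Limit of detection from blank-control replicates
#'
#' Estimates the smallest reliably measurable concentration as the blank
#' pixel-count mean plus two sample standard deviations
#' (`LoD = pixel_count_BC + 2 * sigma`), then converts that pixel count
#' to fM via the calibration curve. The assay protocol measures 24 blank
#' replicates for this purpose; any number >= 2 is accepted.
#'
#' @param bc_readouts numeric vector of blank-control well pixel counts.
#' @param curve an `sfida_calibration` fit (optional; without it only the
#'   pixel-level LoD is returned).
#' @return A list of class `lod_estimate`: `bc_mean_pixel_count`,
#'   `bc_sd`, `n_bc_replicates`, `lod_pixel`, `lod_fM`.
#' @export
compute_lod <- function(bc_readouts, curve = NULL) {
  if (length(bc_readouts) < 2)
    stop_param("need >= 2 blank-control readouts for the LoD")
  m <- mean(bc_readouts); s <- sd(bc_readouts)
  lod_px <- m + 2 * s
  lod_fM <- if (!is.null(curve))
    as.numeric(pixel_to_concentration(lod_px, curve)) else NA_real_
  structure(list(
    bc_mean_pixel_count = m, bc_sd = s,
    n_bc_replicates = length(bc_readouts),
    lod_pixel = lod_px, lod_fM = lod_fM
  ), class = "lod_estimate")
}

#' @export
print.lod_estimate <- function(x, ...) {
  cat(sprintf(
    "LoD: %.1f pixel counts (BC mean %.1f + 2 x SD %.1f, n = %d)",
    x$lod_pixel, x$bc_mean_pixel_count, x$bc_sd, x$n_bc_replicates))
  if (!is.na(x$lod_fM)) cat(sprintf(" = %.3g fM", x$lod_fM))
  cat("\n")
  invisible(x)
}
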