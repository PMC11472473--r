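#' Focus score of an image
#'
#' Sharpness metric used by the defocus check: the variance of the
#' discrete 4-neighbour Laplacian divided by the variance of the image.
#' Pure read noise scores about 20 (the Laplacian amplifies white noise
#' 20-fold), in-focus diffraction-limited spot fields a few tenths, and
#' defocused spot fields orders of magnitude less: blurring inflates the
#' image variance without adding high-frequency energy.
#'
#' @param image numeric or integer matrix.
#' @return A single numeric score (NA for a constant image).
#' @export
focus_score <- function(image) {
  img <- unclass(image)
  h <- nrow(img); w <- ncol(img)
  if (h < 3 || w < 3) stop_param("image too small for focus metric")
  c_ <- img[2:(h - 1), 2:(w - 1)]
  lap <- 4 * c_ -
    img[1:(h - 2), 2:(w - 1)] - img[3:h, 2:(w - 1)] -
    img[2:(h - 1), 1:(w - 2)] - img[2:(h - 1), 3:w]
  v <- var(as.vector(img))
  if (v == 0) return(NA_real_)
  var(as.vector(lap)) / v
}

#' Quality-control verdict for a single image
#'
#' Automates the exclusion of unusable fields of view: images carrying
#' artifacts (saturated regions or large bright connected components,
#' e.g. fibres or aggregate clumps) and out-of-focus images. An image is
#' accepted only when neither flag is raised.
#'
#' @param image integer image matrix.
#' @param params a [qc_params()] object.
#' @param bit_depth camera bit depth used to scale the brightness
#'   thresholds.
#' @return A list of class `qc_verdict`: `accepted`, `artifact_flag`,
#'   `defocus_flag`, `saturated_fraction`, `focus_score`.
#' @export
qc_image <- function(image, params = qc_params(), bit_depth = 14) {
  if (length(image) == 0) stop_param("empty image")
  maxval <- 2^bit_depth - 1
  sat_frac <- mean(image >= maxval)
  artifact <- sat_frac > params$saturated_fraction_max
  if (!artifact) {
    mask <- image > params$bright_quantile * maxval
    if (sum(mask) > params$artifact_area_max) {
      lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(image)))
      if (max(tabulate(as.integer(lab))) > params$artifact_area_max)
        artifact <- TRUE
    }
  }
  fs <- focus_score(image)
  defocus <- !is.na(fs) && fs < params$focus_min
  structure(list(
    accepted = !(artifact || defocus),
    artifact_flag = artifact,
    defocus_flag = defocus,
    saturated_fraction = sat_frac,
    focus_score = fs
  ), class = "qc_verdict")
}

#' Determine the blank-anchored intensity cutoff
#'
#' Pools all pixels of the accepted blank-control images of a plate and
#' returns the smallest integer intensity `c` such that the fraction of
#' pooled blank pixels strictly greater than `c` does not exceed
#' `target_fraction`. The default target of 1e-5 leaves 0.001% of blank
#' pixels positive, the rule that anchors the assay background.
#'
#' @param blank_images list of integer image matrices (accepted BC
#'   images), or a single matrix.
#' @param target_fraction maximum tolerated positive fraction in the
#'   blank (default `1e-5`).
#' @param bit_depth camera bit depth.
#' @return An object of class `intensity_cutoff`: `cutoff`,
#'   `blank_pixel_total`, `positive_fraction_at_cutoff`,
#'   `target_fraction`.
#' @export
determine_cutoff <- function(blank_images, target_fraction = 1e-5,
                             bit_depth = 14) {
  if (is.matrix(blank_images)) blank_images <- list(blank_images)
  if (length(blank_images) == 0)
    stop("no accepted blank-control images: assay invalid without BC",
         call. = FALSE)
  if (target_fraction <= 0 || target_fraction >= 1)
    stop_param("target_fraction must be in (0, 1)")
  maxval <- 2^bit_depth - 1
  px <- unlist(lapply(blank_images, as.vector), use.names = FALSE)
  if (any(px < 0 | px > maxval)) stop_param("pixels outside bit-depth range")
  total <- length(px)
  # counts[v+1] = number of pixels with intensity v
  counts <- tabulate(px + 1L, nbins = maxval + 1L)
  # n_above[c+1] = number of pixels strictly greater than c
  n_above <- total - cumsum(counts)
  ok <- which(n_above / total <= target_fraction)
  cutoff <- ok[1] - 1L   # smallest qualifying integer
  structure(list(
    cutoff = as.integer(cutoff),
    blank_pixel_total = total,
    positive_fraction_at_cutoff = n_above[cutoff + 1L] / total,
    target_fraction = target_fraction,
    bit_depth = bit_depth
  ), class = "intensity_cutoff")
}

#' @export
print.intensity_cutoff <- function(x, ...) {
  cat(sprintf(
    "Intensity cutoff: %d ADU (%.3g%% of %s blank pixels above; target %.3g%%)\n",
    x$cutoff, 100 * x$positive_fraction_at_cutoff,
    format(x$blank_pixel_total, big.mark = ","),
    100 * x$target_fraction))
  invisible(x)
}

#' Pixel count of an image
#'
#' The assay readout primitive: the number of pixels with intensity
#' strictly greater than the blank-derived cutoff.
#'
#' @param image integer image matrix.
#' @param cutoff an `intensity_cutoff` object or a single integer.
#' @param bit_depth camera bit depth used for range validation.
#' @return Integer count.
#' @export
pixel_count <- function(image, cutoff, bit_depth = 14) {
  if (inherits(cutoff, "intensity_cutoff")) {
    bit_depth <- cutoff$bit_depth
    cutoff <- cutoff$cutoff
  }
  if (cutoff < 0 || cutoff > 2^bit_depth - 1)
    stop_param("cutoff outside bit-depth range")
  sum(image > cutoff)
}

#' Aggregate a well's images into a well-level readout
#'
#' Runs QC on each field of view, sums pixel counts over accepted images,
#' and rescales the sum to the nominal image number so wells remain
#' comparable when images are excluded: with `k` of `n` images accepted
#' the readout is `raw_sum * n / k`. Wells with under `min_accepted_frac`
#' of images accepted are flagged invalid.
#'
#' @param images list of integer image matrices for one well.
#' @param cutoff an `intensity_cutoff` object or integer.
#' @param qc a [qc_params()] object, or `NULL` to skip QC (all images
#'   accepted).
#' @param well_id identifier recorded in the readout.
#' @param min_accepted_frac minimum accepted-image fraction for a valid
#'   well (default 0.6).
#' @return A list of class `well_readout`: `well_id`, `images_total`,
#'   `images_accepted`, `raw_pixel_count`, `pixel_count` (rescaled),
#'   `valid`, `qc` (per-image verdicts).
#' @export
well_readout <- function(images, cutoff, qc = qc_params(),
                         well_id = NA_character_,
                         min_accepted_frac = 0.6) {
  if (length(images) == 0) stop_param("well has no images")
  bd <- if (inherits(cutoff, "intensity_cutoff")) cutoff$bit_depth else 14
  verdicts <- if (is.null(qc)) NULL else
    lapply(images, qc_image, params = qc, bit_depth = bd)
  accepted <- if (is.null(qc)) rep(TRUE, length(images)) else
    vapply(verdicts, `[[`, logical(1), "accepted")
  n <- length(images); k <- sum(accepted)
  raw <- if (k > 0)
    sum(vapply(images[accepted], pixel_count, numeric(1),
               cutoff = cutoff)) else NA_real_
  structure(list(
    well_id = well_id,
    images_total = n,
    images_accepted = k,
    raw_pixel_count = raw,
    pixel_count = if (k > 0) raw * n / k else NA_real_,
    valid = k > 0 && k / n >= min_accepted_frac,
    qc = verdicts
  ), class = "well_readout")
}

#' Replicate statistics for one sample
#'
#' Combines the well readouts of a sample's replicate wells into the
#' sample-level readout: mean, sample standard deviation (n - 1
#' denominator), and CV%, gated against the sample-kind-specific
#' acceptance limit — 20% for synthetic standards and IQC, 25% for fecal
#' samples.
#'
#' @param wells list of `well_readout` objects (or a numeric vector of
#'   pixel counts).
#' @param sample_id identifier.
#' @param sample_kind `"standard"`, `"iqc"`, `"fecal"`, or `"blank"`;
#'   selects the CV gate.
#' @param acceptance_cv CV% gate override; default picks 20 or 25 by
#'   `sample_kind`.
#' @return A list of class `sample_readout`: `sample_id`, `sample_kind`,
#'   `replicate_pixel_counts`, `n_replicates`, `mean`, `sd`,
#'   `cv_percent`, `cv_pass`, `reliable`.
#' @export
replicate_stats <- function(wells, sample_id = NA_character_,
                            sample_kind = c("fecal", "standard", "iqc",
                                            "blank"),
                            acceptance_cv = NULL) {
  sample_kind <- match.arg(sample_kind)
  counts <- if (is.numeric(wells)) wells else {
    valid <- vapply(wells, `[[`, logical(1), "valid")
    vapply(wells[valid], `[[`, numeric(1), "pixel_count")
  }
  gate <- acceptance_cv %||%
    if (sample_kind %in% c("standard", "iqc")) 20 else 25
  n <- length(counts)
  m <- if (n) mean(counts) else NA_real_
  s <- if (n >= 2) sd(counts) else NA_real_
  cv <- if (n >= 2 && !is.na(m) && m > 0) 100 * s / m else NA_real_
  structure(list(
    sample_id = sample_id,
    sample_kind = sample_kind,
    replicate_pixel_counts = counts,
    n_replicates = n,
    mean = m, sd = s,
    cv_percent = cv,
    cv_pass = !is.na(cv) && cv < gate,
    acceptance_cv = gate,
    reliable = n >= 2
  ), class = "sample_readout")
}

#' @export
print.sample_readout <- function(x, ...) {
  cat(sprintf(
    "Sample %s (%s): mean %.1f, SD %.1f, CV %.2f%% over %d replicates [%s]\n",
    x$sample_id, x$sample_kind, x$mean, x$sd, x$cv_percent,
    x$n_replicates,
    if (isTRUE(x$cv_pass)) "CV pass" else "CV fail"))
  invisible(x)
}
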