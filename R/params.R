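#' Imaging parameters for the synthetic microscopy generator
#'
#' Bundles the acquisition geometry and noise model used by the synthetic
#' image generators. Defaults mirror the assay's acquisition settings: 25
#' fields of view per well, each 1000 x 1000 pixels, 14-bit grayscale
#' (intensities 0-16383). The noise model is Gaussian read noise on a
#' constant camera offset; an optional Poisson shot-noise term can be
#' switched on for spot photons.
#'
#' @param image_height,image_width image dimensions in pixels.
#' @param bit_depth camera bit depth; pixel values are clipped to
#'   `[0, 2^bit_depth - 1]`.
#' @param images_per_well number of imaged positions per well.
#' @param background_mean,background_sd mean and SD of the background read
#'   noise (ADU).
#' @param psf_sigma standard deviation of the symmetric 2D Gaussian spot
#'   profile, in pixels.
#' @param spot_amplitude_mean,spot_amplitude_sd mean and SD (natural scale,
#'   ADU) of the log-normal spot peak-amplitude distribution.
#' @param poisson_noise logical; add Poisson shot noise on rendered spot
#'   photons (off by default, read noise dominates the cutoff logic).
#' @param seed integer base seed; together with an image index it fixes each
#'   image bit-for-bit.
#' @return An object of class `imaging_params` (a validated list).
#' @examples
#' p <- imaging_params(image_height = 64, image_width = 64, seed = 1)
#' img <- gen_blank_image(p, index = 1)
#' range(img)
#' @export
imaging_params <- function(image_height = 1000, image_width = 1000,
                           bit_depth = 14, images_per_well = 25,
                           background_mean = 500, background_sd = 20,
                           psf_sigma = 1.5,
                           spot_amplitude_mean = 4000,
                           spot_amplitude_sd = 2000,
                           poisson_noise = FALSE,
                           seed = 1L) {
  if (image_height < 1 || image_width < 1)
    stop_param("image dimensions must be positive")
  if (bit_depth < 1 || bit_depth > 16)
    stop_param("bit_depth must be in 1..16")
  if (psf_sigma <= 0) stop_param("psf_sigma must be > 0")
  if (background_sd < 0) stop_param("background_sd must be >= 0")
  if (images_per_well < 1) stop_param("images_per_well must be >= 1")
  structure(list(
    image_height = as.integer(image_height),
    image_width = as.integer(image_width),
    bit_depth = as.integer(bit_depth),
    images_per_well = as.integer(images_per_well),
    background_mean = background_mean,
    background_sd = background_sd,
    psf_sigma = psf_sigma,
    spot_amplitude_mean = spot_amplitude_mean,
    spot_amplitude_sd = spot_amplitude_sd,
    poisson_noise = isTRUE(poisson_noise),
    seed = as.integer(seed)
  ), class = "imaging_params")
}

#' Cohort simulation parameters
#'
#' Parameters of the two-group log-normal concentration model used to
#' emulate a proof-of-concept diagnostic cohort: each subject's true
#' aggregate concentration is drawn log-normally with a group-specific
#' log-mean, and replicate readouts are jittered with a fixed coefficient
#' of variation.
#'
#' Defaults reproduce the study design this generator emulates: 26 disease
#' (AD) and 31 control (HC) subjects, replicate CV 18.7% (the mean fecal
#' intra-assay CV), and a group shift sized so the analytic normal-model
#' AUC, \eqn{\Phi(\Delta/(\sigma\sqrt2))}, is about 0.70. With geometric
#' mean 40 fM for controls and log-SD 1.6 the simulated concentrations span
#' roughly 1.6 fM to 3 pM.
#'
#' @param n_ad,n_hc subjects per group (>= 1).
#' @param log_mean_hc,log_mean_ad natural-log mean concentration (log fM).
#' @param log_sd common log-scale SD (>= 0).
#' @param replicate_cv coefficient of variation of replicate readouts
#'   (fraction, >= 0).
#' @param n_replicates technical replicates per sample.
#' @param seed integer seed.
#' @return An object of class `cohort_sim_params`.
#' @export
cohort_sim_params <- function(n_ad = 26, n_hc = 31,
                              log_mean_hc = log(40),
                              log_mean_ad = log(40) + 0.754 * 1.6,
                              log_sd = 1.6,
                              replicate_cv = 0.187,
                              n_replicates = 4,
                              seed = 1L) {
  if (n_ad < 1 || n_hc < 1) stop_param("group sizes must be >= 1")
  if (log_sd < 0) stop_param("log_sd must be >= 0")
  if (replicate_cv < 0) stop_param("replicate_cv must be >= 0")
  structure(list(
    n_ad = as.integer(n_ad), n_hc = as.integer(n_hc),
    log_mean_hc = log_mean_hc, log_mean_ad = log_mean_ad,
    log_sd = log_sd, replicate_cv = replicate_cv,
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  ), class = "cohort_sim_params")
}

#' Image quality-control parameters
#'
#' Thresholds of the automated image QC: an image is rejected as an
#' artifact when its saturated-pixel fraction exceeds
#' `saturated_fraction_max` or when the largest bright connected component
#' (pixels above `bright_quantile` of the intensity range) exceeds
#' `artifact_area_max` pixels; it is rejected as out-of-focus when the
#' focus score (variance of the discrete Laplacian divided by the image
#' variance) falls below `focus_min`.
#'
#' Pure read noise scores about 20 on this focus metric, in-focus spot
#' fields a few tenths, and defocused spot fields well below 0.05, so the
#' default `focus_min = 0.1` separates defocused images from both.
#'
#' @param saturated_fraction_max maximum tolerated fraction of saturated
#'   pixels (default 0.001).
#' @param artifact_area_max maximum area (pixels) of a bright connected
#'   component (default 500).
#' @param bright_quantile fraction of the bit-depth range above which a
#'   pixel counts as "bright" (default 0.9).
#' @param focus_min minimum focus score (default 0.1).
#' @return An object of class `qc_params`.
#' @export
qc_params <- function(saturated_fraction_max = 0.001,
                      artifact_area_max = 500,
                      bright_quantile = 0.9,
                      focus_min = 0.1) {
  structure(list(
    saturated_fraction_max = saturated_fraction_max,
    artifact_area_max = artifact_area_max,
    bright_quantile = bright_quantile,
    focus_min = focus_min
  ), class = "qc_params")
}
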