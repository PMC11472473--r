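#' Generate a synthetic blank-control image
#'
#' Simulates one field of view of an unspiked blank-control (BC) well:
#' Gaussian read noise on a constant camera offset, rounded to integer
#' analog-digital units (ADU) and clipped to the camera bit depth. The
#' image is a deterministic function of `(params$seed, index)`.
#'
#' @param params an [imaging_params()] object.
#' @param index image (position) index within the well; part of the RNG
#'   stream so every field of view differs but is reproducible.
#' @param well_id optional well identifier stored as an attribute.
#' @return Integer matrix of dimension `image_height x image_width` with
#'   attributes `well_id` and `position_index`.
#' @examples
#' p <- imaging_params(image_height = 32, image_width = 32, seed = 7)
#' identical(gen_blank_image(p, 1), gen_blank_image(p, 1))
#' @export
gen_blank_image <- function(params, index = 1L, well_id = NA_character_) {
  stopifnot(inherits(params, "imaging_params"))
  n <- params$image_height * params$image_width
  img <- with_seed(sub_seed(params$seed, index), {
    matrix(rnorm(n, params$background_mean, params$background_sd),
           nrow = params$image_height, ncol = params$image_width)
  })
  img <- matrix(as.integer(round(clip_adu(img, params$bit_depth))),
                nrow = params$image_height)
  attr(img, "well_id") <- well_id
  attr(img, "position_index") <- as.integer(index)
  img
}

# Add 2D-Gaussian spots onto an intensity matrix (double precision, no
# clipping). x/y are sub-pixel centre coordinates in [0.5, dim + 0.5].
render_spots <- function(img, x, y, amplitude, psf_sigma) {
  h <- nrow(img); w <- ncol(img)
  r <- ceiling(4 * psf_sigma)
  two_s2 <- 2 * psf_sigma^2
  for (k in seq_along(x)) {
    i0 <- max(1L, floor(y[k]) - r); i1 <- min(h, ceiling(y[k]) + r)
    j0 <- max(1L, floor(x[k]) - r); j1 <- min(w, ceiling(x[k]) + r)
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    gy <- exp(-(ii - y[k])^2 / two_s2)
    gx <- exp(-(jj - x[k])^2 / two_s2)
    img[ii, jj] <- img[ii, jj] + amplitude[k] * outer(gy, gx)
  }
  img
}

#' Generate a synthetic image containing fluorescent spots
#'
#' Renders `n_spots` diffraction-limited particles — symmetric 2D Gaussian
#' profiles at uniform random sub-pixel positions with log-normal peak
#' amplitudes — on top of the blank background model, and returns the
#' ground-truth spot table alongside the image. With `n_spots = 0` the
#' image is distributed exactly as [gen_blank_image()].
#'
#' @inheritParams gen_blank_image
#' @param n_spots number of spots (>= 0; at most 10% of the pixel count,
#'   beyond which the single-particle regime is meaningless).
#' @return A list with elements `image` (integer matrix as in
#'   [gen_blank_image()]) and `spots` (data.frame `x`, `y`, `amplitude`).
#' @export
gen_spot_image <- function(params, n_spots, index = 1L,
                           well_id = NA_character_) {
  stopifnot(inherits(params, "imaging_params"))
  n_px <- params$image_height * params$image_width
  if (n_spots < 0) stop_param("n_spots must be >= 0")
  if (n_spots > 0.1 * n_px)
    stop_param("n_spots exceeds 10% of pixels; not a single-particle field")
  out <- with_seed(sub_seed(params$seed, index), {
    img <- matrix(rnorm(n_px, params$background_mean, params$background_sd),
                  nrow = params$image_height)
    spots <- data.frame(x = numeric(0), y = numeric(0),
                        amplitude = numeric(0))
    if (n_spots > 0) {
      m <- params$spot_amplitude_mean; s <- params$spot_amplitude_sd
      sdlog <- sqrt(log(1 + (s / m)^2))
      meanlog <- log(m) - sdlog^2 / 2
      spots <- data.frame(
        x = runif(n_spots, 0.5, params$image_width + 0.5),
        y = runif(n_spots, 0.5, params$image_height + 0.5),
        amplitude = rlnorm(n_spots, meanlog, sdlog)
      )
      signal <- render_spots(matrix(0, params$image_height,
                                    params$image_width),
                             spots$x, spots$y, spots$amplitude,
                             params$psf_sigma)
      if (params$poisson_noise) signal <- matrix(
        rpois(n_px, pmax(signal, 0)), nrow = params$image_height)
      img <- img + signal
    }
    list(img = img, spots = spots)
  })
  img <- matrix(as.integer(round(clip_adu(out$img, params$bit_depth))),
                nrow = params$image_height)
  attr(img, "well_id") <- well_id
  attr(img, "position_index") <- as.integer(index)
  list(image = img, spots = out$spots)
}

#' Generate a corrupted image for QC testing
#'
#' Produces images carrying the two acquisition failure modes the QC stage
#' must catch: `"artifact"` injects a large saturated connected blob
#' (covering at least `blob_fraction` of the pixels at the intensity
#' maximum, e.g. a fluorescent fibre or aggregate clump), and `"defocus"`
#' renders a spot field with the point-spread sigma inflated
#' `defocus_factor`-fold (amplitudes kept), which collapses the
#' variance-of-Laplacian focus score.
#'
#' @inheritParams gen_spot_image
#' @param mode `"artifact"` or `"defocus"`.
#' @param n_spots spots rendered in defocus mode (and below the blob in
#'   artifact mode).
#' @param blob_fraction fraction of pixels covered by the saturated blob
#'   (artifact mode; `0` degenerates to a plain spot/blank image).
#' @param defocus_factor multiplier (>= 4) on `psf_sigma` in defocus mode.
#' @return Integer image matrix as in [gen_blank_image()].
#' @export
gen_corrupted_image <- function(params, mode = c("artifact", "defocus"),
                                index = 1L, n_spots = 150,
                                blob_fraction = 0.005, defocus_factor = 4,
                                well_id = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "imaging_params"))
  if (mode == "defocus") {
    if (defocus_factor < 4)
      stop_param("defocus_factor must be >= 4 to guarantee degradation")
    p2 <- params
    p2$psf_sigma <- params$psf_sigma * defocus_factor
    return(gen_spot_image(p2, n_spots, index, well_id)$image)
  }
  if (blob_fraction < 0 || blob_fraction > 0.5)
    stop_param("blob_fraction must be in [0, 0.5]")
  img <- gen_spot_image(params, n_spots, index, well_id)$image
  if (blob_fraction > 0) {
    h <- nrow(img); w <- ncol(img)
    area <- ceiling(blob_fraction * h * w)
    side <- ceiling(sqrt(area))
    # saturated square blob at a seeded position, clipped to the frame
    pos <- with_seed(sub_seed(params$seed, index) + 1L,
                     c(sample.int(max(1L, h - side), 1L),
                       sample.int(max(1L, w - side), 1L)))
    ii <- pos[1]:min(h, pos[1] + side - 1L)
    jj <- pos[2]:min(w, pos[2] + side - 1L)
    img[ii, jj] <- as.integer(2^params$bit_depth - 1)
  }
  img
}
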