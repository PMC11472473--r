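#' Build a plate layout table
#'
#' Constructs the layout of a 384-well assay plate: blank controls (BC),
#' a calibration-standard dilution series, an internal quality control
#' (IQC), and test samples, each in `replicates`-fold determination.
#' Wells are assigned row-major over the standard 384-well grid (rows
#' A-P, columns 1-24).
#'
#' @param standard_concentrations standard concentrations in fM, strictly
#'   increasing. The default is the assay's 1:5 dilution series from
#'   10 pM down to 0.64 fM.
#' @param sample_ids character vector of test-sample identifiers (may be
#'   empty).
#' @param iqc logical; include an IQC replicate group.
#' @param n_blank_wells blank-control wells; the default 24 matches the
#'   blank replication used for limit-of-detection estimation.
#' @param replicates wells per replicate group (default 4).
#' @return A `data.frame` of class `plate_layout` with columns `well_id`,
#'   `sample_id`, `sample_kind` (`blank`, `standard`, `iqc`, `fecal`),
#'   `nominal_concentration_fM`, `replicate_group`.
#' @export
plate_layout <- function(standard_concentrations = 10000 / 5^(6:0),
                         sample_ids = character(),
                         iqc = TRUE,
                         n_blank_wells = 24,
                         replicates = 4) {
  if (length(standard_concentrations) > 0) {
    if (any(standard_concentrations < 0))
      stop_param("standard concentrations must be non-negative")
    if (is.unsorted(standard_concentrations, strictly = TRUE))
      stop_param("standard concentrations must be strictly increasing")
  }
  rows <- list()
  add <- function(sample_id, kind, conc, n) {
    rows[[length(rows) + 1]] <<- data.frame(
      sample_id = sample_id, sample_kind = kind,
      nominal_concentration_fM = conc,
      replicate_group = sample_id,
      count = n, stringsAsFactors = FALSE)
  }
  add("BC", "blank", 0, n_blank_wells)
  for (conc in standard_concentrations)
    add(sprintf("STD_%g", conc), "standard", conc, replicates)
  if (iqc) add("IQC", "iqc", NA_real_, replicates)
  for (sid in sample_ids) add(sid, "fecal", NA_real_, replicates)
  tab <- do.call(rbind, rows)
  tab <- tab[rep(seq_len(nrow(tab)), tab$count),
             setdiff(names(tab), "count"), drop = FALSE]
  n <- nrow(tab)
  if (n > 384) stop_param("layout exceeds 384 wells")
  grid <- paste0(rep(LETTERS[1:16], each = 24), rep(1:24, 16))
  tab <- cbind(well_id = grid[seq_len(n)], tab)
  rownames(tab) <- NULL
  class(tab) <- c("plate_layout", "data.frame")
  tab
}

# Simulate one well: `images_per_well` spot images with per-image true spot
# counts drawn Poisson(lambda). Returns images plus ground truth.
gen_well_images <- function(params, lambda, well_id, well_index) {
  n_img <- params$images_per_well
  counts <- with_seed(sub_seed(params$seed, 100000L + well_index),
                      rpois(n_img, lambda))
  images <- vector("list", n_img)
  for (i in seq_len(n_img)) {
    idx <- well_index * 1000L + i
    images[[i]] <- gen_spot_image(params, counts[i], index = idx,
                                  well_id = well_id)$image
  }
  list(images = images,
       truth = data.frame(well_id = well_id,
                          position_index = seq_len(n_img),
                          true_spots = counts))
}

#' Simulate a calibration plate with known ground truth
#'
#' Generates image stacks for every well of a layout. Standard wells
#' receive Poisson-distributed spot counts with per-image mean
#' `spots_per_fM * nominal_concentration`; blank wells receive pure
#' background; IQC and test-sample wells draw their mean spot count from
#' `sample_lambda` (per-image mean, named by sample_id) when provided.
#'
#' @param params an [imaging_params()] object.
#' @param layout a [plate_layout()] table.
#' @param spots_per_fM expected true spots per image per fM of standard.
#' @param sample_lambda optional named numeric: per-image mean spot count
#'   for non-standard, non-blank samples.
#' @return A list with `images` (named list well_id -> list of image
#'   matrices), `layout`, and `truth` (per-image true spot counts).
#' @export
gen_calibration_plate <- function(params, layout = plate_layout(),
                                  spots_per_fM = 0.016,
                                  sample_lambda = NULL) {
  stopifnot(inherits(params, "imaging_params"))
  if (!nrow(layout)) stop_param("empty plate layout")
  if (!any(layout$sample_kind == "standard") &&
      !is.null(attr(layout, "require_standards")))
    stop_param("layout has no standard wells")
  images <- list(); truth <- list()
  for (w in seq_len(nrow(layout))) {
    kind <- layout$sample_kind[w]
    lambda <- switch(kind,
      blank = 0,
      standard = spots_per_fM * layout$nominal_concentration_fM[w],
      (sample_lambda %||% numeric())[layout$sample_id[w]] %||% 0)
    if (is.na(lambda)) lambda <- 0
    well <- gen_well_images(params, lambda, layout$well_id[w], w)
    images[[layout$well_id[w]]] <- well$images
    truth[[w]] <- well$truth
  }
  list(images = images, layout = layout, truth = do.call(rbind, truth))
}

#' Simulate a two-group diagnostic cohort
#'
#' Draws per-subject true aggregate concentrations from group-specific
#' log-normal distributions (disease group shifted upward), jitters
#' technical replicates with a fixed CV, and attaches demographic
#' covariates. Stool-consistency (Bristol) scores and ages are drawn from
#' the group means and SDs reported for the cohort this generator
#' emulates, independent of concentration, so covariate correlations are
#' null by construction.
#'
#' @param params a [cohort_sim_params()] object.
#' @return A `data.frame` with columns `sample_id`, `group` (`"AD"`/
#'   `"HC"`), `true_concentration_fM`, `concentration_fM` (mean of the
#'   jittered replicates), `cv_percent`, `bristol`, `age`, `sex`, plus a
#'   `replicates` attribute holding the per-sample replicate matrix.
#' @export
gen_cohort <- function(params = cohort_sim_params()) {
  stopifnot(inherits(params, "cohort_sim_params"))
  with_seed(params$seed, {
    n <- params$n_ad + params$n_hc
    group <- c(rep("AD", params$n_ad), rep("HC", params$n_hc))
    mu <- ifelse(group == "AD", params$log_mean_ad, params$log_mean_hc)
    true_conc <- exp(rnorm(n, mu, params$log_sd))
    reps <- matrix(NA_real_, n, params$n_replicates)
    for (i in seq_len(n)) {
      sdev <- params$replicate_cv * true_conc[i]
      reps[i, ] <- pmax(rnorm(params$n_replicates, true_conc[i], sdev), 0)
    }
    meas <- rowMeans(reps)
    cv <- ifelse(meas > 0, 100 * apply(reps, 1, sd) / meas, NA_real_)
    bristol_mu <- ifelse(group == "AD", 4.4, 5.1)
    bristol_sd <- ifelse(group == "AD", 0.9, 0.8)
    bristol <- pmin(pmax(round(rnorm(n, bristol_mu, bristol_sd)), 1), 7)
    age <- round(ifelse(group == "AD", rnorm(n, 71.1, 8.6),
                        rnorm(n, 49.2, 16.4)))
    sex <- ifelse(runif(n) < ifelse(group == "AD", 0.423, 0.645),
                  "F", "M")
    tab <- data.frame(
      sample_id = sprintf("S%03d", seq_len(n)),
      group = group,
      true_concentration_fM = true_conc,
      concentration_fM = meas,
      cv_percent = cv,
      bristol = bristol, age = age, sex = sex,
      stringsAsFactors = FALSE)
    attr(tab, "replicates") <- reps
    tab
  })
}
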