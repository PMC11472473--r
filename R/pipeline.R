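#' Run configuration
#'
#' Assembles and validates the configuration binding the pipeline stages
#' together. All keys have working defaults; `overrides` (typically
#' parsed from a YAML file via [read_config()]) replace them key-wise.
#'
#' @param images_dir directory for/with per-well TIFF stacks.
#' @param layout_csv plate-layout CSV path.
#' @param cohort_csv cohort-table CSV path.
#' @param output_dir directory for stage outputs.
#' @param target_fraction blank cutoff target fraction.
#' @param alpha calibration inclusion significance level.
#' @param fecal_dilution_factor dilution factor applied to reported fecal
#'   concentrations (assay-specific 1:5 by default).
#' @param seed integer seed recorded in provenance and used by
#'   [run_simulate()].
#' @param imaging list of [imaging_params()] overrides for simulation.
#' @param qc list of [qc_params()] overrides.
#' @param spots_per_fM generative spots/image/fM for simulation.
#' @param sample_lambda named per-image mean spot counts for simulated
#'   non-standard samples.
#' @param overrides named list replacing any of the above.
#' @return A list of class `sfida_config`.
#' @export
sfida_config <- function(images_dir = "images", layout_csv = "layout.csv",
                         cohort_csv = "cohort.csv",
                         output_dir = "results",
                         target_fraction = 1e-5, alpha = 0.05,
                         fecal_dilution_factor = 5,
                         seed = 1L,
                         imaging = list(), qc = list(),
                         spots_per_fM = 0.016,
                         sample_lambda = NULL,
                         overrides = NULL) {
  cfg <- list(images_dir = images_dir, layout_csv = layout_csv,
              cohort_csv = cohort_csv, output_dir = output_dir,
              target_fraction = target_fraction, alpha = alpha,
              fecal_dilution_factor = fecal_dilution_factor,
              seed = as.integer(seed), imaging = imaging, qc = qc,
              spots_per_fM = spots_per_fM,
              sample_lambda = sample_lambda)
  if (!is.null(overrides)) cfg <- modifyList(cfg, overrides)
  if (cfg$target_fraction <= 0 || cfg$target_fraction >= 1)
    stop_param("target_fraction must be in (0, 1)")
  class(cfg) <- "sfida_config"
  cfg
}

#' Read a YAML run configuration
#'
#' @param path YAML file whose keys mirror the [sfida_config()]
#'   arguments.
#' @return An `sfida_config` object.
#' @export
read_config <- function(path) {
  sfida_config(overrides = yaml::read_yaml(path))
}

# provenance block shared by all stages
provenance <- function(config) {
  list(package_version = as.character(utils::packageVersion("sfida")),
       seed = config$seed,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a multi-page 16-bit TIFF stack
#'
#' @param images list of integer image matrices (14-bit ADU).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(images, path) {
  tiff::writeTIFF(lapply(images, function(m) unclass(m) / 65535),
                  path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a multi-page 16-bit TIFF stack
#'
#' @param path TIFF file written by [write_tiff_stack()] (or any 16-bit
#'   grayscale multi-page TIFF).
#' @return List of integer image matrices.
#' @export
read_tiff_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  lapply(pages, function(m) matrix(as.integer(m), nrow(m)))
}

#' Simulate a plate and cohort to disk
#'
#' Generates the synthetic study inputs under `config`: per-well
#' multi-page TIFF stacks, the plate-layout CSV, per-image ground truth,
#' and a simulated cohort table. Deterministic given `config$seed`.
#'
#' @param config an [sfida_config()] object.
#' @param layout optional [plate_layout()]; the default layout holds
#'   blanks, the standard series, IQC, and no fecal wells.
#' @param cohort_params a [cohort_sim_params()] object (seeded from the
#'   config when omitted).
#' @return Invisibly, a list with `layout`, `truth`, `cohort`, and
#'   `provenance`.
#' @export
run_simulate <- function(config = sfida_config(), layout = NULL,
                         cohort_params = NULL) {
  dir.create(config$images_dir, showWarnings = FALSE, recursive = TRUE)
  ip <- do.call(imaging_params,
                modifyList(list(seed = config$seed), config$imaging))
  layout <- layout %||% plate_layout()
  plate <- gen_calibration_plate(ip, layout,
                                 spots_per_fM = config$spots_per_fM,
                                 sample_lambda = config$sample_lambda)
  for (wid in names(plate$images))
    write_tiff_stack(plate$images[[wid]],
                     file.path(config$images_dir,
                               paste0(wid, ".tiff")))
  write.csv(layout, config$layout_csv, row.names = FALSE)
  write.csv(plate$truth,
            file.path(config$images_dir, "ground_truth.csv"),
            row.names = FALSE)
  cp <- cohort_params %||% cohort_sim_params(seed = config$seed)
  cohort <- gen_cohort(cp)
  write.csv(cohort, config$cohort_csv, row.names = FALSE)
  invisible(list(layout = layout, truth = plate$truth, cohort = cohort,
                 provenance = provenance(config)))
}

#' Analyze a plate: readouts, calibration, concentrations
#'
#' Chains the image-analysis and calibration stages over a plate on
#' disk: reads the layout and per-well TIFF stacks, QCs every image,
#' determines the blank cutoff from all accepted blank-control images
#' pooled, computes rescaled well readouts and replicate statistics,
#' selects and fits the calibration curve, estimates the LoD, and
#' calibrates every non-blank sample into fM (fecal samples multiplied
#' by the configured dilution factor). Without standard wells the run
#' stops after readouts with status `"no calibration"`.
#'
#' @param config an [sfida_config()] object.
#' @return A list of class `results_bundle`: `well_readouts`, `samples`
#'   (per-sample table), `cutoff`, `calibration`, `lod`, `status`,
#'   `exclusion_log`, `provenance`.
#' @export
run_analyze <- function(config = sfida_config()) {
  layout <- read.csv(config$layout_csv, stringsAsFactors = FALSE)
  qcp <- do.call(qc_params, config$qc)
  ip_bd <- (config$imaging$bit_depth %||% 14)
  stacks <- lapply(layout$well_id, function(wid) {
    p <- file.path(config$images_dir, paste0(wid, ".tiff"))
    if (!file.exists(p)) stop("missing image stack for well ", wid,
                              call. = FALSE)
    read_tiff_stack(p)
  })
  names(stacks) <- layout$well_id

  bc_wells <- layout$well_id[layout$sample_kind == "blank"]
  if (length(bc_wells) == 0)
    stop("no blank-control wells in layout: assay invalid", call. = FALSE)
  exclusions <- list()
  bc_images <- list()
  for (wid in bc_wells) {
    for (i in seq_along(stacks[[wid]])) {
      v <- qc_image(stacks[[wid]][[i]], qcp, bit_depth = ip_bd)
      if (v$accepted) bc_images[[length(bc_images) + 1]] <-
          stacks[[wid]][[i]]
      else exclusions[[length(exclusions) + 1]] <- data.frame(
        well_id = wid, position_index = i,
        reason = if (v$artifact_flag) "artifact" else "defocus")
    }
  }
  if (length(bc_images) == 0)
    stop("all blank-control images rejected by QC: assay invalid",
         call. = FALSE)
  cutoff <- determine_cutoff(bc_images, config$target_fraction,
                             bit_depth = ip_bd)

  wr <- lapply(layout$well_id, function(wid)
    well_readout(stacks[[wid]], cutoff, qc = qcp, well_id = wid))
  names(wr) <- layout$well_id
  well_tab <- data.frame(
    well_id = layout$well_id,
    sample_id = layout$sample_id,
    sample_kind = layout$sample_kind,
    nominal_concentration_fM = layout$nominal_concentration_fM,
    images_total = vapply(wr, `[[`, numeric(1), "images_total"),
    images_accepted = vapply(wr, `[[`, numeric(1), "images_accepted"),
    pixel_count = vapply(wr, `[[`, numeric(1), "pixel_count"),
    valid = vapply(wr, `[[`, logical(1), "valid"))

  samples <- list()
  for (sid in unique(layout$sample_id)) {
    rows <- well_tab[well_tab$sample_id == sid & well_tab$valid, ]
    kind <- layout$sample_kind[layout$sample_id == sid][1]
    samples[[sid]] <- replicate_stats(
      rows$pixel_count, sample_id = sid,
      sample_kind = if (kind %in% c("standard", "iqc", "fecal",
                                    "blank")) kind else "fecal")
  }

  std_ids <- unique(layout$sample_id[layout$sample_kind == "standard"])
  bundle <- list(cutoff = cutoff, well_readouts = well_tab,
                 exclusion_log = if (length(exclusions))
                   do.call(rbind, exclusions) else NULL,
                 provenance = provenance(config))
  bc_counts <- samples[["BC"]]$replicate_pixel_counts %||%
    well_tab$pixel_count[well_tab$sample_kind == "blank" &
                           well_tab$valid]
  if (length(std_ids) == 0) {
    bundle$status <- "no calibration"
    bundle$samples <- sample_table(samples, NULL, NULL, config)
    class(bundle) <- "results_bundle"
    return(bundle)
  }
  std_conc <- vapply(std_ids, function(sid)
    layout$nominal_concentration_fM[layout$sample_id == sid][1],
    numeric(1))
  o <- order(std_conc)
  pts <- select_calibration_points(samples[std_ids[o]], std_conc[o],
                                   bc_replicates = bc_counts,
                                   alpha = config$alpha)
  curve <- fit_calibration(pts, alpha = config$alpha)
  lod <- compute_lod(bc_counts, curve)
  curve$lod <- lod
  bundle$calibration <- curve
  bundle$lod <- lod
  bundle$status <- "calibrated"
  bundle$samples <- sample_table(samples, curve, lod, config)
  class(bundle) <- "results_bundle"

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(well_tab, file.path(config$output_dir, "well_readouts.csv"),
            row.names = FALSE)
  write.csv(bundle$samples,
            file.path(config$output_dir, "sample_concentrations.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(slope = curve$slope, intercept = curve$intercept,
         r_squared = curve$r_squared, alpha = curve$alpha,
         included_points =
           pts$nominal_concentration_fM[pts$included],
         lod_pixel = lod$lod_pixel, lod_fM = lod$lod_fM,
         provenance = bundle$provenance),
    file.path(config$output_dir, "calibration.json"),
    auto_unbox = TRUE, digits = NA)
  bundle
}

# per-sample summary with calibrated concentrations
sample_table <- function(samples, curve, lod, config) {
  rows <- lapply(samples, function(s) {
    conc <- NA_real_; below_lod <- NA
    if (!is.null(curve) && !is.na(s$mean)) {
      conc <- as.numeric(pixel_to_concentration(s$mean, curve))
      below_lod <- !is.null(lod) && !is.na(lod$lod_fM) &&
        conc < lod$lod_fM
      if (s$sample_kind == "fecal")
        conc <- conc * config$fecal_dilution_factor
    }
    data.frame(sample_id = s$sample_id, sample_kind = s$sample_kind,
               n_replicates = s$n_replicates,
               pixel_count_mean = s$mean, pixel_count_sd = s$sd,
               cv_percent = s$cv_percent, cv_pass = s$cv_pass,
               concentration_fM = conc, below_lod = below_lod)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("sFIDA results bundle: status =", x$status, "\n")
  if (!is.null(x$cutoff)) print(x$cutoff)
  if (!is.null(x$calibration)) print(x$calibration)
  cat(nrow(x$samples), "samples;",
      sum(!is.na(x$samples$concentration_fM)), "calibrated\n")
  invisible(x)
}

#' Cohort statistics stage
#'
#' Runs the proof-of-concept statistical layer on a cohort table:
#' normality screening of the calibrated concentrations, two-group
#' Mann-Whitney comparison, Spearman covariate correlations, and ROC
#' analysis with the Youden-optimal operating point. Samples without a
#' concentration are excluded with a logged count.
#'
#' @param config an [sfida_config()] object (`cohort_csv` must exist),
#'   or pass `cohort` directly.
#' @param cohort optional in-memory cohort `data.frame` with `group` and
#'   `concentration_fM`.
#' @param covariates covariate columns for [covariate_correlations()].
#' @return A list of class `cohort_results`: `normality`, `comparison`,
#'   `correlations`, `roc`, `n_excluded`, `provenance`.
#' @export
run_cohort <- function(config = sfida_config(), cohort = NULL,
                       covariates = c("bristol", "age")) {
  tab <- cohort %||% read.csv(config$cohort_csv,
                              stringsAsFactors = FALSE)
  n0 <- nrow(tab)
  tab <- tab[is.finite(tab$concentration_fM), ]
  if (length(unique(tab$group)) < 2)
    stop("cohort table must contain both groups", call. = FALSE)
  covariates <- intersect(covariates, names(tab))
  res <- structure(list(
    normality = normality_suite(tab$concentration_fM),
    comparison = compare_groups(tab),
    correlations = covariate_correlations(tab, covariates),
    roc = roc_youden(tab),
    n_excluded = n0 - nrow(tab),
    provenance = provenance(config)
  ), class = "cohort_results")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(res$roc$curve, file.path(config$output_dir,
                                     "roc_curve.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(p_value = res$comparison$p_value,
         u_statistic = res$comparison$u_statistic,
         auc = res$roc$auc,
         sensitivity = res$roc$sens_at_youden,
         specificity = res$roc$spec_at_youden,
         youden_threshold_fM = res$roc$youden_threshold,
         non_normal = res$normality$non_normal,
         n_excluded = res$n_excluded,
         provenance = res$provenance),
    file.path(config$output_dir, "cohort_stats.json"),
    auto_unbox = TRUE, digits = NA)
  res
}

#' @export
print.cohort_results <- function(x, ...) {
  print(x$comparison)
  print(x$roc)
  if (x$n_excluded > 0)
    cat(x$n_excluded, "samples excluded (missing concentration)\n")
  invisible(x)
}

#' Full pipeline: simulate, analyze, cohort
#'
#' @param config an [sfida_config()] object.
#' @param ... passed to [run_simulate()].
#' @return List with `simulate`, `analyze`, `cohort` stage results.
#' @export
run_all <- function(config = sfida_config(), ...) {
  sim <- run_simulate(config, ...)
  ana <- run_analyze(config)
  coh <- run_cohort(config)
  invisible(list(simulate = sim, analyze = ana, cohort = coh))
}
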