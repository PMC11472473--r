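test_that("calibration-point inclusion uses the exact one-sided U test", {
  bc <- c(10, 11, 12, 13)
  good <- list(replicate_stats(c(30, 31, 32, 33), "hi", "standard"),
               replicate_stats(bc + 0.5, "null", "standard"))

  # fully separated 4-vs-4: exact one-sided p = 1/70
  pts <- select_calibration_points(
    list(good[[1]]), concentrations = 100, bc_replicates = bc)
  expect_equal(pts$inclusion_pvalue, 1 / 70, tolerance = 1e-12)
  expect_true(pts$included)

  # a standard indistinguishable from BC is excluded
  pts2 <- select_calibration_points(
    list(replicate_stats(c(10.5, 11.5, 12.5, 13.5), "low", "standard"),
         good[[1]]),
    concentrations = c(1, 100), bc_replicates = bc)
  expect_false(pts2$included[1])
  expect_gte(pts2$inclusion_pvalue[1], 0.05)
  expect_true(pts2$included[2])

  # all points excluded aborts calibration
  expect_error(select_calibration_points(
    list(replicate_stats(bc, "null", "standard")),
    concentrations = 1, bc_replicates = bc), "no calibration point")

  expect_error(select_calibration_points(
    list(good[[1]]), concentrations = 1, bc_replicates = c(1, 2)),
    ">= 4")
})

test_that("raising alpha never removes an included point", {
  bc <- c(5, 8, 11, 14)
  set.seed(71)
  standards <- lapply(c(2, 10, 50, 250), function(conc)
    replicate_stats(conc * 2 + rnorm(4, 0, 3), sample_kind = "standard"))
  conc <- c(2, 10, 50, 250)
  inc <- lapply(c(0.01, 0.05, 0.1, 0.25), function(a)
    tryCatch(select_calibration_points(standards, conc, bc, alpha = a)$included,
             error = function(e) rep(FALSE, 4)))
  for (i in seq_len(length(inc) - 1))
    expect_true(all(inc[[i + 1]] | !inc[[i]]))
})

test_that("the linear-range rule trims saturating top points", {
  bc <- c(1, 2, 3, 4)
  conc <- c(10, 50, 250, 1250, 6250)
  mean_pc <- c(100, 500, 2500, 12500, 20000)  # top point rolls off
  standards <- lapply(mean_pc, function(m)
    replicate_stats(m + c(-2, -1, 1, 2), sample_kind = "standard"))
  pts <- select_calibration_points(standards, conc, bc)
  expect_true(all(pts$significant))
  expect_false(pts$in_linear_range[5])
  expect_true(all(pts$in_linear_range[1:4]))
  expect_equal(pts$included, c(TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("weighted fits reproduce the closed-form normal equations", {
  # exact proportional points: slope 10, intercept 0 regardless of weights
  pts <- data.frame(nominal_concentration_fM = c(1, 2, 4),
                    mean_pixel_count = c(10, 20, 40))
  fit <- fit_calibration(pts)
  expect_equal(fit$slope, 10, tolerance = 1e-10)
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)

  # noisy points: coefficients equal the direct 2x2 weighted solve
  x <- c(1, 5, 25); y <- c(14, 48, 260)
  w <- 1 / y
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  slope_cf <- (sw * sxy - sx * sy) / (sw * sxx - sx^2)
  int_cf <- (sy - slope_cf * sx) / sw
  fit2 <- fit_calibration(data.frame(nominal_concentration_fM = x,
                                     mean_pixel_count = y))
  expect_equal(fit2$slope, slope_cf, tolerance = 1e-10)
  expect_equal(fit2$intercept, int_cf, tolerance = 1e-10)

  # 1/y weighting down-weights high-readout points: moving the top point
  # perturbs the weighted fit less than the unweighted one
  y3 <- c(14, 48, 520)
  wfit <- fit_calibration(data.frame(nominal_concentration_fM = x,
                                     mean_pixel_count = y3))
  ufit <- lm(y3 ~ x)
  wfit0 <- fit_calibration(data.frame(nominal_concentration_fM = x,
                                      mean_pixel_count = y))
  ufit0 <- lm(y ~ x)
  expect_lt(abs(wfit$slope - wfit0$slope),
            abs(coef(ufit)[2] - coef(ufit0)[2]))

  expect_error(fit_calibration(data.frame(
    nominal_concentration_fM = c(1, 1),
    mean_pixel_count = c(5, 6))), "singular")
})

test_that("concentration conversion inverts the curve and clamps at zero", {
  curve <- structure(list(slope = 10, intercept = 5),
                     class = "sfida_calibration")
  expect_equal(as.numeric(pixel_to_concentration(25, curve)), 2)
  expect_equal(as.numeric(pixel_to_concentration(5, curve)), 0)
  below <- pixel_to_concentration(2, curve)
  expect_equal(as.numeric(below), 0)
  expect_true(attr(below, "below_blank"))

  # round trip concentration -> pixels -> concentration
  conc <- c(0.5, 3, 120)
  px <- predict(curve, conc, type = "pixel_count")
  expect_equal(as.numeric(pixel_to_concentration(px, curve)), conc,
               tolerance = 1e-12)

  # strictly increasing in pixel count for positive slope
  pc <- seq(0, 1000, by = 50)
  cc <- pixel_to_concentration(pc, curve, clamp = FALSE)
  expect_true(all(diff(cc) > 0))

  bad <- structure(list(slope = -1, intercept = 0),
                   class = "sfida_calibration")
  expect_error(pixel_to_concentration(10, bad), "slope")
})

test_that("the LoD is the blank mean plus twice the blank SD", {
  bc <- c(40, 50, 60, 50)  # mean 50, sd 8.165
  lod <- compute_lod(bc)
  expect_equal(lod$lod_pixel, 50 + 2 * sd(bc))
  expect_equal(compute_lod(c(50, 50, 50))$lod_pixel, 50)  # SD 0

  # adding a constant to every BC readout shifts the LoD by that constant
  lod2 <- compute_lod(bc + 123)
  expect_equal(lod2$lod_pixel, lod$lod_pixel + 123)

  curve <- structure(list(slope = 20, intercept = 50),
                     class = "sfida_calibration")
  expect_equal(compute_lod(bc, curve)$lod_fM, 2 * sd(bc) / 20)
  expect_error(compute_lod(50), ">= 2")
})

test_that("fitted slopes recover the generative slope on synthetic plates", {
  # 12 simulated plates against an independent Monte-Carlo estimate of
  # the generative pixel-count-per-fM rate (high-standard wells vs
  # blanks); the acceptance suite runs the full 50-plate version
  concs <- c(25, 125, 625, 3125)
  lay <- plate_layout(standard_concentrations = concs,
                      n_blank_wells = 6, iqc = FALSE)
  fit_one <- function(seed) {
    plate <- gen_calibration_plate(small_params(seed = seed), lay,
                                   spots_per_fM = 0.016)
    res <- plate_pixel_counts(plate)
    pc <- res$pixel_counts
    bc <- pc[lay$well_id[lay$sample_kind == "blank"]]
    srs <- lapply(paste0("STD_", concs), function(sid)
      replicate_stats(pc[lay$well_id[lay$sample_id == sid]], sid,
                      "standard"))
    fit_calibration(select_calibration_points(srs, concs, bc))$slope
  }
  slopes <- vapply(1:12, fit_one, numeric(1))

  lay2 <- plate_layout(standard_concentrations = 3125,
                       n_blank_wells = 20, iqc = FALSE, replicates = 20)
  plate2 <- gen_calibration_plate(small_params(seed = 999), lay2,
                                  spots_per_fM = 0.016)
  pc2 <- plate_pixel_counts(plate2)$pixel_counts
  oracle <- (mean(pc2[lay2$well_id[lay2$sample_kind == "standard"]]) -
             mean(pc2[lay2$well_id[lay2$sample_kind == "blank"]])) / 3125
  expect_lt(abs(mean(slopes) - oracle) / oracle, 0.10)
})
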