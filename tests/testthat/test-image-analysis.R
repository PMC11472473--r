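test_that("image QC accepts clean fields and flags both corruption modes", {
  p <- small_params(seed = 13)
  expect_true(qc_image(gen_blank_image(p, 1))$accepted)
  expect_true(qc_image(gen_spot_image(p, 40, index = 2)$image)$accepted)

  art <- qc_image(gen_corrupted_image(p, "artifact", index = 3))
  expect_true(art$artifact_flag)
  expect_gte(art$saturated_fraction, 0.005)  # > default 0.001 threshold
  expect_false(art$accepted)

  def <- qc_image(gen_corrupted_image(p, "defocus", index = 4))
  expect_true(def$defocus_flag)
  expect_false(def$accepted)

  expect_error(qc_image(matrix(numeric(0), 0, 0)), "empty")
})

test_that("QC detects at least 95% of corrupted images", {
  p <- small_params(seed = 17)
  detected <- 0
  for (i in 1:100) {
    mode <- if (i %% 2) "artifact" else "defocus"
    v <- qc_image(gen_corrupted_image(p, mode, index = i))
    detected <- detected + !v$accepted
  }
  expect_gte(detected / 100, 0.95)
})

test_that("cutoff determination matches the rule and the exhaustive oracle", {
  # constant blank: smallest cutoff with nothing above is the constant
  const <- matrix(100L, 50, 50)
  co <- determine_cutoff(const)
  expect_equal(co$cutoff, 100)
  expect_equal(co$positive_fraction_at_cutoff, 0)

  # exhaustive integer scan on randomized small images with mixed
  # distributions and random target fractions; any candidate at or above
  # max(px) trivially qualifies, so scanning 0..max(px) covers all 0..16383
  oracle_scan <- function(px, target) {
    frac_above <- vapply(0:max(px), function(cc) mean(px > cc),
                         numeric(1))
    (which(frac_above <= target)[1]) - 1L
  }
  set.seed(404)
  for (rep in 1:1000) {
    n <- sample(50:400, 1)
    px <- switch(sample(3, 1),
      as.integer(round(pmin(pmax(rnorm(n, 500, 50), 0), 2047))),
      as.integer(sample(0:2000, n, replace = TRUE)),
      as.integer(round(pmin(rlnorm(n, 6, 1), 2047))))
    target <- sample(c(1e-5, 1e-3, 0.01, 0.1), 1)
    img <- matrix(px, nrow = 1)
    co <- determine_cutoff(img, target)
    expect_identical(co$cutoff, oracle_scan(px, target))
    expect_lte(mean(px > co$cutoff), target)
  }
})

test_that("lowering the target fraction never lowers the cutoff", {
  p <- small_params(seed = 19)
  imgs <- lapply(1:4, function(i) gen_blank_image(p, i))
  cuts <- vapply(c(0.1, 0.01, 1e-3, 1e-4, 1e-5),
                 function(tf) determine_cutoff(imgs, tf)$cutoff,
                 integer(1))
  expect_true(all(diff(cuts) >= 0))
})

test_that("cutoff requires blank images and a valid target", {
  expect_error(determine_cutoff(list()), "assay invalid")
  expect_error(determine_cutoff(matrix(1L, 2, 2), target_fraction = 0),
               "target_fraction")
})

test_that("pixel counting is a strict threshold count", {
  expect_equal(pixel_count(matrix(0L, 10, 10), 0), 0)  # strict >
  img <- matrix(0L, 100, 100)
  img[sample(1e4, 37)] <- 5000L
  expect_equal(pixel_count(img, 1000), 37)
  expect_equal(pixel_count(img, 16383), 0)
  expect_error(pixel_count(img, 20000), "bit-depth")

  # permutation invariance and additivity over disjoint partitions
  p <- small_params(seed = 23)
  im <- gen_spot_image(p, 30, 1)$image
  cut <- 600
  perm <- matrix(sample(as.vector(im)), nrow(im))
  expect_equal(pixel_count(perm, cut), pixel_count(im, cut))
  halves <- pixel_count(im[1:60, ], cut) + pixel_count(im[61:120, ], cut)
  expect_equal(halves, pixel_count(im, cut))
})

test_that("well readouts rescale to the nominal image number", {
  # 25 accepted images with 4 positive pixels each sum to 100
  imgs <- replicate(25, {
    m <- matrix(0L, 20, 20); m[1:4] <- 5000L; m
  }, simplify = FALSE)
  wr <- well_readout(imgs, cutoff = 100, qc = NULL)
  expect_equal(wr$pixel_count, 100)
  expect_equal(wr$raw_pixel_count, wr$pixel_count)  # all accepted

  # 20 of 25 accepted with raw sum 80 rescales to 100; equals
  # mean-per-accepted-image times the nominal 25
  p <- small_params(seed = 29, images_per_well = 25)
  imgs2 <- c(replicate(5, gen_corrupted_image(p, "artifact", index = 1),
                       simplify = FALSE),
             replicate(20, {
               m <- matrix(0L, 120, 120); m[1:4] <- 5000L; m
             }, simplify = FALSE))
  wr2 <- well_readout(imgs2, cutoff = 100, qc = qc_params())
  expect_equal(wr2$images_accepted, 20)
  expect_equal(wr2$raw_pixel_count, 80)
  expect_equal(wr2$pixel_count, 80 * 25 / 20)
  expect_equal(wr2$pixel_count, (wr2$raw_pixel_count / 20) * 25)
  expect_true(wr2$valid)  # 80% accepted

  # under 60% accepted flags the well invalid; zero accepted is not zero
  imgs3 <- c(replicate(15, gen_corrupted_image(p, "artifact", index = 2),
                       simplify = FALSE), imgs2[6:15])
  wr3 <- well_readout(imgs3, cutoff = 100, qc = qc_params())
  expect_false(wr3$valid)
  wr4 <- well_readout(imgs3[1:15], cutoff = 100, qc = qc_params())
  expect_false(wr4$valid)
  expect_true(is.na(wr4$pixel_count))
})

test_that("replicate statistics use the n-1 SD and kind-specific CV gates", {
  s <- replicate_stats(c(90, 100, 110, 100), "S1", "fecal")
  expect_equal(s$mean, 100)
  expect_equal(s$sd, sqrt(200 / 3), tolerance = 1e-12)  # 8.165
  expect_equal(s$cv_percent, 100 * sqrt(200 / 3) / 100,
               tolerance = 1e-12)
  expect_true(s$cv_pass)

  expect_equal(replicate_stats(rep(50, 4))$cv_percent, 0)

  # CV 24%: passes the 25% fecal gate, fails the 20% standard gate
  x <- c(76, 100, 124, 100)  # CV = 19.6 -- construct exactly 24 instead
  x <- 100 + c(-1, 1, -1, 1) * 24 / sqrt(4 / 3)
  expect_equal(100 * sd(x) / mean(x), 24, tolerance = 1e-9)
  expect_true(replicate_stats(x, sample_kind = "fecal")$cv_pass)
  expect_false(replicate_stats(x, sample_kind = "standard")$cv_pass)
  expect_false(replicate_stats(x, sample_kind = "iqc")$cv_pass)

  # fewer than 2 valid replicates is flagged unreliable
  expect_false(replicate_stats(42)$reliable)
})

test_that("blank wells stay at the cutoff target rate end to end", {
  p <- small_params(seed = 37, image_height = 200, image_width = 200,
                    images_per_well = 5)
  lay <- plate_layout(standard_concentrations = numeric(),
                      n_blank_wells = 12, iqc = FALSE)
  plate <- gen_calibration_plate(p, lay)
  res <- plate_pixel_counts(plate, target_fraction = 1e-3)
  n_px_well <- 5 * 200 * 200
  bound <- 1e-3 * n_px_well * (1 + 5 / sqrt(12))
  expect_lte(mean(res$pixel_counts), bound)
})
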