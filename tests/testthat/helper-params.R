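# Scaled-down imaging parameters shared across tests: same noise model and
# bit depth as the full acquisition geometry, smaller frames so suites stay
# fast. Seeds are fixed per test at the call site.
small_params <- function(seed = 1L, ...) {
  args <- modifyList(list(image_height = 120, image_width = 120,
                          images_per_well = 4, seed = seed), list(...))
  do.call(imaging_params, args)
}

# Analyze an in-memory plate (no QC) down to per-well pixel counts.
plate_pixel_counts <- function(plate, target_fraction = 1e-5) {
  lay <- plate$layout
  bc <- unlist(lapply(lay$well_id[lay$sample_kind == "blank"],
                      function(w) plate$images[[w]]), recursive = FALSE)
  cutoff <- determine_cutoff(bc, target_fraction)
  pc <- vapply(lay$well_id, function(w)
    well_readout(plate$images[[w]], cutoff, qc = NULL,
                 well_id = w)$pixel_count, numeric(1))
  list(cutoff = cutoff, pixel_counts = setNames(pc, lay$well_id))
}

# Brute-force ROC oracle: scan every candidate threshold (all observed
# values plus midpoints and +/-Inf), compute sens/spec directly, report the
# maximal Youden J and the trapezoidal AUC from scratch.
roc_brute_force <- function(pos, neg) {
  vals <- sort(unique(c(pos, neg)))
  thr <- sort(unique(c(-Inf, vals, vals - 1e-9,
                       (head(vals, -1) + tail(vals, -1)) / 2, Inf)))
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  fpr <- 1 - spec
  o <- order(fpr, sens)
  auc <- sum(diff(fpr[o]) * (head(sens[o], -1) + tail(sens[o], -1)) / 2)
  list(max_j = max(j), auc = auc,
       sens = 100 * sens, spec = 100 * spec, thresholds = thr)
}

# Tie-corrected Mann-Whitney U (midranks), computed from first principles.
u_statistic <- function(pos, neg) {
  r <- rank(c(pos, neg))
  sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
}
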