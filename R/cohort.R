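#' Normality screening battery
#'
#' Runs the four normality tests used to decide between parametric and
#' non-parametric downstream analysis: Shapiro-Wilk, Lilliefors
#' (Kolmogorov-Smirnov with estimated parameters), plain
#' Kolmogorov-Smirnov against the sample-moment normal, and
#' Anderson-Darling. The data are flagged non-normal — routing the
#' pipeline to rank-based tests — when any p-value falls below `alpha`.
#'
#' @param values numeric vector (n >= 4; Shapiro-Wilk requires n >= 3,
#'   Anderson-Darling n >= 8 — tests that cannot run return NA).
#' @param alpha flagging level (default 0.05).
#' @return A list of class `normality_suite`: `table` (test, statistic,
#'   p_value) and `non_normal` flag.
#' @export
normality_suite <- function(values, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 4) stop_param("need >= 4 observations")
  if (sd(values) == 0) {
    tab <- data.frame(test = c("shapiro_wilk", "lilliefors",
                               "kolmogorov_smirnov", "anderson_darling"),
                      statistic = NA_real_, p_value = NA_real_)
    return(structure(list(table = tab, non_normal = TRUE,
                          note = "constant input"),
                     class = "normality_suite"))
  }
  run <- function(f) tryCatch({
    r <- suppressWarnings(f())
    c(unname(r$statistic), r$p.value)
  }, error = function(e) c(NA_real_, NA_real_))
  sw <- run(function() shapiro.test(values))
  li <- run(function() nortest::lillie.test(values))
  ks <- run(function() ks.test(values, "pnorm", mean(values),
                               sd(values)))
  ad <- run(function() nortest::ad.test(values))
  tab <- data.frame(
    test = c("shapiro_wilk", "lilliefors", "kolmogorov_smirnov",
             "anderson_darling"),
    statistic = c(sw[1], li[1], ks[1], ad[1]),
    p_value = c(sw[2], li[2], ks[2], ad[2]))
  structure(list(table = tab,
                 non_normal = any(tab$p_value < alpha, na.rm = TRUE),
                 alpha = alpha),
            class = "normality_suite")
}

#' @export
print.normality_suite <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(if (x$non_normal) "=> non-normal: use non-parametric tests\n"
      else "=> no evidence against normality\n")
  invisible(x)
}

#' Two-group Mann-Whitney comparison
#'
#' Compares calibrated concentrations between the disease (AD) and
#' control (HC) groups with a Mann-Whitney U test (midrank ties; exact
#' null distribution when both groups have at most 8 observations and no
#' ties, tie-corrected normal approximation otherwise). Two-sided by
#' default.
#'
#' @param table cohort `data.frame` with columns `group` and
#'   `concentration_fM` (a [gen_cohort()] table works directly), or a
#'   numeric vector for the first group.
#' @param y second-group numeric vector when `table` is numeric.
#' @param alternative test sidedness (default `"two.sided"`).
#' @return A list of class `group_comparison`: `u_statistic`, `p_value`,
#'   `n_ad`, `n_hc`, `median_ad`, `median_hc`, `alternative`.
#' @export
compare_groups <- function(table, y = NULL,
                           alternative = "two.sided") {
  if (is.numeric(table)) {
    ad <- table; hc <- y
  } else {
    ad <- table$concentration_fM[table$group == "AD"]
    hc <- table$concentration_fM[table$group == "HC"]
  }
  if (length(ad) == 0 || length(hc) == 0)
    stop("both groups must be nonempty", call. = FALSE)
  exact <- length(ad) <= 8 && length(hc) <= 8 &&
    !anyDuplicated(c(ad, hc))
  wt <- suppressWarnings(
    wilcox.test(ad, hc, alternative = alternative, exact = exact))
  structure(list(
    u_statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_ad = length(ad), n_hc = length(hc),
    median_ad = median(ad), median_hc = median(hc),
    alternative = alternative
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U = %.1f (n = %d vs %d), %s p = %.3g\n",
    x$u_statistic, x$n_ad, x$n_hc, x$alternative, x$p_value))
  cat(sprintf("medians: AD %.3g, HC %.3g\n", x$median_ad, x$median_hc))
  invisible(x)
}

#' Spearman correlations of concentration with covariates
#'
#' Rank correlation of the calibrated concentration with each requested
#' covariate (stool-consistency score, age, matrix biomarkers, ...),
#' overall and optionally within each diagnostic group. Missing values
#' are dropped pairwise; a covariate with fewer than `min_n` complete
#' pairs is skipped with a warning.
#'
#' @param table cohort `data.frame` with `concentration_fM`, `group`,
#'   and the covariate columns.
#' @param variables character vector of covariate column names.
#' @param by_group also compute per-group correlations (default TRUE).
#' @param min_n minimum complete pairs (default 5).
#' @return A `data.frame`: `variable`, `subset`, `spearman_rho`,
#'   `p_value`, `n`.
#' @export
covariate_correlations <- function(table, variables,
                                   by_group = TRUE, min_n = 5) {
  subsets <- list(all = rep(TRUE, nrow(table)))
  if (by_group && !is.null(table$group))
    for (g in unique(table$group)) subsets[[g]] <- table$group == g
  rows <- list()
  for (v in variables) {
    if (is.null(table[[v]]) || all(is.na(table[[v]]))) {
      warning("covariate '", v, "' missing: skipped", call. = FALSE)
      next
    }
    for (s in names(subsets)) {
      keep <- subsets[[s]] & is.finite(table$concentration_fM) &
        is.finite(suppressWarnings(as.numeric(table[[v]])))
      n <- sum(keep)
      if (n < min_n) next
      ct <- suppressWarnings(cor.test(
        table$concentration_fM[keep], as.numeric(table[[v]][keep]),
        method = "spearman"))
      rows[[length(rows) + 1]] <- data.frame(
        variable = v, subset = s,
        spearman_rho = unname(ct$estimate),
        p_value = ct$p.value, n = n)
    }
  }
  if (!length(rows)) return(data.frame(
    variable = character(), subset = character(),
    spearman_rho = numeric(), p_value = numeric(), n = integer()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' ROC analysis with Youden-optimal operating point
#'
#' Builds the full ROC curve for discriminating the disease group (AD,
#' positive class, elevated concentrations) from controls with the
#' decision rule "concentration >= threshold => AD". Candidate thresholds
#' are the midpoints between consecutive distinct concentrations plus
#' -Inf and +Inf. The AUC is the trapezoidal area, which equals the
#' tie-corrected Mann-Whitney statistic U/(n_AD * n_HC); the reported
#' operating point maximizes Youden's J = sensitivity + specificity - 1,
#' ties broken toward higher specificity.
#'
#' @param table cohort `data.frame` with `group` and `concentration_fM`,
#'   or a numeric vector of positive-class values.
#' @param controls numeric vector of control values when `table` is
#'   numeric.
#' @return An object of class `sfida_roc`: `curve` (threshold,
#'   sensitivity, specificity as %), `auc`, `youden_threshold`,
#'   `youden_j`, `sens_at_youden`, `spec_at_youden`, `n_ad`, `n_hc`,
#'   `degenerate`.
#' @examples
#' roc <- roc_youden(c(3, 4, 5), c(1, 2))
#' roc$auc  # 1
#' @export
roc_youden <- function(table, controls = NULL) {
  if (is.numeric(table)) {
    pos <- table; neg <- controls
  } else {
    pos <- table$concentration_fM[table$group == "AD"]
    neg <- table$concentration_fM[table$group == "HC"]
  }
  if (length(pos) == 0 || length(neg) == 0)
    stop("both groups must be nonempty", call. = FALSE)
  all_v <- sort(unique(c(pos, neg)))
  thr <- if (length(all_v) > 1)
    c(-Inf, (head(all_v, -1) + tail(all_v, -1)) / 2, Inf) else
    c(-Inf, Inf)
  sens <- vapply(thr, function(t) 100 * mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) 100 * mean(neg < t), numeric(1))
  # trapezoid over (FPR, TPR), curve ordered from (1,1) to (0,0)
  fpr <- (100 - spec) / 100; tpr <- sens / 100
  o <- order(fpr, tpr)
  auc <- sum(diff(fpr[o]) * (head(tpr[o], -1) + tail(tpr[o], -1)) / 2)
  j <- (sens + spec) / 100 - 1
  degenerate <- length(all_v) == 1
  # maximal J; among ties prefer higher specificity (higher threshold)
  best <- which(j == max(j))
  best <- best[which.max(spec[best])]
  structure(list(
    curve = data.frame(threshold = thr, sensitivity = sens,
                       specificity = spec),
    auc = auc,
    youden_threshold = thr[best],
    youden_j = j[best],
    sens_at_youden = sens[best],
    spec_at_youden = spec[best],
    n_ad = length(pos), n_hc = length(neg),
    degenerate = degenerate
  ), class = "sfida_roc")
}

#' @export
print.sfida_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (n = %d positive vs %d control)\n",
              x$auc, x$n_ad, x$n_hc))
  if (x$degenerate)
    cat("degenerate: all values identical, no meaningful threshold\n")
  else
    cat(sprintf(
      "Youden-optimal threshold %.4g: sensitivity %.1f%%, specificity %.1f%% (J = %.3f)\n",
      x$youden_threshold, x$sens_at_youden, x$spec_at_youden,
      x$youden_j))
  invisible(x)
}

#' @export
plot.sfida_roc <- function(x, ...) {
  plot(100 - x$curve$specificity, x$curve$sensitivity, type = "s",
       xlab = "100 - specificity [%]", ylab = "sensitivity [%]",
       xlim = c(0, 100), ylim = c(0, 100), ...)
  abline(0, 1, lty = 3)
  i <- which(x$curve$threshold == x$youden_threshold)
  points(100 - x$curve$specificity[i], x$curve$sensitivity[i],
         pch = 19, col = 2)
  invisible(x)
}

#' @export
auc <- function(x, ...) UseMethod("auc")

#' @export
auc.sfida_roc <- function(x, ...) x$auc
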