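#' Normality-gated test choice for paired differences
#'
#' Shapiro–Wilk on the pair differences decides the test: p >= `alpha`
#' keeps the paired t-test, otherwise the Wilcoxon signed-rank test. All
#' differences identical (zero variance) degenerates to Wilcoxon with a
#' warning.
#'
#' @param differences numeric vector of pair differences (n >= 3).
#' @param alpha Shapiro–Wilk gate level (default 0.05).
#' @return `"paired-t"` or `"wilcoxon"`.
#' @export
normality_gate <- function(differences, alpha = 0.05) {
  if (length(differences) < 3) stop("need at least 3 pairs")
  if (sd(differences) == 0) {
    warning("all differences identical; falling back to Wilcoxon (degenerate)")
    return("wilcoxon")
  }
  if (shapiro.test(differences)$p.value >= alpha) "paired-t" else "wilcoxon"
}

# Z statistic of the signed-rank test: normal approximation with
# continuity and tie correction for n >= 10, from the exact two-sided p
# below that.
wilcoxon_z <- function(d) {
  dz <- d[d != 0]
  m <- length(dz)
  if (m == 0) return(list(z = 0, p = 1, statistic = NA_real_))
  rk <- rank(abs(dz))
  v <- sum(rk[dz > 0])
  if (m >= 10) {
    mu <- m * (m + 1) / 4
    ties <- table(rk)
    sig2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(v - mu) * 0.5
    z <- (v - mu - cc) / sqrt(sig2)
    p <- 2 * pnorm(-abs(z))
    p <- min(1, p)
  } else {
    p <- suppressWarnings(wilcox.test(dz, exact = TRUE)$p.value)
    z <- sign(v - m * (m + 1) / 4) * qnorm(1 - p / 2)
  }
  list(z = z, p = p, statistic = v)
}

#' Paired comparison with gated test and effect size
#'
#' Computes x - y differences, chooses the test via [normality_gate()],
#' and reports the matching effect size: Cohen's d = mean(d)/SD(d) for
#' the paired t-test, r = |Z|/sqrt(n) for Wilcoxon (n = pair count).
#' All-zero differences return the degenerate "no effect" result (p = 1);
#' a nonzero constant difference (zero variance, nonzero shift) is an
#' error, since neither test statistic is defined.
#'
#' @param x,y paired numeric vectors (equal length >= 3 after NA
#'   removal).
#' @param alpha gate level passed to [normality_gate()].
#' @param metric optional metric label carried into the result.
#' @return Object of class `paired_comparison`: list with `metric`,
#'   `test_used`, `statistic`, `p`, `effect_size`, `effect_type`,
#'   `n_pairs`.
#' @export
paired_compare <- function(x, y, alpha = 0.05, metric = NA_character_) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  d <- x - y
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(structure(list(metric = metric, test_used = "degenerate",
                            statistic = 0, p = 1, effect_size = 0,
                            effect_type = "cohen_d", n_pairs = length(d)),
                       class = "paired_comparison"))
    }
    stop("zero-variance nonzero differences: paired test undefined")
  }
  test <- suppressWarnings(normality_gate(d, alpha))
  if (test == "paired-t") {
    tt <- t.test(x, y, paired = TRUE)
    out <- list(metric = metric, test_used = "paired-t",
                statistic = unname(tt$statistic), p = tt$p.value,
                effect_size = mean(d) / sd(d), effect_type = "cohen_d",
                n_pairs = length(d))
  } else {
    wz <- wilcoxon_z(d)
    out <- list(metric = metric, test_used = "wilcoxon",
                statistic = wz$statistic, p = wz$p,
                effect_size = abs(wz$z) / sqrt(length(d)),
                effect_type = "wilcoxon_r", n_pairs = length(d))
  }
  structure(out, class = "paired_comparison")
}

#' @export
print.paired_comparison <- function(x, ...) {
  cat(sprintf("%s: %s, statistic %.3f, p = %.4g, %s = %.3f (n = %d)\n",
              x$metric %||% "comparison", x$test_used, x$statistic, x$p,
              x$effect_type, x$effect_size, x$n_pairs))
  invisible(x)
}

#' Bonferroni family threshold
#'
#' alpha/m, reported at full precision and rounded to 3 decimals (a
#' 3-metric x 2-approach family at alpha = 0.05 prints as 0.008).
#'
#' @param alpha familywise level.
#' @param m number of comparisons in the family (>= 1).
#' @return List with `threshold` and `threshold_3dp`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("family size m must be >= 1")
  thr <- alpha / m
  list(threshold = thr, threshold_3dp = round(thr, 3))
}

#' Dual-criterion positivity
#'
#' A finding is positive only when both the raw tumor comparison and the
#' control-subtracted comparison reach significance at the Bonferroni
#' family threshold alpha/m. The verdict is symmetric in the two
#' comparisons.
#'
#' @param raw,ctrl_sub `paired_comparison` objects for the raw and
#'   control-subtracted analyses of the same metric.
#' @param alpha familywise level.
#' @param m family size (metrics x 2 approaches).
#' @return Object of class `dual_criterion`: list with both comparisons,
#'   `m`, `threshold`, `positive`.
#' @export
dual_criterion <- function(raw, ctrl_sub, alpha = 0.05, m) {
  thr <- bonferroni_threshold(alpha, m)$threshold
  structure(list(raw = raw, control_subtracted = ctrl_sub, m = m,
                 threshold = thr,
                 positive = isTRUE(raw$p < thr) && isTRUE(ctrl_sub$p < thr)),
            class = "dual_criterion")
}

# canonical metric families: metrics x 2 analytical approaches
metric_families <- function() {
  list(activity = c("alff", "falff", "reho"),
       connectivity = c("mean_fc", "n_sig", "mean_dist_mm"),
       topology = c("degree_centrality", "betweenness_centrality",
                    "closeness_centrality", "clustering_coefficient"))
}

#' Cohort-level dual-criterion statistics
#'
#' Runs the full paired workflow on a long metric table: per metric, the
#' raw larger-vs-smaller comparison and the control-subtracted comparison
#' ((larger - larger_control) vs (smaller - smaller_control)), the
#' dual-criterion verdict at the family's Bonferroni threshold (family
#' size m = metrics present x 2 approaches: 6 for the activity and
#' connectivity families, 8 for topology), and — for every dual-positive
#' metric with covariates available — a mixed-effects confounder
#' adjustment via [fit_lmm()].
#'
#' @param metrics long tibble with columns `subject`, `seed_type`
#'   (`larger`, `smaller`, `larger_control`, `smaller_control`), `metric`,
#'   `value`, and optionally `volume`, `tsnr`, `n_networks`.
#' @param alpha familywise level (default 0.05).
#' @param families named list mapping family -> metric names (defaults to
#'   the three canonical families).
#' @param fit_lmm_for `"positive"` (default), `"all"` or `"none"`.
#' @return Object of class `cohort_stats`: `table` tibble (one row per
#'   metric with both p-values, tests, effect sizes, threshold, verdict),
#'   `lmm` named list of `glioma_lmm` fits, `alpha`, `families`.
#' @export
run_cohort_stats <- function(metrics, alpha = 0.05,
                             families = metric_families(),
                             fit_lmm_for = c("positive", "all", "none")) {
  fit_lmm_for <- match.arg(fit_lmm_for)
  stopifnot(all(c("subject", "seed_type", "metric", "value") %in%
                  names(metrics)))
  wide <- metrics |>
    dplyr::select("subject", "seed_type", "metric", "value") |>
    tidyr::pivot_wider(names_from = "seed_type", values_from = "value")
  rows <- list()
  lmms <- list()
  for (fam in names(families)) {
    fam_metrics <- intersect(families[[fam]], unique(metrics$metric))
    if (length(fam_metrics) == 0) next
    m <- 2L * length(fam_metrics)
    thr <- bonferroni_threshold(alpha, m)$threshold
    for (mt in fam_metrics) {
      w <- wide[wide$metric == mt, ]
      raw <- try_paired(w$larger, w$smaller, mt)
      cs <- try_paired(w$larger - w$larger_control,
                       w$smaller - w$smaller_control, mt)
      dc <- if (!is.null(raw) && !is.null(cs)) {
        dual_criterion(raw, cs, alpha, m)
      } else {
        NULL
      }
      positive <- isTRUE(dc$positive)
      if (fit_lmm_for == "all" ||
          (fit_lmm_for == "positive" && positive)) {
        lmm_dat <- metrics[metrics$metric == mt &
                             metrics$seed_type %in% c("larger", "smaller"), ]
        if (all(c("volume", "tsnr", "n_networks") %in% names(lmm_dat))) {
          lmms[[mt]] <- fit_lmm(lmm_dat)
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        family = fam, metric = mt, m = m, threshold = thr,
        test_raw = raw$test_used %||% NA_character_,
        p_raw = raw$p %||% NA_real_,
        effect_raw = raw$effect_size %||% NA_real_,
        effect_type_raw = raw$effect_type %||% NA_character_,
        test_ctrl = cs$test_used %||% NA_character_,
        p_ctrl = cs$p %||% NA_real_,
        effect_ctrl = cs$effect_size %||% NA_real_,
        effect_type_ctrl = cs$effect_type %||% NA_character_,
        n_pairs = raw$n_pairs %||% NA_integer_,
        positive = positive)
    }
  }
  structure(list(table = dplyr::bind_rows(rows), lmm = lmms, alpha = alpha,
                 families = lapply(families, function(f)
                   intersect(f, unique(metrics$metric)))),
            class = "cohort_stats")
}

# a paired comparison that degrades to NULL (with a message) instead of
# erroring when a metric has too few complete pairs
try_paired <- function(x, y, metric) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) {
    message("metric '", metric, "': fewer than 3 complete pairs; dropped")
    return(NULL)
  }
  tryCatch(paired_compare(x, y, metric = metric),
           error = function(e) {
             message("metric '", metric, "': ", conditionMessage(e))
             NULL
           })
}

#' @export
print.cohort_stats <- function(x, ...) {
  cat("cohort_stats over", nrow(x$table), "metrics;",
      sum(x$table$positive), "dual-criterion positive\n")
  print(x$table[, c("family", "metric", "p_raw", "p_ctrl", "threshold",
                    "positive")])
  invisible(x)
}

#' @method tidy cohort_stats
#' @export
tidy.cohort_stats <- function(x, ...) x$table
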