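test_that("the Shapiro-Wilk gate keeps t for Gaussian, drops to Wilcoxon for heavy tails", {
  choices <- vapply(1:100, function(i) {
    set.seed(1000 + i)
    normality_gate(rnorm(24))
  }, character(1))
  expect_gte(mean(choices == "paired-t"), 0.90)
  heavy <- vapply(1:100, function(i) {
    set.seed(2000 + i)
    normality_gate(stats::rt(24, df = 1))
  }, character(1))
  expect_gt(mean(heavy == "wilcoxon"), 0.5)
  expect_error(normality_gate(c(1, 2)), "at least 3")
  expect_warning(g <- normality_gate(rep(2, 10)), "degenerate")
  expect_equal(g, "wilcoxon")
})

test_that("paired comparisons handle identity, degenerate shift and recovery", {
  x <- c(1, 2, 3, 4, 5)
  pc <- paired_compare(x, x)
  expect_equal(pc$p, 1)
  expect_equal(pc$effect_size, 0)
  expect_error(paired_compare(x + 1, x), "zero-variance")
  # Cohen's d recovery: difference shift of 0.5 SD, n = 24, 100 replicates
  ds <- vapply(1:100, function(i) {
    set.seed(3000 + i)
    y <- rnorm(24)
    x <- y + rnorm(24, mean = 0.5, sd = 1)
    paired_compare(x, y)$effect_size
  }, numeric(1))
  expect_lt(abs(mean(ds) - 0.5), 0.25)
  set.seed(30)
  a <- rnorm(24, 0.5); b <- rnorm(24)
  raw <- paired_compare(a, b)
  swapped <- paired_compare(b, a)
  expect_equal(raw$p, swapped$p)
  expect_equal(raw$effect_size, -swapped$effect_size)
})

test_that("Wilcoxon branch reports |Z|/sqrt(n) and matches stats::wilcox.test", {
  set.seed(31)
  d <- stats::rt(24, df = 1)
  x <- d; y <- rep(0, 24)
  pc <- paired_compare(x, y)
  if (pc$test_used == "wilcoxon") {
    ref <- wilcox.test(d, correct = TRUE, exact = FALSE)$p.value
    expect_equal(pc$p, ref, tolerance = 1e-10)
    expect_gte(pc$effect_size, 0)
    expect_lte(pc$effect_size, 1)
  }
  # small-n exact branch
  d5 <- c(0.3, -0.1, 0.5, 0.2, 0.4, -0.6, 0.7)
  z <- gliomaconn:::wilcoxon_z(d5)
  expect_equal(z$p, wilcox.test(d5, exact = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("Bonferroni thresholds reproduce the printed family values", {
  b6 <- bonferroni_threshold(0.05, 6)
  expect_equal(b6$threshold, 0.05 / 6)
  expect_equal(b6$threshold_3dp, 0.008)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.05, 8)$threshold, 0.00625)
  expect_error(bonferroni_threshold(0.05, 0), "m must be")
})

test_that("dual-criterion positivity needs both analyses under the family threshold", {
  mk <- function(p) structure(list(metric = "m", test_used = "paired-t",
                                   statistic = 1, p = p, effect_size = 1,
                                   effect_type = "cohen_d", n_pairs = 24),
                              class = "paired_comparison")
  expect_true(dual_criterion(mk(0.001), mk(0.002), m = 6)$positive)
  # the published activity pattern: raw significant, control-subtracted not
  expect_false(dual_criterion(mk(0.003), mk(0.52), m = 6)$positive)
  expect_false(dual_criterion(mk(0.009), mk(0.001), m = 6)$positive)
  # order invariance
  expect_equal(dual_criterion(mk(0.003), mk(0.52), m = 6)$positive,
               dual_criterion(mk(0.52), mk(0.003), m = 6)$positive)
})

test_that("the mixed model recovers a known group effect and flags collinearity", {
  sim_lmm_data <- function(seed, beta_group = 0.2) {
    set.seed(seed)
    n <- 100
    subj <- rep(1:n, each = 2)
    group <- rep(c("larger", "smaller"), n)
    u <- rnorm(n, 0, 0.3)[subj]
    val <- u + beta_group * (group == "larger") + rnorm(2 * n, 0, 0.2)
    tibble::tibble(subject = subj, seed_type = group, value = val,
                   volume = rnorm(2 * n, 50, 10), tsnr = rnorm(2 * n, 90, 5),
                   n_networks = sample(1:5, 2 * n, replace = TRUE))
  }
  est <- vapply(1:25, function(i) {
    fit <- fit_lmm(sim_lmm_data(4000 + i))
    fit$coefficients$estimate[fit$coefficients$term == "group_larger"]
  }, numeric(1))
  expect_gte(mean(est > 0.1 & est < 0.3), 0.9)
  # null effect: p-values roughly uniform
  ps <- vapply(1:60, function(i) {
    fit <- suppressWarnings(fit_lmm(sim_lmm_data(5000 + i, beta_group = 0)))
    fit$coefficients$p_value[fit$coefficients$term == "group_larger"]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
  # covariate perfectly collinear with group
  dat <- sim_lmm_data(1)
  dat$volume <- ifelse(dat$seed_type == "larger", 1, 0)
  expect_warning(fit_lmm(dat, scale_covariates = FALSE), "collinear")
  # broom-style accessors
  fit <- suppressWarnings(fit_lmm(sim_lmm_data(2)))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true("group_larger" %in% tidy(fit)$term)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("cohort stats assert the family sizes and survive degenerate input", {
  set.seed(33)
  n <- 12
  mets <- c("alff", "falff", "reho", "mean_fc", "n_sig", "mean_dist_mm",
            "degree_centrality", "betweenness_centrality",
            "closeness_centrality", "clustering_coefficient")
  long <- tidyr::expand_grid(subject = 1:n,
                             seed_type = c("larger", "smaller",
                                           "larger_control",
                                           "smaller_control"),
                             metric = mets)
  long$value <- rnorm(nrow(long))
  st <- run_cohort_stats(long, fit_lmm_for = "none")
  expect_equal(unique(st$table$m[st$table$family == "activity"]), 6L)
  expect_equal(unique(st$table$m[st$table$family == "connectivity"]), 6L)
  expect_equal(unique(st$table$m[st$table$family == "topology"]), 8L)
  expect_equal(nrow(st$table), 10)
  expect_s3_class(tidy(st), "tbl_df")
  # single-subject cohort: every metric refuses (n < 3) without crashing
  solo <- long[long$subject == 1, ]
  expect_message(st1 <- run_cohort_stats(solo, fit_lmm_for = "none"),
                 "fewer than 3")
  expect_true(all(is.na(st1$table$p_raw)))
  expect_false(any(st1$table$positive))
})
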