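#' Default scaled-down cohort conditions for validation experiments
#'
#' A 24-subject cohort on a 40-parcel atlas — the package's standard
#' desk-scale conditions for specificity and sensitivity experiments
#' (full-size 400-parcel cohorts behave identically but are much slower
#' to replicate hundreds of times).
#'
#' @param kappa_larger,kappa_smaller tumor-cortex couplings.
#' @param grid_shape voxel grid.
#' @param seed master seed.
#' @param ... forwarded to [sim_params()].
#' @return A `sim_params` object.
#' @export
validation_params <- function(kappa_larger = 0.6, kappa_smaller = 0.2,
                              grid_shape = c(14L, 14L, 10L), seed = 1L, ...) {
  sim_params(n_subjects = 24L, n_parcels = 40L, grid_shape = grid_shape,
             kappa_larger = kappa_larger, kappa_smaller = kappa_smaller,
             seed = seed, ...)
}

replicate_seed <- function(base_seed, i) {
  as.integer((as.double(base_seed) * 48271 + as.double(i) * 104729) %%
               2147483629) + 1L
}

#' Familywise false-positive calibration on coupling-equal null cohorts
#'
#' Simulates `n_replicates` cohorts in which both lesions have identical
#' (zero) tumor-cortex coupling, runs the connectivity-family
#' dual-criterion workflow on each, and reports the fraction of cohorts
#' with any dual-positive connectivity finding — the empirical familywise
#' false-positive rate of the workflow.
#'
#' @param n_replicates number of null cohorts.
#' @param base_seed seed from which per-replicate master seeds derive.
#' @param params cohort conditions; defaults to [validation_params()] with
#'   both couplings 0.
#' @return Object of class `fc_null_calibration`: tibble `replicates`
#'   (replicate, any_positive) and scalar `fpr`.
#' @export
fc_null_calibration <- function(n_replicates = 200, base_seed = 1L,
                                params = validation_params(
                                  kappa_larger = 0, kappa_smaller = 0)) {
  reps <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    params$seed <- replicate_seed(base_seed, i)
    co <- simulate_cohort(params)
    met <- cohort_metrics(co, families = "connectivity")
    st <- suppressMessages(run_cohort_stats(met, fit_lmm_for = "none"))
    tibble::tibble(replicate = i, any_positive = any(st$table$positive))
  })
  structure(list(replicates = reps, fpr = mean(reps$any_positive),
                 n_replicates = n_replicates),
            class = "fc_null_calibration")
}

#' Sensitivity of the workflow to a known coupling gap
#'
#' Simulates `n_replicates` cohorts with the default coupling gap
#' (kappa 0.6 vs 0.2), runs the connectivity and topology families, and
#' reports per replicate whether mean FC and seed degree centrality are
#' dual-criterion positive and whether the mixed-model group coefficient
#' for mean FC stays positive after covariate adjustment.
#'
#' @inheritParams fc_null_calibration
#' @return Object of class `coupling_recovery`: tibble `replicates`
#'   (replicate, mean_fc_positive, degree_positive, lmm_beta_group,
#'   lmm_beta_positive) and the three rate scalars.
#' @export
coupling_recovery <- function(n_replicates = 50, base_seed = 1L,
                              params = validation_params(
                                grid_shape = c(16L, 16L, 10L))) {
  reps <- purrr::map_dfr(seq_len(n_replicates), function(i) {
    params$seed <- replicate_seed(base_seed, i)
    co <- simulate_cohort(params)
    met <- cohort_metrics(co, families = c("connectivity", "topology"))
    st <- suppressMessages(run_cohort_stats(met, fit_lmm_for = "none"))
    fit <- suppressWarnings(
      fit_lmm(met[met$metric == "mean_fc" &
                    met$seed_type %in% c("larger", "smaller"), ]))
    beta <- fit$coefficients$estimate[
      fit$coefficients$term == "group_larger"]
    tibble::tibble(
      replicate = i,
      mean_fc_positive = st$table$positive[st$table$metric == "mean_fc"],
      degree_positive =
        st$table$positive[st$table$metric == "degree_centrality"],
      lmm_beta_group = beta,
      lmm_beta_positive = beta > 0)
  })
  structure(list(replicates = reps,
                 rate_mean_fc = mean(reps$mean_fc_positive),
                 rate_degree = mean(reps$degree_positive),
                 rate_lmm_beta = mean(reps$lmm_beta_positive),
                 n_replicates = n_replicates),
            class = "coupling_recovery")
}

#' @export
print.fc_null_calibration <- function(x, ...) {
  cat("fc_null_calibration:", x$n_replicates,
      "null cohorts, familywise FPR =", x$fpr, "\n")
  invisible(x)
}

#' @export
print.coupling_recovery <- function(x, ...) {
  cat("coupling_recovery over", x$n_replicates, "cohorts:\n",
      " mean FC dual-positive rate:", x$rate_mean_fc, "\n",
      " degree centrality dual-positive rate:", x$rate_degree, "\n",
      " LMM group-beta positive rate:", x$rate_lmm_beta, "\n")
  invisible(x)
}
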