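#' Per-subject metric extraction
#'
#' Computes, for each of the four seed ROIs (both tumors and their mirror
#' controls), the long-format metric rows that feed [run_cohort_stats()]:
#' the connectivity summaries (mean FC, number of Bonferroni-significant
#' parcels, mean centroid distance), optionally the four nodal topology
#' metrics of the seed node at the reporting sparsity, optionally the
#' activity summaries (mean z-scored ALFF/fALFF/ReHo over the ROI), and
#' the covariates used by the mixed model (lesion volume, ROI tSNR,
#' number of intersected networks).
#'
#' @param subject a `glioma_subject`.
#' @param atlas the cohort's `parcel_atlas`.
#' @param subject_id identifier copied into the output.
#' @param families character subset of `c("connectivity", "topology",
#'   "activity")`.
#' @param run `bold_run` to analyze (defaults to the subject's simulated
#'   run; pass a preprocessed run to analyze that).
#' @param sparsity reporting sparsity for the topology metrics (default
#'   0.15).
#' @param alpha parcel-selection level.
#' @return Long tibble: subject, seed_type, metric, value, volume, tsnr,
#'   n_networks.
#' @export
subject_metrics <- function(subject, atlas, subject_id = 1L,
                            families = c("connectivity", "topology"),
                            run = subject$bold, sparsity = 0.15,
                            alpha = 0.05) {
  families <- match.arg(families, c("connectivity", "topology", "activity"),
                        several.ok = TRUE)
  les <- subject$lesions
  mask_of <- list(larger = les$larger_mask, smaller = les$smaller_mask,
                  larger_control = les$larger_control,
                  smaller_control = les$smaller_control)
  vox_vol <- abs(det(atlas$affine[1:3, 1:3]))
  covars <- purrr::map_dfr(names(mask_of), function(sn) {
    tibble::tibble(seed_type = sn,
                   volume = sum(mask_of[[sn]]) * vox_vol / 1000, # cm^3
                   tsnr = tsnr(roi_series(run, mask_of[[sn]])),
                   n_networks = count_intersected_networks(mask_of[[sn]],
                                                           atlas))
  })

  out <- list()
  fc_tab <- NULL
  if (any(c("connectivity", "topology") %in% families)) {
    fc_tab <- seed_connectivity(subject, atlas, run = run, alpha = alpha)
  }
  if ("connectivity" %in% families) {
    out$connectivity <- fc_tab |>
      dplyr::select("seed_type", "mean_fc", "n_sig", "mean_dist_mm") |>
      tidyr::pivot_longer(-"seed_type", names_to = "metric",
                          values_to = "value")
  }
  if ("topology" %in% families) {
    tumor_excl <- list(les$larger_mask, les$smaller_mask)
    base_series <- parcel_series(run, atlas, tumor_excl)
    out$topology <- purrr::map_dfr(names(mask_of), function(sn) {
      pmat <- if (grepl("control$", sn)) {
        parcel_series(run, atlas, c(tumor_excl, list(mask_of[[sn]])))
      } else {
        base_series
      }
      z <- fc_matrix(roi_series(run, mask_of[[sn]]), pmat)
      g <- build_graph(z, sparsity)
      nm <- nodal_metrics(g, nodes = 1L) # node 1 is the seed
      tibble::tibble(seed_type = sn,
                     metric = c("degree_centrality",
                                "betweenness_centrality",
                                "closeness_centrality",
                                "clustering_coefficient"),
                     value = c(nm$degree_centrality,
                               nm$betweenness_centrality,
                               nm$closeness_centrality,
                               nm$clustering_coefficient))
    })
  }
  if ("activity" %in% families) {
    maps <- activity_maps(run, atlas$brain_mask)
    out$activity <- activity_roi_table(maps, les) |>
      dplyr::transmute(seed_type = .data$roi, metric = .data$metric,
                       value = .data$zscored)
  }
  dplyr::bind_rows(out) |>
    dplyr::left_join(covars, by = "seed_type") |>
    dplyr::mutate(subject = subject_id, .before = 1)
}

#' Cohort-wide metric table
#'
#' @param cohort a `glioma_cohort`.
#' @inheritParams subject_metrics
#' @return Long tibble over all subjects (see [subject_metrics()]).
#' @export
cohort_metrics <- function(cohort, families = c("connectivity", "topology"),
                           sparsity = 0.15, alpha = 0.05,
                           preprocess = FALSE) {
  purrr::imap_dfr(cohort$subjects, function(s, i) {
    run <- if (preprocess) {
      preprocess_run(s$bold, s$confounds, band = NULL)
    } else {
      s$bold
    }
    subject_metrics(s, cohort$atlas, subject_id = i, families = families,
                    run = run, sparsity = sparsity, alpha = alpha)
  })
}

#' One-call cohort analysis
#'
#' Simulates a cohort from `params`, extracts the requested metric
#' families, and runs the dual-criterion statistical workflow.
#'
#' @param params a `sim_params`.
#' @param families metric families to compute.
#' @param sparsity reporting sparsity.
#' @param alpha familywise level.
#' @param fit_lmm_for which metrics to adjust with the mixed model (see
#'   [run_cohort_stats()]).
#' @return List with `cohort`, `metrics`, `stats`.
#' @export
analyze_cohort <- function(params, families = c("connectivity", "topology"),
                           sparsity = 0.15, alpha = 0.05,
                           fit_lmm_for = "positive") {
  cohort <- simulate_cohort(params)
  metrics <- cohort_metrics(cohort, families = families, sparsity = sparsity,
                            alpha = alpha)
  stats <- run_cohort_stats(metrics, alpha = alpha,
                            fit_lmm_for = fit_lmm_for)
  list(cohort = cohort, metrics = metrics, stats = stats)
}
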