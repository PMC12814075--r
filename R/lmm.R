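#' Mixed-effects confounder adjustment
#'
#' Fits `value ~ group + volume + tsnr + n_networks + (1 | subject)` by
#' REML (lme4), with the lesion group coded so the reported coefficient
#' `group_larger` is the adjusted larger-minus-smaller difference.
#' P-values are Wald z tests (no df correction). A singular fit is
#' flagged and refit by ML.
#'
#' @param data long tibble restricted to tumor rows: columns `subject`,
#'   `seed_type` (`larger` / `smaller`), `value`, `volume`, `tsnr`,
#'   `n_networks`; every subject needs both rows.
#' @param scale_covariates standardize the numeric covariates before
#'   fitting (default TRUE; stabilizes the optimizer without changing the
#'   group coefficient).
#' @return Object of class `glioma_lmm`: list with `fit` (the merMod),
#'   `coefficients` tibble (term, estimate, std_error, statistic,
#'   p_value), `singular`, `reml`.
#' @export
fit_lmm <- function(data, scale_covariates = TRUE) {
  need <- c("subject", "seed_type", "value", "volume", "tsnr", "n_networks")
  stopifnot(all(need %in% names(data)))
  data <- data[data$seed_type %in% c("larger", "smaller"), need]
  if (min(table(data$subject)) < 2) {
    stop("each subject needs both lesion rows")
  }
  df <- data.frame(
    value = data$value,
    group = factor(data$seed_type, levels = c("smaller", "larger")),
    volume = data$volume, tsnr = data$tsnr, n_networks = data$n_networks,
    subject = factor(data$subject))
  if (scale_covariates) {
    for (v in c("volume", "tsnr", "n_networks")) {
      if (sd(df[[v]]) > 0) df[[v]] <- as.numeric(scale(df[[v]]))
    }
  }
  collinear <- vapply(c("volume", "tsnr", "n_networks"), function(v) {
    sd(df[[v]]) == 0 ||
      abs(cor(as.numeric(df$group), df[[v]])) > 1 - 1e-10
  }, logical(1))
  if (any(collinear)) {
    warning("covariate(s) collinear with group: ",
            paste(names(collinear)[collinear], collapse = ", "))
  }
  drop <- names(collinear)[collinear & vapply(
    c("volume", "tsnr", "n_networks"), function(v) sd(df[[v]]) == 0,
    logical(1))]
  fixed <- setdiff(c("group", "volume", "tsnr", "n_networks"), drop)
  fml <- stats::as.formula(paste("value ~", paste(fixed, collapse = " + "),
                                 "+ (1 | subject)"))
  fit <- suppressMessages(lme4::lmer(fml, data = df, REML = TRUE))
  singular <- lme4::isSingular(fit)
  reml <- TRUE
  if (singular) {
    warning("singular REML fit; refitting by ML")
    fit <- suppressMessages(lme4::lmer(fml, data = df, REML = FALSE))
    reml <- FALSE
  }
  sm <- summary(fit)$coefficients
  coefs <- tibble::tibble(term = sub("grouplarger", "group_larger",
                                     rownames(sm)),
                          estimate = sm[, "Estimate"],
                          std_error = sm[, "Std. Error"],
                          statistic = sm[, "t value"],
                          p_value = 2 * pnorm(-abs(sm[, "t value"])))
  structure(list(fit = fit, coefficients = coefs, singular = singular,
                 reml = reml,
                 random_intercept_var = unname(
                   lme4::VarCorr(fit)$subject[1, 1])),
            class = "glioma_lmm")
}

#' @export
print.glioma_lmm <- function(x, ...) {
  cat("glioma_lmm (", if (x$reml) "REML" else "ML",
      if (x$singular) ", singular" else "", ")\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @rdname fit_lmm
#' @param x a `glioma_lmm`.
#' @param ... unused.
#' @method tidy glioma_lmm
#' @export
tidy.glioma_lmm <- function(x, ...) x$coefficients

#' @rdname fit_lmm
#' @method glance glioma_lmm
#' @export
glance.glioma_lmm <- function(x, ...) {
  tibble::tibble(singular = x$singular, reml = x$reml,
                 random_intercept_var = x$random_intercept_var,
                 n_obs = stats::nobs(x$fit),
                 logLik = as.numeric(stats::logLik(x$fit)))
}
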