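#' Symptom-severity GLMs with FDR control
#'
#' Three model families link neural features to wearable symptom scores,
#' with 2-min windows as the units of analysis: (i) static spectral models
#' with 15 band features, (ii) state-resolved spectral models with 15 x K
#' features, and (iii) temporal models fit separately per state x metric
#' (fractional occupancies sum to one across states, so a joint temporal
#' model would be collinear). All are Gaussian-identity GLMs (ordinary least
#' squares) with participant and hemisphere as dummy-coded categorical
#' covariates; predictors of interest are z-scored, two-sided t-tests are
#' reported per coefficient and corrected by Benjamini-Hochberg FDR at
#' alpha = 0.01. Positive coefficients mean the feature predicts a worse
#' symptom score.
#'
#' @name symptom_glm
NULL

#' Benjamini-Hochberg step-up FDR correction
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @param alpha Significance threshold on the adjusted values.
#' @return List with `adjusted` p-values (monotone) and logical `reject`
#'   mask (`adjusted < alpha`).
#' @export
bh_fdr <- function(p, alpha = 0.01) {
  .assert(all(is.finite(p)) && all(p >= 0 & p <= 1),
          "p-values must lie in [0, 1]")
  adj <- p.adjust(p, method = "BH")
  list(adjusted = adj, reject = adj < alpha)
}

#' Fit one Gaussian GLM of a symptom score on neural features
#'
#' @param features Data frame or matrix of predictors of interest (columns
#'   are z-scored internally).
#' @param response Numeric symptom score per row.
#' @param covariates Optional data frame of categorical covariates
#'   (typically `participant` and `hemisphere`), dummy-coded with the first
#'   level as reference.
#' @param alpha FDR significance threshold (default 0.01).
#' @param fdr_family Optional vector of extra p-values to include in the
#'   correction family; by default the family is this model's predictors of
#'   interest.
#' @return A `glm_report`: per-predictor `table` (beta, t, df, p_raw,
#'   p_fdr, sig), `r_squared`, `n`, `df_residual`.
#' @export
fit_symptom_glm <- function(features, response, covariates = NULL,
                            alpha = 0.01) {
  features <- as.data.frame(features)
  n <- nrow(features)
  .assert(length(response) == n, "response length mismatch")
  .assert(all(complete.cases(features)) && all(is.finite(response)),
          "missing values in retained rows; drop incomplete windows first")
  p_int <- ncol(features)
  const <- names(features)[vapply(features, function(v) sd(v) == 0, logical(1))]
  if (length(const))
    stop(sprintf("constant predictor column(s): %s",
                 paste(const, collapse = ", ")), call. = FALSE)
  Z <- as.data.frame(scale(features))
  df_all <- cbind(Z, .y = response)
  if (!is.null(covariates) && ncol(as.data.frame(covariates))) {
    cov_list <- lapply(as.data.frame(covariates), function(v) {
      f <- factor(v)
      if (nlevels(f) > 1) f else NULL  # drop single-level covariates
    })
    cov_list <- cov_list[!vapply(cov_list, is.null, logical(1))]
    if (length(cov_list)) df_all <- cbind(df_all, as.data.frame(cov_list))
  }
  .assert(n >= ncol(df_all) + 10, "too few rows (%d) for %d columns",
          n, ncol(df_all))
  fit <- lm(.y ~ ., data = df_all)
  cf <- coef(fit)
  if (anyNA(cf))
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(names(cf)[is.na(cf)], collapse = ", ")), call. = FALSE)
  sm <- summary(fit)
  ct <- sm$coefficients
  pred_names <- colnames(Z)
  idx <- match(make.names(pred_names), rownames(ct))
  .assert(!anyNA(idx), "predictor rows missing from the coefficient table")
  tab <- data.frame(predictor = pred_names,
                    beta = ct[idx, "Estimate"],
                    t = ct[idx, "t value"],
                    df = fit$df.residual,
                    p_raw = ct[idx, "Pr(>|t|)"],
                    row.names = NULL)
  fdr <- bh_fdr(tab$p_raw, alpha)
  tab$p_fdr <- fdr$adjusted
  tab$sig <- fdr$reject
  structure(list(table = tab, r_squared = sm$r.squared, n = n,
                 df_residual = fit$df.residual, alpha = alpha,
                 fdr_family = "within-model predictors of interest"),
            class = "glm_report")
}

#' @export
print.glm_report <- function(x, ...) {
  cat(sprintf("glm_report: n = %d windows, R^2 = %.1f%%, alpha = %g (BH-FDR over %d tests)\n",
              x$n, 100 * x$r_squared, x$alpha, nrow(x$table)))
  sig <- x$table[x$table$sig, , drop = FALSE]
  if (!nrow(sig)) { cat("  no significant predictors\n"); return(invisible(x)) }
  for (i in seq_len(nrow(sig)))
    cat(sprintf("  %s: t(%d) = %.2f, p %s\n", sig$predictor[i], sig$df[i],
                sig$t[i],
                if (sig$p_fdr[i] < 0.001) "< 0.001"
                else sprintf("= %.3f", sig$p_fdr[i])))
  invisible(x)
}

epoch_covariates <- function(ds) {
  data.frame(participant = ds$epochs$participant,
             hemisphere = ds$epochs$hemisphere)
}

#' Static spectral model: 15 band features per window
#'
#' @param ds A filtered `epoched_dataset`.
#' @param spectra_list List of static `window_spectra`, one per epoch row.
#' @param symptom `"bradykinesia"`, `"dyskinesia"` or `"tremor"`.
#' @param alpha FDR threshold.
#' @return A `glm_report` over the 15 static features.
#' @export
run_static_model <- function(ds, spectra_list, symptom, alpha = 0.01) {
  feats <- as.data.frame(t(vapply(spectra_list, band_features,
                                  numeric(15))))
  fit_symptom_glm(feats, ds$epochs[[symptom]], epoch_covariates(ds), alpha)
}

#' State-resolved spectral model: 15 x K features per window
#'
#' Windows in which any state is missing (below minimum occupancy) are
#' dropped (complete-case) rather than zero-imputed.
#'
#' @param ds A filtered `epoched_dataset`.
#' @param state_spectra_list List (one per epoch row) of per-state
#'   `window_spectra` lists from [state_masked_spectra()].
#' @inheritParams run_static_model
#' @return A `glm_report` over all 15 x K predictors.
#' @export
run_state_model <- function(ds, state_spectra_list, symptom, alpha = 0.01) {
  K <- length(state_spectra_list[[1]])
  feats <- as.data.frame(t(vapply(state_spectra_list, band_features,
                                  numeric(15 * K))))
  ok <- complete.cases(feats)
  if (!all(ok))
    message(sprintf("%d window(s) dropped: missing state spectra", sum(!ok)))
  fit_symptom_glm(feats[ok, , drop = FALSE], ds$epochs[[symptom]][ok],
                  epoch_covariates(ds)[ok, , drop = FALSE], alpha)
}

#' Temporal models: one GLM per state x metric
#'
#' Each temporal property of each state is tested in its own model (single
#' predictor of interest plus covariates) to avoid the multicollinearity of
#' jointly modelling metrics that are linked across states. The FDR family
#' spans all state x metric tests for the symptom.
#'
#' @param metric_table Long table from [temporal_metric_table()].
#' @param symptom `"bradykinesia"`, `"dyskinesia"` or `"tremor"`.
#' @param metrics Which temporal metrics to test.
#' @param alpha FDR threshold.
#' @return A `glm_report` whose rows are `state{k}_{metric}`; per-model
#'   `r_squared` and `n` are attached as columns.
#' @export
run_temporal_models <- function(metric_table, symptom,
                                metrics = c("fo", "mean_lifetime_s",
                                            "mean_interval_s"),
                                alpha = 0.01) {
  K <- max(metric_table$state)
  rows <- list()
  for (k in seq_len(K)) for (m in metrics) {
    sub <- metric_table[metric_table$state == k, , drop = FALSE]
    sub <- sub[is.finite(sub[[m]]) & is.finite(sub[[symptom]]), , drop = FALSE]
    if (!nrow(sub)) next
    rep1 <- fit_symptom_glm(setNames(sub[, m, drop = FALSE],
                                     sprintf("state%d_%s", k, m)),
                            sub[[symptom]],
                            data.frame(participant = sub$participant,
                                       hemisphere = sub$hemisphere),
                            alpha)
    r <- rep1$table
    r$r_squared <- rep1$r_squared
    r$n <- rep1$n
    rows[[length(rows) + 1L]] <- r
  }
  tab <- do.call(rbind, rows)
  fdr <- bh_fdr(tab$p_raw, alpha)   # family: all state x metric tests
  tab$p_fdr <- fdr$adjusted
  tab$sig <- fdr$reject
  structure(list(table = tab, r_squared = NA_real_,
                 n = max(tab$n), df_residual = NA_integer_, alpha = alpha,
                 fdr_family = "all state x metric tests for this symptom"),
            class = "glm_report")
}
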