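#' End-to-end pipeline and model selection
#'
#' [run_pipeline()] chains the whole analysis: simulate (or read)
#' recordings, preprocess, align and filter 2-min epochs, embed and fit the
#' HMM, decode state paths, compute static and state-resolved spectra,
#' temporal metrics, and the three GLM families, writing all artifacts and a
#' provenance record to a run directory. [compare_k()] refits the HMM at
#' several state counts on the same data and tabulates log-likelihood,
#' parameter counts, BIC and a spectral-contrast diagnostic; it performs no
#' automatic selection.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' Defaults follow the analysis conventions used throughout the package:
#' 250 Hz sampling, lag radius 7 (15-point embedding window), 2-120 Hz
#' band-pass, K = 4 states, the canonical five-band scheme, FDR alpha 0.01,
#' sleep threshold 80 and 30th-percentile bradykinesia threshold.
#'
#' @param sim Simulation config from [default_sim_config()], or `NULL` to
#'   read files (`recording_paths`, `symptom_paths`).
#' @param ... Overrides for any config entry.
#' @return Named list.
#' @export
pipeline_config <- function(sim = default_sim_config(), ...) {
  cfg <- list(sim = sim, recording_paths = NULL, symptom_paths = NULL,
              analysis = "bradykinesia", K = 4L, L = 7L,
              norm_percentile = 95, band = c(2, 120), filter_order = 4,
              alpha = 0.01, sleep_threshold = 80, percentile = 30,
              n_restarts = 2, max_iter = 40, tol = 1e-5, seed = 1L,
              max_spectra_windows = Inf, min_occupancy_s = 2)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, c(list(sim = NULL), cfg))
}

#' Run the full analysis pipeline
#'
#' @param config List from [pipeline_config()].
#' @param out_dir Optional directory for artifacts (CSV tables, model JSON,
#'   provenance); created if missing. `NULL` skips writing.
#' @return Invisible list with the dataset, model, filtered epochs, decoded
#'   `state_paths`, `welch`, `state_spectra` lists, `temporal` table, and
#'   `reports` (static, state, temporal `glm_report`s).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  fs <- NULL
  if (!is.null(config$sim)) {
    ds_raw <- make_dataset(config$sim)
    sessions <- ds_raw$sessions
    symptoms <- ds_raw$symptoms
    fs <- config$sim$fs
  } else {
    sessions <- lapply(config$recording_paths, read_recording)
    symptoms <- lapply(config$symptom_paths, read_symptoms)
    fs <- sessions[[1]]$fs
  }
  pre <- lapply(sessions, preprocess_session,
                percentile = config$norm_percentile, band = config$band,
                order = config$filter_order)
  ds <- combine_epochs(mapply(align_epochs, pre, symptoms, SIMPLIFY = FALSE))
  n_aligned <- nrow(ds$epochs)
  ds <- filter_epochs(ds, config$analysis,
                      sleep_threshold = config$sleep_threshold,
                      percentile = config$percentile)
  if (!nrow(ds$epochs)) {
    message("no epochs after filtering; stopping early")
    return(invisible(list(epochs = ds, model = NULL)))
  }

  embedded <- unlist(lapply(pre, embed_session, L = config$L),
                     recursive = FALSE)
  model <- fit_hmm(embedded, K = config$K, seed = config$seed,
                   tol = config$tol, max_iter = config$max_iter,
                   n_restarts = config$n_restarts)
  state_paths <- lapply(pre, decode_session, model = model, L = config$L)
  names(state_paths) <- names(ds$sessions)

  roles <- pre[[1]]$channel_roles
  n_spec <- min(nrow(ds$epochs), config$max_spectra_windows)
  spec_rows <- if (is.finite(config$max_spectra_windows))
    sort(with_seed(config$seed,
                   sample(nrow(ds$epochs), n_spec))) else seq_len(nrow(ds$epochs))
  welch <- vector("list", nrow(ds$epochs))
  stspec <- vector("list", nrow(ds$epochs))
  for (i in spec_rows) {
    x <- epoch_signal(ds, i)
    e <- ds$epochs[i, ]
    p <- state_paths[[e$session]][e$start_sample:e$end_sample]
    welch[[i]] <- welch_spectra(x, roles, fs)
    stspec[[i]] <- state_masked_spectra(x, p, config$K, roles, fs,
                                        min_occupancy_s = config$min_occupancy_s)
  }
  temporal <- temporal_metric_table(ds, state_paths, fs, config$K)

  sub <- ds
  sub$epochs <- ds$epochs[spec_rows, , drop = FALSE]
  # a model family that cannot be fit on this run (e.g. fewer windows than
  # predictors) is recorded as skipped rather than aborting the run
  try_report <- function(expr) tryCatch(expr, error = function(e)
    structure(list(skipped = conditionMessage(e)), class = "skipped_report"))
  reports <- list(
    static = try_report(run_static_model(sub, welch[spec_rows],
                                         config$analysis, config$alpha)),
    state = try_report(run_state_model(sub, stspec[spec_rows],
                                       config$analysis, config$alpha)),
    temporal = try_report(run_temporal_models(temporal, config$analysis,
                                              alpha = config$alpha)))

  res <- list(sessions = pre, epochs = ds, model = model,
              state_paths = state_paths, welch = welch,
              state_spectra = stspec, temporal = temporal,
              reports = reports,
              provenance = list(
                analysis = config$analysis, K = config$K, L = config$L,
                seed = config$seed, fs = fs,
                n_windows_aligned = n_aligned,
                n_windows_retained = nrow(ds$epochs),
                n_windows_excluded = nrow(ds$exclusion_log),
                exclusions = as.list(table(ds$exclusion_log$reason))))
  if (!is.null(out_dir)) write_run(res, out_dir, config)
  invisible(res)
}

write_run <- function(res, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(K = res$model$K, D = res$model$D, means = res$model$means,
         covariances = res$model$covs, transition = res$model$transition,
         initial = res$model$initial, loglik = res$model$loglik,
         converged = res$model$converged, seed = res$model$seed),
    file.path(out_dir, "model.json"), digits = NA, auto_unbox = TRUE)
  write.csv(res$epochs$epochs, file.path(out_dir, "epochs.csv"),
            row.names = FALSE)
  write.csv(res$epochs$exclusion_log, file.path(out_dir, "exclusions.csv"),
            row.names = FALSE)
  write.csv(res$temporal, file.path(out_dir, "temporal_metrics.csv"),
            row.names = FALSE)
  for (nm in names(res$reports))
    if (inherits(res$reports[[nm]], "glm_report")) {
      write.csv(res$reports[[nm]]$table,
                file.path(out_dir, paste0("glm_", nm, ".csv")),
                row.names = FALSE)
      jsonlite::write_json(res$reports[[nm]]["table" != names(res$reports[[nm]])],
                           file.path(out_dir, paste0("glm_", nm, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  jsonlite::write_json(res$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

hmm_n_params <- function(K, D) {
  K * D + K * D * (D + 1) / 2 + K * (K - 1) + (K - 1)
}

#' Compare HMMs with different state counts
#'
#' Fits one model per K on the same embedded data and reports final
#' log-likelihood, free-parameter count, BIC and a spectral sharpness
#' diagnostic (the largest between-state contrast among state-masked band
#' features, computed on an initial stretch of the first session). The table
#' supports a human choice of K; nothing is selected automatically.
#'
#' @param sessions List of preprocessed [recording_session()]s.
#' @param k_list State counts to evaluate (all >= 2).
#' @param L Lag radius.
#' @param seed,n_restarts,max_iter,tol Passed to [fit_hmm()].
#' @param contrast_s Seconds of the first session used for the band-contrast
#'   diagnostic (0 skips it).
#' @return Data frame with one row per K and an attached list of models.
#' @export
compare_k <- function(sessions, k_list = c(3, 4, 6), L = 7, seed = 1,
                      n_restarts = 2, max_iter = 40, tol = 1e-5,
                      contrast_s = 120) {
  .assert(all(k_list >= 2), "k_list values must be >= 2")
  embedded <- unlist(lapply(sessions, embed_session, L = L),
                     recursive = FALSE)
  Ttot <- sum(vapply(embedded, function(e) nrow(e$X), integer(1)))
  fs <- sessions[[1]]$fs
  roles <- sessions[[1]]$channel_roles
  models <- list()
  tab <- lapply(k_list, function(K) {
    m <- fit_hmm(embedded, K = K, seed = seed, tol = tol,
                 max_iter = max_iter, n_restarts = n_restarts)
    models[[as.character(K)]] <<- m
    contrast <- NA_real_
    if (contrast_s > 0) {
      ns <- min(ncol(sessions[[1]]$signal), round(contrast_s * fs))
      seg <- sessions[[1]]$signal[, seq_len(ns), drop = FALSE]
      p <- hmm_viterbi(m, tde_embed(seg, L))
      p_full <- rep(NA_integer_, ns)
      p_full[(L + 1):(ns - L)] <- p
      bf <- band_features(state_masked_spectra(seg, p_full, K, roles, fs))
      M <- matrix(bf, nrow = K, byrow = TRUE)
      contrast <- max(apply(M, 2, function(v)
        if (all(is.finite(v))) diff(range(v)) else NA), na.rm = TRUE)
    }
    np <- hmm_n_params(K, m$D)
    data.frame(K = K, loglik = m$loglik, n_params = np,
               bic = -2 * m$loglik + np * log(Ttot),
               band_contrast = contrast)
  })
  out <- do.call(rbind, tab)
  attr(out, "models") <- models
  out
}
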