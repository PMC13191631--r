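#' Per-window temporal statistics of the decoded state path
#'
#' Visits are maximal runs of one state within the window. Fractional
#' occupancy (FO) is the proportion of (decoded) samples spent in the state;
#' lifetime is the mean visit duration in seconds; visit interval is the
#' mean gap between the end of one visit and the start of the next; the
#' switching rate is visits per second. Runs truncated by the window edges
#' count as visits (excluding them would systematically discard long
#' dwells). States that never occur in a window yield missing values, as do
#' intervals for states with fewer than two visits.
#'
#' @param path Integer state path for one 2-min window (`NA` allowed at
#'   embedding-trimmed samples; `NA`s are ignored and runs are measured on
#'   the decoded samples).
#' @param fs Sampling rate, Hz.
#' @param K Number of states.
#' @return Data frame with one row per state: `state`, `fo`,
#'   `mean_lifetime_s`, `mean_interval_s`, `switching_rate_hz`, `n_visits`.
#'   FO sums to 1 over states.
#' @export
compute_temporal_metrics <- function(path, fs, K) {
  path <- path[!is.na(path)]
  .assert(length(path) > 0, "path is empty")
  .assert(all(path >= 1 & path <= K), "state ids outside 1..%d", K)
  n <- length(path)
  dur <- n / fs
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(state = seq_len(K), fo = NA_real_,
                    mean_lifetime_s = NA_real_, mean_interval_s = NA_real_,
                    switching_rate_hz = NA_real_, n_visits = NA_integer_)
  for (k in seq_len(K)) {
    vis <- which(r$values == k)
    out$fo[k] <- sum(r$lengths[vis]) / n
    if (!length(vis)) { out$fo[k] <- 0; next }
    out$mean_lifetime_s[k] <- mean(r$lengths[vis]) / fs
    out$n_visits[k] <- length(vis)
    out$switching_rate_hz[k] <- length(vis) / dur
    if (length(vis) >= 2)
      out$mean_interval_s[k] <-
        mean(starts[vis[-1]] - ends[vis[-length(vis)]] - 1L) / fs
  }
  # absent states: FO 0 but all other metrics missing (not zero)
  out
}

#' Temporal-metric table for every epoch of a dataset
#'
#' @param ds An `epoched_dataset`.
#' @param state_paths Named list (by session id) of raw-sample-aligned state
#'   paths, as from [decode_session()].
#' @param fs Sampling rate, Hz.
#' @param K Number of states.
#' @return Long data frame: one row per epoch x state with the metrics of
#'   [compute_temporal_metrics()] plus epoch metadata.
#' @export
temporal_metric_table <- function(ds, state_paths, fs, K) {
  rows <- lapply(seq_len(nrow(ds$epochs)), function(i) {
    e <- ds$epochs[i, ]
    p <- state_paths[[e$session]][e$start_sample:e$end_sample]
    if (all(is.na(p))) return(NULL)
    tm <- compute_temporal_metrics(p, fs, K)
    cbind(e[rep(1, K), c("session", "window", "participant", "hemisphere",
                         "bradykinesia", "dyskinesia", "tremor")],
          tm, row.names = NULL)
  })
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

# Global switching rate: label changes per second over the window.
#' @rdname compute_temporal_metrics
#' @export
global_switching_rate <- function(path, fs) {
  path <- path[!is.na(path)]
  .assert(length(path) > 0, "path is empty")
  sum(diff(path) != 0) / (length(path) / fs)
}
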