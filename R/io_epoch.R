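#' Recordings, symptom logs, and 2-min epoching
#'
#' A `recording_session` holds a channels-x-samples matrix sampled at 250 Hz
#' (by default) with per-channel roles (STN or CTX contact pairs), hemisphere
#' and participant labels, and a list of contiguous segments. A
#' `symptom_series` holds wearable scores (bradykinesia, dyskinesia, tremor)
#' at 2-min resolution. [align_epochs()] pairs a hemisphere's recording with
#' the contralateral wrist's scores into exact 2-min epochs and
#' [filter_epochs()] applies the sleep and per-analysis inclusion rules.
#'
#' @name io_epoch
NULL

make_channel_names <- function(roles) {
  idx <- stats::ave(seq_along(roles), roles, FUN = seq_along)
  pair <- ifelse(idx == 1, "1-3", "2-4")
  paste0(roles, "_", pair)
}

#' Construct a recording session
#'
#' @param signal Numeric matrix, channels x samples.
#' @param fs Sampling rate, Hz.
#' @param channel_roles Character vector, one of `"STN"`/`"CTX"` per channel.
#' @param hemisphere `"L"` or `"R"`.
#' @param participant Participant identifier.
#' @param segments Two-column matrix of inclusive (start, end) sample indices
#'   of contiguous stretches; defaults to one segment spanning the signal.
#' @param start_time Session start in seconds (shared time base with the
#'   symptom log; 0 for simulated data).
#' @return A `recording_session` object.
#' @export
recording_session <- function(signal, fs, channel_roles,
                              hemisphere = "L", participant = "P01",
                              segments = NULL, start_time = 0) {
  signal <- as.matrix(signal)
  .assert(fs > 0, "fs must be positive")
  .assert(nrow(signal) == length(channel_roles),
          "channel_roles length (%d) != channel count (%d)",
          length(channel_roles), nrow(signal))
  .assert(all(channel_roles %in% c("STN", "CTX")),
          "channel roles must be STN or CTX")
  .assert(any(channel_roles == "STN") && any(channel_roles == "CTX"),
          "need at least one STN and one CTX channel")
  .assert(hemisphere %in% c("L", "R"), "hemisphere must be L or R")
  if (is.null(segments))
    segments <- cbind(start = 1L, end = ncol(signal))
  segments <- matrix(as.integer(segments), ncol = 2,
                     dimnames = list(NULL, c("start", "end")))
  o <- order(segments[, 1])
  segments <- segments[o, , drop = FALSE]
  if (nrow(segments) > 1)
    .assert(all(segments[-1, 1] > segments[-nrow(segments), 2]),
            "segments must be non-overlapping and ordered")
  if (is.null(rownames(signal)))
    rownames(signal) <- make_channel_names(channel_roles)
  structure(list(signal = signal, fs = fs, channel_roles = channel_roles,
                 hemisphere = hemisphere, participant = participant,
                 segments = segments, start_time = as.numeric(start_time)),
            class = "recording_session")
}

#' @export
print.recording_session <- function(x, ...) {
  cat(sprintf("recording_session: %d channels x %d samples @ %g Hz\n",
              nrow(x$signal), ncol(x$signal), x$fs))
  cat(sprintf("  participant %s, hemisphere %s, %d segment(s)\n",
              x$participant, x$hemisphere, nrow(x$segments)))
  cat("  channels:", paste(rownames(x$signal), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a symptom series
#'
#' Bradykinesia scores are stored as positive values: a source column that is
#' entirely non-positive (the raw wearable convention) is negated, so higher
#' always means worse bradykinesia.
#'
#' @param timestamps Window-end times in seconds, strictly increasing.
#' @param bradykinesia,dyskinesia,tremor Numeric scores, one per window.
#' @param wrist_side `"L"` or `"R"` (side of the wrist-worn sensor).
#' @return A `symptom_series` object.
#' @export
symptom_series <- function(timestamps, bradykinesia, dyskinesia, tremor,
                           wrist_side) {
  n <- length(timestamps)
  .assert(length(bradykinesia) == n && length(dyskinesia) == n &&
            length(tremor) == n, "score columns must match timestamps length")
  .assert(wrist_side %in% c("L", "R"), "wrist_side must be L or R")
  timestamps <- as.numeric(timestamps)
  if (n > 1) {
    d <- diff(timestamps)
    dup <- which(d == 0)
    if (length(dup))
      stop(sprintf("duplicated timestamp at row %d", dup[1] + 1L),
           call. = FALSE)
    .assert(all(d > 0), "timestamps must be strictly increasing")
  }
  b <- as.numeric(bradykinesia)
  if (any(b < 0, na.rm = TRUE)) {
    .assert(all(b <= 0, na.rm = TRUE),
            "bradykinesia column mixes signs; cannot apply sign transform")
    b <- -b
  }
  structure(list(timestamps = timestamps, bradykinesia = b,
                 dyskinesia = as.numeric(dyskinesia),
                 tremor = as.numeric(tremor), wrist_side = wrist_side),
            class = "symptom_series")
}

#' @export
print.symptom_series <- function(x, ...) {
  cat(sprintf("symptom_series: %d 2-min windows, wrist %s\n",
              length(x$timestamps), x$wrist_side))
  invisible(x)
}

reject_recording <- function(reason, path = "<memory>") {
  cond <- structure(
    class = c("recording_rejected", "error", "condition"),
    list(message = sprintf("recording %s rejected: %s", path, reason),
         call = NULL, reason = reason))
  stop(cond)
}

#' Write / read a recording as delimited text
#'
#' The on-disk format is a comment header
#' `# lfpstates-recording fs=<Hz> participant=<id> hemisphere=<L|R> start=<s>`
#' followed by a CSV table whose first column `sample` gives the raw sample
#' index (gaps in the index encode non-contiguous segments) and whose
#' remaining columns are channels named `<ROLE>_<pair>` (e.g. `STN_1-3`).
#'
#' @param session A [recording_session()].
#' @param path File path.
#' @export
write_recording <- function(session, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# lfpstates-recording fs=%g participant=%s hemisphere=%s start=%g",
    session$fs, session$participant, session$hemisphere,
    session$start_time), con)
  idx <- unlist(lapply(seq_len(nrow(session$segments)), function(i)
    session$segments[i, 1]:session$segments[i, 2]))
  df <- data.frame(sample = idx,
                   signif(t(session$signal[, idx, drop = FALSE]), 8),
                   check.names = FALSE)
  names(df) <- c("sample", rownames(session$signal))
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_recording
#' @details `read_recording` rejects files in which any channel lacks valid
#'   signal (all-constant or all-missing), raising a condition of class
#'   `recording_rejected` whose `reason` field is `"flat channel"`. Gaps in
#'   the sample-index column are isolated into contiguous segments.
#' @export
read_recording <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  hdr <- readLines(path, n = 1)
  if (!grepl("^# lfpstates-recording", hdr))
    stop(sprintf("unknown recording format in %s", path), call. = FALSE)
  kv <- regmatches(hdr, gregexpr("[a-z]+=[^ ]+", hdr))[[1]]
  meta <- setNames(sub("^[a-z]+=", "", kv), sub("=.*$", "", kv))
  if (is.na(meta["fs"])) stop("recording header lacks fs", call. = FALSE)
  fs <- as.numeric(meta[["fs"]])
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  .assert("sample" %in% names(df), "recording table lacks 'sample' column")
  ch_names <- setdiff(names(df), "sample")
  roles <- sub("_.*$", "", ch_names)
  sig_cols <- as.matrix(df[, ch_names, drop = FALSE])
  for (j in seq_along(ch_names)) {
    v <- sig_cols[, j]
    if (all(is.na(v)) || (length(unique(v[!is.na(v)])) <= 1))
      reject_recording("flat channel", path)
  }
  idx <- df$sample
  n <- max(idx)
  sig <- matrix(0, length(ch_names), n, dimnames = list(ch_names, NULL))
  sig[, idx] <- t(sig_cols)
  breaks <- which(diff(idx) != 1)
  seg_start <- idx[c(1L, breaks + 1L)]
  seg_end <- idx[c(breaks, length(idx))]
  recording_session(sig, fs = fs, channel_roles = roles,
                    hemisphere = meta[["hemisphere"]] %||% "L",
                    participant = meta[["participant"]] %||% "P01",
                    segments = cbind(seg_start, seg_end),
                    start_time = as.numeric(meta["start"] %||% 0))
}

#' Write / read a symptom log as CSV
#'
#' Columns: `timestamp` (seconds, or ISO-8601 date-times), `bradykinesia`,
#' `dyskinesia`, `tremor`, `wrist_side`.
#'
#' @param series A [symptom_series()].
#' @param path File path.
#' @export
write_symptoms <- function(series, path) {
  df <- data.frame(timestamp = series$timestamps,
                   bradykinesia = series$bradykinesia,
                   dyskinesia = series$dyskinesia,
                   tremor = series$tremor,
                   wrist_side = series$wrist_side)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_symptoms
#' @return `read_symptoms` returns a [symptom_series()]; an empty file (header
#'   only) yields a zero-window series.
#' @export
read_symptoms <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "bradykinesia", "dyskinesia", "tremor")
  .assert(all(need %in% names(df)), "symptom CSV must have columns %s",
          paste(need, collapse = ", "))
  ts <- df$timestamp
  if (is.character(ts))
    ts <- as.numeric(as.POSIXct(ts, tz = "UTC"))
  side <- if ("wrist_side" %in% names(df) && nrow(df)) df$wrist_side[1] else "L"
  symptom_series(ts, df$bradykinesia, df$dyskinesia, df$tremor, side)
}

#' Align a recording with contralateral symptom scores into 2-min epochs
#'
#' One epoch is produced per symptom window whose full 2-min span lies
#' inside a single contiguous recording segment; the score at the window's
#' end is attached. Windows broken by a segment gap are logged as
#' `"discontiguous"`, windows outside the recording as `"out_of_range"`.
#'
#' @param rec A [recording_session()].
#' @param sym A [symptom_series()] from the wrist opposite `rec$hemisphere`.
#' @return An `epoched_dataset`: an `epochs` data frame (one row per kept
#'   window with sample bounds, scores and labels), the source `sessions`,
#'   and an `exclusion_log`.
#' @export
align_epochs <- function(rec, sym) {
  .assert(inherits(rec, "recording_session"), "rec must be a recording_session")
  .assert(inherits(sym, "symptom_series"), "sym must be a symptom_series")
  if (rec$hemisphere == sym$wrist_side)
    stop(sprintf(
      "same-side pairing: hemisphere %s with wrist %s (neural data must be paired with the opposite wrist)",
      rec$hemisphere, sym$wrist_side), call. = FALSE)
  fs <- rec$fs
  win <- as.integer(round(120 * fs))
  sid <- paste0(rec$participant, "_", rec$hemisphere)
  n_win <- length(sym$timestamps)
  rows <- vector("list", n_win)
  excl <- vector("list", n_win)
  for (w in seq_len(n_win)) {
    t_end <- sym$timestamps[w]
    end_sample <- as.integer(round((t_end - rec$start_time) * fs))
    start_sample <- end_sample - win + 1L
    if (start_sample < 1L || end_sample > ncol(rec$signal)) {
      excl[[w]] <- data.frame(session = sid, window = w,
                              reason = "out_of_range")
      next
    }
    inside <- any(rec$segments[, 1] <= start_sample &
                    rec$segments[, 2] >= end_sample)
    if (!inside) {
      excl[[w]] <- data.frame(session = sid, window = w,
                              reason = "discontiguous")
      next
    }
    rows[[w]] <- data.frame(
      session = sid, window = w, start_sample = start_sample,
      end_sample = end_sample, timestamp = t_end,
      bradykinesia = sym$bradykinesia[w], dyskinesia = sym$dyskinesia[w],
      tremor = sym$tremor[w], participant = rec$participant,
      hemisphere = rec$hemisphere, stringsAsFactors = FALSE)
  }
  epochs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(epochs)) {
    warning("no overlap between recording and symptom series")
    epochs <- data.frame()
  }
  sessions <- setNames(list(rec), sid)
  structure(list(epochs = epochs, sessions = sessions,
                 exclusion_log = do.call(rbind,
                   excl[!vapply(excl, is.null, logical(1))]) %||%
                   data.frame(session = character(), window = integer(),
                              reason = character())),
            class = "epoched_dataset")
}

#' Combine epoched datasets from several sessions
#'
#' @param ds_list List of `epoched_dataset` objects.
#' @return A single `epoched_dataset` pooling all epochs and sessions.
#' @export
combine_epochs <- function(ds_list) {
  eps <- do.call(rbind, lapply(ds_list, function(d)
    if (nrow(d$epochs)) d$epochs else NULL))
  sessions <- do.call(c, lapply(ds_list, function(d) d$sessions))
  logs <- do.call(rbind, lapply(ds_list, function(d) d$exclusion_log))
  structure(list(epochs = eps %||% data.frame(), sessions = sessions,
                 exclusion_log = logs),
            class = "epoched_dataset")
}

#' @export
print.epoched_dataset <- function(x, ...) {
  cat(sprintf("epoched_dataset: %d epochs from %d session(s), %d excluded\n",
              nrow(x$epochs), length(x$sessions), nrow(x$exclusion_log)))
  invisible(x)
}

#' Apply sleep and per-analysis inclusion rules to epochs
#'
#' The sleep rule runs first for every analysis: runs of at least
#' `min_run_windows` consecutive windows with bradykinesia above
#' `sleep_threshold` are classified as prolonged immobility (sleep) and
#' excluded. Then, per analysis: bradykinesia keeps windows at or above each
#' participant's `percentile`-th bradykinesia percentile (computed over that
#' participant's post-sleep record, never pooled); dyskinesia keeps windows
#' below it (on-medication periods); tremor keeps windows with tremor score
#' above zero. Filtering is idempotent: a dataset already filtered for the
#' same analysis is returned unchanged.
#'
#' @param ds An `epoched_dataset`.
#' @param analysis One of `"bradykinesia"`, `"dyskinesia"`, `"tremor"`.
#' @param sleep_threshold Bradykinesia score above which a window counts as
#'   immobile (default 80).
#' @param min_run_windows Minimum run length, in consecutive 2-min windows,
#'   for the immobility exclusion (default 2).
#' @param percentile Per-participant bradykinesia percentile threshold
#'   (default 30).
#' @return The filtered `epoched_dataset`, with every exclusion logged.
#' @export
filter_epochs <- function(ds, analysis = c("bradykinesia", "dyskinesia",
                                           "tremor"),
                          sleep_threshold = 80, min_run_windows = 2,
                          percentile = 30) {
  analysis <- match.arg(analysis)
  .assert(inherits(ds, "epoched_dataset"), "ds must be an epoched_dataset")
  if (identical(attr(ds, "filtered_analysis"), analysis)) return(ds)
  .assert(is.null(attr(ds, "filtered_analysis")),
          "dataset already filtered for a different analysis")
  ep <- ds$epochs
  if (!nrow(ep)) return(ds)

  # sleep rule: runs of >= min_run_windows consecutive high-bradykinesia
  # windows (consecutive = same session, timestamps 120 s apart)
  hi <- ep$bradykinesia > sleep_threshold
  consec <- c(FALSE, ep$session[-1] == ep$session[-nrow(ep)] &
                abs(diff(ep$timestamp) - 120) < 1e-6)
  run_id <- integer(nrow(ep)); cur <- 0L
  for (i in seq_len(nrow(ep))) {
    if (!hi[i]) { run_id[i] <- 0L; next }
    if (i > 1 && hi[i - 1] && consec[i]) run_id[i] <- cur
    else { cur <- cur + 1L; run_id[i] <- cur }
  }
  run_len <- table(run_id[run_id > 0])
  sleep <- run_id > 0 & run_id %in%
    as.integer(names(run_len)[run_len >= min_run_windows])
  log_new <- if (any(sleep))
    data.frame(session = ep$session[sleep], window = ep$window[sleep],
               reason = "sleep") else NULL
  ep <- ep[!sleep, , drop = FALSE]

  keep <- switch(analysis,
    bradykinesia = {
      thr <- tapply(ep$bradykinesia, ep$participant,
                    quantile, probs = percentile / 100, names = FALSE)
      ep$bradykinesia >= thr[as.character(ep$participant)]
    },
    dyskinesia = {
      thr <- tapply(ep$bradykinesia, ep$participant,
                    quantile, probs = percentile / 100, names = FALSE)
      ep$bradykinesia < thr[as.character(ep$participant)]
    },
    tremor = ep$tremor > 0)
  reason <- switch(analysis,
    bradykinesia = "below_bradykinesia_percentile",
    dyskinesia = "above_bradykinesia_percentile",
    tremor = "no_tremor")
  if (any(!keep))
    log_new <- rbind(log_new,
                     data.frame(session = ep$session[!keep],
                                window = ep$window[!keep], reason = reason))
  out <- structure(list(epochs = ep[keep, , drop = FALSE],
                        sessions = ds$sessions,
                        exclusion_log = rbind(ds$exclusion_log, log_new)),
                   class = "epoched_dataset")
  attr(out, "filtered_analysis") <- analysis
  if (!nrow(out$epochs))
    message("no epochs after filtering for ", analysis)
  out
}

#' Extract the signal slice of one epoch
#'
#' @param ds An `epoched_dataset`.
#' @param i Row index into `ds$epochs`.
#' @return Channels x samples matrix for that 2-min window.
#' @export
epoch_signal <- function(ds, i) {
  e <- ds$epochs[i, ]
  ses <- ds$sessions[[e$session]]
  ses$signal[, e$start_sample:e$end_sample, drop = FALSE]
}
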