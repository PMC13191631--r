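#' Amplitude normalization and band-limiting
#'
#' Channels are normalized by a robust amplitude statistic (the 95th
#' percentile of absolute amplitude by default) so that gross gain
#' differences between contact pairs do not dominate the embedded-space
#' covariance, then band-pass filtered to the physiological 2-120 Hz range
#' with a zero-phase Butterworth filter applied independently per contiguous
#' segment (zero phase, because phase distortion would corrupt inter-regional
#' coherence estimates).
#'
#' @name preprocess
NULL

#' Percentile amplitude normalization
#'
#' Divides each channel by the `percentile`-th percentile of its absolute
#' amplitude over that channel's retained samples. Scale-equivariant:
#' multiplying an input channel by any c > 0 leaves its output unchanged.
#'
#' @param session A [recording_session()].
#' @param percentile Percentile of |x| used as the divisor (default 95).
#' @return The normalized session.
#' @export
percentile_normalize <- function(session, percentile = 95) {
  .assert(inherits(session, "recording_session"),
          "session must be a recording_session")
  idx <- unlist(lapply(seq_len(nrow(session$segments)), function(i)
    session$segments[i, 1]:session$segments[i, 2]))
  for (ch in seq_len(nrow(session$signal))) {
    denom <- quantile(abs(session$signal[ch, idx]), percentile / 100,
                      names = FALSE, na.rm = TRUE)
    if (!is.finite(denom) || denom == 0)
      stop(sprintf("channel %s is flat: %gth percentile of |x| is zero",
                   rownames(session$signal)[ch] %||% as.character(ch),
                   percentile), call. = FALSE)
    session$signal[ch, ] <- session$signal[ch, ] / denom
  }
  session
}

#' Zero-phase Butterworth band-pass filter
#'
#' A Butterworth filter of order `order` (per pass) is applied forward and
#' backward (`signal::filtfilt`) to every channel of every contiguous
#' segment. Segments shorter than three filter lengths are dropped from the
#' segment list with a message.
#'
#' @param session A [recording_session()].
#' @param band Length-2 numeric, lower and upper pass-band edges in Hz
#'   (default `c(2, 120)`); upper edge must be below Nyquist.
#' @param order Butterworth order per pass (default 4).
#' @return The filtered session (dropped-segment samples are zeroed).
#' @export
bandpass_filter <- function(session, band = c(2, 120), order = 4) {
  .assert(inherits(session, "recording_session"),
          "session must be a recording_session")
  fs <- session$fs
  .assert(band[2] < fs / 2, "upper band edge %g must be below Nyquist %g",
          band[2], fs / 2)
  .assert(band[1] > 0 && band[1] < band[2], "invalid band")
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  min_len <- 3L * length(bf$b)
  keep <- rep(TRUE, nrow(session$segments))
  for (i in seq_len(nrow(session$segments))) {
    s <- session$segments[i, 1]; e <- session$segments[i, 2]
    if (e - s + 1L < min_len) {
      message(sprintf("segment %d (%d samples) shorter than 3 filter lengths; dropped",
                      i, e - s + 1L))
      keep[i] <- FALSE
      session$signal[, s:e] <- 0
      next
    }
    for (ch in seq_len(nrow(session$signal)))
      session$signal[ch, s:e] <-
        signal::filtfilt(bf, session$signal[ch, s:e])
  }
  session$segments <- session$segments[keep, , drop = FALSE]
  session
}

#' Standard preprocessing chain
#'
#' Segment-aware normalization followed by band-pass filtering, in that
#' order.
#'
#' @inheritParams percentile_normalize
#' @inheritParams bandpass_filter
#' @export
preprocess_session <- function(session, percentile = 95, band = c(2, 120),
                               order = 4) {
  bandpass_filter(percentile_normalize(session, percentile), band, order)
}
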