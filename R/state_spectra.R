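#' Welch and multitaper spectra, coherence, band features
#'
#' Static per-window spectra use Welch's method (2-s Hann windows, 50%
#' overlap at 250 Hz, giving a 0.5 Hz grid over 2-100 Hz). State-resolved
#' spectra follow the state-masking approach: the raw signal is multiplied
#' element-wise by the binarized Viterbi state time course and the masked
#' signal is analysed with a Slepian multitaper estimator (seven tapers,
#' time-bandwidth product 4, same 0.5 Hz resolution). PSDs are averaged
#' across same-region channels and magnitude-squared coherence across the
#' STN x CTX channel pairs.
#'
#' @name state_spectra
NULL

#' The canonical band scheme
#'
#' delta-alpha 2-10, low-beta 12-20, high-beta 20-35, low-gamma 40-70 and
#' high-gamma 70-100 Hz. The 10-12 and 35-40 Hz gaps are intentional; bins
#' there are unused by [band_features()].
#'
#' @return Named list of `c(lo, hi)` band edges in Hz.
#' @export
band_scheme <- function() .default_bands

# Discrete prolate spheroidal (Slepian) tapers via the symmetric
# tridiagonal eigenproblem; columns are unit-energy tapers ordered by
# decreasing eigenvalue (spectral concentration).
#' @rdname state_spectra
#' @param n Taper length in samples.
#' @param NW Time-bandwidth product.
#' @param k Number of tapers.
#' @export
dpss_tapers <- function(n, NW = 4, k = 7) {
  .assert(k < n, "need fewer tapers than samples")
  W <- NW / n
  i <- seq_len(n) - 1
  M <- matrix(0, n, n)
  diag(M) <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * W)
  off <- i[-1] * (n - i[-1]) / 2
  M[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  M[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  ev <- eigen(M, symmetric = TRUE)
  tap <- ev$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    tap[, j] <- tap[, j] / sqrt(sum(tap[, j]^2))
    if (sum(tap[, j]) < 0) tap[, j] <- -tap[, j]
  }
  tap
}

# Averaged auto- and cross-spectral densities over sliding segments (and,
# for multitaper, over tapers). x is channels x samples; tapers is an
# nperseg x n_tapers matrix. Returns one-sided densities on the full
# 0..fs/2 grid: auto (channels x F, real) and cross (list over pairs).
cross_spectra <- function(x, fs, tapers, overlap = 0.5, pairs = NULL) {
  n_ch <- nrow(x)
  n <- ncol(x)
  nperseg <- nrow(tapers)
  step <- max(1L, as.integer(round(nperseg * (1 - overlap))))
  starts <- seq(1L, n - nperseg + 1L, by = step)
  .assert(length(starts) >= 2,
          "need at least 2 analysis segments for spectral estimation")
  nf <- nperseg %/% 2L + 1L
  n_tap <- ncol(tapers)
  # FFT of every (segment x taper) for every channel
  F_list <- vector("list", n_ch)
  seg_idx <- outer(seq_len(nperseg) - 1L, starts, `+`)  # nperseg x nseg
  for (ch in seq_len(n_ch)) {
    segs <- matrix(x[ch, seg_idx], nrow = nperseg)
    acc <- vector("list", n_tap)
    for (tp in seq_len(n_tap))
      acc[[tp]] <- stats::mvfft(segs * tapers[, tp])[seq_len(nf), , drop = FALSE]
    F_list[[ch]] <- acc
  }
  scale <- 1 / fs  # unit-energy tapers: density scale is 1/fs
  one_sided <- rep(2, nf); one_sided[1] <- 1
  if (nperseg %% 2L == 0L) one_sided[nf] <- 1
  avg_cross <- function(a, b) {
    s <- 0
    for (tp in seq_len(n_tap))
      s <- s + rowMeans(F_list[[a]][[tp]] * Conj(F_list[[b]][[tp]]))
    s / n_tap * scale * one_sided
  }
  auto <- t(vapply(seq_len(n_ch), function(ch) Re(avg_cross(ch, ch)),
                   numeric(nf)))
  cross <- NULL
  if (!is.null(pairs))
    cross <- lapply(seq_len(nrow(pairs)), function(i)
      avg_cross(pairs[i, 1], pairs[i, 2]))
  list(freq = seq(0, fs / 2, length.out = nf), auto = auto, cross = cross,
       n_segments = length(starts))
}

make_window_spectra <- function(x, roles, fs, tapers, overlap = 0.5,
                                fmin = 2, fmax = 100) {
  stn <- which(roles == "STN"); ctx <- which(roles == "CTX")
  pairs <- as.matrix(expand.grid(stn, ctx))
  cs <- cross_spectra(x, fs, tapers, overlap = overlap, pairs = pairs)
  coh <- rowMeans(vapply(seq_len(nrow(pairs)), function(i) {
    a <- pairs[i, 1]; b <- pairs[i, 2]
    Mod(cs$cross[[i]])^2 / (cs$auto[a, ] * cs$auto[b, ])
  }, numeric(length(cs$freq))))
  sel <- cs$freq >= fmin & cs$freq <= fmax
  structure(list(freq = cs$freq[sel],
                 stn_psd = colMeans(cs$auto[stn, sel, drop = FALSE]),
                 ctx_psd = colMeans(cs$auto[ctx, sel, drop = FALSE]),
                 coherence = pmin(coh[sel], 1),
                 n_segments = cs$n_segments),
            class = "window_spectra")
}

#' Static Welch spectra and coherence for one 2-min window
#'
#' @param x Channels x samples matrix (one 2-min window).
#' @param roles Per-channel roles (`"STN"`/`"CTX"`).
#' @param fs Sampling rate, Hz.
#' @param seg_len_s Welch segment length in seconds (default 2, giving
#'   0.5 Hz resolution at any fs).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return A `window_spectra`: `freq` (0.5 Hz grid over 2-100 Hz),
#'   channel-averaged `stn_psd` and `ctx_psd`, and pair-averaged
#'   magnitude-squared `coherence` pooled over all the window's segments.
#' @export
welch_spectra <- function(x, roles, fs = 250, seg_len_s = 2, overlap = 0.5) {
  nperseg <- as.integer(round(seg_len_s * fs))
  .assert(ncol(x) >= nperseg, "window shorter than one analysis segment")
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nperseg - 1) / (nperseg - 1))  # Hann
  w <- w / sqrt(sum(w^2))
  make_window_spectra(x, roles, fs, tapers = matrix(w, ncol = 1),
                      overlap = overlap)
}

#' State-masked multitaper spectra for one 2-min window
#'
#' For each state k the raw (non-embedded) signal is multiplied by the
#' indicator of the Viterbi path equalling k, and the masked signal is
#' analysed with the multitaper estimator. States occupying less than
#' `min_occupancy_s` seconds of the window are returned as `NULL`
#' (missing), not as zero-power spectra.
#'
#' @param x Channels x samples matrix (one 2-min window).
#' @param path Raw-sample-aligned state path for the window (`NA` allowed at
#'   embedding-trimmed samples).
#' @param K Number of states.
#' @param roles,fs As in [welch_spectra()].
#' @param NW Time-bandwidth product (default 4).
#' @param n_tapers Number of Slepian tapers (default 7 = 2*NW - 1).
#' @param seg_len_s,overlap Analysis-segment length and overlap.
#' @param min_occupancy_s Minimum total occupancy for a state to be
#'   estimated (default 2 s).
#' @return List of length K of `window_spectra` (or `NULL` for missing
#'   states).
#' @export
state_masked_spectra <- function(x, path, K, roles, fs = 250, NW = 4,
                                 n_tapers = 7, seg_len_s = 2, overlap = 0.5,
                                 min_occupancy_s = 2) {
  .assert(length(path) == ncol(x),
          "path length %d != window samples %d", length(path), ncol(x))
  nperseg <- as.integer(round(seg_len_s * fs))
  tapers <- dpss_tapers(nperseg, NW, n_tapers)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    mask <- as.numeric(!is.na(path) & path == k)
    if (sum(mask) < min_occupancy_s * fs) next
    out[[k]] <- make_window_spectra(x * rep(mask, each = nrow(x)),
                                    roles, fs, tapers, overlap = overlap)
  }
  if (all(vapply(out, is.null, logical(1))))
    message("no state reaches the minimum occupancy in this window")
  out
}

#' Whole-window multitaper spectra (no state masking)
#'
#' @inheritParams state_masked_spectra
#' @export
multitaper_spectra <- function(x, roles, fs = 250, NW = 4, n_tapers = 7,
                               seg_len_s = 2, overlap = 0.5) {
  nperseg <- as.integer(round(seg_len_s * fs))
  make_window_spectra(x, roles, fs, dpss_tapers(nperseg, NW, n_tapers),
                      overlap = overlap)
}

#' Band-averaged spectral features
#'
#' Averages each region-metric (STN PSD, CTX PSD, STN-CTX coherence) over
#' the bins of each canonical band (edges inclusive): 3 metrics x 5 bands =
#' 15 features for a static `window_spectra`, or 15 x K named
#' `state{k}_{metric}_{band}` for a state-resolved list (missing states
#' yield `NA` features).
#'
#' @param spectra A `window_spectra` or a list of K of them (as returned by
#'   [state_masked_spectra()]).
#' @param scheme Band scheme, see [band_scheme()].
#' @return Named numeric feature vector.
#' @export
band_features <- function(spectra, scheme = band_scheme()) {
  one <- function(ws, prefix = "") {
    if (is.null(ws)) {
      v <- rep(NA_real_, 3 * length(scheme))
    } else {
      .assert(all(vapply(scheme, function(b) b[1] >= min(ws$freq) &&
                           b[2] <= max(ws$freq), logical(1))),
              "band edges outside the spectral grid")
      v <- unlist(lapply(c("stn_psd", "ctx_psd", "coherence"), function(m)
        vapply(scheme, function(b) {
          sel <- ws$freq >= b[1] & ws$freq <= b[2]
          mean(ws[[m]][sel])
        }, numeric(1))))
    }
    names(v) <- paste0(prefix,
                       rep(c("stn", "ctx", "coh"), each = length(scheme)),
                       "_", rep(names(scheme), 3))
    v
  }
  if (inherits(spectra, "window_spectra")) return(one(spectra))
  .assert(is.list(spectra), "spectra must be a window_spectra or list of them")
  unlist(lapply(seq_along(spectra), function(k)
    one(spectra[[k]], sprintf("state%d_", k))))
}

#' Decile-stratified mean spectra
#'
#' Splits windows into the top and bottom deciles of a symptom score within
#' each participant-hemisphere unit, averages window spectra within unit and
#' decile, and reports the mean and standard error across units.
#'
#' @param spectra_list List of `window_spectra` (or `NULL` for missing
#'   windows), one per row of `meta`.
#' @param meta Data frame with `participant`, `hemisphere` and `score`
#'   columns aligned with `spectra_list`.
#' @param metric One of `"stn_psd"`, `"ctx_psd"`, `"coherence"`.
#' @param decile Fraction defining the extreme groups (default 0.1).
#' @return Data frame: `freq`, `top_mean`, `top_sem`, `bottom_mean`,
#'   `bottom_sem`, and the unit counts as attributes.
#' @export
decile_stratified_spectra <- function(spectra_list, meta,
                                      metric = c("stn_psd", "ctx_psd",
                                                 "coherence"),
                                      decile = 0.1) {
  metric <- match.arg(metric)
  ok <- !vapply(spectra_list, is.null, logical(1))
  .assert(any(ok), "no spectra available")
  freq <- spectra_list[[which(ok)[1]]]$freq
  unit <- paste0(meta$participant, "_", meta$hemisphere)
  units <- unique(unit)
  top <- bottom <- matrix(NA_real_, length(units), length(freq))
  for (i in seq_along(units)) {
    sel <- which(unit == units[i] & ok)
    if (length(sel) < 2) next
    sc <- meta$score[sel]
    lo <- quantile(sc, decile, names = FALSE)
    hi <- quantile(sc, 1 - decile, names = FALSE)
    avg <- function(rows) {
      if (!length(rows)) return(rep(NA_real_, length(freq)))
      colMeans(do.call(rbind, lapply(spectra_list[rows],
                                     function(s) s[[metric]])))
    }
    bottom[i, ] <- avg(sel[sc <= lo])
    top[i, ] <- avg(sel[sc >= hi])
  }
  msem <- function(M) {
    n <- colSums(!is.na(M))
    list(mean = colMeans(M, na.rm = TRUE),
         sem = apply(M, 2, sd, na.rm = TRUE) / sqrt(pmax(n, 1)))
  }
  tt <- msem(top); bb <- msem(bottom)
  structure(data.frame(freq = freq, top_mean = tt$mean, top_sem = tt$sem,
                       bottom_mean = bb$mean, bottom_sem = bb$sem),
            n_units = length(units))
}
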