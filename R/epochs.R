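#' Epoched multichannel EEG recording
#'
#' The basic data container of the package: a `channels x trials x samples`
#' numeric array of epoched EEG, together with the sampling rate, the position
#' of the cue onset inside the epoch, channel labels, and the study cell the
#' epochs belong to (subject, session, condition).
#'
#' Epochs span 2.5 s: 0.5 s before cue onset and 2 s after, so `time0 = 0.5`
#' by default and the sample at index `time0 * fs` (0-based) falls on the
#' onset. All window arithmetic in the package is 0-based and half-open.
#'
#' @param data numeric array, `channels x trials x samples`.
#' @param fs sampling rate in Hz.
#' @param channel_labels character vector of unique channel names
#'   (10-20 positions for real montages).
#' @param time0 seconds from epoch start to cue onset (default 0.5).
#' @param session one of `"Pre"`, `"Sleep"`, `"Post"` (or `NA`).
#' @param condition cued hand, `"L"` or `"R"` (or `NA`).
#' @param subject_id subject identifier.
#' @param meta optional named list of extra metadata (filter settings,
#'   normalisation factors, ...).
#'
#' @return an object of class `epoched_recording`.
#' @export
epoched_recording <- function(data, fs, channel_labels,
                              time0 = 0.5,
                              session = NA_character_,
                              condition = NA_character_,
                              subject_id = NA_character_,
                              meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a channels x trials x samples array")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar")
  if (length(channel_labels) != dim(data)[1L])
    stop("length(channel_labels) must equal the number of channels")
  if (anyDuplicated(channel_labels))
    stop("channel labels must be unique")
  if (anyNA(data))
    stop("epoched data must not contain NAs")
  dimnames(data) <- list(channel_labels, NULL, NULL)
  structure(
    list(data = data, fs = fs, time0 = time0,
         channel_labels = as.character(channel_labels),
         session = session, condition = condition,
         subject_id = subject_id, meta = meta),
    class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_recording> %d channels x %d trials x %d samples @ %g Hz\n",
              d[1L], d[2L], d[3L], x$fs))
  cat(sprintf("  onset at %.3g s; subject %s, session %s, condition %s\n",
              x$time0, x$subject_id, x$session, x$condition))
  cat("  channels: ", paste(x$channel_labels, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.epoched_recording <- function(x) dim(x$data)

n_trials <- function(rec) dim(rec$data)[2L]
n_samples <- function(rec) dim(rec$data)[3L]
n_channels <- function(rec) dim(rec$data)[1L]

#' Cut continuous multichannel data into cue-locked epochs
#'
#' Extracts one 2.5 s trial per cue onset: 0.5 s before the onset sample to
#' 2 s after it, as the half-open sample window
#' `[onset - 0.5 * fs, onset + 2 * fs)` in 0-based indexing. Onsets too close
#' to either end of the recording are dropped, and the number dropped is
#' recorded in the result's metadata (and reported via `message()`).
#'
#' @param continuous numeric matrix, `channels x samples`.
#' @param onsets integer vector of cue-onset sample indices (0-based).
#' @param fs sampling rate in Hz.
#' @param channel_labels optional channel names; defaults to rownames or
#'   `ch1..chN`.
#' @param ... passed on to [epoched_recording()] (session, condition, ...).
#'
#' @return an `epoched_recording`; `meta$n_dropped` counts rejected onsets,
#'   `meta$onsets_used` the retained 0-based onsets.
#' @export
epoch <- function(continuous, onsets, fs, channel_labels = NULL, ...) {
  if (!is.matrix(continuous)) stop("`continuous` must be a channels x samples matrix")
  if (length(onsets) == 0L) stop("`onsets` must not be empty")
  if (!is.numeric(fs) || fs <= 0) stop("`fs` must be positive")
  pre <- round(0.5 * fs); post <- round(2 * fs)
  n <- ncol(continuous)
  onsets <- as.integer(onsets)
  ok <- onsets - pre >= 0L & onsets + post <= n
  n_dropped <- sum(!ok)
  if (n_dropped > 0L)
    message(sprintf("epoch(): dropped %d onset(s) without a full [-0.5, 2) s window", n_dropped))
  kept <- onsets[ok]
  if (length(kept) == 0L) stop("no onset has a full epoch window inside the recording")
  len <- pre + post
  dat <- array(0, dim = c(nrow(continuous), length(kept), len))
  for (k in seq_along(kept)) {
    idx <- (kept[k] - pre):(kept[k] + post - 1L) + 1L  # to 1-based
    dat[, k, ] <- continuous[, idx]
  }
  if (is.null(channel_labels))
    channel_labels <- rownames(continuous) %||% paste0("ch", seq_len(nrow(continuous)))
  epoched_recording(dat, fs, channel_labels, time0 = pre / fs,
                    meta = list(n_dropped = n_dropped, onsets_used = kept,
                                edge = "extend"), ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Zero-phase FIR band-pass kernel: Hamming-window design (signal::fir1) with an
# odd tap count chosen for a ~2 Hz transition band, applied as a centred
# symmetric convolution (linear phase exactly cancelled). Reflection padding
# absorbs the filter half-length at the epoch edges.
theta_fir <- function(fs, band, transition = 2) {
  ntaps <- ceiling(3.3 * fs / transition)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  as.numeric(signal::fir1(ntaps - 1, band / (fs / 2), type = "pass"))
}

# Apply an odd-length symmetric FIR to the columns of a matrix; output has
# the same number of rows, zero phase. Edge padding is either an odd
# (point-symmetric) reflection, or an AR(2) damped-sinusoid extrapolation
# that continues a dominant oscillation past the boundary (used for the
# band-pass so that the end of the epoch is not distorted).
filtfilt_sym <- function(x, h, pad = c("reflect", "extend")) {
  pad <- match.arg(pad)
  k <- (length(h) - 1L) / 2L
  n <- nrow(x)
  if (k >= n) stop("epoch too short for the designed filter")
  if (pad == "reflect") {
    pad_top <- 2 * x[rep(1L, k), , drop = FALSE] - x[seq(k + 1L, 2L), , drop = FALSE]
    pad_bot <- 2 * x[rep(n, k), , drop = FALSE] - x[seq(n - 1L, n - k), , drop = FALSE]
  } else {
    ext <- edge_extend(x, k)
    pad_top <- ext$top
    pad_bot <- ext$bot
  }
  xp <- rbind(pad_top, x, pad_bot)
  y <- stats::filter(xp, h, method = "convolution", sides = 2L)
  y <- as.matrix(y)[(k + 1L):(k + n), , drop = FALSE]
  y
}

# Frequency-sampled zero-phase band-pass response on the length-n FFT grid,
# for circular application by spectral multiplication: gain exactly 1 inside
# the band (so band-limited content passes untouched and the filter is
# exactly idempotent on it), raised-cosine roll-off over `transition` Hz,
# exactly 0 beyond.
band_response <- function(n, fs, band, transition = 2) {
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) * fs / n        # two-sided frequency of each bin
  g <- numeric(n)
  g[f >= band[1] & f <= band[2]] <- 1
  lo <- max(band[1] - transition, 0)
  rise <- f > lo & f < band[1]
  g[rise] <- 0.5 * (1 - cos(pi * (f[rise] - lo) / (band[1] - lo)))
  fall <- f > band[2] & f < band[2] + transition
  g[fall] <- 0.5 * (1 + cos(pi * (f[fall] - band[2]) / transition))
  g
}

#' Band-pass filter epochs to the theta band
#'
#' Zero-phase FIR band-pass (default 3-8 Hz) applied per channel and trial.
#' The filter is a Hamming-window FIR (odd tap count, ~2 Hz transition band,
#' stopband attenuation >= 40 dB at 1 Hz and 12 Hz for the default band)
#' applied as a centred symmetric convolution, so the group delay is zero by
#' construction. Epoch edges are handled by signal reflection; the outermost
#' 0.25 s at each end are still flagged as edge-affected in the metadata.
#'
#' @param rec an `epoched_recording`.
#' @param band numeric length-2, passband edges in Hz (default `c(3, 8)`).
#' @param edge boundary handling: `"periodic"` applies the filter circularly
#'   by spectral multiplication (exact for circularly constructed epochs,
#'   e.g. from the synthetic generator); `"extend"` pads each epoch with a
#'   damped-sinusoid carrier extrapolation before convolving (for epochs cut
#'   out of a continuous recording, see [epoch()]); `"auto"` (default) reads
#'   the recording's own edge provenance (`meta$edge`), falling back to
#'   `"periodic"`.
#'
#' @return the filtered `epoched_recording`; `meta$filter` records the design
#'   (taps, band, transition width) and `meta$edge_flag_s = 0.25`.
#' @export
bandpass_theta <- function(rec, band = c(3, 8),
                           edge = c("auto", "periodic", "extend")) {
  stopifnot(inherits(rec, "epoched_recording"))
  edge <- match.arg(edge)
  if (edge == "auto") edge <- rec$meta$edge %||% "periodic"
  if (length(band) != 2L || band[1] <= 0 || band[2] >= rec$fs / 2 || band[1] >= band[2])
    stop("`band` must lie strictly inside (0, fs/2)")
  d <- dim(rec$data)
  # samples x (channels*trials) matrix view
  m <- matrix(aperm(rec$data, c(3, 1, 2)), nrow = d[3L])
  if (edge == "periodic") {
    fr <- band_response(d[3L], rec$fs, band, transition = 0)
    y <- Re(stats::mvfft(stats::mvfft(m) * fr, inverse = TRUE)) / d[3L]
    design <- list(design = "frequency-sampled, flat passband, raised-cosine roll-off",
                   band = band, transition_hz = 2, edge = edge)
  } else {
    h <- theta_fir(rec$fs, band)
    y <- filtfilt_sym(m, h, pad = "extend")
    design <- list(design = "hamming fir1, zero-phase symmetric",
                   taps = length(h), band = band, transition_hz = 2, edge = edge)
  }
  out <- aperm(array(y, dim = c(d[3L], d[1L], d[2L])), c(2, 3, 1))
  rec$data <- out
  dimnames(rec$data) <- list(rec$channel_labels, NULL, NULL)
  rec$meta$filter <- design
  rec$meta$edge <- edge
  rec$meta$edge_flag_s <- 0.25
  rec
}

#' Normalise trial amplitudes by the pooled two-condition average
#'
#' Divides every trial of every channel by that channel's grand mean RMS
#' amplitude, pooled over all trials of both conditions (left- and right-hand
#' cues) of the same subject and session. Because the connectivity metrics
#' downstream are phase-based, this normalisation leaves them unchanged; it is
#' retained so that amplitudes are on a common scale across subjects and
#' conditions.
#'
#' @param rec_L,rec_R `epoched_recording`s for the two conditions of one
#'   subject and session (same channels, same fs).
#'
#' @return a list with elements `L` and `R`, the normalised recordings; each
#'   carries the per-channel scaling factors in `meta$norm_factors`.
#' @export
normalise_trials <- function(rec_L, rec_R) {
  stopifnot(inherits(rec_L, "epoched_recording"), inherits(rec_R, "epoched_recording"))
  if (!identical(rec_L$channel_labels, rec_R$channel_labels))
    stop("conditions must share the same channels")
  if (rec_L$fs != rec_R$fs) stop("conditions must share the same sampling rate")
  rms_by_trial <- function(rec) sqrt(apply(rec$data^2, c(1, 2), mean))
  pooled <- cbind(rms_by_trial(rec_L), rms_by_trial(rec_R))  # channels x all trials
  factors <- rowMeans(pooled)
  zero <- factors == 0
  if (any(zero))
    stop("zero grand-mean RMS on channel(s): ",
         paste(rec_L$channel_labels[zero], collapse = ", "))
  scale_rec <- function(rec) {
    rec$data <- rec$data / factors  # recycles over the channel (first) axis
    rec$meta$norm_factors <- stats::setNames(factors, rec$channel_labels)
    rec
  }
  list(L = scale_rec(rec_L), R = scale_rec(rec_R))
}
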