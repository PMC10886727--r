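#' The three overlapping analysis windows
#'
#' Connectivity is estimated in 1 s sliding windows with 50% overlap, giving
#' three windows per trial: w1 = [0, 1) s, w2 = [0.5, 1.5) s and w3 = [1, 2) s
#' after cue onset. One second of theta (3-8 Hz) holds 3-8 cycles, the minimum
#' recommended for a stable phase-synchrony estimate.
#'
#' @param fs sampling rate in Hz.
#' @param time0 cue-onset position within the epoch, seconds (default 0.5).
#'
#' @return a data.frame with columns `label`, `start_s`, `stop_s`,
#'   `start_sample`, `n_samples` (`start_sample` is the 0-based offset of the
#'   window within the epoch).
#' @export
analysis_windows <- function(fs, time0 = 0.5) {
  start_s <- c(0, 0.5, 1)
  data.frame(label = c("w1", "w2", "w3"),
             start_s = start_s, stop_s = start_s + 1,
             start_sample = as.integer(round((time0 + start_s) * fs)),
             n_samples = as.integer(round(fs)),
             stringsAsFactors = FALSE)
}

# Frequency-domain analytic-signal construction: positive-frequency bins
# doubled, negative bins zeroed, DC and Nyquist kept. Operates on the columns
# of a real matrix (samples x series).
analytic_fft <- function(x) {
  n <- nrow(x)
  X <- stats::mvfft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::mvfft(X * h, inverse = TRUE) / n
}

# Damped-sinusoid edge extrapolation of each column by k samples at both
# ends. A first-pass (periodic) analytic transform gives the local complex
# carrier; a complex AR(1) fit over the last / first `m` samples estimates
# its rotation-and-decay factor per column (clamped inside the unit circle),
# and the carrier is continued geometrically past the boundary. This follows
# the dominant narrowband oscillation through envelope minima; broadband
# columns simply decay. Returns real padding matrices `top` and `bot`.
edge_extend <- function(x, k, m = 40L) {
  n <- nrow(x)
  m <- min(m, n - 1L)
  a <- analytic_fft(x)
  fit <- function(lead, lagd, anchor) {
    den <- colSums(Mod(lagd)^2)
    rho <- colSums(lead * Conj(lagd)) / pmax(den, 1e-300)
    rho[den <= 1e-300] <- 0 + 0i
    rho <- rho * pmin(1, 0.9999 / pmax(Mod(rho), 1e-12))
    out <- matrix(0 + 0i, k, ncol(x))
    cur <- anchor
    for (i in seq_len(k)) {
      cur <- cur * rho
      out[i, ] <- cur
    }
    Re(out)
  }
  idx <- (n - m):(n - 1L)
  bot <- fit(a[idx + 1L, , drop = FALSE], a[idx, , drop = FALSE], a[n, ])
  idx2 <- 2L:(m + 1L)
  top <- fit(a[idx2 - 1L, , drop = FALSE], a[idx2, , drop = FALSE], a[1L, ])
  list(top = top[k:1L, , drop = FALSE], bot = bot)
}

# Analytic signal of each column. `edge = "periodic"` applies the FFT
# construction directly (exact when the epoch is circular, as for the
# synthetic generator's spectrally constructed epochs and for all Fourier
# surrogates). `edge = "extend"` first continues each column by half an
# epoch at both ends with the damped-sinusoid carrier extrapolation
# (edge_extend) so that the wrap-around transient of the FFT stays outside
# the epoch -- appropriate for epochs cut out of a continuous recording.
analytic_signal <- function(x, edge = c("periodic", "extend")) {
  edge <- match.arg(edge)
  x <- as.matrix(x)
  if (edge == "periodic") return(analytic_fft(x))
  n <- nrow(x)
  k <- max(2L, floor(n / 2))
  ext <- edge_extend(x, k)
  a <- analytic_fft(rbind(ext$top, x, ext$bot))
  a[(k + 1L):(k + n), , drop = FALSE]
}

#' Instantaneous phase of a band-limited signal
#'
#' Phase of the analytic signal (Hilbert-transform construction). The analytic
#' signal is computed over the full 2.5 s epoch and only then sliced into
#' analysis windows, which keeps the transform's edge transients out of the
#' windows of interest (epochs carry 0.5 s of pre-onset padding).
#'
#' @param x numeric vector (one channel of one trial) or a samples x series
#'   matrix.
#' @param edge boundary handling: `"periodic"` (plain FFT construction,
#'   exact for circularly constructed epochs) or `"extend"` (damped-sinusoid
#'   carrier extrapolation past both ends, for epochs cut from a continuous
#'   recording).
#'
#' @return phase in radians wrapped to (-pi, pi], same shape as `x`.
#' @export
instantaneous_phase <- function(x, edge = c("periodic", "extend")) {
  if (all(x == 0)) stop("instantaneous phase is undefined for an all-zero signal")
  a <- analytic_signal(x, edge = edge)
  ph <- Arg(a)
  if (is.matrix(x)) ph else as.numeric(ph)
}

#' Phase-locking value
#'
#' PLV of a phase-difference series theta(t): the modulus of the mean unit
#' phasor, `|mean(exp(i * theta))|`. Equals 1 iff the phase difference is
#' constant and tends to 0 for unsynchronised phases; for T i.i.d. uniform
#' phases the null expectation is approximately `sqrt(pi) / (2 * sqrt(T))`.
#'
#' @param theta numeric vector of phase differences in radians.
#'
#' @return a value in `[0, 1]`.
#' @export
plv <- function(theta) {
  if (length(theta) == 0L) stop("PLV of an empty phase series is undefined")
  min(Mod(mean(exp(1i * theta))), 1)
}

#' Weighted phase lag index
#'
#' wPLI of a cross-spectral sample series for one channel pair:
#' `|mean(Im Pxy)| / mean(|Im Pxy|)`. Weighting by the magnitude of the
#' imaginary cross-spectrum makes near-zero-lag samples (the volume-conduction
#' signature) carry little weight. If every imaginary part is exactly zero
#' (pure zero-lag coupling) the index is undefined; the convention here is a
#' value of 0 with `degenerate = TRUE`.
#'
#' @param pxy complex cross-spectral samples (or their imaginary parts as a
#'   numeric vector).
#'
#' @return a list with `value` in `[0, 1]` and logical `degenerate`.
#' @export
wpli <- function(pxy) {
  if (length(pxy) == 0L) stop("wPLI of an empty cross-spectrum is undefined")
  im <- if (is.complex(pxy)) Im(pxy) else as.numeric(pxy)
  denom <- mean(abs(im))
  if (denom == 0) return(list(value = 0, degenerate = TRUE))
  list(value = min(abs(mean(im)) / denom, 1), degenerate = FALSE)
}

all_pairs <- function(labels) {
  idx <- utils::combn(length(labels), 2L)
  data.frame(i = idx[1L, ], j = idx[2L, ],
             chan_i = labels[idx[1L, ]], chan_j = labels[idx[2L, ]],
             stringsAsFactors = FALSE)
}

#' Windowed phase connectivity for all channel pairs
#'
#' Computes PLV and/or wPLI for every unordered channel pair, in each analysis
#' window of each trial. Phases come from the analytic signal of the full
#' epoch; the cross-spectral samples for wPLI are the per-sample products of
#' the two analytic signals, `x(t) * Conj(y(t))`, within the window
#' (time-domain Hilbert formulation).
#'
#' @param rec a theta-filtered (and typically normalised) `epoched_recording`.
#' @param metrics character vector, subset of `c("plv", "wpli")`.
#' @param windows window table from [analysis_windows()]; defaults to the
#'   standard w1/w2/w3 layout for `rec$fs`.
#'
#' @return a `connectivity_tensor`: list with `values` (named list of
#'   `pairs x windows x trials` arrays per metric, each value in `[0, 1]`),
#'   `degenerate` (logical array for wPLI), `pairs`, `windows`, and the
#'   recording's cell metadata.
#' @export
windowed_connectivity <- function(rec, metrics = c("plv", "wpli"), windows = NULL) {
  stopifnot(inherits(rec, "epoched_recording"))
  metrics <- match.arg(metrics, c("plv", "wpli"), several.ok = TRUE)
  if (is.null(windows)) windows <- analysis_windows(rec$fs, rec$time0)
  if (n_channels(rec) < 13L)
    warning("fewer than 13 channels configured; proceeding on available pairs")
  d <- dim(rec$data)
  m <- matrix(aperm(rec$data, c(3, 1, 2)), nrow = d[3L])  # samples x (ch*trials)
  a <- analytic_signal(m, edge = rec$meta$edge %||% "periodic")
  cube <- array(a, dim = c(d[3L], d[1L], d[2L]))          # samples x ch x trials
  pairs <- all_pairs(rec$channel_labels)
  win_mat <- cbind(windows$start_sample, windows$start_sample + windows$n_samples)
  res <- pair_metrics_cpp(cube, as.matrix(pairs[, c("i", "j")]) - 1L,
                          win_mat, "plv" %in% metrics, "wpli" %in% metrics)
  values <- list()
  dn <- list(NULL, windows$label, NULL)
  if ("plv" %in% metrics) { values$plv <- res$plv; dimnames(values$plv) <- dn }
  degenerate <- NULL
  if ("wpli" %in% metrics) {
    values$wpli <- res$wpli; dimnames(values$wpli) <- dn
    degenerate <- res$degenerate; dimnames(degenerate) <- dn
  }
  structure(
    list(values = values, degenerate = degenerate, pairs = pairs,
         windows = windows, channel_labels = rec$channel_labels,
         subject_id = rec$subject_id, session = rec$session,
         condition = rec$condition, fs = rec$fs),
    class = "connectivity_tensor")
}

#' @export
print.connectivity_tensor <- function(x, ...) {
  v <- x$values[[1L]]
  cat(sprintf("<connectivity_tensor> %s: %d pairs x %d windows x %d trials\n",
              paste(names(x$values), collapse = "+"),
              dim(v)[1L], dim(v)[2L], dim(v)[3L]))
  cat(sprintf("  subject %s, session %s, condition %s\n",
              x$subject_id, x$session, x$condition))
  invisible(x)
}

#' Long-format view of a connectivity tensor
#'
#' @param x a `connectivity_tensor`.
#' @param ... unused.
#' @return a data.frame with columns subject, session, condition, metric,
#'   window, chan_i, chan_j, trial, value, degenerate.
#' @export
as.data.frame.connectivity_tensor <- function(x, ...) {
  out <- list()
  for (metric in names(x$values)) {
    v <- x$values[[metric]]
    d <- dim(v)
    df <- expand.grid(pair = seq_len(d[1L]), window = x$windows$label,
                      trial = seq_len(d[3L]), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
    df$metric <- metric
    df$chan_i <- x$pairs$chan_i[df$pair]
    df$chan_j <- x$pairs$chan_j[df$pair]
    df$value <- as.vector(v)
    df$degenerate <- if (metric == "wpli" && !is.null(x$degenerate))
      as.vector(x$degenerate) else FALSE
    out[[metric]] <- df
  }
  df <- do.call(rbind, out)
  df$subject <- x$subject_id; df$session <- x$session; df$condition <- x$condition
  rownames(df) <- NULL
  df[, c("subject", "session", "condition", "metric", "window",
         "chan_i", "chan_j", "trial", "value", "degenerate")]
}
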