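# Permute the phases of the positive-frequency bins of each column of a
# complex spectrum (amplitudes stay in place), then restore Hermitian
# symmetry so the inverse transform is real. DC and Nyquist are kept real.
# The within-column permutations come from ranking one block of uniform
# draws per column (vectorised over all columns).
shuffle_phases_fft <- function(X) {
  n <- nrow(X)
  nc <- ncol(X)
  hi <- if (n %% 2L == 0L) n / 2L else (n + 1L) / 2L
  pos <- seq(2L, hi)
  np <- length(pos)
  Z <- X[pos, , drop = FALSE]
  ord <- order(rep(seq_len(nc), each = np), stats::runif(np * nc))
  X[pos, ] <- Mod(Z) * exp(1i * matrix(Arg(Z)[ord], np, nc))
  X[1L, ] <- Re(X[1L, ])
  if (n %% 2L == 0L) X[n / 2L + 1L, ] <- Re(X[n / 2L + 1L, ])
  X[n - pos + 2L, ] <- Conj(X[pos, , drop = FALSE])
  X
}

#' Phase-shuffled surrogate of an epoch
#'
#' Fourier-based surrogate: the discrete Fourier transform is taken per
#' channel, the phases of the positive-frequency bins are randomly permuted
#' (independently per channel), the negative-frequency bins are set to the
#' conjugate mirror, and the inverse transform is returned. The per-channel
#' amplitude spectrum is preserved exactly while phase relationships across
#' channels are destroyed.
#'
#' @param x numeric vector (one channel) or samples x channels matrix.
#' @return surrogate data, same shape as `x`.
#' @export
phase_shuffle <- function(x) {
  vec <- !is.matrix(x)
  m <- as.matrix(x)
  S <- shuffle_phases_fft(stats::mvfft(m))
  out <- Re(stats::mvfft(S, inverse = TRUE)) / nrow(m)
  if (vec) as.numeric(out) else out
}

#' Time-shuffled surrogate of an epoch
#'
#' Randomly permutes the samples of each channel independently; the sample
#' multiset (hence variance and all moments) is preserved exactly while all
#' temporal and cross-channel structure is destroyed.
#'
#' @param x numeric vector or samples x channels matrix.
#' @return surrogate data, same shape as `x`.
#' @export
time_shuffle <- function(x) {
  vec <- !is.matrix(x)
  m <- as.matrix(x)
  out <- apply(m, 2L, function(col) col[sample.int(length(col))])
  if (vec) as.numeric(out) else out
}

#' Build a surrogate null ensemble for a recording
#'
#' Applies the full windowed-connectivity computation to `n` surrogate copies
#' of every trial, giving an empirical null distribution of the metric for
#' each (pair, window, trial) cell. Surrogates are drawn per channel and
#' trial with [phase_shuffle()] or [time_shuffle()].
#'
#' @param rec a preprocessed `epoched_recording` (same preprocessing as the
#'   real computation).
#' @param metrics subset of `c("plv", "wpli")`.
#' @param n number of surrogates (default 100; fewer than 20 triggers a
#'   warning because the 95th centile becomes unstable).
#' @param method `"phase"` or `"time"`.
#' @param seed integer seed for the surrogate RNG stream.
#' @param windows window table, defaulting to the standard w1/w2/w3 layout.
#' @param band passband used to re-band-limit time-shuffled surrogates
#'   (default 3-8 Hz). Scrambling samples whitens the spectrum, so without
#'   re-filtering the time-method null would not share the real data's
#'   narrowband phase smoothness; phase-shuffled surrogates keep the
#'   amplitude spectrum by construction and are never re-filtered.
#'
#' @return a `surrogate_ensemble`: list with `null` (named list per metric of
#'   `pairs x windows x trials x n` arrays), `n`, `method`, `seed`, `pairs`,
#'   `windows`.
#' @export
build_null <- function(rec, metrics = c("plv", "wpli"), n = 100,
                       method = c("phase", "time"), seed = 1, windows = NULL,
                       band = c(3, 8)) {
  stopifnot(inherits(rec, "epoched_recording"))
  method <- match.arg(method)
  metrics <- match.arg(metrics, c("plv", "wpli"), several.ok = TRUE)
  if (n < 20) warning("fewer than 20 surrogates: the 95th centile is unstable")
  if (is.null(windows)) windows <- analysis_windows(rec$fs, rec$time0)
  d <- dim(rec$data)
  m <- matrix(aperm(rec$data, c(3, 1, 2)), nrow = d[3L])  # samples x (ch*trials)
  X <- stats::mvfft(m)
  ns <- d[3L]
  fresp <- NULL
  if (method == "time")
    fresp <- band_response(ns, rec$fs, band, transition = 0)
  edge <- rec$meta$edge %||% "periodic"
  h <- numeric(ns)  # analytic-signal spectral multiplier
  if (ns %% 2L == 0L) { h[1] <- 1; h[ns / 2 + 1] <- 1; h[2:(ns / 2)] <- 2
  } else { h[1] <- 1; h[2:((ns + 1) / 2)] <- 2 }
  pairs <- all_pairs(rec$channel_labels)
  win_mat <- cbind(windows$start_sample, windows$start_sample + windows$n_samples)
  n_pairs <- nrow(pairs)
  null <- lapply(stats::setNames(metrics, metrics), function(mm)
    array(NA_real_, dim = c(n_pairs, nrow(windows), d[2L], n)))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  for (k in seq_len(n)) {
    S <- if (method == "phase") {
      shuffle_phases_fft(X)
    } else {
      ms <- apply(m, 2L, function(col) col[sample.int(ns)])
      stats::mvfft(ms) * fresp
    }
    if (edge == "periodic") {
      # fused: the analytic signal straight from the surrogate spectrum
      a <- stats::mvfft(S * h, inverse = TRUE) / ns
    } else {
      xs <- Re(stats::mvfft(S, inverse = TRUE)) / ns
      a <- analytic_signal(xs, edge = "extend")
    }
    cube <- array(a, dim = c(ns, d[1L], d[2L]))
    res <- pair_metrics_cpp(cube, as.matrix(pairs[, c("i", "j")]) - 1L,
                            win_mat, "plv" %in% metrics, "wpli" %in% metrics)
    for (mm in metrics) null[[mm]][, , , k] <- res[[mm]]
  }
  structure(list(null = null, n = n, method = method, seed = seed,
                 pairs = pairs, windows = windows,
                 subject_id = rec$subject_id, session = rec$session,
                 condition = rec$condition),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  d <- dim(x$null[[1L]])
  cat(sprintf("<surrogate_ensemble> %s-shuffled, %d surrogates: %d pairs x %d windows x %d trials\n",
              x$method, x$n, d[1L], d[2L], d[3L]))
  invisible(x)
}

row_order_stat <- function(m, k) {
  apply(m, 1L, function(r) sort.int(r, partial = k)[k])
}

#' Prune links not exceeding the surrogate null
#'
#' Compares every (pair, window, trial) cell of the real connectivity tensor
#' against its own surrogate null: cells at or below the null's
#' `(1 - alpha)` centile are set to zero and flagged not-significant; cells
#' above it are kept. The centile is the empirical `ceil((1-alpha)(n+1))`-th
#' order statistic of the n surrogate values, so that keeping is equivalent
#' to the rank-based empirical p-value (+1 correction,
#' `p = (1 + #{null >= real}) / (n + 1)`, returned for audit) falling at or
#' below `alpha` -- the rule's false-positive rate is at most `alpha`
#' exactly, with no interpolation bias. Benjamini-Hochberg FDR on the
#' empirical p-values is available as an alternative keep rule. Degenerate
#' wPLI cells (zero-lag, 0/0) are excluded: never kept, p set to `NA`.
#'
#' @param real a `connectivity_tensor`.
#' @param null a `surrogate_ensemble` built from the same recording.
#' @param alpha significance level (default 0.05, i.e. the 95th centile).
#' @param rule `"centile"` (default: keep if real > (1-alpha) null centile)
#'   or `"bh"` (keep if the BH-adjusted empirical p <= alpha).
#'
#' @return a list with `pruned` (the tensor with non-significant cells
#'   zeroed) and `mask` (a `significance_mask`: per-metric logical `keep`
#'   arrays, null centiles, empirical and adjusted p-values, alpha).
#' @export
significance_prune <- function(real, null, alpha = 0.05,
                               rule = c("centile", "bh")) {
  stopifnot(inherits(real, "connectivity_tensor"),
            inherits(null, "surrogate_ensemble"))
  rule <- match.arg(rule)
  metrics <- intersect(names(real$values), names(null$null))
  if (length(metrics) == 0L) stop("real tensor and null share no metric")
  keep <- centile <- pval <- padj <- list()
  pruned <- real
  for (mm in metrics) {
    rv <- real$values[[mm]]
    nv <- null$null[[mm]]
    if (!identical(dim(rv), dim(nv)[1:3]))
      stop("real and null shapes do not match for metric ", mm)
    d <- dim(rv)
    nm <- matrix(nv, nrow = prod(d))              # cells x n surrogates
    k_idx <- min(ceiling((1 - alpha) * (null$n + 1)), null$n)
    q <- row_order_stat(nm, k_idx)
    p <- (1 + rowSums(nm >= as.vector(rv))) / (null$n + 1)
    k <- as.vector(rv) > q
    pa <- stats::p.adjust(p, method = "BH")
    if (rule == "bh") k <- pa <= alpha
    if (mm == "wpli" && !is.null(real$degenerate)) {
      degen <- as.vector(real$degenerate)
      k[degen] <- FALSE
      p[degen] <- NA_real_
    }
    keep[[mm]] <- array(k, dim = d, dimnames = dimnames(rv))
    centile[[mm]] <- array(q, dim = d, dimnames = dimnames(rv))
    pval[[mm]] <- array(p, dim = d, dimnames = dimnames(rv))
    padj[[mm]] <- array(pa, dim = d, dimnames = dimnames(rv))
    zv <- rv; zv[!keep[[mm]]] <- 0
    pruned$values[[mm]] <- zv
  }
  mask <- structure(list(keep = keep, centile = centile, p = pval,
                         p_adj = padj, alpha = alpha, rule = rule,
                         n_surrogates = null$n, method = null$method,
                         pairs = real$pairs, windows = real$windows,
                         subject_id = real$subject_id, session = real$session,
                         condition = real$condition),
                    class = "significance_mask")
  list(pruned = pruned, mask = mask)
}

#' @export
print.significance_mask <- function(x, ...) {
  for (mm in names(x$keep)) {
    k <- x$keep[[mm]]
    cat(sprintf("<significance_mask> %s: keep rate %.1f%% (%d of %d cells), alpha %.3g, %s rule, %d %s surrogates\n",
                mm, 100 * mean(k), sum(k), length(k), x$alpha, x$rule,
                x$n_surrogates, x$method))
  }
  invisible(x)
}
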