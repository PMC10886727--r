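# Straight-line reference implementations, kept deliberately independent of
# the package's vectorised / compiled code paths: everything here is plain
# loops over the defining formulas.

# analytic signal of one numeric vector by the direct DFT construction
ref_analytic <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

ref_plv <- function(theta) {
  s <- 0 + 0i
  for (t in seq_along(theta)) s <- s + exp(1i * theta[t])
  Mod(s / length(theta))
}

ref_wpli <- function(im) {
  num <- 0; den <- 0
  for (t in seq_along(im)) {
    num <- num + im[t]
    den <- den + abs(im[t])
  }
  if (den == 0) return(list(value = 0, degenerate = TRUE))
  list(value = abs(num) / den, degenerate = FALSE)
}

# windowed connectivity of an epoched recording, one value at a time
# (periodic analytic transform, as for the generator's epochs)
ref_windowed_connectivity <- function(rec) {
  labels <- rec$channel_labels
  wins <- analysis_windows(rec$fs, rec$time0)
  n_ch <- length(labels)
  n_tr <- dim(rec$data)[2]
  pair_idx <- utils::combn(n_ch, 2)
  n_p <- ncol(pair_idx)
  plv_arr <- array(NA_real_, c(n_p, nrow(wins), n_tr))
  wpli_arr <- array(NA_real_, c(n_p, nrow(wins), n_tr))
  for (tr in seq_len(n_tr)) {
    analytic <- lapply(seq_len(n_ch), function(c) ref_analytic(rec$data[c, tr, ]))
    for (p in seq_len(n_p)) {
      ax <- analytic[[pair_idx[1, p]]]
      ay <- analytic[[pair_idx[2, p]]]
      for (w in seq_len(nrow(wins))) {
        sel <- wins$start_sample[w] + seq_len(wins$n_samples[w])  # 1-based slice
        cx <- ax[sel] * Conj(ay[sel])
        plv_arr[p, w, tr] <- ref_plv(Arg(cx))
        wpli_arr[p, w, tr] <- ref_wpli(Im(cx))$value
      }
    }
  }
  list(plv = plv_arr, wpli = wpli_arr)
}

# split-plot (one within, one between factor) sums-of-squares ANOVA,
# computed from the textbook decomposition
ref_split_plot_anova <- function(d, dv, within, between, unit) {
  y <- d[[dv]]; W <- factor(d[[within]]); B <- factor(d[[between]]); U <- factor(d[[unit]])
  N <- length(y); a <- nlevels(B); k <- nlevels(W)
  n_units <- nlevels(U)
  grand <- mean(y)
  ss <- function(means, counts) sum(counts * (means - grand)^2)
  m_b <- tapply(y, B, mean); n_b <- tapply(y, B, length)
  ss_b <- ss(m_b, n_b)
  m_u <- tapply(y, U, mean); n_u <- tapply(y, U, length)
  ss_units <- ss(m_u, n_u)
  ss_subj_within <- ss_units - ss_b
  m_w <- tapply(y, W, mean); n_w <- tapply(y, W, length)
  ss_w <- ss(m_w, n_w)
  m_bw <- tapply(y, interaction(B, W), mean); n_bw <- tapply(y, interaction(B, W), length)
  ss_cells <- ss(m_bw, n_bw)
  ss_bw <- ss_cells - ss_b - ss_w
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_units - ss_w - ss_bw
  df_b <- a - 1; df_subj <- n_units - a
  df_w <- k - 1; df_bw <- (a - 1) * (k - 1); df_err <- (n_units - a) * (k - 1)
  list(
    F_between = (ss_b / df_b) / (ss_subj_within / df_subj),
    F_within = (ss_w / df_w) / (ss_err / df_err),
    F_inter = (ss_bw / df_bw) / (ss_err / df_err),
    df = c(between = df_b, subj = df_subj, within = df_w,
           inter = df_bw, err = df_err))
}

# Holm step-down adjustment by the defining recursion
ref_holm <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# tiny epoched recording holding given per-channel signals (samples vectors)
make_rec <- function(signals, fs, labels = names(signals), time0 = 0.5, ...) {
  n <- length(signals[[1]])
  a <- array(0, c(length(signals), 1, n))
  for (i in seq_along(signals)) a[i, 1, ] <- signals[[i]]
  epoched_recording(a, fs, labels, time0 = time0, ...)
}
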