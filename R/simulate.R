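#' Standard 13-channel scalp montage
#'
#' The 13 scalp positions of the 10-20 system used throughout the package.
#' @return character vector of channel labels.
#' @export
standard_channels <- function() {
  c("Fz", "Cz", "Pz", "F3", "F4", "C5", "CP3", "C6", "CP4", "P7", "P8", "O1", "O2")
}

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-study generator. Defaults describe the
#' study conditions the package is validated under: 16 subjects, 60 trials per
#' (session, condition) cell, 100 Hz sampling, 2.5 s epochs (0.5 s pre-cue),
#' theta-band (3-8 Hz) oscillators over a 1/f background at an
#' oscillation-to-noise amplitude ratio of 2.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param n_trials_per_cell trials per (subject, session, condition) cell.
#' @param fs sampling rate, Hz.
#' @param epoch_span numeric length-2, epoch start/end in seconds relative to
#'   cue onset; must cover at least `[0, 2]`.
#' @param channel_labels ordered channel names (default the 13-channel 10-20
#'   montage).
#' @param carrier_band Hz interval the oscillators drift inside (default 3-8).
#' @param noise_exponent spectral slope of the 1/f background (power ~
#'   1/f^exponent).
#' @param snr oscillation-to-noise RMS amplitude ratio; `Inf` disables noise.
#' @param mixing_matrix optional channels x channels instantaneous mixing
#'   matrix (rows are sum-normalised on construction), e.g. from
#'   [volume_conduction_matrix()]; applied last, emulating volume conduction.
#' @param subject_link_sd SD of the latent per-subject factor that jointly
#'   scales the hand-specific coupling and the behavioural TMR gain (creates a
#'   planted connectivity-behaviour correlation across subjects; 0 disables).
#' @param seed master integer seed; every cell's RNG stream is derived from it
#'   (see [cell_seed()]).
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 16, n_trials_per_cell = 60, fs = 100,
                       epoch_span = c(-0.5, 2), channel_labels = standard_channels(),
                       carrier_band = c(3, 8), noise_exponent = 1, snr = 2,
                       mixing_matrix = NULL, subject_link_sd = 1, seed = 1) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (epoch_span[2] < 2) stop("epoch_span must extend at least 2 s past cue onset")
  if (epoch_span[1] > 0) stop("epoch_span must start at or before cue onset")
  if (!is.null(mixing_matrix)) {
    if (nrow(mixing_matrix) != length(channel_labels) ||
        ncol(mixing_matrix) != length(channel_labels))
      stop("mixing_matrix must be channels x channels")
    mixing_matrix <- mixing_matrix / rowSums(mixing_matrix)
  }
  structure(list(n_subjects = n_subjects, n_trials_per_cell = n_trials_per_cell,
                 fs = fs, epoch_span = epoch_span,
                 channel_labels = as.character(channel_labels),
                 carrier_band = carrier_band, noise_exponent = noise_exponent,
                 snr = snr, mixing_matrix = mixing_matrix,
                 subject_link_sd = subject_link_sd, seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted pairwise phase coupling
#'
#' Declares that the channels appearing in `pairs` phase-lock to one shared
#' latent theta oscillator with mixture weight `kappa`, in the sessions and
#' conditions listed. Each member channel locks at a distinct multiple of
#' `lag`, so all within-set pairs have a non-zero phase lag (visible to both
#' PLV and wPLI).
#'
#' @param pairs 2-column character matrix (or list of length-2 vectors) of
#'   unordered channel-label pairs.
#' @param kappa coupling strength in `[0, 1]`: the mixture weight of the
#'   shared oscillator in each member channel.
#' @param lag base phase lag in radians, in `(-pi, pi]`.
#' @param sessions,conditions the study cells the coupling applies to.
#' @param channel_kappa optional named vector overriding `kappa` for
#'   individual member channels (e.g. to strengthen one ROI's lock on the
#'   shared oscillator without touching the others).
#'
#' @return a list of class `planted_coupling`.
#' @export
planted_coupling <- function(pairs, kappa, lag = pi / 4,
                             sessions = c("Pre", "Sleep", "Post"),
                             conditions = c("L", "R"),
                             channel_kappa = NULL) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop("`pairs` must have two columns")
  if (kappa < 0 || kappa > 1) stop("kappa must be in [0, 1]")
  if (lag <= -pi || lag > pi) stop("lag must be in (-pi, pi]")
  channels <- unique(as.vector(t(pairs)))
  ck <- stats::setNames(rep(kappa, length(channels)), channels)
  if (!is.null(channel_kappa)) {
    bad <- setdiff(names(channel_kappa), channels)
    if (length(bad)) stop("channel_kappa names not in the pair set: ",
                          paste(bad, collapse = ", "))
    if (any(channel_kappa < 0 | channel_kappa > 1))
      stop("channel_kappa must be in [0, 1]")
    ck[names(channel_kappa)] <- channel_kappa
  }
  structure(list(pairs = pairs, kappa = kappa, lag = lag,
                 sessions = sessions, conditions = conditions,
                 channels = channels, channel_kappa = ck),
            class = "planted_coupling")
}

coupling_applies <- function(coupling, session, condition) {
  session %in% coupling$sessions && condition %in% coupling$conditions
}

#' Deterministic per-cell seed derivation
#'
#' Every (subject, session, condition) cell draws from its own RNG stream so
#' any cell can be regenerated in isolation. The stream seed is an integer
#' hash of the master seed and the cell indices:
#' `(master * 100003 + subject * 7919 + session_index * 104729 +
#' condition_index * 11) mod (2^31 - 1)`, with sessions indexed
#' Pre = 1, Sleep = 2, Post = 3 and conditions L = 1, R = 2.
#'
#' @param master master seed (integer).
#' @param subject subject index (1-based).
#' @param session session name.
#' @param condition condition name.
#' @return an integer seed.
#' @export
cell_seed <- function(master, subject, session, condition) {
  s_idx <- match(session, c("Pre", "Sleep", "Post", "behaviour"))
  c_idx <- match(condition, c("L", "R", "all"))
  if (is.na(s_idx) || is.na(c_idx)) stop("unknown session or condition")
  as.integer((as.numeric(master) * 100003 + subject * 7919 +
                s_idx * 104729 + c_idx * 11) %% 2147483647)
}

# Complex band-limited Gaussian oscillator: an analytic signal whose
# spectrum occupies exactly `band` (i.i.d. complex-Gaussian coefficients on
# the in-band positive-frequency bins). Its real part is a narrowband
# oscillation whose instantaneous frequency and amplitude both drift inside
# the band, so PLV < 1 for partial coupling and the process class is closed
# under Fourier phase randomisation (the surrogate null is exact for
# uncoupled channels). A phase lag of `lag` radians is planted by rotating
# the complex carrier, which lags every spectral component exactly.
cx_band_oscillator <- function(n, fs, band) {
  freqs <- (seq_len(n) - 1) * fs / n
  sel <- which(freqs >= band[1] & freqs <= band[2] & freqs < fs / 2)
  X <- rep(0 + 0i, n)
  X[sel] <- complex(real = stats::rnorm(length(sel)),
                           imaginary = stats::rnorm(length(sel)))
  x <- stats::fft(X, inverse = TRUE) / n
  x / stats::sd(Re(x))
}

# 1/f^alpha (power) noise via spectral shaping of white noise, unit variance.
pink_noise <- function(n, alpha = 1) {
  w <- stats::rnorm(n)
  W <- stats::fft(w)
  f <- c(1, seq_len(n - 1))
  f <- pmin(f, n - f + 1)          # symmetric frequency index, DC guarded
  W <- W * f^(-alpha / 2)
  x <- Re(stats::fft(W, inverse = TRUE)) / n
  x / stats::sd(x)
}

#' Generate one cell of synthetic epoched EEG
#'
#' Builds `n_trials_per_cell` epochs for one (subject, session, condition)
#' cell. Each channel is a unit-amplitude theta oscillator plus 1/f noise at
#' the configured SNR. Channels named in an applicable [planted_coupling()]
#' replace a `kappa` fraction of their oscillator with the coupling's shared
#' latent oscillator (delayed by a channel-specific multiple of the coupling
#' lag); with several overlapping couplings the mixture weights are
#' `kappa_m` per coupling plus `prod(1 - kappa_m)` for the channel's own
#' oscillator, renormalised to sum to 1. Uncoupled channels are independent.
#' The optional mixing matrix is applied last.
#'
#' The RNG is seeded with [cell_seed()], so any cell regenerates bit-
#' identically in isolation.
#'
#' @param config a [sim_config()].
#' @param couplings list of [planted_coupling()] objects (possibly empty).
#' @param session,condition the cell to generate.
#' @param subject subject index (default 1).
#'
#' @return an `epoched_recording` for the cell.
#' @export
generate_epochs <- function(config, couplings = list(), session = "Pre",
                            condition = "L", subject = 1L) {
  stopifnot(inherits(config, "sim_config"))
  if (inherits(couplings, "planted_coupling")) couplings <- list(couplings)
  labels <- config$channel_labels
  for (cp in couplings) {
    bad <- setdiff(cp$channels, labels)
    if (length(bad))
      stop("coupling references unknown channel(s): ", paste(bad, collapse = ", "))
  }
  active <- Filter(function(cp) coupling_applies(cp, session, condition), couplings)
  fs <- config$fs
  n <- round((config$epoch_span[2] - config$epoch_span[1]) * fs)
  n_ch <- length(labels)
  n_tr <- config$n_trials_per_cell
  # per-channel membership: list of (coupling index, lag multiplier)
  membership <- vector("list", n_ch)
  names(membership) <- labels
  for (m in seq_along(active)) {
    chs <- active[[m]]$channels
    for (k in seq_along(chs)) {
      ch <- chs[k]
      membership[[ch]] <- rbind(membership[[ch]], c(m, k - 1))
    }
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cell_seed(config$seed, subject, session, condition))
  dat <- array(0, dim = c(n_ch, n_tr, n))
  for (tr in seq_len(n_tr)) {
    common <- lapply(active, function(cp) cx_band_oscillator(n, fs, config$carrier_band))
    x <- matrix(0, n_ch, n)
    for (c_i in seq_len(n_ch)) {
      mem <- membership[[c_i]]
      own <- cx_band_oscillator(n, fs, config$carrier_band)
      if (is.null(mem)) {
        osc <- Re(own)
      } else {
        w <- vapply(seq_len(nrow(mem)), function(r)
          unname(active[[mem[r, 1L]]]$channel_kappa[[labels[c_i]]]), 0)
        w_own <- prod(1 - w)
        parts <- own * w_own
        for (r in seq_len(nrow(mem))) {
          m <- mem[r, 1L]
          parts <- parts + w[r] * common[[m]] * exp(-1i * mem[r, 2L] * active[[m]]$lag)
        }
        osc <- Re(parts) / (sum(w) + w_own)
      }
      if (is.finite(config$snr)) {
        noise <- pink_noise(n, config$noise_exponent)
        osc <- osc + noise * stats::sd(osc) / config$snr
      }
      x[c_i, ] <- osc
    }
    if (!is.null(config$mixing_matrix)) x <- config$mixing_matrix %*% x
    dat[, tr, ] <- x
  }
  epoched_recording(dat, fs, labels, time0 = -config$epoch_span[1],
                    session = session, condition = condition,
                    subject_id = sprintf("S%02d", subject),
                    meta = list(seed = cell_seed(config$seed, subject, session, condition),
                                edge = "periodic"))
}

#' Volume-conduction mixing matrix for a 10-20 montage
#'
#' Gaussian spatial spread over approximate 2-D electrode positions of the
#' 13-channel montage: `M[i, j] = exp(-(d_ij / spread)^2)`, rows normalised to
#' sum to 1 (so the diagonal dominates for small `spread`). Applying it to
#' independent sources creates the instantaneous (zero-lag) mixing that
#' inflates PLV but not wPLI.
#'
#' @param labels channel labels (subset of [standard_channels()]).
#' @param spread Gaussian spread in head-radius units (default 0.7).
#' @return a rows-normalised mixing matrix.
#' @export
volume_conduction_matrix <- function(labels = standard_channels(), spread = 0.7) {
  pos <- rbind(Fz = c(0, 0.6), Cz = c(0, 0), Pz = c(0, -0.6),
               F3 = c(-0.35, 0.55), F4 = c(0.35, 0.55),
               C5 = c(-0.7, 0), CP3 = c(-0.45, -0.3),
               C6 = c(0.7, 0), CP4 = c(0.45, -0.3),
               P7 = c(-0.65, -0.55), P8 = c(0.65, -0.55),
               O1 = c(-0.25, -0.85), O2 = c(0.25, -0.85))
  bad <- setdiff(labels, rownames(pos))
  if (length(bad)) stop("no stored position for: ", paste(bad, collapse = ", "))
  p <- pos[labels, , drop = FALSE]
  d <- as.matrix(stats::dist(p))
  m <- exp(-(d / spread)^2)
  m / rowSums(m)
}

#' Default behavioural effect structure
#'
#' The planted behavioural model: block medians decay with practice
#' (exponential learning curve), sequence blocks gain `overnight_gain` ms
#' after sleep, and the reactivated sequence gains `tmr_gain_left` ms more --
#' for left-hand trials only. Block reaction times are lognormal around the
#' model median with multiplicative noise `sigma`.
#'
#' @param learning_rate exponential learning rate per block.
#' @param overnight_gain ms dropped by all sequence blocks after sleep.
#' @param tmr_gain_left extra ms dropped post-sleep by the reactivated (Re)
#'   sequence on left-hand trials.
#' @param skill_scale asymptotic sequence-specific skill, ms.
#' @param sigma lognormal noise SD (0 gives the deterministic limit).
#' @param rt_base baseline block RT, ms (must be positive).
#' @param n_seq_blocks,n_random_blocks blocks per sequence per session.
#' @return a named list of effects.
#' @export
default_effects <- function(learning_rate = 0.05, overnight_gain = 25,
                            tmr_gain_left = 40, skill_scale = 80, sigma = 0.06,
                            rt_base = 500, n_seq_blocks = 48, n_random_blocks = 4) {
  list(learning_rate = learning_rate, overnight_gain = overnight_gain,
       tmr_gain_left = tmr_gain_left, skill_scale = skill_scale, sigma = sigma,
       rt_base = rt_base, n_seq_blocks = n_seq_blocks,
       n_random_blocks = n_random_blocks)
}

#' Generate a behavioural block-RT table for one subject
#'
#' One row per (session, sequence, hand, block): sequence blocks follow the
#' learning curve (cumulative across sessions) minus the planted overnight and
#' TMR gains; random blocks sit at the baseline with no sequence-specific
#' gain. RTs are lognormal around the model median.
#'
#' @param config a [sim_config()] (supplies the master seed).
#' @param effects effect list from [default_effects()].
#' @param subject subject index.
#' @param tmr_gain optional per-subject override of `effects$tmr_gain_left`
#'   (used by [simulate_study()] to plant subject-level variation).
#'
#' @return a data.frame with columns subject, session (`pre`/`post`),
#'   sequence (`Re`/`NRe`), hand (`L`/`R`), block_index, block_type
#'   (`sequence`/`random`), rt (ms).
#' @export
generate_behavioural <- function(config, effects = default_effects(),
                                 subject = 1L, tmr_gain = NULL) {
  stopifnot(inherits(config, "sim_config"))
  for (v in c("learning_rate", "overnight_gain", "tmr_gain_left"))
    if (!is.finite(effects[[v]])) stop("effect `", v, "` must be finite")
  if (effects$rt_base <= 0) stop("rt_base must be positive")
  if (is.null(tmr_gain)) tmr_gain <- effects$tmr_gain_left
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cell_seed(config$seed, subject, "behaviour", "all"))
  nseq <- effects$n_seq_blocks; nrand <- effects$n_random_blocks
  grid <- expand.grid(hand = c("L", "R"), sequence = c("Re", "NRe"),
                      session = c("pre", "post"), KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    ses <- grid$session[g]; sq <- grid$sequence[g]; hd <- grid$hand[g]
    b <- seq_len(nseq)
    b_cum <- if (ses == "pre") b else nseq + b
    skill <- effects$skill_scale * (1 - exp(-effects$learning_rate * b_cum))
    med_seq <- effects$rt_base - skill -
      (ses == "post") * effects$overnight_gain -
      (ses == "post" && sq == "Re" && hd == "L") * tmr_gain
    med_rand <- rep(effects$rt_base, nrand)
    med <- c(med_seq, med_rand)
    if (any(med <= 0)) stop("planted effects drive block RT non-positive")
    rt <- med * exp(effects$sigma * stats::rnorm(length(med)))
    rows[[g]] <- data.frame(
      subject = sprintf("S%02d", subject), session = ses, sequence = sq,
      hand = hd, block_index = c(b, nseq + seq_len(nrand)),
      block_type = c(rep("sequence", nseq), rep("random", nrand)),
      rt = rt, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Default planted coupling structure of a TMR study
#'
#' The effect structure the package's validation studies plant. One latent
#' theta oscillator per (session, condition) cell drives all nine ROI
#' channels (frontal F3/Fz/F4, left-hemisphere C5/CP3/P7, right-hemisphere
#' C6/CP4/P8), with distinct per-channel lags:
#' * every channel locks at the session strength `kappa_session` --
#'   `Sleep > Pre > Post` -- creating the session ordering on the
#'   hemisphere-frontal, inter-hemispheric, and within-hemisphere contrasts
#'   alike, identically for both cued hands;
#' * in Sleep and Post, the motor channels *contralateral to the cued hand*
#'   lock more strongly (`kappa_hand`), raising within-hemisphere coupling
#'   on that side only -- the hand signature, absent in Pre.
#'
#' Strengths are expressed as lock weights on the shared oscillator rather
#' than as a second oscillator, so the hand boost cannot dilute the
#' hemisphere-frontal links.
#'
#' @param kappa_session named vector of session lock strengths (Pre, Sleep,
#'   Post).
#' @param kappa_hand named vector: contralateral motor-channel lock strength
#'   in Sleep and Post.
#' @param lag base phase lag in radians; member channels lock at distinct
#'   multiples of it. The default (the golden angle, ~2.4 rad) keeps every
#'   pairwise lag away from 0 and pi, so all planted pairs stay visible to
#'   wPLI.
#' @return list of [planted_coupling()] objects, one per (session,
#'   condition) cell.
#' @export
tmr_study_couplings <- function(kappa_session = c(Pre = 0.78, Sleep = 0.85, Post = 0.72),
                                kappa_hand = c(Sleep = 0.91, Post = 0.88),
                                lag = 2.399) {
  frontal <- roi_channels("Frontal")
  lhem <- roi_channels("LHem")
  rhem <- roi_channels("RHem")
  roi9 <- c(frontal, lhem, rhem)
  all_roi_pairs <- t(utils::combn(roi9, 2))
  contralateral <- c(L = "RHem", R = "LHem")
  out <- list()
  for (ses in names(kappa_session)) {
    for (cond in c("L", "R")) {
      boost <- NULL
      if (ses %in% names(kappa_hand)) {
        motor <- roi_channels(contralateral[[cond]])
        boost <- stats::setNames(rep(kappa_hand[[ses]], length(motor)), motor)
      }
      out[[paste(ses, cond, sep = ".")]] <-
        planted_coupling(all_roi_pairs, kappa = kappa_session[[ses]],
                         lag = lag, sessions = ses, conditions = cond,
                         channel_kappa = boost)
    }
  }
  out
}

#' Simulate a complete synthetic TMR study
#'
#' Generates every (subject, session, condition) recording plus one
#' behavioural table per subject, with the planted truth attached. A latent
#' per-subject factor (SD `config$subject_link_sd`) jointly scales the
#' hand-specific coupling strength and the behavioural TMR gain, planting a
#' connectivity-behaviour correlation across subjects.
#'
#' @param config a [sim_config()].
#' @param couplings list of [planted_coupling()]; default
#'   [tmr_study_couplings()].
#' @param effects behavioural effects; default [default_effects()].
#'
#' @return a `synthetic_study`: list with `recordings` (nested list
#'   `[[subject]][[session]][[condition]]`), `behavioural` (one data.frame),
#'   `truth` (couplings and per-subject factors), `config`.
#' @export
simulate_study <- function(config = sim_config(), couplings = tmr_study_couplings(),
                           effects = default_effects()) {
  stopifnot(inherits(config, "sim_config"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(cell_seed(config$seed, 0L, "behaviour", "all"))
  u <- stats::rnorm(config$n_subjects, 0, config$subject_link_sd)
  sessions <- c("Pre", "Sleep", "Post")
  conditions <- c("L", "R")
  recordings <- vector("list", config$n_subjects)
  behav <- vector("list", config$n_subjects)
  hand_kappa <- kappa_link <- numeric(config$n_subjects)
  for (s in seq_len(config$n_subjects)) {
    # subject-specific hand-coupling boost and TMR gain, tied through u[s]
    cps <- lapply(couplings, function(cp) {
      boosted <- cp$channel_kappa != cp$kappa
      if (!any(boosted)) return(cp)
      # bounded shift: tanh keeps every subject's boost inside the sloped
      # part of the kappa -> summary response (no saturation clipping)
      cp$channel_kappa[boosted] <-
        pmin(pmax(cp$channel_kappa[boosted] + 0.075 * tanh(u[s]), 0.05), 0.995)
      cp
    })
    hand_kappa[s] <- 0.075 * tanh(u[s])  # boost offset applied
    gain_s <- effects$tmr_gain_left + 45 * u[s]
    kappa_link[s] <- gain_s
    recordings[[s]] <- lapply(sessions, function(ses)
      lapply(stats::setNames(conditions, conditions), function(cond)
        generate_epochs(config, cps, session = ses, condition = cond, subject = s)))
    names(recordings[[s]]) <- sessions
    behav[[s]] <- generate_behavioural(config, effects, subject = s, tmr_gain = gain_s)
  }
  structure(list(recordings = recordings,
                 behavioural = do.call(rbind, behav),
                 truth = list(couplings = couplings, subject_factor = u,
                              subject_tmr_gain = kappa_link,
                              subject_hand_kappa = hand_kappa,
                              effects = effects),
                 config = config,
                 seed_used = config$seed),
            class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d subjects x 3 sessions x 2 conditions, %d trials/cell @ %g Hz\n",
              x$config$n_subjects, x$config$n_trials_per_cell, x$config$fs))
  cat(sprintf("  %d planted coupling(s); behavioural table: %d rows; seed %d\n",
              length(x$truth$couplings), nrow(x$behavioural), x$seed_used))
  invisible(x)
}
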