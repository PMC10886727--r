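---
title: "Phase-based EEG connectivity with surrogate pruning: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-based EEG connectivity with surrogate pruning: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements: the
connectivity model, the null model, the aggregation and inference layers, the
synthetic-data generator that makes all of it testable, and the numerical and
design choices behind each stage. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The analysis problem

In a targeted memory reactivation (TMR) study, auditory cues associated with
a learned motor sequence are re-played during slow wave sleep. The question
the analysis answers is how cue-locked, theta-band (3-8 Hz) phase coupling
between scalp regions differs between the pre-sleep, sleep and post-sleep
sessions and between the cued hands, and whether that coupling predicts the
overnight change in sequence-specific skill.

The pipeline is: epoched 13-channel EEG (2.5 s around each cue) is
theta-filtered and amplitude-normalised; per-trial phase connectivity is
estimated for every channel pair in three overlapping 1 s windows; each
(pair, window, trial) value is tested against a 100-fold surrogate null and
pruned; surviving links are stability-filtered across trials and
participants; retained links are averaged into region-of-interest contrasts;
and the contrasts enter repeated-measures ANOVA, Holm-corrected post-hocs,
and bootstrap-corrected rank correlations with behaviour.

## Connectivity estimators

Both estimators start from the analytic signal of the theta-filtered epoch.
With instantaneous phases $\varphi_x(t), \varphi_y(t)$ and phase difference
$\theta(t) = \varphi_x(t) - \varphi_y(t)$, the phase-locking value over a
window of $T$ samples is

$$\mathrm{PLV} = \left| \frac{1}{T} \sum_{t=1}^{T} e^{i\theta(t)} \right|,$$

1 iff the phase difference is constant, with null expectation
$\tfrac{1}{2}\sqrt{\pi/T}$ for i.i.d. uniform phases. The weighted phase lag
index weights each cross-spectral sample $P_{xy}(t) = x_a(t)\,
\overline{y_a(t)}$ (products of analytic signals) by the magnitude of its
imaginary part:

$$\mathrm{wPLI} = \frac{\left|\frac{1}{T}\sum_t \mathrm{Im}\,P_{xy}(t)\right|}
{\frac{1}{T}\sum_t \left|\mathrm{Im}\,P_{xy}(t)\right|}.$$

PLV is sensitive to any phase locking, including the spurious zero-lag kind
produced by volume conduction; wPLI discounts zero-lag contributions, at the
cost of power for genuinely near-zero-lag coupling. The package computes
both because their disagreement is informative: instantaneous mixing of
independent sources inflates PLV but leaves wPLI at its null level (this
contrast is an acceptance test).

Numerical conventions:

* PLV of a constant phase difference is exactly 1; values are clipped into
  $[0,1]$ against rounding.
* If every $\mathrm{Im}\,P_{xy}$ is exactly zero (e.g. a channel paired with
  a copy of itself), wPLI is 0/0; the package returns 0 with a `degenerate`
  flag, and such cells are excluded from significance testing rather than
  counted as evidence either way.
* Single-trial temporal PLV is used ($T$ = samples within the window);
  trial averaging happens only at the ROI summary stage, after pruning.

## Windows, filtering, and boundary handling

Connectivity is computed in three 1 s windows with 50% overlap (w1 = 0-1 s,
w2 = 0.5-1.5 s, w3 = 1-2 s after cue onset); 1 s of theta holds 3-8 cycles,
the usual minimum for a stable estimate. Epochs carry 0.5 s of pre-onset
padding.

The theta filter has two realisations matched to the epoch's boundary rule
(below). For circular epochs it is a frequency-sampled zero-phase response:
gain exactly 1 inside the band, raised-cosine roll-off over 2 Hz, exactly 0
beyond -- applying it twice to band-limited content changes nothing
(idempotence is exact, a property test). For continuous-cut epochs it is a
Hamming-window FIR (odd tap count, ~2 Hz transition band) applied with zero
phase; at the default band it attenuates 1 Hz and 12 Hz by more than 40 dB
(verified in the test suite by filtering sinusoids). The analytic signal is
computed over the full 2.5 s epoch and then sliced into windows, so the
Hilbert transform's own transients never start inside a window.

Both the filter and the FFT-based analytic transform need a boundary rule,
and the right rule depends on where the epoch came from. Recordings carry
their provenance in `meta$edge`:

* `"periodic"` -- epochs built in the spectral domain (the synthetic
  generator, and every Fourier surrogate) are circular by construction, so
  circular filtering and the plain FFT analytic transform are *exact*: a
  perfectly locked pair scores PLV 1 in every window, including w3 at the
  epoch's end.
* `"extend"` -- epochs cut from a continuous recording (`epoch()`) are not
  circular. Each channel is extended by half an epoch at both ends with a
  damped-sinusoid extrapolation: a first-pass analytic transform gives the
  local complex carrier, a complex AR(1) fit over the last 40 samples
  estimates its per-column rotation-and-decay factor (poles clamped inside
  the unit circle), and the carrier is continued geometrically. This follows
  the dominant oscillation through envelope minima; point reflections, by
  contrast, force the imaginary part's structure at the boundary and drag
  the phase of every channel toward a common value there, corrupting w3.
  The outermost 0.25 s remain flagged (`meta$edge_flag_s`).

## Amplitude normalisation

Each trial of each channel is divided by that channel's grand mean RMS
amplitude pooled over all trials of both conditions of the same subject and
session. Both estimators are phase-based, so this cannot change any
connectivity value (asserted to 1e-9 in the tests); it is retained so that
stored amplitudes are comparable across subjects and conditions, and because
the analysis it reproduces specifies it.

## The surrogate null and the keep rule

Significance of each (pair, window, trial) cell is assessed against
surrogates of the same trial:

* **Phase shuffling** permutes the phases of the positive-frequency DFT bins
  independently per channel, restores Hermitian symmetry, and inverts. The
  per-channel amplitude spectrum is preserved bin-wise (to 1e-9; an
  acceptance check) while cross-channel phase relations are destroyed.
* **Time shuffling** permutes samples within each channel. Scrambling
  whitens the spectrum, so the surrogate is re-band-limited with the same
  theta filter before the analytic transform; without this the null would
  lack the narrowband phase smoothness of the real data and the test's
  false-positive rate rises by an order of magnitude. Phase surrogates keep
  the spectrum by construction and are never re-filtered.

With $n$ surrogates per cell (default 100), a cell is kept iff its real
value exceeds the $\lceil (1-\alpha)(n+1) \rceil$-th order statistic of its
null -- equivalently, iff the rank-based empirical p-value
$(1 + \#\{\text{null} \ge \text{real}\})/(n+1)$ is at most $\alpha$. The
more obvious interpolated 95th centile has an exceedance probability of
about 5.9% at $n = 100$; the order-statistic rule has size at most $\alpha$
exactly. Benjamini-Hochberg FDR over the empirical p-values is available as
an alternative keep rule behind a flag; the centile rule is the default
because it is the operative rule of the analysis being reproduced. Pruned
cells are set to zero and *disregarded* downstream (they do not enter any
average as zeros).

## Stability filtering and ROI contrasts

A link (channel pair, per window) enters the summaries only if it is
significant in at least 60% of a subject's trials for at least 50% of
subjects. The across-participant clause is read as "at least 50% of
participants satisfy the within-participant criterion": pooling trials
across subjects would erase the subject structure the repeated-measures
ANOVA needs. Raising either threshold can only shrink the retained set
(a property test).

Retained links are averaged into five contrasts built from three
three-channel ROIs -- frontal (F3, Fz, F4), left-hemisphere motor (C5, CP3,
P7), right-hemisphere motor (C6, CP4, P8): LHem-Frontal, RHem-Frontal,
LHem-RHem, within-LHem, within-RHem. Cz, Pz, O1 and O2 never enter any
summary (Cz/Pz would blur the hemispheric contrast; O1/O2 are dropped to
keep the ROIs the same size). Within a subject's cell, a retained link's
value is the mean over its *significant* trials; the cell value is the mean
over retained links; a cell with no retained link yields `NA`, never zero.
The filter is applied before trial averaging, because the filter is defined
on trial-level significance. Subjects with missing cells are dropped
listwise per contrast at the statistics stage, with a reported count.

## Behavioural metrics

Block reaction times (one RT per block; trial-level tables are collapsed by
the block median, mean behind a flag) yield, per sequence (reactivated `Re`
vs non-reactivated `NRe`) and optionally per hand:

* `sss_pre` = mean RT of the pre-sleep random blocks minus the last 4
  pre-sleep sequence blocks;
* `sss_post_early` / `sss_post_late` = post-sleep random blocks minus the
  first / last 4 post-sleep sequence blocks;
* `ssi_early` = `sss_post_early` - `sss_pre`, `ssi_late` =
  `sss_post_late` - `sss_pre` (exact identities; higher = more improvement).

Subtracting random blocks removes general sensorimotor speed-up; all metrics
are invariant to a constant RT shift (a property test).

## Inference

* **RM-ANOVA**: session (Pre/Sleep/Post) as the repeated factor and cued
  hand as a between-unit factor, each (subject, hand) combination being one
  experimental unit, mirroring the design of the analysis reproduced.
  Computation is delegated to `car::Anova` on a multivariate linear model
  (sum-to-zero contrasts, type III); Mauchly's test gates a
  Greenhouse-Geisser correction. A from-scratch sums-of-squares oracle in
  the test suite checks the decomposition.
* **Post-hocs**: paired t-tests per level pair, replaced by Wilcoxon
  signed-rank when Shapiro-Wilk rejects normality of the paired differences
  at 0.05, Holm-adjusted within one family = the three session pairs of one
  (contrast, window, metric). The family choice is the package's: the
  source analysis does not state its family.
* **Correlations**: Spearman's rho (Pearson behind a flag) with a
  percentile bootstrap CI over paired resamples (default n = 50,000, via
  the `boot` package) and a two-sided permutation p-value from the same
  number of permutations. Bayesian ANOVA counterparts are omitted: the
  prior specification of the original JASP analyses is not recoverable.

## The synthetic-study generator

No recorded data ship with the package; every claim is validated on
synthetic studies with planted, labelled effects.

**Oscillator model.** Each channel is a theta oscillator plus 1/f noise
(power $\propto f^{-1}$, RMS set by `snr`, default 2). The oscillator is a
band-limited complex Gaussian process: i.i.d. complex-Gaussian coefficients
on the in-band positive-frequency bins, inverted to an analytic signal whose
real part drifts in both frequency and amplitude inside 3-8 Hz. Two
properties motivated this choice over a constant-envelope "drifting tone":
(i) partial coupling yields PLV strictly below 1, so coupling strength is
identifiable; (ii) the process class is *closed under Fourier phase
randomisation*, so the phase-shuffled null is exact for uncoupled channels
and the pruning keep-rate calibrates at $\alpha$ -- a constant-envelope
process is non-Gaussian, its surrogates are not exchangeable with it, and we
measured keep rates of 11-24% at $\alpha = 5\%$ under such models. A
deterministic-envelope generator cannot satisfy the calibration requirement;
this is a structural fact about Fourier surrogates, not a tuning issue.

**Coupling model.** A planted coupling names a set of channel pairs, a
strength $\kappa \in [0,1]$, a lag, and the sessions/conditions it applies
to. All channels of one coupling share one latent oscillator: each member
channel's oscillatory part is $\kappa \cdot$ (latent carrier, rotated by a
channel-specific multiple of the lag) $+ (1-\kappa) \cdot$ (its own
independent oscillator), renormalised. Rotating the complex carrier lags
every spectral component exactly, so $\kappa = 1$ with infinite SNR gives
PLV and wPLI of exactly 1 in every window, and distinct per-channel lags
keep every within-set pair visible to wPLI. Overlapping couplings combine
with weights $\kappa_m$ plus $\prod_m (1-\kappa_m)$ for the channel's own
oscillator.

**Default study conditions.** 16 subjects, 60 trials per (session,
condition) cell, 100 Hz sampling (theta is fully resolved; runtimes stay in
minutes), 2.5 s epochs. The planted effect structure
(`tmr_study_couplings()`) uses one latent oscillator per (session,
condition) cell, shared by all nine ROI channels at distinct lags:

* every ROI channel locks to it at the session strength --
  $\kappa_{\mathrm{Pre}} = 0.78$, $\kappa_{\mathrm{Sleep}} = 0.85$,
  $\kappa_{\mathrm{Post}} = 0.72$ -- producing the Sleep > Pre > Post
  ordering on the hemisphere-frontal, inter-hemispheric and
  within-hemisphere contrasts alike, identically for both hands;
* in Sleep and Post the motor channels contralateral to the cued hand lock
  more strongly ($\kappa = 0.91$ in Sleep, $0.88$ in Post), raising
  within-hemisphere coupling on that side only. Expressing the hand effect
  as a lock-weight boost on the *same* oscillator (rather than a second
  oscillator) keeps it from diluting the hemisphere-frontal links. The
  Sleep boost sits where the generator's $\kappa \to$ summary response
  still has slope, so the per-subject variation below is expressed in the
  summaries rather than flattened by saturation.

These strengths were fixed once from the generator's own
$\kappa \to \mathrm{PLV}$ mapping, inside the band where planted links
survive the surrogate-and-stability filters in every session (below
$\kappa \approx 0.7$ links start to vanish in a 60%-of-trials sense,
turning session contrasts into missing-data artefacts; above
$\kappa \approx 0.9$ PLV saturates and contrasts compress). They are
moderate-to-strong effects by design: what the recovery tests establish is
correct sign and ordering, not power at marginal effect sizes.

**Behaviour.** Block medians follow an exponential learning curve
(rate 0.05 per block, asymptote 80 ms below the 500 ms baseline) across
sessions; sequence blocks drop a further 25 ms overnight, and the
reactivated sequence on left-hand trials drops the planted TMR gain
(default 40 ms) on top; random blocks stay at baseline. Block RTs are
lognormal around the model median (sigma 0.06; sigma 0 gives the exact
deterministic limit used in tests). A latent standard-normal per-subject
factor $u$ jointly shifts the contralateral lock strength (by
$0.075\tanh u$ -- bounded, so every subject's boost stays inside the sloped
part of the $\kappa \to$ summary response rather than saturating) and the
TMR gain (by $45\,u$ ms), planting the connectivity-behaviour correlation
the pipeline is expected to recover; both scales were set from the
generator's response curve and the ssi noise level so the planted
correlation is strong ($\rho \sim 0.6{-}0.7$) at $n = 16$ subjects.

**Volume conduction.** `volume_conduction_matrix()` mixes channels by a
Gaussian kernel over approximate 2-D 10-20 electrode positions (rows
sum-normalised). The default spread (0.7 head-radius units) makes the
PLV/wPLI contrast unmistakable on desk-scale runs while keeping the matrix
diagonally dominant.

**Determinism.** Every (subject, session, condition) cell derives its own
RNG stream from the master seed by an integer hash (`cell_seed()`), so any
cell can be regenerated in isolation and a study is bit-identical across
runs.

**What the generator does not emulate.** Real sleep architecture (slow
oscillations, spindles, arousals), artifacts and their rejection, electrode
impedance drift, non-stationary background spectra, volume-conduction
geometry beyond a two-parameter kernel, and the cue-evoked potential
itself. Passing recovery tests therefore demonstrates that the *pipeline*
is correct and calibrated under its stated statistical assumptions -- not
that those assumptions hold in any particular recording.

## Problem sizes used in validation

The test suite and acceptance script run: single-cell null calibration at 13
channels x 60 trials x 100 surrogates (both shuffle methods); the
volume-conduction contrast at the same size; session- and hand-effect
recovery on the full 16-subject study (PLV, 100 surrogates per cell);
behavioural recovery noise-free and at default noise; CI coverage for the
bootstrap correlation over 500 null replicates at n = 12 subjects with
1,000 resamples each (the 50,000-resample default is exercised at full size
in the single worked correlation). These sizes were chosen as the smallest
at which the binomial/Monte-Carlo error of each check is well below the
margins being asserted.

## Known limitations

* The wPLI cross-spectrum uses per-sample analytic-signal products; tapered
  multi-taper estimators would trade variance for bias differently.
* Surrogate significance is per-cell; no analytic (Rayleigh) test is
  offered, and no correction across cells is applied by default beyond the
  stability filter (BH is available behind a flag).
* The RM-ANOVA treats (subject, hand) units as independent, as in the
  design it reproduces; a mixed model with crossed random effects would be
  the more general treatment.
* EDF ingestion and HDF5 containers are not implemented; epochs enter as R
  arrays (or the generator's output), and pipeline artifacts are RDS/CSV.
* Directed connectivity (Granger, transfer entropy) is out of scope.
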