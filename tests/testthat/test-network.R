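test_that("ROI definitions are the three disjoint 3-channel sets; Cz/Pz/O1/O2 never enter", {
  rois <- lapply(c("Frontal", "LHem", "RHem"), roi_channels)
  expect_equal(lengths(rois), rep(3L, 3))
  expect_equal(anyDuplicated(unlist(rois)), 0L)
  expect_length(intersect(unlist(rois), excluded_channels()), 0L)
  # no contrast's pair set touches an excluded channel
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 2, seed = 2)
  tens <- windowed_connectivity(bandpass_theta(generate_epochs(cfg, list(), "Pre", "L")),
                                metrics = "plv")
  for (cn in names(roi_contrasts())) {
    ab <- roi_contrasts()[[cn]]
    idx <- phaseconn:::roi_pair_index(tens$pairs, ab[1], ab[2])
    expect_equal(length(idx), if (ab[1] == ab[2]) 3L else 9L)
    chans <- unique(c(tens$pairs$chan_i[idx], tens$pairs$chan_j[idx]))
    expect_length(intersect(chans, excluded_channels()), 0L)
  }
})

test_that("stability filter applies the 60%-within / 50%-across rule", {
  # one link, one window, 100 trials, 4 subjects
  mk <- function(frac) {
    k <- array(FALSE, c(1, 1, 100))
    if (frac > 0) k[1, 1, seq_len(round(100 * frac))] <- TRUE
    k
  }
  expect_true(stability_filter(list(mk(1), mk(1), mk(1), mk(1)))[1, 1])
  # 59% within for every subject -> discarded
  expect_false(stability_filter(list(mk(0.59), mk(0.59), mk(0.59), mk(0.59)))[1, 1])
  # exactly at both thresholds -> retained (>= semantics)
  expect_true(stability_filter(list(mk(0.6), mk(0.6), mk(0), mk(0)))[1, 1])
  expect_false(stability_filter(list(mk(0.6), mk(0), mk(0), mk(0)))[1, 1])
  expect_error(stability_filter(list()), "at least one")
})

test_that("retained set matches exhaustive enumeration on a 3-subject toy", {
  set.seed(61)
  n_pairs <- 10; n_win <- 3; n_tr <- 20; n_sub <- 3
  masks <- lapply(1:n_sub, function(s)
    array(runif(n_pairs * n_win * n_tr) < 0.5, c(n_pairs, n_win, n_tr)))
  got <- stability_filter(masks, within_thr = 0.6, across_thr = 0.5)
  for (p in 1:n_pairs) for (w in 1:n_win) {
    ok <- 0
    for (s in 1:n_sub) {
      hits <- 0
      for (tr in 1:n_tr) hits <- hits + masks[[s]][p, w, tr]
      if (hits / n_tr >= 0.6) ok <- ok + 1
    }
    expect_identical(got[p, w], ok / n_sub >= 0.5)
  }
})

test_that("raising either stability threshold never grows the retained set", {
  set.seed(62)
  masks <- lapply(1:5, function(s) array(runif(78 * 3 * 30) < 0.4, c(78, 3, 30)))
  base <- stability_filter(masks, 0.5, 0.4)
  for (thr in list(c(0.7, 0.4), c(0.5, 0.8), c(0.9, 0.9))) {
    tighter <- stability_filter(masks, thr[1], thr[2])
    expect_true(all(base | !tighter))  # tighter subset of base
  }
})

test_that("ROI aggregation averages retained significant links and propagates NA", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 4, seed = 71)
  rec <- bandpass_theta(generate_epochs(cfg, list(), "Sleep", "L"))
  tens <- windowed_connectivity(rec, metrics = "plv")
  # synthetic mask/tensor with constant value v on all RHem-Frontal links
  idx <- phaseconn:::roi_pair_index(tens$pairs, "RHem", "Frontal")
  v <- 0.42
  tens$values$plv[] <- 0
  tens$values$plv[idx, , ] <- v
  mask <- list(keep = list(plv = array(FALSE, dim(tens$values$plv))))
  mask$keep$plv[idx, , ] <- TRUE
  retained <- matrix(FALSE, nrow(tens$pairs), 3)
  retained[idx, ] <- TRUE
  out <- roi_connectivity(tens, mask, retained, "RHem", "Frontal", metric = "plv")
  expect_equal(out$value, rep(v, 3))
  expect_equal(out$contrast, rep("RHem-Frontal", 3))
  # order of the ROI arguments is irrelevant
  out_swap <- roi_connectivity(tens, mask, retained, "Frontal", "RHem", metric = "plv")
  expect_equal(out_swap$value, out$value)
  # no retained links -> NA, not zero
  none <- matrix(FALSE, nrow(tens$pairs), 3)
  out_na <- roi_connectivity(tens, mask, none, "RHem", "Frontal", metric = "plv")
  expect_true(all(is.na(out_na$value)))
  # within-ROI variant uses the 3 within pairs
  idx_w <- phaseconn:::roi_pair_index(tens$pairs, "RHem", "RHem")
  expect_length(idx_w, 3L)
  # pruned-out trials are disregarded, not averaged as zeros
  mask2 <- mask
  mask2$keep$plv[idx, , 1:2] <- FALSE
  tens2 <- tens
  tens2$values$plv[idx, , 1:2] <- 0
  out2 <- roi_connectivity(tens2, mask2, retained, "RHem", "Frontal", metric = "plv")
  expect_equal(out2$value, rep(v, 3))
  # missing ROI channel errors
  tens3 <- tens
  tens3$channel_labels <- setdiff(tens3$channel_labels, "CP4")
  expect_error(roi_connectivity(tens3, mask, retained, "RHem", "Frontal",
                                metric = "plv"), "CP4")
})

test_that("planted within-RHem coupling for L cues only separates the hands", {
  cfg <- sim_config(n_subjects = 1, n_trials_per_cell = 30, seed = 81)
  cps <- list(planted_coupling(t(utils::combn(roi_channels("RHem"), 2)),
                               kappa = 0.75, lag = pi / 4,
                               sessions = "Sleep", conditions = "L"))
  study <- list(recordings = list(list(
    Sleep = list(L = generate_epochs(cfg, cps, "Sleep", "L"),
                 R = generate_epochs(cfg, cps, "Sleep", "R")))),
    config = cfg)
  # run the study driver on the single session
  an <- analyse_study(structure(study, class = "synthetic_study"),
                      metrics = "plv", n_surrogates = 40)
  roi <- an$roi
  rl <- roi[roi$contrast == "within-RHem" & roi$condition == "L", "value"]
  rr <- roi[roi$contrast == "within-RHem" & roi$condition == "R", "value"]
  # L cues: the planted links are stable and strong; R cues: nothing survives
  # the stability filter, so the summary is missing (never zero)
  expect_gt(mean(rl, na.rm = TRUE), 0.4)
  expect_true(all(is.na(rr)))
})
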