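# Hof normalisation, discrete feature extraction, GPS, side selection.

test_that("Hof normalisation matches hand-computed values", {
  z <- hof_normalize(0, 0, 0, 0.65)
  expect_equal(unlist(z), c(wv_norm = 0, sl_norm = 0, sw_norm = 0))
  # wv / sqrt(l g) with l = 0.65, g = 9.81
  expect_equal(hof_normalize(1.20, 0.5, 0.18, 0.65)$wv_norm,
               1.20 / sqrt(0.65 * 9.81), tolerance = 1e-12)
  expect_equal(round(hof_normalize(1.20, 0.5, 0.18, 0.65)$wv_norm, 4),
               0.4752)
  h <- hof_normalize(1.0, 0.50, 0.18, 0.65)
  expect_equal(round(h$sl_norm, 4), 0.7692)
  expect_equal(round(h$sw_norm, 4), 0.2769)
  expect_error(hof_normalize(1, 1, 1, 0), "leg length")
})

test_that("discrete features honour their phase windows", {
  # constant pelvic tilt: max = the constant; constant obliquity: ROM 0
  ses <- session_from_waves(list(pelvic_tilt = rep(12, 101)))
  f <- extract_discrete_features(average_cycles(ses), "left")
  expect_equal(unname(f["max_ant_pelvic_tilt"]), 12)
  expect_equal(unname(f["rom_pelvic_obliquity"]), 0)

  # knee flexion 35 - 30 cos(2 pi p / 100), foot-off 60: the global max
  # (65 at p = 50) lies in stance; the swing max is the curve at the
  # first swing grid point, verified by a dense scan of the analytic
  # curve over the swing window
  k <- function(p) 35 - 30 * cos(2 * pi * p / 100)
  ses <- session_from_waves(list(knee_flexion = k(0:100)), foot_off = 60)
  f <- extract_discrete_features(average_cycles(ses), "left")
  oracle_swing <- max(k(seq(61, 100, 0.01)))
  expect_equal(unname(f["max_knee_flex_swing"]), oracle_swing,
               tolerance = 1e-9)
  expect_false(isTRUE(all.equal(unname(f["max_knee_flex_swing"]), 65)))
  expect_equal(unname(f["max_knee_flex_stance"]), 65)
  expect_equal(unname(f["rom_knee_sagittal_stance"]), 65 - k(0))

  # ankle moment ramp 0 -> 1 over stance (foot-off 60), lr_end 12:
  # LR min = 0 at 0%, PO max = value at 60%
  ramp <- c(seq(0, 1, length.out = 61), rep(0, 40))
  kin <- session_from_waves(foot_off = 60)
  cyc <- c(kin$cycles,
           list(gait_cycle("ankle_moment_sagittal", "left", ramp, 60)))
  ses <- gait_session("S", "1", cyc)
  f <- extract_discrete_features(average_cycles(ses), "left")
  expect_equal(unname(f["min_plantarflex_mom_lr"]), 0)
  expect_equal(unname(f["max_plantarflex_mom_po"]), 1)

  expect_error(phase_windows(foot_off = 10), "degenerate")
})

test_that("constant shifts move extrema and leave ROMs unchanged", {
  tg <- random_waveform_targets(seed = 4)
  ses <- simulate_session_waveforms(targets = tg, seed = 4, n_cycles = 3)
  avg <- average_cycles(ses)
  f0 <- extract_discrete_features(avg, "left")
  shift <- 7.5
  avg2 <- avg
  avg2$waveforms$left <- lapply(avg$waveforms$left, `+`, shift)
  f1 <- extract_discrete_features(avg2, "left")
  reg <- gait_feature_registry()
  rom_ids <- reg$id[!is.na(reg$stat) & reg$stat == "rom"]
  ext_ids <- reg$id[!is.na(reg$stat) & reg$stat %in% c("max", "min", "ic")]
  expect_equal(f1[rom_ids], f0[rom_ids], tolerance = 1e-12)
  expect_equal(f1[ext_ids], f0[ext_ids] + shift, tolerance = 1e-12)
})

test_that("time reversal leaves full-cycle max/min/ROM invariant", {
  tg <- random_waveform_targets(seed = 9)
  ses <- simulate_session_waveforms(targets = tg, seed = 9, n_cycles = 3)
  avg <- average_cycles(ses)
  f0 <- extract_discrete_features(avg, "left")
  avg2 <- avg
  avg2$waveforms$left <- lapply(avg$waveforms$left, rev)
  f1 <- extract_discrete_features(avg2, "left")
  full_ids <- c("max_ant_pelvic_tilt", "rom_pelvic_obliquity",
                "rom_pelvic_rotation", "rom_hip_sagittal")
  expect_equal(f1[full_ids], f0[full_ids], tolerance = 1e-12)
})

test_that("GPS closed forms hold and scale linearly", {
  ref <- synthetic_reference_bands()
  refl <- lapply(split(ref, ref$variable),
                 function(d) d$value[order(d$percent)])
  # identical to reference: all scores zero
  g0 <- compute_gps(refl, ref)
  expect_equal(g0$gps, 0)
  expect_equal(unname(g0$gvs), rep(0, 9))

  # +3 degrees on one variable: that GVS = 3, GPS = sqrt(9/9) = 1
  one <- refl
  one[["hip_rotation"]] <- one[["hip_rotation"]] + 3
  g1 <- compute_gps(one, ref)
  expect_equal(unname(g1$gvs["hip_rotation"]), 3)
  expect_equal(g1$gps, 1)

  # +3 on all nine: GPS = 3; doubling deviations doubles GPS
  all3 <- lapply(refl, `+`, 3)
  expect_equal(compute_gps(all3, ref)$gps, 3)
  all6 <- lapply(refl, `+`, 6)
  expect_equal(compute_gps(all6, ref)$gps, 6)

  # order of variables is irrelevant
  expect_equal(compute_gps(rev(all3), ref)$gps, 3)

  expect_error(compute_gps(refl[-1], ref), "missing GPS variable")
})

test_that("analysed side follows the weaker side, else a seeded draw", {
  ses <- simulate_session_waveforms(seed = 1, weaker_side = "left")
  expect_identical(select_analysis_side(ses), "left")
  ses$weaker_side <- "unknown"
  s7 <- select_analysis_side(ses, seed = 7)
  expect_true(all(replicate(5, select_analysis_side(ses, seed = 7)) == s7))
  # seeded draws are fair: each side in 50% +/- 2% over 10^4 seeds
  draws <- vapply(1:10000, function(s) select_analysis_side(ses, s), "")
  expect_gt(mean(draws == "left"), 0.48)
  expect_lt(mean(draws == "left"), 0.52)
})

test_that("a complete session yields exactly 31 features", {
  ref <- synthetic_reference_bands()
  ses <- simulate_session_waveforms(seed = 2)
  sf <- session_features(ses, ref)
  reg <- gait_feature_registry()
  expect_equal(nrow(reg), 31L)
  expect_true(all(reg$id %in% names(sf)))
  expect_true(all(is.finite(unlist(sf[reg$id]))))
  expect_equal(sum(reg$class == "spatiotemporal"), 4L)
  expect_equal(sum(reg$class == "kinematic"), 17L)
  expect_equal(sum(reg$class == "kinetic"), 10L)
  # ROM and GPS non-negativity
  rom_ids <- reg$id[!is.na(reg$stat) & reg$stat == "rom"]
  expect_true(all(sf[rom_ids] >= 0))
  expect_gte(sf$gps, 0)
})
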