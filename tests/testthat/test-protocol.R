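test_that("the reference configuration is self-consistent by construction", {
  p <- ref_params()
  geom <- ref_geometry()
  s <- solve_static(mmhg_to_kpa(100), 1, geom, p, "relaxed")
  expect_equal(s$lam_th, 1, tolerance = 1e-7)
  expect_equal(s$r_o_mm, geom$rho_o, tolerance = 1e-6)
})

test_that("the generated protocol has the expected structure and fidelity", {
  ds <- tiny_dataset()
  man <- ds$manifest
  expect_equal(sum(man$kind == "pressure_sweep"), 3)
  expect_equal(sum(man$kind == "dynamic_loop"), 6) # 2 freqs x 3 ranges
  expect_equal(sum(man$kind == "axial_sweep"), 2)

  # controlled variables held constant: length in sweeps/loops, pressure
  # in axial sweeps
  for (nm in man$step[man$kind != "axial_sweep"]) {
    expect_lt(diff(range(ds$steps[[nm]]$length_mm)), 1e-12)
  }
  for (nm in man$step[man$kind == "axial_sweep"]) {
    p_tgt <- mmhg_to_kpa(man$p_low_mmhg[man$step == nm])
    expect_lt(max(abs(ds$steps[[nm]]$pressure_kpa - p_tgt)),
              mmhg_to_kpa(1e-4))
  }

  # loops cover their nominal pressure ranges
  st <- ds$steps$loop_high_10Hz
  expect_equal(kpa_to_mmhg(range(st$pressure_kpa)), c(120, 160),
               tolerance = 1e-6)

  # dissipativity: every viscoelastic loop has positive hysteresis area
  for (nm in man$step[man$kind == "dynamic_loop"]) {
    lp <- loop_from_step(ds$steps[[nm]], ds$geometry, cycles = "last")
    x <- c(lp$lam_th, lp$lam_th[1]); y <- c(lp$sigma_tt, lp$sigma_tt[1])
    area <- sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)]) / 2
    expect_gt(abs(area), 0)
  }
})

test_that("an elastic ground truth produces coincident loading and unloading branches", {
  # symmetric triangular sweep: mirrored samples see identical pressures,
  # so with nu = 0 the response must be path-independent
  geom <- ref_geometry()
  tt <- seq(0, 120, by = 0.5)
  pw <- mmhg_to_kpa(10 + 170 * (1 - abs(tt - 60) / 60))
  sim <- solve_pressure_driven(tt, pw, 1, geom, elastic_params())
  expect_rel_equal(sim$lam_th, rev(sim$lam_th), 1e-8)
  expect_rel_equal(sim$F_mN, rev(sim$F_mN), 1e-6)
})

test_that("noise application is deterministic under a fixed seed", {
  geom <- ref_geometry()
  p <- ref_params()
  spec <- protocol_spec(qs_levels = 1.0, qs_dt = 2, dyn_freqs = 10,
                       dyn_ranges = list(medium = c(80, 120)),
                       ax_pressures = 100, ax_dt = 0.1)
  ns <- noise_spec(misalign_ms = 0.5)
  d1 <- generate_dataset(geom, p, spec, noise = ns, seed = 7)
  d2 <- generate_dataset(geom, p, spec, noise = ns, seed = 7)
  expect_identical(d1$steps, d2$steps)
  d3 <- generate_dataset(geom, p, spec, noise = ns, seed = 8)
  expect_false(identical(d1$steps$qs_sweep_100$pressure_kpa,
                         d3$steps$qs_sweep_100$pressure_kpa))
  # noise magnitude is as configured
  clean <- generate_dataset(geom, p, spec)
  resid <- kpa_to_mmhg(d1$steps$qs_sweep_100$pressure_kpa -
                         clean$steps$qs_sweep_100$pressure_kpa)
  expect_equal(stats::sd(resid), 0.5, tolerance = 0.25)
})

test_that("misalignment injection shifts the diameter channel and inverts", {
  ds <- tiny_dataset()
  st <- ds$steps$loop_medium_10Hz
  expect_identical(inject_misalignment(st, 0), st)
  sh <- inject_misalignment(st, 1)
  back <- inject_misalignment(sh, -1)
  inner <- 20:(nrow(st) - 20) # edge samples are held, not invertible
  amp <- diff(range(st$r_o_mm))
  expect_lt(max(abs(back$r_o_mm[inner] - st$r_o_mm[inner])) / amp, 1e-3)
  # 1 ms at 10 Hz (dt = 0.5 ms) moves the diameter peak two samples later
  lag <- which.max(sh$r_o_mm[60:140]) - which.max(st$r_o_mm[60:140])
  expect_true(lag %in% 1:3)
  expect_error(inject_misalignment(st, 10), "at most 5")
})

test_that("alignment delays are recovered from the loss-factor criterion", {
  ds <- tiny_dataset()
  null_est <- estimate_alignment_shift(ds)
  expect_true(all(abs(null_est$delay_ms) <= 2))
  expect_lt(max(abs(null_est$delay_ms)), 0.2)

  ds_mis <- ds
  for (nm in ds$manifest$step[ds$manifest$kind == "dynamic_loop" &
                                ds$manifest$frequency_hz == 10]) {
    ds_mis$steps[[nm]] <- inject_misalignment(ds$steps[[nm]], 1)
  }
  est <- estimate_alignment_shift(ds_mis)
  d10 <- est$delay_ms[est$frequency_hz == 10]
  expect_equal(d10, -1, tolerance = 0.3)

  ds_no_ref <- ds
  is25 <- ds$manifest$kind == "dynamic_loop" & ds$manifest$frequency_hz == 2.5
  ds_no_ref$manifest$frequency_hz[is25] <- 3.5
  expect_error(estimate_alignment_shift(ds_no_ref), "2.5 Hz")
})
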