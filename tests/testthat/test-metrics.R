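kv_loop <- function(tand, e0 = 0.05, emod = 100, n = 401, phase = 0) {
  om <- 2 * pi
  tt <- seq(0, 1, length.out = n)
  eps <- e0 * sin(om * tt + phase)
  tibble::tibble(time_s = tt, strain = eps,
                 sigma_tt = emod * (eps + tand * e0 * cos(om * tt + phase)))
}

test_that("the loss factor recovers tan(delta) for a linear viscoelastic sinusoid", {
  for (tand in c(0.02, 0.1, 0.25)) {
    expect_equal(loss_factor(kv_loop(tand)), tand, tolerance = 0.05 * tand + 1e-4)
  }
  # independent of where the recording starts within the cycle
  expect_equal(loss_factor(kv_loop(0.1, phase = 1.3)), 0.1, tolerance = 5e-3)
  # invariant under a stress unit change
  lp <- kv_loop(0.1)
  lp$sigma_tt <- lp$sigma_tt / 1000 # kPa -> MPa
  expect_equal(loss_factor(lp), 0.1, tolerance = 5e-3)
})

test_that("degenerate and open loops are rejected", {
  lp <- kv_loop(0.1)[1:150, ] # cycle chopped mid-way
  expect_error(loss_factor(lp), "closed")
  flat <- tibble::tibble(strain = rep(0.1, 10), sigma_tt = rep(1, 10))
  expect_error(loss_factor(flat), "degenerate")
})

test_that("an elastic loop collapses to ratio one and zero loss", {
  geom <- ref_geometry()
  p0 <- elastic_params()
  tt <- seq(0, 0.4, by = 0.4 / 800)
  pw <- mmhg_to_kpa(100 - 20 * cos(2 * pi * 2.5 * tt))
  sim <- solve_pressure_driven(tt, pw, 1, geom, p0)
  lp <- tibble::tibble(time_s = tt, pressure_kpa = sim$pressure_kpa,
                       lam_th = sim$lam_th, sigma_tt = sim$sigma_tt)
  qs <- tibble::tibble(
    pressure_kpa = sim$pressure_kpa, lam_th = sim$lam_th,
    sigma_tt = sim$sigma_tt,
    branch = ifelse(seq_along(tt) <= which.max(pw), "loading", "unloading")
  )
  sr <- stiffness_ratio(lp, qs)
  expect_equal(sr$ratio, 1, tolerance = 1e-5)
  expect_lt(loss_factor(lp), 1e-8)
})

test_that("the stiffness ratio matches the linear standard-solid closed form", {
  # analytic sinusoids: sigma = |E*| e0 sin(wt + delta) against the relaxed
  # quasi-static line sigma = E_rel eps
  e_rel <- 80
  e_star <- 100
  delta <- atan(0.02)
  e0 <- 0.04
  tt <- seq(0, 1, length.out = 501)
  eps <- e0 * sin(2 * pi * tt)
  lp <- tibble::tibble(
    time_s = tt, lam_th = 1 + eps,
    sigma_tt = e_star * e0 * sin(2 * pi * tt + delta),
    pressure_kpa = 5 + 4 * sin(2 * pi * tt)
  )
  qs_eps <- seq(-1.5 * e0, 1.5 * e0, length.out = 201)
  qs <- dplyr::bind_rows(
    tibble::tibble(pressure_kpa = 5 + 4 * qs_eps / e0, lam_th = 1 + qs_eps,
                   sigma_tt = e_rel * qs_eps, branch = "loading"),
    tibble::tibble(pressure_kpa = 5 + 4 * qs_eps / e0, lam_th = 1 + qs_eps,
                   sigma_tt = e_rel * qs_eps, branch = "unloading")
  )
  sr <- stiffness_ratio(lp, qs)
  expect_equal(sr$ratio, e_star / e_rel, tolerance = 1e-3)

  # affine rescaling of the strain axis leaves the ratio unchanged
  lp2 <- lp; lp2$lam_th <- 3 * lp$lam_th - 1.7
  qs2 <- qs; qs2$lam_th <- 3 * qs$lam_th - 1.7
  expect_equal(stiffness_ratio(lp2, qs2)$ratio, sr$ratio, tolerance = 1e-12)

  # uncovered pressure range errors
  lp3 <- lp; lp3$pressure_kpa <- lp$pressure_kpa + 100
  expect_error(stiffness_ratio(lp3, qs), "cover")
})

test_that("simulated loops dissipate and stiffen with pressure", {
  ds <- tiny_dataset()
  geom <- ref_geometry()
  qs <- qs_branches(ds$steps$qs_sweep_100, geom)
  etas <- c()
  ratios <- c()
  for (rng in c("low", "medium", "high")) {
    lp <- loop_from_step(ds$steps[[paste0("loop_", rng, "_10Hz")]], geom,
                         cycles = "last")
    etas[rng] <- loss_factor(lp)
    ratios[rng] <- stiffness_ratio(lp, qs)$ratio
  }
  expect_true(all(etas >= 0))
  expect_gt(ratios["high"], ratios["low"])
  expect_gt(ratios["medium"], 1)
})

test_that("loop extraction finds the final cycle", {
  ds <- tiny_dataset()
  st <- ds$steps$loop_medium_10Hz
  lp <- loop_from_step(st, ref_geometry(), cycles = "last")
  expect_equal(diff(range(lp$time_s)), 0.1, tolerance = 0.01)
  # endpoints close onto each other in pressure
  expect_lt(abs(lp$pressure_kpa[1] - lp$pressure_kpa[nrow(lp)]) /
              diff(range(lp$pressure_kpa)), 0.05)
})
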