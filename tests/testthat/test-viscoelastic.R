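test_that("fully relaxed initial stress scales each constituent by its plateau", {
  p <- ref_params()
  d0 <- tibble::tibble(lam_r = 1 / 1.1, lam_th = 1.1, lam_z = 1)
  s0 <- initial_stress(d0, p)
  el <- constituent_cauchy_elastic(d0, p)
  qe <- q_infinity(p$nu_e, p$tau1, p$tau2_e)$q_inf
  qc <- q_infinity(p$nu_c, p$tau1, p$tau2_c)$q_inf
  expect_equal(s0$S_tt_e, el$S_tt_e * qe, tolerance = 1e-12)
  expect_equal(s0$S_tt_c, el$S_tt_c * qc, tolerance = 1e-12)
  expect_equal(s0$S_zz, el$S_zz_e * qe + el$S_zz_c * qc, tolerance = 1e-12)

  # nu = 0 collapses to the elastic stress
  p0 <- p; p0$nu_e <- 0; p0$nu_c <- 0
  s00 <- initial_stress(d0, p0)
  expect_equal(s00$S_tt, el$S_tt, tolerance = 1e-12)

  id0 <- tibble::tibble(lam_r = 1, lam_th = 1, lam_z = 1)
  pu <- p; pu$lam_th_e <- 1; pu$lam_z_e <- 1; pu$lam_c <- 1
  expect_equal(initial_stress(id0, pu)$S_tt, 0, tolerance = 1e-12)
})

test_that("a constant history keeps the relaxed stress constant and nu = 0 is purely elastic", {
  p <- ref_params()
  n <- 80
  hist_const <- tibble::tibble(time_s = seq(0, 4, length.out = n),
                               lam_r = 1 / 1.08, lam_th = 1.08, lam_z = 1)
  sh <- viscoelastic_stress(hist_const, p)
  expect_rel_equal(sh$sigma_tt, rep(sh$sigma_tt[1], n), 1e-12)

  p0 <- p; p0$nu_e <- 0; p0$nu_c <- 0
  h <- sine_history(n = 101, lam0 = 1.05, amp = 0.03)
  sh0 <- viscoelastic_stress(h, p0)
  el <- constituent_cauchy_elastic(h, p0)
  expect_rel_equal(sh0$sigma_tt, el$sigma_tt, 1e-10)
  expect_rel_equal(sh0$sigma_zz, el$sigma_zz, 1e-10)
})

test_that("the step response reproduces the reduced relaxation function", {
  p <- ref_params()
  dt <- p$tau1 / 10
  tt <- seq(0, 0.2, by = dt)
  l <- ifelse(tt < 0.05, 1, 1.05)
  sh <- viscoelastic_stress(tibble::tibble(time_s = tt, lam_r = 1 / l,
                                           lam_th = l, lam_z = 1), p)
  i_star <- which(l > 1)[1]
  t_star <- (tt[i_star] + tt[i_star - 1]) / 2 # jump at the interval midpoint
  hatA <- constituent_cauchy_elastic(
    tibble::tibble(lam_r = 1, lam_th = 1, lam_z = 1), p)
  hatB <- constituent_cauchy_elastic(
    tibble::tibble(lam_r = 1 / 1.05, lam_th = 1.05, lam_z = 1), p)
  after <- seq(i_star, length(tt))
  qc_inf <- q_infinity(p$nu_c, p$tau1, p$tau2_c)$q_inf
  pred <- hatA$S_tt_c * qc_inf +
    (hatB$S_tt_c - hatA$S_tt_c) *
      reduced_relaxation(tt[after] - t_star, p$nu_c, p$tau1, p$tau2_c)
  expect_lt(max(abs(sh$S_tt_c[after] - pred) /
                  abs(hatB$S_tt_c - hatA$S_tt_c)), 1e-3)
})

test_that("the discrete hereditary integral converges at second order to quadrature", {
  # smooth kernel (tau1 well above the step sizes) isolates the
  # integrator's order
  p <- ref_params()
  p$nu_c <- 0.2; p$tau1 <- 0.05; p$tau2_c <- 5; p$nu_e <- 0
  lam_fun <- function(t) 1 + 0.05 * sin(2 * pi * t)
  hat_tt <- function(t) {
    l <- lam_fun(t)
    constituent_cauchy_elastic(
      tibble::tibble(lam_r = 1 / l, lam_th = l, lam_z = 1), p)$S_tt_c
  }
  t_end <- 2
  qinf <- q_infinity(p$nu_c, p$tau1, p$tau2_c)$q_inf
  dhat <- function(s) {
    l <- lam_fun(s); dl <- 2 * pi * 0.05 * cos(2 * pi * s); h <- 1e-4
    sp <- constituent_cauchy_elastic(
      tibble::tibble(lam_r = 1 / (l + h), lam_th = l + h, lam_z = 1), p)$S_tt_c
    sm <- constituent_cauchy_elastic(
      tibble::tibble(lam_r = 1 / (l - h), lam_th = l - h, lam_z = 1), p)$S_tt_c
    (sp - sm) / (2 * h) * dl
  }
  ref <- hat_tt(0) * qinf +
    integrate(function(s) {
      reduced_relaxation(t_end - s, p$nu_c, p$tau1, p$tau2_c) * dhat(s)
    }, 0, t_end, rel.tol = 1e-10, subdivisions = 2000)$value
  errs <- vapply(c(50, 100, 200, 400), function(npc) {
    tt <- seq(0, t_end, by = 1 / npc)
    l <- lam_fun(tt)
    sh <- viscoelastic_stress(tibble::tibble(time_s = tt, lam_r = 1 / l,
                                             lam_th = l, lam_z = 1), p)
    abs(sh$S_tt_c[length(tt)] - ref)
  }, numeric(1))
  ratios <- errs[-length(errs)] / errs[-1]
  expect_true(all(ratios > 3.3 & ratios < 4.8))
})

test_that("identical constituent kernels reproduce the sQLV special case exactly", {
  p <- ref_params()
  p$nu_e <- p$nu_c
  p$tau2_e <- p$tau2_c
  ps <- sqlv_constrain(ref_params())
  expect_equal(ps$mode, "sqlv")
  expect_equal(ps$nu_e, ps$nu_c)
  expect_identical(sqlv_constrain(ps), ps) # idempotent

  withr::with_seed(7, {
    tt <- seq(0, 3, length.out = 151)
    l <- 1.05 + 0.04 * sin(2 * pi * tt) + cumsum(rnorm(151, 0, 1e-4))
  })
  h <- tibble::tibble(time_s = tt, lam_r = 1 / l, lam_th = l, lam_z = 1)
  s_cb <- viscoelastic_stress(h, p)
  s_sq <- viscoelastic_stress(h, ps)
  expect_rel_equal(s_cb$sigma_tt, s_sq$sigma_tt, 1e-12)
  expect_rel_equal(s_cb$sigma_zz, s_sq$sigma_zz, 1e-12)
})

test_that("the hereditary integral is causal", {
  p <- ref_params()
  h <- sine_history(n = 161, t_end = 4, lam0 = 1.04, amp = 0.05)
  full <- viscoelastic_stress(h, p)
  cut <- viscoelastic_stress(h[1:101, ], p)
  expect_rel_equal(cut$sigma_tt, full$sigma_tt[1:101], 1e-13)
})

test_that("relaxation weighting shifts from the elastin to the collagen kernel with stretch", {
  # hold a stretch step and compare the late-time relaxed fraction of the
  # total stress with the constituent plateaus
  p <- ref_params()
  p$nu_e <- 0.02; p$tau2_e <- 20; p$nu_c <- 0.12; p$tau2_c <- 20
  relax_frac <- function(lam) {
    tt <- seq(0, 400, by = 0.5)
    l <- ifelse(tt < 1, lam * 0.999, lam)
    sh <- viscoelastic_stress(tibble::tibble(time_s = tt, lam_r = 1 / l,
                                             lam_th = l, lam_z = 1), p)
    n <- length(tt)
    jump <- sh$sigma_tt[3] # right after the step, nearly unrelaxed
    (jump - sh$sigma_tt[n]) / jump
  }
  lo <- relax_frac(0.92) # elastin-dominated
  hi <- relax_frac(1.15) # collagen recruited
  expect_lt(lo, hi)
})

test_that("non-uniform histories are rejected unless resampling is requested", {
  p <- ref_params()
  h <- sine_history(n = 81)
  h$time_s[40] <- h$time_s[40] + 0.004
  expect_error(viscoelastic_stress(h, p), "uniform")
  expect_silent(viscoelastic_stress(h, p, resample = TRUE))
  h$time_s[40] <- h$time_s[38]
  expect_error(viscoelastic_stress(h, p), "increasing")
})
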