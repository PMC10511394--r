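test_that("branch resampling honours its contract", {
  # symmetric hysteresis closing at the reversal point: the branch mean
  # must recover the backbone exactly (all signals piecewise linear)
  n <- 101
  ctrl <- c(seq(0, 1, length.out = 51), seq(1, 0, length.out = 51)[-1])
  f_of <- function(x) 2 + 3 * x
  g_of <- function(x) 0.4 * (1 - x)
  up <- seq_len(51)
  y <- c(f_of(ctrl[up]) - g_of(ctrl[up]),
         f_of(ctrl[-up]) + g_of(ctrl[-up]))
  st <- tibble::tibble(
    time_s = seq(0, 10, length.out = n),
    pressure_kpa = ctrl, r_o_mm = y, force_mn = 2 * y, length_mm = 5
  )
  avg <- resample_branch_average(st, "pressure_sweep", n = 35)
  expect_equal(nrow(avg), 35)
  expect_equal(nrow(attr(avg, "branches")), 70)
  expect_rel_equal(avg$r_o_mm, f_of(avg$ctrl), 1e-9)
  br <- attr(avg, "branches")
  expect_rel_equal(br$r_o_mm[br$branch == "loading"],
                   f_of(avg$ctrl) - g_of(avg$ctrl), 1e-9)

  # zero-hysteresis loop: average equals either branch
  y2 <- f_of(ctrl)
  st2 <- st; st2$r_o_mm <- y2; st2$force_mn <- 2 * y2
  avg2 <- resample_branch_average(st2, "pressure_sweep", n = 35)
  expect_rel_equal(avg2$r_o_mm, f_of(avg2$ctrl), 1e-9)

  expect_error(resample_branch_average(st[1:3, ], "pressure_sweep"),
               "4 samples")
})

test_that("axial sweeps share a unit weight proportional to path length", {
  ds <- tiny_dataset()
  w <- axial_sweep_weights(ds)
  expect_equal(sum(w$weight[grepl("ax_", w$step)]), 1, tolerance = 1e-12)
  expect_true(all(w$weight[grepl("qs_", w$step)] == 1))
  # the low-pressure sweep spans a wider stretch path than the 100 mmHg one
  w_ax <- setNames(w$weight, w$step)
  expect_gt(w_ax[["ax_sweep_010mmHg"]], w_ax[["ax_sweep_100mmHg"]])
})

test_that("costs vanish at the generating parameters and grow quadratically", {
  ds <- tiny_dataset()
  p <- ref_params()
  cfg <- fit_config(n_starts = 2)
  expect_lt(suppressWarnings(cost_quasistatic(p, ds, cfg)), 1e-6)
  expect_lt(suppressWarnings(cost_dynamic(p, ds, cfg)), 1e-4)

  # quadratic growth of the cost around its minimum: doubling a parameter
  # perturbation quadruples the cost
  cost_at <- function(eps) {
    pp <- p; pp$mu <- p$mu * (1 + eps)
    suppressWarnings(cost_quasistatic(pp, ds, cfg))
  }
  expect_equal(cost_at(0.01) / cost_at(0.005), 4, tolerance = 0.1)
})

test_that("the elastic-average cost sees the hysteresis the viscoelastic cost explains", {
  ds <- tiny_dataset()
  p <- ref_params()
  cfg <- fit_config(n_starts = 2)
  base <- suppressWarnings(cost_quasistatic(p, ds, cfg,
                                            average_branches = TRUE))
  expect_gt(base, 1) # hysteretic data is far from any elastic curve at truth
  worse <- p; worse$mu <- 10 * p$mu
  expect_gt(suppressWarnings(cost_quasistatic(worse, ds, cfg,
                                              average_branches = TRUE)), base)
})

test_that("a small multistart fit is reproducible and respects constraints", {
  ds <- tiny_dataset()
  cfg <- fit_config(n_starts = 2, seed = 11, max_iter = 6,
                    decimate_dyn = 4, resample_n = 20)
  f1 <- suppressWarnings(fit_cbqlv(ds, cfg))
  f2 <- suppressWarnings(fit_cbqlv(ds, cfg))
  expect_identical(tidy(f1)$value, tidy(f2)$value)
  expect_identical(glance(f1), glance(f2))

  # fixed parameters never move
  expect_equal(f1$params$beta, 0.15)
  expect_equal(f1$params$k2_comp, 1e-6)
  expect_equal(f1$params$tau1, 1e-3)
  expect_equal(f1$params$lam_z_e, ds$geometry$l_iv / ds$geometry$L0)
  # lam_c and lam_th_e frozen after step 1
  expect_equal(f1$params$lam_c,
               unname(f1$stages$step1$par[["lam_c"]]))
  expect_equal(f1$params$lam_th_e,
               unname(f1$stages$step1$par[["lam_th_e"]]))
  # best reported cost is the minimum over starts
  expect_equal(f1$stages$step2$cost, min(f1$stages$step2$starts$cost))
  # bounds respected
  b <- cbqlv_bounds()
  tb <- tidy(f1)
  for (tm in c("mu", "k1", "lam_c", "alpha_diag")) {
    v <- tb$value[tb$term == tm]
    expect_gte(v, b$lower[b$term == tm])
    expect_lte(v, b$upper[b$term == tm])
  }
})

test_that("a purely elastic dataset drives the spectrum magnitudes to zero", {
  ds <- elastic_dataset()
  cfg <- fit_config(n_starts = 5, seed = 5, max_iter = 60,
                    decimate_dyn = 4, resample_n = 20)
  fit <- suppressWarnings(fit_cbqlv(ds, cfg))
  expect_lt(fit$params$nu_e, 0.01)
  expect_lt(fit$params$nu_c, 0.01)
})

test_that("the sQLV constraint averages between the constituent spectra", {
  # data generated with nu_e = 0 < nu_c; the shared spectrum must land
  # strictly between them
  geom <- ref_geometry()
  p <- ref_params()
  p$nu_e <- 0
  ds <- generate_dataset(geom, p, tiny_protocol())
  cfg <- fit_config(n_starts = 5, seed = 9, max_iter = 60, mode = "sqlv",
                    decimate_dyn = 4, resample_n = 20)
  fit <- suppressWarnings(fit_cbqlv(ds, cfg))
  expect_equal(fit$mode, "sqlv")
  expect_equal(fit$params$nu_e, fit$params$nu_c)
  expect_gt(fit$params$nu_c, 0.005)
  expect_lt(fit$params$nu_c, p$nu_c)
})
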