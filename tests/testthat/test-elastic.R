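id_defm <- tibble::tibble(lam_r = 1, lam_th = 1, lam_z = 1)

unit_dep <- function(p) {
  p$lam_th_e <- 1
  p$lam_z_e <- 1
  p$lam_c <- 1
  p
}

test_that("elastin invariant matches direct arithmetic", {
  p <- ref_params()
  expect_equal(elastin_invariant(id_defm, unit_dep(p)), 3, tolerance = 1e-12)
  # sample II deposition stretches at the identity
  ref <- 1 / (1.56 * 1.62)^2 + 1.56^2 + 1.62^2
  expect_equal(elastin_invariant(id_defm, p), ref, tolerance = 1e-12)
})

test_that("fibre invariants follow the deposition stretch along the fibre", {
  p <- ref_params()
  expect_equal(fibre_invariant(id_defm, p, "circ"), p$lam_c^2,
               tolerance = 1e-12)
  d2 <- tibble::tibble(lam_r = 1.17, lam_th = 1, lam_z = 1 / 1.17)
  expect_equal(fibre_invariant(d2, p, "axial"), 1, tolerance = 1e-12)

  p45 <- p
  p45$alpha_diag <- 45
  p45$lam_c <- 1.08
  d3 <- tibble::tibble(lam_r = 1 / 1.1, lam_th = 1.1, lam_z = 1.0)
  expect_equal(fibre_invariant(d3, p45, "diag"),
               1.08^2 * (1.1^2 * 0.5 + 1.0^2 * 0.5), tolerance = 1e-12)
})

test_that("strain energy matches the family closed form and vanishes at the natural state", {
  p <- ref_params()
  en0 <- strain_energy(id_defm, unit_dep(p))
  expect_equal(en0$psi_e, 0)
  expect_equal(en0$psi_c, 0)

  # one family with I4 = 1.1: k1/(4 k2) (exp(k2 (I4-1)^2) - 1)
  p1 <- p
  p1$mu <- 1e-12 # silence the matrix term
  p1$k1 <- 7.1
  p1$k2_ax <- 14.6
  p1$k2_circ <- 1e-3
  p1$k2_diag <- 1e-3
  # choose lam_z so the axial family sits at I4 = 1.1, others compressed
  lam_z <- sqrt(1.1) / p1$lam_c
  d <- tibble::tibble(lam_r = 1, lam_th = 1 / lam_z, lam_z = lam_z)
  fam_ref <- 7.1 / (4 * 14.6) * (exp(14.6 * 0.1^2) - 1)
  i4_circ <- fibre_invariant(d, p1, "circ")
  i4_diag <- fibre_invariant(d, p1, "diag")
  fam_en <- function(i4, k2) {
    k2e <- ifelse(i4 < 1, p1$k2_comp, k2)
    p1$k1 / (4 * k2e) * (exp(k2e * (i4 - 1)^2) - 1)
  }
  other <- fam_en(i4_circ, p1$k2_circ) + 2 * fam_en(i4_diag, p1$k2_diag)
  expect_equal(strain_energy(d, p1)$psi_c, fam_ref + other, tolerance = 1e-9)
  expect_equal(fam_ref, 0.01911, tolerance = 1e-3)

  # near-quadratic response in compression (k2_comp -> 0 limit)
  pq <- p1
  d_comp <- tibble::tibble(lam_r = 1.2, lam_th = sqrt(0.95) / pq$lam_c,
                           lam_z = 1 / (1.2 * sqrt(0.95) / pq$lam_c))
  i4 <- fibre_invariant(d_comp, pq, "circ")
  expect_lt(i4, 1)
  en <- pq$k1 / (4 * pq$k2_comp) * (exp(pq$k2_comp * (i4 - 1)^2) - 1)
  expect_equal(en, pq$k1 / 4 * (i4 - 1)^2, tolerance = 1e-6)
})

test_that("extra 2nd PK components match finite differences of the energy", {
  p <- ref_params()
  states <- list(c(1.05, 1.02), c(1.12, 0.97), c(0.95, 1.05))
  for (s in states) {
    lt <- s[1]; lz <- s[2]; lr <- 1 / (lt * lz)
    d <- tibble::tibble(lam_r = lr, lam_th = lt, lam_z = lz)
    got <- constituent_second_pk_extra(d, p)
    h <- 1e-6
    # derivative w.r.t. lam_th^2 at fixed lam_r, lam_z
    num_th <- function(which) {
      lt2 <- lt^2
      dp <- tibble::tibble(lam_r = lr, lam_th = sqrt(lt2 + h), lam_z = lz)
      dm <- tibble::tibble(lam_r = lr, lam_th = sqrt(lt2 - h), lam_z = lz)
      (strain_energy(dp, p)[[which]] - strain_energy(dm, p)[[which]]) / h
    }
    num_zz <- function(which) {
      lz2 <- lz^2
      dp <- tibble::tibble(lam_r = lr, lam_th = lt, lam_z = sqrt(lz2 + h))
      dm <- tibble::tibble(lam_r = lr, lam_th = lt, lam_z = sqrt(lz2 - h))
      (strain_energy(dp, p)[[which]] - strain_energy(dm, p)[[which]]) / h
    }
    # central difference over 2h: (Psi(x+h) - Psi(x-h)) / h = 2 dPsi/dx
    expect_equal(got$e_tt, num_th("psi_e"), tolerance = 1e-5)
    expect_equal(got$e_zz, num_zz("psi_e"), tolerance = 1e-5)
    expect_equal(got$c_tt, num_th("psi_c"), tolerance = 1e-5)
    expect_equal(got$c_zz, num_zz("psi_c"), tolerance = 1e-5)
    expect_equal(got$c_rr, 0)
  }
})

test_that("membrane closure zeroes the radial stress and leaves observables hydrostatically invariant", {
  p <- ref_params()
  d <- tibble::tibble(lam_r = 1 / (1.08 * 1.01), lam_th = 1.08, lam_z = 1.01)
  st <- constituent_cauchy_elastic(d, p)
  expect_equal(st$sigma_rr, 0)
  # P and F depend on differences only
  expect_equal(luminal_pressure(st$sigma_tt + 7, st$sigma_rr + 7, 0.3, 0.03),
               luminal_pressure(st$sigma_tt, st$sigma_rr, 0.3, 0.03))
  expect_equal(
    transducer_force(st$sigma_zz + 7, st$sigma_tt + 7, st$sigma_rr + 7, 0.3, 0.03),
    transducer_force(st$sigma_zz, st$sigma_tt, st$sigma_rr, 0.3, 0.03),
    tolerance = 1e-12
  )
  # all stresses vanish at the constituent natural state
  st0 <- constituent_cauchy_elastic(id_defm, unit_dep(p))
  expect_equal(unlist(st0[1, 1:13]), setNames(rep(0, 13), names(st0)[1:13]),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("fibre stress is slope-continuous across the tension-compression switch", {
  p <- ref_params()
  # sweep lam_th through the point where the circumferential family crosses I4 = 1
  lam_cross <- 1 / p$lam_c
  eps <- 1e-7
  d <- function(lt) tibble::tibble(lam_r = 1 / lt, lam_th = lt, lam_z = 1)
  s_at <- function(lt) constituent_cauchy_elastic(d(lt), p)$S_tt_c
  slope_lo <- (s_at(lam_cross) - s_at(lam_cross - eps)) / eps
  slope_hi <- (s_at(lam_cross + eps) - s_at(lam_cross)) / eps
  expect_equal(slope_lo, slope_hi, tolerance = 1e-4)
})

test_that("the literal diagonal invariant agrees with the standard form at axial and circumferential angles", {
  p <- ref_params()
  d <- tibble::tibble(lam_r = 1 / (1.1 * 1.02), lam_th = 1.1, lam_z = 1.02)
  for (a in c(1e-6, 90 - 1e-6)) {
    p_std <- p; p_std$alpha_diag <- a
    p_lit <- p_std; p_lit$literal_diag_invariant <- TRUE
    expect_equal(fibre_invariant(d, p_std, "diag"),
                 fibre_invariant(d, p_lit, "diag"), tolerance = 1e-4)
  }
  # and they genuinely differ at oblique angles
  p_lit <- p; p_lit$literal_diag_invariant <- TRUE
  expect_gt(abs(fibre_invariant(d, p, "diag") -
                  fibre_invariant(d, p_lit, "diag")), 1e-3)
})
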