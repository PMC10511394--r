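## Four-fibre-family elastic law with constituent deposition stretches.
##
## Internal workhorses operate on plain numeric vectors of principal
## stretches (relative to the in-vivo reference kappa_r); exported wrappers
## accept/return tibbles.

.deg2rad <- function(a) a * pi / 180

.i1_elastin <- function(lam_r, lam_th, lam_z, p) {
  lam_r^2 / (p$lam_th_e * p$lam_z_e)^2 +
    (p$lam_th_e * lam_th)^2 + (p$lam_z_e * lam_z)^2
}

## fibre-family description: fourth invariant and its derivative weights
## w_tt = dI4/d(lam_th^2), w_zz = dI4/d(lam_z^2); `mult` counts symmetric
## diagonal families
.fibre_families <- function(p) {
  a <- .deg2rad(p$alpha_diag)
  s2 <- sin(a)^2
  c2 <- cos(a)^2
  lc2 <- p$lam_c^2
  if (p$literal_diag_invariant) {
    w_tt_d <- lc2 * s2^2
    w_zz_d <- lc2 * c2^2
  } else {
    w_tt_d <- lc2 * s2
    w_zz_d <- lc2 * c2
  }
  list(
    list(name = "axial", k2 = p$k2_ax,  w_tt = 0,        w_zz = lc2,   mult = 1),
    list(name = "circ",  k2 = p$k2_circ, w_tt = lc2,      w_zz = 0,     mult = 1),
    list(name = "diag",  k2 = p$k2_diag, w_tt = w_tt_d,   w_zz = w_zz_d, mult = 2)
  )
}

.fam_i4 <- function(fam, lam_th, lam_z) {
  fam$w_tt * lam_th^2 + fam$w_zz * lam_z^2
}

## per-constituent "hat" 2nd PK stress: extra stress plus the constituent
## Lagrange term, with p_j fixed by zero radial Cauchy stress per
## constituent (membrane closure); the radial hat component is identically 0
.hat_stress <- function(lam_r, lam_th, lam_z, p) {
  ge_r <- 1 / (p$lam_th_e * p$lam_z_e)^2
  ge_t <- p$lam_th_e^2
  ge_z <- p$lam_z_e^2
  i1 <- lam_r^2 * ge_r + ge_t * lam_th^2 + ge_z * lam_z^2
  a <- p$mu * (1 + p$beta) * pmax(i1 - 3, 0)^p$beta
  p_e <- lam_r^2 * a * ge_r
  e_tt <- a * ge_t - p_e / lam_th^2
  e_zz <- a * ge_z - p_e / lam_z^2

  c_tt <- 0
  c_zz <- 0
  for (fam in .fibre_families(p)) {
    i4 <- .fam_i4(fam, lam_th, lam_z)
    k2 <- ifelse(i4 < 1, p$k2_comp, fam$k2)
    g <- p$k1 * (i4 - 1) * exp(k2 * (i4 - 1)^2)
    c_tt <- c_tt + fam$mult * g * fam$w_tt
    c_zz <- c_zz + fam$mult * g * fam$w_zz
  }
  list(e_tt = e_tt, e_zz = e_zz, c_tt = c_tt, c_zz = c_zz, p_e = p_e)
}

.as_defm <- function(defm) {
  if (is.data.frame(defm)) {
    stopifnot(all(c("lam_r", "lam_th", "lam_z") %in% names(defm)))
    defm
  } else {
    abort("`defm` must be a data frame with columns lam_r, lam_th, lam_z")
  }
}

#' First invariant of the elastin right Cauchy--Green tensor
#'
#' \eqn{I_{1,e} = \lambda_r^2/(\lambda_{\theta,e}\lambda_{z,e})^2 +
#' (\lambda_{\theta,e}\lambda_\theta)^2 + (\lambda_{z,e}\lambda_z)^2},
#' where the elastin deposition-stretch matrix has unit determinant.
#'
#' @param defm Data frame with columns `lam_r`, `lam_th`, `lam_z` (stretches
#'   relative to the in-vivo reference).
#' @param p A [qlv_params()].
#' @return Numeric vector \eqn{I_{1,e}}.
#' @export
elastin_invariant <- function(defm, p) {
  defm <- .as_defm(defm)
  .i1_elastin(defm$lam_r, defm$lam_th, defm$lam_z, p)
}

#' Fourth invariant of a collagen fibre family
#'
#' \eqn{I_4 = \lambda_c^2(\lambda_\theta^2\sin^2\alpha +
#' \lambda_z^2\cos^2\alpha)} with \eqn{\alpha = 0} for the axial family,
#' \eqn{90^\circ} for the circumferential family and \eqn{\pm\alpha_{diag}}
#' for the two (identical under orthotropic deformation) diagonal families.
#'
#' @inheritParams elastin_invariant
#' @param family One of `"axial"`, `"circ"`, `"diag"` (the two diagonal
#'   families coincide for torsion-free deformations).
#' @return Numeric vector \eqn{I_4}.
#' @export
fibre_invariant <- function(defm, p, family = c("axial", "circ", "diag")) {
  family <- match.arg(family)
  defm <- .as_defm(defm)
  fams <- .fibre_families(p)
  fam <- fams[[match(family, vapply(fams, `[[`, "", "name"))]]
  .fam_i4(fam, defm$lam_th, defm$lam_z)
}

#' Strain energy of the matrix and fibre constituents
#'
#' \eqn{\Psi_e = (\mu/2)(I_{1,e}-3)^{1+\beta}} for the isotropic matrix
#' (with \eqn{I_{1,e}-3} clamped at 0 against round-off) and
#' \eqn{\Psi_c = \sum_i k_1/(4 k_2^i)\,[e^{k_2^i (I_4^i-1)^2}-1]} over the
#' four fibre families, with `k2_comp` substituted for any family whose
#' \eqn{I_4 < 1}.
#'
#' @inheritParams elastin_invariant
#' @return Tibble with columns `psi_e`, `psi_c` (kPa).
#' @export
strain_energy <- function(defm, p) {
  defm <- .as_defm(defm)
  i1 <- .i1_elastin(defm$lam_r, defm$lam_th, defm$lam_z, p)
  psi_e <- p$mu / 2 * pmax(i1 - 3, 0)^(1 + p$beta)
  psi_c <- 0
  for (fam in .fibre_families(p)) {
    i4 <- .fam_i4(fam, defm$lam_th, defm$lam_z)
    k2 <- ifelse(i4 < 1, p$k2_comp, fam$k2)
    psi_c <- psi_c + fam$mult * p$k1 / (4 * k2) * (exp(k2 * (i4 - 1)^2) - 1)
  }
  tibble(psi_e = psi_e, psi_c = psi_c)
}

#' Per-constituent elastic stresses under the membrane closure
#'
#' Returns the constituent "hat" 2nd Piola--Kirchhoff stresses (the extra
#' stress \eqn{2\partial\Psi_j/\partial\lambda_i^2} plus the constituent
#' Lagrange term) and the corresponding Cauchy stresses
#' \eqn{\sigma_{ii,j} = \hat S_{ii,j}\lambda_i^2}. Each constituent's
#' Lagrange multiplier is fixed by requiring zero radial Cauchy stress for
#' that constituent (so the radial hat components, and the total
#' \eqn{\sigma_{rr}}, are identically zero); pressure and axial force depend
#' only on stress differences and are unaffected by this closure.
#'
#' @inheritParams elastin_invariant
#' @return Tibble with per-state columns: hat 2nd PK components `S_tt_e`,
#'   `S_zz_e`, `S_tt_c`, `S_zz_c`, totals `S_tt`, `S_zz`, Cauchy stresses
#'   `sigma_tt_e`, `sigma_zz_e`, `sigma_tt_c`, `sigma_zz_c`, `sigma_tt`,
#'   `sigma_zz`, `sigma_rr` (all kPa, `sigma_rr` always 0) and the elastin
#'   multiplier `p_e`.
#' @export
constituent_cauchy_elastic <- function(defm, p) {
  defm <- .as_defm(defm)
  h <- .hat_stress(defm$lam_r, defm$lam_th, defm$lam_z, p)
  lt2 <- defm$lam_th^2
  lz2 <- defm$lam_z^2
  tibble(
    S_tt_e = h$e_tt, S_zz_e = h$e_zz,
    S_tt_c = h$c_tt, S_zz_c = h$c_zz,
    S_tt = h$e_tt + h$c_tt, S_zz = h$e_zz + h$c_zz,
    sigma_tt_e = h$e_tt * lt2, sigma_zz_e = h$e_zz * lz2,
    sigma_tt_c = h$c_tt * lt2, sigma_zz_c = h$c_zz * lz2,
    sigma_tt = (h$e_tt + h$c_tt) * lt2,
    sigma_zz = (h$e_zz + h$c_zz) * lz2,
    sigma_rr = 0,
    p_e = h$p_e
  )
}

#' Per-constituent extra 2nd Piola--Kirchhoff stress components
#'
#' The raw derivatives \eqn{2\partial\Psi_j/\partial\lambda_i^2} without any
#' Lagrange term: elastin contributes in all three directions, collagen only
#' circumferentially and axially.
#'
#' @inheritParams elastin_invariant
#' @return Tibble with columns `e_rr`, `e_tt`, `e_zz` (elastin) and `c_rr`,
#'   `c_tt`, `c_zz` (collagen, `c_rr` always 0), kPa.
#' @export
constituent_second_pk_extra <- function(defm, p) {
  defm <- .as_defm(defm)
  ge_r <- 1 / (p$lam_th_e * p$lam_z_e)^2
  i1 <- .i1_elastin(defm$lam_r, defm$lam_th, defm$lam_z, p)
  a <- p$mu * (1 + p$beta) * pmax(i1 - 3, 0)^p$beta
  c_tt <- 0
  c_zz <- 0
  for (fam in .fibre_families(p)) {
    i4 <- .fam_i4(fam, defm$lam_th, defm$lam_z)
    k2 <- ifelse(i4 < 1, p$k2_comp, fam$k2)
    g <- p$k1 * (i4 - 1) * exp(k2 * (i4 - 1)^2)
    c_tt <- c_tt + fam$mult * g * fam$w_tt
    c_zz <- c_zz + fam$mult * g * fam$w_zz
  }
  tibble(
    e_rr = a * ge_r, e_tt = a * p$lam_th_e^2, e_zz = a * p$lam_z_e^2,
    c_rr = 0 * c_tt, c_tt = c_tt, c_zz = c_zz
  )
}
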