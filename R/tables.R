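#' Reference parameter estimates for five mouse common carotid arteries
#'
#' Parameter sets estimated with the three-step pipeline from biaxial
#' quasi-static and dynamic testing of n = 5 adult male C57BL/6 mouse left
#' common carotid arteries, for the constituent-based model
#' (`model = "cbqlv"`, independent elastin and collagen relaxation
#' spectra) and for the single-kernel special case (`model = "sqlv"`).
#' `tau2_e_s` is `NA` where `nu_e = 0` (elastin purely elastic: the time
#' constant is then unidentifiable). `lam_z_e` was fixed to the in-vivo to
#' unloaded length ratio; `tau1` was fixed at 1e-3 s for both spectra.
#' `rmse_d` and `rmse_qs` are the dynamic (step 2) and quasi-static
#' (step 3) fit errors.
#'
#' @param model `"cbqlv"` or `"sqlv"`.
#' @return A tibble, one row per artery.
#' @examples
#' carotid_parameter_table("cbqlv")
#' @export
carotid_parameter_table <- function(model = c("cbqlv", "sqlv")) {
  model <- match.arg(model)
  if (model == "cbqlv") {
    tibble(
      sample = c("I", "II", "III", "IV", "V"),
      mu_kPa = c(27.7, 46.8, 30.0, 21.7, 15.2),
      lam_th_e = c(1.79, 1.56, 2.01, 1.84, 2.07),
      lam_z_e = c(1.92, 1.62, 2.05, 1.83, 1.92),
      nu_e = c(0.000, 0.033, 0.000, 0.000, 0.000),
      tau2_e_s = c(NA, 100.0, NA, NA, NA),
      k1_kPa = c(56.3, 7.1, 137.5, 62.2, 86.4),
      k2_ax = c(4.3, 3.9, 3.7, 0.0, 3.0),
      k2_circ = c(27.5, 14.6, 16.1, 3.9, 3.0),
      k2_diag = c(72.9, 25.1, 49.1, 8.8, 19.7),
      alpha_diag_deg = c(42.4, 44.3, 42.1, 42.4, 44.5),
      lam_c = c(1.08, 1.17, 1.07, 1.19, 1.12),
      nu_c = c(0.059, 0.061, 0.104, 0.137, 0.135),
      tau2_c_s = c(59.3, 46.2, 76.4, 20.6, 17.7),
      rmse_d = c(0.049, 0.035, 0.069, 0.076, 0.090),
      rmse_qs = c(0.044, 0.059, 0.060, 0.092, 0.078)
    )
  } else {
    tibble(
      sample = c("I", "II", "III", "IV", "V"),
      mu_kPa = c(40.7, 53.7, 52.9, 43.4, 31.0),
      lam_th_e = c(1.79, 1.56, 2.01, 1.84, 2.07),
      lam_z_e = c(1.92, 1.62, 2.05, 1.83, 1.92),
      k1_kPa = c(50.9, 6.8, 118.9, 59.2, 79.9),
      k2_ax = c(4.5, 3.9, 4.4, 0.0, 3.3),
      k2_circ = c(27.6, 14.6, 16.6, 3.8, 3.1),
      k2_diag = c(73.5, 25.1, 50.7, 8.8, 19.9),
      alpha_diag_deg = c(42.4, 44.3, 42.4, 42.4, 44.6),
      lam_c = c(1.08, 1.17, 1.08, 1.19, 1.12),
      nu = c(0.046, 0.054, 0.079, 0.117, 0.115),
      tau2_s = c(38.6, 50.9, 30.8, 11.7, 16.2),
      rmse_d = c(0.062, 0.037, 0.114, 0.101, 0.125),
      rmse_qs = c(0.049, 0.059, 0.076, 0.095, 0.091)
    )
  }
}

#' Long-time relaxation summary of the reference parameter tables
#'
#' Per-artery and mean percent stress relaxation implied by the relaxation
#' spectra of [carotid_parameter_table()]: for each artery the closed-form
#' plateau \eqn{100\,(1 - [1+\nu\ln(\tau_2/\tau_1)]^{-1})} with
#' \eqn{\tau_1 = 10^{-3}} s, evaluated for the collagen and elastin
#' kernels (cbQLV; arteries with \eqn{\nu_e = 0} contribute zero elastin
#' relaxation) or the shared kernel (sQLV).
#'
#' @param model `"cbqlv"` or `"sqlv"`.
#' @param tau1 Short time constant, s.
#' @return A tibble with one row per artery plus a `"mean"` row; columns
#'   depend on the model (`relax_c_pct`/`relax_e_pct` or `relax_pct`).
#' @examples
#' relaxation_summary("cbqlv")
#' @export
relaxation_summary <- function(model = c("cbqlv", "sqlv"), tau1 = 1e-3) {
  model <- match.arg(model)
  tb <- carotid_parameter_table(model)
  if (model == "cbqlv") {
    rc <- q_infinity(tb$nu_c, tau1, tb$tau2_c_s)$relaxation_pct
    re <- ifelse(tb$nu_e == 0, 0,
                 q_infinity(tb$nu_e, tau1, tb$tau2_e_s)$relaxation_pct)
    out <- tibble(sample = tb$sample, relax_c_pct = rc, relax_e_pct = re)
    dplyr::bind_rows(out, tibble(sample = "mean",
                                 relax_c_pct = mean(rc),
                                 relax_e_pct = mean(re)))
  } else {
    r <- q_infinity(tb$nu, tau1, tb$tau2_s)$relaxation_pct
    out <- tibble(sample = tb$sample, relax_pct = r)
    dplyr::bind_rows(out, tibble(sample = "mean", relax_pct = mean(r)))
  }
}

#' Parameters of a reference artery as a `qlv_params` object
#'
#' Convenience constructor turning one row of
#' [carotid_parameter_table()] into a parameter object, e.g. as ground
#' truth for the synthetic protocol generator.
#'
#' @param sample Sample label `"I"`..`"V"`.
#' @param model `"cbqlv"` or `"sqlv"`.
#' @return A [qlv_params()].
#' @examples
#' carotid_params("II")
#' @export
carotid_params <- function(sample = "II", model = c("cbqlv", "sqlv")) {
  model <- match.arg(model)
  tb <- carotid_parameter_table(model)
  r <- tb[tb$sample == sample, ]
  if (nrow(r) != 1) abort("unknown sample label")
  if (model == "cbqlv") {
    qlv_params(
      mu = r$mu_kPa, lam_th_e = r$lam_th_e, lam_z_e = r$lam_z_e,
      k1 = r$k1_kPa, k2_ax = max(r$k2_ax, 1e-3), k2_circ = r$k2_circ,
      k2_diag = r$k2_diag, alpha_diag = r$alpha_diag_deg, lam_c = r$lam_c,
      nu_e = r$nu_e, tau2_e = ifelse(is.na(r$tau2_e_s), 100, r$tau2_e_s),
      nu_c = r$nu_c, tau2_c = r$tau2_c_s, mode = "cbqlv"
    )
  } else {
    qlv_params(
      mu = r$mu_kPa, lam_th_e = r$lam_th_e, lam_z_e = r$lam_z_e,
      k1 = r$k1_kPa, k2_ax = max(r$k2_ax, 1e-3), k2_circ = r$k2_circ,
      k2_diag = r$k2_diag, alpha_diag = r$alpha_diag_deg, lam_c = r$lam_c,
      nu_c = r$nu, tau2_c = r$tau2_s, mode = "sqlv"
    )
  }
}

#' Synthetic geometry of a reference-like mouse carotid artery
#'
#' Builds a [vessel_geometry()] from the measured unloaded dimensions of
#' the reference arteries (outer diameter 470 um, wall thickness 75 um)
#' and synthetic axial lengths (in-vivo length 6 mm; unloaded length set
#' so the in-vivo axial stretch matches the parameter set's fixed
#' `lam_z_e`). The reference outer diameter is solved with
#' [consistent_reference_diameter()] so that the fully relaxed model
#' pressure at the identity deformation is exactly 100 mmHg. The axial
#' lengths are modelling choices, not measurements.
#'
#' @param p A [qlv_params()] used for the self-consistency solve.
#' @param in_vivo_length_mm Assumed in-vivo length, mm.
#' @return A [vessel_geometry()].
#' @examples
#' synthetic_carotid_geometry(carotid_params("II"))
#' @export
synthetic_carotid_geometry <- function(p, in_vivo_length_mm = 6) {
  L0 <- in_vivo_length_mm / p$lam_z_e
  rho <- consistent_reference_diameter(470, 75, L0, in_vivo_length_mm, p)
  vessel_geometry(470, 75, unloaded_length_mm = L0,
                  in_vivo_length_mm = in_vivo_length_mm,
                  reference_outer_diameter_um = rho)
}
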