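## Hereditary-integral (cbQLV) stress for deformation histories.
##
## Discretisation: uniform time step; elastic hat stresses evaluated at the
## sample points, increments between consecutive samples convolved with each
## constituent's reduced relaxation function evaluated at interval midpoints
## (second-order accurate). The first state is treated as fully relaxed.

## direct O(N^2) midpoint convolution; d_inc has length n-1, q holds kernel
## weights at half lags (reference R implementation; the package hot path
## uses the compiled .conv_hereditary)
.convolve_increments <- function(d_inc, q, s0) {
  n <- length(d_inc) + 1L
  out <- numeric(n)
  out[1] <- s0
  if (n > 1L) {
    for (i in 2:n) {
      k <- i - 1L
      out[i] <- s0 + sum(q[k:1] * d_inc[1:k])
    }
  }
  out
}

.check_uniform_dt <- function(t, resample = FALSE) {
  if (length(t) < 2L) abort("history must contain at least two time points")
  if (any(diff(t) <= 0)) abort("time must be strictly increasing")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-8 * max(dt)) {
    if (!resample) {
      abort("history is not uniform in time; resample it first (resample = TRUE)")
    }
    return(NULL)
  }
  mean(dt)
}

#' Fully relaxed initial 2nd Piola--Kirchhoff stress
#'
#' Assuming complete relaxation of the prior history, the stress at the
#' start of an experiment equals each constituent's elastic hat stress
#' scaled by its long-time plateau \eqn{Q_j(\infty) =
#' [1+\nu_j\ln(\tau_{2,j}/\tau_{1,j})]^{-1}}, summed over constituents.
#'
#' @param defm0 One-row data frame with `lam_r`, `lam_th`, `lam_z`: the
#'   first state of the history.
#' @param p A [qlv_params()].
#' @return One-row tibble with per-constituent and total hat components
#'   `S_tt_e`, `S_zz_e`, `S_tt_c`, `S_zz_c`, `S_tt`, `S_zz` (kPa; radial
#'   components are identically zero under the membrane closure).
#' @export
initial_stress <- function(defm0, p) {
  defm0 <- .as_defm(defm0)
  h <- .hat_stress(defm0$lam_r[1], defm0$lam_th[1], defm0$lam_z[1], p)
  qe <- q_infinity(p$nu_e, p$tau1, p$tau2_e)$q_inf
  qc <- q_infinity(p$nu_c, p$tau1, p$tau2_c)$q_inf
  tibble(
    S_tt_e = h$e_tt * qe, S_zz_e = h$e_zz * qe,
    S_tt_c = h$c_tt * qc, S_zz_c = h$c_zz * qc,
    S_tt = h$e_tt * qe + h$c_tt * qc,
    S_zz = h$e_zz * qe + h$c_zz * qc
  )
}

## internal engine on plain vectors; returns list of stress component vectors
.viscoelastic_stress <- function(time_s, lam_r, lam_th, lam_z, p) {
  n <- length(time_s)
  dt <- mean(diff(time_s))
  h <- .hat_stress(lam_r, lam_th, lam_z, p)
  qe_inf <- q_infinity(p$nu_e, p$tau1, p$tau2_e)$q_inf
  qc_inf <- q_infinity(p$nu_c, p$tau1, p$tau2_c)$q_inf
  qe <- .q_kernel(n - 1L, dt, p$nu_e, p$tau1, p$tau2_e)
  qc <- .q_kernel(n - 1L, dt, p$nu_c, p$tau1, p$tau2_c)
  d <- cbind(diff(h$e_tt), diff(h$e_zz), diff(h$c_tt), diff(h$c_zz))
  q <- cbind(qe, qe, qc, qc)
  s0 <- c(h$e_tt[1] * qe_inf, h$e_zz[1] * qe_inf,
          h$c_tt[1] * qc_inf, h$c_zz[1] * qc_inf)
  s <- .conv_hereditary(d, q, s0)
  list(S_tt_e = s[, 1], S_zz_e = s[, 2], S_tt_c = s[, 3], S_zz_c = s[, 4])
}

#' Viscoelastic stress history for a deformation history
#'
#' Evaluates the constituent-based hereditary integral
#' \deqn{\sigma_{ii}(t) = \Big\{S_{ii}(0) + \int_0^t
#'   Q_e(t-s)\,\mathrm{d}\hat S^e_{ii,e}(s) +
#'   Q_c(t-s)\,\mathrm{d}\hat S^e_{ii,c}(s)\Big\}\,\lambda_i^2(t)}
#' on a uniform time grid, with each constituent's elastic hat stress (extra
#' stress plus its membrane-closure Lagrange term) differenced between
#' samples and the kernels evaluated at interval midpoints. The first state
#' is assumed fully relaxed. In sQLV mode both constituents share one
#' kernel.
#'
#' @param history Data frame with columns `time_s`, `lam_r`, `lam_th`,
#'   `lam_z`; time strictly increasing and uniform (or set
#'   `resample = TRUE` to interpolate onto a uniform grid of the same
#'   length first).
#' @param p A [qlv_params()].
#' @param resample Interpolate a non-uniform history onto a uniform grid.
#' @return A tibble (`time_s`, per-constituent 2nd PK components `S_tt_e`,
#'   `S_zz_e`, `S_tt_c`, `S_zz_c`, totals `S_tt`, `S_zz`, `S_rr` = 0, and
#'   Cauchy stresses `sigma_tt`, `sigma_zz`, `sigma_rr` = 0, kPa).
#' @export
viscoelastic_stress <- function(history, p, resample = FALSE) {
  stopifnot(is.data.frame(history),
            all(c("time_s", "lam_r", "lam_th", "lam_z") %in% names(history)))
  dt <- .check_uniform_dt(history$time_s, resample = resample)
  if (is.null(dt)) {
    tu <- seq(min(history$time_s), max(history$time_s),
              length.out = nrow(history))
    history <- tibble(
      time_s = tu,
      lam_th = approx(history$time_s, history$lam_th, tu)$y,
      lam_z = approx(history$time_s, history$lam_z, tu)$y
    )
    history$lam_r <- 1 / (history$lam_th * history$lam_z)
  }
  s <- .viscoelastic_stress(history$time_s, history$lam_r,
                            history$lam_th, history$lam_z, p)
  lt2 <- history$lam_th^2
  lz2 <- history$lam_z^2
  tibble(
    time_s = history$time_s,
    S_tt_e = s$S_tt_e, S_zz_e = s$S_zz_e,
    S_tt_c = s$S_tt_c, S_zz_c = s$S_zz_c,
    S_tt = s$S_tt_e + s$S_tt_c, S_zz = s$S_zz_e + s$S_zz_c, S_rr = 0,
    sigma_tt = (s$S_tt_e + s$S_tt_c) * lt2,
    sigma_zz = (s$S_zz_e + s$S_zz_c) * lz2,
    sigma_rr = 0
  )
}
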