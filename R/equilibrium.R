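#' Thin-wall equilibrium: luminal pressure and transducer axial force
#'
#' Membrane approximations of radial and axial equilibrium for a pressurised
#' cylinder: \eqn{P = (\sigma_{\theta\theta} - \sigma_{rr})\,h/r_m} and
#' \eqn{F = \pi(2\sigma_{zz} - \sigma_{\theta\theta} - \sigma_{rr})\,r_m h}.
#' Both depend on stress differences only, so they are invariant to any
#' hydrostatic shift.
#'
#' @param sigma_tt,sigma_zz,sigma_rr Cauchy stress components, kPa
#'   (vectorised).
#' @param r_m Mid-wall radius, mm.
#' @param h Wall thickness, mm.
#' @return `luminal_pressure()`: pressure in kPa (multiply by
#'   [kpa_to_mmhg()] for mmHg); `transducer_force()`: axial force in mN
#'   (kPa mm^2 = mN).
#' @examples
#' kpa_to_mmhg(luminal_pressure(100, 0, r_m = 0.4, h = 0.04))
#' @export
luminal_pressure <- function(sigma_tt, sigma_rr = 0, r_m, h) {
  if (any(r_m <= 0) || any(h <= 0)) abort("`r_m` and `h` must be positive")
  (sigma_tt - sigma_rr) * h / r_m
}

#' @rdname luminal_pressure
#' @export
transducer_force <- function(sigma_zz, sigma_tt, sigma_rr = 0, r_m, h) {
  if (any(r_m <= 0) || any(h <= 0)) abort("`r_m` and `h` must be positive")
  pi * (2 * sigma_zz - sigma_tt - sigma_rr) * r_m * h
}

## pressure implied by a trial circumferential stretch, for root solving:
## sigma_tt supplied as a function of lam_th
.pressure_of_stretch <- function(lam_th, lam_z, geom, sigma_tt_fun) {
  r_m <- lam_th * geom$rho_m
  r_o2 <- r_m^2 + geom$A_m / lam_z
  r_i <- sqrt(r_o2 - geom$A_i / lam_z)
  h <- sqrt(r_o2) - r_i
  sigma_tt_fun(lam_th) * h / r_m
}

## bracketed root solve for lam_th such that model pressure matches target;
## expands around a starting guess, hard limits [0.3, 3]
.solve_lam_th <- function(target_kpa, lam_z, geom, sigma_tt_fun,
                          start = 1, tol = 1e-10) {
  f <- function(l) {
    out <- tryCatch(
      .pressure_of_stretch(l, lam_z, geom, sigma_tt_fun) - target_kpa,
      error = function(e) NaN
    )
    if (!is.finite(out)) NaN else out
  }
  fail <- function() {
    abort(sprintf(
      "pressure solve failed: no circumferential stretch in [0.3, 3] matches %.3f mmHg (lam_z = %.3f)",
      kpa_to_mmhg(target_kpa), lam_z
    ))
  }
  # fast path: expand a bracket around the previous solution
  lo <- max(0.3, start * 0.98)
  hi <- min(3, start * 1.02)
  flo <- f(lo)
  fhi <- f(hi)
  for (grow in 1:60) {
    if (is.finite(flo) && is.finite(fhi) && flo * fhi <= 0) {
      return(uniroot(f, lower = lo, upper = hi, f.lower = flo,
                     f.upper = fhi, tol = tol)$root)
    }
    lo_new <- max(0.3, lo * 0.95)
    hi_new <- min(3, hi * 1.05)
    if (!is.finite(flo) && !is.finite(f(lo_new))) lo_new <- lo # stuck at invalid geometry
    lo <- lo_new
    hi <- hi_new
    flo <- f(lo)
    fhi <- f(hi)
    if (lo <= 0.3 && hi >= 3) break
  }
  # slow path: scan the admissible range for a sign change
  grid <- exp(seq(log(0.3), log(3), length.out = 121))
  vals <- vapply(grid, f, numeric(1))
  ok <- which(is.finite(vals))
  if (length(ok) < 2) fail()
  sgn <- which(vals[ok[-length(ok)]] * vals[ok[-1]] <= 0 &
                 diff(ok) == 1L)
  if (!length(sgn)) fail()
  i <- ok[sgn[1]]
  uniroot(f, lower = grid[i], upper = grid[i + 1], f.lower = vals[i],
          f.upper = vals[i + 1], tol = tol)$root
}

#' Static (elastic or fully relaxed) inflation solve
#'
#' Finds the circumferential stretch at which the thin-wall pressure of the
#' purely elastic stress (`state = "elastic"`) or of the fully relaxed
#' stress (`state = "relaxed"`, each constituent scaled by its
#' \eqn{Q_j(\infty)}) balances a prescribed pressure at fixed axial stretch.
#'
#' @param pressure_kpa Target pressure, kPa (vectorised).
#' @param lam_z Axial stretch (scalar or vectorised).
#' @param geom A [vessel_geometry()].
#' @param p A [qlv_params()].
#' @param state `"relaxed"` or `"elastic"`.
#' @return Tibble with `lam_th`, `lam_r`, `lam_z`, radii and thickness, and
#'   the balancing stresses `sigma_tt`, `sigma_zz` (kPa) and force `F_mN`.
#' @export
solve_static <- function(pressure_kpa, lam_z = 1, geom, p,
                         state = c("relaxed", "elastic")) {
  state <- match.arg(state)
  qe <- if (state == "relaxed") q_infinity(p$nu_e, p$tau1, p$tau2_e)$q_inf else 1
  qc <- if (state == "relaxed") q_infinity(p$nu_c, p$tau1, p$tau2_c)$q_inf else 1
  n <- max(length(pressure_kpa), length(lam_z))
  pressure_kpa <- rep_len(pressure_kpa, n)
  lam_z <- rep_len(lam_z, n)
  lam_th <- numeric(n)
  start <- 1
  for (i in seq_len(n)) {
    lz <- lam_z[i]
    sfun <- function(lt) {
      hh <- .hat_stress(1 / (lt * lz), lt, lz, p)
      (hh$e_tt * qe + hh$c_tt * qc) * lt^2
    }
    lam_th[i] <- .solve_lam_th(pressure_kpa[i], lz, geom, sfun, start = start)
    start <- lam_th[i]
  }
  rad <- radii_from_stretch(geom, lam_th, lam_z)
  hh <- .hat_stress(1 / (lam_th * lam_z), lam_th, lam_z, p)
  sigma_tt <- (hh$e_tt * qe + hh$c_tt * qc) * lam_th^2
  sigma_zz <- (hh$e_zz * qe + hh$c_zz * qc) * lam_z^2
  tibble(
    lam_th = lam_th, lam_r = 1 / (lam_th * lam_z), lam_z = lam_z,
    r_o_mm = rad$r_o_mm, r_m_mm = rad$r_m_mm, r_i_mm = rad$r_i_mm,
    h_mm = rad$h_mm,
    sigma_tt = sigma_tt, sigma_zz = sigma_zz,
    F_mN = transducer_force(sigma_zz, sigma_tt, 0, rad$r_m_mm, rad$h_mm)
  )
}

#' Pressure-driven viscoelastic time stepping
#'
#' Simulates the vessel response to a prescribed pressure waveform at
#' prescribed axial stretch. At each time step the scalar root problem
#' "thin-wall pressure of the viscoelastic stress (frozen history plus the
#' current increment) equals the prescribed pressure" is solved for the
#' circumferential stretch. The first state is fully relaxed at the first
#' prescribed pressure.
#'
#' @param time_s Uniform, strictly increasing time grid, s.
#' @param pressure_kpa Prescribed pressure at each time, kPa.
#' @param lam_z Axial stretch: scalar or one value per time point.
#' @param geom A [vessel_geometry()].
#' @param p A [qlv_params()].
#' @return A tibble with the deformation history (`lam_r`, `lam_th`,
#'   `lam_z`), geometry (`r_o_mm`, `r_m_mm`, `h_mm`), stresses `sigma_tt`,
#'   `sigma_zz` (kPa), the achieved `pressure_kpa` and axial force `F_mN`.
#' @export
solve_pressure_driven <- function(time_s, pressure_kpa, lam_z = 1, geom, p) {
  dt <- .check_uniform_dt(time_s)
  n <- length(time_s)
  stopifnot(length(pressure_kpa) == n)
  lam_z <- rep_len(lam_z, n)

  qe_inf <- q_infinity(p$nu_e, p$tau1, p$tau2_e)$q_inf
  qc_inf <- q_infinity(p$nu_c, p$tau1, p$tau2_c)$q_inf
  qe <- .q_kernel(n - 1L, dt, p$nu_e, p$tau1, p$tau2_e)
  qc <- .q_kernel(n - 1L, dt, p$nu_c, p$tau1, p$tau2_c)

  lam_th <- numeric(n)
  e_tt <- numeric(n); e_zz <- numeric(n)
  c_tt <- numeric(n); c_zz <- numeric(n)
  S_tt <- numeric(n); S_zz <- numeric(n)

  # fully relaxed start
  sfun0 <- function(lt) {
    hh <- .hat_stress(1 / (lt * lam_z[1]), lt, lam_z[1], p)
    (hh$e_tt * qe_inf + hh$c_tt * qc_inf) * lt^2
  }
  lam_th[1] <- .solve_lam_th(pressure_kpa[1], lam_z[1], geom, sfun0)
  h1 <- .hat_stress(1 / (lam_th[1] * lam_z[1]), lam_th[1], lam_z[1], p)
  e_tt[1] <- h1$e_tt; e_zz[1] <- h1$e_zz
  c_tt[1] <- h1$c_tt; c_zz[1] <- h1$c_zz
  S0_e_tt <- h1$e_tt * qe_inf; S0_e_zz <- h1$e_zz * qe_inf
  S0_c_tt <- h1$c_tt * qc_inf; S0_c_zz <- h1$c_zz * qc_inf
  S_tt[1] <- S0_e_tt + S0_c_tt
  S_zz[1] <- S0_e_zz + S0_c_zz

  for (i in 2:n) {
    k <- i - 2L # completed increments before the current one
    if (k > 0L) {
      we <- qe[(k + 1L):2]
      wc <- qc[(k + 1L):2]
      idx <- 1:k
      froz_e_tt <- sum(we * (e_tt[idx + 1L] - e_tt[idx]))
      froz_e_zz <- sum(we * (e_zz[idx + 1L] - e_zz[idx]))
      froz_c_tt <- sum(wc * (c_tt[idx + 1L] - c_tt[idx]))
      froz_c_zz <- sum(wc * (c_zz[idx + 1L] - c_zz[idx]))
    } else {
      froz_e_tt <- froz_e_zz <- froz_c_tt <- froz_c_zz <- 0
    }
    base_tt <- S0_e_tt + S0_c_tt + froz_e_tt + froz_c_tt
    lz <- lam_z[i]
    ep <- e_tt[i - 1L]
    cp <- c_tt[i - 1L]
    sfun <- function(lt) {
      hh <- .hat_stress(1 / (lt * lz), lt, lz, p)
      (base_tt + qe[1] * (hh$e_tt - ep) + qc[1] * (hh$c_tt - cp)) * lt^2
    }
    lam_th[i] <- .solve_lam_th(pressure_kpa[i], lz, geom, sfun,
                               start = lam_th[i - 1L])
    hi <- .hat_stress(1 / (lam_th[i] * lz), lam_th[i], lz, p)
    e_tt[i] <- hi$e_tt; e_zz[i] <- hi$e_zz
    c_tt[i] <- hi$c_tt; c_zz[i] <- hi$c_zz
    S_tt[i] <- base_tt + qe[1] * (hi$e_tt - ep) + qc[1] * (hi$c_tt - cp)
    S_zz[i] <- S0_e_zz + S0_c_zz + froz_e_zz + froz_c_zz +
      qe[1] * (hi$e_zz - e_zz[i - 1L]) + qc[1] * (hi$c_zz - c_zz[i - 1L])
  }

  rad <- radii_from_stretch(geom, lam_th, lam_z)
  sigma_tt <- S_tt * lam_th^2
  sigma_zz <- S_zz * lam_z^2
  tibble(
    time_s = time_s,
    pressure_kpa = sigma_tt * rad$h_mm / rad$r_m_mm,
    lam_r = 1 / (lam_th * lam_z), lam_th = lam_th, lam_z = lam_z,
    r_o_mm = rad$r_o_mm, r_m_mm = rad$r_m_mm, h_mm = rad$h_mm,
    sigma_tt = sigma_tt, sigma_zz = sigma_zz,
    F_mN = transducer_force(sigma_zz, sigma_tt, 0, rad$r_m_mm, rad$h_mm)
  )
}

#' Deformation-driven response of a protocol step
#'
#' Computes the model pressure and transducer force for measured outer
#' radius and length signals: stretches via [current_deformation()], the
#' hereditary-integral stress via [viscoelastic_stress()], then thin-wall
#' equilibrium.
#'
#' @param time_s Uniform time grid, s.
#' @param r_o_mm,l_mm Measured outer radius and axial length signals, mm.
#' @param geom A [vessel_geometry()].
#' @param p A [qlv_params()].
#' @return A tibble with the deformation, stresses (kPa), model
#'   `pressure_kpa` and `F_mN`.
#' @export
predict_response <- function(time_s, r_o_mm, l_mm, geom, p) {
  defm <- current_deformation(geom, r_o_mm, l_mm)
  s <- .viscoelastic_stress(time_s, defm$lam_r, defm$lam_th, defm$lam_z, p)
  sigma_tt <- (s$S_tt_e + s$S_tt_c) * defm$lam_th^2
  sigma_zz <- (s$S_zz_e + s$S_zz_c) * defm$lam_z^2
  tibble(
    time_s = time_s,
    lam_r = defm$lam_r, lam_th = defm$lam_th, lam_z = defm$lam_z,
    r_m_mm = defm$r_m_mm, h_mm = defm$h_mm,
    sigma_tt = sigma_tt, sigma_zz = sigma_zz,
    S_tt = s$S_tt_e + s$S_tt_c, S_zz = s$S_zz_e + s$S_zz_c,
    pressure_kpa = sigma_tt * defm$h_mm / defm$r_m_mm,
    F_mN = transducer_force(sigma_zz, sigma_tt, 0, defm$r_m_mm, defm$h_mm)
  )
}
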