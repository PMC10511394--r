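## Viscoelastic summary metrics: dynamic-to-quasi-static stiffness ratio,
## loss factor and the dynamic-to-static modulus grid.

.ols_slope <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sum((x - mx)^2)
}

#' Build a stress--stretch loop from a recorded protocol step
#'
#' Converts the measured signals of a dynamic loop into the
#' (circumferential stretch, Cauchy stress) plane. The experimental wall
#' stress is recovered from pressure and geometry through thin-wall
#' equilibrium, \eqn{\sigma_{\theta\theta} = P\,r_m/h}.
#'
#' @param step Protocol-step tibble (`time_s`, `pressure_kpa`, `r_o_mm`,
#'   `length_mm`).
#' @param geom A [vessel_geometry()].
#' @param cycles `"all"` or `"last"` (extract the final full cycle, found
#'   from the dominant pressure period).
#' @param sigma_tt Optional replacement stress signal (kPa), e.g. a model
#'   prediction evaluated on the measured deformation.
#' @return Tibble with `time_s`, `pressure_kpa`, `lam_th`, `sigma_tt`.
#' @export
loop_from_step <- function(step, geom, cycles = c("all", "last"),
                           sigma_tt = NULL) {
  cycles <- match.arg(cycles)
  defm <- current_deformation(geom, step$r_o_mm, step$length_mm)
  sig <- if (is.null(sigma_tt)) {
    step$pressure_kpa * defm$r_m_mm / defm$h_mm
  } else {
    sigma_tt
  }
  out <- tibble(time_s = step$time_s, pressure_kpa = step$pressure_kpa,
                lam_th = defm$lam_th, sigma_tt = sig)
  if (cycles == "last") {
    per <- .dominant_period(out$time_s, out$pressure_kpa)
    t_end <- max(out$time_s)
    out <- out[out$time_s >= t_end - per - 1e-12, ]
  }
  out
}

## robust period estimate: median spacing of upward mean crossings of the
## lightly smoothed signal (raw crossings shatter under measurement noise)
.dominant_period <- function(t, x) {
  n <- length(x)
  k <- max(1L, round(n / 100))
  if (k > 1L) {
    xs <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
  } else {
    xs <- x
  }
  xc <- xs - mean(xs, na.rm = TRUE)
  ok <- !is.na(xc[-1]) & !is.na(xc[-n])
  up <- which(ok & xc[-1] > 0 & xc[-n] <= 0)
  if (length(up) < 2) return(diff(range(t)))
  stats::median(diff(t[up]))
}

.split_branches <- function(x) {
  i_max <- which.max(x)
  list(loading = seq_len(i_max), unloading = seq(i_max, length(x)))
}

#' Dynamic-to-quasi-static stiffness ratio of a loop
#'
#' \eqn{\mathcal{K}_D} is the ordinary least-squares slope of Cauchy stress
#' versus circumferential stretch over the whole dynamic loop;
#' \eqn{\mathcal{K}_{QS}} is the mean of the loading- and unloading-branch
#' slopes of the quasi-static curve restricted to the loop's pressure
#' range. The ratio is invariant to affine rescaling of the strain axis.
#'
#' @param loop Tibble from [loop_from_step()] (columns `pressure_kpa`,
#'   `lam_th`, `sigma_tt`).
#' @param qs_curve Quasi-static curve with columns `pressure_kpa`,
#'   `lam_th`, `sigma_tt` and `branch` (`"loading"`/`"unloading"`), e.g.
#'   from [qs_branches()].
#' @return One-row tibble with `K_D`, `K_QS` (kPa per unit stretch) and
#'   `ratio`.
#' @export
stiffness_ratio <- function(loop, qs_curve) {
  k_d <- .ols_slope(loop$lam_th, loop$sigma_tt)
  p_rng <- range(loop$pressure_kpa)
  slopes <- vapply(c("loading", "unloading"), function(b) {
    sel <- qs_curve$branch == b &
      qs_curve$pressure_kpa >= p_rng[1] & qs_curve$pressure_kpa <= p_rng[2]
    if (sum(sel) < 3) {
      abort("quasi-static curve does not cover the loop's pressure range")
    }
    .ols_slope(qs_curve$lam_th[sel], qs_curve$sigma_tt[sel])
  }, numeric(1))
  k_qs <- mean(slopes)
  tibble(K_D = k_d, K_QS = k_qs, ratio = k_d / k_qs)
}

#' Quasi-static stress--stretch branches of a pressure sweep
#'
#' Splits a quasi-static pressure sweep at its pressure maximum into
#' loading and unloading branches, in the (stretch, Cauchy stress) plane,
#' for use as the quasi-static reference of [stiffness_ratio()].
#'
#' @inheritParams loop_from_step
#' @return Tibble with `pressure_kpa`, `lam_th`, `sigma_tt`, `branch`.
#' @export
qs_branches <- function(step, geom, sigma_tt = NULL) {
  defm <- current_deformation(geom, step$r_o_mm, step$length_mm)
  sig <- if (is.null(sigma_tt)) {
    step$pressure_kpa * defm$r_m_mm / defm$h_mm
  } else {
    sigma_tt
  }
  br <- .split_branches(step$pressure_kpa)
  dplyr::bind_rows(
    tibble(pressure_kpa = step$pressure_kpa[br$loading],
           lam_th = defm$lam_th[br$loading], sigma_tt = sig[br$loading],
           branch = "loading"),
    tibble(pressure_kpa = step$pressure_kpa[br$unloading],
           lam_th = defm$lam_th[br$unloading], sigma_tt = sig[br$unloading],
           branch = "unloading")
  )
}

#' Loss factor of a stress--strain loop
#'
#' Ratio of the dissipated energy (hysteresis-loop area, by the shoelace
#' formula) to \eqn{2\pi} times the stored elastic energy, where the
#' stored energy is the average area under a quarter of the cycle: the
#' branch-averaged stress curve is integrated from the mid-strain point to
#' each strain extreme about the mid-point stress, and the two
#' quarter-areas are averaged. This normalisation returns
#' \eqn{\eta = \tan\delta} exactly for a linear viscoelastic sinusoid.
#'
#' @param loop Tibble with columns `lam_th` (or `strain`) and `sigma_tt`;
#'   first and last points must close the cycle.
#' @param closure_tol Allowed gap between the first and last point,
#'   relative to the signal ranges.
#' @return The dimensionless loss factor (non-negative for a dissipative
#'   loop).
#' @export
loss_factor <- function(loop, closure_tol = 0.05) {
  eps <- if ("strain" %in% names(loop)) loop$strain else loop$lam_th
  sig <- loop$sigma_tt
  rng_e <- diff(range(eps)); rng_s <- diff(range(sig))
  if (rng_e <= 0 || rng_s <= 0) abort("degenerate loop")
  gap <- max(abs(eps[1] - eps[length(eps)]) / rng_e,
             abs(sig[1] - sig[length(sig)]) / rng_s)
  if (gap > closure_tol) {
    abort(sprintf("loop is not closed (relative gap %.3g)", gap))
  }
  # shoelace area (dissipated energy per cycle per unit volume)
  x <- c(eps, eps[1]); y <- c(sig, sig[1])
  a_loop <- abs(sum(x[-length(x)] * y[-1] - x[-1] * y[-length(y)])) / 2

  # rotate the closed cycle to start at the strain minimum so the two
  # branches each span the full strain range
  rot <- c(which.min(eps):length(eps), seq_len(which.min(eps) - 1L))
  eps <- eps[rot]
  sig <- sig[rot]

  # branch-averaged backbone curve on a common strain grid
  br <- .split_branches(eps)
  grid <- seq(min(eps), max(eps), length.out = 101)
  interp_branch <- function(idx) {
    o <- order(eps[idx])
    approx(eps[idx][o], sig[idx][o], xout = grid, rule = 2, ties = mean)$y
  }
  backbone <- (interp_branch(br$loading) + interp_branch(br$unloading)) / 2

  e_mid <- (min(eps) + max(eps)) / 2
  s_mid <- approx(grid, backbone, xout = e_mid)$y
  upper <- grid >= e_mid
  q_up <- .trapz(grid[upper], backbone[upper] - s_mid)
  q_dn <- .trapz(grid[!upper | grid == e_mid], # lower quarter, reflected
                 s_mid - backbone[!upper | grid == e_mid])
  w_q <- (q_up + q_dn) / 2
  if (w_q <= 0) return(0)
  a_loop / (2 * pi * w_q)
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Dynamic-to-static modulus ratio over a pressure--frequency grid
#'
#' Simulates small sinusoidal pressure cycles (default amplitude 0.5 mmHg)
#' centred at each grid pressure and frequency, at the in-vivo length, and
#' evaluates the slope \eqn{E_D} of 2nd Piola--Kirchhoff stress versus
#' Green--Lagrange strain over the final cycle. The response at the lowest
#' frequency of `static_freq_hz` (default 1e-5 Hz, far below
#' \eqn{1/\tau_2}) serves as the fully static reference \eqn{E_S}. Each
#' cycle is fitted with a quadratic in strain plus a linear time term
#' (removing residual creep), and the dynamic slope is evaluated at the
#' mean strain of the static reference cycle, so that \eqn{E_D} and
#' \eqn{E_S} compare the material at a common operating strain and the
#' leading finite-amplitude bias of the elastic nonlinearity cancels.
#' Variants zero one constituent's spectrum magnitude to isolate the other
#' constituent's contribution to wall viscoelasticity.
#'
#' @param p A [qlv_params()].
#' @param geom A [vessel_geometry()].
#' @param pressures_mmhg Centre pressures, mmHg (default 20--180 by 5).
#' @param freqs_hz Loading frequencies, Hz (default 1e-5 to 1e5, half-decade
#'   steps).
#' @param amplitude_mmhg Pressure half-amplitude, mmHg.
#' @param variant `"full"`, `"elastin_only"` (nu_c = 0) or
#'   `"collagen_only"` (nu_e = 0).
#' @param static_freq_hz Reference frequency for \eqn{E_S}.
#' @param cycles,samples_per_cycle Cycles simulated after a one-cycle
#'   run-in, and the sampling density; the final cycle is used.
#' @return A tidy tibble of class `cbqlv_grid`: `variant`, `frequency_hz`,
#'   `pressure_mmhg`, `E_D` (kPa), `E_S` (kPa), `ratio`.
#' @export
modulus_ratio_grid <- function(p, geom,
                               pressures_mmhg = seq(20, 180, by = 5),
                               freqs_hz = 10^seq(-5, 5, by = 0.5),
                               amplitude_mmhg = 0.5,
                               variant = c("full", "elastin_only",
                                           "collagen_only"),
                               static_freq_hz = 1e-5,
                               cycles = 3, samples_per_cycle = 200) {
  variant <- match.arg(variant)
  pv <- p
  if (variant == "elastin_only") pv$nu_c <- 0
  if (variant == "collagen_only") pv$nu_e <- 0

  # quadratic-in-strain fit of the final cycle with a linear time term
  # (removes residual creep); slopes of different cycles are compared at a
  # common operating strain, the mean strain of the static reference cycle
  cycle_fit <- function(p0_mmhg, f) {
    dt <- 1 / (f * samples_per_cycle)
    n_cyc <- cycles + 1 # one run-in cycle from the relaxed state
    tt <- seq(0, n_cyc / f, by = dt)
    pw <- p0_mmhg - amplitude_mmhg * cos(2 * pi * f * tt)
    sim <- solve_pressure_driven(tt, mmhg_to_kpa(pw), lam_z = 1, geom, pv)
    last <- tt >= (n_cyc - 1) / f - 1e-12
    s2pk <- sim$sigma_tt[last] / sim$lam_th[last]^2
    gl <- green_lagrange(sim$lam_th[last])
    g0 <- mean(gl)
    x <- gl - g0
    cf <- stats::coef(stats::lm(s2pk ~ x + I(x^2) + tt[last]))
    list(g0 = g0, b1 = unname(cf[2]), b2 = unname(cf[3]))
  }

  out <- list()
  for (p0 in pressures_mmhg) {
    fs <- cycle_fit(p0, static_freq_hz)
    e_s <- fs$b1
    for (f in freqs_hz) {
      if (abs(f - static_freq_hz) < 1e-15) {
        e_d <- e_s
      } else {
        fd <- cycle_fit(p0, f)
        e_d <- fd$b1 + 2 * fd$b2 * (fs$g0 - fd$g0)
      }
      out[[length(out) + 1]] <- tibble(
        variant = variant, frequency_hz = f, pressure_mmhg = p0,
        E_D = e_d, E_S = e_s, ratio = e_d / e_s
      )
    }
  }
  res <- dplyr::bind_rows(out)
  class(res) <- c("cbqlv_grid", class(res))
  res
}
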