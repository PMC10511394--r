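#' Specification of the synthetic biaxial testing protocol
#'
#' Describes the 20-step protocol used to characterise murine carotid
#' viscoelasticity: three quasi-static inflation/deflation pressure sweeps
#' (10--180 mmHg at about 3 mmHg/s, at 105/95/100 % of the in-vivo length),
#' twelve trains of sinusoidal pressure loops (frequencies 2.5/5/10/20 Hz
#' crossed with the 40--80, 80--120 and 120--160 mmHg ranges, at the
#' in-vivo length) and five quasi-static axial force sweeps (0 to the
#' maximum force seen in the 105 % pressure sweep, stretch rate 0.11 1/s,
#' at 10/60/100/140/180 mmHg).
#'
#' @param qs_levels Axial-length levels of the pressure sweeps (fractions
#'   of the in-vivo length).
#' @param qs_range Pressure range of the sweeps, mmHg.
#' @param qs_rate Inflation rate, mmHg/s.
#' @param qs_dt Sampling interval of the quasi-static sweeps, s.
#' @param dyn_freqs Loop frequencies, Hz.
#' @param dyn_ranges Named list of `c(low, high)` pressure ranges, mmHg.
#' @param dyn_cycles Cycles per loop train (recorded in full, starting
#'   from the fully relaxed state at the range minimum).
#' @param dyn_samples_per_cycle Samples per loop cycle.
#' @param ax_pressures Constant pressures of the axial sweeps, mmHg.
#' @param ax_rate Axial stretch rate, 1/s.
#' @param ax_dt Sampling interval of the axial sweeps, s.
#' @return A list of class `protocol_spec`.
#' @export
protocol_spec <- function(qs_levels = c(1.05, 0.95, 1.00),
                          qs_range = c(10, 180),
                          qs_rate = 3,
                          qs_dt = 0.25,
                          dyn_freqs = c(2.5, 5, 10, 20),
                          dyn_ranges = list(low = c(40, 80),
                                            medium = c(80, 120),
                                            high = c(120, 160)),
                          dyn_cycles = 4,
                          dyn_samples_per_cycle = 200,
                          ax_pressures = c(10, 60, 100, 140, 180),
                          ax_rate = 0.11,
                          ax_dt = 0.02) {
  stopifnot(all(dyn_freqs > 0), qs_rate > 0, ax_rate > 0,
            all(unlist(dyn_ranges) >= 0), all(unlist(dyn_ranges) <= 200))
  structure(
    list(qs_levels = qs_levels, qs_range = qs_range, qs_rate = qs_rate,
         qs_dt = qs_dt, dyn_freqs = dyn_freqs, dyn_ranges = dyn_ranges,
         dyn_cycles = dyn_cycles,
         dyn_samples_per_cycle = dyn_samples_per_cycle,
         ax_pressures = ax_pressures, ax_rate = ax_rate, ax_dt = ax_dt),
    class = "protocol_spec"
  )
}

#' Measurement-noise and signal-misalignment model
#'
#' Additive Gaussian noise on the recorded pressure, outer diameter and
#' axial force, plus an optional sub-millisecond time misalignment of the
#' diameter signal relative to pressure in the dynamic loops (emulating
#' camera/DAQ synchronisation and pressure-wave travel delays, which in the
#' experiment required corrections of at most 2 ms).
#'
#' @param pressure_mmhg,diameter_um,force_mn Noise standard deviations.
#' @param misalign_ms Diameter-vs-pressure delay applied to each dynamic
#'   loop, ms (single value or one per loop; magnitude at most 2 ms).
#' @param seed RNG seed used when the dataset generator applies the noise.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(pressure_mmhg = 0.5, diameter_um = 1,
                       force_mn = 0.05, misalign_ms = 0,
                       seed = 20230502) {
  stopifnot(pressure_mmhg >= 0, diameter_um >= 0, force_mn >= 0,
            all(abs(misalign_ms) <= 2))
  structure(
    list(pressure_mmhg = pressure_mmhg, diameter_um = diameter_um,
         force_mn = force_mn, misalign_ms = misalign_ms, seed = seed),
    class = "noise_spec"
  )
}

.new_dataset <- function(geometry, steps, manifest, seed = NA) {
  structure(list(geometry = geometry, steps = steps, manifest = manifest,
                 seed = seed),
            class = "cbqlv_dataset")
}

#' @export
print.cbqlv_dataset <- function(x, ...) {
  cat(sprintf("<cbqlv_dataset> %d steps (%s)\n", length(x$steps),
              paste(table(x$manifest$kind), names(table(x$manifest$kind)),
                    collapse = ", ")))
  print(x$manifest, n = Inf)
  invisible(x)
}

## triangular pressure ramp low -> high -> low, mmHg, uniform dt
.ramp_pressure <- function(p_lo, p_hi, rate, dt) {
  t_half <- (p_hi - p_lo) / rate
  tt <- seq(0, 2 * t_half, by = dt)
  p <- p_lo + rate * tt
  down <- tt > t_half
  p[down] <- p_hi - rate * (tt[down] - t_half)
  list(time_s = tt, p_mmhg = pmin(pmax(p, p_lo), p_hi))
}

.sim_to_step <- function(sim) {
  tibble(
    time_s = sim$time_s - sim$time_s[1],
    pressure_kpa = sim$pressure_kpa,
    r_o_mm = sim$r_o_mm,
    force_mn = sim$F_mN,
    length_mm = NA_real_ # filled by caller
  )
}

#' Reference outer diameter consistent with the in-vivo definition
#'
#' The in-vivo reference configuration is the vessel at 100 mmHg and the
#' in-vivo length, so a synthetic vessel is only self-consistent if the
#' fully relaxed model pressure at the identity deformation equals
#' 100 mmHg. Given the unloaded geometry and a parameter set, this solves
#' for the reference outer diameter that closes that loop.
#'
#' @param unloaded_outer_diameter_um,wall_thickness_um Unloaded geometry.
#' @param unloaded_length_mm,in_vivo_length_mm Axial lengths, mm.
#' @param p A [qlv_params()].
#' @return Reference outer diameter at 100 mmHg, micrometres.
#' @export
consistent_reference_diameter <- function(unloaded_outer_diameter_um,
                                          wall_thickness_um,
                                          unloaded_length_mm,
                                          in_vivo_length_mm, p) {
  R_o <- unloaded_outer_diameter_um / 2000
  R_i <- R_o - wall_thickness_um / 1000
  R_m <- (R_i + R_o) / 2
  Lam_Z <- unloaded_length_mm / in_vivo_length_mm
  A_m <- (R_o^2 - R_m^2) * Lam_Z
  A_i <- (R_o^2 - R_i^2) * Lam_Z
  qe <- q_infinity(p$nu_e, p$tau1, p$tau2_e)$q_inf
  qc <- q_infinity(p$nu_c, p$tau1, p$tau2_c)$q_inf
  h0 <- .hat_stress(1, 1, 1, p)
  sig <- (h0$e_tt * qe + h0$c_tt * qc) # sigma_tt at identity, relaxed
  f <- function(rho_o) {
    r_m <- sqrt(rho_o^2 - A_m)
    r_i <- sqrt(rho_o^2 - A_i)
    sig * (rho_o - r_i) / r_m - mmhg_to_kpa(100)
  }
  lo <- sqrt(A_i) * 1.001
  rho_o <- uniroot(f, lower = lo, upper = 5, tol = 1e-10)$root
  2000 * rho_o
}

#' Generate a synthetic biaxial testing dataset from known parameters
#'
#' Simulates the full 20-step protocol from ground-truth model parameters:
#' pressure sweeps and dynamic loops by pressure-driven time stepping at
#' fixed axial stretch, axial force sweeps by ramping the axial stretch at
#' constant pressure between the zero-force and target-force lengths
#' (bracketed on the fully relaxed response). Every step starts from the
#' fully relaxed state. Measurement noise and loop signal misalignment are
#' applied last; the result is deterministic for a fixed seed.
#'
#' @param geom A [vessel_geometry()].
#' @param truth A [qlv_params()] ground truth.
#' @param spec A [protocol_spec()].
#' @param noise A [noise_spec()], or `NULL` for noise-free signals.
#' @param seed Integer seed for the noise RNG (overrides `noise$seed`).
#' @return A `cbqlv_dataset`: geometry, named list of step tibbles
#'   (`time_s`, `pressure_kpa`, `r_o_mm`, `force_mn`, `length_mm`) and a
#'   manifest tibble.
#' @export
generate_dataset <- function(geom, truth, spec = protocol_spec(),
                             noise = NULL, seed = NULL) {
  stopifnot(inherits(geom, "vessel_geometry"), inherits(truth, "qlv_params"),
            inherits(spec, "protocol_spec"))
  steps <- list()
  man <- list()

  # --- quasi-static pressure sweeps ------------------------------------
  f_max <- NA_real_
  for (lev in spec$qs_levels) {
    nm <- sprintf("qs_sweep_%03d", round(100 * lev))
    ramp <- .ramp_pressure(spec$qs_range[1], spec$qs_range[2],
                           spec$qs_rate, spec$qs_dt)
    sim <- withCallingHandlers(
      solve_pressure_driven(ramp$time_s, mmhg_to_kpa(ramp$p_mmhg),
                            lam_z = lev, geom, truth),
      error = function(e) abort(sprintf("step %s: %s", nm, conditionMessage(e)))
    )
    st <- .sim_to_step(sim)
    st$length_mm <- lev * geom$l_iv
    steps[[nm]] <- st
    if (lev == max(spec$qs_levels)) f_max <- max(sim$F_mN)
    man[[nm]] <- tibble(step = nm, kind = "pressure_sweep",
                        label = sprintf("%d%% l_iv", round(100 * lev)),
                        axial_level = lev, p_low_mmhg = spec$qs_range[1],
                        p_high_mmhg = spec$qs_range[2],
                        frequency_hz = NA_real_)
  }

  # --- dynamic pressure loops ------------------------------------------
  for (rng_name in names(spec$dyn_ranges)) {
    rng <- spec$dyn_ranges[[rng_name]]
    for (f in spec$dyn_freqs) {
      nm <- sprintf("loop_%s_%gHz", rng_name, f)
      dt <- 1 / (f * spec$dyn_samples_per_cycle)
      tt <- seq(0, spec$dyn_cycles / f, by = dt)
      mid <- mean(rng)
      amp <- diff(rng) / 2
      pw <- mid - amp * cos(2 * pi * f * tt)
      sim <- withCallingHandlers(
        solve_pressure_driven(tt, mmhg_to_kpa(pw), lam_z = 1, geom, truth),
        error = function(e) abort(sprintf("step %s: %s", nm, conditionMessage(e)))
      )
      st <- .sim_to_step(sim)
      st$length_mm <- geom$l_iv
      steps[[nm]] <- st
      man[[nm]] <- tibble(step = nm, kind = "dynamic_loop",
                          label = sprintf("%s %g Hz", rng_name, f),
                          axial_level = 1, p_low_mmhg = rng[1],
                          p_high_mmhg = rng[2], frequency_hz = f)
    }
  }

  # --- axial force sweeps ----------------------------------------------
  for (pr in spec$ax_pressures) {
    nm <- sprintf("ax_sweep_%03dmmHg", pr)
    p_kpa <- mmhg_to_kpa(pr)
    f_of_lz <- function(lz) solve_static(p_kpa, lz, geom, truth, "relaxed")$F_mN
    lz0 <- tryCatch(
      uniroot(function(lz) f_of_lz(lz), lower = 0.5, upper = 1.4,
              tol = 1e-8)$root,
      error = function(e) abort(sprintf("step %s: zero-force length solve failed: %s",
                                        nm, conditionMessage(e)))
    )
    # walk outward from the zero-force length until the force target is
    # bracketed (the fibre exponentials make a fixed wide bracket unusable)
    lz_hi <- lz0
    f_hi <- 0
    repeat {
      lz_try <- lz_hi + 0.01
      f_try <- tryCatch(f_of_lz(lz_try), error = function(e) NA_real_)
      if (!is.finite(f_try)) {
        abort(sprintf("step %s: force target %.2f mN unreachable", nm, f_max))
      }
      lz_hi <- lz_try
      f_hi <- f_try
      if (f_hi >= f_max) break
      if (lz_hi > 1.8) {
        abort(sprintf("step %s: force target %.2f mN unreachable", nm, f_max))
      }
    }
    lz1 <- tryCatch(
      uniroot(function(lz) f_of_lz(lz) - f_max, lower = lz_hi - 0.01,
              upper = lz_hi, tol = 1e-8)$root,
      error = function(e) abort(sprintf("step %s: target-force length solve failed: %s",
                                        nm, conditionMessage(e)))
    )
    t_half <- (lz1 - lz0) / spec$ax_rate
    tt <- seq(0, 2 * t_half, by = spec$ax_dt)
    lz <- lz0 + spec$ax_rate * tt
    down <- tt > t_half
    lz[down] <- lz1 - spec$ax_rate * (tt[down] - t_half)
    lz <- pmin(pmax(lz, lz0), lz1)
    sim <- withCallingHandlers(
      solve_pressure_driven(tt, rep(p_kpa, length(tt)), lam_z = lz,
                            geom, truth),
      error = function(e) abort(sprintf("step %s: %s", nm, conditionMessage(e)))
    )
    st <- .sim_to_step(sim)
    st$length_mm <- lz * geom$l_iv
    steps[[nm]] <- st
    man[[nm]] <- tibble(step = nm, kind = "axial_sweep",
                        label = sprintf("%d mmHg", pr), axial_level = NA_real_,
                        p_low_mmhg = pr, p_high_mmhg = pr,
                        frequency_hz = NA_real_)
  }

  manifest <- dplyr::bind_rows(man)
  ds <- .new_dataset(geom, steps, manifest,
                     seed = if (is.null(seed)) noise$seed else seed)

  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    if (!is.null(seed)) noise$seed <- seed
    ds <- withr::with_seed(noise$seed, .apply_noise(ds, noise))
  }
  ds
}

.apply_noise <- function(ds, noise) {
  loops <- ds$manifest$step[ds$manifest$kind == "dynamic_loop"]
  mis <- rep_len(noise$misalign_ms, length(loops))
  names(mis) <- loops
  ds$steps <- purrr::imap(ds$steps, function(st, nm) {
    if (nm %in% loops && mis[[nm]] != 0) {
      st <- inject_misalignment(st, mis[[nm]])
    }
    n <- nrow(st)
    st$pressure_kpa <- st$pressure_kpa + mmhg_to_kpa(rnorm(n, 0, noise$pressure_mmhg))
    st$r_o_mm <- st$r_o_mm + rnorm(n, 0, noise$diameter_um / 2000)
    st$force_mn <- st$force_mn + rnorm(n, 0, noise$force_mn)
    st
  })
  ds
}

#' Shift the diameter signal of a loop relative to pressure
#'
#' Emulates (or corrects) a small acquisition delay between the pressure
#' and diameter channels: the diameter signal is re-interpolated at
#' `t - delay_ms`, leaving the time base untouched; end samples are held.
#'
#' @param step A protocol-step tibble (`time_s`, `r_o_mm`, ...).
#' @param delay_ms Delay of the diameter signal relative to pressure, ms
#'   (positive means the recorded diameter lags).
#' @return The step with the shifted diameter signal.
#' @export
inject_misalignment <- function(step, delay_ms) {
  if (abs(delay_ms) > 5) abort("|delay_ms| must be at most 5 ms")
  dur <- diff(range(step$time_s))
  if (abs(delay_ms) / 1000 > dur / 10) {
    abort("delay exceeds a tenth of the loop duration")
  }
  if (delay_ms == 0) return(step)
  step$r_o_mm <- approx(step$time_s, step$r_o_mm,
                        xout = step$time_s - delay_ms / 1000, rule = 2)$y
  step
}

#' Estimate diameter-channel alignment delays from loop trains
#'
#' Uses the empirical near rate-independence of the loss factor of soft
#' tissue: the lowest loop frequency (2.5 Hz) is taken as delay-free, and
#' for every higher frequency the delay in \[-2, 2\] ms that brings the
#' loop's loss factor closest to the 2.5 Hz value at the same pressure
#' range is found by a grid search refined with golden-section
#' minimisation.
#'
#' @param ds A `cbqlv_dataset` containing dynamic loops at 2.5 Hz and at
#'   least one higher frequency.
#' @return A tibble with `frequency_hz` and the estimated `delay_ms` (the
#'   correction to apply via [inject_misalignment()] is its negative).
#' @export
estimate_alignment_shift <- function(ds) {
  man <- ds$manifest[ds$manifest$kind == "dynamic_loop", ]
  freqs <- sort(unique(man$frequency_hz))
  if (length(freqs) < 2) abort("need dynamic loops at two or more frequencies")
  if (!any(abs(freqs - 2.5) < 1e-9)) abort("no 2.5 Hz reference loops present")
  ranges <- unique(man$label)
  range_of <- function(lbl) strsplit(lbl, " ")[[1]][1]
  rng_names <- unique(vapply(man$label, range_of, ""))

  eta_of <- function(step, delay_ms = 0) {
    st <- if (delay_ms != 0) inject_misalignment(step, delay_ms) else step
    lp <- loop_from_step(st, ds$geometry, cycles = "last")
    # endpoint noise on stiff loops must not abort the search
    loss_factor(lp, closure_tol = 0.25)
  }
  ref <- list()
  for (rn in rng_names) {
    nm <- man$step[man$frequency_hz == 2.5 &
                     startsWith(man$label, rn)][1]
    ref[[rn]] <- eta_of(ds$steps[[nm]])
  }
  out <- list()
  for (f in freqs[freqs > 2.5]) {
    obj <- function(d) {
      errs <- vapply(rng_names, function(rn) {
        nm <- man$step[man$frequency_hz == f & startsWith(man$label, rn)][1]
        abs(eta_of(ds$steps[[nm]], d) - ref[[rn]])
      }, numeric(1))
      mean(errs)
    }
    grid <- seq(-2, 2, by = 0.1)
    vals <- vapply(grid, obj, numeric(1))
    best <- grid[which.min(vals)]
    opt <- optimize(obj, lower = max(-2, best - 0.15),
                    upper = min(2, best + 0.15), tol = 1e-4)
    out[[length(out) + 1]] <- tibble(frequency_hz = f,
                                     delay_ms = opt$minimum)
  }
  dplyr::bind_rows(out)
}
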