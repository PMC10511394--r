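## Three-step parameter-estimation pipeline.
##
## Step 1 fits a purely elastic model to branch-averaged quasi-static data
## and fixes the deposition stretches lam_c and lam_th_e. Step 2 fits the
## full viscoelastic model (elastic stiffness/nonlinearity parameters plus
## the relaxation spectra) to the in-vivo-length protocol steps: the
## quasi-static sweep with loading and unloading kept separate, plus the
## dynamic-to-quasi-static stiffness ratios of the twelve loops. Step 3
## refines the six remaining elastic parameters on all quasi-static data
## with the viscous parameters frozen.

#' Default parameter bounds for the fitting pipeline
#'
#' Box bounds bracketing physiologically plausible values for murine
#' elastic arteries with generous margin.
#'
#' @return Tibble with `term`, `lower`, `upper`.
#' @export
cbqlv_bounds <- function() {
  tibble(
    term = c("mu", "lam_th_e", "k1", "k2_ax", "k2_circ", "k2_diag",
             "alpha_diag", "lam_c", "nu_e", "tau2_e", "nu_c", "tau2_c"),
    lower = c(0.1, 1.1, 1e-3, 1e-3, 1e-3, 1e-3, 5, 1.0, 0, 1, 0, 1),
    upper = c(500, 2.5, 500, 200, 200, 200, 85, 1.4, 0.5, 500, 0.5, 500)
  )
}

#' Configuration of the fitting pipeline
#'
#' @param n_starts Multistart initial guesses per fitting step (Latin
#'   hypercube over the bounds; the first start of steps 2 and 3 is warm,
#'   seeded from the preceding step's estimate).
#' @param seed RNG seed for the initial guesses.
#' @param resample_n Datapoints per branch when resampling quasi-static
#'   curves.
#' @param mode `"cbqlv"` (independent constituent kernels, 10 free
#'   parameters in step 2) or `"sqlv"` (one shared kernel, 8 free).
#' @param bounds Bounds tibble as from [cbqlv_bounds()].
#' @param decimate_qs,decimate_dyn Keep every k-th sample of the
#'   quasi-static / dynamic signals when building fitting histories (the
#'   hereditary integral is evaluated on the decimated grid).
#' @param max_iter Levenberg--Marquardt iteration cap per start.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(n_starts = 50, seed = 1, resample_n = 35,
                       mode = c("cbqlv", "sqlv"), bounds = cbqlv_bounds(),
                       decimate_qs = 1, decimate_dyn = 2, max_iter = 100) {
  mode <- match.arg(mode)
  stopifnot(n_starts >= 1, resample_n >= 4)
  structure(list(n_starts = n_starts, seed = seed, resample_n = resample_n,
                 mode = mode, bounds = bounds, decimate_qs = decimate_qs,
                 decimate_dyn = decimate_dyn, max_iter = max_iter),
            class = "fit_config")
}

## --------------------------------------------------------------------
## data preparation

.decimate <- function(st, k) {
  if (k <= 1) st else st[seq(1, nrow(st), by = k), ]
}

.ctrl_signal <- function(st, kind) {
  if (kind == "axial_sweep") st$length_mm else st$pressure_kpa
}

#' Resample and average the two branches of a quasi-static curve
#'
#' Splits a quasi-static protocol step at the extremum of its controlled
#' variable (pressure for pressure sweeps, axial length for axial force
#' sweeps) into loading and unloading branches, interpolates every signal
#' onto `n` points uniform in the controlled variable over the branches'
#' common range, and averages the branches pointwise. The per-branch
#' resampled curves are attached as attribute `"branches"`.
#'
#' @param step Protocol-step tibble (`time_s`, `pressure_kpa`, `r_o_mm`,
#'   `force_mn`, `length_mm`).
#' @param kind `"pressure_sweep"` or `"axial_sweep"`.
#' @param n Datapoints per branch.
#' @return Tibble with `n` rows of branch-averaged signals; attribute
#'   `"branches"` holds a 2`n`-row tibble with a `branch` column and
#'   per-node interpolated `time_s`.
#' @export
resample_branch_average <- function(step, kind = "pressure_sweep", n = 35) {
  ctrl <- .ctrl_signal(step, kind)
  i_max <- which.max(ctrl)
  idx_l <- seq_len(i_max)
  idx_u <- seq(i_max, length(ctrl))
  if (length(idx_l) < 4 || length(idx_u) < 4) {
    abort("each branch needs at least 4 samples")
  }
  lo <- max(min(ctrl[idx_l]), min(ctrl[idx_u]))
  hi <- min(max(ctrl[idx_l]), max(ctrl[idx_u]))
  grid <- seq(lo, hi, length.out = n)
  interp <- function(idx) {
    o <- idx[order(ctrl[idx])]
    f <- function(y) approx(ctrl[o], y[o], xout = grid, rule = 2,
                            ties = mean)$y
    tibble(ctrl = grid,
           time_s = f(step$time_s),
           pressure_kpa = f(step$pressure_kpa),
           r_o_mm = f(step$r_o_mm),
           force_mn = f(step$force_mn),
           length_mm = f(step$length_mm))
  }
  bl <- interp(idx_l)
  bu <- interp(idx_u)
  avg <- tibble(
    ctrl = grid,
    pressure_kpa = (bl$pressure_kpa + bu$pressure_kpa) / 2,
    r_o_mm = (bl$r_o_mm + bu$r_o_mm) / 2,
    force_mn = (bl$force_mn + bu$force_mn) / 2,
    length_mm = (bl$length_mm + bu$length_mm) / 2
  )
  attr(avg, "branches") <- dplyr::bind_rows(
    dplyr::mutate(bl, branch = "loading"),
    dplyr::mutate(bu, branch = "unloading")
  )
  avg
}

#' Weights of the quasi-static protocol steps in the cost function
#'
#' Pressure sweeps each get weight 1; the axial force sweeps share a
#' cumulative weight of 1, split proportionally to the arc length each
#' sweep traces in the (circumferential stretch, axial stretch) plane.
#'
#' @param ds A `cbqlv_dataset`.
#' @param n Resampling density used for the arc-length polyline.
#' @return Tibble with `step` and `weight`.
#' @export
axial_sweep_weights <- function(ds, n = 35) {
  man <- ds$manifest
  out <- list()
  arcs <- c()
  for (nm in man$step[man$kind == "axial_sweep"]) {
    avg <- resample_branch_average(ds$steps[[nm]], "axial_sweep", n)
    defm <- current_deformation(ds$geometry, avg$r_o_mm, avg$length_mm)
    arc <- sum(sqrt(diff(defm$lam_th)^2 + diff(defm$lam_z)^2))
    if (arc <= 0) warn(sprintf("degenerate axial sweep %s: zero path length", nm))
    arcs[nm] <- arc
  }
  tot <- sum(arcs)
  w_ax <- if (tot > 0) arcs / tot else rep(0, length(arcs))
  dplyr::bind_rows(
    tibble(step = man$step[man$kind == "pressure_sweep"], weight = 1),
    tibble(step = names(w_ax), weight = unname(w_ax))
  )
}

## precompute everything the residual functions need
.prep_fit <- function(ds, cfg) {
  geom <- ds$geometry
  man <- ds$manifest
  qs_names <- man$step[man$kind %in% c("pressure_sweep", "axial_sweep")]
  dyn_names <- man$step[man$kind == "dynamic_loop"]
  if (length(qs_names) < 8 || length(dyn_names) < 12) {
    warn(sprintf("protocol subset: %d quasi-static steps, %d dynamic loops",
                 length(qs_names), length(dyn_names)))
  }
  w_tbl <- axial_sweep_weights(ds, cfg$resample_n)
  weights <- setNames(w_tbl$weight, w_tbl$step)

  pbar <- mean(unlist(lapply(qs_names, function(nm) ds$steps[[nm]]$pressure_kpa)))
  fbar <- mean(unlist(lapply(qs_names, function(nm) ds$steps[[nm]]$force_mn)))

  qs <- list()
  for (nm in qs_names) {
    kind <- man$kind[man$step == nm]
    st <- .decimate(ds$steps[[nm]], cfg$decimate_qs)
    defm <- current_deformation(geom, st$r_o_mm, st$length_mm)
    avg <- resample_branch_average(st, kind, cfg$resample_n)
    br <- attr(avg, "branches")
    avg_defm <- current_deformation(geom, avg$r_o_mm, avg$length_mm)
    qs[[nm]] <- list(
      name = nm, kind = kind, w = weights[[nm]],
      time_s = st$time_s, p_exp = st$pressure_kpa, f_exp = st$force_mn,
      lam_r = defm$lam_r, lam_th = defm$lam_th, lam_z = defm$lam_z,
      r_m = defm$r_m_mm, h = defm$h_mm,
      node_time = br$time_s, node_p = br$pressure_kpa, node_f = br$force_mn,
      avg = avg_defm, avg_p = avg$pressure_kpa, avg_f = avg$force_mn,
      at_liv = kind == "pressure_sweep" &&
        isTRUE(all.equal(man$axial_level[man$step == nm], 1))
    )
  }
  liv_name <- qs_names[vapply(qs, `[[`, TRUE, "at_liv")][1]
  if (is.na(liv_name)) abort("no quasi-static pressure sweep at the in-vivo length")
  liv <- qs[[liv_name]]
  liv_branch <- .split_branches(liv$p_exp)
  liv_sigma_exp <- liv$p_exp * liv$r_m / liv$h

  dyn <- list()
  for (nm in dyn_names) {
    st <- .decimate(ds$steps[[nm]], cfg$decimate_dyn)
    defm <- current_deformation(geom, st$r_o_mm, st$length_mm)
    sigma_exp <- st$pressure_kpa * defm$r_m_mm / defm$h_mm
    p_rng <- range(st$pressure_kpa)
    win <- lapply(liv_branch, function(idx) {
      sel <- idx[liv$p_exp[idx] >= p_rng[1] & liv$p_exp[idx] <= p_rng[2]]
      if (length(sel) < 3) {
        abort(sprintf("loop %s: in-vivo sweep does not cover its pressure range", nm))
      }
      sel
    })
    k_qs_exp <- mean(vapply(win, function(sel) {
      .ols_slope(liv$lam_th[sel], liv_sigma_exp[sel])
    }, numeric(1)))
    k_d_exp <- .ols_slope(defm$lam_th, sigma_exp)
    dyn[[nm]] <- list(
      name = nm, time_s = st$time_s,
      lam_r = defm$lam_r, lam_th = defm$lam_th, lam_z = defm$lam_z,
      window = win, ratio_exp = k_d_exp / k_qs_exp
    )
  }
  list(geom = geom, qs = qs, dyn = dyn, liv_name = liv_name,
       pbar = pbar, fbar = fbar)
}

## --------------------------------------------------------------------
## model evaluation on prepared histories

.elastic_pf <- function(s, p) {
  hh <- .hat_stress(s$avg$lam_r, s$avg$lam_th, s$avg$lam_z, p)
  sig_tt <- (hh$e_tt + hh$c_tt) * s$avg$lam_th^2
  sig_zz <- (hh$e_zz + hh$c_zz) * s$avg$lam_z^2
  list(p = sig_tt * s$avg$h_mm / s$avg$r_m_mm,
       f = pi * (2 * sig_zz - sig_tt) * s$avg$r_m_mm * s$avg$h_mm)
}

.visco_sigma <- function(s, p) {
  sv <- .viscoelastic_stress(s$time_s, s$lam_r, s$lam_th, s$lam_z, p)
  list(sig_tt = (sv$S_tt_e + sv$S_tt_c) * s$lam_th^2,
       sig_zz = (sv$S_zz_e + sv$S_zz_c) * s$lam_z^2)
}

.visco_pf_nodes <- function(s, p) {
  sig <- .visco_sigma(s, p)
  p_mod <- sig$sig_tt * s$h / s$r_m
  f_mod <- pi * (2 * sig$sig_zz - sig$sig_tt) * s$r_m * s$h
  list(p = approx(s$time_s, p_mod, xout = s$node_time, rule = 2)$y,
       f = approx(s$time_s, f_mod, xout = s$node_time, rule = 2)$y,
       sig_tt = sig$sig_tt)
}

## --------------------------------------------------------------------
## cost functions

#' Quasi-static cost of a parameter set
#'
#' Weighted sum over the quasi-static protocol steps of the squared
#' pressure and force residuals, each normalised by the protocol-wide mean
#' experimental pressure and force. Model pressure and force are computed
#' deformation-driven through the viscoelastic model (or the purely
#' elastic model on branch-averaged curves when `average_branches = TRUE`,
#' as in fitting step 1).
#'
#' @param p A [qlv_params()].
#' @param ds A `cbqlv_dataset`.
#' @param cfg A [fit_config()] (controls resampling and decimation).
#' @param average_branches Use branch-averaged curves and the purely
#'   elastic stress (step-1 behaviour) instead of branch-separate
#'   viscoelastic evaluation.
#' @return The scalar cost.
#' @export
cost_quasistatic <- function(p, ds, cfg = fit_config(),
                             average_branches = FALSE) {
  prep <- .prep_fit(ds, cfg)
  res <- if (average_branches) .res_elastic_avg(p, prep) else .res_visco_qs(p, prep)
  sum(res^2)
}

#' Dynamic cost of a parameter set
#'
#' The quasi-static cost restricted to the in-vivo-length pressure sweep
#' (loading and unloading kept separate) plus the sum of squared
#' differences between modelled and experimental dynamic-to-quasi-static
#' stiffness ratios over the dynamic loops.
#'
#' @inheritParams cost_quasistatic
#' @return The scalar cost.
#' @export
cost_dynamic <- function(p, ds, cfg = fit_config()) {
  prep <- .prep_fit(ds, cfg)
  sum(.res_dynamic(p, prep)^2)
}

.res_elastic_avg <- function(p, prep) {
  out <- lapply(prep$qs, function(s) {
    pf <- .elastic_pf(s, p)
    sqrt(s$w) * c((pf$p - s$avg_p) / prep$pbar, (pf$f - s$avg_f) / prep$fbar)
  })
  unlist(out, use.names = FALSE)
}

.res_visco_qs <- function(p, prep, steps = NULL) {
  use <- if (is.null(steps)) prep$qs else prep$qs[steps]
  out <- lapply(use, function(s) {
    pf <- .visco_pf_nodes(s, p)
    sqrt(s$w) * c((pf$p - s$node_p) / prep$pbar,
                  (pf$f - s$node_f) / prep$fbar)
  })
  unlist(out, use.names = FALSE)
}

.res_dynamic <- function(p, prep) {
  liv <- prep$qs[[prep$liv_name]]
  pf <- .visco_pf_nodes(liv, p)
  res_qs <- c((pf$p - liv$node_p) / prep$pbar,
              (pf$f - liv$node_f) / prep$fbar)
  k_qs_mod <- vapply(names(prep$dyn), function(nm) {
    mean(vapply(prep$dyn[[nm]]$window, function(sel) {
      .ols_slope(liv$lam_th[sel], pf$sig_tt[sel])
    }, numeric(1)))
  }, numeric(1))
  res_ratio <- vapply(names(prep$dyn), function(nm) {
    d <- prep$dyn[[nm]]
    sig <- .visco_sigma(d, p)
    k_d <- .ols_slope(d$lam_th, sig$sig_tt)
    k_d / k_qs_mod[[nm]] - d$ratio_exp
  }, numeric(1))
  c(res_qs, unname(res_ratio))
}

## --------------------------------------------------------------------
## multistart driver

.params_with <- function(p, theta) {
  for (nm in names(theta)) {
    if (nm == "nu") {
      p$nu_e <- p$nu_c <- theta[[nm]]
    } else if (nm == "tau2") {
      p$tau2_e <- p$tau2_c <- theta[[nm]]
    } else {
      p[[nm]] <- theta[[nm]]
    }
  }
  p
}

## scale-like parameters are optimised (and Latin-hypercube sampled) on a
## log10 scale; angles, stretches and spectrum magnitudes stay linear
.log_terms <- c("mu", "k1", "k2_ax", "k2_circ", "k2_diag",
                "tau2_e", "tau2_c", "tau2")

.multistart <- function(res_fun, terms, bounds, n_starts, warm = NULL,
                        max_iter = 100) {
  b <- bounds[match(terms, bounds$term), ]
  # shared nu/tau2 terms in sQLV mode reuse the constituent bounds
  b$term <- terms
  miss <- is.na(b$lower)
  if (any(miss)) {
    base <- sub("^(nu|tau2)$", "\\1_c", terms[miss])
    bb <- bounds[match(base, bounds$term), ]
    b$lower[miss] <- bb$lower
    b$upper[miss] <- bb$upper
  }
  is_log <- terms %in% .log_terms
  tr <- function(x) ifelse(is_log, log10(x), x)
  inv <- function(x) ifelse(is_log, 10^x, x)
  lo_t <- tr(b$lower)
  hi_t <- tr(b$upper)
  res_t <- function(theta_t) res_fun(setNames(inv(theta_t), terms))

  n_par <- length(terms)
  lhs_mat <- lhs::randomLHS(n_starts, n_par)
  starts <- t(t(lhs_mat) * (hi_t - lo_t) + lo_t)
  colnames(starts) <- terms
  if (!is.null(warm)) {
    w <- tr(pmin(pmax(warm[terms], b$lower), b$upper))
    starts[1, ] <- w
  }

  runs <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = starts[i, ], lower = lo_t, upper = hi_t, fn = res_t,
        control = minpack.lm::nls.lm.control(maxiter = max_iter)
      ),
      error = function(e) NULL
    )
    runs[[i]] <- if (is.null(fit)) {
      list(cost = Inf, par = setNames(inv(starts[i, ]), terms),
           info = -1L, niter = 0L)
    } else {
      list(cost = sum(fit$fvec^2), par = setNames(inv(coef(fit)), terms),
           info = fit$info, niter = fit$niter)
    }
  }
  costs <- vapply(runs, `[[`, numeric(1), "cost")
  if (all(!is.finite(costs))) {
    abort("all multistart attempts failed to converge")
  }
  best <- which.min(costs)
  list(
    par = runs[[best]]$par, cost = costs[best], best_start = best,
    starts = tibble(
      start = seq_len(n_starts), cost = costs,
      info = vapply(runs, `[[`, integer(1), "info"),
      iterations = vapply(runs, `[[`, integer(1), "niter")
    )
  )
}

## guarded residual wrapper: constant-length, finite output
.safe_res <- function(build, template_len) {
  function(theta) {
    r <- tryCatch(build(theta), error = function(e) NULL)
    if (is.null(r) || length(r) != template_len || any(!is.finite(r))) {
      rep(1e3, template_len)
    } else {
      r
    }
  }
}

#' Fit the cbQLV (or sQLV) model to a biaxial dataset
#'
#' Runs the three-step estimation pipeline. Step 1: purely elastic least
#' squares of the eight unconstrained elastic parameters on branch-averaged
#' quasi-static data; the deposition stretches `lam_c` and `lam_th_e` are
#' then fixed. Step 2: the full viscoelastic model is fitted to the
#' in-vivo-length steps (quasi-static sweep with branches kept separate
#' plus the stiffness ratios of the dynamic loops), estimating the six
#' remaining elastic parameters and the relaxation spectra (shared between
#' constituents in sQLV mode). Step 3: the six elastic parameters are
#' refined on all quasi-static data with the viscous parameters frozen.
#' Every step is repeated from `n_starts` seeded initial guesses and the
#' best final cost wins. `lam_z_e` is fixed to `l_iv / L0` throughout (the
#' elastin matrix is assumed axially unstretched in the unloaded state);
#' `beta`, `k2_comp` and `tau1` are fixed at their defaults.
#'
#' @param ds A `cbqlv_dataset` with 8 quasi-static steps and 12 dynamic
#'   loops (subsets are allowed with a warning).
#' @param cfg A [fit_config()].
#' @return An object of class `cbqlv_fit` with elements `params`
#'   ([qlv_params()]), `stages` (per-step estimates, costs and multistart
#'   tables), `pi_qs`, `pi_d`, `rmse_qs`, `rmse_d` and `config`. `tidy()`
#'   and `glance()` methods are provided.
#' @export
fit_cbqlv <- function(ds, cfg = fit_config()) {
  stopifnot(inherits(ds, "cbqlv_dataset"), inherits(cfg, "fit_config"))
  prep <- .prep_fit(ds, cfg)
  lam_z_e_fix <- ds$geometry$l_iv / ds$geometry$L0
  base <- qlv_params(mu = 30, lam_th_e = 1.8, lam_z_e = lam_z_e_fix,
                     k1 = 50, k2_ax = 5, k2_circ = 5, k2_diag = 5,
                     alpha_diag = 45, lam_c = 1.1,
                     nu_e = 0, nu_c = 0, mode = "cbqlv")

  withr::local_seed(cfg$seed)

  # ---- step 1: purely elastic, branch-averaged -----------------------
  terms1 <- c("mu", "lam_th_e", "k1", "k2_ax", "k2_circ", "k2_diag",
              "alpha_diag", "lam_c")
  len1 <- length(.res_elastic_avg(base, prep))
  res1 <- .safe_res(function(th) {
    .res_elastic_avg(.params_with(base, th), prep)
  }, len1)
  s1 <- .multistart(res1, terms1, cfg$bounds, cfg$n_starts,
                    max_iter = cfg$max_iter)
  p1 <- .params_with(base, s1$par)

  # ---- step 2: viscoelastic at the in-vivo length --------------------
  terms2 <- c("mu", "k1", "k2_ax", "k2_circ", "k2_diag", "alpha_diag")
  terms2 <- if (cfg$mode == "sqlv") {
    c(terms2, "nu", "tau2")
  } else {
    c(terms2, "nu_e", "tau2_e", "nu_c", "tau2_c")
  }
  p2base <- p1
  p2base$mode <- cfg$mode
  len2 <- length(.res_dynamic(p2base, prep))
  res2 <- .safe_res(function(th) {
    .res_dynamic(.params_with(p2base, th), prep)
  }, len2)
  warm2 <- setNames(
    c(s1$par[c("mu", "k1", "k2_ax", "k2_circ", "k2_diag", "alpha_diag")],
      rep(c(0.05, 50), length.out = length(terms2) - 6)),
    terms2
  )
  s2 <- .multistart(res2, terms2, cfg$bounds, cfg$n_starts, warm = warm2,
                    max_iter = cfg$max_iter)
  p2 <- .params_with(p2base, s2$par)

  # ---- step 3: elastic refinement, all quasi-static data -------------
  terms3 <- c("mu", "k1", "k2_ax", "k2_circ", "k2_diag", "alpha_diag")
  len3 <- length(.res_visco_qs(p2, prep))
  res3 <- .safe_res(function(th) {
    .res_visco_qs(.params_with(p2, th), prep)
  }, len3)
  warm3 <- s2$par[terms3]
  s3 <- .multistart(res3, terms3, cfg$bounds, cfg$n_starts, warm = warm3,
                    max_iter = cfg$max_iter)
  p_final <- .params_with(p2, s3$par)

  n_qs_terms <- 2 * cfg$resample_n * length(prep$qs)
  n_d_terms <- 2 * cfg$resample_n + length(prep$dyn)
  structure(
    list(
      params = p_final, geometry = ds$geometry, mode = cfg$mode,
      stages = list(step1 = s1, step2 = s2, step3 = s3),
      pi_qs = s3$cost, pi_d = s2$cost,
      rmse_qs = s3$cost / n_qs_terms, rmse_d = s2$cost / n_d_terms,
      config = cfg
    ),
    class = "cbqlv_fit"
  )
}

#' @export
print.cbqlv_fit <- function(x, ...) {
  cat(sprintf("<cbqlv_fit> mode %s\n", x$mode))
  cat(sprintf("  Pi_QS %.4g (RMSE_QS %.4g), Pi_D %.4g (RMSE_D %.4g)\n",
              x$pi_qs, x$rmse_qs, x$pi_d, x$rmse_d))
  print(x$params)
  invisible(x)
}

#' @method tidy cbqlv_fit
#' @export
tidy.cbqlv_fit <- function(x, ...) {
  p <- x$params
  free2 <- names(x$stages$step2$par)
  tb <- tidy.qlv_params(p)
  tb$fixed <- !(tb$term %in% c(names(x$stages$step1$par), free2,
                               if ("nu" %in% free2) c("nu_e", "nu_c"),
                               if ("tau2" %in% free2) c("tau2_e", "tau2_c")))
  tb
}

#' @method glance cbqlv_fit
#' @export
glance.cbqlv_fit <- function(x, ...) {
  tibble(
    mode = x$mode, pi_qs = x$pi_qs, pi_d = x$pi_d,
    rmse_qs = x$rmse_qs, rmse_d = x$rmse_d,
    n_starts = x$config$n_starts, seed = x$config$seed,
    best_start_step2 = x$stages$step2$best_start
  )
}
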