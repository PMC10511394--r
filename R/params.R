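#' Constitutive and relaxation parameters of the cbQLV wall model
#'
#' Bundles the elastic four-fibre-family strain-energy parameters with the
#' constituent relaxation spectra. The elastic part comprises an isotropic
#' matrix term (elastin, stiffness `mu`, exponent `beta`) and four collagen
#' fibre families (axial, circumferential and two symmetric diagonal
#' families at `+/- alpha_diag` from the axial direction) sharing the
#' stiffness `k1` but with family-specific nonlinearity `k2_*`. Deposition
#' stretches (`lam_c` for collagen along the fibre, `lam_th_e`/`lam_z_e`
#' for elastin) prestrain the constituents in the in-vivo reference
#' configuration. Each constituent carries a continuous-spectrum reduced
#' relaxation function with magnitude `nu_*` and time constants
#' `tau1 < tau2_*`.
#'
#' @param mu Isotropic (elastin) stiffness-like parameter, kPa.
#' @param lam_th_e,lam_z_e Circumferential and axial deposition stretches of
#'   elastin (dimensionless).
#' @param k1 Fibre stiffness-like parameter shared by all families, kPa.
#' @param k2_ax,k2_circ,k2_diag Fibre nonlinearity parameters
#'   (dimensionless) for the axial, circumferential and diagonal families.
#' @param alpha_diag Diagonal fibre angle, degrees from the axial direction
#'   (strictly between 0 and 90).
#' @param lam_c Collagen deposition stretch along the fibre direction.
#' @param nu_e,tau2_e Relaxation-spectrum magnitude and long time constant
#'   (s) of the elastin matrix.
#' @param nu_c,tau2_c Same for the collagen fibre families.
#' @param beta Matrix exponent; 0.15 by default (nearly neo-Hookean).
#' @param k2_comp Nonlinearity used for any fibre family whose fourth
#'   invariant falls below 1 (compression); near-zero by default so
#'   compressed fibres respond quadratically.
#' @param tau1 Short time constant of both spectra, s; 1e-3 by default.
#' @param mode `"cbqlv"` (independent constituent kernels) or `"sqlv"`
#'   (one shared kernel; the elastin kernel is forced equal to collagen's).
#' @param literal_diag_invariant If `TRUE`, use the literal diagonal-family
#'   fourth invariant \eqn{\lambda_c^2(\lambda_\theta^2\sin^4\alpha +
#'   \lambda_z^2\cos^4\alpha)} instead of the standard
#'   \eqn{\sin^2\alpha/\cos^2\alpha} form (sensitivity checks only).
#' @return An object of class `qlv_params` (a validated list).
#' @examples
#' p <- qlv_params(mu = 46.8, lam_th_e = 1.56, lam_z_e = 1.62, k1 = 7.1,
#'                 k2_ax = 3.9, k2_circ = 14.6, k2_diag = 25.1,
#'                 alpha_diag = 44.3, lam_c = 1.17,
#'                 nu_e = 0.033, tau2_e = 100, nu_c = 0.061, tau2_c = 46.2)
#' p
#' @export
qlv_params <- function(mu, lam_th_e, lam_z_e, k1,
                       k2_ax, k2_circ, k2_diag, alpha_diag, lam_c,
                       nu_e = 0, tau2_e = 100, nu_c = 0, tau2_c = 100,
                       beta = 0.15, k2_comp = 1e-6, tau1 = 1e-3,
                       mode = c("cbqlv", "sqlv"),
                       literal_diag_invariant = FALSE) {
  mode <- match.arg(mode)
  p <- list(
    mu = mu, lam_th_e = lam_th_e, lam_z_e = lam_z_e, k1 = k1,
    k2_ax = k2_ax, k2_circ = k2_circ, k2_diag = k2_diag,
    alpha_diag = alpha_diag, lam_c = lam_c,
    nu_e = nu_e, tau2_e = tau2_e, nu_c = nu_c, tau2_c = tau2_c,
    beta = beta, k2_comp = k2_comp, tau1 = tau1,
    mode = mode, literal_diag_invariant = isTRUE(literal_diag_invariant)
  )
  if (mode == "sqlv") {
    p$nu_e <- p$nu_c
    p$tau2_e <- p$tau2_c
  }
  validate_qlv_params(p)
  structure(p, class = "qlv_params")
}

validate_qlv_params <- function(p) {
  if (p$mu <= 0) abort("`mu` must be positive")
  if (p$k1 < 0) abort("`k1` must be non-negative")
  k2s <- c(p$k2_ax, p$k2_circ, p$k2_diag)
  if (any(k2s < 0)) abort("fibre `k2` parameters must be non-negative")
  if (p$k2_comp <= 0) abort("`k2_comp` must be positive")
  if (p$alpha_diag <= 0 || p$alpha_diag >= 90) {
    abort("`alpha_diag` must lie strictly between 0 and 90 degrees")
  }
  if (any(c(p$lam_c, p$lam_th_e, p$lam_z_e) <= 0)) {
    abort("deposition stretches must be positive")
  }
  for (j in c("e", "c")) {
    nu <- p[[paste0("nu_", j)]]
    tau2 <- p[[paste0("tau2_", j)]]
    if (nu < 0) abort(sprintf("`nu_%s` must be non-negative", j))
    if (nu > 0 && !(p$tau1 > 0 && p$tau1 < tau2)) {
      abort(sprintf("need 0 < tau1 < tau2_%s when nu_%s > 0", j, j))
    }
  }
  if (p$mode == "sqlv" &&
      !(identical(p$nu_e, p$nu_c) && identical(p$tau2_e, p$tau2_c))) {
    abort("sQLV mode requires identical elastin and collagen kernels")
  }
  invisible(p)
}

#' @export
print.qlv_params <- function(x, ...) {
  cat(sprintf("<qlv_params> mode: %s\n", x$mode))
  cat(sprintf("  elastin: mu %.3g kPa, beta %.3g, lam_th_e %.3f, lam_z_e %.3f\n",
              x$mu, x$beta, x$lam_th_e, x$lam_z_e))
  cat(sprintf("  collagen: k1 %.3g kPa, k2 (ax/circ/diag) %.3g/%.3g/%.3g, alpha %.1f deg, lam_c %.3f\n",
              x$k1, x$k2_ax, x$k2_circ, x$k2_diag, x$alpha_diag, x$lam_c))
  cat(sprintf("  relaxation: nu_e %.3g (tau2 %.3g s), nu_c %.3g (tau2 %.3g s), tau1 %.3g s\n",
              x$nu_e, x$tau2_e, x$nu_c, x$tau2_c, x$tau1))
  invisible(x)
}

#' Constrain a parameter set to standard (single-kernel) QLV
#'
#' Replaces the elastin relaxation kernel by the collagen one and flags the
#' parameter set as sQLV, the special case in which the whole wall shares a
#' single reduced relaxation function. Idempotent.
#'
#' @param p A [qlv_params()] object.
#' @return A `qlv_params` object in `"sqlv"` mode with `nu_e == nu_c` and
#'   `tau2_e == tau2_c`.
#' @export
sqlv_constrain <- function(p) {
  stopifnot(inherits(p, "qlv_params"))
  p$nu_e <- p$nu_c
  p$tau2_e <- p$tau2_c
  p$mode <- "sqlv"
  validate_qlv_params(p)
  p
}

#' @method tidy qlv_params
#' @export
tidy.qlv_params <- function(x, ...) {
  nm <- c("mu", "lam_th_e", "lam_z_e", "k1", "k2_ax", "k2_circ", "k2_diag",
          "alpha_diag", "lam_c", "nu_e", "tau2_e", "nu_c", "tau2_c",
          "beta", "k2_comp", "tau1")
  tibble(term = nm, value = vapply(nm, function(f) x[[f]], numeric(1)))
}

## JSON field names used in parameter files
.param_json_map <- c(
  mu = "mu_kPa", lam_th_e = "lam_th_e", lam_z_e = "lam_z_e",
  nu_e = "nu_e", tau2_e = "tau2_e_s",
  k1 = "k1_kPa", k2_ax = "k2_ax", k2_circ = "k2_circ", k2_diag = "k2_diag",
  alpha_diag = "alpha_diag_deg", lam_c = "lam_c",
  nu_c = "nu_c", tau2_c = "tau2_c_s",
  beta = "beta", k2_comp = "k2_comp", tau1 = "tau1_s"
)

#' Read and write model parameters as JSON
#'
#' Field names mirror the parameter-table column names (`mu_kPa`,
#' `lam_th_e`, `lam_z_e`, `nu_e`, `tau2_e_s`, `k1_kPa`, `k2_ax`, `k2_circ`,
#' `k2_diag`, `alpha_diag_deg`, `lam_c`, `nu_c`, `tau2_c_s`) plus the fixed
#' fields `beta`, `k2_comp` and `tau1_s`, and optionally `mode`.
#'
#' @param path File path.
#' @param p A [qlv_params()] object.
#' @return `read_params_json()` returns a `qlv_params`;
#'   `write_params_json()` returns `path` invisibly.
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  args <- list()
  for (field in names(.param_json_map)) {
    key <- .param_json_map[[field]]
    if (!is.null(raw[[key]])) args[[field]] <- raw[[key]]
  }
  if (!is.null(raw$mode)) args$mode <- raw$mode
  do.call(qlv_params, args)
}

#' @rdname read_params_json
#' @export
write_params_json <- function(p, path) {
  stopifnot(inherits(p, "qlv_params"))
  out <- lapply(names(.param_json_map), function(f) p[[f]])
  names(out) <- unname(.param_json_map)
  out$mode <- p$mode
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
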