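#' Vessel geometry for the thin-walled membrane model
#'
#' Collects the measurements that define the unloaded configuration
#' \eqn{\kappa_u} and the in-vivo reference configuration \eqn{\kappa_r}
#' (vessel at 100 mmHg and the in-vivo axial length). All radii are mid-wall
#' quantities in the thin-wall sense; derived fields (mid-wall radii, the
#' unloaded prestretches) are computed on construction.
#'
#' The axial prestretch is \eqn{\Lambda_Z = L_0 / l_{iv}} and the
#' circumferential prestretch follows from wall incompressibility,
#' \eqn{\Lambda_\Theta = R_m / \rho_m} with
#' \eqn{\rho_m^2 = \rho_o^2 - (R_o^2 - R_m^2)\Lambda_Z}.
#'
#' @param unloaded_outer_diameter_um Outer diameter in the unloaded state
#'   \eqn{\kappa_u} (micrometres).
#' @param wall_thickness_um Wall thickness in \eqn{\kappa_u} (micrometres).
#'   Give either this or `unloaded_inner_diameter_um`.
#' @param unloaded_inner_diameter_um Inner diameter in \eqn{\kappa_u}
#'   (micrometres); alternative to `wall_thickness_um`.
#' @param unloaded_length_mm Unloaded axial length \eqn{L_0} (mm).
#' @param in_vivo_length_mm In-vivo axial length \eqn{l_{iv}} (mm), the
#'   length at which axial force decouples from pressure.
#' @param reference_outer_diameter_um Outer diameter at 100 mmHg and
#'   \eqn{l_{iv}} (micrometres), i.e. in \eqn{\kappa_r}.
#' @return An object of class `vessel_geometry`: a list with radii in mm
#'   (`R_i`, `R_o`, `R_m`, `rho_o`, `rho_m`), lengths (`L0`, `l_iv`) and the
#'   unloaded prestretches (`Lam_R`, `Lam_Th`, `Lam_Z`).
#' @examples
#' geom <- vessel_geometry(470, 75, unloaded_length_mm = 3.7,
#'                         in_vivo_length_mm = 6, reference_outer_diameter_um = 660)
#' unloaded_prestretch(geom)
#' @export
vessel_geometry <- function(unloaded_outer_diameter_um,
                            wall_thickness_um = NULL,
                            unloaded_inner_diameter_um = NULL,
                            unloaded_length_mm,
                            in_vivo_length_mm,
                            reference_outer_diameter_um) {
  R_o <- unloaded_outer_diameter_um / 2000
  if (is.null(unloaded_inner_diameter_um)) {
    if (is.null(wall_thickness_um)) {
      abort("give either `wall_thickness_um` or `unloaded_inner_diameter_um`")
    }
    R_i <- R_o - wall_thickness_um / 1000
  } else {
    R_i <- unloaded_inner_diameter_um / 2000
  }
  if (!(R_i > 0 && R_i < R_o)) {
    abort("unloaded radii must satisfy 0 < R_i < R_o")
  }
  if (unloaded_length_mm <= 0 || in_vivo_length_mm <= 0) {
    abort("`unloaded_length_mm` and `in_vivo_length_mm` must be positive")
  }
  rho_o <- reference_outer_diameter_um / 2000
  if (rho_o <= 0) abort("`reference_outer_diameter_um` must be positive")
  R_m <- (R_i + R_o) / 2
  Lam_Z <- unloaded_length_mm / in_vivo_length_mm
  A_m <- (R_o^2 - R_m^2) * Lam_Z # mid-wall annulus constant
  rad <- rho_o^2 - A_m
  if (rad <= 0) {
    abort(paste0(
      "geometrically inconsistent `reference_outer_diameter_um`: ",
      "rho_o^2 - (R_o^2 - R_m^2) Lam_Z is non-positive"
    ))
  }
  rho_m <- sqrt(rad)
  Lam_Th <- R_m / rho_m
  structure(
    list(
      R_i = R_i, R_o = R_o, R_m = R_m,
      L0 = unloaded_length_mm, l_iv = in_vivo_length_mm,
      rho_o = rho_o, rho_m = rho_m,
      Lam_R = 1 / (Lam_Z * Lam_Th), Lam_Th = Lam_Th, Lam_Z = Lam_Z,
      A_m = A_m, A_i = (R_o^2 - R_i^2) * Lam_Z
    ),
    class = "vessel_geometry"
  )
}

#' @export
print.vessel_geometry <- function(x, ...) {
  cat("<vessel_geometry>\n")
  cat(sprintf("  unloaded: R_i %.4f, R_o %.4f, L0 %.3f mm\n", x$R_i, x$R_o, x$L0))
  cat(sprintf("  reference (100 mmHg, l_iv %.3f mm): rho_o %.4f, rho_m %.4f mm\n",
              x$l_iv, x$rho_o, x$rho_m))
  cat(sprintf("  prestretch kappa_r -> kappa_u: Lam_R %.4f, Lam_Th %.4f, Lam_Z %.4f\n",
              x$Lam_R, x$Lam_Th, x$Lam_Z))
  invisible(x)
}

#' Prestretch of the unloaded configuration relative to the in-vivo reference
#'
#' Principal stretches of the deformation \eqn{\kappa_r \to \kappa_u}:
#' \eqn{\Lambda_Z = L_0/l_{iv}}, \eqn{\Lambda_\Theta} from wall-volume
#' conservation and \eqn{\Lambda_R = 1/(\Lambda_Z \Lambda_\Theta)}.
#'
#' @param geom A [vessel_geometry()].
#' @return A one-row tibble with columns `lam_r`, `lam_th`, `lam_z`
#'   (product exactly 1).
#' @export
unloaded_prestretch <- function(geom) {
  stopifnot(inherits(geom, "vessel_geometry"))
  tibble(lam_r = geom$Lam_R, lam_th = geom$Lam_Th, lam_z = geom$Lam_Z)
}

#' Principal stretches of a current state relative to the in-vivo reference
#'
#' Maps measured outer radius and axial length to mid-wall principal
#' stretches using incompressibility: \eqn{\lambda_z = l/l_{iv}},
#' \eqn{\lambda_\theta = r_m/\rho_m} with
#' \eqn{r_m^2 = r_o^2 - (R_o^2 - R_m^2)\Lambda_Z/\lambda_z}, and
#' \eqn{\lambda_r = 1/(\lambda_z\lambda_\theta)}. Also returns the current
#' mid-wall radius, inner radius and wall thickness from wall-volume
#' conservation.
#'
#' @param geom A [vessel_geometry()].
#' @param r_o_mm Current outer radius (mm), vectorised.
#' @param l_mm Current axial length (mm), vectorised (recycled).
#' @return A tibble with columns `lam_r`, `lam_th`, `lam_z`, `r_m_mm`,
#'   `r_i_mm`, `h_mm`.
#' @examples
#' geom <- vessel_geometry(470, 75, unloaded_length_mm = 3.7,
#'                         in_vivo_length_mm = 6, reference_outer_diameter_um = 660)
#' current_deformation(geom, geom$rho_o, geom$l_iv) # identity
#' @export
current_deformation <- function(geom, r_o_mm, l_mm) {
  stopifnot(inherits(geom, "vessel_geometry"))
  n <- max(length(r_o_mm), length(l_mm))
  r_o <- rep_len(r_o_mm, n)
  lam_z <- rep_len(l_mm, n) / geom$l_iv
  rm2 <- r_o^2 - geom$A_m / lam_z
  if (any(rm2 <= 0)) {
    abort("outer radius too small: current mid-wall radius radicand non-positive")
  }
  ri2 <- r_o^2 - geom$A_i / lam_z
  if (any(ri2 <= 0)) {
    abort("outer radius too small: current inner radius radicand non-positive")
  }
  r_m <- sqrt(rm2)
  r_i <- sqrt(ri2)
  lam_th <- r_m / geom$rho_m
  tibble(
    lam_r = 1 / (lam_z * lam_th), lam_th = lam_th, lam_z = lam_z,
    r_m_mm = r_m, r_i_mm = r_i, h_mm = r_o - r_i
  )
}

#' Current radii from mid-wall stretches
#'
#' Inverse of [current_deformation()]: given circumferential and axial
#' stretch relative to \eqn{\kappa_r}, returns the outer, mid-wall and inner
#' radii and the wall thickness implied by incompressibility.
#'
#' @param geom A [vessel_geometry()].
#' @param lam_th,lam_z Principal stretches (vectorised, recycled).
#' @return A tibble with columns `r_o_mm`, `r_m_mm`, `r_i_mm`, `h_mm`.
#' @export
radii_from_stretch <- function(geom, lam_th, lam_z = 1) {
  stopifnot(inherits(geom, "vessel_geometry"))
  n <- max(length(lam_th), length(lam_z))
  lam_th <- rep_len(lam_th, n)
  lam_z <- rep_len(lam_z, n)
  r_m <- lam_th * geom$rho_m
  r_o <- sqrt(r_m^2 + geom$A_m / lam_z)
  ri2 <- r_o^2 - geom$A_i / lam_z
  if (any(ri2 <= 0)) abort("stretch state implies non-positive inner radius")
  r_i <- sqrt(ri2)
  tibble(r_o_mm = r_o, r_m_mm = r_m, r_i_mm = r_i, h_mm = r_o - r_i)
}

#' Green--Lagrange strain of a principal stretch
#'
#' @param lam Stretch (vectorised, positive).
#' @return \eqn{(\lambda^2 - 1)/2}.
#' @examples
#' green_lagrange(1.2)
#' @export
green_lagrange <- function(lam) {
  if (any(lam <= 0)) abort("stretch must be positive")
  (lam^2 - 1) / 2
}

#' Convert reference-configuration stretches to unloaded-referred stretches
#'
#' All internal stretches refer to the in-vivo reference \eqn{\kappa_r}. For
#' reporting against the unloaded configuration \eqn{\kappa_u}, divide each
#' principal stretch by the corresponding unloaded prestretch.
#'
#' @param defm A tibble/data frame with columns `lam_r`, `lam_th`, `lam_z`
#'   relative to \eqn{\kappa_r}.
#' @param geom A [vessel_geometry()].
#' @return Tibble of stretches relative to \eqn{\kappa_u}.
#' @export
stretch_rel_unloaded <- function(defm, geom) {
  stopifnot(inherits(geom, "vessel_geometry"))
  tibble(
    lam_r = defm$lam_r / geom$Lam_R,
    lam_th = defm$lam_th / geom$Lam_Th,
    lam_z = defm$lam_z / geom$Lam_Z
  )
}
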