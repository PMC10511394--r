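## Readers and writers. External files carry experimental units (mmHg, um,
## mN or gf, mm, s); everything internal is kPa / mm / mN / s.

.default_units <- list(pressure = "mmHg", diameter = "um", force = "mN",
                       length = "mm")

#' Read a protocol-step time series from CSV
#'
#' Expects a header row with columns `t_s`, `pressure_mmHg`,
#' `outer_diameter_um`, `axial_force_mN` (or `axial_force_gf`) and
#' `axial_length_mm`. Signals are converted to the internal units (kPa,
#' mm, mN, s); gram-force is converted at 9.80665 mN/gf. Time must be
#' strictly increasing.
#'
#' @param path CSV file path.
#' @param units Named list overriding the declared units; supported:
#'   `pressure` (`"mmHg"`/`"kPa"`), `diameter` (`"um"`/`"mm"`), `force`
#'   (`"mN"`/`"gf"`), `length` (`"mm"`).
#' @return A step tibble (`time_s`, `pressure_kpa`, `r_o_mm`, `force_mn`,
#'   `length_mm`).
#' @export
read_step_csv <- function(path, units = list()) {
  units <- modifyList(.default_units, units)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  force_col <- if ("axial_force_gf" %in% names(df)) "axial_force_gf" else "axial_force_mN"
  need <- c("t_s", "pressure_mmHg", "outer_diameter_um", force_col,
            "axial_length_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(miss, collapse = ", ")))
  }
  bad <- which(diff(df$t_s) <= 0)
  if (length(bad)) {
    abort(sprintf("%s: time not strictly increasing at data row %d", path,
                  bad[1] + 1L))
  }
  pres <- switch(units$pressure,
                 mmHg = mmhg_to_kpa(df$pressure_mmHg),
                 kPa = df$pressure_mmHg,
                 abort(sprintf("%s: unsupported pressure unit '%s'", path,
                               units$pressure)))
  diam <- switch(units$diameter,
                 um = df$outer_diameter_um / 2000,
                 mm = df$outer_diameter_um / 2,
                 abort(sprintf("%s: unsupported diameter unit '%s'", path,
                               units$diameter)))
  frc <- df[[force_col]]
  frc <- if (force_col == "axial_force_gf" || identical(units$force, "gf")) {
    gf_to_mn(frc)
  } else {
    frc
  }
  tibble(time_s = df$t_s, pressure_kpa = pres, r_o_mm = diam,
         force_mn = frc, length_mm = df$axial_length_mm)
}

#' @rdname read_step_csv
#' @param step A step tibble in internal units.
#' @export
write_step_csv <- function(step, path) {
  out <- tibble(
    t_s = step$time_s,
    pressure_mmHg = kpa_to_mmhg(step$pressure_kpa),
    outer_diameter_um = 2000 * step$r_o_mm,
    axial_force_mN = step$force_mn,
    axial_length_mm = step$length_mm
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write vessel geometry files
#'
#' YAML (or JSON) with keys `unloaded_outer_diameter_um`,
#' `wall_thickness_um`, `unloaded_length_mm`, `in_vivo_length_mm`,
#' `reference_outer_diameter_um`.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @param geom A [vessel_geometry()].
#' @return `read_geometry()` returns a [vessel_geometry()].
#' @export
read_geometry <- function(path) {
  g <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  need <- c("unloaded_outer_diameter_um", "wall_thickness_um",
            "unloaded_length_mm", "in_vivo_length_mm",
            "reference_outer_diameter_um")
  miss <- setdiff(need, names(g))
  if (length(miss)) {
    abort(sprintf("%s: missing geometry key(s) %s", path,
                  paste(miss, collapse = ", ")))
  }
  vessel_geometry(g$unloaded_outer_diameter_um, g$wall_thickness_um,
                  unloaded_length_mm = g$unloaded_length_mm,
                  in_vivo_length_mm = g$in_vivo_length_mm,
                  reference_outer_diameter_um = g$reference_outer_diameter_um)
}

#' @rdname read_geometry
#' @export
write_geometry <- function(geom, path) {
  yaml::write_yaml(list(
    unloaded_outer_diameter_um = 2000 * geom$R_o,
    wall_thickness_um = 1000 * (geom$R_o - geom$R_i),
    unloaded_length_mm = geom$L0,
    in_vivo_length_mm = geom$l_iv,
    reference_outer_diameter_um = 2000 * geom$rho_o
  ), path)
  invisible(path)
}

#' Write and read a dataset directory
#'
#' A dataset directory holds `manifest.yaml` (geometry, units, step list
#' with kinds/labels/frequencies, provenance seed) plus one CSV per
#' protocol step.
#'
#' @param ds A `cbqlv_dataset`.
#' @param dir Directory path (created if needed).
#' @return `read_dataset()` returns a `cbqlv_dataset`; `write_dataset()`
#'   returns `dir` invisibly.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "cbqlv_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(ds$steps)) {
    f <- paste0(nm, ".csv")
    write_step_csv(ds$steps[[nm]], file.path(dir, f))
    files[nm] <- f
  }
  man <- ds$manifest
  man$file <- unname(files[man$step])
  yaml::write_yaml(list(
    units = .default_units,
    seed = if (is.null(ds$seed) || is.na(ds$seed)) NULL else ds$seed,
    geometry = list(
      unloaded_outer_diameter_um = 2000 * ds$geometry$R_o,
      wall_thickness_um = 1000 * (ds$geometry$R_o - ds$geometry$R_i),
      unloaded_length_mm = ds$geometry$L0,
      in_vivo_length_mm = ds$geometry$l_iv,
      reference_outer_diameter_um = 2000 * ds$geometry$rho_o
    ),
    steps = purrr::pmap(man, function(step, kind, label, axial_level,
                                      p_low_mmhg, p_high_mmhg, frequency_hz,
                                      file, ...) {
      list(step = step, kind = kind, label = label,
           axial_level = if (is.na(axial_level)) NULL else axial_level,
           p_low_mmhg = p_low_mmhg, p_high_mmhg = p_high_mmhg,
           frequency_hz = if (is.na(frequency_hz)) NULL else frequency_hz,
           file = file)
    })
  ), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(dir) {
  man_path <- file.path(dir, "manifest.yaml")
  if (!file.exists(man_path)) abort(sprintf("no manifest.yaml in %s", dir))
  m <- yaml::read_yaml(man_path)
  g <- m$geometry
  geom <- vessel_geometry(g$unloaded_outer_diameter_um, g$wall_thickness_um,
                          unloaded_length_mm = g$unloaded_length_mm,
                          in_vivo_length_mm = g$in_vivo_length_mm,
                          reference_outer_diameter_um = g$reference_outer_diameter_um)
  units <- modifyList(.default_units, m$units %||% list())
  steps <- list()
  man <- list()
  for (e in m$steps) {
    f <- file.path(dir, e$file)
    if (!file.exists(f)) abort(sprintf("referenced step file missing: %s", f))
    steps[[e$step]] <- read_step_csv(f, units)
    man[[e$step]] <- tibble(
      step = e$step, kind = e$kind, label = e$label,
      axial_level = e$axial_level %||% NA_real_,
      p_low_mmhg = e$p_low_mmhg, p_high_mmhg = e$p_high_mmhg,
      frequency_hz = e$frequency_hz %||% NA_real_
    )
  }
  .new_dataset(geom, steps, dplyr::bind_rows(man), seed = m$seed %||% NA)
}

#' @importFrom rlang %||%
NULL

#' Write a stress history as CSV
#'
#' @param sh A tibble from [viscoelastic_stress()].
#' @param path CSV path.
#' @export
write_stress_history_csv <- function(sh, path) {
  readr::write_csv(sh, path, progress = FALSE)
  invisible(path)
}
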