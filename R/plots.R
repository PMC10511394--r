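#' Plot a biaxial dataset
#'
#' Pressure--diameter curves of the quasi-static sweeps and dynamic loops,
#' and force--length curves of the axial sweeps.
#'
#' @param object A `cbqlv_dataset`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cbqlv_dataset
#' @export
autoplot.cbqlv_dataset <- function(object, ...) {
  man <- object$manifest
  df <- purrr::imap(object$steps, function(st, nm) {
    k <- man$kind[man$step == nm]
    tibble(
      step = nm, kind = k,
      x = if (k == "axial_sweep") st$length_mm else 2000 * st$r_o_mm,
      y = if (k == "axial_sweep") st$force_mn else kpa_to_mmhg(st$pressure_kpa)
    )
  })
  df <- dplyr::bind_rows(df)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, colour = .data$step)) +
    ggplot2::geom_path(linewidth = 0.3, show.legend = FALSE) +
    ggplot2::facet_wrap(~kind, scales = "free",
                        labeller = ggplot2::as_labeller(c(
                          pressure_sweep = "pressure sweeps (P vs d)",
                          dynamic_loop = "dynamic loops (P vs d)",
                          axial_sweep = "axial sweeps (F vs l)"
                        ))) +
    ggplot2::labs(x = "outer diameter [µm] / length [mm]",
                  y = "pressure [mmHg] / force [mN]") +
    ggplot2::theme_bw()
}

#' Plot a dynamic-to-static modulus grid
#'
#' \eqn{E_D/E_S} versus loading frequency, one curve per centre pressure.
#'
#' @param object A `cbqlv_grid` from [modulus_ratio_grid()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cbqlv_grid
#' @export
autoplot.cbqlv_grid <- function(object, ...) {
  df <- dplyr::mutate(as_tibble(object),
                      pressure = factor(.data$pressure_mmhg))
  ggplot2::ggplot(df,
                  ggplot2::aes(.data$frequency_hz, .data$ratio,
                               colour = .data$pressure,
                               group = .data$pressure)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "loading frequency [Hz]", y = expression(E[D] / E[S]),
                  colour = "pressure [mmHg]") +
    ggplot2::facet_wrap(~variant) +
    ggplot2::theme_bw()
}

#' @method autoplot cbqlv_fit
#' @export
autoplot.cbqlv_fit <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb[!tb$fixed, ],
                  ggplot2::aes(.data$term, .data$value)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "estimate (log scale)",
                  title = "fitted free parameters") +
    ggplot2::theme_bw()
}
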