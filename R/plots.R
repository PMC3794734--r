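#' Plot a dilute-ensemble concentration sweep
#'
#' Sheet fraction, fibril mass share and aggregated mass fraction against
#' total protein concentration on a log axis.
#'
#' @param object An [ensemble_curve()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.ensemble_curve <- function(object, ...) {
  df <- .curve_long(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$phi_uM, y = .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "total protein (µM)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

## minimal long-format helper (avoids a tidyr dependency for one call)
.curve_long <- function(cur) {
  keep <- c(theta2 = "sheet fraction",
            fibril_mass_share = "fibril mass share",
            eta = "aggregated mass fraction")
  purrr::map_dfr(names(keep), function(nm) {
    v <- cur[[nm]]
    if (all(is.na(v))) return(NULL)
    tibble::tibble(phi_uM = cur$phi_uM, quantity = keep[[nm]], value = v)
  })
}

#' Plot a grand-canonical concentration sweep
#'
#' @param object A [gc_curve()] result.
#' @param ... Unused.
#' @export
autoplot.gc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$conc_uM,
                                       y = .data$sheet_fraction)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (µM)",
                  y = "sheet fraction ⟨θ⟩/⟨Np⟩") +
    ggplot2::theme_minimal()
}

#' Plot a fitted observable curve over its data
#'
#' @param object An [fit_observable_curve()] result.
#' @param ... Unused.
#' @export
autoplot.amyloid_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$conc_uM)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#7a3db8") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "concentration (µM)", y = object$observable) +
    ggplot2::theme_minimal()
}
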