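#' Plot a simulation result
#'
#' Facetted time-series view of the state variables, conductances and the
#' recorded observable.
#'
#' @param object A [simulate_synapse()] result.
#' @param vars Columns to show; defaults to the concentrations, plasticity
#'   factors and the recorded observable.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.synapse_sim <- function(object,
                                 vars = intersect(
                                   c("c_glu", "c_periph", "F", "D",
                                     "g_ampa", "g_nmda", "i_vc", "v_m"),
                                   names(object)),
                                 ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "time",
                  dplyr::all_of(vars)),
    -"time", names_to = "series", values_to = "value")
  long$series <- factor(long$series, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 2) +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay fitted model traces on the recordings
#'
#' @param fit A [staged_fit()] result.
#' @param ... Unused.
#' @return A ggplot object with one facet per recording.
#' @export
plot_fit_overlay <- function(fit, ...) {
  stopifnot(inherits(fit, "synapse_fit"))
  dat <- purrr::imap_dfr(fit$recordings, function(rec, id) {
    sim <- .simulate_for_recording(fit$params, rec)
    dplyr::bind_rows(
      tibble::tibble(id = id, time = rec$time, value = rec$value,
                     which = "data"),
      tibble::tibble(id = id, time = sim$time, value = sim$value,
                     which = "model"))
  })
  ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$value,
                                    color = .data$which)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~id, scales = "free") +
    ggplot2::labs(x = "time (ms)", y = NULL, color = NULL) +
    ggplot2::theme_minimal()
}
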