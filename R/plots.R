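#' Plot DVHs
#'
#' `autoplot()` on a single cumulative DVH draws the curve; on a
#' `dvh_cohort` it overlays per-patient curves faceted by structure and
#' coloured by technique - the standard visual check that the generated
#' cohort has the intended target fall-off and OAR tails.
#'
#' @param object A `cumulative_dvh` or `dvh_cohort`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cumulative_dvh
#' @export
autoplot.cumulative_dvh <- function(object, ...) {
  info <- dvh_info(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose, y = 100 * .data$volume)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)",
                  title = sprintf("Cumulative DVH: %s", info$structure)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cumulative_dvh
#' @method autoplot dvh_cohort
#' @export
autoplot.dvh_cohort <- function(object, ...) {
  curves <- object$dvhs |>
    dplyr::mutate(data = purrr::map(.data$dvh, function(d) {
      tibble::as_tibble(as_cumulative(d))
    })) |>
    dplyr::select(-"dvh") |>
    tidyr::unnest("data")
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$dose, y = 100 * .data$volume,
                               colour = .data$technique,
                               group = interaction(.data$patient_id, .data$technique))) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::facet_wrap(~structure, scales = "free_x") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", colour = "Technique") +
    ggplot2::theme_minimal()
}
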