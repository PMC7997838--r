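#' Plot a simulated trajectory
#'
#' Concentration versus time for every compound, faceted by aromatic class
#' (H, G, S, other), with unmeasured intracellular intermediates drawn
#' dashed.
#'
#' @param object an `aromkin_trajectory` from [simulate_network()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.aromkin_trajectory <- function(object, ...) {
  cls <- attr(object, "network")$compounds
  df <- dplyr::left_join(tibble::as_tibble(object),
                         cls[, c("compound", "class")], by = "compound")
  ggplot2::ggplot(df, ggplot2::aes(.data$time_h, .data$conc_umol_per_l,
                                   colour = .data$compound,
                                   linetype = .data$measurable)) +
    ggplot2::geom_line() +
    ggplot2::scale_linetype_manual(values = c(`TRUE` = "solid", `FALSE` = "dashed"),
                                   guide = "none") +
    ggplot2::facet_wrap(ggplot2::vars(.data$class), scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = expression("concentration ("*mu*"mol "*l^-1*")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fit: observed points over simulated curves
#'
#' One panel per measurable compound, observed concentrations as points and
#' the fitted model trajectory as a line.
#'
#' @param object an `aromkin_fit` from [fit_network()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.aromkin_fit <- function(object, ...) {
  traj <- simulate_network(object$network, object$biomass,
                           t_end = max(object$data$time_h), dt = object$dt,
                           warn_clip = FALSE)
  measurable <- object$network$compounds$compound[object$network$compounds$measurable]
  sim <- dplyr::filter(tibble::as_tibble(traj), .data$compound %in% measurable)
  obs <- tidyr::pivot_longer(object$data, -"time_h", names_to = "compound",
                             values_to = "conc_umol_per_l")
  ord <- intersect(object$network$compounds$compound, unique(obs$compound))
  sim$compound <- factor(sim$compound, levels = ord)
  obs$compound <- factor(obs$compound, levels = ord)
  ggplot2::ggplot(sim, ggplot2::aes(.data$time_h, .data$conc_umol_per_l)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = obs, size = 0.8, colour = "grey30") +
    ggplot2::facet_wrap(ggplot2::vars(.data$compound), scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = expression("concentration ("*mu*"mol "*l^-1*")")) +
    ggplot2::theme_minimal()
}

#' Plot a case comparison
#'
#' Total fitted RSS per case on a log scale — the at-a-glance version of
#' the case-comparison table.
#'
#' @param object a `case_comparison` from [compare_cases()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.case_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)[, c("case", "total")]
  ggplot2::ggplot(df, ggplot2::aes(.data$case, .data$total)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = expression("total RSS ("*mu*"mol"^2*" "*l^-2*")")) +
    ggplot2::theme_minimal()
}
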