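#' Plot the developmental physiology curves
#'
#' @param object A `huddle_curves` tibble from [physiology_curves()].
#' @param vars Which curves to draw (facets), a subset of the tibble's
#'   columns.
#' @param ... Unused.
#' @return A ggplot.
#' @examples
#' autoplot(physiology_curves())
#' @method autoplot huddle_curves
#' @export
autoplot.huddle_curves <- function(object,
                                   vars = c("P", "S", "G", "W", "selected_temp", "drive"),
                                   ...) {
  long <- tidyr::pivot_longer(object, dplyr::all_of(vars),
                              names_to = "quantity", values_to = "value")
  long$quantity <- factor(long$quantity, levels = vars)
  ggplot2::ggplot(long, ggplot2::aes(.data$day, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "postnatal day", y = NULL,
                  title = "Developmental thermal physiology") +
    ggplot2::theme_minimal()
}

#' Plot group-size trajectories of one or more developmental runs
#'
#' @param object A `huddle_development` object.
#' @param ... Further `huddle_development` objects to overlay (e.g. the
#'   matched control for a learning run).
#' @return A ggplot of the replicate-averaged mean group size per day, with a
#'   between-replicate +/- 1 sd ribbon, coloured by condition.
#' @examples
#' ctrl <- run_development("control", days = 0:10, iters_per_day = 100,
#'                         replicates = 2, seed = 1)
#' autoplot(ctrl)
#' @method autoplot huddle_development
#' @export
autoplot.huddle_development <- function(object, ...) {
  extra <- purrr::keep(list(...), inherits, "huddle_development")
  stats <- dplyr::bind_rows(lapply(c(list(object), extra), tidy))
  ggplot2::ggplot(stats, ggplot2::aes(.data$day, .data$mean_group_size,
                                      colour = .data$condition,
                                      fill = .data$condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_group_size - .data$sd,
                                      ymax = .data$mean_group_size + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "postnatal day", y = "mean group size",
                  title = "Huddling across development") +
    ggplot2::theme_minimal()
}

#' Plot a pup's learnt association trajectories
#'
#' Shows how one pup's associative strengths for each littermate's odour
#' develop: an early common rise while contacts are thermally rewarding,
#' then increasing discrimination, with some associations turning strongly
#' positive and others negative.
#'
#' @param object A learning-condition `huddle_development` with association
#'   snapshots.
#' @param pup The focal pup id.
#' @param replicate Which replicate litter to show.
#' @return A ggplot with one line per littermate.
#' @export
plot_association_trajectories <- function(object, pup = 1, replicate = 1) {
  if (!inherits(object, "huddle_development") || is.null(object$alpha)) {
    rlang::abort("`object` must be a learning-condition run with alpha snapshots")
  }
  dat <- dplyr::filter(object$alpha, .data$a == pup, .data$replicate == !!replicate)
  ggplot2::ggplot(dat, ggplot2::aes(.data$day, .data$alpha,
                                    group = .data$b, colour = factor(.data$b))) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "postnatal day", y = expression(alpha),
                  colour = "littermate",
                  title = sprintf("Associative strengths of pup %d", pup)) +
    ggplot2::theme_minimal()
}

#' Plot a synthetic dataset against its generating curves
#'
#' @param object A `huddle_synth` tibble from [simulate_development_data()].
#' @param ... Unused.
#' @return A ggplot faceted by measured variable.
#' @method autoplot huddle_synth
#' @export
autoplot.huddle_synth <- function(object, ...) {
  vars <- c("bat_percent", "metabolic_rate", "body_mass", "selected_temp")
  obs <- tidyr::pivot_longer(tibble::as_tibble(object), dplyr::all_of(vars),
                             names_to = "variable", values_to = "value")
  tru <- tidyr::pivot_longer(attr(object, "truth"), dplyr::all_of(vars),
                             names_to = "variable", values_to = "value")
  ggplot2::ggplot(obs, ggplot2::aes(.data$day, .data$value)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(data = tru, colour = "firebrick") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "postnatal day", y = NULL,
                  title = "Synthetic developmental observations") +
    ggplot2::theme_minimal()
}
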