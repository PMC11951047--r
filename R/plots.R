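# ggplot2 views of the analysis results.

#' @importFrom ggplot2 autoplot ggplot aes geom_segment geom_point geom_col
#'   geom_histogram labs theme_minimal facet_wrap
#' @export
ggplot2::autoplot

#' Plot flux/usage variability ranges
#'
#' Min-max segments per target, ordered by range width.
#'
#' @param object a `coral_fva`.
#' @param top show only the `top` widest ranges (default 40).
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot coral_fva
#' @export
autoplot.coral_fva <- function(object, top = 40, ...) {
  d <- tidy(object) |>
    arrange(dplyr::desc(.data$range)) |>
    head(top) |>
    mutate(target = factor(.data$target, levels = rev(.data$target)))
  ggplot(d, aes(y = .data$target)) +
    geom_segment(aes(x = .data$min, xend = .data$max, yend = .data$target),
                 linewidth = 1.2, colour = "steelblue") +
    geom_point(aes(x = .data$min)) +
    geom_point(aes(x = .data$max)) +
    labs(x = if (identical(attr(object, "kind"), "subpool"))
      "subpool usage range (mmol/gDW)" else "flux range (mmol/gDW/h)",
      y = NULL) +
    theme_minimal()
}

#' Plot the growth-ratio distribution of a pair-block screen
#'
#' Histogram of growth ratios faceted by the promiscuity status of the pair,
#' the structure behind the "promiscuous pairs hurt less" comparison.
#'
#' @param object a `pair_screen`.
#' @param bins histogram bins.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot pair_screen
#' @export
autoplot.pair_screen <- function(object, bins = 30, ...) {
  ggplot(as_tibble(object), aes(x = .data$ratio)) +
    geom_histogram(bins = bins, fill = "steelblue", colour = "white") +
    facet_wrap(~promiscuity) +
    labs(x = expression(mu[del] / mu[WT]), y = "enzyme pairs") +
    theme_minimal()
}

#' Plot subpool redistribution after blocking an enzyme's main reaction
#'
#' @param object a `defect_report` from [block_main_single()].
#' @param ... unused.
#' @return a ggplot comparing wild-type and post-block subpool usages.
#' @method autoplot defect_report
#' @export
autoplot.defect_report <- function(object, ...) {
  redist <- attr(object, "redistribution")
  if (is.null(redist)) abort("defect report carries no redistribution table")
  d <- redist |>
    tidyr::pivot_longer(c("usage_wt", "usage_del"), names_to = "state",
                        values_to = "usage") |>
    mutate(state = if_else(.data$state == "usage_wt", "wild type", "defect"))
  ggplot(d, aes(x = factor(.data$rank), y = .data$usage, fill = .data$state)) +
    geom_col(position = "dodge") +
    labs(x = "subpool rank", y = "usage (mmol/gDW)", fill = NULL,
         title = unique(redist$enzyme)) +
    theme_minimal()
}

#' Plot flux-sum differences between defect and wild type
#'
#' @param object tibble from [flux_sum_delta()].
#' @param top show the `top` largest |delta| metabolites (default 30).
#' @param ... unused.
#' @return a ggplot.
#' @export
plot_flux_sum_delta <- function(object, top = 30, ...) {
  d <- object |>
    arrange(dplyr::desc(abs(.data$delta))) |>
    head(top) |>
    mutate(metabolite = factor(.data$metabolite, levels = rev(.data$metabolite)))
  ggplot(d, aes(x = .data$delta, y = .data$metabolite)) +
    geom_col(fill = "steelblue") +
    labs(x = expression(phi[del] - phi[WT]), y = NULL) +
    theme_minimal()
}
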