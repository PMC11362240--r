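# ---------------------------------------------------------------------------
# ggplot2 graphics: autoplot methods and plot_* helpers
# ---------------------------------------------------------------------------

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Density plot of group-level parameter draws
#'
#' @param object An `mpt_draws` object (prior or posterior).
#' @param scale `"probability"` or `"probit"`.
#' @param parameters Optional subset of parameter names.
#' @param ... Unused.
#' @return A ggplot: one density panel per parameter.
#' @export
autoplot.mpt_draws <- function(object, scale = c("probability", "probit"),
                               parameters = NULL, ...) {
  scale <- match.arg(scale)
  df <- tidy_group_draws(object, scale = scale)
  if (!is.null(parameters)) {
    df <- dplyr::filter(df, .data$parameter %in% parameters)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mu)) +
    ggplot2::geom_density() +
    ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free") +
    ggplot2::labs(
      x = paste0("group-level value (", scale, " scale)"), y = "density",
      title = paste0(object$provenance, " draws")
    )
}

#' Interval plot of group-level posterior estimates
#'
#' @param object An `mpt_fit`.
#' @param scale,conf_level Passed to [tidy.mpt_fit()].
#' @param truth Optional truth tibble (from [generate_dataset()]) overlaid as
#'   points.
#' @param ... Unused.
#' @return A ggplot of posterior medians with credible intervals.
#' @export
autoplot.mpt_fit <- function(object, scale = c("probability", "probit"),
                             conf_level = 0.95, truth = NULL, ...) {
  scale <- match.arg(scale)
  td <- tidy(object, scale = scale, conf_level = conf_level)
  p <- ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                        y = .data$parameter)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(x = paste0("group-level estimate (", scale, " scale)"),
                  y = NULL)
  if (!is.null(truth)) {
    tr <- truth
    tr$value <- if (scale == "probability") tr$prob else tr$mu
    p <- p + ggplot2::geom_point(
      data = tr, ggplot2::aes(x = .data$value, y = .data$parameter),
      shape = 4, size = 3, colour = "red"
    )
  }
  p
}

#' Predictive distribution of a response rate
#'
#' Histogram of the predicted per-draw individual response probabilities for
#' one tree/category cell, with the observed pooled rate overlaid when data
#' are supplied -- the prior-predictive "response rate" check.
#'
#' @param object A `predictive_sample`.
#' @param tree,category Cell to display.
#' @param data Optional observed `freq_table`.
#' @param bins Histogram bins.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.predictive_sample <- function(object, tree, category, data = NULL,
                                       bins = 50, ...) {
  rr <- response_rate_draws(object, tree, category)
  p <- ggplot2::ggplot(rr, ggplot2::aes(x = .data$prob)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::labs(
      x = paste0("P(", category, " | ", tree, ")"), y = "draws",
      title = paste0(object$provenance, "-predictive response probability")
    )
  if (!is.null(data)) {
    cell <- paste0(tree, ":", category)
    items <- object$design$design$items[object$design$design$tree == tree]
    obs <- sum(data[[cell]]) / (items * nrow(data))
    p <- p + ggplot2::geom_vline(xintercept = obs, colour = "red")
  }
  p
}

#' Compare extremeness indices across prior specifications
#'
#' @param draws_list A named list of `mpt_draws` objects (e.g. one per prior
#'   preset).
#' @param parameters Parameter names to compare.
#' @param band Boundary band width, see [extremeness_index()].
#' @return A ggplot bar chart of the index per prior and parameter, with
#'   Monte Carlo error bars.
#' @export
plot_extremeness <- function(draws_list, parameters, band = 0.1) {
  stopifnot(is.list(draws_list), !is.null(names(draws_list)))
  df <- purrr::map_dfr(names(draws_list), function(nm) {
    purrr::map_dfr(parameters, function(p) {
      out <- extremeness_index(draws_list[[nm]], p, band = band)
      out$prior <- nm
      out
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$index,
                                   fill = .data$prior)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$index - 2 * .data$mc_se,
                   ymax = .data$index + 2 * .data$mc_se),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2
    ) +
    ggplot2::labs(y = paste0("mass within ", band, " of 0 or 1"), x = NULL)
}

#' Plot individual-level effect estimates against an order constraint
#'
#' @param effects The tibble from [descriptive_individual_effects()] (single
#'   constraint, so `median_diff` is present).
#' @return A ggplot of per-participant median differences, ordered, coloured
#'   by interval conformity.
#' @export
plot_individual_effects <- function(effects) {
  if (is.null(effects$median_diff)) {
    abort("plot_individual_effects() needs a single-constraint effects table",
          class = "ordtree_value_error")
  }
  df <- dplyr::arrange(effects, .data$median_diff)
  df$rank <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rank, y = .data$median_diff,
                                   colour = .data$interval_conforms)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "participant (ordered)", y = "median difference",
                  colour = "interval conforms")
}
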