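#' Plot an S-distribution with optional fitted models
#'
#' @param object An `sdist`.
#' @param fits Optional named list of `div_fit` objects whose expected
#'   class weights are overlaid as lines.
#' @param ... Unused.
#' @return A ggplot.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.sdist <- function(object, fits = NULL, ...) {
  df <- tibble::tibble(k = object$k, count = object$count)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$count)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::labs(x = "pairwise differences S", y = "block weight") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    total <- sum(object$count)
    kmax <- max(object$k)
    lines <- purrr::map_dfr(fits, function(f) {
      probs <- pmf_at(f$model, f$params, kmax)
      tibble::tibble(k = 0:kmax, expected = probs * total, model = f$model)
    })
    p <- p +
      ggplot2::geom_line(data = lines,
                         ggplot2::aes(y = .data$expected, colour = .data$model)) +
      ggplot2::geom_point(data = lines,
                          ggplot2::aes(y = .data$expected, colour = .data$model),
                          size = 1) +
      ggplot2::labs(colour = "model")
  }
  p
}

#' Model-support plane for a set of species pairs
#'
#' Scatter of the two likelihood-ratio statistics that drive model choice:
#' support for secondary contact over strict isolation (x) against support
#' for migration over strict isolation (y), with the chi-square decision
#' thresholds drawn as dashed lines and points coloured by best model.
#'
#' @param selections A data frame row-binding `div_selection` results.
#' @param thresholds From [select_thresholds()].
#' @return A ggplot.
#' @export
plot_model_support <- function(selections, thresholds = select_thresholds()) {
  ggplot2::ggplot(selections,
                  ggplot2::aes(x = .data$two_delta_si_sc,
                               y = .data$two_delta_si_im,
                               colour = .data$best_model)) +
    ggplot2::geom_vline(xintercept = thresholds$df2, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = thresholds$df1, linetype = "dashed") +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red", alpha = 0.5) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(2 * Delta * lnL ~ "(SI vs SC)"),
                  y = expression(2 * Delta * lnL ~ "(SI vs IM)"),
                  colour = "best model") +
    ggplot2::theme_minimal()
}

#' Plot the null distribution of the gene-flow LRT statistic
#'
#' @param power_table Output of [power_analysis()].
#' @param threshold Decision threshold drawn as a dashed line.
#' @return A ggplot.
#' @export
plot_power <- function(power_table, threshold = stats::qchisq(0.95, 1)) {
  ggplot2::ggplot(power_table, ggplot2::aes(x = .data$two_delta)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70") +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = expression(2 * Delta * lnL ~ "(SI vs IM)"),
                  y = "replicates") +
    ggplot2::theme_minimal()
}
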