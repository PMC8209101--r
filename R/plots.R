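#' Plot the normalized trade-off curve
#'
#' Normalized task count and normalized TAT dissatisfaction against the
#' waiting interval M; their crossing region is where the two objectives
#' balance.
#'
#' @param norm a [normalize_curve()] result (a raw [tradeoff_curve()] is
#'   normalized on the fly).
#' @return a `ggplot` object.
#' @export
plot_tradeoff <- function(norm) {
  if (!inherits(norm, "normalized_curve")) norm <- normalize_curve(norm)
  df <- rbind(
    data.frame(M = norm$M, value = norm$f1,
               objective = "TAT dissatisfaction (f1)"),
    data.frame(M = norm$M, value = norm$f2,
               objective = "task count (f2)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = M, y = value, colour = objective)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "waiting interval M (min)", y = "normalized objective",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot scalarized objectives for several weightings
#'
#' One curve of `g(M) = w_tat * f1 + w_switch * f2` per weight pair, with
#' each selected `M0` marked.
#'
#' @param results a list of [scalarize()] results (a single result is
#'   wrapped).
#' @return a `ggplot` object.
#' @export
plot_objective <- function(results) {
  if (inherits(results, "optimization_result")) results <- list(results)
  df <- do.call(rbind, lapply(results, function(res) {
    lab <- sprintf("w_tat = %.1f, w_switch = %.1f",
                   res$weights[["w_tat"]], res$weights[["w_switch"]])
    cbind(res$curve[, c("M", "g")], weights = lab, M0 = res$M0)
  }))
  marks <- unique(df[df$M == df$M0, c("M", "g", "weights")])
  ggplot2::ggplot(df, ggplot2::aes(x = M, y = g, colour = weights)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point(data = marks, size = 3, shape = 18) +
    ggplot2::labs(x = "waiting interval M (min)",
                  y = "scalarized objective g(M)", colour = NULL) +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("M", "value", "objective", "g", "weights"))
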