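#' Plot a simulated life course
#'
#' BMD (relative to the reference age) and the baseline-normalized turnover
#' markers over age, with dose events indicated by rug marks.
#'
#' @param object A `bone_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.bone_sim <- function(object, ...) {
  tr <- object$trajectory
  long <- tidyr::pivot_longer(
    tr[c("age", "bmd_relative", "ctx_change", "p1np_change")],
    -"age", names_to = "observable", values_to = "value")
  long$observable <- factor(long$observable,
                            levels = c("bmd_relative", "ctx_change",
                                       "p1np_change"),
                            labels = c("relative BMD", "CTX change",
                                       "P1NP change"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$age, y = .data$value)) +
    ggplot2::geom_line(color = "#2c5f8a") +
    ggplot2::facet_wrap(~observable, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "age (years)", y = NULL) +
    ggplot2::theme_minimal()
  if (nrow(object$regimen) > 0) {
    p <- p + ggplot2::geom_rug(
      data = tibble::tibble(age = object$regimen$time, value = NA_real_),
      sides = "b", color = "grey40", na.rm = TRUE)
  }
  p
}

#' Plot sequence-experiment outcomes
#'
#' Bar panels of the two outcome metrics (maximum BMD gain during
#' treatment; relative BMD 10 years after treatment end) across drug
#' sequences, each ordered by its own ranking.
#'
#' @param object An `osteo_sequences` tibble from
#'   [run_sequence_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.osteo_sequences <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[c("label", "max_bmd_gain", "residual_bmd_10y")],
    -"label", names_to = "metric", values_to = "value")
  long$metric <- factor(long$metric,
                        levels = c("max_bmd_gain", "residual_bmd_10y"),
                        labels = c("max BMD gain", "BMD 10 y after end"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$label, -.data$value),
                               y = .data$value)) +
    ggplot2::geom_col(fill = "#2c5f8a") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::coord_cartesian(ylim = c(min(long$value) * 0.98, NA)) +
    ggplot2::labs(x = "drug sequence",
                  y = "BMD relative to treatment start") +
    ggplot2::theme_minimal()
}

#' Plot model overlays for hybrid datasets
#'
#' Simulated BMD against the aging anchors and a hybrid dataset's treatment
#' series.
#'
#' @param params An `osteo_params` registry.
#' @param hybrid An `osteo_hybrid` dataset.
#' @param config See [calibration_config()].
#' @return A ggplot object.
#' @export
plot_hybrid_overlay <- function(params, hybrid,
                                config = calibration_config()) {
  pred <- simulate_for_dataset(params, hybrid, config)
  tr <- pred$sim$trajectory
  ggplot2::ggplot() +
    ggplot2::geom_line(data = tr,
                       ggplot2::aes(x = .data$age, y = .data$bmd_relative),
                       color = "black") +
    ggplot2::geom_point(data = hybrid$aging_anchors,
                        ggplot2::aes(x = .data$age, y = .data$bmd_rel),
                        color = "#3a7d44", size = 2) +
    ggplot2::geom_point(data = hybrid$treatment,
                        ggplot2::aes(x = .data$age, y = .data$bmd_rel),
                        color = "black", shape = 1, size = 2) +
    ggplot2::labs(x = "age (years)", y = "relative BMD",
                  title = hybrid$label) +
    ggplot2::theme_minimal()
}
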