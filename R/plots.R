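#' Plot a simulated trial
#'
#' Shows the tongue-center path in the midsagittal plane (with the
#' palate/pharynx outline) and the produced formant tracks.
#'
#' @param object An `sfc_trial`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfc_trial <- function(object, ...) {
  tr <- object$trajectory
  arts <- articulator_inventory()
  A <- t(as.matrix(tr[, paste0("a_", arts)]))
  rownames(A) <- arts
  tc <- tongue_center(A)
  df <- tibble::tibble(t = tr$t, x = tc["x", ], y = tc["y", ])
  phi <- seq(0.4, 2.6, length.out = 200)
  outline <- tibble::tibble(x = outline_radius(phi) * cos(phi),
                            y = outline_radius(phi) * sin(phi))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = outline, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_path(ggplot2::aes(colour = .data$t)) +
    ggplot2::scale_x_reverse() +  # anterior (front) to the right
    ggplot2::coord_equal() +
    ggplot2::labs(x = "posterior <- x (cm) -> anterior", y = "y (cm)",
                  colour = "time (s)",
                  title = "Tongue-center trajectory")
}

#' Plot endpoint variability by feedback condition
#'
#' @param object An `sfc_feedback_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfc_feedback_summary <- function(object, ...) {
  s <- object$summary
  s$condition <- factor(s$condition, levels = s$condition)
  ggplot2::ggplot(s, ggplot2::aes(x = .data$condition, y = .data$endpoint_sd)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$endpoint_sd_lo,
                                        ymax = .data$endpoint_sd_hi),
                           width = 0.2) +
    ggplot2::labs(x = "feedback condition",
                  y = "endpoint tongue-center s.d. (cm)",
                  title = "Variability by feedback availability")
}

#' Plot a sensory-noise sweep
#'
#' @param object An `sfc_sweep` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfc_sweep <- function(object, ...) {
  df <- tidyr::pivot_longer(as.data.frame(object),
                            c("pred_error", "sd_CA"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "noise level", y = NULL,
                  title = paste0("Noise sweep (", object$channel[1],
                                 "-only feedback)"))
}

#' Plot the F1-perturbation response
#'
#' Produced F1 for the example baseline and perturbed trials, with the
#' perturbation onset marked.
#'
#' @param object An `sfc_f1_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sfc_f1_result <- function(object, ...) {
  ex <- object$example
  df <- dplyr::bind_rows(
    tibble::tibble(t = ex$baseline$trajectory$t,
                   F1 = ex$baseline$trajectory$F1, run = "baseline"),
    tibble::tibble(t = ex$perturbed$trajectory$t,
                   F1 = ex$perturbed$trajectory$F1, run = "perturbed")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$F1,
                                   colour = .data$run)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$summary$stabilization,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = "produced F1 (Hz)",
                  title = "Response to a perceived-F1 shift")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
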