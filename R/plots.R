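#' Plot a simulated path
#'
#' @param object a `cx_trial` from [run_trial()].
#' @param ... unused.
#' @return a ggplot: the 2-D path, coloured by whether the celestial rotation
#'   was active, with the start marked.
#' @exportS3Method ggplot2::autoplot
autoplot.cx_trial <- function(object, ...) {
  start <- attr(object, "start")$position
  ggplot(object, aes(x = .data$x, y = .data$y)) +
    geom_path(aes(colour = .data$rotation_on), linewidth = 0.4) +
    annotate("point", x = start[1], y = start[2], shape = 4, size = 2) +
    coord_equal() +
    scale_colour_manual(values = c(`FALSE` = "grey25", `TRUE` = "#D55E00"),
                        name = "cue rotated") +
    labs(x = "x (steps)", y = "y (steps)", title = "Simulated path") +
    theme_minimal()
}

#' Plot cohort paths
#'
#' @param object a `cx_cohort` from [run_cohort()].
#' @param ... unused.
#' @return a ggplot of all agents' paths.
#' @exportS3Method ggplot2::autoplot
autoplot.cx_cohort <- function(object, ...) {
  ggplot(object, aes(x = .data$x, y = .data$y, group = .data$agent)) +
    geom_path(alpha = 0.5, linewidth = 0.3, colour = "grey25") +
    coord_equal() +
    labs(x = "x (steps)", y = "y (steps)", title = "Cohort paths") +
    theme_minimal()
}

#' Heatmap of the bias-by-noise sweep
#'
#' @param object a `cx_sweep` from [sweep_bias_noise()].
#' @param ... unused.
#' @return a ggplot heatmap of mean directional error over the grid.
#' @exportS3Method ggplot2::autoplot
autoplot.cx_sweep <- function(object, ...) {
  ggplot(object, aes(x = .data$bias, y = .data$noise, fill = .data$mean_error)) +
    geom_tile() +
    scale_fill_viridis_c(name = "mean error (deg)", limits = c(0, 180)) +
    labs(x = "directional bias (deg)", y = "directional noise SD (deg)",
         title = "Directional error after the trial") +
    theme_minimal()
}

#' Time courses around the rotation onset
#'
#' @param object a `cx_rotation` from [sun_rotation_experiment()].
#' @param ... unused.
#' @return a ggplot with bearings (relative to route) and absolute turn
#'   angles against segment index, mean +/- SE, onset at index 0.
#' @exportS3Method ggplot2::autoplot
autoplot.cx_rotation <- function(object, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object),
    cols = c("bearing_mean", "turn_mean"),
    names_to = "measure", values_to = "mean"
  )
  long$se <- ifelse(long$measure == "bearing_mean", object$bearing_se[match(long$index, object$index)],
                    object$turn_se[match(long$index, object$index)])
  long$measure <- factor(long$measure, c("bearing_mean", "turn_mean"),
                         c("bearing rel. route (deg)", "|turn angle| (deg)"))
  ggplot(long, aes(x = .data$index, y = .data$mean)) +
    geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    geom_ribbon(aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
                alpha = 0.25, fill = "#0072B2") +
    geom_line(colour = "#0072B2") +
    facet_wrap(~measure, ncol = 1, scales = "free_y") +
    labs(x = "segment index (0 = rotation onset)", y = NULL,
         title = "Cohort response to celestial-cue rotation") +
    theme_minimal()
}

#' Expected familiarity tuning curves
#'
#' @param cfg a [familiarity_config()].
#' @param headings headings at which to draw the curves.
#' @return a ggplot of the expected left/right familiarity response.
#' @export
plot_familiarity_curves <- function(cfg = familiarity_config(),
                                    headings = seq(-180, 179, by = 1)) {
  curve <- mean_response_curve(cfg, headings)
  long <- tidyr::pivot_longer(curve, c("f_left", "f_right"),
                              names_to = "side", values_to = "familiarity")
  ggplot(long, aes(x = .data$heading, y = .data$familiarity,
                   colour = .data$side)) +
    geom_line() +
    scale_colour_manual(values = c(f_left = "#009E73", f_right = "#E69F00"),
                        labels = c("left", "right"), name = NULL) +
    labs(x = "body orientation (deg, route = 0)", y = "expected familiarity",
         title = "Lateralised familiarity tuning") +
    theme_minimal()
}
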