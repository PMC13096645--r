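#' Tidy and glance methods for experiment results
#'
#' `tidy()` returns the result as a plain tibble (dropping attributes and
#' result classes); `glance()` returns a one-row summary.
#'
#' @param x a `cx_sweep`, `cx_rotation`, or `cx_trial` object.
#' @param ... unused.
#' @name routecx-tidiers
NULL

#' @rdname routecx-tidiers
#' @exportS3Method generics::tidy
tidy.cx_sweep <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname routecx-tidiers
#' @exportS3Method generics::glance
glance.cx_sweep <- function(x, ...) {
  best <- x[which.min(x$mean_error), ]
  worst <- x[which.max(x$mean_error), ]
  tibble(
    n_cells = nrow(x),
    reps = x$reps[1],
    min_error = best$mean_error, min_error_bias = best$bias, min_error_noise = best$noise,
    max_error = worst$mean_error, max_error_bias = worst$bias, max_error_noise = worst$noise
  )
}

#' @rdname routecx-tidiers
#' @exportS3Method generics::tidy
tidy.cx_rotation <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname routecx-tidiers
#' @exportS3Method generics::glance
glance.cx_rotation <- function(x, ...) {
  pre <- x[x$index < 0 & !is.na(x$turn_mean), ]
  onset <- x[x$index == 0 & !is.na(x$turn_mean), ]
  post <- x[x$index > 0, ]
  tibble(
    rotation_deg = attr(x, "rotation_deg"),
    segment_stride = attr(x, "segment_stride"),
    pre_turn_mean = mean(pre$turn_mean),
    onset_turn_mean = if (nrow(onset)) onset$turn_mean else NA_real_,
    final_bearing = post$bearing_mean[which.max(post$index)],
    n_agents = max(x$n, na.rm = TRUE)
  )
}

#' @rdname routecx-tidiers
#' @exportS3Method generics::tidy
tidy.cx_trial <- function(x, ...) {
  as_tibble(unclass_result(x))
}

unclass_result <- function(x) {
  for (a in c("circuit", "familiarity", "trial", "cohort", "start", "seeds",
              "base_seed", "n_steps", "rotation_deg", "rotation_step",
              "segment_stride", "goal_field", "spec", "familiar")) {
    attr(x, a) <- NULL
  }
  class(x) <- c("tbl_df", "tbl", "data.frame")
  x
}
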