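#' Configure the lateralised familiarity input
#'
#' Familiarity stands in for mushroom-body visual recognition: an
#' orientation-tuned signal that is strong only when the body points near a
#' memorised offset from the route direction, and decays rapidly away from it.
#' The left signal peaks, on average, `directional_bias` degrees clockwise of
#' the route direction; the right signal peaks symmetrically at
#' `-directional_bias`. Directional noise shifts each side's tuning curve
#' around its mean peak independently at every step.
#'
#' @param route_direction allocentric goal (route) direction, degrees.
#' @param directional_bias mean angular offset of the left signal's peak
#'   clockwise of the route direction, degrees. Positive bias means the left
#'   signal fires when the body points right of the goal (and vice versa);
#'   negative bias swaps the sides.
#' @param directional_noise_sd SD of the per-step Gaussian shift of each
#'   tuning curve around its mean peak, degrees.
#' @param tuning_kappa concentration of the exponential-cosine (von-Mises
#'   shaped) tuning curve; the default 5 gives a half-maximum width of about
#'   +/-30 degrees, a rapid decay away from the preferred gaze orientation.
#' @param amplitude peak familiarity value, in `[0, 1]` (0 switches the
#'   familiarity input off entirely).
#' @param threshold floor below which a familiarity value is zeroed, making
#'   the signal sporadic over most headings.
#' @return a `cx_familiarity` configuration list.
#' @examples
#' familiarity_config(directional_bias = 45, directional_noise_sd = 10)
#' @export
familiarity_config <- function(route_direction = 0,
                               directional_bias = 45,
                               directional_noise_sd = 10,
                               tuning_kappa = 5,
                               amplitude = 1,
                               threshold = 0.05) {
  stop_if(!is_num1(route_direction), "`route_direction` must be a finite number")
  stop_if(!is_num1(directional_bias), "`directional_bias` must be a finite number")
  stop_if(!is_num1(directional_noise_sd) || directional_noise_sd < 0,
          "`directional_noise_sd` must be >= 0")
  stop_if(!is_num1(tuning_kappa) || tuning_kappa <= 0, "`tuning_kappa` must be > 0")
  stop_if(!is_num1(amplitude) || amplitude < 0 || amplitude > 1,
          "`amplitude` must be in [0, 1] (0 switches familiarity off)")
  stop_if(!is_num1(threshold) || threshold < 0 ||
            (amplitude > 0 && threshold >= amplitude),
          "`threshold` must satisfy 0 <= threshold < amplitude")
  structure(
    list(
      route_direction = route_direction,
      directional_bias = directional_bias,
      directional_noise_sd = directional_noise_sd,
      tuning_kappa = tuning_kappa,
      amplitude = amplitude,
      threshold = threshold
    ),
    class = "cx_familiarity"
  )
}

#' @export
print.cx_familiarity <- function(x, ...) {
  cat("<cx_familiarity> route ", x$route_direction, " deg; bias ",
      x$directional_bias, " deg, noise sd ", x$directional_noise_sd,
      " deg, kappa ", x$tuning_kappa, ", threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

# raw tuning curve value at angular distance `delta` from the (shifted) peak
familiarity_tuning <- function(delta, kappa) exp(kappa * (cos_deg(delta) - 1))

# deterministic kernel: familiarity of one side given its (noise-shifted)
# tuning centre; thresholded to zero below cfg$threshold
familiarity_value <- function(heading, center, cfg) {
  raw <- cfg$amplitude * familiarity_tuning(heading - center, cfg$tuning_kappa)
  if (raw >= cfg$threshold) raw else 0
}

#' Sample the lateralised familiarity signals at a heading
#'
#' Draws fresh, independent Gaussian shifts for the left and right tuning
#' centres, evaluates the tuning curve at the current heading, and zeroes
#' values below the configured threshold.
#'
#' @param heading current allocentric heading, degrees.
#' @param cfg a [familiarity_config()].
#' @param noise optional length-2 vector of the left and right centre shifts
#'   in degrees (for reproducible replay); `NULL` draws them from
#'   `Normal(0, directional_noise_sd)`.
#' @return a list with `f_left`, `f_right` (each in `[0, amplitude]`) and
#'   `noise_draws` (the two shifts used).
#' @examples
#' withr::with_seed(1, sample_familiarity(45, familiarity_config()))
#' @export
sample_familiarity <- function(heading, cfg = familiarity_config(), noise = NULL) {
  stop_if(!is_num1(heading), "`heading` must be a single finite number (degrees)")
  eps <- noise %||% rnorm(2, 0, cfg$directional_noise_sd)
  stop_if(length(eps) != 2 || any(!is.finite(eps)),
          "`noise` must be two finite centre shifts (degrees)")
  center_left  <- cfg$route_direction + cfg$directional_bias + eps[1]
  center_right <- cfg$route_direction - cfg$directional_bias - eps[2]
  list(
    f_left  = familiarity_value(heading, center_left, cfg),
    f_right = familiarity_value(heading, center_right, cfg),
    noise_draws = eps
  )
}

#' Expected familiarity response curves
#'
#' The analytic expectation of the left and right familiarity signals over the
#' Gaussian directional-noise shift, computed by numerical integration
#' (Gauss-type quadrature on a +/- 6 SD grid). The expected left curve peaks
#' at `route_direction + directional_bias`, the right curve symmetrically.
#'
#' @param cfg a [familiarity_config()].
#' @param headings headings (degrees) at which to evaluate the curves.
#' @param n_nodes number of quadrature nodes for the noise integral.
#' @return a tibble with columns `heading`, `f_left`, `f_right`.
#' @examples
#' curve <- mean_response_curve(familiarity_config(), seq(-180, 179, 3))
#' curve$heading[which.max(curve$f_left)]
#' @export
mean_response_curve <- function(cfg = familiarity_config(),
                                headings = seq(-180, 179, by = 1),
                                n_nodes = 201) {
  stop_if(!is.numeric(headings) || !all(is.finite(headings)),
          "`headings` must be finite numbers (degrees)")
  s <- cfg$directional_noise_sd
  if (s == 0) {
    eps <- 0
    w <- 1
  } else {
    eps <- seq(-6 * s, 6 * s, length.out = n_nodes)
    w <- dnorm(eps, 0, s)
    w <- w / sum(w)
  }
  expect_side <- function(center_mean, sign_eps) {
    # centre = center_mean + sign_eps * eps; threshold applied inside the
    # expectation (the threshold acts on each sampled value, not on the mean)
    vapply(headings, function(h) {
      raw <- cfg$amplitude *
        familiarity_tuning(h - (center_mean + sign_eps * eps), cfg$tuning_kappa)
      sum(w * ifelse(raw >= cfg$threshold, raw, 0))
    }, numeric(1))
  }
  tibble(
    heading = headings,
    f_left  = expect_side(cfg$route_direction + cfg$directional_bias, +1),
    f_right = expect_side(cfg$route_direction - cfg$directional_bias, -1)
  )
}
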