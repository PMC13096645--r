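#' Specification for a synthetic trackball cohort
#'
#' Emulates open-loop trackball recordings of individuals fixed in eight
#' compass orientations on a familiar route: each (individual, orientation)
#' trace is a constant expected angular velocity whose sign points toward the
#' route (goal to the right of the body = positive/rightward), plus smooth
#' AR(1) noise. When the body faces the route or anti-route direction the
#' expected sign is the individual's fixed side bias ("left or right,
#' depending on individuals"). Ground-truth labels are emitted alongside the
#' traces so sign-recovery by the metrics pipeline can be scored.
#'
#' @param n_individuals number of individuals.
#' @param orientations body orientations, degrees (default the 8 compass
#'   directions at 45-degree spacing).
#' @param route_direction allocentric route direction, degrees.
#' @param mean_turn_speed expected absolute angular velocity, degrees/s.
#' @param noise_sd marginal SD of the AR(1) noise, degrees/s (SNR =
#'   `mean_turn_speed / noise_sd`).
#' @param ar_coef AR(1) coefficient of the noise at the sampling rate (0.8 at
#'   10 Hz gives behaviourally smooth traces).
#' @param duration trace duration, seconds.
#' @param rate sampling rate, Hz.
#' @param seed RNG seed.
#' @return a `cx_trackball_spec` list.
#' @export
trackball_spec <- function(n_individuals = 17,
                           orientations = seq(0, 315, by = 45),
                           route_direction = 0,
                           mean_turn_speed = 20,
                           noise_sd = 10,
                           ar_coef = 0.8,
                           duration = 12,
                           rate = 10,
                           seed = 1) {
  stop_if(!is_num1(n_individuals) || n_individuals < 1, "`n_individuals` must be >= 1")
  stop_if(!is.numeric(orientations) || length(orientations) < 1,
          "`orientations` must be a non-empty numeric vector")
  stop_if(!is_num1(rate) || rate <= 0, "`rate` must be > 0")
  stop_if(!is_num1(duration) || duration <= 0, "`duration` must be > 0")
  stop_if(!is_num1(mean_turn_speed) || mean_turn_speed < 0,
          "`mean_turn_speed` must be >= 0")
  stop_if(!is_num1(noise_sd) || noise_sd < 0, "`noise_sd` must be >= 0")
  stop_if(!is_num1(ar_coef) || abs(ar_coef) >= 1, "`ar_coef` must be in (-1, 1)")
  structure(
    list(
      n_individuals = as.integer(n_individuals),
      orientations = orientations,
      route_direction = route_direction,
      mean_turn_speed = mean_turn_speed,
      noise_sd = noise_sd,
      ar_coef = ar_coef,
      duration = duration,
      rate = rate,
      seed = seed
    ),
    class = "cx_trackball_spec"
  )
}

# AR(1) series with marginal SD `sd_marg`, stationary start
ar1_noise <- function(n, sd_marg, rho) {
  if (sd_marg == 0) return(numeric(n))
  innov_sd <- sd_marg * sqrt(1 - rho^2)
  x <- numeric(n)
  x[1] <- rnorm(1, 0, sd_marg)
  e <- rnorm(n - 1, 0, innov_sd)
  for (i in seq_len(n - 1)) x[i + 1] <- rho * x[i] + e[i]
  x
}

# expected turn sign at a body orientation: +1 if the route lies clockwise
# (to the right) of the body axis, -1 if counter-clockwise, side bias at the
# aligned/anti-aligned orientations
expected_turn_sign <- function(orientation, route_direction, side_bias) {
  d <- wrap_deg(route_direction - orientation)
  if (d == 0 || d == 180) side_bias else sign(d)
}

#' Generate a synthetic trackball cohort
#'
#' @param spec a [trackball_spec()].
#' @return a `cx_synth_cohort` tibble with one row per (individual,
#'   orientation): `individual`, `orientation`, `expected_sign`, `side_bias`
#'   (the ground-truth labels) and `trace`, a list column of
#'   `time`/`omega` tibbles satisfying the angular-velocity trace contract.
#' @examples
#' coh <- gen_trackball_cohort(trackball_spec(n_individuals = 2, seed = 3))
#' coh$expected_sign
#' @export
gen_trackball_cohort <- function(spec = trackball_spec()) {
  gen_cohort_impl(spec, familiar = TRUE)
}

#' Generate a synthetic cohort recorded in unfamiliar surroundings
#'
#' Same generator as [gen_trackball_cohort()] but the expected turn sign of
#' every trace is an independent random sign, with no dependence on body
#' orientation: individuals remain side-biased but the scene carries no
#' directional information.
#'
#' @inheritParams gen_trackball_cohort
#' @return see [gen_trackball_cohort()].
#' @export
gen_unfamiliar_cohort <- function(spec = trackball_spec()) {
  gen_cohort_impl(spec, familiar = FALSE)
}

gen_cohort_impl <- function(spec, familiar) {
  stop_if(!inherits(spec, "cx_trackball_spec"), "`spec` must come from trackball_spec()")
  withr::with_seed(spec$seed, {
    n_samp <- floor(spec$duration * spec$rate) + 1
    time <- (seq_len(n_samp) - 1) / spec$rate
    side_bias <- sample(c(-1, 1), spec$n_individuals, replace = TRUE)
    rows <- tidyr::expand_grid(
      individual = seq_len(spec$n_individuals),
      orientation = spec$orientations
    )
    rows$side_bias <- side_bias[rows$individual]
    rows$expected_sign <- if (familiar) {
      map_dbl(seq_len(nrow(rows)), function(i) {
        expected_turn_sign(rows$orientation[i], spec$route_direction, rows$side_bias[i])
      })
    } else {
      sample(c(-1, 1), nrow(rows), replace = TRUE)
    }
    rows$trace <- map(rows$expected_sign, function(sgn) {
      tibble(time = time,
             omega = sgn * spec$mean_turn_speed +
               ar1_noise(n_samp, spec$noise_sd, spec$ar_coef))
    })
    out <- dplyr::relocate(rows, "individual", "orientation", "expected_sign",
                           "side_bias", "trace")
    attr(out, "spec") <- spec
    attr(out, "familiar") <- familiar
    class(out) <- c("cx_synth_cohort", class(out))
    out
  })
}

#' Export a (perturbed) simulated homing path as a path table
#'
#' Bridges the closed-loop simulator and the path-metrics input format: runs
#' one trial (optionally with a mid-path celestial rotation) and exports the
#' position track, including the start point, subsampled at a fixed stride.
#'
#' @inheritParams run_trial
#' @param stride sampling stride in steps (1 keeps every step).
#' @return a tibble with columns `time` (step index), `x`, `y`; the trial
#'   record is attached as attribute `"record"`.
#' @examples
#' p <- gen_perturbed_path(trial = trial_config(n_steps = 60, rotation_deg = 135,
#'                                              rotation_step = 30, seed = 1))
#' nrow(p)
#' @export
gen_perturbed_path <- function(circuit = circuit_config(),
                               familiarity = familiarity_config(),
                               trial = trial_config(),
                               stride = 1) {
  stop_if(!is_num1(stride) || stride < 1 || stride %% 1 != 0,
          "`stride` must be a positive integer")
  rec <- run_trial(circuit, familiarity, trial)
  start <- attr(rec, "start")$position
  steps <- seq(stride, trial$n_steps, by = stride)
  out <- tibble(
    time = c(0, steps),
    x = c(start[1], rec$x[steps]),
    y = c(start[2], rec$y[steps])
  )
  attr(out, "record") <- rec
  out
}
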