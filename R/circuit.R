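#' Configure the central-complex steering circuit
#'
#' The circuit is discretised into `n_columns` angular columns spanning 360
#' degrees, mirroring the columnar organisation of the protocerebral bridge and
#' fan-shaped body. Three layers are modelled: a compass bump over the columns
#' (current heading, possibly shifted by a celestial-cue rotation), a pair of
#' left/right goal-field banks that decay each step and are charged by
#' lateralised familiarity input at an anatomical column offset, and a steering
#' comparison that reads the goal field against laterally shifted copies of the
#' compass bump to produce a signed turn command.
#'
#' @param n_columns number of compass columns (even, >= 4). The default 8 gives
#'   45 degrees per column, so a 135-degree celestial rotation is exactly a
#'   3-column bump shift.
#' @param anatomical_offset_cols column offset (per hemisphere) at which
#'   familiarity input writes into the goal field; 1 column = one column
#'   spacing, i.e. the +/-45 degree lateral offsets of the velocity-style
#'   inputs the circuit is built around.
#' @param pfl_offset_cols column offset used by the steering comparison stage.
#' @param decay per-step goal-field decay lambda in `[0, 1]`; each update
#'   multiplies both banks by `1 - decay` before adding input.
#' @param gain dimensionless steering gain.
#' @param motor_noise_sd standard deviation of per-step Gaussian motor noise,
#'   degrees/step.
#' @param turn_scale degrees mapped from a fully lateralised (normalised
#'   difference = 1) steering drive; together with the mass-normalised drive
#'   quotient this keeps the dynamics invariant to goal-field amplitude. The
#'   default 60 is calibrated so that a compass/goal mismatch produces an
#'   immediate, clearly supra-baseline veer followed by recovery (the
#'   celestial-rotation dynamics); see the methods vignette.
#' @param turn_cap hard cap on the absolute per-step turn command, degrees.
#' @param bump_kernel shape of the compass bump: `"cosine"` (half-wave
#'   rectified cosine, the default) or `"vonmises"` (exponential-cosine with
#'   concentration `kernel_kappa`). Any single-peaked symmetric kernel
#'   supports the same circuit properties.
#' @param kernel_kappa concentration of the `"vonmises"` kernel.
#' @return a `cx_circuit` configuration list with the derived
#'   `column_spacing` (= 360 / n_columns) filled in.
#' @examples
#' cfg <- circuit_config()
#' cfg$column_spacing
#' @export
circuit_config <- function(n_columns = 8,
                           anatomical_offset_cols = 1,
                           pfl_offset_cols = 1,
                           decay = 0.2,
                           gain = 1,
                           motor_noise_sd = 10,
                           turn_scale = 60,
                           turn_cap = 90,
                           bump_kernel = c("cosine", "vonmises"),
                           kernel_kappa = 2) {
  bump_kernel <- match.arg(bump_kernel)
  stop_if(!is_num1(n_columns) || n_columns < 4 || n_columns %% 2 != 0,
          "`n_columns` must be a single even integer >= 4, got %s", toString(n_columns))
  stop_if(!is_num1(decay) || decay < 0 || decay > 1,
          "`decay` must be in [0, 1], got %s", toString(decay))
  stop_if(!is_num1(motor_noise_sd) || motor_noise_sd < 0,
          "`motor_noise_sd` must be a non-negative number")
  stop_if(!is_num1(gain), "`gain` must be a single finite number")
  stop_if(!is_num1(turn_scale) || turn_scale <= 0, "`turn_scale` must be > 0")
  stop_if(!is_num1(turn_cap) || turn_cap <= 0, "`turn_cap` must be > 0")
  stop_if(!is_num1(anatomical_offset_cols), "`anatomical_offset_cols` must be a number")
  stop_if(!is_num1(pfl_offset_cols), "`pfl_offset_cols` must be a number")
  stop_if(!is_num1(kernel_kappa) || kernel_kappa <= 0, "`kernel_kappa` must be > 0")
  structure(
    list(
      n_columns = as.integer(n_columns),
      column_spacing = 360 / n_columns,
      anatomical_offset_cols = as.integer(anatomical_offset_cols),
      pfl_offset_cols = as.integer(pfl_offset_cols),
      decay = decay,
      gain = gain,
      motor_noise_sd = motor_noise_sd,
      turn_scale = turn_scale,
      turn_cap = turn_cap,
      bump_kernel = bump_kernel,
      kernel_kappa = kernel_kappa
    ),
    class = "cx_circuit"
  )
}

#' @export
print.cx_circuit <- function(x, ...) {
  cat("<cx_circuit> ", x$n_columns, " columns x ", x$column_spacing,
      " deg; decay ", x$decay, ", gain ", x$gain,
      ", motor noise ", x$motor_noise_sd, " deg/step, kernel ",
      x$bump_kernel, "\n", sep = "")
  invisible(x)
}

# preferred direction of column j (1-based): (j - 1) * spacing
preferred_directions <- function(cfg) (seq_len(cfg$n_columns) - 1) * cfg$column_spacing

# bare-vector bump over the columns, peak normalised to 1
bump_values <- function(heading_apparent, cfg) {
  d <- cos_deg(heading_apparent - preferred_directions(cfg))
  v <- switch(cfg$bump_kernel,
    cosine   = pmax(0, d),
    vonmises = exp(cfg$kernel_kappa * (d - 1))
  )
  v / max(v)
}

# circular rotation of column values: positive k moves the bump k columns
# toward larger preferred directions (clockwise)
shift_columns <- function(values, k) {
  n <- length(values)
  values[((seq_len(n) - 1 - k) %% n) + 1]
}

#' Map a celestial-cue rotation onto an integer compass-bump shift
#'
#' Rotations of the celestial reference (e.g. displacing the apparent sun) are
#' implemented as an integer shift of the heading bump across compass columns,
#' quantised to the nearest column. With the default 8-column circuit a
#' 135-degree rotation is exactly a 3-column shift.
#'
#' @param rotation_deg rotation of the celestial cue, degrees.
#' @param cfg a [circuit_config()].
#' @return integer number of columns.
#' @examples
#' celestial_rotation_cells(135, circuit_config())
#' @export
celestial_rotation_cells <- function(rotation_deg, cfg = circuit_config()) {
  stop_if(!is_num1(rotation_deg), "`rotation_deg` must be a single finite number")
  as.integer(round(rotation_deg / cfg$column_spacing))
}

#' Encode a heading as a compass-column activity bump
#'
#' Produces the columnar activity of the compass layer for a given allocentric
#' heading, optionally shifted by an integer number of columns to emulate a
#' rotated celestial reference. Activity is a half-wave rectified cosine (or
#' von-Mises-shaped) bump over the columns' preferred directions, peak
#' normalised to 1.
#'
#' @param heading allocentric heading, degrees.
#' @param rotation_cells integer bump shift applied to the encoded heading
#'   (celestial rotation), any integer; see [celestial_rotation_cells()].
#' @param cfg a [circuit_config()].
#' @return a `cx_compass` object: list with `values` (length `n_columns`,
#'   non-negative, max 1) and `preferred` (column preferred directions).
#' @examples
#' encode_compass(0, 0, circuit_config())$values
#' @export
encode_compass <- function(heading, rotation_cells = 0, cfg = circuit_config()) {
  stop_if(!is_num1(heading), "`heading` must be a single finite number (degrees)")
  stop_if(!is_num1(rotation_cells) || rotation_cells %% 1 != 0,
          "`rotation_cells` must be an integer")
  ha <- heading + rotation_cells * cfg$column_spacing
  structure(
    list(values = bump_values(ha, cfg), preferred = preferred_directions(cfg)),
    class = "cx_compass"
  )
}

#' Decode a column activity pattern to an angle
#'
#' Population-vector readout: the circular mean of the columns' preferred
#' directions weighted by their activity. For the rectified-cosine bump on an
#' even column grid this inverts [encode_compass()] exactly (up to floating
#' point).
#'
#' @param activity a `cx_compass`, a `cx_goal` bank, or a bare non-negative
#'   numeric vector over equally spaced columns starting at 0 degrees.
#' @return decoded angle in (-180, 180].
#' @examples
#' decode_compass(encode_compass(72))
#' @export
decode_compass <- function(activity) {
  if (inherits(activity, "cx_compass")) {
    v <- activity$values
    phi <- activity$preferred
  } else if (is.numeric(activity)) {
    v <- activity
    phi <- (seq_along(v) - 1) * (360 / length(v))
  } else {
    abort("`activity` must be a cx_compass or a numeric vector")
  }
  stop_if(any(!is.finite(v)) || any(v < 0), "activity must be finite and non-negative")
  stop_if(all(v == 0), "cannot decode an all-zero activity pattern")
  s <- sum(v * sin_deg(phi))
  c_ <- sum(v * cos_deg(phi))
  r <- sqrt(s^2 + c_^2)
  stop_if(r < 1e-9 * sum(v),
          "undefined angle: activity pattern has (near-)zero resultant")
  wrap_deg(atan2(s, c_) * 180 / pi)
}

#' Create an empty goal field
#'
#' The goal field holds two per-hemisphere banks of sustained column activity
#' (left and right); their elementwise sum encodes the allocentric goal
#' heading. Banks decay multiplicatively each update and are charged by
#' lateralised familiarity input.
#'
#' @param cfg a [circuit_config()].
#' @return a `cx_goal` object with zeroed `left` and `right` banks.
#' @export
goal_field <- function(cfg = circuit_config()) {
  z <- numeric(cfg$n_columns)
  structure(list(left = z, right = z), class = "cx_goal")
}

#' @rdname goal_field
#' @param goal a `cx_goal`.
#' @return `goal_combined()`: the elementwise sum of the two banks.
#' @export
goal_combined <- function(goal) goal$left + goal$right

#' Charge and decay the goal field from lateralised familiarity input
#'
#' Each bank first decays by `1 - decay`, then receives the compass bump
#' shifted by the anatomical column offset, scaled by that side's familiarity:
#' the left signal writes a bump displaced counter-clockwise of the current
#' (apparent) heading, the right signal a bump displaced clockwise. A left
#' familiarity peak when the body sits clockwise of the goal therefore writes
#' goal activity back toward the goal, and symmetrically for the right.
#'
#' @param goal a `cx_goal`.
#' @param compass a `cx_compass` for the current (apparent) heading.
#' @param f_left,f_right familiarity drive per hemisphere, each in `[0, 1]`.
#' @param cfg a [circuit_config()].
#' @return the updated `cx_goal`.
#' @examples
#' g <- update_goal(goal_field(), encode_compass(0), 1, 0, circuit_config())
#' decode_compass(g$left)
#' @export
update_goal <- function(goal, compass, f_left, f_right, cfg = circuit_config()) {
  stop_if(!is_num1(f_left) || f_left < 0 || f_left > 1,
          "`f_left` must be in [0, 1], got %s", toString(f_left))
  stop_if(!is_num1(f_right) || f_right < 0 || f_right > 1,
          "`f_right` must be in [0, 1], got %s", toString(f_right))
  keep <- 1 - cfg$decay
  k <- cfg$anatomical_offset_cols
  goal$left  <- keep * goal$left  + f_left  * shift_columns(compass$values, -k)
  goal$right <- keep * goal$right + f_right * shift_columns(compass$values, +k)
  goal
}

#' Steering comparison between goal field and compass bump
#'
#' The combined goal field is compared with two laterally shifted copies of
#' the compass bump (the comparison-stage offsets): the overlap with the
#' clockwise-shifted copy drives right turns, the counter-clockwise copy left
#' turns. The signed turn command is the gain-scaled, mass-normalised drive
#' difference plus Gaussian motor noise, capped at `turn_cap`.
#'
#' @param goal a `cx_goal`.
#' @param compass a `cx_compass`.
#' @param cfg a [circuit_config()].
#' @param noise motor-noise draw in degrees; `NULL` (default) draws one from
#'   `Normal(0, motor_noise_sd)` using the current RNG stream.
#' @return a `cx_steer` list: `drive_left`, `drive_right`, `turn_deg`
#'   (positive = right/clockwise turn).
#' @examples
#' st <- steer(update_goal(goal_field(), encode_compass(90), 1, 1),
#'             encode_compass(0), noise = 0)
#' st$turn_deg > 0
#' @export
steer <- function(goal, compass, cfg = circuit_config(), noise = NULL) {
  stop_if(length(goal$left) != length(compass$values),
          "goal field and compass have different column counts")
  combined <- goal_combined(goal)
  k <- cfg$pfl_offset_cols
  drive_right <- sum(combined * shift_columns(compass$values, +k))
  drive_left  <- sum(combined * shift_columns(compass$values, -k))
  eta <- noise %||% rnorm(1, 0, cfg$motor_noise_sd)
  turn <- cfg$gain * cfg$turn_scale *
    (drive_right - drive_left) / (drive_right + drive_left + 1e-9) + eta
  turn <- max(-cfg$turn_cap, min(cfg$turn_cap, turn))
  structure(
    list(drive_left = drive_left, drive_right = drive_right, turn_deg = turn),
    class = "cx_steer"
  )
}
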