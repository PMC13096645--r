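#' Configure a closed-loop trial
#'
#' A trial steps an agent through familiarity sampling, goal-field update,
#' steering, and kinematics: the turn command is applied to the heading first,
#' then the agent advances one step of `step_length` along the new heading.
#' An optional celestial-cue rotation (applied from `rotation_step` onward) is
#' quantised to an integer compass-column shift.
#'
#' @param n_steps number of steps (default 200).
#' @param step_length distance advanced per step, arbitrary spatial units.
#' @param initial_heading starting heading in degrees; `NULL` (default) means
#'   route direction + 90 degrees, so the agent must acquire the goal from
#'   familiarity input alone.
#' @param initial_position length-2 numeric `(x, y)` start position.
#' @param rotation_deg celestial-cue rotation in degrees (0 = none).
#' @param rotation_step step index from which the rotation is active, in
#'   `[0, n_steps]`; `NA` disables the rotation.
#' @param seed RNG seed for the trial; `NULL` uses the current RNG stream.
#' @param record_goal if `TRUE`, per-step snapshots of the combined goal field
#'   are kept as an attribute of the trial record (for diagnostics).
#' @return a `cx_trial_config` list.
#' @export
trial_config <- function(n_steps = 200,
                         step_length = 1,
                         initial_heading = NULL,
                         initial_position = c(0, 0),
                         rotation_deg = 0,
                         rotation_step = NA,
                         seed = NULL,
                         record_goal = FALSE) {
  stop_if(!is_num1(n_steps) || n_steps < 1, "`n_steps` must be >= 1")
  stop_if(!is_num1(step_length) || step_length <= 0, "`step_length` must be > 0")
  stop_if(!is.null(initial_heading) && !is_num1(initial_heading),
          "`initial_heading` must be NULL or a finite number")
  stop_if(length(initial_position) != 2 || !all(is.finite(initial_position)),
          "`initial_position` must be two finite coordinates")
  stop_if(!is_num1(rotation_deg), "`rotation_deg` must be a finite number")
  if (!is.na(rotation_step)) {
    stop_if(!is_num1(rotation_step) || rotation_step < 0 || rotation_step > n_steps,
            "`rotation_step` must lie in [0, n_steps]")
  }
  structure(
    list(
      n_steps = as.integer(n_steps),
      step_length = step_length,
      initial_heading = initial_heading,
      initial_position = as.numeric(initial_position),
      rotation_deg = rotation_deg,
      rotation_step = if (is.na(rotation_step)) NA_integer_ else as.integer(rotation_step),
      seed = seed,
      record_goal = isTRUE(record_goal)
    ),
    class = "cx_trial_config"
  )
}

#' Run one closed-loop trial
#'
#' Per step: encode the compass bump at the current heading (with the
#' rotation-cell shift if the celestial rotation is active), sample the
#' lateralised familiarity signals at the current heading, charge/decay the
#' goal field, compute the steering command, turn, then advance one step.
#' Fully reproducible from the trial seed.
#'
#' @param circuit a [circuit_config()].
#' @param familiarity a [familiarity_config()].
#' @param trial a [trial_config()].
#' @return a `cx_trial` tibble with one row per step: `step`, `heading` (after
#'   the turn), `x`, `y` (after the step), `f_left`, `f_right`, `turn_deg`,
#'   `rotation_on`. Attributes carry the three configs and the start state.
#' @examples
#' rec <- run_trial(trial = trial_config(n_steps = 50, seed = 1))
#' glance(rec)
#' @export
run_trial <- function(circuit = circuit_config(),
                      familiarity = familiarity_config(),
                      trial = trial_config()) {
  stop_if(!inherits(circuit, "cx_circuit"), "`circuit` must come from circuit_config()")
  stop_if(!inherits(familiarity, "cx_familiarity"),
          "`familiarity` must come from familiarity_config()")
  stop_if(!inherits(trial, "cx_trial_config"), "`trial` must come from trial_config()")
  run <- function() run_trial_impl(circuit, familiarity, trial)
  if (is.null(trial$seed)) run() else withr::with_seed(trial$seed, run())
}

run_trial_impl <- function(circuit, familiarity, trial) {
  n <- trial$n_steps
  heading <- trial$initial_heading %||% (familiarity$route_direction + 90)
  heading <- wrap_deg(heading)
  pos <- trial$initial_position
  rot_cells_full <- celestial_rotation_cells(trial$rotation_deg, circuit)
  rot_from <- trial$rotation_step

  # all noise drawn up front so the step loop is pure given the draws
  eps_l <- rnorm(n, 0, familiarity$directional_noise_sd)
  eps_r <- rnorm(n, 0, familiarity$directional_noise_sd)
  eta <- rnorm(n, 0, circuit$motor_noise_sd)

  phi <- preferred_directions(circuit)
  k_in <- circuit$anatomical_offset_cols
  k_out <- circuit$pfl_offset_cols
  keep <- 1 - circuit$decay
  left <- right <- numeric(circuit$n_columns)

  headings <- xs <- ys <- fl <- fr <- turns <- numeric(n)
  rot_on <- logical(n)
  goal_snap <- if (trial$record_goal) matrix(0, n, circuit$n_columns) else NULL

  for (t in seq_len(n)) {
    active <- !is.na(rot_from) && t >= rot_from
    rot_on[t] <- active && rot_cells_full != 0
    cells <- if (active) rot_cells_full else 0L
    cv <- bump_values(heading + cells * circuit$column_spacing, circuit)

    f_l <- familiarity_value(
      heading, familiarity$route_direction + familiarity$directional_bias + eps_l[t],
      familiarity
    )
    f_r <- familiarity_value(
      heading, familiarity$route_direction - familiarity$directional_bias - eps_r[t],
      familiarity
    )
    left <- keep * left + f_l * shift_columns(cv, -k_in)
    right <- keep * right + f_r * shift_columns(cv, +k_in)

    combined <- left + right
    d_r <- sum(combined * shift_columns(cv, +k_out))
    d_l <- sum(combined * shift_columns(cv, -k_out))
    turn <- circuit$gain * circuit$turn_scale * (d_r - d_l) / (d_r + d_l + 1e-9) + eta[t]
    turn <- max(-circuit$turn_cap, min(circuit$turn_cap, turn))

    heading <- wrap_deg(heading + turn)
    pos <- pos + trial$step_length * c(cos_deg(heading), sin_deg(heading))

    headings[t] <- heading; xs[t] <- pos[1]; ys[t] <- pos[2]
    fl[t] <- f_l; fr[t] <- f_r; turns[t] <- turn
    if (trial$record_goal) goal_snap[t, ] <- combined
  }

  out <- tibble(
    step = seq_len(n), heading = headings, x = xs, y = ys,
    f_left = fl, f_right = fr, turn_deg = turns, rotation_on = rot_on
  )
  attr(out, "circuit") <- circuit
  attr(out, "familiarity") <- familiarity
  attr(out, "trial") <- trial
  attr(out, "start") <- list(
    heading = wrap_deg(trial$initial_heading %||% (familiarity$route_direction + 90)),
    position = trial$initial_position
  )
  if (trial$record_goal) attr(out, "goal_field") <- goal_snap
  class(out) <- c("cx_trial", class(out))
  out
}

#' Run a cohort of independently seeded trials
#'
#' @inheritParams run_trial
#' @param n_agents number of agents (>= 1).
#' @param base_seed seed for agent 1; agent `i` uses `base_seed + i - 1`.
#' @return a `cx_cohort` tibble: the row-bound trial records with a leading
#'   `agent` column. Configs and seeds are carried as attributes.
#' @examples
#' coh <- run_cohort(trial = trial_config(n_steps = 20), n_agents = 3, base_seed = 7)
#' dplyr::count(coh, agent)
#' @export
run_cohort <- function(circuit = circuit_config(),
                       familiarity = familiarity_config(),
                       trial = trial_config(),
                       n_agents = 20,
                       base_seed = 1) {
  stop_if(!is_num1(n_agents) || n_agents < 1, "`n_agents` must be >= 1")
  stop_if(!is_num1(base_seed), "`base_seed` must be a single number")
  seeds <- base_seed + seq_len(n_agents) - 1
  recs <- map(seq_len(n_agents), function(i) {
    tr <- trial
    tr$seed <- seeds[i]
    rec <- run_trial(circuit, familiarity, tr)
    rec$agent <- i
    rec
  })
  out <- list_rbind(map(recs, as_tibble))
  out <- dplyr::relocate(out, "agent")
  attr(out, "circuit") <- circuit
  attr(out, "familiarity") <- familiarity
  attr(out, "trial") <- trial
  attr(out, "seeds") <- seeds
  attr(out, "start") <- attr(recs[[1]], "start")
  class(out) <- c("cx_cohort", class(out))
  out
}

#' Start-to-end directional error of a trial record
#'
#' Absolute angular error between the start-to-arrival chord of the recorded
#' path and the start-to-goal (route) direction, in `[0, 180]` degrees.
#'
#' @param record a `cx_trial` from [run_trial()].
#' @param goal_direction goal direction in degrees; defaults to the trial's
#'   route direction.
#' @return error in degrees.
#' @export
trial_directional_error <- function(record, goal_direction = NULL) {
  stop_if(!inherits(record, "cx_trial"), "`record` must be a cx_trial")
  goal <- goal_direction %||% attr(record, "familiarity")$route_direction
  start <- attr(record, "start")$position
  end <- c(record$x[nrow(record)], record$y[nrow(record)])
  chord <- end - start
  stop_if(sqrt(sum(chord^2)) == 0, "zero displacement: direction undefined")
  ang_dist(atan2(chord[2], chord[1]) * 180 / pi, goal)
}

#' @exportS3Method generics::glance
glance.cx_trial <- function(x, ...) {
  fam <- attr(x, "familiarity")
  tibble(
    n_steps = nrow(x),
    final_heading = x$heading[nrow(x)],
    directional_error = trial_directional_error(x),
    mean_abs_turn = mean(abs(x$turn_deg)),
    prop_familiarity_silent = mean(x$f_left == 0 & x$f_right == 0),
    route_direction = fam$route_direction
  )
}
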