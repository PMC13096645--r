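#' Directional-bias by directional-noise robustness sweep
#'
#' Runs seeded closed-loop trials over a grid of familiarity directional
#' biases and directional noise levels and summarises, per cell, the
#' start-to-end directional error after `n_steps` steps. Three regimes emerge
#' along the bias axis: stable route following for positive bias, stable
#' following of the opposite direction for negative bias, and a labile
#' high-variance zone around zero bias.
#'
#' @param bias_grid directional biases to test, degrees.
#' @param noise_grid directional noise SDs to test, degrees.
#' @param circuit a [circuit_config()].
#' @param familiarity a [familiarity_config()]; its bias and noise fields are
#'   overwritten cell by cell.
#' @param reps seeded repetitions per cell.
#' @param n_steps steps per trial.
#' @param base_seed base seed; each (cell, rep) derives its own seed
#'   deterministically from it.
#' @return a `cx_sweep` tibble: `bias`, `noise`, `mean_error`, `sd_error`,
#'   `reps` (errors in degrees, in `[0, 180]`).
#' @examples
#' sw <- sweep_bias_noise(c(-45, 45), 10, reps = 3, n_steps = 50, base_seed = 1)
#' sw
#' @export
sweep_bias_noise <- function(bias_grid = seq(-90, 90, by = 5),
                             noise_grid = seq(0, 60, by = 5),
                             circuit = circuit_config(),
                             familiarity = familiarity_config(),
                             reps = 20,
                             n_steps = 200,
                             base_seed = 1) {
  stop_if(length(bias_grid) < 1 || length(noise_grid) < 1, "grids must be non-empty")
  stop_if(!is_num1(reps) || reps < 1, "`reps` must be >= 1")
  cells <- tidyr::expand_grid(bias = bias_grid, noise = noise_grid)
  res <- pmap(list(cells$bias, cells$noise, seq_len(nrow(cells))), function(b, s, i) {
    fam <- familiarity
    fam$directional_bias <- b
    fam$directional_noise_sd <- s
    errs <- vapply(seq_len(reps), function(r) {
      tr <- trial_config(n_steps = n_steps, seed = sweep_seed(base_seed, i, r))
      trial_directional_error(run_trial(circuit, fam, tr))
    }, numeric(1))
    tibble(bias = b, noise = s, mean_error = mean(errs),
           sd_error = sd(errs), reps = as.integer(reps))
  })
  out <- list_rbind(res)
  attr(out, "circuit") <- circuit
  attr(out, "familiarity") <- familiarity
  attr(out, "base_seed") <- base_seed
  attr(out, "n_steps") <- n_steps
  class(out) <- c("cx_sweep", class(out))
  out
}

# deterministic per-(cell, rep) seed kept inside 32-bit integer range
sweep_seed <- function(base_seed, cell, rep) {
  (as.numeric(base_seed) + 7919 * cell + rep) %% 2147483647
}

#' Celestial-rotation cohort experiment
#'
#' Runs a cohort of agents along an established route, applies a celestial-cue
#' rotation (an integer compass-bump shift) at `rotation_step`, subsamples each
#' path every `segment_stride` steps, and summarises per segment index (aligned
#' on rotation onset, onset junction = index 0) the cohort's bearings relative
#' to the route and the absolute turn angles between successive segments.
#'
#' Agents start aligned with the route (they are retracing a familiar route),
#' so the pre-onset window reflects steady-state route following.
#'
#' @param circuit a [circuit_config()].
#' @param familiarity a [familiarity_config()].
#' @param n_agents number of simulated agents.
#' @param rotation_deg rotation of the celestial cue, degrees (e.g. 135).
#' @param rotation_step step at which the rotation switches on; must be a
#'   multiple of `segment_stride` so the onset falls on a segment junction.
#' @param segment_stride steps per path segment for the discretisation.
#' @param n_steps steps per trial.
#' @param base_seed cohort base seed.
#' @param initial_heading starting heading; defaults to the route direction.
#' @return a `cx_rotation` tibble with one row per segment index: `index`
#'   (segments relative to onset), `bearing_mean`, `bearing_se` (circular,
#'   relative to route = 0), `turn_mean`, `turn_se` (absolute turn angles),
#'   `n`. The underlying cohort record is attached as attribute `"cohort"`.
#' @examples
#' rs <- sun_rotation_experiment(n_agents = 3, n_steps = 60, rotation_step = 30,
#'                               base_seed = 2)
#' head(rs)
#' @export
sun_rotation_experiment <- function(circuit = circuit_config(),
                                    familiarity = familiarity_config(),
                                    n_agents = 20,
                                    rotation_deg = 135,
                                    rotation_step = 120,
                                    segment_stride = 3,
                                    n_steps = 300,
                                    base_seed = 1,
                                    initial_heading = NULL) {
  stop_if(!is_num1(segment_stride) || segment_stride < 1, "`segment_stride` must be >= 1")
  stop_if(rotation_step %% segment_stride != 0,
          "`rotation_step` must be a multiple of `segment_stride`")
  stop_if(floor(n_steps / segment_stride) < 2, "fewer than 2 segments: increase n_steps")
  stop_if(rotation_step > n_steps - segment_stride,
          "`rotation_step` must leave at least one post-onset segment")
  # the cue rotates between step `rotation_step` and `rotation_step + 1`, so
  # the onset falls exactly on the segment junction labelled index 0
  trial <- trial_config(
    n_steps = n_steps,
    initial_heading = initial_heading %||% familiarity$route_direction,
    rotation_deg = rotation_deg,
    rotation_step = rotation_step + 1
  )
  cohort <- run_cohort(circuit, familiarity, trial, n_agents, base_seed)
  start <- attr(cohort, "start")$position
  route <- familiarity$route_direction

  seg <- cohort |>
    dplyr::group_by(.data$agent) |>
    dplyr::group_map(function(d, key) {
      steps <- seq(segment_stride, n_steps, by = segment_stride)
      vx <- c(start[1], d$x[steps])
      vy <- c(start[2], d$y[steps])
      bearing <- atan2(diff(vy), diff(vx)) * 180 / pi
      turn <- abs(wrap_deg(diff(bearing)))
      end_step <- steps
      tibble(
        agent = key$agent,
        bearing_index = (end_step - rotation_step) / segment_stride,
        bearing_rel = wrap_deg(bearing - route),
        # junction between segment i and i+1 sits at the end of segment i
        turn_index = c((end_step[-length(end_step)] - rotation_step) / segment_stride, NA),
        turn_angle = c(turn, NA)
      )
    }) |>
    list_rbind()

  bearings <- seg |>
    dplyr::group_by(index = .data$bearing_index) |>
    dplyr::summarise(
      bearing_mean = circular_mean_se(.data$bearing_rel)$mean,
      bearing_se = circular_mean_se(.data$bearing_rel)$se,
      n = dplyr::n(), .groups = "drop"
    )
  turns <- seg |>
    dplyr::filter(!is.na(.data$turn_index)) |>
    dplyr::group_by(index = .data$turn_index) |>
    dplyr::summarise(
      turn_mean = mean(.data$turn_angle),
      turn_se = sd(.data$turn_angle) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  out <- dplyr::full_join(bearings, turns, by = "index") |>
    dplyr::arrange(.data$index) |>
    dplyr::relocate("index", "bearing_mean", "bearing_se", "turn_mean", "turn_se", "n")
  attr(out, "cohort") <- cohort
  attr(out, "rotation_deg") <- rotation_deg
  attr(out, "rotation_step") <- rotation_step
  attr(out, "segment_stride") <- segment_stride
  class(out) <- c("cx_rotation", class(out))
  out
}

#' Phase markers of the rotation response
#'
#' Operationalises the qualitative phases of the cohort's response to a
#' celestial rotation: (i) a pre-onset baseline of the cohort-mean absolute
#' per-step turn; (ii) the signed deflection summed over the first
#' `onset_window` post-onset steps; (iii) the mean latency of the first
#' corrective turn (opposite sign to the onset deflection, above the step
#' baseline + 2 SD); (iv) a meandering window; and (v) the restabilisation
#' step at which it ends.
#'
#' Per-step absolute turns are dominated by motor noise, which hides the
#' conflict phase; the meander window is therefore detected on the
#' segment-level turn-angle series (paths discretised every `segment_stride`
#' steps, as in [sun_rotation_experiment()]): post-onset segment indices whose
#' cohort-mean turn angle exceeds the pre-onset segment baseline + 2 SD,
#' chained from the onset with a tolerance of `gap` below-threshold segments,
#' so isolated noise exceedances far from the onset never count.
#'
#' @param cohort a `cx_cohort` from [run_cohort()] (or the `"cohort"`
#'   attribute carried by [sun_rotation_experiment()] results).
#' @param rotation_step onset junction (last unrotated step); defaults to the
#'   cohort's trial config (`rotation_step - 1`, since the trial applies the
#'   rotation from its `rotation_step` onward).
#' @param baseline_window number of pre-onset steps used for the baselines.
#' @param onset_window steps after onset summed for the deflection marker.
#' @param segment_stride steps per segment for the meander series.
#' @param gap segments the meander chain may skip below threshold.
#' @return a one-row tibble: `baseline_mean`, `baseline_sd` (per-step),
#'   `seg_threshold` (segment-level), `onset_sign`, `onset_magnitude`,
#'   `corrective_latency` (steps), `meander_length` and
#'   `restabilisation_step` (steps after onset; 0 / `NA` when no meander
#'   window is detected).
#' @export
phase_report <- function(cohort,
                         rotation_step = NULL,
                         baseline_window = 60,
                         onset_window = 3,
                         segment_stride = 3,
                         gap = 2) {
  stop_if(!inherits(cohort, "cx_cohort"), "`cohort` must come from run_cohort()")
  trial_rstep <- attr(cohort, "trial")$rotation_step
  junction <- rotation_step %||% (if (is.null(trial_rstep) || is.na(trial_rstep)) NA else trial_rstep - 1)
  stop_if(is.na(junction), "no rotation step recorded or supplied")
  n_steps <- max(cohort$step)
  stop_if(junction < baseline_window + 1, "not enough pre-onset steps for the baseline")

  # cohort-mean per-step turns
  m <- cohort |>
    dplyr::group_by(.data$step) |>
    dplyr::summarise(abs_turn = mean(abs(.data$turn_deg)),
                     signed_turn = mean(.data$turn_deg), .groups = "drop")
  base_idx <- (junction - baseline_window + 1):junction
  baseline_mean <- mean(m$abs_turn[base_idx])
  baseline_sd <- sd(m$abs_turn[base_idx])
  step_threshold <- baseline_mean + 2 * baseline_sd

  onset_idx <- (junction + 1):min(n_steps, junction + onset_window)
  onset_magnitude <- sum(m$signed_turn[onset_idx])
  onset_sign <- sign(onset_magnitude)

  # per-agent first corrective turn after onset
  latency <- cohort |>
    dplyr::filter(.data$step > junction) |>
    dplyr::group_by(.data$agent) |>
    dplyr::summarise(lat = {
      hit <- which(sign(.data$turn_deg) == -onset_sign & abs(.data$turn_deg) > step_threshold)
      if (length(hit)) .data$step[hit[1]] - junction else NA_real_
    }, .groups = "drop")
  corrective_latency <- mean(latency$lat, na.rm = TRUE)

  # segment-level turn-angle series aligned on the onset junction
  start <- attr(cohort, "start")$position
  seg <- cohort |>
    dplyr::group_by(.data$agent) |>
    dplyr::group_map(function(d, key) {
      vsteps <- seq(junction %% segment_stride, n_steps, by = segment_stride)
      vx <- ifelse(vsteps == 0, start[1], d$x[pmax(vsteps, 1)])
      vy <- ifelse(vsteps == 0, start[2], d$y[pmax(vsteps, 1)])
      bearing <- atan2(diff(vy), diff(vx)) * 180 / pi
      tibble(index = (vsteps[-c(1, length(vsteps))] - junction) / segment_stride,
             turn = abs(wrap_deg(diff(bearing))))
    }) |>
    list_rbind() |>
    dplyr::group_by(.data$index) |>
    dplyr::summarise(turn = mean(.data$turn), .groups = "drop")
  pre <- seg$turn[seg$index < 0 & seg$index >= -floor(baseline_window / segment_stride)]
  seg_threshold <- mean(pre) + 2 * sd(pre)
  post <- seg[seg$index >= 0, ]
  exceed <- post$index[post$turn > seg_threshold]
  if (length(exceed) && min(exceed) <= 1) {
    last <- min(exceed)
    for (i in exceed[-1]) {
      if (i - last <= gap + 1) last <- i else break
    }
    meander_length <- (last + 1) * segment_stride
    restabilisation_step <- (last + 1) * segment_stride
  } else {
    meander_length <- 0
    restabilisation_step <- NA_real_
  }
  tibble(
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    seg_threshold = seg_threshold,
    onset_sign = onset_sign,
    onset_magnitude = onset_magnitude,
    corrective_latency = corrective_latency,
    meander_length = meander_length,
    restabilisation_step = restabilisation_step
  )
}
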