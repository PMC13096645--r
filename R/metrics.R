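#' Turn ratio of an angular-velocity trace
#'
#' `(right - left) / (right + left)`, where `right` and `left` are the time
#' integrals of absolute angular velocity over the periods spent turning right
#' (omega > 0) and left (omega < 0). The integral is the exact integral of the
#' piecewise-linear interpolant of the recorded samples, split at interpolated
#' zero crossings, so it is consistent with trapezoidal integration away from
#' sign changes. Positive omega = right turn.
#'
#' @param trace a data frame with numeric columns `time` (strictly
#'   increasing, seconds) and `omega` (degrees/second, signed).
#' @return a number in `[-1, 1]`; 0 when the trace never turns.
#' @examples
#' turn_ratio(tibble::tibble(time = 0:12, omega = 10))
#' @export
turn_ratio <- function(trace) {
  v <- validate_trace(trace)
  parts <- signed_area_parts(v$time, v$omega)
  if (parts$pos + parts$neg == 0) return(0)
  (parts$pos - parts$neg) / (parts$pos + parts$neg)
}

#' Proportion of turning time spent on the preferred side
#'
#' The preferred side is the side (left or right) on which the trace spends
#' the larger total turning time; the value is that side's fraction of the
#' total turning time, computed on the piecewise-linear interpolant with
#' intervals split at zero crossings. Ties (and traces that never turn)
#' return 0.5. Invariant under a global sign flip of omega.
#'
#' @inheritParams turn_ratio
#' @return a number in `[0.5, 1]`.
#' @export
preferred_side_proportion <- function(trace) {
  v <- validate_trace(trace)
  parts <- signed_area_parts(v$time, v$omega)
  total <- parts$t_pos + parts$t_neg
  if (total == 0) return(0.5)
  max(parts$t_pos, parts$t_neg) / total
}

validate_trace <- function(trace) {
  stop_if(!is.data.frame(trace) || !all(c("time", "omega") %in% names(trace)),
          "trace must be a data frame with columns `time` and `omega`")
  stop_if(nrow(trace) < 1, "trace is empty")
  t <- as.numeric(trace$time); w <- as.numeric(trace$omega)
  stop_if(any(!is.finite(t)) || any(!is.finite(w)), "trace contains non-finite values")
  stop_if(any(diff(t) <= 0), "trace `time` must be strictly increasing")
  list(time = t, omega = w)
}

# integral of |piecewise-linear interpolant| split by sign, plus the time
# spent on each sign (intervals split exactly at interpolated zero crossings)
signed_area_parts <- function(t, w) {
  pos <- neg <- t_pos <- t_neg <- 0
  for (i in seq_len(length(t) - 1)) {
    t1 <- t[i]; t2 <- t[i + 1]; w1 <- w[i]; w2 <- w[i + 1]
    dt <- t2 - t1
    if (w1 >= 0 && w2 >= 0) {
      pos <- pos + (w1 + w2) / 2 * dt
      if (w1 > 0 || w2 > 0) t_pos <- t_pos + dt
    } else if (w1 <= 0 && w2 <= 0) {
      neg <- neg - (w1 + w2) / 2 * dt
      if (w1 < 0 || w2 < 0) t_neg <- t_neg + dt
    } else {
      tc <- dt * w1 / (w1 - w2)          # time from t1 to the zero crossing
      a1 <- w1 / 2 * tc                  # signed triangle before the crossing
      a2 <- w2 / 2 * (dt - tc)           # signed triangle after the crossing
      if (a1 >= 0) { pos <- pos + a1; t_pos <- t_pos + tc }
      else { neg <- neg - a1; t_neg <- t_neg + tc }
      if (a2 >= 0) { pos <- pos + a2; t_pos <- t_pos + (dt - tc) }
      else { neg <- neg - a2; t_neg <- t_neg + (dt - tc) }
    }
  }
  list(pos = pos, neg = neg, t_pos = t_pos, t_neg = t_neg)
}

#' Discretise a 2-D path at a fixed arc length
#'
#' Resamples the path by linear interpolation at cumulative arc lengths
#' `0, L, 2L, ...` (the trailing remainder shorter than `L` is discarded) and
#' computes per-segment allocentric bearings and per-junction absolute turn
#' angles, the discretisation used to compare real and simulated paths.
#'
#' @param path a data frame with numeric columns `x` and `y` (a `time` or
#'   step column may be present but is ignored).
#' @param resample_length arc length `L` between successive vertices, in the
#'   path's spatial units (e.g. 12 cm for digitised ant paths, 3 steps for
#'   simulated agents).
#' @return a `cx_segments` tibble with one row per vertex: `vertex`, `s`
#'   (cumulative arc length), `x`, `y`, `bearing` (degrees, of the segment
#'   leaving this vertex; `NA` on the last vertex), `turn_angle` (absolute
#'   turn at this junction in `[0, 180]`; `NA` on the first and last vertex).
#' @examples
#' p <- tibble::tibble(x = c(0, 24, 24), y = c(0, 0, 24))
#' discretise_path(p, 12)
#' @export
discretise_path <- function(path, resample_length) {
  stop_if(!is.data.frame(path) || !all(c("x", "y") %in% names(path)),
          "path must be a data frame with columns `x` and `y`")
  stop_if(!is_num1(resample_length) || resample_length <= 0,
          "`resample_length` must be > 0")
  x <- as.numeric(path$x); y <- as.numeric(path$y)
  stop_if(any(!is.finite(x)) || any(!is.finite(y)), "path contains non-finite coordinates")
  stop_if(length(x) < 2, "path needs at least 2 points")
  seglen <- sqrt(diff(x)^2 + diff(y)^2)
  keep <- c(TRUE, seglen > 0)            # drop exactly repeated points
  x <- x[keep]; y <- y[keep]
  s <- c(0, cumsum(sqrt(diff(x)^2 + diff(y)^2)))
  total <- s[length(s)]
  stop_if(total < 2 * resample_length,
          "path too short: total length %.6g < 2 * resample_length = %.6g",
          total, 2 * resample_length)
  targets <- seq(0, floor(total / resample_length) * resample_length,
                 by = resample_length)
  vx <- approx(s, x, xout = targets)$y
  vy <- approx(s, y, xout = targets)$y
  bearing <- c(atan2(diff(vy), diff(vx)) * 180 / pi, NA)
  turn <- c(NA, abs(wrap_deg(diff(bearing[-length(bearing)]))), NA)
  out <- tibble(
    vertex = seq_along(targets), s = targets, x = vx, y = vy,
    bearing = bearing, turn_angle = turn
  )
  attr(out, "resample_length") <- resample_length
  class(out) <- c("cx_segments", class(out))
  out
}

#' Directional error of a path relative to a goal direction
#'
#' Absolute angular difference between the start-to-arrival chord of the path
#' and the goal direction, in `[0, 180]` degrees.
#'
#' @inheritParams discretise_path
#' @param goal_direction allocentric goal direction, degrees.
#' @return error in degrees.
#' @examples
#' directional_error(tibble::tibble(x = c(0, 1), y = c(0, 1)), 0)
#' @export
directional_error <- function(path, goal_direction) {
  stop_if(!is.data.frame(path) || !all(c("x", "y") %in% names(path)),
          "path must be a data frame with columns `x` and `y`")
  stop_if(!is_num1(goal_direction), "`goal_direction` must be a finite number")
  n <- nrow(path)
  stop_if(n < 2, "path needs at least 2 points")
  dx <- path$x[n] - path$x[1]
  dy <- path$y[n] - path$y[1]
  stop_if(dx == 0 && dy == 0, "start and end coincide: direction undefined")
  ang_dist(atan2(dy, dx) * 180 / pi, goal_direction)
}

#' Circular mean and standard error of angles
#'
#' The circular mean is the direction of the resultant vector; the standard
#' error is the circular standard deviation `sqrt(-2 log Rbar)` (converted to
#' degrees) divided by `sqrt(n)`. If `ids` are supplied, angles are first
#' averaged (circularly) within each id and the summary taken across ids, the
#' usual treatment for repeated measures per individual.
#'
#' @param angles angles in degrees.
#' @param ids optional grouping vector (e.g. individual), same length.
#' @return a list with `mean` (degrees, in (-180, 180]), `se` (degrees) and
#'   `n` (number of angles, or of ids).
#' @examples
#' circular_mean_se(c(10, 350))
#' @export
circular_mean_se <- function(angles, ids = NULL) {
  stop_if(!is.numeric(angles) || any(!is.finite(angles)),
          "`angles` must be finite numbers (degrees)")
  if (!is.null(ids)) {
    stop_if(length(ids) != length(angles), "`ids` must match `angles` in length")
    per_id <- vapply(split(angles, ids),
                     function(a) circ_mean(a)$mean, numeric(1))
    angles <- unname(per_id)
  }
  stop_if(length(angles) < 2, "need at least 2 angles (or 2 ids)")
  cm <- circ_mean(angles)
  stop_if(cm$rbar < 1e-12, "undefined circular mean: resultant length is 0")
  # identical angles give rbar = 1 up to summation error; snap so SE is 0
  rbar <- if (cm$rbar > 1 - 1e-14) 1 else cm$rbar
  csd <- sqrt(pmax(0, -2 * log(rbar))) * 180 / pi
  list(mean = cm$mean, se = csd / sqrt(length(angles)), n = length(angles))
}

circ_mean <- function(angles) {
  s <- mean(sin_deg(angles))
  c_ <- mean(cos_deg(angles))
  rbar <- sqrt(s^2 + c_^2)
  m <- if (rbar < 1e-12) NA_real_ else wrap_deg(atan2(s, c_) * 180 / pi)
  list(mean = m, rbar = rbar)
}

#' Exact Wilcoxon signed-rank test
#'
#' Exact p-value of the one-sample Wilcoxon signed-rank statistic, computed
#' from the full null distribution over all `2^n` sign assignments of the
#' ranked absolute values (evaluated by subset-sum dynamic programming, which
#' enumerates the same distribution without materialising the `2^n` patterns;
#' ties are handled with midranks). Zeros are dropped before ranking, the
#' classical treatment.
#'
#' @param values numeric observations (e.g. per-individual mean angular
#'   velocities); the null is symmetry about zero.
#' @param alternative `"greater"` (location > 0), `"less"`, or `"two_sided"`
#'   (twice the smaller one-sided p, capped at 1).
#' @return a list: `p`, `statistic` (sum of positive ranks `V`), `n` (after
#'   dropping zeros).
#' @examples
#' signed_rank_exact(c(3, 1, 4, 1.5, 5, 9), "greater")$p  # 1/64
#' @export
signed_rank_exact <- function(values, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  stop_if(!is.numeric(values) || any(!is.finite(values)),
          "`values` must be finite numbers")
  v <- values[values != 0]
  stop_if(length(v) == 0, "all values are zero: test undefined")
  n <- length(v)
  stop_if(n > 25, "exact enumeration supported for n <= 25 (after dropping zeros), got %d", n)
  r2 <- as.integer(round(2 * rank(abs(v))))  # doubled midranks are integers
  w_obs <- sum(r2[v > 0])
  # null distribution of the (doubled) positive-rank sum: dist[k + 1] =
  # number of sign assignments with statistic k
  dist <- numeric(sum(r2) + 1)
  dist[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), dist[seq_len(length(dist) - r)])
    dist <- dist + shifted
  }
  total <- 2^n
  p_greater <- sum(dist[(w_obs + 1):length(dist)]) / total
  p_less <- sum(dist[1:(w_obs + 1)]) / total
  p <- switch(alternative,
    greater = p_greater,
    less = p_less,
    two_sided = min(1, 2 * min(p_greater, p_less))
  )
  list(p = p, statistic = w_obs / 2, n = n)
}
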