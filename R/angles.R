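#' Angle helpers (degrees, compass sign convention)
#'
#' All angles in this package are in degrees and wrapped to the half-open
#' interval (-180, 180]. Positive differences mean clockwise / to the right of
#' the reference direction, matching the sign convention used for angular
#' velocities (positive = right turn) throughout.
#'
#' @param x numeric vector of angles in degrees.
#' @return `wrap_deg()`: angles wrapped to (-180, 180]. `cos_deg()`,
#'   `sin_deg()`: the trigonometric values of angles given in degrees.
#' @examples
#' wrap_deg(c(270, -180, 180, 725))
#' @export
wrap_deg <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' @rdname wrap_deg
#' @export
cos_deg <- function(x) cospi(x / 180)

#' @rdname wrap_deg
#' @export
sin_deg <- function(x) sinpi(x / 180)

# absolute angular difference in [0, 180]
ang_dist <- function(a, b) abs(wrap_deg(a - b))

stop_if <- function(cond, ...) {
  if (cond) abort(sprintf(...))
  invisible(NULL)
}

is_num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
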