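#' Read and write angular-velocity traces and path tables
#'
#' Traces and paths are plain comma-separated text with a header row naming
#' the columns (`time, omega` for traces; `time, x, y` for paths, `time` may
#' be a step index). Column order is free (matched by name), lines starting
#' with `#` are comments, and values round-trip at full double precision.
#' Malformed files are rejected with the offending row and column named.
#'
#' @param path file path.
#' @param trace,pathtab the data frame to write.
#' @return the read functions return a tibble; the write functions return
#'   `path` invisibly.
#' @export
read_trace <- function(path) {
  d <- read_delim_checked(path, c("time", "omega"))
  stop_if(any(diff(d$time) <= 0),
          "%s: `time` not strictly increasing at data row %d",
          path, which(diff(d$time) <= 0)[1] + 1)
  d
}

#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  v <- validate_trace(trace)
  write_csv_precise(tibble(time = v$time, omega = v$omega), path)
  invisible(path)
}

# 17 significant digits round-trip IEEE doubles exactly
write_csv_precise <- function(d, path) {
  chr <- as_tibble(lapply(d, function(col) sprintf("%.17g", col)))
  readr::write_csv(chr, path)
}

#' @rdname read_trace
#' @export
read_path <- function(path) {
  read_delim_checked(path, c("time", "x", "y"))
}

#' @rdname read_trace
#' @export
write_path <- function(pathtab, path) {
  stop_if(!is.data.frame(pathtab) || !all(c("time", "x", "y") %in% names(pathtab)),
          "path table must have columns `time`, `x`, `y`")
  write_csv_precise(tibble(time = as.numeric(pathtab$time),
                           x = as.numeric(pathtab$x),
                           y = as.numeric(pathtab$y)), path)
  invisible(path)
}

read_delim_checked <- function(path, required) {
  stop_if(!file.exists(path), "file not found: %s", path)
  # columns come in as text and are parsed with base strtod (correctly
  # rounded), so writing 17 significant digits round-trips doubles bitwise
  d <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(required, names(d))
  stop_if(length(missing) > 0, "%s: missing column(s): %s",
          path, paste(missing, collapse = ", "))
  d <- d[required]
  for (col in required) {
    v <- d[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    stop_if(length(bad) > 0,
            "%s: non-numeric value in column `%s` at data row %d (value: %s)",
            path, col, bad[1], v[bad[1]])
    bad_na <- which(is.na(num))
    stop_if(length(bad_na) > 0, "%s: missing value in column `%s` at data row %d",
            path, col, bad_na[1])
    d[[col]] <- num
  }
  stop_if(nrow(d) < 1, "%s: no data rows", path)
  as_tibble(d)
}

#' Read a run configuration file
#'
#' A single YAML file with optional blocks `circuit`, `familiarity`, `trial`,
#' `sweep`, `rotation`, `synth`, plus top-level `seed` and `out_dir`. Each
#' block is validated by its owning constructor; unknown top-level keys and
#' unknown fields inside a block are rejected.
#'
#' @param path YAML file path.
#' @return a `cx_run_config` list with constructed config objects.
#' @export
read_run_config <- function(path) {
  stop_if(!file.exists(path), "config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  raw <- raw %||% list()
  allowed <- c("circuit", "familiarity", "trial", "sweep", "rotation", "synth",
               "seed", "out_dir")
  unknown <- setdiff(names(raw), allowed)
  stop_if(length(unknown) > 0, "unknown config key(s): %s",
          paste(unknown, collapse = ", "))
  build <- function(block, ctor) {
    args <- raw[[block]] %||% list()
    tryCatch(do.call(ctor, args), error = function(e) {
      abort(sprintf("invalid `%s` block: %s", block, conditionMessage(e)))
    })
  }
  check_keys <- function(block, allowed_keys) {
    extra <- setdiff(names(raw[[block]] %||% list()), allowed_keys)
    stop_if(length(extra) > 0, "unknown key(s) in `%s` block: %s",
            block, paste(extra, collapse = ", "))
    raw[[block]] %||% list()
  }
  structure(
    list(
      circuit = build("circuit", circuit_config),
      familiarity = build("familiarity", familiarity_config),
      trial = build("trial", trial_config),
      sweep = check_keys("sweep", c("bias_grid", "noise_grid", "reps", "n_steps")),
      rotation = check_keys("rotation", c("n_agents", "rotation_deg", "rotation_step",
                                          "segment_stride", "n_steps")),
      synth = build("synth", trackball_spec),
      seed = raw$seed %||% 1,
      out_dir = raw$out_dir %||% "."
    ),
    class = "cx_run_config"
  )
}

#' @rdname read_run_config
#' @param config a `cx_run_config` (or plain nested list) to serialise.
#' @export
write_run_config <- function(config, path) {
  ser <- lapply(unclass(config), function(x) {
    if (is.list(x)) unclass(x) else x
  })
  # drop non-serialisable nulls (e.g. unset seeds) so the echo stays clean
  ser <- lapply(ser, function(x) if (is.list(x)) x[!vapply(x, is.null, logical(1))] else x)
  yaml::write_yaml(ser, path)
  invisible(path)
}
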