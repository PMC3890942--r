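#' Environment configuration for the perceptual crossing paradigm
#'
#' Bundles every geometric and temporal constant of the paradigm: a
#' wrap-around 1D space in which each player moves a small avatar, with a
#' "shadow" object rigidly attached to each avatar at a fixed offset and one
#' static object per player. All lengths are in environment units, all times
#' in the units stated per argument.
#'
#' @param space_length Length of the circular space in units.
#' @param body_length Length of every object (avatar, shadow, static) in units.
#' @param shadow_offset Rigid displacement from an avatar to its shadow, units.
#' @param sample_period Recording period in ms (10 ms = 100 Hz).
#' @param trial_duration Trial length in seconds.
#' @param target_range Half-width in units of the window used to attribute a
#'   click to an object; an object is "within range" when the absolute wrapped
#'   displacement between avatar centers is at most this value.
#' @param click_lookback Time in seconds before a click at which positions are
#'   sampled for target attribution.
#' @param tt_window Length in seconds of the window preceding a click over
#'   which turn-taking is scored.
#' @param move_threshold Per-step displacement in units above which a player
#'   counts as moving (defaults to an eighth of the body length).
#' @param min_pause_steps Minimum run of sub-threshold steps (in samples) for
#'   a pause to count as genuine non-movement rather than a micro-pause.
#'
#' @return An object of class `env_config` (a named list).
#' @examples
#' cfg <- env_config()
#' n_steps(cfg)
#' @export
env_config <- function(space_length = 600,
                       body_length = 4,
                       shadow_offset = 150,
                       sample_period = 10,
                       trial_duration = 60,
                       target_range = 70,
                       click_lookback = 1,
                       tt_window = 10,
                       move_threshold = body_length / 8,
                       min_pause_steps = 50) {
  cfg <- structure(
    list(
      space_length = as.numeric(space_length),
      body_length = as.numeric(body_length),
      shadow_offset = as.numeric(shadow_offset),
      sample_period = as.numeric(sample_period),
      trial_duration = as.numeric(trial_duration),
      target_range = as.numeric(target_range),
      click_lookback = as.numeric(click_lookback),
      tt_window = as.numeric(tt_window),
      move_threshold = as.numeric(move_threshold),
      min_pause_steps = as.integer(min_pause_steps)
    ),
    class = "env_config"
  )
  validate_env_config(cfg)
}

validate_env_config <- function(cfg) {
  stopifnot(is.list(cfg))
  if (!is.finite(cfg$space_length) || cfg$space_length <= 0) {
    stop("`space_length` must be a positive finite number.", call. = FALSE)
  }
  if (cfg$body_length <= 0) {
    stop("`body_length` must be positive.", call. = FALSE)
  }
  if (cfg$shadow_offset >= cfg$space_length) {
    stop("`shadow_offset` must be smaller than `space_length`.", call. = FALSE)
  }
  if (2 * cfg$target_range >= cfg$shadow_offset) {
    stop(
      "2 * `target_range` must be smaller than `shadow_offset`; otherwise an ",
      "avatar and its shadow could both be attributable for one click.",
      call. = FALSE
    )
  }
  steps <- cfg$trial_duration * 1000 / cfg$sample_period
  if (abs(steps - round(steps)) > 1e-9) {
    stop("`trial_duration` must be an integer number of sample periods.",
      call. = FALSE
    )
  }
  if (cfg$min_pause_steps < 1) {
    stop("`min_pause_steps` must be at least 1.", call. = FALSE)
  }
  cfg
}

#' @describeIn env_config Number of recorded steps in one trial.
#' @export
n_steps <- function(cfg) {
  as.integer(round(cfg$trial_duration * 1000 / cfg$sample_period))
}

#' @export
print.env_config <- function(x, ...) {
  cat("<env_config>\n")
  for (nm in names(x)) cat(sprintf("  %-16s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write an environment configuration as YAML
#'
#' The configuration is serialized as a flat key/value mapping; any key left
#' out of the file takes its [env_config()] default.
#'
#' @param path File path.
#' @param cfg An `env_config` object.
#' @return `read_env_config()` returns an `env_config`;
#'   `write_env_config()` returns `path` invisibly.
#' @export
read_env_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(env_config))
  extra <- setdiff(names(vals), known)
  if (length(extra) > 0) {
    stop("Unknown configuration key(s): ", paste(extra, collapse = ", "),
      call. = FALSE
    )
  }
  do.call(env_config, vals)
}

#' @rdname read_env_config
#' @export
write_env_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Circular-space arithmetic
#'
#' `wrap_position()` maps any real position into `[0, L)`.
#' `signed_displacement()` returns the minimal-magnitude signed offset taking
#' `a` to `b` on the circle, in `(-L/2, L/2]` (a tie at exactly half the
#' circumference resolves to `+L/2`). `objects_overlap()` tests whether two
#' equal-length objects at the given centre positions touch, i.e. whether the
#' absolute wrapped displacement is strictly less than the body length.
#'
#' @param x,a,b Positions (vectorized).
#' @param L Space length, positive.
#' @param cfg An [env_config()].
#' @return Numeric (positions/offsets) or logical vector.
#' @examples
#' wrap_position(610, 600)
#' signed_displacement(0, 450, 600)
#' objects_overlap(598, 1, env_config())
#' @export
wrap_position <- function(x, L) {
  if (!is.numeric(L) || any(!is.finite(L)) || any(L <= 0)) {
    stop("Space length `L` must be positive and finite.", call. = FALSE)
  }
  x %% L
}

#' @rdname wrap_position
#' @export
signed_displacement <- function(a, b, L) {
  d <- wrap_position(b - a, L)
  ifelse(d > L / 2, d - L, d)
}

#' @rdname wrap_position
#' @export
objects_overlap <- function(a, b, cfg) {
  abs(signed_displacement(a, b, cfg$space_length)) < cfg$body_length
}
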