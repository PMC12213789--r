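#' Default simulation configuration
#'
#' Returns the full nested configuration with every tunable of the model.
#' The default experimental conditions are: a square field
#' holding 50 objects of each of four colors placed uniformly at random,
#' color-numbers 8/2/1/-1 for red/green/yellow/blue, a vision cone of pi
#' radians split over 8 receptors, 28 initial goal neurons in Mode 4 and
#' 1000 in Modes 1-3.
#'
#' @section Sections:
#' * `field`: `side_length` (field units), `n_per_color`, `color_numbers`
#'   (named list; red/green/yellow positive, blue negative),
#'   `organism_radius`, `vision_angle` (radians), `n_receptors`,
#'   `max_range` (perception range; `Inf` disables the cut-off).
#' * `network`: `n_perceptive`, `n_motor` (even, smaller than the goal
#'   layer), `nc` (connections per unit).
#' * `plasticity`: gates `tact`, `t1`, `t2`; touch factors `k1`, `k2` and
#'   `colr_decay` with `colr_init` (`"color_number"` or `"constant"` plus
#'   `colr_const`); reinforcement rate `kb`; growth parameters `p`
#'   (donor-1 copy probability, in (0.5, 1]), `df` (memory increment),
#'   `t_coherence` (coherence threshold ending a growth event),
#'   `max_goal_neurons` (hard cap).
#' * `sim`: `mode` (1-4), `n_steps`, `seed`, `rotation_step` (radians per
#'   tick when nothing is seen), `k_dx`/`k_dy` (displacement coefficients),
#'   `n_goal` (`NULL` = 28 in Mode 4, 1000 otherwise), `egocentric`
#'   (move in the heading frame instead of world axes), `leap_origin`
#'   (`"initial"`: border leaps aim at the simulation's start position).
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    field = list(
      side_length = 500,
      n_per_color = 50L,
      color_numbers = list(red = 8, green = 2, yellow = 1, blue = -1),
      organism_radius = 10,
      vision_angle = pi,
      n_receptors = 8L,
      max_range = Inf
    ),
    network = list(
      n_perceptive = 16L,
      n_motor = 8L,
      nc = 4L
    ),
    plasticity = list(
      tact = 0.5, t1 = 0.01, t2 = 0.1,
      k1 = 0.05, k2 = 0.05, kb = 0.1,
      colr_decay = 0.99, colr_init = "color_number", colr_const = 1,
      p = 0.7, df = 0.1, t_coherence = 1.0,
      max_goal_neurons = 2500L
    ),
    sim = list(
      mode = 4L,
      n_steps = 5000L,
      seed = 1L,
      rotation_step = pi / 8,
      k_dx = 6, k_dy = 6,
      n_goal = NULL,
      egocentric = FALSE,
      leap_origin = "initial"
    )
  )
}

#' Load and resolve a configuration from JSON
#'
#' Reads a (possibly partial) JSON configuration, fills missing keys from
#' [default_config()], rejects unknown keys, and validates the result. An
#' empty JSON object yields the full default configuration.
#'
#' @param path path to a JSON file.
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  resolve_config(as_config_list(user))
}

# read_json(simplifyVector=) may turn color_numbers into a vector; keep lists.
as_config_list <- function(x) {
  if (is.list(x)) lapply(x, as_config_list) else x
}

#' Resolve a (partial) configuration against the defaults
#'
#' @param config partial nested list; unknown keys are an error.
#' @return Full validated configuration.
#' @export
resolve_config <- function(config = list()) {
  def <- default_config()
  cfg <- merge_config(def, config, path = "")
  # "very large" thresholds by mode; n_goal default depends on the mode
  if (is.null(cfg$sim$n_goal)) {
    cfg$sim$n_goal <- if (cfg$sim$mode == 4L) 28L else 1000L
  }
  validate_config(cfg)
  cfg
}

merge_config <- function(def, user, path) {
  if (!is.list(user)) stop("config section '", path, "' must be an object")
  unknown <- setdiff(names(user), names(def))
  if (length(unknown)) {
    stop("unknown config key: ", paste0(path, unknown, collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(def[[k]]) && !is.null(names(def[[k]]))) {
      def[[k]] <- merge_config(def[[k]], user[[k]], paste0(path, k, "/"))
    } else {
      def[[k]] <- user[[k]]
    }
  }
  def
}

validate_field <- function(f) {
  chk <- function(ok, key, msg) if (!ok) stop("invalid config key 'field/", key, "': ", msg)
  chk(is.numeric(f$side_length) && f$side_length > 0, "side_length", "must be positive")
  chk(f$side_length > 2 * f$organism_radius, "side_length",
      "must exceed twice the organism radius")
  chk(is.numeric(f$n_per_color) && f$n_per_color >= 0, "n_per_color", "must be >= 0")
  chk(identical(sort(names(f$color_numbers)), sort(COLOR_NAMES)),
      "color_numbers", "must name exactly red, green, yellow, blue")
  chk(all(unlist(f$color_numbers[c("red", "green", "yellow")]) > 0),
      "color_numbers", "red/green/yellow must be positive")
  chk(f$color_numbers$blue < 0, "color_numbers", "blue must be negative")
  chk(f$organism_radius > 0, "organism_radius", "must be positive")
  chk(f$vision_angle > 0 && f$vision_angle <= 2 * pi, "vision_angle",
      "must lie in (0, 2*pi]")
  chk(f$n_receptors >= 1, "n_receptors", "must be a positive integer")
  invisible(f)
}

validate_config <- function(cfg) {
  validate_field(cfg$field)
  net <- cfg$network; pl <- cfg$plasticity; sim <- cfg$sim
  chk <- function(ok, key, msg) if (!ok) stop("invalid config key '", key, "': ", msg)
  chk(net$n_perceptive > cfg$field$n_receptors, "network/n_perceptive",
      "must exceed the number of receptors")
  chk(net$n_motor %% 2 == 0 && net$n_motor > 0, "network/n_motor",
      "must be even and positive")
  chk(net$nc >= 1, "network/nc", "must be a positive integer")
  chk(sim$mode %in% 1:4, "sim/mode", "must be 1, 2, 3 or 4")
  chk(sim$n_steps >= 0, "sim/n_steps", "must be non-negative")
  chk(sim$n_goal > net$n_perceptive, "sim/n_goal",
      "goal layer must be larger than the perceptive layer")
  chk(net$n_motor < sim$n_goal, "network/n_motor",
      "must be smaller than the goal layer")
  chk(net$nc < sim$n_goal, "network/nc",
      "recurrent wiring needs nc < number of goal neurons")
  chk(pl$t1 <= pl$t2, "plasticity/t1", "requires t1 <= t2")
  chk(pl$p > 0.5 && pl$p <= 1, "plasticity/p", "must lie in (0.5, 1]")
  chk(pl$df > 0, "plasticity/df", "must be positive (guarantees growth stops)")
  chk(pl$t_coherence > 0, "plasticity/t_coherence", "must be positive")
  chk(pl$colr_decay > 0 && pl$colr_decay < 1, "plasticity/colr_decay",
      "must lie in (0, 1)")
  chk(pl$colr_init %in% c("color_number", "constant"), "plasticity/colr_init",
      "must be 'color_number' or 'constant'")
  chk(pl$max_goal_neurons >= sim$n_goal, "plasticity/max_goal_neurons",
      "must be at least the initial goal-neuron count")
  invisible(cfg)
}
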