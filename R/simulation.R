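#' Effective plasticity gates for a learning mode
#'
#' The four modes open plasticity gates cumulatively by substituting
#' `Inf` ("very large") for the thresholds a mode lacks:
#' Mode 1 `(Inf, Inf, Inf)` - no learning at all;
#' Mode 2 `(tact, Inf, Inf)` - touch learning only;
#' Mode 3 `(tact, t1, Inf)` - touch plus gradient reinforcement;
#' Mode 4 `(tact, t1, t2)` - full plasticity including structural growth.
#'
#' @param mode_id integer 1-4.
#' @param params plasticity parameter list (see [default_config()]).
#' @return The parameter list with substituted gates and a `mode_id`
#'   field, classed `mode_spec`.
#' @export
make_mode <- function(mode_id, params = default_config()$plasticity) {
  if (!length(mode_id) == 1L || !mode_id %in% 1:4)
    stop("unknown mode_id: must be 1, 2, 3 or 4")
  if (mode_id <= 3L) params$t2 <- Inf
  if (mode_id <= 2L) params$t1 <- Inf
  if (mode_id == 1L) params$tact <- Inf
  params$mode_id <- as.integer(mode_id)
  class(params) <- "mode_spec"
  params
}

#' Initialize a simulation state
#'
#' Resolves the configuration, derives the named RNG substreams from the
#' master seed, builds the world (or accepts a fixture world) and the
#' network, and returns a mutable state environment consumed by
#' [sim_step()].
#'
#' @param config (partial) configuration list; see [default_config()].
#' @param world optional pre-built `jca_world` (fixtures); the organism
#'   pose is taken from it.
#' @return Environment of class `organism_sim`.
#' @export
sim_init <- function(config = list(), world = NULL) {
  cfg <- resolve_config(config)
  streams <- make_streams(cfg$sim$seed)
  if (is.null(world)) {
    world <- init_world(cfg$field, streams$world)
  } else {
    stopifnot(inherits(world, "jca_world"))
  }
  net <- init_network(
    n_receptors = cfg$field$n_receptors,
    n_perceptive = cfg$network$n_perceptive,
    n_motor = cfg$network$n_motor,
    nc = cfg$network$nc,
    n_goal = cfg$sim$n_goal,
    max_goal = if (cfg$sim$mode == 4L) cfg$plasticity$max_goal_neurons
               else cfg$sim$n_goal,
    stream = streams$weights
  )
  st <- new.env(parent = emptyenv())
  st$config <- cfg
  st$params <- make_mode(cfg$sim$mode, cfg$plasticity)
  st$world <- world
  st$pose <- world$pose
  st$net <- net
  st$streams <- streams
  st$t <- 0L
  class(st) <- "organism_sim"
  st
}

#' Advance the simulation by one tick
#'
#' The canonical per-tick order: (1) sense; (2) forward pass through the
#' three layers; (3) compute lambda; (4) exactly one lambda-gated action -
#' gradient reinforcement if `t1 < lambda < t2`, structural growth if
#' `lambda > t2`; (5) after growth, re-run the forward pass on the
#' enlarged layer (same t-1 outputs); (6) if no receptor saw an object,
#' rotate by `rotation_step` without translating, otherwise translate by
#' `(DX, DY)` and point the heading along the move; (7) leap if the
#' center reached the border; (8) detect touches, remove touched objects
#' and apply the touch update for each red/green touch.
#'
#' @param st an [sim_init()] state.
#' @return Invisibly, the tick record: `t`, `x`, `y`, `heading`,
#'   `lambda`, `n_goal`, `touches`, `growth` (a `growth_event` or
#'   `NULL`), `rotated`.
#' @export
sim_step <- function(st) {
  st$t <- st$t + 1L
  cfg <- st$config; params <- st$params
  field <- st$world$field

  readings <- sense(st$world, st$pose, field)
  pout <- forward_perceptive(readings, st$net)
  st$net <- forward_goal(st$net, pout, rollover = TRUE)
  st$net <- forward_motor(st$net)
  lam <- compute_lambda(st$net)

  growth <- NULL
  if (lam > params$t2) {
    gr <- grow_goal_neurons(st$net, params, st$streams$growth, tick = st$t)
    st$net <- gr$net
    growth <- gr$event
    st$net <- forward_goal(st$net, pout, rollover = FALSE)
    st$net <- forward_motor(st$net)
  } else if (lam > params$t1 && lam < params$t2) {
    st$net <- reinforcement_update(st$net, params)
  }

  rotated <- !any(readings[, "has_object"] > 0)
  if (rotated) {
    st$pose$heading <- (st$pose$heading + cfg$sim$rotation_step) %% (2 * pi)
  } else {
    d <- motion_from_motor(st$net$mout, cfg$sim$k_dx, cfg$sim$k_dy)
    if (isTRUE(cfg$sim$egocentric)) {
      h <- st$pose$heading
      d <- c(cos(h) * d[1] - sin(h) * d[2], sin(h) * d[1] + cos(h) * d[2])
    }
    p0 <- c(st$pose$x, st$pose$y)
    p1 <- p0 + d
    if (any(d != 0)) st$pose$heading <- atan2(d[2], d[1]) %% (2 * pi)
    L <- field$side_length
    if (p1[1] <= 0 || p1[1] >= L || p1[2] <= 0 || p1[2] >= L) {
      tmp_pose <- st$pose; tmp_pose$x <- p1[1]; tmp_pose$y <- p1[2]
      p1 <- apply_border_leap(tmp_pose, field, st$streams$leaps, prev = p0)
    }
    st$pose$x <- p1[1]; st$pose$y <- p1[2]
  }

  tt <- detect_touches(st$world, st$pose, field)
  st$world <- tt$world
  for (col in tt$colors) {
    st$net <- touch_update(st$net, col, params, field$color_numbers)
  }

  rec <- list(t = st$t, x = st$pose$x, y = st$pose$y,
              heading = st$pose$heading, lambda = lam,
              n_goal = st$net$n_goal, touches = tt$colors,
              growth = growth, rotated = rotated)
  invisible(rec)
}

#' Run a full simulation
#'
#' Executes `n_steps` ticks from a fresh state and collects the
#' disappeared-object counts per color, the lambda series, the position
#' trajectory and all growth events. Identical configuration (including
#' the seed) reproduces the result exactly.
#'
#' @param config (partial) configuration list.
#' @param world optional fixture world (see [sim_init()]).
#' @return Object of class `simulation_result`: `disappeared` (named
#'   per-color counts), `total`, `final_goal_neurons`, `trajectory`
#'   (data frame t/x/y/heading/lambda/n_goal), `touches` (per-tick list),
#'   `growth_events`, `seed`, `mode`, `n_steps`, `config`.
#' @export
run_simulation <- function(config = list(), world = NULL) {
  st <- sim_init(config, world)
  cfg <- st$config
  n <- as.integer(cfg$sim$n_steps)
  init_by_color <- tabulate(st$world$color, nbins = 4L)
  x <- numeric(n); y <- numeric(n); heading <- numeric(n)
  lambda <- numeric(n); n_goal <- integer(n)
  touches <- vector("list", n)
  growth_events <- list()
  for (i in seq_len(n)) {
    rec <- sim_step(st)
    x[i] <- rec$x; y[i] <- rec$y; heading[i] <- rec$heading
    lambda[i] <- rec$lambda; n_goal[i] <- rec$n_goal
    touches[[i]] <- rec$touches
    if (!is.null(rec$growth)) growth_events[[length(growth_events) + 1L]] <- rec$growth
  }
  live_by_color <- tabulate(st$world$color[st$world$alive], nbins = 4L)
  disappeared <- setNames(init_by_color - live_by_color, COLOR_NAMES)
  structure(list(
    disappeared = disappeared,
    total = sum(disappeared),
    final_goal_neurons = st$net$n_goal,
    trajectory = data.frame(t = seq_len(n), x = x, y = y,
                            heading = heading, lambda = lambda,
                            n_goal = n_goal),
    touches = touches,
    growth_events = growth_events,
    seed = cfg$sim$seed,
    mode = cfg$sim$mode,
    n_steps = n,
    config = cfg,
    state = st
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result> Mode ", x$mode, ", seed ", x$seed, ", ",
      x$n_steps, " steps\n", sep = "")
  cat("  disappeared:", paste(names(x$disappeared), x$disappeared,
                              sep = "=", collapse = ", "),
      "(total", x$total, ")\n")
  cat("  final goal neurons:", x$final_goal_neurons,
      "| growth events:", length(x$growth_events), "\n")
  invisible(x)
}

#' Run the batch mode-comparison experiment
#'
#' `n_sims` independent simulations per mode, each with its own derived
#' seed, collecting per-run disappeared counts by color, plus the
#' aggregate per-mode mean counts.
#'
#' @param config base (partial) configuration; `mode` and `seed` are
#'   overridden per run.
#' @param modes integer vector of modes to run.
#' @param n_sims replicate simulations per mode (>= 2).
#' @param seed master seed; run r of mode m uses
#'   `seed + 100000 * (m - 1) + r - 1`.
#' @param quiet suppress per-run progress.
#' @return Data frame of class `experiment_table` with columns `sim_id`,
#'   `mode`, `seed`, `n_steps`, `red`, `green`, `yellow`, `blue`,
#'   `total`, `final_goal_neurons`; the total object count is attached as
#'   attribute `n_objects`.
#' @export
run_experiment <- function(config = list(), modes = 1:4, n_sims = 20L,
                           seed = 1L, quiet = TRUE) {
  if (n_sims < 2L) stop("n_sims must be at least 2")
  rows <- list()
  for (m in modes) {
    for (r in seq_len(n_sims)) {
      cfg <- config
      cfg$sim$mode <- as.integer(m)
      cfg$sim$seed <- as.integer(seed + 100000L * (as.integer(m) - 1L) + r - 1L)
      cfg$sim$n_goal <- NULL  # re-resolve per mode
      res <- run_simulation(cfg)
      if (!quiet) message("mode ", m, " run ", r, ": total ", res$total)
      rows[[length(rows) + 1L]] <- data.frame(
        sim_id = r, mode = as.integer(m), seed = res$seed,
        n_steps = res$n_steps,
        red = res$disappeared[["red"]], green = res$disappeared[["green"]],
        yellow = res$disappeared[["yellow"]], blue = res$disappeared[["blue"]],
        total = res$total, final_goal_neurons = res$final_goal_neurons
      )
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "n_objects") <- 4L * resolve_config(config)$field$n_per_color
  class(tab) <- c("experiment_table", "data.frame")
  tab
}

#' Relocation ("come back") probe
#'
#' Runs a simulation normally; after `relocate_after` ticks the organism
#' is teleported (network untouched) to a random point at distance at
#' least `0.4 * side_length` from its current position, or to `target`
#' if given. The probe then reports whether and when the trajectory
#' re-enters the pre-relocation confinement region - the bounding box of
#' the last [confinement_episodes()] episode before the move (falling
#' back to the bounding box of the last `window` pre-move positions when
#' no episode qualified).
#'
#' @param config (partial) configuration list.
#' @param relocate_after trigger tick (`< n_steps`).
#' @param window,trap_diameter confinement parameters; defaults 200 ticks
#'   and `0.15 * side_length`.
#' @param target optional explicit teleport position `c(x, y)`.
#' @return List of class `return_report`: `returned`, `return_tick`,
#'   `relocate_tick`, `region` (xmin/xmax/ymin/ymax), `pre_episodes`,
#'   `trajectory`, `result` fields from the underlying run.
#' @export
relocation_probe <- function(config = list(), relocate_after = 2500L,
                             window = 200L, trap_diameter = NULL,
                             target = NULL) {
  st <- sim_init(config)
  cfg <- st$config
  n <- as.integer(cfg$sim$n_steps)
  relocate_after <- as.integer(relocate_after)
  if (relocate_after >= n) stop("relocate_after must be below n_steps")
  L <- cfg$field$side_length
  if (is.null(trap_diameter)) trap_diameter <- 0.15 * L

  x <- numeric(n); y <- numeric(n)
  lambda <- numeric(n); n_goal <- integer(n)
  for (i in seq_len(relocate_after)) {
    rec <- sim_step(st)
    x[i] <- rec$x; y[i] <- rec$y; lambda[i] <- rec$lambda; n_goal[i] <- rec$n_goal
  }

  pre <- cbind(x = x[seq_len(relocate_after)], y = y[seq_len(relocate_after)])
  eps <- confinement_episodes(pre, window = window,
                              trap_diameter = trap_diameter)
  region <- if (length(eps)) {
    e <- eps[[length(eps)]]
    seg <- pre[e$start:e$end, , drop = FALSE]
    list(xmin = min(seg[, 1]), xmax = max(seg[, 1]),
         ymin = min(seg[, 2]), ymax = max(seg[, 2]))
  } else {
    seg <- pre[max(1L, relocate_after - window + 1L):relocate_after, ,
               drop = FALSE]
    list(xmin = min(seg[, 1]), xmax = max(seg[, 1]),
         ymin = min(seg[, 2]), ymax = max(seg[, 2]))
  }

  if (is.null(target)) {
    cur <- c(st$pose$x, st$pose$y)
    target <- with_stream(st$streams$relocation, {
      repeat {
        cand <- runif(2, 0, L)
        if (sqrt(sum((cand - cur)^2)) >= 0.4 * L) break
      }
      cand
    })
  }
  st$pose$x <- target[1]; st$pose$y <- target[2]

  returned <- FALSE; return_tick <- NA_integer_
  in_region <- function(px, py) {
    px >= region$xmin && px <= region$xmax &&
      py >= region$ymin && py <= region$ymax
  }
  if (in_region(st$pose$x, st$pose$y)) {
    returned <- TRUE; return_tick <- relocate_after
  }
  for (i in (relocate_after + 1L):n) {
    rec <- sim_step(st)
    x[i] <- rec$x; y[i] <- rec$y; lambda[i] <- rec$lambda; n_goal[i] <- rec$n_goal
    if (!returned && in_region(rec$x, rec$y)) {
      returned <- TRUE; return_tick <- i
    }
  }
  structure(list(
    returned = returned, return_tick = return_tick,
    relocate_tick = relocate_after, region = region,
    pre_episodes = eps,
    trajectory = data.frame(t = seq_len(n), x = x, y = y,
                            lambda = lambda, n_goal = n_goal),
    mode = cfg$sim$mode, seed = cfg$sim$seed,
    final_goal_neurons = st$net$n_goal
  ), class = "return_report")
}

#' @export
print.return_report <- function(x, ...) {
  cat("<return_report> Mode ", x$mode, ", relocated at tick ",
      x$relocate_tick, ": ",
      if (x$returned) paste0("returned at tick ", x$return_tick)
      else "did not return", "\n", sep = "")
  invisible(x)
}
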