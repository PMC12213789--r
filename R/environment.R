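#' Create a world of colored objects and place the organism
#'
#' Builds the square field with `n_per_color` objects of each color at
#' uniform random positions, and places the organism uniformly at random
#' with a uniform random heading; the start position is recorded for the
#' border-leap rule.
#'
#' @param field a `field` configuration section (see [default_config()]).
#' @param stream an [new_rng_stream()] supplying the placement draws.
#' @return A list with class `jca_world`:
#' `field`, object vectors `id`, `color` (integer index into
#' `c("red","green","yellow","blue")`), `colnum`, `x`, `y`, `alive`,
#' and `pose` (the initial [organism pose][sense]).
#' @examples
#' w <- init_world(default_config()$field, new_rng_stream(1))
#' sum(w$alive)  # 200 live objects
#' @export
init_world <- function(field = default_config()$field,
                       stream = new_rng_stream(1L)) {
  validate_field(field)
  n <- as.integer(field$n_per_color)
  ntot <- 4L * n
  L <- field$side_length
  draws <- with_stream(stream, {
    list(x = runif(ntot, 0, L), y = runif(ntot, 0, L),
         org = runif(3))
  })
  color <- rep(seq_along(COLOR_NAMES), each = n)
  pose <- list(
    x = draws$org[1] * L, y = draws$org[2] * L,
    heading = draws$org[3] * 2 * pi,
    start_x = draws$org[1] * L, start_y = draws$org[2] * L
  )
  structure(list(
    field = field,
    id = seq_len(ntot),
    color = color,
    colnum = unlist(field$color_numbers[COLOR_NAMES])[color],
    x = draws$x, y = draws$y,
    alive = rep(TRUE, ntot),
    pose = pose
  ), class = "jca_world")
}

# Construct a world from explicit coordinates (fixtures, tests).
make_world <- function(colors, x, y, field = default_config()$field,
                       pose = NULL) {
  stopifnot(length(colors) == length(x), length(x) == length(y))
  ci <- match(colors, COLOR_NAMES)
  if (anyNA(ci)) stop("unknown color in fixture world")
  if (is.null(pose)) {
    c0 <- field$side_length / 2
    pose <- list(x = c0, y = c0, heading = 0, start_x = c0, start_y = c0)
  }
  structure(list(
    field = field,
    id = seq_along(ci),
    color = ci,
    colnum = unlist(field$color_numbers[COLOR_NAMES])[ci],
    x = as.numeric(x), y = as.numeric(y),
    alive = rep(TRUE, length(ci)),
    pose = pose
  ), class = "jca_world")
}

# wrap an angle to [-pi, pi)
wrap_pi <- function(a) ((a + pi) %% (2 * pi)) - pi

#' Receptor readings for the current pose
#'
#' The organism's vision cone of `vision_angle` radians, centered on the
#' heading, is split into `n_receptors` equal angular sectors. Each
#' receptor reports the Euclidean-nearest live object in its sector as a
#' normalized triple: the object's color-number, `dist_norm = 1/(1+D)` and
#' `ang_norm = 1/(1+A)` where `A` is the absolute angular deviation from
#' the heading in radians. An empty sector reads all zeros. Pure function:
#' no state is modified.
#'
#' @param world a [init_world()] world.
#' @param pose a pose list (`x`, `y`, `heading`, `start_x`, `start_y`);
#'   defaults to the world's stored pose.
#' @param field field configuration; defaults to the world's.
#' @return Numeric matrix `n_receptors` x 4 with columns `color_number`,
#'   `dist_norm`, `ang_norm`, `has_object`.
#' @export
sense <- function(world, pose = world$pose, field = world$field) {
  n_rec <- as.integer(field$n_receptors)
  va <- field$vision_angle
  out <- matrix(0, n_rec, 4L,
                dimnames = list(NULL, c("color_number", "dist_norm",
                                        "ang_norm", "has_object")))
  alive <- world$alive
  if (!any(alive)) return(out)
  dx <- world$x[alive] - pose$x
  dy <- world$y[alive] - pose$y
  d <- sqrt(dx * dx + dy * dy)
  rel <- wrap_pi(atan2(dy, dx) - pose$heading)
  inc <- rel >= -va / 2 & rel < va / 2
  if (is.finite(field$max_range)) inc <- inc & d <= field$max_range
  if (!any(inc)) return(out)
  d <- d[inc]; rel <- rel[inc]
  sec <- pmin(floor((rel + va / 2) / (va / n_rec)) + 1L, n_rec)
  o <- order(sec, d)
  keep <- o[!duplicated(sec[o])]   # nearest object per occupied sector
  cn <- world$colnum[alive][inc][keep]
  out[sec[keep], ] <- cbind(cn, 1 / (1 + d[keep]), 1 / (1 + abs(rel[keep])), 1)
  out
}

#' Touch detection and object removal
#'
#' Every live object strictly closer than `organism_radius` to the
#' organism's center *and* inside the vision cone is touched: it is marked
#' dead and its color reported. Objects behind the organism are never
#' touched, whatever their distance.
#'
#' @inheritParams sense
#' @return A list with the updated `world` and `colors`, the character
#'   vector of touched colors ordered nearest first.
#' @export
detect_touches <- function(world, pose = world$pose, field = world$field) {
  va <- field$vision_angle
  idx <- which(world$alive)
  if (!length(idx)) return(list(world = world, colors = character()))
  dx <- world$x[idx] - pose$x
  dy <- world$y[idx] - pose$y
  d <- sqrt(dx * dx + dy * dy)
  rel <- wrap_pi(atan2(dy, dx) - pose$heading)
  hit <- d < field$organism_radius & abs(rel) <= va / 2
  if (!any(hit)) return(list(world = world, colors = character()))
  hit_idx <- idx[hit][order(d[hit])]
  world$alive[hit_idx] <- FALSE
  list(world = world, colors = COLOR_NAMES[world$color[hit_idx]])
}

# First parameter t in (0, 1] at which the segment p0 -> p1 meets the
# border of [0, L]^2. Assumes p0 is inside and p1 is on/outside.
border_exit_point <- function(p0, p1, L) {
  d <- p1 - p0
  ts <- c(
    if (d[1] > 0) (L - p0[1]) / d[1], if (d[1] < 0) -p0[1] / d[1],
    if (d[2] > 0) (L - p0[2]) / d[2], if (d[2] < 0) -p0[2] / d[2]
  )
  ts <- ts[ts >= 0 & ts <= 1]
  t <- if (length(ts)) min(ts) else 1
  p0 + t * d
}

#' Border leap
#'
#' When the organism's center reaches the field border it leaps to a
#' position drawn uniformly on the straight segment between the
#' border-crossing point and the start position, then is nudged strictly
#' inside the field by a tiny epsilon.
#'
#' @param pose pose whose position is the border-crossing point (or, with
#'   `prev`, the out-of-field position after the move).
#' @param field field configuration.
#' @param stream RNG stream for the leap draw.
#' @param prev optional previous (inside) position `c(x, y)`; when given
#'   and the pose lies outside the field, the crossing point is computed
#'   on the segment `prev -> pose`.
#' @return Numeric `c(x, y)`, strictly inside the field.
#' @export
apply_border_leap <- function(pose, field, stream, prev = NULL) {
  L <- field$side_length
  p <- c(pose$x, pose$y)
  b <- if (!is.null(prev)) border_exit_point(prev, p, L) else pmin(pmax(p, 0), L)
  s <- c(pose$start_x, pose$start_y)
  u <- with_stream(stream, runif(1))
  pos <- b + u * (s - b)
  eps <- 1e-9 * L
  pmin(pmax(pos, eps), L - eps)
}

#' Named deterministic fixture worlds
#'
#' Tiny hand-placed worlds for unit tests and worked examples, each with
#' the organism at the field center heading along +x:
#' * `empty` - no objects; the organism can only rotate.
#' * `single_red` - one red object 3 units dead ahead (receptor reading
#'   `(8, 0.25, 1)` under the defaults).
#' * `red_green_pair` - a red and a green object ahead, symmetric about
#'   the heading.
#' * `ring_trap` - twelve objects of cycling colors encircling the start
#'   position at radius 40, so conflicting pulls confine the organism.
#'
#' @param field field configuration used for every fixture.
#' @return Named list of `jca_world` objects.
#' @export
fixture_worlds <- function(field = default_config()$field) {
  c0 <- field$side_length / 2
  ring_ang <- (0:11) * pi / 6
  list(
    empty = make_world(character(), numeric(), numeric(), field),
    single_red = make_world("red", c0 + 3, c0, field),
    red_green_pair = make_world(c("red", "green"),
                                c(c0 + 10, c0 + 10), c(c0 + 5, c0 - 5), field),
    ring_trap = make_world(rep(COLOR_NAMES, 3),
                           c0 + 40 * cos(ring_ang), c0 + 40 * sin(ring_ang),
                           field)
  )
}

#' @export
print.jca_world <- function(x, ...) {
  cat("<jca_world> ", sum(x$alive), "/", length(x$alive),
      " live objects on a ", x$field$side_length, "-unit square field\n",
      sep = "")
  tab <- table(factor(COLOR_NAMES[x$color[x$alive]], levels = COLOR_NAMES))
  print(tab)
  invisible(x)
}
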