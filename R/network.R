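#' Sigmoid squashing function
#'
#' `squash(x) = 2 / (1 + exp(-x)) - 1`, the odd logistic used by every
#' layer; outputs lie strictly in (-1, 1). To preserve the open interval
#' in floating point the value is clamped away from +/-1 by 1e-12.
#'
#' @param x numeric vector.
#' @return Numeric vector of the same length.
#' @examples
#' squash(0)       # 0
#' squash(log(3))  # 0.5
#' @export
squash <- function(x) {
  y <- 2 / (1 + exp(-x)) - 1
  # 2/(1+exp(-x))-1 only reaches 1-1e-12 beyond |x| ~ 28.3
  if (length(x) && max(abs(x)) > 28) {
    y[y > 1 - 1e-12] <- 1 - 1e-12
    y[y < -1 + 1e-12] <- -1 + 1e-12
  }
  y
}

# Topographic map: unit j of a layer of size M draws its NC consecutive
# sources starting at round((j-1) * S / M), wrapping cyclically, so
# neighboring units read neighboring sources.
topo_sources <- function(M, S, NC) {
  matrix(vapply(seq_len(M), function(j) {
    as.integer(((round((j - 1) * S / M) + 0:(NC - 1)) %% S) + 1L)
  }, integer(NC)), nrow = M, ncol = NC, byrow = TRUE)
}

#' Initialize the three-layer controller
#'
#' Wires receptors to perceptive neurons and perceptive neurons to goal
#' neurons topographically; gives each goal neuron `nc` random recurrent
#' inputs from other goal neurons and each motor neuron `nc` random
#' goal-neuron inputs. Receptor->perceptive, perceptive->goal and
#' goal->motor weights are uniform on [0, 0.5); recurrent goal->goal
#' weights are uniform on [-0.5, 0.5). All outputs start at zero.
#'
#' Goal-neuron input connections (conI) are stored as `max_goal`-row
#' matrices `ci_src`/`ci_w` whose columns 1..nc are perceptive sources and
#' nc+1..2nc recurrent sources (`ci_kind` records the per-column kind).
#' Output connections (conO) are flat triplets `go_owner`/`go_motor`/`go_w`.
#' Rows and entries beyond the live counts `n_goal`/`n_conO` are
#' preallocated capacity for structural growth.
#'
#' @param n_receptors,n_perceptive,n_motor,nc layer sizes; requires
#'   `n_receptors < n_perceptive < n_goal`, `n_motor` even and smaller
#'   than the goal layer.
#' @param n_goal initial number of goal neurons.
#' @param max_goal capacity for growth (defaults to `n_goal`).
#' @param stream RNG stream for the weight draws.
#' @return A list of class `network_state`.
#' @export
init_network <- function(n_receptors = 8L, n_perceptive = 16L, n_motor = 8L,
                         nc = 4L, n_goal = 1000L, max_goal = n_goal,
                         stream = new_rng_stream(1L)) {
  n_receptors <- as.integer(n_receptors); n_perceptive <- as.integer(n_perceptive)
  n_motor <- as.integer(n_motor); nc <- as.integer(nc)
  n_goal <- as.integer(n_goal); max_goal <- as.integer(max_goal)
  if (!(n_receptors < n_perceptive && n_perceptive < n_goal))
    stop("layer sizes must satisfy receptors < perceptive < goal")
  if (n_motor %% 2L != 0L || n_motor >= n_goal)
    stop("n_motor must be even and smaller than the goal layer")
  if (nc >= n_goal) stop("nc must be smaller than the goal layer")
  if (max_goal < n_goal) stop("max_goal must be at least n_goal")

  Wcol <- Wdist <- Wang <- matrix(0, n_perceptive, n_receptors)
  ci_src <- matrix(0L, max_goal, 2L * nc)
  ci_w <- matrix(0, max_goal, 2L * nc)
  cap0 <- max(4L * n_motor * nc, 64L)
  go_owner <- integer(cap0); go_motor <- integer(cap0); go_w <- numeric(cap0)

  pmap <- topo_sources(n_perceptive, n_receptors, nc)
  gmap <- topo_sources(n_goal, n_perceptive, nc)
  with_stream(stream, {
    for (j in seq_len(n_perceptive)) {
      Wcol[j, pmap[j, ]] <- runif(nc, 0, 0.5)
      Wdist[j, pmap[j, ]] <- runif(nc, 0, 0.5)
      Wang[j, pmap[j, ]] <- runif(nc, 0, 0.5)
    }
    for (m in seq_len(n_goal)) {
      ci_src[m, 1:nc] <- gmap[m, ]
      ci_w[m, 1:nc] <- runif(nc, 0, 0.5)
      ci_src[m, nc + (1:nc)] <- sample(seq_len(n_goal)[-m], nc)
      ci_w[m, nc + (1:nc)] <- runif(nc, -0.5, 0.5)
    }
    k <- 0L
    for (n in seq_len(n_motor)) {
      owners <- sample(seq_len(n_goal), nc)
      go_owner[k + (1:nc)] <- owners
      go_motor[k + (1:nc)] <- n
      go_w[k + (1:nc)] <- runif(nc, 0, 0.5)
      k <- k + nc
    }
  })

  structure(list(
    n_receptors = n_receptors, n_perceptive = n_perceptive,
    TM = n_motor, NC = nc, n_goal = n_goal, max_goal = max_goal,
    Wcol = Wcol, Wdist = Wdist, Wang = Wang,
    ci_kind = c(rep(1L, nc), rep(2L, nc)),
    ci_src = ci_src, ci_w = ci_w,
    go_owner = go_owner, go_motor = go_motor, go_w = go_w,
    n_conO = n_motor * nc,
    out_curr = numeric(max_goal), out_prev = numeric(max_goal),
    t_memory = numeric(max_goal), colr = rep(NA_real_, max_goal),
    pout = numeric(n_perceptive), mout = numeric(n_motor)
  ), class = "network_state")
}

#' One goal neuron as an explicit connection-list view
#'
#' @param net a `network_state`.
#' @param id goal-neuron index.
#' @return List with `conI` (data frame: kind, source, weight), `conO`
#'   (data frame: motor, weight), `output_curr`, `output_prev`,
#'   `t_memory`, `colr`.
#' @export
goal_neuron <- function(net, id) {
  stopifnot(id >= 1, id <= net$n_goal)
  own <- which(net$go_owner[seq_len(net$n_conO)] == id)
  list(
    conI = data.frame(kind = c("perceptive", "goal")[net$ci_kind],
                      source = net$ci_src[id, ], weight = net$ci_w[id, ]),
    conO = data.frame(motor = net$go_motor[own], weight = net$go_w[own]),
    output_curr = net$out_curr[id], output_prev = net$out_prev[id],
    t_memory = net$t_memory[id], colr = net$colr[id]
  )
}

#' Forward pass: receptors to perceptive layer
#'
#' `Input_j = sum over j's receptors of (w_col * color_number +
#' w_dist * dist_norm + w_ang * ang_norm)`, squashed.
#'
#' @param readings matrix from [sense()].
#' @param net a `network_state`.
#' @return Numeric vector of perceptive outputs.
#' @export
forward_perceptive <- function(readings, net) {
  stopifnot(nrow(readings) == net$n_receptors)
  inp <- net$Wcol %*% readings[, 1L] + net$Wdist %*% readings[, 2L] +
    net$Wang %*% readings[, 3L]
  squash(as.vector(inp))
}

#' Forward pass: goal layer (synchronous recurrent update)
#'
#' The recurrent term uses only the previous tick's goal outputs. With
#' `rollover = TRUE` (the once-per-tick call) current outputs first become
#' the previous outputs; the re-run after structural growth uses
#' `rollover = FALSE` so the same t-1 outputs feed the enlarged layer.
#'
#' @param net a `network_state`.
#' @param pout perceptive outputs (stored on the state as `pout`).
#' @param rollover whether to advance `output_prev` first.
#' @return The updated `network_state`.
#' @export
forward_goal <- function(net, pout, rollover = TRUE) {
  n <- net$n_goal
  idx <- seq_len(n)
  # source-index matrices only change when the layer grows; cache them,
  # and run the structural-integrity check on each rebuild
  if (is.null(net$fg_cache) || net$fg_cache$n != n) {
    pc <- which(net$ci_kind == 1L); gc <- which(net$ci_kind == 2L)
    iP <- net$ci_src[idx, pc, drop = FALSE]
    iG <- net$ci_src[idx, gc, drop = FALSE]
    if ((length(iP) && (max(iP) > net$n_perceptive || min(iP) < 1L)) ||
        (length(iG) && (max(iG) > n || min(iG) < 1L)))
      stop("dangling connection id in goal layer")
    net$fg_cache <- list(n = n, pc = pc, gc = gc, iP = iP, iG = iG)
  }
  ch <- net$fg_cache
  if (rollover) net$out_prev[idx] <- net$out_curr[idx]
  prev <- net$out_prev
  inp <- numeric(n)
  if (length(ch$pc)) {
    sP <- pout[ch$iP]; dim(sP) <- dim(ch$iP)
    inp <- inp + .rowSums(net$ci_w[idx, ch$pc, drop = FALSE] * sP,
                          n, length(ch$pc))
  }
  if (length(ch$gc)) {
    sG <- prev[ch$iG]; dim(sG) <- dim(ch$iG)
    inp <- inp + .rowSums(net$ci_w[idx, ch$gc, drop = FALSE] * sG,
                          n, length(ch$gc))
  }
  net$out_curr[idx] <- squash(inp)
  net$pout <- pout
  net
}

#' Forward pass: motor layer
#'
#' `Input_n = sum of w_mn * Output_m` over every goal neuron holding an
#' output connection to motor neuron n; a motor neuron with no incoming
#' connections outputs `squash(0) = 0`.
#'
#' @param net a `network_state`.
#' @return The updated `network_state` (motor outputs in `mout`).
#' @export
forward_motor <- function(net) {
  idx <- seq_len(net$n_conO)
  x <- net$go_w[idx] * net$out_curr[net$go_owner[idx]]
  # dummy zero per motor neuron so every group is present
  inp <- as.vector(rowsum(c(x, numeric(net$TM)),
                          c(net$go_motor[idx], seq_len(net$TM))))
  net$mout <- squash(inp)
  net
}

#' Planar displacement from motor outputs
#'
#' Odd-indexed motor neurons drive the x displacement, even-indexed the y
#' displacement: `DX = 2 * k_dx * sum(odd outputs) / TM` and likewise
#' `DY`, so `|DX| <= k_dx` and `|DY| <= k_dy`.
#'
#' @param mout motor output vector (even length).
#' @param k_dx,k_dy displacement coefficients (field units).
#' @return Numeric `c(DX, DY)`.
#' @export
motion_from_motor <- function(mout, k_dx = 6, k_dy = 6) {
  TM <- length(mout)
  stopifnot(TM %% 2 == 0)
  c(2 * k_dx * sum(mout[seq(1, TM, 2)]) / TM,
    2 * k_dy * sum(mout[seq(2, TM, 2)]) / TM)
}

#' @export
print.network_state <- function(x, ...) {
  cat("<network_state> ", x$n_receptors, " receptors -> ", x$n_perceptive,
      " perceptive -> ", x$n_goal, " goal (cap ", x$max_goal, ") -> ",
      x$TM, " motor; NC=", x$NC, ", ", x$n_conO, " conO entries\n", sep = "")
  invisible(x)
}

# Serialize the full connectivity and weights (replay / inspection).
# include_outputs = FALSE drops the transient per-tick outputs, leaving
# only the learnable state: weights, wiring, memories and colr.
network_to_list <- function(net, include_outputs = TRUE) {
  n <- net$n_goal
  goal <- list(ci_kind = net$ci_kind,
               ci_src = net$ci_src[seq_len(n), , drop = FALSE],
               ci_w = net$ci_w[seq_len(n), , drop = FALSE],
               t_memory = net$t_memory[seq_len(n)],
               colr = net$colr[seq_len(n)])
  if (include_outputs) {
    goal$out_curr <- net$out_curr[seq_len(n)]
    goal$out_prev <- net$out_prev[seq_len(n)]
  }
  list(
    sizes = list(n_receptors = net$n_receptors,
                 n_perceptive = net$n_perceptive,
                 n_goal = n, n_motor = net$TM, nc = net$NC),
    perceptive = list(w_col = net$Wcol, w_dist = net$Wdist, w_ang = net$Wang),
    goal = goal,
    conO = list(owner = net$go_owner[seq_len(net$n_conO)],
                motor = net$go_motor[seq_len(net$n_conO)],
                weight = net$go_w[seq_len(net$n_conO)])
  )
}
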