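#' Global activity estimate of the goal layer
#'
#' `lambda(t)` is the mean squared one-step output change over all goal
#' neurons - the organism's EEG-like summary of how much the goal layer
#' just moved. Its position relative to the gates `t1 < t2` decides
#' whether nothing, gradient reinforcement, or structural growth happens
#' this tick.
#'
#' @param net a `network_state` whose outputs at t and t-1 are current.
#' @return Non-negative scalar.
#' @export
compute_lambda <- function(net) {
  n <- net$n_goal
  if (n < 1L) stop("empty goal layer")
  idx <- seq_len(n)
  mean((net$out_curr[idx] - net$out_prev[idx])^2)
}

#' Per-neuron instability metric
#'
#' `rho(gn_i) = (Output_i(t) - Output_i(t-1))^2`, the metric used to pick
#' growth donors. By definition `mean(rho(net)) == compute_lambda(net)`.
#'
#' @param net a `network_state`.
#' @param id optional neuron index; default returns the whole vector.
#' @return Numeric vector (or scalar when `id` is given).
#' @export
rho <- function(net, id = NULL) {
  idx <- if (is.null(id)) seq_len(net$n_goal) else id
  (net$out_curr[idx] - net$out_prev[idx])^2
}

#' Touch-triggered multiplicative weight update
#'
#' Fires when a red or green object is touched (blue and yellow touches
#' change nothing). Every goal neuron whose current output exceeds `tact`
#' in magnitude is gated: its perceptive-input weights are multiplied by
#' `(1 + k1 * colr_m)` and its motor-output weights by `(1 + k2 * colr_m)`
#' for green, or `(-1 - k2 * colr_m)` for red - so repeated red touches
#' drive motor projections negative and the organism learns avoidance.
#' A neuron's `colr_m` is set on its first gated update (to the touched
#' object's |color-number| under `colr_init = "color_number"`) and is
#' multiplied by `colr_decay` after every update it takes part in, which
#' bounds the cumulative weight growth.
#'
#' @param net a `network_state`.
#' @param color touched color name.
#' @param params plasticity parameter list (see [default_config()]).
#' @param color_numbers named list of color-numbers.
#' @return The updated `network_state`.
#' @export
touch_update <- function(net, color, params,
                         color_numbers = default_config()$field$color_numbers) {
  if (!color %in% c("red", "green")) return(net)
  if (!is.finite(params$tact)) return(net)
  n <- net$n_goal
  g <- which(abs(net$out_curr[seq_len(n)]) > params$tact)
  if (!length(g)) return(net)
  unset <- g[is.na(net$colr[g])]
  if (length(unset)) {
    net$colr[unset] <- if (identical(params$colr_init, "constant"))
      params$colr_const else abs(color_numbers[[color]])
  }
  cg <- net$colr[g]
  pc <- which(net$ci_kind == 1L)
  net$ci_w[g, pc] <- net$ci_w[g, pc, drop = FALSE] * (1 + params$k1 * cg)
  fac <- if (color == "green") 1 + params$k2 * cg else -1 - params$k2 * cg
  gated <- logical(n); gated[g] <- TRUE
  facv <- numeric(n); facv[g] <- fac
  idx <- seq_len(net$n_conO)
  sel <- idx[gated[net$go_owner[idx]]]
  net$go_w[sel] <- net$go_w[sel] * facv[net$go_owner[sel]]
  net$colr[g] <- net$colr[g] * params$colr_decay
  net
}

#' Gradient reinforcement of goal-neuron inputs
#'
#' Applied when `t1 < lambda(t) < t2`: moderate global change is treated
#' as useful for leaving traps and is reinforced. For every goal neuron m
#' and each input connection with source output `O_src` (perceptive
#' outputs for perceptive sources, t-1 goal outputs for recurrent ones):
#'
#' `w <- w + kb * O_src * 0.5 * (Out_m(t) - Out_m(t-1)) *
#'   (1 + Out_m(t)) * (1 - Out_m(t))`
#'
#' i.e. the one-step output delta scaled by the derivative of [squash()]
#' at the current output. Motor-output weights are untouched, as are the
#' receptor->perceptive weights, which stay frozen for the organism's
#' lifetime.
#'
#' @param net a `network_state` (with `pout` holding the perceptive
#'   outputs that fed the current goal outputs).
#' @param params plasticity parameter list.
#' @return The updated `network_state`.
#' @export
reinforcement_update <- function(net, params) {
  n <- net$n_goal
  idx <- seq_len(n)
  oc <- net$out_curr[idx]
  fac <- params$kb * 0.5 * (oc - net$out_prev[idx]) * (1 + oc) * (1 - oc)
  pc <- which(net$ci_kind == 1L); gc <- which(net$ci_kind == 2L)
  ch <- net$fg_cache
  cached <- !is.null(ch) && ch$n == n
  if (length(pc)) {
    iP <- if (cached) ch$iP else net$ci_src[idx, pc, drop = FALSE]
    sP <- net$pout[iP]; dim(sP) <- dim(iP)
    net$ci_w[idx, pc] <- net$ci_w[idx, pc, drop = FALSE] + sP * fac
  }
  if (length(gc)) {
    iG <- if (cached) ch$iG else net$ci_src[idx, gc, drop = FALSE]
    sG <- net$out_prev[iG]; dim(sG) <- dim(iG)
    net$ci_w[idx, gc] <- net$ci_w[idx, gc, drop = FALSE] + sG * fac
  }
  net
}

#' Coherence-gated generation of goal neurons
#'
#' Fires when `lambda(t) > t2`: the situation changed so much that a new
#' goal-directed process is constructed by growing the layer. Repeatedly
#' (re-selecting every iteration, newly created neurons included):
#'
#' 1. Take the two neurons with smallest [rho()] as donors, donor 1 the
#'    smaller (ties broken by lowest id).
#' 2. Create a new neuron: each input slot is copied from donor 1 with
#'    probability `p`, else from donor 2; the chosen donor's `t_memory`
#'    grows by `df` and the running coherence `zeta` accumulates the
#'    donor's updated memory. Each of donor 1's output slots is copied
#'    with probability `p`, else rewired to a uniformly random motor
#'    neuron with a fresh weight in [0, 0.5).
#' 3. The new neuron's previous output is donor 1's t-1 output, its
#'    current output is 0 until the next forward pass, and its stored
#'    metric is `(Output_new(t) - Output_1(t-1))^2`.
#'
#' The loop ends once `zeta >= t_coherence`. Because every copied slot
#' raises some donor memory by `df > 0`, `zeta` grows without bound and
#' the loop always terminates; neurons with large memories end events
#' after fewer creations (the minimal-structural-change principle).
#' Hitting `max_goal_neurons` stops the event early with a truncation
#' flag.
#'
#' @param net a `network_state` with at least two goal neurons.
#' @param params plasticity parameter list.
#' @param stream RNG stream for the copy decisions.
#' @param tick tick index recorded on the event.
#' @return List with the grown `net` and `event`, a `growth_event`:
#'   `tick`, `donors` (first pair), `n_created`, `zeta_final`,
#'   `truncated`.
#' @export
grow_goal_neurons <- function(net, params, stream = new_rng_stream(1L),
                              tick = NA_integer_) {
  n0 <- net$n_goal
  if (n0 < 2L) stop("growth needs at least two goal neurons")
  width <- ncol(net$ci_src)
  rho_v <- (net$out_curr[seq_len(n0)] - net$out_prev[seq_len(n0)])^2
  zeta <- 0; created <- 0L; donors_first <- NULL; truncated <- FALSE
  with_stream(stream, {
    while (zeta < params$t_coherence) {
      if (net$n_goal >= net$max_goal) {
        truncated <- TRUE
        warning("growth truncated at max_goal_neurons = ", net$max_goal)
        break
      }
      o <- order(rho_v)[1:2]   # stable: ties resolved by lowest id
      d1 <- o[1]; d2 <- o[2]
      if (is.null(donors_first)) donors_first <- c(d1, d2)
      nid <- net$n_goal + 1L

      # input slots: per-slot donor choice; zeta accumulates each chosen
      # donor's successively incremented memory (order-independent sum)
      fromA <- runif(width) < params$p
      k1n <- sum(fromA); k2n <- width - k1n
      src <- net$ci_src[d1, ]; wts <- net$ci_w[d1, ]
      src[!fromA] <- net$ci_src[d2, !fromA]
      wts[!fromA] <- net$ci_w[d2, !fromA]
      zeta <- zeta +
        k1n * net$t_memory[d1] + params$df * k1n * (k1n + 1) / 2 +
        k2n * net$t_memory[d2] + params$df * k2n * (k2n + 1) / 2
      net$t_memory[d1] <- net$t_memory[d1] + k1n * params$df
      net$t_memory[d2] <- net$t_memory[d2] + k2n * params$df

      # output slots: copy donor 1's or rewire to a random motor neuron
      d1o <- which(net$go_owner[seq_len(net$n_conO)] == d1)
      m <- length(d1o)
      if (m) {
        keep <- runif(m) < params$p
        mot <- net$go_motor[d1o]; ow <- net$go_w[d1o]
        nrw <- sum(!keep)
        if (nrw) {
          mot[!keep] <- sample.int(net$TM, nrw, replace = TRUE)
          ow[!keep] <- runif(nrw, 0, 0.5)
        }
        if (net$n_conO + m > length(net$go_owner)) {
          grow <- max(length(net$go_owner), m)
          net$go_owner <- c(net$go_owner, integer(grow))
          net$go_motor <- c(net$go_motor, integer(grow))
          net$go_w <- c(net$go_w, numeric(grow))
        }
        at <- net$n_conO + seq_len(m)
        net$go_owner[at] <- nid
        net$go_motor[at] <- mot
        net$go_w[at] <- ow
        net$n_conO <- net$n_conO + m
      }

      net$ci_src[nid, ] <- src
      net$ci_w[nid, ] <- wts
      net$out_prev[nid] <- net$out_prev[d1]
      net$out_curr[nid] <- 0
      net$t_memory[nid] <- 0
      net$colr[nid] <- NA_real_
      rho_v <- c(rho_v, (0 - net$out_prev[d1])^2)
      net$n_goal <- nid
      created <- created + 1L
    }
  })
  event <- structure(list(tick = tick, donors = donors_first,
                          n_created = created, zeta_final = zeta,
                          truncated = truncated),
                     class = "growth_event")
  list(net = net, event = event)
}

#' @export
print.growth_event <- function(x, ...) {
  cat("<growth_event> tick ", x$tick, ": +", x$n_created,
      " neuron(s), donors (", x$donors[1], ", ", x$donors[2],
      "), zeta = ", signif(x$zeta_final, 4),
      if (x$truncated) " [truncated at cap]" else "", "\n", sep = "")
  invisible(x)
}
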