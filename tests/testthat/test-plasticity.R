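test_that("lambda is the mean squared one-step output change", {
  net <- hand_network(n_goal = 4)
  net$out_prev[1:4] <- c(0, 0, 0, 0)
  net$out_curr[1:4] <- c(0, 0, 0, 0)
  expect_equal(compute_lambda(net), 0)

  net$out_curr[1:4] <- c(0.5, -0.5, 0, 0)
  expect_equal(compute_lambda(net), 0.125)   # (0.25 + 0.25) / 4

  net1 <- net; net1$n_goal <- 1L
  net1$out_prev[1] <- 0; net1$out_curr[1] <- 1
  expect_equal(compute_lambda(net1), 1)

  net0 <- net; net0$n_goal <- 0L
  expect_error(compute_lambda(net0), "empty")
})

test_that("rho is the per-neuron metric and lambda is its mean", {
  net <- hand_network(n_goal = 4)
  net$out_prev[1:4] <- c(0.8, 0.1, -0.2, 0.4)
  net$out_curr[1:4] <- c(0.3, 0.1, 0.2, -0.1)
  expect_equal(rho(net, 1), 0.25)   # (0.3 - 0.8)^2
  expect_equal(rho(net, 2), 0)
  expect_equal(mean(rho(net)), compute_lambda(net))  # definitional identity
  expect_equal(mean(rho(net)) - compute_lambda(net), 0, tolerance = 1e-12)
})

test_that("touch updates are gated, multiplicative, and color-signed", {
  params <- default_config()$plasticity
  cn <- default_config()$field$color_numbers
  net <- hand_network(n_goal = 4)
  net$out_curr[1:4] <- c(0.9, 0.1, -0.8, 0.4)   # neurons 1 and 3 gated

  # closed gate: Tact infinite (no-learning mode) -> nothing changes
  p_inf <- params; p_inf$tact <- Inf
  expect_identical(touch_update(net, "red", p_inf, cn)$ci_w, net$ci_w)
  # blue and yellow touches are no-ops
  expect_identical(touch_update(net, "blue", params, cn)$ci_w, net$ci_w)
  expect_identical(touch_update(net, "yellow", params, cn)$ci_w, net$ci_w)

  # red touch, rigged numbers: conO weight 0.4, k2 = 0.1, colr = 2
  # -> 0.4 * (-1 - 0.2) = -0.48
  p <- params; p$k1 <- 0.2; p$k2 <- 0.1
  p$colr_init <- "constant"; p$colr_const <- 2
  net1 <- net
  net1$go_owner <- 1L; net1$go_motor <- 1L; net1$go_w <- 0.4
  net1$n_conO <- 1L
  out <- touch_update(net1, "red", p, cn)
  expect_equal(out$go_w[1], -0.48)
  # gated perceptive weights multiplied by (1 + k1 * colr) = 1.4;
  # recurrent inputs and ungated neurons untouched
  pc <- out$ci_kind == 1L
  expect_equal(out$ci_w[1, pc], net1$ci_w[1, pc] * 1.4)
  expect_equal(out$ci_w[3, pc], net1$ci_w[3, pc] * 1.4)
  expect_identical(out$ci_w[2, ], net1$ci_w[2, ])
  expect_identical(out$ci_w[, !pc], net1$ci_w[, !pc])
  # colr decayed for the updated neurons only
  expect_equal(out$colr[1], 2 * p$colr_decay)
  expect_true(is.na(out$colr[2]))

  # colr_init = "color_number": first gated green touch sets colr to 2
  p2 <- params
  out2 <- touch_update(net1, "green", p2, cn)
  expect_equal(out2$colr[1], abs(cn$green) * p2$colr_decay)

  # repeated red touches drive conO weights negative -> avoidance
  netr <- net1
  for (i in 1:3) netr <- touch_update(netr, "red", p, cn)
  expect_lt(netr$go_w[1], 0)
})

test_that("gradient reinforcement follows the squash-derivative rule", {
  params <- default_config()$plasticity
  net <- hand_network(n_goal = 4)
  pout <- c(0.5, -0.2, 0.1)
  net <- forward_goal(net, pout)

  # no output change -> zero update
  net0 <- net; net0$out_prev[1:4] <- net0$out_curr[1:4]
  expect_equal(reinforcement_update(net0, params)$ci_w, net0$ci_w)

  # saturated outputs -> vanishing derivative factor
  nets <- net
  nets$out_curr[1:4] <- 1 - 1e-12
  upd <- reinforcement_update(nets, params)
  expect_equal(upd$ci_w[1:4, ], nets$ci_w[1:4, ], tolerance = 1e-9)

  # one-connection hand case
  idx <- 1:4
  oc <- net$out_curr[idx]; op <- net$out_prev[idx]
  fac <- params$kb * 0.5 * (oc - op) * (1 + oc) * (1 - oc)
  sP <- pout[net$ci_src[idx, 1]]
  sG <- net$out_prev[net$ci_src[idx, 2]]
  upd <- reinforcement_update(net, params)
  expect_equal(upd$ci_w[idx, 1], net$ci_w[idx, 1] + sP * fac)
  expect_equal(upd$ci_w[idx, 2], net$ci_w[idx, 2] + sG * fac)
  # conO weights untouched
  expect_identical(upd$go_w, net$go_w)
})

test_that("growth matches the hand-enumerated donor-copy trace", {
  # three-slot donors, t_memory 0, df = 1, p = 1 (every rand(0,1) < 1):
  # the single created neuron accumulates zeta = 1 + 2 + 3 = 6 from
  # donor 1's successive memory increments, ending the event at
  # T_coherence = 5 with exactly one neuron.
  net <- list(
    n_receptors = 2L, n_perceptive = 2L, TM = 2L, NC = 3L,
    n_goal = 2L, max_goal = 10L,
    ci_kind = rep(1L, 3),
    ci_src = rbind(matrix(c(1L, 2L, 1L), 1), matrix(c(2L, 1L, 2L), 1),
                   matrix(0L, 8, 3)),
    ci_w = rbind(c(0.1, 0.2, 0.3), c(0.4, 0.5, 0.6), matrix(0, 8, 3)),
    go_owner = c(1L, integer(7)), go_motor = c(1L, integer(7)),
    go_w = c(0.25, numeric(7)), n_conO = 1L,
    out_curr = c(0.1, 0.5, numeric(8)), out_prev = c(0.1, 0.1, numeric(8)),
    t_memory = numeric(10), colr = rep(NA_real_, 10)
  )
  class(net) <- "network_state"
  params <- default_config()$plasticity
  params$p <- 1; params$df <- 1; params$t_coherence <- 5

  # rho(1) = 0 < rho(2) = 0.16: donor 1 is neuron 1
  gr <- grow_goal_neurons(net, params, new_rng_stream(1), tick = 7L)
  expect_equal(gr$event$n_created, 1L)
  expect_equal(gr$event$zeta_final, 6)
  expect_equal(gr$event$donors, c(1L, 2L))
  expect_equal(gr$event$tick, 7L)
  expect_equal(gr$net$n_goal, 3L)
  # p = 1: every slot copied from donor 1, conO copied from donor 1
  expect_equal(gr$net$ci_w[3, ], net$ci_w[1, ])
  expect_equal(gr$net$ci_src[3, ], net$ci_src[1, ])
  expect_equal(gr$net$go_owner[2], 3L)
  expect_equal(gr$net$go_w[2], 0.25)
  # donor 1's memory rose by 3 * df; donor 2 untouched
  expect_equal(gr$net$t_memory[1:3], c(3, 0, 0))
  # new neuron: output_prev = donor 1's t-1 output, output_curr = 0
  expect_equal(gr$net$out_prev[3], 0.1)
  expect_equal(gr$net$out_curr[3], 0)
})

test_that("growth always terminates, adds >= 1 neuron, keeps integrity", {
  params <- default_config()$plasticity
  for (seed in 1:5) {
    net <- init_network(n_goal = 30, max_goal = 200,
                        stream = new_rng_stream(seed))
    pout <- with_stream(new_rng_stream(seed + 50), runif(16, -1, 1))
    net <- forward_goal(net, pout)
    net <- forward_goal(net, pout)
    before <- net$n_goal
    mem_before <- sum(net$t_memory)
    gr <- grow_goal_neurons(net, params, new_rng_stream(seed), tick = 1L)
    expect_gte(gr$event$n_created, 1L)
    expect_equal(gr$net$n_goal, before + gr$event$n_created)
    expect_gte(gr$event$zeta_final, params$t_coherence)
    # total memory grew by df per processed input slot
    expect_equal(sum(gr$net$t_memory) - mem_before,
                 params$df * gr$event$n_created * ncol(net$ci_src))
    # referential integrity of every new neuron
    idx <- (before + 1):gr$net$n_goal
    pc <- gr$net$ci_kind == 1L
    expect_true(all(gr$net$ci_src[idx, pc] >= 1 &
                      gr$net$ci_src[idx, pc] <= net$n_perceptive))
    expect_true(all(gr$net$ci_src[idx, !pc] >= 1 &
                      gr$net$ci_src[idx, !pc] <= gr$net$n_goal))
    sel <- seq_len(gr$net$n_conO)
    expect_true(all(gr$net$go_motor[sel] >= 1 & gr$net$go_motor[sel] <= net$TM))
    # t_memory never decreased
    expect_true(all(gr$net$t_memory >= net$t_memory))
  }

  # degenerate layer
  net1 <- hand_network(n_goal = 4); net1$n_goal <- 1L
  expect_error(grow_goal_neurons(net1, params), "at least two")

  # hitting the cap truncates with a warning on the event
  netc <- init_network(n_goal = 30, max_goal = 31,
                       stream = new_rng_stream(2))
  netc$out_curr[1:30] <- 0.9   # huge rho everywhere -> zeta needs many adds
  pars <- params; pars$t_coherence <- 1e6
  expect_warning(gr <- grow_goal_neurons(netc, pars, new_rng_stream(3)),
                 "truncated")
  expect_true(gr$event$truncated)
  expect_equal(gr$net$n_goal, 31L)
})

test_that("mode gates: growth only fires in Mode 4, donors re-selected", {
  # make_mode substitutions
  m1 <- make_mode(1)
  expect_true(all(is.infinite(c(m1$tact, m1$t1, m1$t2))))
  m2 <- make_mode(2)
  expect_true(is.finite(m2$tact) && is.infinite(m2$t1) && is.infinite(m2$t2))
  m3 <- make_mode(3)
  expect_true(is.finite(m3$t1) && is.infinite(m3$t2))
  m4 <- make_mode(4)
  expect_true(all(is.finite(c(m4$tact, m4$t1, m4$t2))))
  expect_error(make_mode(5), "unknown mode")

  # gates only open as mode_id increases
  finite_gates <- vapply(1:4, function(m) {
    sp <- make_mode(m); sum(is.finite(c(sp$tact, sp$t1, sp$t2)))
  }, numeric(1))
  expect_true(all(diff(finite_gates) == 1))
})
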