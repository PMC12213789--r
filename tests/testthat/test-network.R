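test_that("squash is the odd logistic with the right landmarks", {
  expect_equal(squash(0), 0)
  expect_equal(squash(log(3)), 0.5)   # 2/(1 + 1/3) - 1
  expect_equal(squash(5), -squash(-5))
  expect_lt(squash(1000), 1)
  expect_gt(squash(-1000), -1)
  x <- seq(-30, 30, length.out = 101)
  expect_true(all(squash(x) > -1 & squash(x) < 1))
  expect_true(all(diff(squash(seq(-8, 8, length.out = 101))) > 0))
})

test_that("init_network wires topographically with the stated weight ranges", {
  net <- init_network(n_receptors = 8, n_perceptive = 16, n_motor = 8,
                      nc = 4, n_goal = 40, stream = new_rng_stream(5))
  # perceptive weights: NC entries per neuron in [0, 0.5), rest zero
  nz <- rowSums(net$Wcol != 0)
  expect_true(all(nz == 4))
  w <- net$Wcol[net$Wcol != 0]
  expect_true(all(w >= 0 & w < 0.5))
  # neighboring perceptive neurons read neighboring receptors
  src1 <- which(net$Wcol[1, ] != 0)
  src2 <- which(net$Wcol[2, ] != 0)
  expect_gt(length(intersect(src1, src2)), 0)
  # goal conI: perceptive weights in [0, 0.5), recurrent in [-0.5, 0.5),
  # no self-recurrence
  pc <- net$ci_kind == 1L; gc <- net$ci_kind == 2L
  idx <- seq_len(net$n_goal)
  expect_true(all(net$ci_w[idx, pc] >= 0 & net$ci_w[idx, pc] < 0.5))
  expect_true(all(net$ci_w[idx, gc] >= -0.5 & net$ci_w[idx, gc] < 0.5))
  expect_true(all(net$ci_src[idx, gc] != row(net$ci_src[idx, gc])))
  # conO: each motor neuron has NC incoming entries, weights in [0, 0.5)
  expect_equal(unname(table(net$go_motor[seq_len(net$n_conO)])),
               rep(4L, 8), ignore_attr = TRUE)
  expect_true(all(net$go_w[seq_len(net$n_conO)] >= 0 &
                    net$go_w[seq_len(net$n_conO)] < 0.5))
  # outputs zeroed
  expect_true(all(net$out_curr == 0) && all(net$out_prev == 0))

  # determinism: same seed -> bit-identical weights
  net2 <- init_network(n_receptors = 8, n_perceptive = 16, n_motor = 8,
                       nc = 4, n_goal = 40, stream = new_rng_stream(5))
  expect_identical(net$ci_w, net2$ci_w)
  expect_identical(net$Wang, net2$Wang)

  expect_error(init_network(n_receptors = 8, n_perceptive = 8, n_goal = 40),
               "receptors < perceptive")
  expect_error(init_network(n_motor = 7, n_goal = 40), "even")
})

test_that("forward_perceptive matches a hand-computed dot product", {
  net <- hand_network(n_rec = 2, n_perc = 3, n_goal = 4, TM = 2, nc = 1)
  readings <- matrix(0, 2, 4,
                     dimnames = list(NULL, c("color_number", "dist_norm",
                                             "ang_norm", "has_object")))
  expect_true(all(forward_perceptive(readings, net) == 0))

  readings[1, ] <- c(8, 0.25, 1, 1)
  pout <- forward_perceptive(readings, net)
  for (j in 1:3) {
    expected <- squash(net$Wcol[j, 1] * 8 + net$Wdist[j, 1] * 0.25 +
                         net$Wang[j, 1] * 1)
    expect_equal(pout[j], expected)
  }
  # negative color-number with positive weights -> non-positive outputs
  readings[1, 1] <- -1
  expect_true(all(forward_perceptive(readings, net) <= 0))
})

test_that("forward_goal does a synchronous recurrent update", {
  # 2-neuron hand example iterated two steps against a manual trace
  net <- hand_network(n_rec = 2, n_perc = 3, n_goal = 4, TM = 2, nc = 1)
  pout <- c(0.5, -0.2, 0.1)
  w_p <- net$ci_w[1:4, 1]; s_p <- net$ci_src[1:4, 1]
  w_g <- net$ci_w[1:4, 2]; s_g <- net$ci_src[1:4, 2]

  net1 <- forward_goal(net, pout)
  manual1 <- squash(w_p * pout[s_p] + w_g * 0)   # prev outputs all zero
  expect_equal(net1$out_curr[1:4], manual1)
  net2 <- forward_goal(net1, pout)
  manual2 <- squash(w_p * pout[s_p] + w_g * manual1[s_g])
  expect_equal(net2$out_curr[1:4], manual2)
  expect_equal(net2$out_prev[1:4], manual1)   # rollover happened

  # zero recurrent weights reduce to the feed-forward case
  net0 <- net; net0$ci_w[, 2] <- 0
  netf <- forward_goal(forward_goal(net0, pout), pout)
  expect_equal(netf$out_curr[1:4], squash(w_p * pout[s_p]))

  # outputs stay in (-1, 1) over many steps
  netx <- net
  for (i in 1:50) netx <- forward_goal(netx, pout)
  expect_true(all(abs(netx$out_curr[1:4]) < 1))

  # dangling recurrent id -> structural integrity error
  bad <- net; bad$ci_src[1, 2] <- 99L
  expect_error(forward_goal(bad, pout), "dangling")
})

test_that("forward_motor sums conO contributions through squash", {
  net <- hand_network(n_rec = 2, n_perc = 3, n_goal = 4, TM = 2, nc = 1)
  net$out_curr[1:4] <- c(0.8, -0.3, 0.5, 0.1)
  net <- forward_motor(net)
  idx <- seq_len(net$n_conO)
  for (n in 1:2) {
    sel <- idx[net$go_motor[idx] == n]
    expect_equal(net$mout[n],
                 squash(sum(net$go_w[sel] * net$out_curr[net$go_owner[sel]])))
  }
  # no incoming connections -> output 0
  net0 <- net; net0$n_conO <- 0L
  net0 <- forward_motor(net0)
  expect_true(all(net0$mout == 0))
  # single connection: squash(w * g); sign flip on the weight flips output
  net1 <- net
  net1$go_owner <- 1L; net1$go_motor <- 1L; net1$go_w <- 0.4
  net1$n_conO <- 1L
  net1 <- forward_motor(net1)
  expect_equal(net1$mout[1], squash(0.4 * 0.8))
  net1$go_w <- -0.4
  net1 <- forward_motor(net1)
  expect_equal(net1$mout[1], -squash(0.4 * 0.8))
})

test_that("motion splits odd/even motors into DX/DY with the 2k/TM scale", {
  expect_equal(motion_from_motor(rep(0, 8)), c(0, 0))
  # TM = 4, odd outputs 0.5 and 0.5, k_dx = 1 -> DX = 2*1*1.0/4 = 0.5
  expect_equal(motion_from_motor(c(0.5, 0, 0.5, 0), k_dx = 1, k_dy = 1),
               c(0.5, 0))
  expect_equal(motion_from_motor(c(0, 0.25, 0, 0.75), k_dx = 1, k_dy = 1),
               c(0, 0.5))
  m <- c(0.9, -0.2, 0.8, 0.3, -0.1, 0.9, 0.5, -0.4)
  d <- motion_from_motor(m, 6, 6)
  expect_lte(abs(d[1]), 6); expect_lte(abs(d[2]), 6)
})

test_that("a lone color reading maps sign-symmetrically onto movement", {
  # color-only perception (dist/ang weights zeroed), fresh net: first-tick
  # recurrence is zero so the whole cascade is odd in the color-number
  net <- init_network(n_goal = 40, stream = new_rng_stream(8))
  net$Wdist[] <- 0; net$Wang[] <- 0
  push <- function(cn) {
    readings <- matrix(0, 8, 4)
    colnames(readings) <- c("color_number", "dist_norm", "ang_norm",
                            "has_object")
    readings[3, ] <- c(cn, 0.2, 0.8, 1)
    n <- forward_motor(forward_goal(net, forward_perceptive(readings, net)))
    motion_from_motor(n$mout)
  }
  d_pos <- push(8)
  d_neg <- push(-8)
  expect_equal(d_pos, -d_neg)
  expect_true(all(d_pos >= 0))  # all-positive weights approach positive colors

  # movement magnitude grows with |color-number| (velocity ~ color salience)
  mag <- vapply(c(1, 2, 8), function(cn) sum(abs(push(cn))), numeric(1))
  expect_true(all(diff(mag) > 0))
})
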