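# Independent statistical oracles, hand-rolled from the rank definitions
# so package wrappers are checked against a second code path.

# Friedman chi-square from within-block ranks (classic statistic, average
# ranks for ties; use tie-free fixtures when comparing to the wrapper).
oracle_friedman <- function(m) {
  b <- nrow(m); k <- ncol(m)
  R <- t(apply(m, 1, rank))
  stat <- 12 / (b * k * (k + 1)) * sum(colSums(R)^2) - 3 * b * (k + 1)
  list(statistic = stat, df = k - 1,
       p = stats::pchisq(stat, k - 1, lower.tail = FALSE))
}

# Exact two-sided signed-rank p by full 2^n sign enumeration (no ties,
# no zero differences).
oracle_wilcoxon_exact <- function(x, y) {
  d <- x - y
  stopifnot(all(d != 0), !anyDuplicated(abs(d)))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  mean_v <- n * (n + 1) / 4
  p <- mean(abs(vs - mean_v) >= abs(v - mean_v) - 1e-12)
  list(V = v, p = min(1, p))
}

# Pooled two-sample t and Cohen's d from the closed forms.
oracle_t_cohend <- function(a, b) {
  na <- length(a); nb <- length(b); dof <- na + nb - 2
  sp <- sqrt(((na - 1) * var(a) + (nb - 1) * var(b)) / dof)
  tval <- (mean(a) - mean(b)) / (sp * sqrt(1 / na + 1 / nb))
  list(t = tval, dof = dof, p = 2 * stats::pt(-abs(tval), dof),
       d = (mean(a) - mean(b)) / sp)
}

# A tiny hand-wired controller: every weight explicit, for worked-example
# forward traces. Layout: n_rec receptors, n_perc perceptive, n_goal goal
# (nc perceptive + nc recurrent inputs each), TM motors.
hand_network <- function(n_rec = 2L, n_perc = 3L, n_goal = 4L, TM = 2L,
                         nc = 1L) {
  net <- init_network(n_receptors = n_rec, n_perceptive = n_perc,
                      n_motor = TM, nc = nc, n_goal = n_goal,
                      stream = new_rng_stream(42))
  net
}

# Small fast configuration for whole-run tests.
tiny_config <- function(mode = 1L, n_steps = 200L, seed = 1L, ...) {
  cfg <- list(
    field = list(side_length = 200, n_per_color = 10L),
    sim = list(mode = mode, n_steps = n_steps, seed = seed,
               n_goal = if (mode == 4L) 28L else 50L)
  )
  extra <- list(...)
  for (nm in names(extra)) cfg[[nm]] <- utils::modifyList(
    if (is.null(cfg[[nm]])) list() else cfg[[nm]], extra[[nm]])
  cfg
}

# Strip the mutable state environment before comparing results.
result_fingerprint <- function(res) {
  res$state <- NULL
  serialize(res, NULL)
}
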