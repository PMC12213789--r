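#' Friedman test across colors within one mode
#'
#' Nonparametric matched ANOVA on the per-run disappeared counts: the four
#' color columns are treatments, the replicate simulations are blocks.
#'
#' @param rows `experiment_table` rows of a single mode (or any data frame
#'   with the four color columns).
#' @return List `statistic` (Friedman chi-square), `df`, `p`.
#' @export
friedman_by_color <- function(rows) {
  m <- as.matrix(rows[, COLOR_NAMES])
  if (nrow(m) < 2L) stop("need at least 2 simulations")
  if (all(apply(m, 1, function(r) length(unique(r)) == 1L))) {
    return(list(statistic = 0, df = ncol(m) - 1L, p = 1))
  }
  ft <- stats::friedman.test(m)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p = ft$p.value)
}

#' Wilcoxon matched-pairs tests: red versus each other color
#'
#' Signed-rank tests of the per-run red counts against the green, blue
#' and yellow counts of the same runs. Small samples without ties use the
#' exact distribution; otherwise the normal approximation with continuity
#' correction applies. All-zero differences are degenerate and reported
#' as p = 1 with a flag.
#'
#' @param rows `experiment_table` rows of a single mode (>= 6 runs for a
#'   meaningful test).
#' @return Data frame with `comparison`, `p`, `degenerate`.
#' @export
wilcoxon_red_vs_colors <- function(rows) {
  if (nrow(rows) < 6L) warning("fewer than 6 paired simulations")
  others <- setdiff(COLOR_NAMES, "red")
  out <- lapply(others, function(col) {
    d <- rows$red - rows[[col]]
    if (all(d == 0)) {
      return(data.frame(comparison = paste0("red_vs_", col), p = 1,
                        degenerate = TRUE))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(rows$red, rows[[col]], paired = TRUE,
                         exact = NULL, correct = TRUE)
    )
    data.frame(comparison = paste0("red_vs_", col), p = wt$p.value,
               degenerate = FALSE)
  })
  do.call(rbind, out)
}

#' Two-sample t test with Cohen's d
#'
#' Pooled-variance two-sample t on run totals, with
#' `dof = n_A + n_B - 2` and `d = (mean_A - mean_B) / pooled SD`.
#' Zero pooled variance with unequal means is flagged as an infinite
#' effect.
#'
#' @param totals_a,totals_b numeric vectors (each length >= 2).
#' @return List `t`, `dof`, `p` (two-sided), `d`, `infinite_effect`.
#' @export
ttest_cohend <- function(totals_a, totals_b) {
  na <- length(totals_a); nb <- length(totals_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 values")
  dof <- na + nb - 2L
  md <- mean(totals_a) - mean(totals_b)
  sp2 <- ((na - 1) * stats::var(totals_a) + (nb - 1) * stats::var(totals_b)) / dof
  if (sp2 == 0) {
    if (md == 0) return(list(t = 0, dof = dof, p = 1, d = 0,
                             infinite_effect = FALSE))
    return(list(t = sign(md) * Inf, dof = dof, p = 0, d = sign(md) * Inf,
                infinite_effect = TRUE))
  }
  tval <- md / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tval, dof = dof, p = 2 * stats::pt(-abs(tval), dof),
       d = md / sqrt(sp2), infinite_effect = FALSE)
}

#' Confinement (trap) episodes of a trajectory
#'
#' Greedy scan for maximal runs of at least `window` consecutive ticks
#' whose position bounding-box diagonal stays at or below
#' `trap_diameter` - a quantitative stand-in for the informal notion of
#' the organism being trapped in a limited area.
#'
#' @param xy two-column matrix (or data frame) of positions in tick order.
#' @param window minimum episode length in ticks (>= 2).
#' @param trap_diameter maximum bounding-box diagonal of an episode.
#' @return List of episodes, each `start`, `end`, `diagonal`, `center`.
#' @export
confinement_episodes <- function(xy, window = 200L,
                                 trap_diameter = 75) {
  if (window < 2L) stop("window must be >= 2")
  xy <- as.matrix(xy)
  n <- nrow(xy)
  episodes <- list()
  s <- 1L
  while (s <= n - 1L) {
    xmin <- xmax <- xy[s, 1]; ymin <- ymax <- xy[s, 2]
    e <- s
    while (e < n) {
      nx <- xy[e + 1L, 1]; ny <- xy[e + 1L, 2]
      x0 <- min(xmin, nx); x1 <- max(xmax, nx)
      y0 <- min(ymin, ny); y1 <- max(ymax, ny)
      if (sqrt((x1 - x0)^2 + (y1 - y0)^2) > trap_diameter) break
      xmin <- x0; xmax <- x1; ymin <- y0; ymax <- y1
      e <- e + 1L
    }
    if (e - s + 1L >= window) {
      episodes[[length(episodes) + 1L]] <- list(
        start = s, end = e,
        diagonal = sqrt((xmax - xmin)^2 + (ymax - ymin)^2),
        center = c((xmin + xmax) / 2, (ymin + ymax) / 2)
      )
      s <- e + 1L
    } else {
      s <- s + 1L
    }
  }
  episodes
}

#' Aggregate an experiment table
#'
#' Per-mode mean disappeared counts by color, mean totals, and the mean
#' fraction of all field objects touched.
#'
#' @param rows an `experiment_table` (any subset of rows).
#' @param n_objects total number of objects per run; defaults to the
#'   table's `n_objects` attribute, else 200.
#' @return Data frame: `mode`, the four color means, `total`,
#'   `fraction_touched`, `n_sims`.
#' @export
summarize_table <- function(rows, n_objects = NULL) {
  if (is.null(n_objects)) {
    n_objects <- attr(rows, "n_objects")
    if (is.null(n_objects)) n_objects <- 200L
  }
  out <- lapply(sort(unique(rows$mode)), function(m) {
    sub <- rows[rows$mode == m, , drop = FALSE]
    data.frame(
      mode = m,
      red = mean(sub$red), green = mean(sub$green),
      yellow = mean(sub$yellow), blue = mean(sub$blue),
      total = mean(sub$total),
      fraction_touched = mean(sub$total) / n_objects,
      n_sims = nrow(sub)
    )
  })
  do.call(rbind, out)
}

#' Full statistical report of a mode-comparison experiment
#'
#' Aggregates the table and evaluates the three directional hypotheses:
#' H1, in Mode 1 the organism stays largely trapped (fraction of objects
#' touched at most `h1_max_fraction`); H2, in the learning modes red
#' objects disappear significantly less than every other color (Wilcoxon
#' matched pairs, p < `alpha`, with lower red means); H3, the mean total
#' in Mode 4 strictly exceeds every other mode run in the same
#' experiment.
#'
#' @param rows an `experiment_table` covering the modes of interest.
#' @param alpha significance level for H2.
#' @param h1_max_fraction threshold fraction for H1.
#' @return List: `summary`, `friedman` (per mode), `wilcoxon` (per
#'   learning mode), `hypotheses` (named logicals, `NA` when the needed
#'   modes are absent).
#' @export
analyze_experiment <- function(rows, alpha = 0.05, h1_max_fraction = 0.10) {
  summ <- summarize_table(rows)
  modes <- sort(unique(rows$mode))
  fried <- setNames(lapply(modes, function(m) {
    friedman_by_color(rows[rows$mode == m, , drop = FALSE])
  }), paste0("mode", modes, recycle0 = TRUE))
  lmodes <- intersect(modes, 2:4)
  wilc <- setNames(lapply(lmodes, function(m) {
    wilcoxon_red_vs_colors(rows[rows$mode == m, , drop = FALSE])
  }), paste0("mode", lmodes, recycle0 = TRUE))

  h1 <- if (1 %in% modes)
    summ$fraction_touched[summ$mode == 1] <= h1_max_fraction else NA
  h2 <- if (length(lmodes)) {
    all(vapply(lmodes, function(m) {
      sub <- rows[rows$mode == m, , drop = FALSE]
      w <- wilc[[paste0("mode", m)]]
      all(w$p < alpha) &&
        all(mean(sub$red) < c(mean(sub$green), mean(sub$yellow),
                              mean(sub$blue)))
    }, logical(1)))
  } else NA
  h3 <- if (4 %in% modes && length(setdiff(modes, 4))) {
    m4 <- summ$total[summ$mode == 4]
    all(m4 > summ$total[summ$mode != 4])
  } else NA

  list(summary = summ, friedman = fried, wilcoxon = wilc,
       hypotheses = list(h1_mode1_inactive = h1,
                         h2_red_avoided = h2,
                         h3_mode4_dominant = h3))
}
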