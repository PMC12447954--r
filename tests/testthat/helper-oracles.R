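# Independent oracles used by the geometry and regression tests. These are
# deliberately naive implementations that share no code with the package.

# O(n^3) brute-force convex hull: a pair (i, j) is a hull edge iff every
# other point lies (weakly) on one side of the line through i and j; the
# hull vertex set is the set of edge endpoints. Suitable for continuous
# random clouds (no exact collinearity).
brute_hull_vertices <- function(x, y, eps = 1e-12) {
  n <- length(x)
  on_hull <- rep(FALSE, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cr <- (x[j] - x[i]) * (y - y[i]) - (y[j] - y[i]) * (x - x[i])
      if (all(cr <= eps) || all(cr >= -eps)) {
        on_hull[i] <- TRUE
        on_hull[j] <- TRUE
      }
    }
  }
  which(on_hull)
}

# Grid-refinement least squares of log10(y) on log10(x): the intercept is
# profiled out in closed form, the slope found by three rounds of grid
# search. Agrees with the analytic OLS slope to ~1e-7.
grid_loglog_slope <- function(x, y) {
  lx <- log10(x); ly <- log10(y)
  sse <- function(s) sum((ly - (mean(ly) - s * mean(lx)) - s * lx)^2)
  lo <- -10; hi <- 10
  for (round in 1:4) {
    grid <- seq(lo, hi, length.out = 1001)
    vals <- vapply(grid, sse, 0)
    best <- grid[which.min(vals)]
    step <- grid[2] - grid[1]
    lo <- best - 2 * step
    hi <- best + 2 * step
  }
  best
}

# shared fixture loads (quiet)
load_table1 <- function() suppressMessages(read_specimens("table1_mammals"))
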