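# Independent oracles used to freeze expected values.

# strict bisection on Y(x) = Y(0)/2 for the competition model; independent of
# the closed-form implied_ic50 it checks
ic50_bisection <- function(l_dis, k_d_dis, k_d_x, lo = 1e-12, hi = 1e15,
                           iter = 200) {
  y_half <- competition_saturation(0, l_dis, k_d_dis, k_d_x) / 2
  f <- function(x) competition_saturation(x, l_dis, k_d_dis, k_d_x) - y_half
  stopifnot(f(lo) > 0, f(hi) < 0)
  for (i in seq_len(iter)) {
    mid <- sqrt(lo * hi)  # geometric bisection suits the positive axis
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  sqrt(lo * hi)
}

# brute-force lattice search over a parameter box; returns the lowest RSS on
# the grid, an upper bound no optimizer should exceed by more than epsilon
grid_search_rss <- function(model, x, y, grids) {
  combos <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  best <- Inf
  for (i in seq_len(nrow(combos))) {
    p <- as.list(combos[i, ])
    rss <- sum((y - model(x, p))^2)
    if (rss < best) best <- rss
  }
  best
}
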