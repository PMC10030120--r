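direct_xy <- function(k_d, n = 24, b_max = 100, ns = 0.0125, bg = 220,
                      sd = 0, seed = 1) {
  x <- 6000 / (6000 / 13)^((seq_len(n) - 1) / (n - 1))
  set.seed(seed)
  y <- direct_binding_fp(x, b_max, k_d, ns, bg) + rnorm(n, 0, sd)
  list(x = x, y = y)
}

dmodel <- function(x, p)
  p$b_max * x / (x + p$k_d) + p$ns_slope * x + p$background

dspecs <- function(shared = FALSE) rbind(
  par_spec("b_max", 50, 0, Inf, shared = shared),
  par_spec("background", 0, -Inf, Inf, shared = shared),
  par_spec("k_d", 500, 1e-3, 1e7, log_scale = TRUE),
  par_spec("ns_slope", 0.001, 0, 1))

test_that("noiseless data are recovered exactly", {
  d <- direct_xy(100)
  fit <- fit_global(dmodel, fpn_dataset("a", d$x, d$y), dspecs())
  expect_true(fit$converged)
  expect_equal(fit_estimate(fit, "k_d")$value, 100, tolerance = 1e-6)
  expect_equal(fit_estimate(fit, "b_max")$value, 100, tolerance = 1e-6)
  expect_equal(fit_estimate(fit, "background")$value, 220, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-12)
})

test_that("sharing across noiseless datasets equals independent fits", {
  d1 <- direct_xy(100); d2 <- direct_xy(500)
  ds <- list(fpn_dataset("a", d1$x, d1$y), fpn_dataset("b", d2$x, d2$y))
  shared <- fit_global(dmodel, ds, dspecs(shared = TRUE))
  f1 <- fit_global(dmodel, fpn_dataset("a", d1$x, d1$y), dspecs())
  f2 <- fit_global(dmodel, fpn_dataset("b", d2$x, d2$y), dspecs())
  expect_equal(fit_estimate(shared, "k_d", "a")$value,
               fit_estimate(f1, "k_d")$value, tolerance = 1e-6)
  expect_equal(fit_estimate(shared, "k_d", "b")$value,
               fit_estimate(f2, "k_d")$value, tolerance = 1e-6)
  expect_equal(fit_estimate(shared, "b_max")$value, 100, tolerance = 1e-6)
})

test_that("optimizer RSS is never beaten by a coarse lattice search", {
  set.seed(5)
  d <- direct_xy(150, sd = 5, seed = 7)
  fit <- fit_global(dmodel, fpn_dataset("a", d$x, d$y), dspecs())
  grid_best <- grid_search_rss(
    function(x, p) dmodel(x, p), d$x, d$y,
    list(b_max = seq(80, 120, by = 2), k_d = 10^seq(1.5, 2.8, by = 0.05),
         ns_slope = seq(0, 0.03, by = 0.002),
         background = seq(210, 230, by = 1)))
  expect_lt(fit$rss, grid_best + 1e-8)
})

test_that("estimates are invariant to dataset ordering", {
  d1 <- direct_xy(100, sd = 3, seed = 2); d2 <- direct_xy(700, sd = 3, seed = 3)
  a <- fit_global(dmodel, list(fpn_dataset("a", d1$x, d1$y),
                               fpn_dataset("b", d2$x, d2$y)),
                  dspecs(shared = TRUE))
  b <- fit_global(dmodel, list(fpn_dataset("b", d2$x, d2$y),
                               fpn_dataset("a", d1$x, d1$y)),
                  dspecs(shared = TRUE))
  expect_equal(fit_estimate(a, "k_d", "a")$value,
               fit_estimate(b, "k_d", "a")$value, tolerance = 1e-6)
  expect_equal(a$rss, b$rss, tolerance = 1e-8)
})

test_that("bounds are respected and boundary solutions are flagged", {
  d <- direct_xy(100)
  specs <- rbind(
    par_spec("b_max", 40, 0, 50),  # truth 100 lies above the box
    par_spec("background", 220, fixed = TRUE),
    par_spec("k_d", 100, fixed = TRUE),
    par_spec("ns_slope", 0.0125, fixed = TRUE))
  fit <- fit_global(dmodel, fpn_dataset("a", d$x, d$y), specs)
  est <- fit$estimates[fit$estimates$name == "b_max", ]
  expect_equal(est$value, 50)
  expect_true(est$at_bound)
})

test_that("underdetermined problems are refused", {
  specs <- dspecs()
  expect_error(fit_global(dmodel, fpn_dataset("a", c(1, 10, 100), c(1, 2, 3)),
                          specs),
               "underdetermined")
})

test_that("asymptotic SEs calibrate against known noise", {
  # kd SE should make the 3-SE interval cover truth for most seeds
  hits <- vapply(1:40, function(s) {
    d <- direct_xy(100, sd = 5, seed = s)
    fit <- fit_global(dmodel, fpn_dataset("a", d$x, d$y), dspecs())
    kd <- fit_estimate(fit, "k_d")
    abs(kd$value - 100) <= 3 * kd$se
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("bootstrap SEs: zero noise collapses, seed reproduces, noise scales", {
  d <- direct_xy(100)
  fit <- fit_global(dmodel, fpn_dataset("a", d$x, d$y, rep(1:3, 8)), dspecs())
  b1 <- bootstrap_se(fit, n_boot = 20, seed = 4)
  expect_true(all(b1$se_boot < 1e-6))
  expect_error(bootstrap_se(fit, n_boot = 5), "insufficient")

  dn <- direct_xy(100, n = 60, sd = 5, seed = 9)
  fitn <- fit_global(dmodel, fpn_dataset("a", dn$x, dn$y, rep(1:6, 10)),
                     dspecs())
  b2 <- bootstrap_se(fitn, n_boot = 60, seed = 4)
  b3 <- bootstrap_se(fitn, n_boot = 60, seed = 4)
  expect_identical(b2$se_boot, b3$se_boot)
  kd_row <- which(b2$name == "k_d")
  ratio <- b2$se_boot[kd_row] / b2$se[kd_row]
  expect_gt(ratio, 0.5); expect_lt(ratio, 2)
})
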