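test_that("FP from intensities: arithmetic, symmetry, bounds, errors", {
  expect_equal(fp_from_intensities(300, 100), 500)
  for (k in c(0.5, 1, 37, 1e6)) expect_equal(fp_from_intensities(k, k), 0)
  expect_equal(fp_from_intensities(200, 0), 1000)
  expect_error(fp_from_intensities(0, 0), "degenerate")
  expect_error(fp_from_intensities(-1, 10), "invalid read")
  # bounded and antisymmetric under channel swap at g = 1
  set.seed(11)
  a <- runif(200, 0, 1e4); b <- runif(200, 0, 1e4)
  ok <- a + b > 0
  fp <- fp_from_intensities(a[ok], b[ok])
  expect_true(all(fp >= -1000 & fp <= 1000))
  expect_equal(fp_from_intensities(b[ok], a[ok]), -fp)
})

test_that("FP from intensities honors the G-factor", {
  # g scaling the perpendicular channel: fp = 0 when f_para = g * f_perp
  expect_equal(fp_from_intensities(200, 100, g_factor = 2), 0)
  expect_equal(fp_from_intensities(300, 100, g_factor = 1.5),
               1000 * (300 - 150) / (300 + 150))
})

test_that("direct-binding model: zero input, half saturation, substitution", {
  expect_equal(direct_binding_fp(0, 150, 100, 0.01, 150), 150)
  expect_equal(direct_binding_fp(100, 150, 100, 0, 150), 150 + 75)
  expect_equal(direct_binding_fp(100, 150, 100, 0.01, 150), 226)
  expect_error(direct_binding_fp(-5, 150, 100), "invalid concentration")
  # monotone nondecreasing for nonnegative nonspecific slope
  x <- sort(runif(100, 0, 1e4))
  expect_true(all(diff(direct_binding_fp(x, 80, 250, 0.002, 10)) >= 0))
})

test_that("Hill displacement curve decreases with competitor", {
  # midpoint identity at the study's shared plateaus (225/307 mP)
  expect_equal(hill_fp(10^2.5, 225, 307, 2.5, 1), (225 + 307) / 2)
  # the retained sign convention gives the decreasing displacement curve:
  # the increasing-argument variant of the same four-parameter form would
  # return 90.909...; the displacement read must fall below midpoint
  expect_equal(hill_fp(1000, 0, 100, 2, 1), 100 / 11)
  x <- 10^seq(-1, 5, by = 0.25)
  y <- hill_fp(x, 225, 307, 2, 1)
  expect_true(all(diff(y) < 0))
  expect_true(all(y > 225 & y < 307))
  # high-concentration limit is the bottom asymptote
  expect_equal(hill_fp(1e12, 225, 307, 2, 1), 225, tolerance = 1e-6)
  expect_error(hill_fp(0, 0, 100, 2, 1), "excluded")
})

test_that("competition model: anchor point, half point, limits", {
  expect_equal(competition_saturation(0, 400, 100, 25), 0.8)
  # half-displacement concentration verified against the bisection oracle
  half_x <- 25 * (1 + 400 / 100)
  expect_equal(competition_saturation(half_x, 400, 100, 25), 0.4)
  expect_equal(ic50_bisection(400, 100, 25), half_x, tolerance = 1e-9)
  # an infinitely weak competitor displaces nothing
  expect_equal(competition_saturation(5000, 400, 100, 1e15), 0.8,
               tolerance = 1e-9)
})

test_that("competition model monotonicity on randomized parameter grids", {
  set.seed(21)
  for (i in 1:50) {
    l <- runif(1, 10, 2000); kd <- runif(1, 1, 2000); kx <- runif(1, 1, 2000)
    x <- sort(runif(20, 0, 1e5))
    expect_true(all(diff(competition_saturation(x, l, kd, kx)) < 0))
    # increasing in l_dis and k_d_x, decreasing in k_d_dis
    x0 <- runif(1, 1, 1e4)
    expect_lt(competition_saturation(x0, l, kd, kx),
              competition_saturation(x0, l * 2, kd, kx))
    expect_gt(competition_saturation(x0, l, kd, kx),
              competition_saturation(x0, l, kd * 2, kx))
    expect_lt(competition_saturation(x0, l, kd, kx),
              competition_saturation(x0, l, kd, kx * 2))
  }
})

test_that("implied IC50 closed form matches the bisection oracle", {
  expect_equal(implied_ic50(400, 100, 25), 125)
  expect_equal(implied_ic50(400, 100, 150), 750)
  # l_dis -> 0 recovers the bare KD
  expect_equal(implied_ic50(1e-9, 100, 42), 42, tolerance = 1e-9)
  set.seed(31)
  for (i in 1:100) {
    l <- 10^runif(1, 0, 4); kd <- 10^runif(1, -1, 4); kx <- 10^runif(1, -1, 4)
    expect_equal(implied_ic50(l, kd, kx), ic50_bisection(l, kd, kx),
                 tolerance = 1e-9)
  }
})

test_that("KD from IC50 inverts the implied IC50 exactly", {
  expect_equal(kd_from_ic50(125, 400, 100), 25)
  expect_equal(kd_from_ic50(750, 400, 100), 150)
  set.seed(41)
  for (i in 1:100) {
    l <- 10^runif(1, 0, 4); kd <- 10^runif(1, -1, 4); kx <- 10^runif(1, -1, 4)
    expect_equal(kd_from_ic50(implied_ic50(l, kd, kx), l, kd), kx,
                 tolerance = 1e-9)
  }
})

test_that("FP to fractional saturation is the linear stage-1 inversion", {
  bg <- 220; ns <- 0.0125; bm <- 100; l <- 400
  expect_equal(fractional_saturation_from_fp(bg + ns * l, bm, ns, bg, l), 0)
  expect_equal(
    fractional_saturation_from_fp(bg + ns * l + bm * 0.8, bm, ns, bg, l), 0.8)
  expect_warning(fractional_saturation_from_fp(bg - 50, bm, ns, bg, l),
                 "outside")
  expect_error(fractional_saturation_from_fp(250, 0, ns, bg, l), "degenerate")
})

test_that("Michaelis-Menten and melting-curve identities", {
  expect_equal(mm_rate(0, 2, 5), 0)
  expect_equal(mm_rate(5, 2, 5), 1)
  expect_equal(mm_rate(45, 2, 5), 1.8)
  expect_error(mm_rate(-1, 2, 5), "invalid concentration")
  expect_equal(melt_fraction(47, 47, 0.5, 100, 0), 50)
  expect_equal(melt_fraction(-1e4, 47, 0.5, 100, 0), 100)
  expect_equal(melt_fraction(1e4, 47, 0.5, 100, 0), 0)
})

test_that("1:1 SPR model: steady state, half-life, errors", {
  kon <- 1e5; koff <- 0.05; rmax <- 100; kd <- koff / kon
  expect_equal(spr_response(1e9, conc = 2 * kd, phase = "association",
                            k_on = kon, k_off = koff, r_max = rmax),
               rmax * 2 / 3)
  expect_equal(spr_response(1e9, conc = kd, phase = "association",
                            k_on = kon, k_off = koff, r_max = rmax),
               rmax / 2)
  expect_equal(spr_response(log(2) / koff, phase = "dissociation",
                            k_on = kon, k_off = koff, r_max = rmax, r0 = 80),
               40)
  expect_error(spr_response(1, conc = 0, phase = "association",
                            k_on = kon, k_off = koff, r_max = rmax),
               "invalid analyte")
})
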