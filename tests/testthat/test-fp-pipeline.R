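test_that("per-well FP computation round-trips and flags degenerate wells", {
  d <- direct_design(noise_sd = 0)
  pl <- gen_direct_titration(d, seed = 1)
  out <- compute_plate_fp(pl)
  expect_equal(nrow(out), nrow(pl))  # every input well accounted for
  expect_equal(out$fp_mp,
               fp_from_intensities(pl$f_para, pl$f_perp), tolerance = 1e-12)
  # one zero-intensity well is flagged, the rest processed
  pl$f_para[5] <- 0; pl$f_perp[5] <- 0
  out2 <- compute_plate_fp(pl)
  expect_equal(out2$flag[5], "degenerate")
  expect_true(is.na(out2$fp_mp[5]))
  expect_equal(sum(out2$flag == "ok"), nrow(pl) - 1)
})

test_that("stage-1 global fit recovers noiseless truths with shared Bmax", {
  truths <- study_truths()[1:3, ]
  pl <- gen_study_plate(seed = 3, truths = truths, noise_sd = 0)
  fd <- fit_direct(pl)
  expect_equal(fd$b_max, 100, tolerance = 1e-6)
  expect_equal(fd$background, 220, tolerance = 1e-6)
  for (i in seq_len(nrow(truths))) {
    k <- fd$params$k_d[fd$params$construct == truths$construct[i]]
    expect_equal(k, truths$k_d_tracer[i], tolerance = 1e-6)
  }
  expect_true(all(fd$params$specific_binding))
})

test_that("stage-1 rejects constructs with too few points by name", {
  pl <- gen_direct_titration(direct_design(noise_sd = 0), seed = 1)
  tiny <- pl[1:3, ]; tiny$construct <- "STUB"
  expect_error(fit_direct(rbind(pl, tiny)), "STUB")
})

test_that("Hill fit of a noiseless competition series recovers n = 1 and the closed-form IC50", {
  sd_ <- displacement_design(k_d_x = 25, l_dis = 400, k_d_dis = 100,
                             noise_sd = 0)
  pd <- gen_displacement(sd_, seed = 2)
  hf <- fit_displacement_hill(pd, "WT")
  expect_equal(hf$params$hill_n, 1, tolerance = 1e-6)
  expect_equal(hf$params$ic50, implied_ic50(400, 100, 25), tolerance = 1e-6)
  # shared plateaus bracket the curve: top at zero competitor FP
  expect_equal(hf$top, 220 + 0.0125 * 400 + 100 * 0.8, tolerance = 1e-4)
})

test_that("a flat inactive-competitor series is flagged unconstrained", {
  sd0 <- displacement_design(k_d_x = Inf, noise_sd = 2)
  pd <- gen_displacement(sd0, seed = 5, competitor = "hep20")
  hf <- suppressWarnings(fit_displacement_hill(pd, "WT"))
  expect_false(hf$params$constrained)
})

test_that("competition fit requires stage 1 and recovers the competitor KD", {
  truths <- study_truths()[1, , drop = FALSE]
  pl <- gen_study_plate(seed = 7, truths = truths, noise_sd = 0)
  expect_error(fit_displacement_competition(pl, "WT", "vamifeport"),
               "pipeline order violation")
  fd <- fit_direct(pl)
  expect_error(fit_displacement_competition(pl, "NOPE", "vamifeport",
                                            direct = fd),
               "pipeline order violation")
  cf <- fit_displacement_competition(pl, "WT", "vamifeport", l_dis = 400,
                                     direct = fd)
  expect_equal(cf$k_d_x, 24, tolerance = 1e-6)
  expect_equal(cf$ic50_implied, implied_ic50(400, 100, 24), tolerance = 1e-6)
})

test_that("stage-2 KD is invariant to the constant nonspecific offset", {
  # two generators differing only in ns_slope (a constant offset at fixed
  # protein) give the same competitor KD after stage-1 conversion
  kds <- vapply(c(0, 0.05), function(ns) {
    tr <- study_truths()[1, , drop = FALSE]
    pl <- gen_study_plate(seed = 11, truths = tr, noise_sd = 0, ns_slope = ns)
    fd <- fit_direct(pl)
    fit_displacement_competition(pl, "WT", "vamifeport", l_dis = 400,
                                 direct = fd)$k_d_x
  }, 0)
  expect_equal(kds[1], kds[2], tolerance = 1e-5)
})

test_that("cross-model consistency: Hill IC50 agrees with the competition-implied IC50", {
  tr <- study_truths()[1, , drop = FALSE]
  # noiseless: agreement to numerical precision
  pl0 <- gen_study_plate(seed = 13, truths = tr, noise_sd = 0)
  fd0 <- fit_direct(pl0)
  h0 <- fit_displacement_hill(pl0, "WT", competitors = "vamifeport")
  c0 <- fit_displacement_competition(pl0, "WT", "vamifeport", direct = fd0)
  expect_equal(h0$params$ic50, c0$ic50_implied, tolerance = 1e-5)
  # at assay noise: within 15%
  pl5 <- gen_study_plate(seed = 13, truths = tr, noise_sd = 5)
  fd5 <- fit_direct(pl5)
  h5 <- fit_displacement_hill(pl5, "WT", competitors = "vamifeport")
  c5 <- fit_displacement_competition(pl5, "WT", "vamifeport", direct = fd5)
  expect_lt(abs(h5$params$ic50 - c5$ic50_implied) / c5$ic50_implied, 0.15)
})

test_that("full pipeline: noiseless end-to-end identity and determinism", {
  truths <- study_truths()
  pl <- gen_study_plate(seed = 17, truths = truths, noise_sd = 0)
  rep1 <- run_pipeline(pl, study_config(seed = 17))
  for (i in seq_len(nrow(truths))) {
    r <- rep1$table[rep1$table$construct == truths$construct[i], ]
    expect_equal(r$k_d_tracer, truths$k_d_tracer[i], tolerance = 1e-6)
    if (!is.na(truths$k_d_hep25[i]))
      expect_equal(r$k_d_hep25, truths$k_d_hep25[i], tolerance = 1e-6)
    if (!is.na(truths$k_d_vamifeport[i]))
      expect_equal(r$k_d_vamifeport, truths$k_d_vamifeport[i],
                   tolerance = 1e-6)
  }
  # identical inputs and seed give an identical report
  rep2 <- run_pipeline(pl, study_config(seed = 17))
  expect_identical(rep1$table, rep2$table)
  # well conservation
  expect_equal(rep1$wells$total,
               rep1$wells$used_direct + rep1$wells$used_displacement +
                 rep1$wells$flagged)
})

test_that("pipeline handles empty and minimal plates", {
  expect_error(run_pipeline(data.frame()), "empty plate")
  tr <- study_truths()[1, , drop = FALSE]
  pl <- gen_study_plate(seed = 19, truths = tr, noise_sd = 0)
  rep <- run_pipeline(pl, study_config(seed = 19, truths = tr))
  expect_equal(nrow(rep$table), 1)
  expect_equal(rep$table$construct, "WT")
})

test_that("constructs without specific binding are excluded from stage 2", {
  # a construct whose KD is far beyond the titration range and whose signal
  # is dominated by the nonspecific slope
  tr <- data.frame(construct = c("WT", "DEAD"),
                   k_d_tracer = c(100, 3e5), k_d_hep25 = c(131, NA),
                   k_d_vamifeport = c(24, NA), l_dis = c(400, 400))
  pl <- gen_study_plate(seed = 23, truths = tr, noise_sd = 5)
  rep <- run_pipeline(pl, study_config(seed = 23, truths = tr))
  dead <- rep$table[rep$table$construct == "DEAD", ]
  expect_equal(dead$note, "no specific binding")
  expect_true(is.na(dead$k_d_tracer))
  wt <- rep$table[rep$table$construct == "WT", ]
  expect_equal(wt$note, "")
  expect_false(is.na(wt$k_d_vamifeport))
})
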