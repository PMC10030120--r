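#' Study-design ground truths and full-plate generator
#'
#' The reference experiment this package emulates: direct-binding titrations
#' of wild-type ferroportin and binding-site point mutants against 10 nM
#' TMR-hepcidin tracer, followed by displacement of the tracer with
#' unlabeled hepcidin-25 and vamifeport at fixed protein concentration
#' (400 nM; 800 nM for the low-affinity R466A mutant). The ground-truth KDs
#' are the construct-level binding constants of that study.
#'
#' @name study_design
NULL

#' Ground-truth binding constants of the reference study design
#'
#' One row per construct: tracer KD, hepcidin-25 KD, vamifeport KD (nM; NA
#' where the study determined none) and the fixed protein concentration used
#' in its displacement series. V68S binds tracer weakly and has no
#' displacement data.
#'
#' @return data.frame with columns construct, k_d_tracer, k_d_hep25,
#'   k_d_vamifeport, l_dis
#' @export
study_truths <- function() {
  data.frame(
    construct = c("WT", "R466A", "L469A", "L469S", "W470S", "V68S"),
    k_d_tracer = c(100, 501, 57, 94, 227, 1044),
    k_d_hep25 = c(131, 713, 108, 180, 222, NA),
    k_d_vamifeport = c(24, 83, 37, 60, 82, NA),
    l_dis = c(400, 800, 400, 400, 400, 400),
    stringsAsFactors = FALSE)
}

#' Generate the full synthetic study plate
#'
#' Direct titrations (13 nM to 6 uM, 24 points, blocked 30 uM controls) for
#' every construct in `truths`, plus hepcidin-25 and vamifeport displacement
#' ladders at the per-construct protein concentration for constructs with
#' competition truths. Optionally adds an inactive-competitor (hepcidin-20
#' analog) flat series for WT.
#'
#' @param seed integer seed
#' @param truths ground-truth table as from [study_truths()]
#' @param noise_sd Gaussian FP noise (mP); 0 for the noiseless identity
#' @param replicates wells per concentration
#' @param include_inactive add a flat hepcidin-20-like series for WT
#' @param b_max,ns_slope,background shared signal truth
#' @return plate table covering the whole design
#' @export
gen_study_plate <- function(seed, truths = study_truths(), noise_sd = 5,
                            replicates = 3, include_inactive = FALSE,
                            b_max = 100, ns_slope = 0.0125,
                            background = 220) {
  plates <- list()
  for (i in seq_len(nrow(truths))) {
    tr <- truths[i, ]
    dd <- direct_design(k_d = tr$k_d_tracer, b_max = b_max,
                        ns_slope = ns_slope, background = background,
                        noise_sd = noise_sd, replicates = replicates)
    plates[[paste0("dir_", tr$construct)]] <-
      gen_direct_titration(dd, seed = seed + i, construct = tr$construct)
    for (cp in c("hep25", "vamifeport")) {
      kdx <- tr[[paste0("k_d_", cp)]]
      if (is.na(kdx)) next
      sd_ <- displacement_design(k_d_x = kdx, l_dis = tr$l_dis,
                                 k_d_dis = tr$k_d_tracer, b_max = b_max,
                                 ns_slope = ns_slope,
                                 background = background,
                                 noise_sd = noise_sd,
                                 replicates = replicates)
      plates[[paste(tr$construct, cp, sep = "_")]] <-
        gen_displacement(sd_, seed = seed + 100 * i + match(cp, c("hep25", "vamifeport")),
                         construct = tr$construct, competitor = cp)
    }
  }
  if (include_inactive) {
    sd0 <- displacement_design(k_d_x = Inf, l_dis = 400, k_d_dis = 100,
                               b_max = b_max, ns_slope = ns_slope,
                               background = background, noise_sd = noise_sd,
                               replicates = replicates)
    plates[["WT_hep20"]] <- gen_displacement(sd0, seed = seed + 999,
                                             construct = "WT",
                                             competitor = "hep20")
  }
  do.call(rbind, c(plates, make.row.names = FALSE))
}

#' Pipeline configuration matching the study design
#'
#' Per-construct protein concentrations from `truths` plus the seed, suitable
#' as the `config` of [run_pipeline()].
#'
#' @param seed integer seed recorded in provenance
#' @param truths ground-truth table
#' @param options [fit_options()]
#' @return config list
#' @export
study_config <- function(seed, truths = study_truths(),
                         options = fit_options()) {
  list(l_dis = stats::setNames(as.list(truths$l_dis), truths$construct),
       options = options, seed = seed)
}
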