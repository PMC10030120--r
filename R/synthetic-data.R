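#' Seeded synthetic-data generators
#'
#' Each generator is a deterministic function of a design and a seed and
#' emits the same tabular shapes the readers consume, so every stage of the
#' pipeline is testable without instrument data. The default designs mirror
#' the study conditions: protein titrations from 13 nM to 6 uM against 10 nM
#' tracer, serial-dilution displacement series at 400 nM protein (800 nM for
#' low-affinity constructs), nonspecific-binding controls blocked with 30 uM
#' inhibitor, melting series up to 75 C normalized to a 4 C reference,
#' calcein-quench transport traces with a valinomycin/CoCl2/calcimycin event
#' schedule, and multi-concentration SPR association/dissociation ladders.
#'
#' @name synthetic_data
NULL

#' Invert the FP formula at fixed total intensity
#'
#' Splits a total fluorescence intensity into parallel/perpendicular channels
#' reproducing a target FP at G-factor 1:
#' `f_parallel = total (1 + fp/1000)/2`, `f_perpendicular = total (1 - fp/1000)/2`.
#'
#' @param fp FP in mP, |fp| <= 1000; vectorized
#' @param total_intensity total intensity (AU), > 0
#' @return data.frame with columns `f_para`, `f_perp`
#' @export
intensities_from_fp <- function(fp, total_intensity = 2000) {
  if (any(abs(fp) > 1000, na.rm = TRUE)) stop("|fp| exceeds 1000 mP")
  stopifnot(all(total_intensity > 0))
  data.frame(f_para = total_intensity * (1 + fp / 1000) / 2,
             f_perp = total_intensity * (1 - fp / 1000) / 2)
}

# geometric concentration ladder from top down
dilution_ladder <- function(top, n, factor = NULL, bottom = NULL) {
  stopifnot(n >= 2, top > 0)
  if (is.null(factor)) {
    stopifnot(bottom > 0, bottom < top)
    factor <- (top / bottom)^(1 / (n - 1))
  }
  top / factor^(seq_len(n) - 1)
}

#' Design of a direct-binding titration
#'
#' Defaults emulate the study layout: 24 protein concentrations spanning
#' 13 nM to 6 uM, 10 nM tracer, three replicates, Gaussian FP noise of
#' 5 mP, and blocked control wells containing 30 uM inhibitor in which the
#' specific signal is abolished.
#'
#' @param k_d true tracer dissociation constant (nM)
#' @param b_max,ns_slope,background true signal parameters (mP, mP/nM, mP)
#' @param top_conc,bottom_conc,n_points titration ladder (nM)
#' @param replicates replicate wells per concentration
#' @param noise_sd Gaussian noise on the FP scale (mP)
#' @param noise_model `"fp"` (additive mP noise, mapped to intensities at
#'   fixed total) or `"intensity"` (multiplicative CV on each channel)
#' @param intensity_cv channel CV when `noise_model = "intensity"`
#' @param total_intensity per-well total fluorescence (AU)
#' @param tracer_conc tracer concentration (nM); recorded metadata
#' @param blocked_wells include nonspecific-control wells at 30 uM blocker
#' @return list of class `direct_design`
#' @export
direct_design <- function(k_d = 100, b_max = 100, ns_slope = 0.0125,
                          background = 220, top_conc = 6000,
                          bottom_conc = 13, n_points = 24, replicates = 3,
                          noise_sd = 5, noise_model = c("fp", "intensity"),
                          intensity_cv = 0.01, total_intensity = 2000,
                          tracer_conc = 10, blocked_wells = TRUE) {
  stopifnot(n_points >= 4, noise_sd >= 0, k_d > 0)
  structure(list(k_d = k_d, b_max = b_max, ns_slope = ns_slope,
                 background = background, top_conc = top_conc,
                 bottom_conc = bottom_conc, n_points = n_points,
                 replicates = replicates, noise_sd = noise_sd,
                 noise_model = match.arg(noise_model),
                 intensity_cv = intensity_cv,
                 total_intensity = total_intensity,
                 tracer_conc = tracer_conc, blocked_wells = blocked_wells),
            class = "direct_design")
}

add_noise_and_wells <- function(fp_true, d, seed_offset = 0, seed) {
  set.seed(seed + seed_offset)
  if (d$noise_model == "fp") {
    fp <- fp_true + stats::rnorm(length(fp_true), 0, d$noise_sd)
    ints <- intensities_from_fp(pmin(pmax(fp, -999.9), 999.9),
                                d$total_intensity)
  } else {
    ints <- intensities_from_fp(fp_true, d$total_intensity)
    ints$f_para <- ints$f_para * (1 + stats::rnorm(nrow(ints), 0, d$intensity_cv))
    ints$f_perp <- ints$f_perp * (1 + stats::rnorm(nrow(ints), 0, d$intensity_cv))
  }
  ints
}

#' Generate a direct-binding titration plate
#'
#' @param design a [direct_design()]
#' @param seed integer seed (mandatory; the table is a deterministic function
#'   of design and seed)
#' @param construct construct label for the plate rows
#' @return plate table (data.frame) with columns sample_id, construct,
#'   competitor, conc_nm, competitor_conc_nm, f_para, f_perp, replicate,
#'   blocked
#' @export
gen_direct_titration <- function(design, seed, construct = "WT") {
  stopifnot(inherits(design, "direct_design"), is.numeric(seed))
  d <- design
  conc <- dilution_ladder(d$top_conc, d$n_points, bottom = d$bottom_conc)
  grid <- expand.grid(conc_nm = conc, replicate = seq_len(d$replicates))
  fp_true <- direct_binding_fp(grid$conc_nm, d$b_max, d$k_d, d$ns_slope,
                               d$background)
  blocked <- rep(FALSE, nrow(grid))
  if (d$blocked_wells) {
    # blocked wells: 30 uM inhibitor abolishes the specific term
    gb <- expand.grid(conc_nm = conc, replicate = seq_len(d$replicates))
    fp_b <- d$background + d$ns_slope * gb$conc_nm
    grid <- rbind(grid, gb)
    fp_true <- c(fp_true, fp_b)
    blocked <- c(blocked, rep(TRUE, nrow(gb)))
  }
  ints <- add_noise_and_wells(fp_true, d, seed_offset = 0, seed = seed)
  data.frame(sample_id = sprintf("%s_dir_%03d", construct, seq_len(nrow(grid))),
             construct = construct,
             competitor = ifelse(blocked, "vamifeport", ""),
             conc_nm = grid$conc_nm,
             competitor_conc_nm = ifelse(blocked, 30000, 0),
             f_para = ints$f_para, f_perp = ints$f_perp,
             replicate = grid$replicate, blocked = blocked,
             stringsAsFactors = FALSE)
}

#' Design of a displacement (competition) series
#'
#' Defaults: 16-point two-fold serial dilution from 30 uM competitor plus a
#' zero-competitor well, protein fixed at `l_dis`, three replicates, 5 mP
#' Gaussian FP noise. Set `k_d_x = Inf` for an inactive competitor (flat
#' series).
#'
#' @param k_d_x true competitor KD (nM); `Inf` for an inactive competitor
#' @param l_dis fixed protein concentration (nM)
#' @param k_d_dis true tracer KD for this construct (nM)
#' @param b_max,ns_slope,background signal parameters as in [direct_design()]
#' @param top_conc,dilution_factor,n_points competitor ladder
#' @param include_zero include a zero-competitor well per replicate
#' @param replicates,noise_sd,noise_model,intensity_cv,total_intensity noise
#'   model as in [direct_design()]
#' @return list of class `displacement_design`
#' @export
displacement_design <- function(k_d_x, l_dis = 400, k_d_dis = 100,
                                b_max = 100, ns_slope = 0.0125,
                                background = 220, top_conc = 30000,
                                dilution_factor = 2, n_points = 16,
                                include_zero = TRUE, replicates = 3,
                                noise_sd = 5, noise_model = c("fp", "intensity"),
                                intensity_cv = 0.01, total_intensity = 2000) {
  stopifnot(n_points >= 4, l_dis > 0, k_d_dis > 0, k_d_x > 0)
  structure(list(k_d_x = k_d_x, l_dis = l_dis, k_d_dis = k_d_dis,
                 b_max = b_max, ns_slope = ns_slope, background = background,
                 top_conc = top_conc, dilution_factor = dilution_factor,
                 n_points = n_points, include_zero = include_zero,
                 replicates = replicates, noise_sd = noise_sd,
                 noise_model = match.arg(noise_model),
                 intensity_cv = intensity_cv,
                 total_intensity = total_intensity),
            class = "displacement_design")
}

#' Generate a displacement series plate
#'
#' FP wells follow `background + ns_slope * l_dis + b_max * Y(x)` with `Y`
#' the competition-model fractional saturation, so a zero-competitor well
#' reproduces the direct-binding FP at `x = l_dis`.
#'
#' @param design a [displacement_design()]
#' @param seed integer seed
#' @param construct,competitor labels for the plate rows
#' @return plate table as in [gen_direct_titration()]
#' @export
gen_displacement <- function(design, seed, construct = "WT",
                             competitor = "vamifeport") {
  stopifnot(inherits(design, "displacement_design"), is.numeric(seed))
  d <- design
  conc <- dilution_ladder(d$top_conc, d$n_points, factor = d$dilution_factor)
  if (d$include_zero) conc <- c(conc, 0)
  grid <- expand.grid(x = conc, replicate = seq_len(d$replicates))
  sat <- if (is.finite(d$k_d_x)) {
    competition_saturation(grid$x, d$l_dis, d$k_d_dis, d$k_d_x)
  } else {
    rep(d$l_dis / (d$l_dis + d$k_d_dis), nrow(grid))  # no displacement
  }
  fp_true <- d$background + d$ns_slope * d$l_dis + d$b_max * sat
  ints <- add_noise_and_wells(fp_true, d, seed_offset = 1000, seed = seed)
  data.frame(sample_id = sprintf("%s_%s_%03d", construct, competitor,
                                 seq_len(nrow(grid))),
             construct = construct, competitor = competitor,
             conc_nm = d$l_dis, competitor_conc_nm = grid$x,
             f_para = ints$f_para, f_perp = ints$f_perp,
             replicate = grid$replicate, blocked = FALSE,
             stringsAsFactors = FALSE)
}

#' Generate a thermal-stability melting series
#'
#' Logistic decay of the normalized monomer-peak height with pre-incubation
#' temperature; the 4 C reference defines 100% stability. Default sampling:
#' 4 C plus 20-75 C in 5 C steps.
#'
#' @param t_m,slope,top,bottom truth of the melting sigmoid
#' @param temperatures temperatures sampled (degrees C)
#' @param noise_sd Gaussian noise on the % scale
#' @param replicates replicate series
#' @param seed integer seed
#' @param condition label, e.g. `"apo"` or `"+vamifeport"`
#' @return data.frame with columns temperature_c, peak_height, replicate,
#'   condition
#' @export
gen_melt <- function(t_m = 47, slope = 0.35, top = 100, bottom = 0,
                     temperatures = c(4, seq(20, 75, by = 5)),
                     noise_sd = 2, replicates = 3, seed, condition = "apo") {
  stopifnot(is.numeric(seed), length(temperatures) >= 5)
  set.seed(seed + 2000)
  grid <- expand.grid(temperature_c = temperatures,
                      replicate = seq_len(replicates))
  y <- melt_fraction(grid$temperature_c, t_m, slope, top, bottom)
  y <- pmax(y + stats::rnorm(nrow(grid), 0, noise_sd), 0)
  data.frame(temperature_c = grid$temperature_c, peak_height = y,
             replicate = grid$replicate, condition = condition,
             stringsAsFactors = FALSE)
}

#' Generate a calcein-quench transport trace
#'
#' Baseline fluorescence, a valinomycin addition that leaves the rate
#' unchanged (electroneutral transport), a CoCl2 addition starting an
#' exponential-approach quench whose initial slope is the Michaelis-Menten
#' rate scaled to the quenchable span, and a calcimycin addition dropping the
#' signal to the full-quench plateau. The single-exponential approach is a
#' generator convenience whose initial slope equals the target rate, not a
#' mechanistic model of the liposome interior.
#'
#' @param co_conc_um CoCl2 concentration (uM); 0 gives a flat control trace
#' @param v_max,k_m transport truth (fraction of quenchable signal per s; uM)
#' @param f0 baseline fluorescence (AU)
#' @param span quenchable signal span (AU)
#' @param t_valinomycin,t_cocl2,t_calcimycin,t_end event schedule (s)
#' @param dt sampling interval (s); instrument default 4 s
#' @param noise_sd additive Gaussian noise (AU)
#' @param seed integer seed
#' @return list with `trace` (data.frame time_s, fluorescence_au) and
#'   `events` (data.frame event, time_s, conc_um)
#' @export
gen_transport_trace <- function(co_conc_um, v_max = 0.002, k_m = 5,
                                f0 = 100, span = 80, t_valinomycin = 60,
                                t_cocl2 = 120, t_calcimycin = 600,
                                t_end = 720, dt = 4, noise_sd = 0.2, seed) {
  stopifnot(is.numeric(seed), co_conc_um >= 0)
  if (!(t_valinomycin < t_cocl2 && t_cocl2 < t_calcimycin))
    stop("invalid event ordering: valinomycin < CoCl2 < calcimycin required")
  set.seed(seed + 3000)
  tt <- seq(0, t_end, by = dt)
  r <- mm_rate(co_conc_um, v_max, k_m)  # fraction of span per s
  f <- rep(f0, length(tt))
  post_co <- tt >= t_cocl2 & tt < t_calcimycin
  f[post_co] <- f0 - span * (1 - exp(-r * (tt[post_co] - t_cocl2)))
  f[tt >= t_calcimycin] <- f0 - span
  f <- f + stats::rnorm(length(tt), 0, noise_sd)
  list(trace = data.frame(time_s = tt, fluorescence_au = f),
       events = data.frame(
         event = c("valinomycin", "cocl2", "calcimycin"),
         time_s = c(t_valinomycin, t_cocl2, t_calcimycin),
         conc_um = c(NA, co_conc_um, NA), stringsAsFactors = FALSE))
}

#' Generate an SPR sensorgram ladder
#'
#' Closed-form 1:1 Langmuir association/dissociation traces for a ladder of
#' analyte concentrations, with additive Gaussian RU noise. The default
#' ladder is the Sy3-style two-fold series from 3.4 to 870 nM.
#'
#' @param conc_nm analyte concentrations (nM), >= 2 values
#' @param k_on,k_off,r_max kinetic truth (/M/s, /s, RU)
#' @param t_assoc,t_dissoc phase durations (s)
#' @param dt sampling interval (s)
#' @param noise_sd additive RU noise
#' @param seed integer seed
#' @return long data.frame with columns time_s, response_ru, conc_nm, phase
#' @export
gen_spr <- function(conc_nm = c(3.4, 13.5, 54.5, 109, 217.5, 435, 870),
                    k_on = 1e5, k_off = 0.05, r_max = 100,
                    t_assoc = 120, t_dissoc = 180, dt = 1,
                    noise_sd = 0.5, seed) {
  stopifnot(is.numeric(seed), length(conc_nm) >= 2, all(conc_nm > 0))
  set.seed(seed + 4000)
  out <- do.call(rbind, lapply(conc_nm, function(cn) {
    ta <- seq(0, t_assoc, by = dt)
    ra <- spr_response(ta, conc = cn * 1e-9, phase = "association",
                       k_on = k_on, k_off = k_off, r_max = r_max)
    r0 <- ra[length(ra)]
    td <- seq(dt, t_dissoc, by = dt)
    rd <- spr_response(td, phase = "dissociation",
                       k_on = k_on, k_off = k_off, r_max = r_max, r0 = r0)
    rbind(data.frame(time_s = ta, response_ru = ra, conc_nm = cn,
                     phase = "association"),
          data.frame(time_s = t_assoc + td, response_ru = rd, conc_nm = cn,
                     phase = "dissociation"))
  }))
  out$response_ru <- out$response_ru + stats::rnorm(nrow(out), 0, noise_sd)
  out
}
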