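#' Auxiliary assay fits: thermal stability, transport, SPR
#'
#' Melting-curve (Tm) fits of normalized monomer-peak heights, initial-rate
#' extraction from calcein-quench transport traces with Michaelis-Menten KM
#' estimation, and global 1:1 Langmuir kinetic fits of SPR sensorgram
#' ladders.
#'
#' @name aux_assays
NULL

melt_model <- function(x, p) {
  p$bottom + (p$top - p$bottom) / (1 + exp(p$slope * (x - p$t_m)))
}

#' Fit a sigmoidal melting curve
#'
#' Logistic fit of % stability against pre-incubation temperature; the upper
#' plateau initializes at 100% (the cold reference), the lower plateau is
#' bounded at 0. A series that does not decrease is reported as
#' "no transition detected"; a midpoint outside the sampled range is flagged
#' extrapolated.
#'
#' @param series data.frame with columns `temperature_c` and `peak_height`
#'   (>= 5 temperatures spanning the transition)
#' @param options [fit_options()]
#' @return object of class `fpn_melt_fit`: `t_m`, `t_m_se`, `slope`, `top`,
#'   `bottom`, `extrapolated`, and the `fpn_fit`
#' @export
fit_melt <- function(series, options = fit_options()) {
  stopifnot(all(c("temperature_c", "peak_height") %in% names(series)))
  series <- series[is.finite(series$peak_height), , drop = FALSE]
  if (length(unique(series$temperature_c)) < 5)
    stop("need at least 5 temperatures spanning the transition")
  tt <- series$temperature_c; y <- series$peak_height
  lo <- mean(y[tt <= stats::quantile(tt, 0.25)])
  hi <- mean(y[tt >= stats::quantile(tt, 0.75)])
  if (hi >= lo)
    stop("no transition detected: stability does not decrease with temperature")
  ds <- fpn_dataset("melt", tt, y,
                    if ("replicate" %in% names(series)) series$replicate
                    else seq_along(y))
  specs <- rbind(
    par_spec("t_m", stats::median(tt), min(tt) - 50, max(tt) + 50),
    par_spec("slope", 0.3, 1e-4, 10),
    par_spec("top", 100, 0, Inf),
    par_spec("bottom", 0, 0, Inf))
  fit <- fit_global(melt_model, ds, specs, options)
  tm <- fit_estimate(fit, "t_m")
  structure(list(fit = fit, t_m = tm$value, t_m_se = tm$se,
                 slope = fit_estimate(fit, "slope")$value,
                 top = fit_estimate(fit, "top")$value,
                 bottom = fit_estimate(fit, "bottom")$value,
                 extrapolated = tm$value < min(tt) || tm$value > max(tt),
                 converged = fit$converged),
            class = "fpn_melt_fit")
}

#' Melting-temperature shift between two conditions
#'
#' `holo$t_m - apo$t_m` with the SE propagated under independence
#' (`sqrt(se_apo^2 + se_holo^2)`).
#'
#' @param apo,holo `fpn_melt_fit` objects (e.g. without / with ligand)
#' @return list with `delta_tm`, `se`, `flagged` (TRUE when either fit failed
#'   to converge or was extrapolated)
#' @export
delta_tm <- function(apo, holo) {
  stopifnot(inherits(apo, "fpn_melt_fit"), inherits(holo, "fpn_melt_fit"))
  list(delta_tm = holo$t_m - apo$t_m,
       se = sqrt(apo$t_m_se^2 + holo$t_m_se^2),
       flagged = !(apo$converged && holo$converged) ||
         apo$extrapolated || holo$extrapolated)
}

#' Initial transport rate from a calcein-quench trace
#'
#' Linear-fit slope of the fluorescence over the first `window_s` seconds
#' after the CoCl2 addition, normalized by the quenchable span (baseline mean
#' before CoCl2 minus the post-calcimycin plateau mean) and sign-flipped so
#' influx is positive. Normalization makes the rate invariant to affine
#' rescaling of the raw fluorescence. Without a calcimycin plateau the raw
#' slope is returned with a warning.
#'
#' @param trace data.frame with columns `time_s`, `fluorescence_au`
#' @param events data.frame with columns `event`, `time_s` (must contain a
#'   `cocl2` event; `calcimycin` defines the full-quench plateau)
#' @param window_s rate window after CoCl2 addition (s), default 30
#' @param baseline_s baseline window before CoCl2 (s), default 60
#' @return list with `rate` (fraction of quenchable signal per s), `span`,
#'   `normalized` flag
#' @export
extract_initial_rate <- function(trace, events, window_s = 30,
                                 baseline_s = 60) {
  stopifnot(all(c("time_s", "fluorescence_au") %in% names(trace)))
  if (is.null(events) || !"cocl2" %in% events$event)
    stop("event schedule with a cocl2 event is required")
  t_co <- events$time_s[events$event == "cocl2"][1]
  tt <- trace$time_s; f <- trace$fluorescence_au
  win <- tt >= t_co & tt <= t_co + window_s
  if (sum(win) < 5)
    stop("need at least 5 samples in the post-CoCl2 window")
  slope <- stats::coef(stats::lm(f[win] ~ tt[win]))[2]
  base <- mean(f[tt >= t_co - baseline_s & tt < t_co])
  if ("calcimycin" %in% events$event) {
    t_cal <- events$time_s[events$event == "calcimycin"][1]
    plateau <- mean(f[tt > t_cal + 5])
    span <- base - plateau
    list(rate = as.numeric(-slope / span), span = span, normalized = TRUE)
  } else {
    warning("missing calcimycin plateau: returning unnormalized rate")
    list(rate = as.numeric(-slope), span = NA_real_, normalized = FALSE)
  }
}

mm_model <- function(x, p) p$v_max * x / (p$k_m + x)

#' Michaelis-Menten fit of initial rates
#'
#' The zero-substrate rate (blank) is averaged and subtracted from every
#' rate before fitting `v = v_max s/(k_m + s)`. A KM at or beyond the highest
#' substrate concentration is flagged poorly constrained.
#'
#' @param rates initial rates (per s), one per concentration entry
#' @param concentrations substrate concentrations (uM), >= 4 distinct values
#'   including the blank if present
#' @param options [fit_options()]
#' @return object of class `fpn_km_fit`: `v_max`, `k_m` with SEs,
#'   `poorly_constrained` flag, the `fpn_fit`
#' @export
fit_km <- function(rates, concentrations, options = fit_options()) {
  stopifnot(length(rates) == length(concentrations))
  if (length(unique(concentrations)) < 4)
    stop("need at least 4 substrate concentrations")
  blank <- mean(rates[concentrations == 0])
  if (is.finite(blank)) rates <- rates - blank
  keep <- concentrations > 0
  s <- concentrations[keep]; v <- rates[keep]
  if (all(abs(v) < .Machine$double.eps^0.5)) stop("no transport: all rates zero")
  ds <- fpn_dataset("km", s, v)
  specs <- rbind(
    par_spec("v_max", max(v), 0, Inf),
    par_spec("k_m", exp(mean(log(s))), 1e-6, 1e6, log_scale = TRUE))
  fit <- fit_global(mm_model, ds, specs, options)
  km <- fit_estimate(fit, "k_m"); vm <- fit_estimate(fit, "v_max")
  structure(list(fit = fit, v_max = vm$value, v_max_se = vm$se,
                 k_m = km$value, k_m_se = km$se,
                 poorly_constrained = km$value >= max(s)),
            class = "fpn_km_fit")
}

# piecewise 1:1 Langmuir model over one sensorgram; x carries conc (M),
# time within phase, and the phase indicator
spr_model <- function(x, p) {
  k_obs <- p$k_on * x$conc + p$k_off
  r_eq <- p$r_max * x$conc / (x$conc + p$k_off / p$k_on)
  r_assoc <- r_eq * (1 - exp(-k_obs * x$t_phase))
  # dissociation starts from the model's own end-of-association response
  r0 <- r_eq * (1 - exp(-k_obs * x$t_assoc_end))
  ifelse(x$assoc, r_assoc, r0 * exp(-p$k_off * x$t_phase))
}

#' Global 1:1 kinetic fit of an SPR sensorgram ladder
#'
#' Fits one `k_on`, `k_off`, and `r_max` across all analyte concentrations
#' (single-site semantics); the dissociation phase of each curve starts from
#' the model's end-of-association response. Reports `k_d = k_off/k_on` in nM.
#' With a single concentration the rate constants are not separately
#' identifiable and the fit is flagged.
#'
#' @param sensorgrams long data.frame with columns `time_s`, `response_ru`,
#'   `conc_nm`, `phase` (`"association"`/`"dissociation"`); association is
#'   assumed to start at `time_s = 0` and end at the phase switch
#' @param options [fit_options()]
#' @return object of class `fpn_spr_fit`: `k_on`, `k_off`, `r_max`, `k_d_nm`
#'   with SEs, `flagged`, the `fpn_fit`
#' @export
fit_spr <- function(sensorgrams, options = fit_options()) {
  stopifnot(all(c("time_s", "response_ru", "conc_nm", "phase") %in%
                  names(sensorgrams)))
  concs <- sort(unique(sensorgrams$conc_nm))
  if (length(concs) < 3)
    warning("fewer than 3 analyte concentrations; kinetic fit may be weak")
  datasets <- lapply(concs, function(cn) {
    s <- sensorgrams[sensorgrams$conc_nm == cn, , drop = FALSE]
    assoc <- s$phase == "association"
    if (!any(assoc)) stop("missing association phase at ", cn, " nM")
    t_end <- max(s$time_s[assoc])
    if (!any(!assoc))
      warning("dissociation phase missing at ", cn,
              " nM; k_off weakly constrained")
    x <- data.frame(conc = cn * 1e-9,
                    t_phase = ifelse(assoc, s$time_s, s$time_s - t_end),
                    t_assoc_end = t_end, assoc = assoc)
    fpn_dataset(as.character(cn), x, s$response_ru)
  })
  r_guess <- max(sensorgrams$response_ru)
  specs <- rbind(
    par_spec("k_on", 1e5, 1, 1e12, shared = TRUE, log_scale = TRUE),
    par_spec("k_off", 0.01, 1e-8, 100, shared = TRUE, log_scale = TRUE),
    par_spec("r_max", r_guess, 0, Inf, shared = TRUE))
  fit <- fit_global(spr_model, datasets, specs, options)
  kon <- fit_estimate(fit, "k_on"); koff <- fit_estimate(fit, "k_off")
  rmax <- fit_estimate(fit, "r_max")
  kd_m <- koff$value / kon$value
  # SE of the ratio by the delta method, ignoring kon/koff covariance terms
  # would understate; use full covariance on the internal log scale
  i_on <- which(fit$estimates$name == "k_on")
  i_off <- which(fit$estimates$name == "k_off")
  var_log <- fit$cov[i_off, i_off] + fit$cov[i_on, i_on] -
    2 * fit$cov[i_on, i_off]
  kd_se_m <- kd_m * log(10) * sqrt(max(var_log, 0))
  structure(list(fit = fit, k_on = kon$value, k_on_se = kon$se,
                 k_off = koff$value, k_off_se = koff$se,
                 r_max = rmax$value, r_max_se = rmax$se,
                 k_d_nm = kd_m * 1e9, k_d_nm_se = kd_se_m * 1e9,
                 flagged = length(concs) < 3 || !fit$converged),
            class = "fpn_spr_fit")
}
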