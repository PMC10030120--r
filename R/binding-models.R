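#' Model equations for fluorescence-polarization and auxiliary assays
#'
#' Pure model functions shared by the fitting pipeline and the synthetic-data
#' generators. All concentrations are in nM for binding models, uM for the
#' transport substrate; FP values are in millipolarization units (mP).
#'
#' @name binding_models
NULL

#' Fluorescence polarization from raw intensities
#'
#' Computes FP in millipolarization units from the fluorescence intensities
#' measured parallel and perpendicular to the excitation polarization:
#' \deqn{FP = 1000 \cdot \frac{F_{par} - g\,F_{perp}}{F_{par} + g\,F_{perp}}}
#' The instrument G-factor multiplies the perpendicular channel; it defaults
#' to 1 (no correction).
#'
#' @param f_parallel parallel-channel intensity (arbitrary units, >= 0)
#' @param f_perpendicular perpendicular-channel intensity (>= 0)
#' @param g_factor dimensionless instrument correction, default 1
#' @return FP in mP, in \[-1000, 1000\]. Vectorized over the intensities.
#' @examples
#' fp_from_intensities(300, 100)  # 500 mP
#' @export
fp_from_intensities <- function(f_parallel, f_perpendicular, g_factor = 1) {
  if (any(f_parallel < 0 | f_perpendicular < 0, na.rm = TRUE))
    stop("invalid read: negative fluorescence intensity")
  tot <- f_parallel + g_factor * f_perpendicular
  if (any(tot <= 0, na.rm = TRUE))
    stop("degenerate well: zero total intensity")
  1000 * (f_parallel - g_factor * f_perpendicular) / tot
}

#' One-site direct-binding saturation model with linear nonspecific term
#'
#' FP signal of a fixed tracer titrated with protein at concentration `x`:
#' \deqn{Y = B_{max} \frac{x}{x + K_D} + NS \cdot x + background}
#'
#' @param x titrant (protein) concentration in nM, >= 0; vectorized
#' @param b_max maximal specific FP signal (mP), >= 0
#' @param k_d dissociation constant (nM), > 0
#' @param ns_slope nonspecific signal slope (mP per nM), >= 0
#' @param background baseline FP of the free tracer (mP)
#' @return FP in mP
#' @export
direct_binding_fp <- function(x, b_max, k_d, ns_slope = 0, background = 0) {
  if (any(x < 0, na.rm = TRUE)) stop("invalid concentration: x < 0")
  stopifnot(k_d > 0, b_max >= 0, ns_slope >= 0)
  b_max * x / (x + k_d) + ns_slope * x + background
}

#' Four-parameter Hill (logistic) dose-response on a log10 concentration axis
#'
#' Displacement curves are read as decreasing FP with competitor, so the
#' logistic argument is `(log10(x) - log_ic50) * hill_n`: with `hill_n > 0`
#' the curve runs from `top` (no competitor) down to `bottom` (full
#' displacement). This equals the textbook form written with
#' `10^((logIC50 - x) n)` after negating `n`.
#' \deqn{Y = bottom + \frac{top - bottom}{1 + 10^{(\log_{10} x - logIC50)\,n}}}
#'
#' @param x competitor concentration in nM, > 0 (zero has no log; such wells
#'   are excluded from Hill fits and handled by the competition model instead)
#' @param bottom,top lower/upper asymptotes (mP)
#' @param log_ic50 log10 of the half-maximal competitor concentration (log10 nM)
#' @param hill_n Hill coefficient; positive for a decreasing displacement read
#' @return FP in mP; `(top + bottom)/2` exactly at `x = 10^log_ic50`
#' @export
hill_fp <- function(x, bottom, top, log_ic50, hill_n) {
  if (any(x <= 0, na.rm = TRUE))
    stop("point excluded from log-scale model: x <= 0")
  bottom + (top - bottom) / (1 + 10^((log10(x) - log_ic50) * hill_n))
}

#' Competition binding model in fractional-saturation space
#'
#' Fractional saturation of the tracer on protein held at `l_dis` when a
#' competitor at concentration `x` raises the apparent tracer KD:
#' \deqn{Y = \frac{L_{dis}}{L_{dis} + K_{D(dis)} (1 + x / K_{D(x)})}}
#' Free-ligand depletion is neglected (free ~ total), matching the usual
#' analysis of plate-based displacement data.
#'
#' @param x competitor concentration (nM), >= 0; vectorized
#' @param l_dis fixed protein concentration (nM), > 0
#' @param k_d_dis tracer dissociation constant from the direct-binding stage (nM)
#' @param k_d_x competitor dissociation constant (nM), > 0
#' @return fractional saturation in (0, l_dis/(l_dis + k_d_dis)\]
#' @export
competition_saturation <- function(x, l_dis, k_d_dis, k_d_x) {
  if (any(x < 0, na.rm = TRUE)) stop("invalid concentration: x < 0")
  stopifnot(l_dis > 0, k_d_dis > 0, k_d_x > 0)
  l_dis / (l_dis + k_d_dis * (1 + x / k_d_x))
}

#' Half-displacement concentration implied by competition-model parameters
#'
#' Closed form of the `x` solving `Y(x) = Y(0)/2` for the competition model:
#' `IC50 = k_d_x * (1 + l_dis / k_d_dis)` (the Cheng-Prusoff-type relation for
#' this protein-titration layout).
#'
#' @inheritParams competition_saturation
#' @return implied IC50 in nM
#' @export
implied_ic50 <- function(l_dis, k_d_dis, k_d_x) {
  stopifnot(l_dis >= 0, k_d_dis > 0, k_d_x > 0)
  k_d_x * (1 + l_dis / k_d_dis)
}

#' Competitor KD from an empirical IC50
#'
#' Algebraic inverse of [implied_ic50()].
#'
#' @param ic50 half-displacement concentration (nM), > 0
#' @param l_dis fixed protein concentration (nM)
#' @param k_d_dis tracer dissociation constant (nM)
#' @return competitor KD in nM
#' @export
kd_from_ic50 <- function(ic50, l_dis, k_d_dis) {
  stopifnot(ic50 > 0, k_d_dis > 0, l_dis >= 0)
  ic50 / (1 + l_dis / k_d_dis)
}

#' Convert an FP reading to fractional tracer saturation
#'
#' Linear inversion through the stage-1 direct-binding parameters at the fixed
#' protein concentration `l_dis` used in a displacement series:
#' `(fp - background - ns_slope * l_dis) / b_max`. The nonspecific term is a
#' constant offset at fixed `l_dis`. Values outside \[0, 1\] are reported
#' raw with a warning (noise can push points past the physical bounds).
#'
#' @param fp FP reading(s) in mP
#' @param b_max,ns_slope,background stage-1 direct-binding parameters
#' @param l_dis fixed protein concentration of the displacement series (nM)
#' @return fractional saturation (raw, not clipped)
#' @export
fractional_saturation_from_fp <- function(fp, b_max, ns_slope, background,
                                          l_dis) {
  if (b_max <= 0) stop("degenerate conversion: b_max must be positive")
  y <- (fp - background - ns_slope * l_dis) / b_max
  out <- y < 0 | y > 1
  if (any(out, na.rm = TRUE))
    warning(sprintf("%d fractional-saturation value(s) outside [0, 1]; raw values retained",
                    sum(out, na.rm = TRUE)))
  y
}

#' Michaelis-Menten rate law
#'
#' @param s substrate concentration (uM), >= 0; vectorized
#' @param v_max maximal rate (normalized fluorescence change per s)
#' @param k_m apparent Michaelis constant (uM), > 0
#' @return rate `v_max * s / (k_m + s)`
#' @export
mm_rate <- function(s, v_max, k_m) {
  if (any(s < 0, na.rm = TRUE)) stop("invalid concentration: s < 0")
  stopifnot(k_m > 0)
  v_max * s / (k_m + s)
}

#' Sigmoidal melting curve (percent stability vs temperature)
#'
#' Logistic in temperature, decreasing for `slope > 0`:
#' \deqn{Y = bottom + \frac{top - bottom}{1 + e^{slope (t - t_m)}}}
#'
#' @param t temperature (degrees C); vectorized
#' @param t_m midpoint (melting) temperature (degrees C)
#' @param slope transition steepness (per degree C), > 0 for a melt
#' @param top,bottom plateaus (% stability relative to the cold reference)
#' @return % stability; `(top + bottom)/2` exactly at `t = t_m`
#' @export
melt_fraction <- function(t, t_m, slope, top = 100, bottom = 0) {
  bottom + (top - bottom) / (1 + exp(slope * (t - t_m)))
}

#' 1:1 Langmuir SPR response
#'
#' Association phase (analyte at molar concentration `conc`, time from
#' injection start):
#' \deqn{R(t) = R_{eq} (1 - e^{-(k_{on} c + k_{off}) t}),\quad
#'       R_{eq} = R_{max} \frac{c}{c + k_{off}/k_{on}}}
#' Dissociation phase (time from injection stop, response `r0` at stop):
#' \deqn{R(t) = r_0 e^{-k_{off} t}}
#'
#' @param t time since phase start (s), >= 0; vectorized
#' @param conc analyte concentration in M (association phase only)
#' @param phase `"association"` or `"dissociation"`
#' @param k_on association rate constant (per M per s)
#' @param k_off dissociation rate constant (per s)
#' @param r_max maximal response (RU)
#' @param r0 response at the start of dissociation (RU)
#' @return response in RU
#' @export
spr_response <- function(t, conc = NULL,
                         phase = c("association", "dissociation"),
                         k_on, k_off, r_max, r0 = NULL) {
  phase <- match.arg(phase)
  stopifnot(k_on > 0, k_off > 0, r_max > 0)
  if (phase == "association") {
    if (is.null(conc) || any(conc <= 0))
      stop("invalid analyte concentration")
    k_d <- k_off / k_on
    r_eq <- r_max * conc / (conc + k_d)
    r_eq * (1 - exp(-(k_on * conc + k_off) * t))
  } else {
    if (is.null(r0)) stop("r0 required for the dissociation phase")
    r0 * exp(-k_off * t)
  }
}
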