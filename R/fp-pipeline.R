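#' Two-stage FP inference pipeline
#'
#' Stage 1 fits the direct-binding titrations of all constructs globally with
#' the maximal signal and background shared ("constrained") across
#' constructs, yielding a tracer KD per construct. Stage 2 analyses the
#' displacement series twice: an empirical four-parameter Hill fit on the FP
#' scale (IC50), and a mechanistic competition-model fit in
#' fractional-saturation space with the protein concentration and the
#' stage-1 tracer KD fixed (competitor KD). [run_pipeline()] orchestrates
#' both stages and emits a per-construct report.
#'
#' @name fp_pipeline
NULL

required_plate_cols <- c("sample_id", "construct", "competitor", "conc_nm",
                         "competitor_conc_nm", "f_para", "f_perp", "replicate")

validate_plate <- function(plate) {
  miss <- setdiff(required_plate_cols, names(plate))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (!"blocked" %in% names(plate)) plate$blocked <- FALSE
  plate$competitor[is.na(plate$competitor)] <- ""
  plate
}

#' Compute per-well FP for a plate table
#'
#' Adds an `fp_mp` column and a `flag` column. Invalid wells (negative
#' intensity, nonpositive total intensity, or nonnumeric reads) are flagged
#' `"invalid"`/`"degenerate"` with `fp_mp = NA`; they are never dropped
#' silently.
#'
#' @param plate plate table with `f_para`/`f_perp` columns
#' @param g_factor instrument G-factor applied to the perpendicular channel
#' @return the plate with `fp_mp` and `flag` columns appended
#' @export
compute_plate_fp <- function(plate, g_factor = 1) {
  plate <- validate_plate(plate)
  fpar <- plate$f_para; fperp <- plate$f_perp
  tot <- fpar + g_factor * fperp
  flag <- rep("ok", nrow(plate))
  flag[!is.finite(fpar) | !is.finite(fperp)] <- "invalid"
  flag[flag == "ok" & (fpar < 0 | fperp < 0)] <- "invalid"
  flag[flag == "ok" & tot <= 0] <- "degenerate"
  fp <- rep(NA_real_, nrow(plate))
  ok <- flag == "ok"
  fp[ok] <- 1000 * (fpar[ok] - g_factor * fperp[ok]) / tot[ok]
  plate$fp_mp <- fp
  plate$flag <- flag
  plate
}

direct_model <- function(x, p) {
  spec <- p$b_max * x$conc / (x$conc + p$k_d)
  ifelse(x$blocked, 0, spec) + p$ns_slope * x$conc + p$background
}

#' Stage 1: global direct-binding fit with shared Bmax and background
#'
#' Fits `Y = Bmax x/(x + KD) + NS x + background` to the titration wells of
#' every construct simultaneously. `Bmax` and `background` are shared across
#' constructs; `KD` and `NS` are per construct. Blocked control wells (30 uM
#' inhibitor) are co-fit with the specific term zeroed, which anchors the
#' nonspecific slope and background.
#'
#' @param plate plate table carrying `fp_mp` (see [compute_plate_fp()]);
#'   only rows with empty `competitor` or `blocked = TRUE` are used
#' @param constructs constructs to fit (default: all present)
#' @param share character vector of parameters shared across constructs
#' @param options [fit_options()]
#' @return object of class `fpn_direct_fit`: `fit` (the `fpn_fit`),
#'   `params` (per-construct table with k_d, se, ns_slope, and a
#'   `specific_binding` flag), `b_max`, `background`
#' @export
fit_direct <- function(plate, constructs = NULL,
                       share = c("b_max", "background"),
                       options = fit_options()) {
  plate <- validate_plate(plate)
  if (!"fp_mp" %in% names(plate)) plate <- compute_plate_fp(plate)
  rows <- plate$flag == "ok" & (plate$competitor == "" | plate$blocked)
  plate <- plate[rows, , drop = FALSE]
  if (nrow(plate) == 0) stop("no direct-binding wells on the plate")
  if (is.null(constructs)) constructs <- unique(plate$construct)

  datasets <- list()
  for (cn in constructs) {
    sub <- plate[plate$construct == cn, , drop = FALSE]
    if (nrow(sub) < 5)
      stop("construct rejected (too few points): ", cn)
    datasets[[cn]] <- fpn_dataset(cn,
      data.frame(conc = sub$conc_nm, blocked = sub$blocked),
      sub$fp_mp, sub$replicate)
  }
  fp_all <- plate$fp_mp
  conc_all <- plate$conc_nm
  init_bg <- stats::quantile(fp_all, 0.05, names = FALSE)
  init_bmax <- max(diff(range(fp_all)), 10)
  init_kd <- exp(mean(log(conc_all[conc_all > 0])))
  specs <- rbind(
    par_spec("b_max", init_bmax, 0, Inf, shared = "b_max" %in% share),
    par_spec("background", init_bg, -Inf, Inf,
             shared = "background" %in% share),
    par_spec("k_d", init_kd, 1e-3, 1e8, log_scale = TRUE),
    par_spec("ns_slope", 0.005, 0, 10))
  fit <- fit_global(direct_model, datasets, specs, options)

  b_max <- fit_estimate(fit, "b_max")
  background <- fit_estimate(fit, "background")
  xmax <- max(conc_all)
  params <- do.call(rbind, lapply(constructs, function(cn) {
    kd <- fit_estimate(fit, "k_d", cn)
    ns <- fit_estimate(fit, "ns_slope", cn)
    sb <- specific_binding_test(fit, cn, xmax)
    data.frame(construct = cn, k_d = kd$value, k_d_se = kd$se,
               ns_slope = ns$value, ns_slope_se = ns$se,
               specific_signal = sb$value, specific_signal_se = sb$se,
               specific_binding = sb$value >= 2 * sb$se,
               stringsAsFactors = FALSE)
  }))
  structure(list(fit = fit, params = params,
                 b_max = b_max$value, b_max_se = b_max$se,
                 background = background$value,
                 background_se = background$se),
            class = "fpn_direct_fit")
}

# delta-method SE of the specific signal Bmax*xmax/(xmax+KD) at the top
# titration concentration; constructs whose specific contribution is < 2 SE
# are indistinguishable from nonspecific binding
specific_binding_test <- function(fit, construct, xmax) {
  d <- match(construct, fit$labels)
  m <- fit$map$map[[d]]
  v <- ifelse(fit$is_log, 10^fit$theta, fit$theta)
  bmax <- if (m$b_max$kind == "fixed") m$b_max$value else v[m$b_max$slot]
  kd <- if (m$k_d$kind == "fixed") m$k_d$value else v[m$k_d$slot]
  s_val <- bmax * xmax / (xmax + kd)
  g <- rep(0, length(fit$theta))
  if (m$b_max$kind == "free") g[m$b_max$slot] <- xmax / (xmax + kd)
  if (m$k_d$kind == "free") {
    dk <- -bmax * xmax / (xmax + kd)^2
    # chain rule through the internal log10 scale
    if (fit$is_log[m$k_d$slot]) dk <- dk * kd * log(10)
    g[m$k_d$slot] <- dk
  }
  s_se <- sqrt(max(drop(t(g) %*% fit$cov %*% g), 0))
  list(value = s_val, se = s_se)
}

hill_model <- function(x, p) {
  p$bottom + (p$top - p$bottom) / (1 + (x / p$ic50)^p$hill_n)
}

#' Stage 2a: four-parameter Hill fits of displacement series
#'
#' Empirical IC50 fits on the FP scale with `top` and `bottom` shared across
#' competitors of the same construct. The IC50 is fitted on a log10-internal
#' scale; its SE is delta-method. Zero-competitor wells are excluded (no
#' log), flat or unconstrained series are flagged rather than reported as
#' estimates.
#'
#' @param plate plate with `fp_mp`; displacement rows (nonempty competitor,
#'   not blocked) of one construct are used
#' @param construct construct whose series to fit
#' @param competitors competitors to fit (default: all present for the
#'   construct)
#' @param share parameters shared across competitors
#' @param options [fit_options()]
#' @return object of class `fpn_hill_fit` with per-competitor `ic50`,
#'   `log_ic50`, `hill_n` (each with SE), shared `top`/`bottom`, and a
#'   `constrained` flag
#' @export
fit_displacement_hill <- function(plate, construct, competitors = NULL,
                                  share = c("top", "bottom"),
                                  options = fit_options()) {
  plate <- validate_plate(plate)
  if (!"fp_mp" %in% names(plate)) plate <- compute_plate_fp(plate)
  rows <- plate$flag == "ok" & plate$construct == construct &
    plate$competitor != "" & !plate$blocked
  sub <- plate[rows, , drop = FALSE]
  if (nrow(sub) == 0) stop("no displacement wells for construct ", construct)
  if (is.null(competitors)) competitors <- unique(sub$competitor)

  datasets <- list()
  for (cp in competitors) {
    s <- sub[sub$competitor == cp & sub$competitor_conc_nm > 0, , drop = FALSE]
    if (nrow(s) < 5) stop("competitor rejected (too few points): ", cp)
    # direction check: displacement should decrease with competitor
    trend <- stats::coef(stats::lm(s$fp_mp ~ log10(s$competitor_conc_nm)))[2]
    if (is.finite(trend) && trend > 0 &&
        abs(trend) > stats::sd(s$fp_mp) / 2)
      warning("unexpected direction: FP increases with competitor ", cp)
    datasets[[cp]] <- fpn_dataset(cp, s$competitor_conc_nm, s$fp_mp,
                                  s$replicate)
  }
  ymin <- min(sub$fp_mp); ymax <- max(sub$fp_mp)
  cx <- sub$competitor_conc_nm[sub$competitor_conc_nm > 0]
  specs <- rbind(
    par_spec("bottom", ymin, -Inf, Inf, shared = "bottom" %in% share),
    par_spec("top", ymax, -Inf, Inf, shared = "top" %in% share),
    par_spec("ic50", exp(mean(log(cx))), 1e-3, 1e9, log_scale = TRUE),
    par_spec("hill_n", 1, 0.05, 10))
  fit <- fit_global(hill_model, datasets, specs, options)

  res <- do.call(rbind, lapply(competitors, function(cp) {
    ic <- fit_estimate(fit, "ic50", cp)
    hn <- fit_estimate(fit, "hill_n", cp)
    at_b <- fit$estimates$at_bound[fit$estimates$name == "ic50" &
                                     fit$estimates$dataset == cp]
    constrained <- fit$converged && !any(at_b) &&
      is.finite(ic$se) && ic$se < ic$value
    data.frame(competitor = cp, ic50 = ic$value, ic50_se = ic$se,
               log_ic50 = log10(ic$value),
               log_ic50_se = ic$se / (ic$value * log(10)),
               hill_n = hn$value, hill_n_se = hn$se,
               constrained = constrained, stringsAsFactors = FALSE)
  }))
  top <- fit_estimate(fit, "top"); bottom <- fit_estimate(fit, "bottom")
  structure(list(fit = fit, params = res, construct = construct,
                 top = top$value, top_se = top$se,
                 bottom = bottom$value, bottom_se = bottom$se),
            class = "fpn_hill_fit")
}

competition_model <- function(x, p) {
  p$l_dis / (p$l_dis + p$k_d_dis * (1 + x / p$k_d_x))
}

#' Stage 2b: competition-model KD fit in fractional-saturation space
#'
#' Converts displacement FP to fractional saturation through the stage-1
#' parameters ([fractional_saturation_from_fp()]) and fits the competition
#' model with `l_dis` and the stage-1 tracer KD fixed; the competitor KD is
#' the single free parameter. Refuses to run without a stage-1 fit or
#' explicit stage-1 parameters (strict stage order).
#'
#' @param plate plate with `fp_mp`
#' @param construct,competitor series to fit
#' @param l_dis fixed protein concentration of the series (nM)
#' @param direct a `fpn_direct_fit` from [fit_direct()] covering `construct`;
#'   alternatively pass `stage1` explicitly
#' @param stage1 optional named list (k_d_dis, b_max, ns_slope, background)
#'   overriding `direct`
#' @param options [fit_options()]
#' @return object of class `fpn_competition_fit` with `k_d_x`, `k_d_x_se`,
#'   the implied IC50, and the underlying `fpn_fit`
#' @export
fit_displacement_competition <- function(plate, construct, competitor,
                                         l_dis = 400, direct = NULL,
                                         stage1 = NULL,
                                         options = fit_options()) {
  if (is.null(stage1)) {
    if (is.null(direct) || !inherits(direct, "fpn_direct_fit"))
      stop("pipeline order violation: stage-1 direct-binding fit required")
    p <- direct$params[direct$params$construct == construct, , drop = FALSE]
    if (nrow(p) == 0)
      stop("pipeline order violation: no stage-1 parameters for construct ",
           construct)
    stage1 <- list(k_d_dis = p$k_d[1], ns_slope = p$ns_slope[1],
                   b_max = direct$b_max, background = direct$background)
  }
  stopifnot(all(c("k_d_dis", "b_max", "ns_slope", "background") %in%
                  names(stage1)))
  plate <- validate_plate(plate)
  if (!"fp_mp" %in% names(plate)) plate <- compute_plate_fp(plate)
  rows <- plate$flag == "ok" & plate$construct == construct &
    plate$competitor == competitor & !plate$blocked
  sub <- plate[rows, , drop = FALSE]
  if (nrow(sub) < 3) stop("too few displacement wells for ", construct,
                          " / ", competitor)
  y <- suppressWarnings(fractional_saturation_from_fp(
    sub$fp_mp, stage1$b_max, stage1$ns_slope, stage1$background, l_dis))
  ds <- fpn_dataset(paste(construct, competitor, sep = "/"),
                    sub$competitor_conc_nm, y, sub$replicate)
  cx <- sub$competitor_conc_nm[sub$competitor_conc_nm > 0]
  specs <- rbind(
    par_spec("l_dis", l_dis, fixed = TRUE),
    par_spec("k_d_dis", stage1$k_d_dis, fixed = TRUE),
    par_spec("k_d_x", exp(mean(log(cx))), 1e-4, 1e9, log_scale = TRUE))
  fit <- fit_global(competition_model, ds, specs, options)
  kd <- fit_estimate(fit, "k_d_x")
  structure(list(fit = fit, construct = construct, competitor = competitor,
                 l_dis = l_dis, k_d_dis = stage1$k_d_dis,
                 k_d_x = kd$value, k_d_x_se = kd$se,
                 ic50_implied = implied_ic50(l_dis, stage1$k_d_dis,
                                             kd$value)),
            class = "fpn_competition_fit")
}

#' Run the full two-stage FP pipeline
#'
#' Computes per-well FP, runs the stage-1 global direct-binding fit, then for
#' every construct with displacement data and detectable specific binding
#' fits the Hill model (IC50s, top/bottom shared across competitors) and the
#' competition model (KDs). Constructs without specific binding are reported
#' `"no specific binding"` and excluded from stage 2; a failing stage for one
#' construct does not stop the others.
#'
#' @param plate raw plate table (intensities)
#' @param config list: `l_dis` (named per-construct protein concentrations,
#'   default 400 nM), `g_factor`, `options` ([fit_options()]), `seed`
#'   (recorded in provenance)
#' @return object of class `fpn_report`: `table` (one row per construct:
#'   tracer KD, then per-competitor KD columns), `details` (per-fit objects),
#'   `wells` (per-well accounting), `errors`, `provenance`
#' @export
run_pipeline <- function(plate, config = list()) {
  if (is.null(plate) || nrow(plate) == 0) stop("empty plate: no wells to analyse")
  g <- config$g_factor %||% 1
  opts <- config$options %||% fit_options()
  plate <- compute_plate_fp(plate, g_factor = g)
  errors <- list()

  direct <- fit_direct(plate, options = opts)
  constructs <- direct$params$construct
  disp <- plate[plate$competitor != "" & !plate$blocked, , drop = FALSE]

  details <- list(direct = direct, hill = list(), competition = list())
  rows <- list()
  for (cn in constructs) {
    p1 <- direct$params[direct$params$construct == cn, ]
    row <- list(construct = cn, k_d_tracer = p1$k_d, k_d_tracer_se = p1$k_d_se,
                note = "")
    has_disp <- any(disp$construct == cn)
    if (!p1$specific_binding) {
      row$note <- "no specific binding"
      row$k_d_tracer <- NA_real_; row$k_d_tracer_se <- NA_real_
    } else if (has_disp) {
      l_dis <- if (!is.null(config$l_dis) && cn %in% names(config$l_dis))
        config$l_dis[[cn]] else 400
      hill <- tryCatch(
        fit_displacement_hill(plate, cn, options = opts),
        error = function(e) { errors[[cn]] <<- conditionMessage(e); NULL })
      if (!is.null(hill)) details$hill[[cn]] <- hill
      for (cp in unique(disp$competitor[disp$construct == cn])) {
        comp <- tryCatch(
          fit_displacement_competition(plate, cn, cp, l_dis = l_dis,
                                       direct = direct, options = opts),
          error = function(e) {
            errors[[paste(cn, cp)]] <<- conditionMessage(e); NULL })
        if (!is.null(comp)) {
          details$competition[[paste(cn, cp, sep = "/")]] <- comp
          row[[paste0("k_d_", cp)]] <- comp$k_d_x
          row[[paste0("k_d_", cp, "_se")]] <- comp$k_d_x_se
        }
      }
    }
    rows[[cn]] <- row
  }
  # assemble a rectangular table across heterogeneous rows
  all_names <- unique(unlist(lapply(rows, names)))
  table <- do.call(rbind, lapply(rows, function(r) {
    r[setdiff(all_names, names(r))] <- NA
    as.data.frame(r[all_names], stringsAsFactors = FALSE)
  }))
  rownames(table) <- NULL

  wells <- data.frame(
    total = nrow(plate),
    used_direct = sum(plate$flag == "ok" &
                        (plate$competitor == "" | plate$blocked)),
    used_displacement = sum(plate$flag == "ok" & plate$competitor != "" &
                              !plate$blocked),
    flagged = sum(plate$flag != "ok"))
  structure(list(table = table, details = details, wells = wells,
                 errors = errors,
                 provenance = list(
                   seed = config$seed %||% NA,
                   n_wells = nrow(plate),
                   g_factor = g,
                   package_version = as.character(utils::packageVersion("fpnbind")),
                   timestamp = NA)),
            class = "fpn_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.fpn_report <- function(x, ...) {
  cat("FP two-stage pipeline report\n")
  cat(sprintf("  wells: %d (%d direct, %d displacement, %d flagged)\n",
              x$wells$total, x$wells$used_direct, x$wells$used_displacement,
              x$wells$flagged))
  print(x$table, row.names = FALSE, digits = 4)
  if (length(x$errors)) {
    cat("stage errors:\n")
    for (n in names(x$errors)) cat("  ", n, ": ", x$errors[[n]], "\n", sep = "")
  }
  invisible(x)
}
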