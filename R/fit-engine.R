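#' Generic nonlinear least-squares engine with parameter sharing
#'
#' All fitting stages (direct binding, Hill, competition, melting, transport,
#' SPR) run through one unweighted least-squares engine built on
#' Levenberg-Marquardt ([minpack.lm::nls.lm()]). It supports per-dataset and
#' shared parameters, fixed parameters, box bounds, an internal log10
#' transform for concentration-scale parameters (positivity by construction,
#' delta-method standard errors on the linear scale), and multi-start over
#' log-spaced initializations.
#'
#' @name fit_engine
NULL

#' Construct a dataset for [fit_global()]
#'
#' @param label construct/competitor identifier
#' @param x abscissa: numeric vector, or a data.frame with a numeric `conc`
#'   column plus any covariates the model function understands
#' @param y observed responses, same length as `x`
#' @param replicate_id optional integer per point; used by [bootstrap_se()]
#'   to resample whole replicates
#' @return an object of class `fpn_dataset`
#' @export
fpn_dataset <- function(label, x, y, replicate_id = NULL) {
  nx <- if (is.data.frame(x)) nrow(x) else length(x)
  stopifnot(nx == length(y))
  if (is.null(replicate_id)) replicate_id <- seq_along(y)
  stopifnot(length(replicate_id) == length(y))
  keep <- is.finite(y)
  if (is.data.frame(x)) {
    keep <- keep & is.finite(x$conc)
    x <- x[keep, , drop = FALSE]
  } else {
    keep <- keep & is.finite(x)
    x <- x[keep]
  }
  structure(list(label = as.character(label), x = x, y = y[keep],
                 replicate_id = replicate_id[keep]),
            class = "fpn_dataset")
}

#' Parameter specification for [fit_global()]
#'
#' @param name parameter name as used by the model function
#' @param init initial value (linear scale)
#' @param lower,upper box bounds (linear scale)
#' @param shared if `TRUE`, one value is tied across all datasets; otherwise
#'   each dataset gets its own copy
#' @param fixed if `TRUE`, held at `init` and excluded from the free vector
#' @param log_scale if `TRUE`, fitted internally as log10(value); requires
#'   a positive `init` and nonnegative bounds
#' @return one-row data.frame; rbind rows to build a spec table
#' @export
par_spec <- function(name, init, lower = -Inf, upper = Inf, shared = FALSE,
                     fixed = FALSE, log_scale = FALSE) {
  stopifnot(lower <= init, init <= upper)
  if (log_scale && !fixed) stopifnot(init > 0, lower >= 0)
  data.frame(name = name, init = init, lower = lower, upper = upper,
             shared = shared, fixed = fixed, log_scale = log_scale,
             stringsAsFactors = FALSE)
}

#' Fit options
#'
#' @param n_starts number of additional log-spaced initializations for
#'   log-scale (concentration-like) parameters; the user-supplied `init` is
#'   always tried as well
#' @param ftol relative tolerance on the residual sum of squares
#' @param maxfev maximum model evaluations per start
#' @return list of options
#' @export
fit_options <- function(n_starts = 7, ftol = 1e-10, maxfev = 10000) {
  list(n_starts = n_starts, ftol = ftol, maxfev = maxfev)
}

# map free parameter slots: one slot per shared free spec, one per
# (dataset, spec) otherwise; fixed specs carry their init as a constant
build_par_map <- function(specs, n_data) {
  slots <- list(); map <- vector("list", n_data)
  for (d in seq_len(n_data)) map[[d]] <- list()
  idx <- 0L
  shared_slot <- list()
  for (i in seq_len(nrow(specs))) {
    s <- specs[i, ]
    for (d in seq_len(n_data)) {
      if (s$fixed) {
        map[[d]][[s$name]] <- list(kind = "fixed", value = s$init)
      } else if (s$shared) {
        if (is.null(shared_slot[[s$name]])) {
          idx <- idx + 1L
          shared_slot[[s$name]] <- idx
          slots[[idx]] <- list(name = s$name, dataset = NA_integer_, spec = i)
        }
        map[[d]][[s$name]] <- list(kind = "free", slot = shared_slot[[s$name]])
      } else {
        idx <- idx + 1L
        slots[[idx]] <- list(name = s$name, dataset = d, spec = i)
        map[[d]][[s$name]] <- list(kind = "free", slot = idx)
      }
    }
  }
  list(slots = slots, map = map)
}

conc_of <- function(x) if (is.data.frame(x)) x$conc else x

#' Global unweighted nonlinear least squares
#'
#' Minimizes the pooled residual sum of squares over one or more datasets
#' under the sharing/fixing scheme in `specs`. Concentration-scale parameters
#' (`log_scale = TRUE`) are fitted as log10 values and additionally restarted
#' from `n_starts` log-spaced values spanning the positive x-range; the start
#' with the lowest RSS wins (ties broken by fewest iterations).
#'
#' @param model function `model(x, pars)` returning fitted responses for one
#'   dataset, with `pars` a named list of that dataset's parameter values
#' @param datasets an `fpn_dataset` or list of them
#' @param specs data.frame of [par_spec()] rows
#' @param options see [fit_options()]
#' @return object of class `fpn_fit`: `estimates` (data.frame with dataset
#'   label, parameter name, value, asymptotic SE, at-bound flag), `rss`,
#'   `dof`, `sigma`, `cov` (internal scale), `converged`, `niter`, and the
#'   per-dataset fitted values
#' @export
fit_global <- function(model, datasets, specs, options = fit_options()) {
  if (inherits(datasets, "fpn_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1, nrow(specs) >= 1)
  n_data <- length(datasets)
  pm <- build_par_map(specs, n_data)
  n_free <- length(pm$slots)
  n_points <- sum(vapply(datasets, function(d) length(d$y), 0L))
  dof <- n_points - n_free
  if (dof < 1) stop("underdetermined: fewer residual degrees of freedom than 1")

  # internal (theta) scale: log10 for log_scale slots
  slot_spec <- vapply(pm$slots, function(s) s$spec, 0L)
  is_log <- specs$log_scale[slot_spec]
  to_theta <- function(v) { v[is_log] <- log10(v[is_log]); v }
  from_theta <- function(th) { th[is_log] <- 10^th[is_log]; th }
  lower <- to_theta(pmax(specs$lower[slot_spec],
                         ifelse(is_log, 1e-12, -Inf)))
  upper <- to_theta(specs$upper[slot_spec])
  theta0 <- to_theta(specs$init[slot_spec])

  pars_for <- function(th, d) {
    v <- from_theta(th)
    lapply(pm$map[[d]], function(m)
      if (m$kind == "fixed") m$value else v[m$slot])
  }
  resid_fun <- function(th) {
    unlist(lapply(seq_len(n_data), function(d) {
      ds <- datasets[[d]]
      ds$y - model(ds$x, pars_for(th, d))
    }), use.names = FALSE)
  }

  # start set: user inits, plus log-spaced restarts of the log-scale slots
  starts <- list(theta0)
  if (any(is_log) && options$n_starts > 0) {
    cx <- unlist(lapply(datasets, function(d) conc_of(d$x)))
    cx <- cx[is.finite(cx) & cx > 0]
    if (length(cx) >= 2) {
      grid <- seq(log10(min(cx)), log10(max(cx)),
                  length.out = options$n_starts)
      for (g in grid) {
        th <- theta0
        th[is_log] <- pmin(pmax(g, lower[is_log]), upper[is_log])
        starts <- c(starts, list(th))
      }
    }
  }

  best <- NULL
  ctrl <- minpack.lm::nls.lm.control(ftol = options$ftol, ptol = 1e-12,
                                     maxfev = options$maxfev, maxiter = 1000)
  for (th0 in starts) {
    ans <- try(minpack.lm::nls.lm(par = th0, lower = lower, upper = upper,
                                  fn = resid_fun, control = ctrl),
               silent = TRUE)
    if (inherits(ans, "try-error")) next
    rss <- sum(ans$fvec^2)
    if (is.null(best) || rss < best$rss - 1e-12 ||
        (abs(rss - best$rss) <= 1e-12 && ans$niter < best$niter)) {
      best <- list(ans = ans, rss = rss, niter = ans$niter)
    }
  }
  if (is.null(best)) stop("fit failed: no start converged")
  ans <- best$ans
  theta <- ans$par
  rss <- best$rss
  sigma2 <- rss / dof

  # asymptotic covariance from a forward-difference Jacobian at the optimum
  r0 <- resid_fun(theta)
  J <- matrix(0, length(r0), n_free)
  for (j in seq_len(n_free)) {
    h <- max(1e-7, abs(theta[j]) * 1e-7)
    thj <- theta; thj[j] <- thj[j] + h
    J[, j] <- (resid_fun(thj) - r0) / h
  }
  JtJ <- crossprod(J)
  cov_theta <- tryCatch(sigma2 * solve(JtJ), error = function(e) {
    sigma2 * MASS_ginv(JtJ)
  })
  se_theta <- sqrt(pmax(diag(cov_theta), 0))
  value <- from_theta(theta)
  se <- ifelse(is_log, value * log(10) * se_theta, se_theta)
  at_bound <- (is.finite(lower) & abs(theta - lower) < 1e-8) |
              (is.finite(upper) & abs(theta - upper) < 1e-8)

  slot_name <- vapply(pm$slots, function(s) s$name, "")
  slot_ds <- vapply(pm$slots, function(s) s$dataset, 0L)
  labels <- vapply(datasets, function(d) d$label, "")
  estimates <- data.frame(
    dataset = ifelse(is.na(slot_ds), "(shared)", labels[slot_ds]),
    name = slot_name, value = value, se = se, at_bound = at_bound,
    stringsAsFactors = FALSE)

  fitted <- lapply(seq_len(n_data), function(d)
    model(datasets[[d]]$x, pars_for(theta, d)))
  structure(list(estimates = estimates, rss = rss, dof = dof,
                 sigma = sqrt(sigma2), cov = cov_theta, theta = theta,
                 converged = ans$info %in% 1:4, niter = best$niter,
                 info = ans$info, message = ans$message,
                 fitted = fitted, map = pm, specs = specs,
                 is_log = is_log, labels = labels,
                 model = model, datasets = datasets, options = options),
            class = "fpn_fit")
}

# Moore-Penrose fallback for rank-deficient normal equations
MASS_ginv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > tol * s$d[1]
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

#' Extract parameter values from an `fpn_fit`
#'
#' @param fit an `fpn_fit`
#' @param dataset dataset label, or `NULL` for the first dataset (shared
#'   parameters are visible from every dataset)
#' @return named list with every model parameter for that dataset, fixed
#'   values included
#' @export
fit_params <- function(fit, dataset = NULL) {
  d <- if (is.null(dataset)) 1L else match(dataset, fit$labels)
  if (is.na(d)) stop("unknown dataset label: ", dataset)
  v <- ifelse(fit$is_log, 10^fit$theta, fit$theta)
  lapply(fit$map$map[[d]], function(m)
    if (m$kind == "fixed") m$value else v[m$slot])
}

#' Look up one estimate (value, se) from an `fpn_fit`
#' @param fit an `fpn_fit`
#' @param name parameter name
#' @param dataset dataset label; ignored for shared parameters
#' @return list with `value` and `se`
#' @export
fit_estimate <- function(fit, name, dataset = NULL) {
  est <- fit$estimates
  rows <- est[est$name == name, , drop = FALSE]
  if (nrow(rows) > 1 && !is.null(dataset))
    rows <- rows[rows$dataset == dataset, , drop = FALSE]
  if (nrow(rows) == 0) stop("no free estimate for parameter: ", name)
  list(value = rows$value[1], se = rows$se[1])
}

#' @export
print.fpn_fit <- function(x, ...) {
  cat(sprintf("Global least-squares fit: %d dataset(s), %d free parameter(s)\n",
              length(x$datasets), length(x$theta)))
  cat(sprintf("  RSS %.6g on %d dof (sigma %.4g); converged: %s; %d iter\n",
              x$rss, x$dof, x$sigma, x$converged, x$niter))
  print(x$estimates, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Bootstrap standard errors for a converged fit
#'
#' Case bootstrap: within each dataset, whole replicates (groups of points
#' sharing a `replicate_id`) are resampled with replacement and the model is
#' refit from the original solution. Reported as the standard deviation of
#' the bootstrap estimates, a cross-check on the asymptotic SEs.
#'
#' @param fit a converged `fpn_fit`
#' @param n_boot number of resamples (>= 10)
#' @param seed integer seed; results are reproducible given the seed
#' @return data.frame like `fit$estimates` with a `se_boot` column
#' @export
bootstrap_se <- function(fit, n_boot = 200, seed = 1) {
  if (!fit$converged) stop("bootstrap requires a converged fit")
  if (n_boot < 10) stop("insufficient resamples: n_boot must be >= 10")
  rng <- local({ set.seed(seed); function(n, k) sample.int(n, k, replace = TRUE) })
  # restart each refit from the solution; no multistart needed
  opt <- fit$options; opt$n_starts <- 0
  specs <- fit$specs
  v_hat <- ifelse(fit$is_log, 10^fit$theta, fit$theta)
  slot_spec <- vapply(fit$map$slots, function(s) s$spec, 0L)
  for (i in seq_len(nrow(specs))) {
    sl <- which(slot_spec == i)
    if (length(sl))
      specs$init[i] <- min(max(mean(v_hat[sl]), specs$lower[i]), specs$upper[i])
  }
  boots <- matrix(NA_real_, n_boot, length(fit$theta))
  for (b in seq_len(n_boot)) {
    ds_b <- lapply(fit$datasets, function(ds) {
      reps <- unique(ds$replicate_id)
      pick <- reps[rng(length(reps), length(reps))]
      idx <- unlist(lapply(pick, function(r) which(ds$replicate_id == r)))
      xb <- if (is.data.frame(ds$x)) ds$x[idx, , drop = FALSE] else ds$x[idx]
      fpn_dataset(ds$label, xb, ds$y[idx], seq_along(idx))
    })
    fb <- try(fit_global(fit$model, ds_b, specs, opt), silent = TRUE)
    if (!inherits(fb, "try-error") && length(fb$theta) == length(fit$theta))
      boots[b, ] <- ifelse(fb$is_log, 10^fb$theta, fb$theta)
  }
  ok <- stats::complete.cases(boots)
  out <- fit$estimates
  out$se_boot <- apply(boots[ok, , drop = FALSE], 2, stats::sd)
  attr(out, "n_effective") <- sum(ok)
  out
}
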