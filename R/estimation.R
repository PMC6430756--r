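#' Calibration/validation split
#'
#' The screen-analysis split rule: records whose initial protein level is
#' among the `n_protein_excluded` highest distinct levels, or whose PEG
#' level is among the `n_peg_excluded` highest distinct levels, go to the
#' validation set; everything else is calibration. On the full 8 protein x
#' 12 PEG grid this leaves the 5 lowest protein x 10 lowest PEG levels —
#' 50 calibration and 46 validation conditions. The partition is level
#' based, so duplicate conditions always land on the same side, and it is
#' exhaustive and disjoint by construction.
#'
#' @param data A [screen_data()] object.
#' @param n_protein_excluded Number of highest protein levels excluded from
#'   calibration; default 3.
#' @param n_peg_excluded Number of highest PEG levels excluded; default 2.
#' @return A list with `calibration` and `validation`, both `screen_data`.
#' @export
split_calibration_validation <- function(data, n_protein_excluded = 3L,
                                         n_peg_excluded = 2L) {
  stopifnot(inherits(data, "screen_data"))
  lp <- .level_index(data$c_p0)
  lg <- .level_index(data$c_peg)
  if (length(lp$levels) < n_protein_excluded + 1L) {
    stop("need more distinct protein levels than excluded (have ",
         length(lp$levels), ")", call. = FALSE)
  }
  if (length(lg$levels) < n_peg_excluded + 1L) {
    stop("need more distinct PEG levels than excluded (have ",
         length(lg$levels), ")", call. = FALSE)
  }
  p_cut <- length(lp$levels) - n_protein_excluded
  g_cut <- length(lg$levels) - n_peg_excluded
  in_cal <- lp$index <= p_cut & lg$index <= g_cut
  cal <- data[in_cal, , drop = FALSE]
  val <- data[!in_cal, , drop = FALSE]
  for (obj in c("cal", "val")) {
    x <- get(obj)
    attr(x, "protein_id") <- attr(data, "protein_id")
    attr(x, "ph") <- attr(data, "ph")
    attr(x, "source") <- attr(data, "source")
    attr(x, "mw") <- attr(data, "mw")
    class(x) <- class(data)
    assign(obj, x)
  }
  list(calibration = cal, validation = val)
}

# Condition-level means (filtered) or pass-through when already collapsed.
.as_means <- function(data, threshold_pct = 5) {
  if (inherits(data, "screen_data")) {
    screen_means(data, threshold_pct = threshold_pct)
  } else if (is.data.frame(data) &&
             all(c("c_p0", "c_peg", "c_p_obs") %in% names(data))) {
    data
  } else {
    stop("`data` must be a screen_data object or a condition-level ",
         "data.frame with c_p0, c_peg, c_p_obs", call. = FALSE)
  }
}

#' Sum-of-squares objective
#'
#' The fitting loss: the sum over conditions of squared differences between
#' the observed replicate-mean supernatant concentration and the model's
#' equilibrium supernatant concentration, in mol^2/L^2.
#'
#' @param params An [isotherm_parameters()] object.
#' @param data A [screen_data()] object (collapsed to filtered replicate
#'   means internally) or a condition-level data.frame with columns `c_p0`,
#'   `c_peg`, `c_p_obs`.
#' @return The scalar sum of squared residuals.
#' @export
sse_objective <- function(params, data) {
  means <- .as_means(data)
  if (nrow(means) == 0L) stop("`data` is empty", call. = FALSE)
  q <- .solve_bisect(params, means$c_p0, means$c_peg)
  pred <- means$c_p0 - q
  sum((means$c_p_obs - pred)^2)
}

#' Root mean square error of prediction
#'
#' RMSEP of the model's supernatant predictions against a dataset's
#' replicate means, in mol/L. Applied to held-out conditions this is the
#' validation metric; applied to the calibration set it is the calibration
#' RMSE.
#'
#' @inheritParams sse_objective
#' @return RMSEP in mol/L.
#' @export
rmsep <- function(params, data) {
  means <- .as_means(data)
  if (nrow(means) == 0L) stop("`data` is empty", call. = FALSE)
  sqrt(sse_objective(params, means) / nrow(means))
}

#' Default optimizer bounds
#'
#' Box constraints for [fit_parameters()], covering the bundled reference
#' parameter sets with generous margin. `ln_k_eq` and `beta0` are searched
#' on the log scale because fitted values span orders of magnitude.
#'
#' @return Named list of length-2 `c(lower, upper)` vectors for `ln_k_eq`,
#'   `n`, `ln_beta0`, `beta1`, `beta2`.
#' @export
default_fit_bounds <- function() {
  list(ln_k_eq = c(0, 60), n = c(0.5, 10), ln_beta0 = c(-12, 0),
       beta1 = c(0, 1e3), beta2 = c(0, 1e5))
}

.theta_to_params <- function(theta) {
  isotherm_parameters(ln_k_eq = theta[1], n = theta[2],
                      beta0 = exp(theta[3]), beta1 = theta[4],
                      beta2 = theta[5])
}

.params_to_theta <- function(params) {
  c(params$ln_k_eq, params$n, log(params$beta0), params$beta1, params$beta2)
}

.bounds_matrix <- function(bounds) {
  b <- default_fit_bounds()
  b[names(bounds)] <- bounds
  lower <- vapply(b, `[`, numeric(1), 1L)
  upper <- vapply(b, `[`, numeric(1), 2L)
  if (any(lower >= upper)) stop("invalid bounds", call. = FALSE)
  rbind(lower = lower, upper = upper)
}

# Draw multi-start points: Latin hypercube in the box, with beta1/beta2
# cubically biased toward small values since plausible magnitudes sit far
# below the upper bound.
.draw_starts <- function(n, bm) {
  u <- lhs::randomLHS(n, 5L)
  u[, 4L] <- u[, 4L]^3
  u[, 5L] <- u[, 5L]^3
  t(apply(u, 1L, function(ui) bm["lower", ] + ui * (bm["upper", ] -
                                                      bm["lower", ])))
}

# One optimization start: bounded simulated annealing (reflecting Gaussian
# proposal) followed by a bounded Levenberg-Marquardt polish on the
# residual vector.
.fit_one_start <- function(theta0, means, bm, sann_iter) {
  lower <- bm["lower", ]; upper <- bm["upper", ]
  span <- upper - lower
  fn <- function(theta) {
    theta <- pmin(pmax(theta, lower), upper)
    sum(.resid_vec(theta, means)^2)
  }
  propose <- function(theta, ...) {
    step <- stats::rnorm(5L, sd = span / 20)
    cand <- theta + step
    # reflect into the box
    cand <- ifelse(cand < lower, 2 * lower - cand, cand)
    cand <- ifelse(cand > upper, 2 * upper - cand, cand)
    pmin(pmax(cand, lower), upper)
  }
  sann <- stats::optim(theta0, fn, gr = propose, method = "SANN",
                       control = list(maxit = sann_iter, temp = 1e-7,
                                      tmax = 10L))
  lm <- minpack.lm::nls.lm(
    par = sann$par, lower = lower, upper = upper,
    fn = function(theta) .resid_vec(theta, means),
    control = minpack.lm::nls.lm.control(ftol = 1e-15, ptol = 1e-15,
                                         maxiter = 500L)
  )
  list(theta = pmin(pmax(lm$par, lower), upper),
       sse = lm$deviance, sann_sse = sann$value, lm_info = lm$info,
       lm_iter = lm$niter)
}

.resid_vec <- function(theta, means) {
  p <- .theta_to_params(theta)
  q <- .solve_bisect(p, means$c_p0, means$c_peg)
  means$c_p_obs - (means$c_p0 - q)
}

#' Fit isotherm parameters to a screen
#'
#' Global estimation of the five isotherm constants by multi-start bounded
#' simulated annealing with Levenberg-Marquardt polishing, minimizing
#' [sse_objective()] on the replicate-mean supernatant concentrations.
#' Starts are drawn by a seeded Latin hypercube over the (log-scaled)
#' bounds; the best polished solution across all restarts is returned.
#' Given the same `(seed, restarts, bounds, data)` the result is
#' bit-identical.
#'
#' @param data A [screen_data()] object or condition-level means
#'   data.frame; needs at least 5 distinct conditions spanning at least 2
#'   protein and 2 PEG levels (otherwise the parameters are structurally
#'   non-identifiable).
#' @param bounds Named list overriding entries of [default_fit_bounds()].
#' @param seed Integer seed controlling starts and annealing proposals.
#' @param restarts Number of optimization starts; default 10.
#' @param sann_iter Annealing function evaluations per start; default 1000.
#' @param threshold_pct Outlier-filter threshold used when collapsing
#'   replicates; default 5.
#' @return An object of class `isotherm_fit`: `params` (the estimate),
#'   `objective` (SSE, mol^2/L^2), `rmse_calibration` (mol/L),
#'   `rmsep_validation` (`NA` here; filled by [fit_screen()]), and a
#'   `diagnostics` list (per-restart table, seed, bounds, convergence).
#' @export
fit_parameters <- function(data, bounds = list(), seed = 1L,
                           restarts = 10L, sann_iter = 1000L,
                           threshold_pct = 5) {
  means <- .as_means(data, threshold_pct = threshold_pct)
  lp <- .level_index(means$c_p0)
  lg <- .level_index(means$c_peg)
  if (nrow(means) < 5L || length(lp$levels) < 2L || length(lg$levels) < 2L) {
    stop("non-identifiable design: need >= 5 distinct conditions spanning ",
         ">= 2 protein and >= 2 PEG levels", call. = FALSE)
  }
  restarts <- as.integer(restarts)
  if (restarts < 1L) stop("`restarts` must be >= 1", call. = FALSE)
  bm <- .bounds_matrix(bounds)

  runs <- .with_seed(seed, {
    starts <- .draw_starts(restarts, bm)
    lapply(seq_len(restarts), function(i) {
      .fit_one_start(starts[i, ], means, bm, sann_iter)
    })
  })
  sses <- vapply(runs, `[[`, numeric(1), "sse")
  best <- which.min(sses)
  theta <- runs[[best]]$theta
  params <- .theta_to_params(theta)
  obj <- sum(.resid_vec(theta, means)^2)

  diag_tab <- data.frame(
    restart = seq_len(restarts),
    sse_annealed = vapply(runs, `[[`, numeric(1), "sann_sse"),
    sse_polished = sses,
    lm_info = vapply(runs, `[[`, numeric(1), "lm_info"),
    lm_iterations = vapply(runs, `[[`, numeric(1), "lm_iter")
  )
  structure(list(
    params = params,
    objective = obj,
    rmse_calibration = sqrt(obj / nrow(means)),
    rmsep_validation = NA_real_,
    diagnostics = list(
      restarts = diag_tab, best_restart = best,
      seed = as.integer(seed), n_restarts = restarts,
      sann_iter = as.integer(sann_iter),
      bounds = list(lower = bm["lower", ], upper = bm["upper", ]),
      n_conditions = nrow(means),
      converged = runs[[best]]$lm_info %in% c(1, 2, 3)
    )
  ), class = "isotherm_fit")
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat("<isotherm_fit>\n")
  print(x$params)
  cat(sprintf("  SSE = %.4g mol^2/L^2, calibration RMSE = %.4g mol/L\n",
              x$objective, x$rmse_calibration))
  if (!is.na(x$rmsep_validation)) {
    cat(sprintf("  validation RMSEP = %.4g mol/L\n", x$rmsep_validation))
  }
  invisible(x)
}

#' Calibrate and validate on one screen
#'
#' The full workflow on a single screen dataset: split per
#' [split_calibration_validation()], fit on the calibration set, and report
#' the validation RMSEP on the held-out conditions.
#'
#' @inheritParams fit_parameters
#' @param data A [screen_data()] object covering enough levels for the
#'   split (>= 4 protein, >= 3 PEG).
#' @param ... Passed on to [fit_parameters()].
#' @return An `isotherm_fit` with `rmsep_validation` filled in and split
#'   sizes recorded in the diagnostics.
#' @export
fit_screen <- function(data, seed = 1L, ...) {
  sp <- split_calibration_validation(data)
  fit <- fit_parameters(sp$calibration, seed = seed, ...)
  fit$rmsep_validation <- rmsep(fit$params, sp$validation)
  fit$diagnostics$n_calibration <- nrow(screen_means(sp$calibration))
  fit$diagnostics$n_validation <- nrow(screen_means(sp$validation))
  fit
}

#' Serialize a fit result
#'
#' JSON-compatible structured report of an `isotherm_fit` — parameters,
#' objective, errors, seed, bounds and per-restart diagnostics — for
#' machine consumption and reproducibility.
#'
#' @param fit An `isotherm_fit`.
#' @param path Optional output path; when given, pretty JSON is written
#'   there.
#' @return The report list, invisibly when `path` is given.
#' @export
fit_report <- function(fit, path = NULL) {
  stopifnot(inherits(fit, "isotherm_fit"))
  rep <- list(
    parameters = as.list(.params_vec(fit$params)),
    objective_mol2_per_l2 = fit$objective,
    rmse_calibration_mol_per_l = fit$rmse_calibration,
    rmsep_validation_mol_per_l = fit$rmsep_validation,
    diagnostics = list(
      seed = fit$diagnostics$seed,
      restarts = fit$diagnostics$n_restarts,
      sann_iter = fit$diagnostics$sann_iter,
      best_restart = fit$diagnostics$best_restart,
      converged = fit$diagnostics$converged,
      bounds = fit$diagnostics$bounds,
      n_conditions = fit$diagnostics$n_conditions,
      n_calibration = fit$diagnostics$n_calibration,
      n_validation = fit$diagnostics$n_validation,
      per_restart = fit$diagnostics$restarts
    )
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
    return(invisible(rep))
  }
  rep
}

#' Read isotherm parameters from a JSON file
#'
#' Accepts either a bare parameter object (`ln_k_eq`, `n`, `beta0`,
#' `beta1`, `beta2`) or a full [fit_report()] file.
#'
#' @param path JSON file path.
#' @return An [isotherm_parameters()] object.
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$parameters)) x <- x$parameters
  need <- c("ln_k_eq", "n", "beta0", "beta1", "beta2")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) {
    stop("parameter file missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  isotherm_parameters(x$ln_k_eq, x$n, x$beta0, x$beta1, x$beta2)
}

#' Write isotherm parameters to a JSON file
#'
#' @param params An [isotherm_parameters()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_params_json <- function(params, path) {
  stopifnot(inherits(params, "isotherm_parameters"))
  jsonlite::write_json(as.list(.params_vec(params)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
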