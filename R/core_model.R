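#' Concentration-dependent hydration number
#'
#' The number of bulk-like ordered water molecules stabilizing the
#' protein-protein complex, modeled as
#' `beta = beta0 * exp(beta1 * c_peg + beta2 * c_p0)`. It reduces to `beta0`
#' at infinite dilution and is non-decreasing in both concentrations.
#'
#' @param params An [isotherm_parameters()] object.
#' @param c_peg PEG concentration(s), mol/L; non-negative.
#' @param c_p0 Initial protein concentration(s), mol/L; non-negative.
#' @return The hydration number(s), dimensionless and strictly positive.
#' @examples
#' p <- builtin_isotherm_parameters("lysozyme")
#' hydration_number(p, c_peg = 0.02, c_p0 = 1.0274e-4)  # ~5.48e-2
#' @export
hydration_number <- function(params, c_peg, c_p0) {
  stopifnot(inherits(params, "isotherm_parameters"))
  if (any(!is.finite(c_peg)) || any(c_peg < 0)) {
    stop("`c_peg` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(c_p0)) || any(c_p0 < 0)) {
    stop("`c_p0` must be finite and >= 0", call. = FALSE)
  }
  beta <- params$beta0 * exp(params$beta1 * c_peg + params$beta2 * c_p0)
  if (any(!is.finite(beta))) {
    stop("hydration number overflowed: parameter/condition combination ",
         "is outside the model's valid range", call. = FALSE)
  }
  beta
}

#' Isotherm equilibrium residual
#'
#' The implicit isotherm written as a signed residual in the precipitated
#' protein concentration `q`:
#' `f(q) = q^(1 + n*beta) - exp(ln_k_eq) * (c_p0 - q)^n * c_peg`,
#' with the hydration number `beta` evaluated at `(c_peg, c_p0)` and the
#' supernatant concentration expressed through the mass balance
#' `c_p = c_p0 - q`. For `c_peg > 0` and `c_p0 > 0` the residual is negative
#' at `q = 0`, positive at `q = c_p0`, and strictly increasing in between
#' (all concentrations are far below 1 mol/L for realistic protein
#' solutions), so the equilibrium root is unique.
#'
#' Powers are evaluated in log space to avoid overflow/underflow of the
#' large exponent `1 + n*beta`.
#'
#' @inheritParams hydration_number
#' @param q Precipitated protein concentration(s), mol/L; must satisfy
#'   `0 <= q <= c_p0`.
#' @return Signed residual(s); zero at equilibrium.
#' @seealso [solve_equilibrium()]
#' @export
equilibrium_residual <- function(params, q, c_p0, c_peg) {
  stopifnot(inherits(params, "isotherm_parameters"))
  k <- max(length(q), length(c_p0), length(c_peg))
  q <- rep_len(q, k); c_p0 <- rep_len(c_p0, k); c_peg <- rep_len(c_peg, k)
  if (any(q < 0 | q > c_p0)) {
    stop("`q` must lie in [0, c_p0]", call. = FALSE)
  }
  beta <- hydration_number(params, c_peg, c_p0)
  expo <- 1 + params$n * beta
  a <- ifelse(q > 0, exp(expo * log(q)), 0)
  cp <- c_p0 - q
  b <- ifelse(cp > 0 & c_peg > 0,
              exp(params$ln_k_eq + params$n * log(cp) + log(c_peg)),
              0)
  a - b
}

# Log-form residual g(q) = (1 + n*beta) log q - (ln_k_eq + n log(c_p0 - q)
# + log c_peg); same sign and root as equilibrium_residual but well scaled
# for root bracketing. Only valid for 0 < q < c_p0, c_peg > 0.
.log_residual <- function(params, q, c_p0, c_peg, beta) {
  (1 + params$n * beta) * log(q) -
    (params$ln_k_eq + params$n * log(c_p0 - q) + log(c_peg))
}

# Vectorized fixed-iteration bisection on the log-form residual. The fast
# path used in fitting: 90 halvings of [0, c_p0] resolve q beyond double
# precision. Returns q (mol/L) for each condition.
.solve_bisect <- function(params, c_p0, c_peg, iters = 90L) {
  k <- max(length(c_p0), length(c_peg))
  c_p0 <- rep_len(c_p0, k); c_peg <- rep_len(c_peg, k)
  q <- numeric(k)
  act <- which(c_p0 > 0 & c_peg > 0)
  if (length(act) == 0L) return(q)
  p0 <- c_p0[act]; pg <- c_peg[act]
  beta <- hydration_number(params, pg, p0)
  coef <- 1 + params$n * beta
  rhs <- params$ln_k_eq + log(pg)
  lo <- numeric(length(act))
  hi <- p0
  for (i in seq_len(iters)) {
    m <- (lo + hi) / 2
    g <- coef * log(m) - (rhs + params$n * log(p0 - m))
    up <- is.na(g) | g >= 0   # NaN only when p0 - m underflows: root below m
    hi[up] <- m[up]
    lo[!up] <- m[!up]
  }
  q[act] <- (lo + hi) / 2
  q
}

#' Solve the precipitation equilibrium
#'
#' Finds the unique root of [equilibrium_residual()] on `[0, c_p0]` and
#' closes the mass balance `c_p = c_p0 - q`. Root finding uses Brent's
#' method on the log-form residual; when the root sits within 1e-6 relative
#' of either bracket endpoint the solve is repeated on a log-substituted
#' coordinate (`log q` near zero, `log(c_p0 - q)` near complete
#' precipitation) so extreme phase splits are still resolved to full
#' relative precision. Degenerate inputs (`c_peg = 0` or `c_p0 = 0`) return
#' `q = 0` without invoking the solver.
#'
#' @inheritParams hydration_number
#' @param c_p0 Initial protein concentration(s), mol/L.
#' @param c_peg PEG concentration(s), mol/L. Recycled against `c_p0`.
#' @param protein_id,ph Optional metadata carried into the result.
#' @return A data.frame of class `equilibrium_state` with columns `c_p0`,
#'   `c_peg`, `q` (precipitated, mol/L), `c_p` (supernatant, mol/L) and
#'   `residual` (the linear-form residual at the root).
#' @examples
#' p <- builtin_isotherm_parameters("lysozyme")
#' solve_equilibrium(p, c_p0 = 8.219e-4, c_peg = 0.04)
#' @export
solve_equilibrium <- function(params, c_p0, c_peg,
                              protein_id = NA_character_, ph = NA_real_) {
  stopifnot(inherits(params, "isotherm_parameters"))
  if (any(!is.finite(c_p0)) || any(c_p0 < 0)) {
    stop("`c_p0` must be finite and >= 0", call. = FALSE)
  }
  if (any(!is.finite(c_peg)) || any(c_peg < 0)) {
    stop("`c_peg` must be finite and >= 0", call. = FALSE)
  }
  k <- max(length(c_p0), length(c_peg))
  c_p0 <- rep_len(c_p0, k); c_peg <- rep_len(c_peg, k)
  q <- vapply(seq_len(k), function(i) {
    .solve_one(params, c_p0[i], c_peg[i])
  }, numeric(1))
  out <- data.frame(c_p0 = c_p0, c_peg = c_peg, q = q, c_p = c_p0 - q)
  out$residual <- equilibrium_residual(params, out$q, out$c_p0, out$c_peg)
  attr(out, "protein_id") <- protein_id
  attr(out, "ph") <- ph
  class(out) <- c("equilibrium_state", "data.frame")
  out
}

.solve_one <- function(params, c_p0, c_peg, eps_edge = 1e-6) {
  if (c_p0 == 0 || c_peg == 0) return(0)
  beta <- hydration_number(params, c_peg, c_p0)
  coef <- 1 + params$n * beta
  rhs <- params$ln_k_eq + log(c_peg)
  g <- function(q) coef * log(q) - (rhs + params$n * log(c_p0 - q))
  q_lo <- c_p0 * eps_edge
  q_hi <- c_p0 * (1 - eps_edge)
  fail <- function(e) {
    stop(sprintf(paste0("equilibrium solve failed (%s) for ln_k_eq=%g, ",
                        "n=%g, beta0=%g, beta1=%g, beta2=%g at c_p0=%g, ",
                        "c_peg=%g"),
                 conditionMessage(e), params$ln_k_eq, params$n,
                 params$beta0, params$beta1, params$beta2, c_p0, c_peg),
         call. = FALSE)
  }
  if (g(q_lo) >= 0) {
    # root below q_lo: solve in t = log(q); exp(t) << c_p0 so the
    # supernatant term is evaluated without cancellation
    gt <- function(t) coef * t - (rhs + params$n * log(c_p0 - exp(t)))
    t_lo <- log(c_p0) - 745
    if (gt(t_lo) >= 0) return(0)  # root below double-precision range
    r <- tryCatch(stats::uniroot(gt, c(t_lo, log(q_lo)),
                                 tol = 1e-15, maxiter = 20000L),
                  error = fail)
    return(exp(r$root))
  }
  g_hi <- g(q_hi)
  if (!is.finite(g_hi) || g_hi <= 0) {
    # root above q_hi: solve in s = log(c_p) with c_p = c_p0 - q, which
    # enters the residual directly (no subtraction of nearly equal numbers)
    gs <- function(s) coef * log1p(-exp(s) / c_p0) + coef * log(c_p0) -
      (rhs + params$n * s)
    s_lo <- log(c_p0) - 745
    if (gs(s_lo) <= 0) return(c_p0)  # supernatant below double range
    r <- tryCatch(stats::uniroot(gs, c(s_lo, log(q_lo)),
                                 tol = 1e-15, maxiter = 20000L),
                  error = fail)
    return(c_p0 * (-expm1(r$root - log(c_p0))))
  }
  r <- tryCatch(stats::uniroot(g, c(q_lo, q_hi), tol = 1e-24,
                               maxiter = 20000L),
                error = fail)
  r$root
}

#' Predict a supernatant precipitation curve
#'
#' Supernatant protein concentration as a function of PEG concentration at a
#' fixed initial protein load — the model curve drawn through a measured
#' precipitation series. Non-increasing along an ascending PEG grid.
#'
#' @inheritParams hydration_number
#' @param c_p0 Initial protein concentration, mol/L (scalar).
#' @param peg_grid Vector of PEG concentrations, mol/L; may be empty.
#' @return Numeric vector of supernatant concentrations (mol/L), one per
#'   grid point.
#' @export
predict_supernatant_curve <- function(params, c_p0, peg_grid) {
  stopifnot(inherits(params, "isotherm_parameters"), length(c_p0) == 1L)
  if (length(peg_grid) == 0L) return(numeric(0))
  st <- solve_equilibrium(params, c_p0 = c_p0, c_peg = peg_grid)
  st$c_p
}
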