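#' Isotherm parameter set
#'
#' The five constants of the mechanistic precipitation isotherm. The model
#' describes the equilibrium in which one PEG molecule affects `n` protein
#' molecules, forming a precipitate stabilized by bulk-like ordered water;
#' the effective hydration number grows exponentially with PEG and initial
#' protein concentration.
#'
#' All concentrations entering the model are in mol/L, so `beta1` and `beta2`
#' carry units of L/mol and the equilibrium coefficient is on the molar
#' scale. The equilibrium coefficient is stored as its natural logarithm
#' because fitted values span many orders of magnitude.
#'
#' @param ln_k_eq Natural log of the lumped equilibrium coefficient
#'   (dimensionless on the molar scale; absorbs the stoichiometric constant of
#'   the water-activity substitution). Must be finite.
#' @param n Number of protein molecules affected per PEG molecule; positive,
#'   not necessarily an integer.
#' @param beta0 Hydration number at infinite dilution of PEG and protein;
#'   positive, dimensionless.
#' @param beta1 PEG-concentration dependence of the hydration number, L/mol;
#'   non-negative.
#' @param beta2 Initial-protein-concentration dependence of the hydration
#'   number, L/mol; non-negative.
#'
#' @return An object of class `isotherm_parameters`.
#' @seealso [hydration_number()], [solve_equilibrium()], [fit_parameters()]
#' @examples
#' isotherm_parameters(ln_k_eq = 34.71, n = 5.55, beta0 = 6.92e-3,
#'                     beta1 = 92.9, beta2 = 2060)
#' @export
isotherm_parameters <- function(ln_k_eq, n, beta0, beta1, beta2) {
  vals <- c(ln_k_eq = ln_k_eq, n = n, beta0 = beta0,
            beta1 = beta1, beta2 = beta2)
  if (!all(is.finite(vals))) {
    stop("all isotherm parameters must be finite numbers", call. = FALSE)
  }
  if (n <= 0) stop("`n` must be > 0", call. = FALSE)
  if (beta0 <= 0) stop("`beta0` must be > 0", call. = FALSE)
  if (beta1 < 0) stop("`beta1` must be >= 0", call. = FALSE)
  if (beta2 < 0) stop("`beta2` must be >= 0", call. = FALSE)
  structure(as.list(vals), class = "isotherm_parameters")
}

#' @export
print.isotherm_parameters <- function(x, ...) {
  cat("<isotherm_parameters>\n")
  cat(sprintf("  ln_k_eq = %.4g   n = %.4g\n", x$ln_k_eq, x$n))
  cat(sprintf("  beta0 = %.4g   beta1 = %.4g L/mol   beta2 = %.4g L/mol\n",
              x$beta0, x$beta1, x$beta2))
  invisible(x)
}

#' @export
as.numeric.isotherm_parameters <- function(x, ...) {
  c(ln_k_eq = x$ln_k_eq, n = x$n, beta0 = x$beta0,
    beta1 = x$beta1, beta2 = x$beta2)
}

# named parameter vector (as.numeric() is a primitive and may drop names)
.params_vec <- function(x) {
  c(ln_k_eq = x$ln_k_eq, n = x$n, beta0 = x$beta0,
    beta1 = x$beta1, beta2 = x$beta2)
}

#' Well condition
#'
#' One well's composition: the initial (total) protein concentration and the
#' PEG concentration, both in mol/L, plus identity metadata. The pH is
#' context only — it is not a model input; different pH values correspond to
#' different fitted parameter sets.
#'
#' @param c_p0 Initial protein concentration, mol/L; non-negative.
#' @param c_peg PEG concentration, mol/L; non-negative.
#' @param protein_id Protein label.
#' @param ph pH value (metadata).
#'
#' @return An object of class `condition`.
#' @export
condition <- function(c_p0, c_peg, protein_id = NA_character_, ph = NA_real_) {
  if (!is.numeric(c_p0) || any(c_p0 < 0) || any(!is.finite(c_p0))) {
    stop("`c_p0` must be finite and >= 0 (mol/L)", call. = FALSE)
  }
  if (!is.numeric(c_peg) || any(c_peg < 0) || any(!is.finite(c_peg))) {
    stop("`c_peg` must be finite and >= 0 (mol/L)", call. = FALSE)
  }
  structure(list(c_p0 = c_p0, c_peg = c_peg,
                 protein_id = protein_id, ph = ph),
            class = "condition")
}

#' Cohn baseline parameters
#'
#' Parameters of the classical semi-logarithmic solubility relation
#' `log(S) = s0 - alpha * m`, with `S` the protein solubility in mg/mL and
#' `m` the PEG concentration in % (w/w). The log base is historically 10 and
#' is configurable in [cohn_solubility()].
#'
#' @param s0 Intercept: log-solubility in the absence of PEG.
#' @param alpha Precipitation efficiency, per % (w/w) PEG.
#' @return An object of class `cohn_parameters`.
#' @export
cohn_parameters <- function(s0, alpha) {
  if (!is.finite(s0) || !is.finite(alpha)) {
    stop("`s0` and `alpha` must be finite", call. = FALSE)
  }
  structure(list(s0 = as.numeric(s0), alpha = as.numeric(alpha)),
            class = "cohn_parameters")
}

#' Cohn baseline solubility
#'
#' Evaluates the semi-logarithmic baseline `S = base^(s0 - alpha * m)`.
#'
#' @param cohn A [cohn_parameters()] object.
#' @param m PEG concentration(s) in % (w/w); non-negative.
#' @param base Logarithm base; 10 by default (the historic convention).
#' @return Solubility in mg/mL.
#' @examples
#' cohn_solubility(cohn_parameters(s0 = 1, alpha = 0.1), m = 10)  # 1 mg/mL
#' @export
cohn_solubility <- function(cohn, m, base = 10) {
  if (!inherits(cohn, "cohn_parameters")) {
    stop("`cohn` must be a cohn_parameters object", call. = FALSE)
  }
  if (any(!is.finite(m)) || any(m < 0)) {
    stop("`m` must be finite and >= 0 (% w/w)", call. = FALSE)
  }
  base^(cohn$s0 - cohn$alpha * m)
}

#' Bundled reference parameter sets
#'
#' Fitted isotherm constants for four model proteins from a published
#' PEG-6000 high-throughput precipitation screen: lysozyme, myoglobin, BSA,
#' and an industrial mAb at pH 7.5 and pH 8.5. Useful as realistic ground
#' truth for simulation studies and as sanity anchors for fitting.
#'
#' `mw` carries the molecular weight used for unit conversion (BSA and mAb
#' values are registry defaults, see [default_protein_registry()]), and
#' `peg_max` the highest PEG level of each protein's screen grid (0.056 mol/L
#' for the small proteins; 0.02 mol/L for the mAb, which precipitates at
#' lower PEG).
#'
#' @return A data.frame with one row per parameter set and columns
#'   `protein`, `ph`, `ln_k_eq`, `n`, `beta0`, `beta1`, `beta2`, `mw`,
#'   `peg_max`.
#' @seealso [builtin_isotherm_parameters()], [default_screen_levels()]
#' @export
reference_parameter_table <- function() {
  data.frame(
    protein = c("lysozyme", "myoglobin", "bsa", "mab_ph7.5", "mab_ph8.5"),
    ph      = c(NA, NA, NA, 7.5, 8.5),
    ln_k_eq = c(34.71, 15.41, 19.78, 22.53, 19.83),
    n       = c(5.55, 3.06, 2.60, 3.65, 3.22),
    beta0   = c(6.92e-3, 4.30e-4, 2.74e-3, 1.46e-2, 3.77e-2),
    beta1   = c(92.9, 118, 140, 237, 250),
    beta2   = c(2060, 1510, 1580, 10500, 6610),
    mw      = c(14600, 17000, 66500, 150000, 150000),
    peg_max = c(0.056, 0.056, 0.056, 0.020, 0.020),
    stringsAsFactors = FALSE
  )
}

#' Retrieve one bundled parameter set
#'
#' @param protein One of `"lysozyme"`, `"myoglobin"`, `"bsa"`,
#'   `"mab_ph7.5"`, `"mab_ph8.5"`.
#' @return An [isotherm_parameters()] object with attributes `protein`, `mw`
#'   and `peg_max`.
#' @examples
#' builtin_isotherm_parameters("lysozyme")
#' @export
builtin_isotherm_parameters <- function(protein = c("lysozyme", "myoglobin",
                                                    "bsa", "mab_ph7.5",
                                                    "mab_ph8.5")) {
  protein <- match.arg(protein)
  tab <- reference_parameter_table()
  row <- tab[tab$protein == protein, ]
  p <- isotherm_parameters(row$ln_k_eq, row$n, row$beta0, row$beta1,
                           row$beta2)
  attr(p, "protein") <- protein
  attr(p, "mw") <- row$mw
  attr(p, "peg_max") <- row$peg_max
  p
}

#' Default screen level grids
#'
#' The screen design used throughout: eight equidistant initial protein
#' levels from 1.5 to 12 mg/mL, and twelve equidistant PEG levels from
#' `peg_max/12` up to `peg_max` mol/L, where `peg_max` is 0.056 mol/L for
#' small proteins and 0.020 mol/L for mAb-like proteins.
#'
#' @param protein_class `"small"` or `"mab"`; alternatively pass `peg_max`
#'   directly.
#' @param peg_max Override for the maximum PEG level, mol/L.
#' @return A list with `protein_mgml` (mg/mL) and `peg` (mol/L) level
#'   vectors.
#' @export
default_screen_levels <- function(protein_class = c("small", "mab"),
                                  peg_max = NULL) {
  protein_class <- match.arg(protein_class)
  if (is.null(peg_max)) {
    peg_max <- if (protein_class == "small") 0.056 else 0.020
  }
  list(protein_mgml = seq(1.5, 12, by = 1.5),
       peg = seq(peg_max / 12, peg_max, length.out = 12))
}
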