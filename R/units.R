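#' Protein specification
#'
#' Bundles the identity and molecular weight of a protein, used to convert
#' between laboratory mass concentrations (mg/mL) and the model's molar scale.
#'
#' @param name Protein label, e.g. `"lysozyme"`.
#' @param molecular_weight Molecular weight in g/mol; must be positive.
#' @param note Optional free-text annotation (e.g. extinction-coefficient
#'   context); not used computationally.
#'
#' @return An object of class `protein_spec`.
#' @examples
#' lys <- protein_spec("lysozyme", 14600)
#' protein_mgml_to_molar(1.5, lys)
#' @export
protein_spec <- function(name, molecular_weight, note = NULL) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(molecular_weight) || length(molecular_weight) != 1L ||
      !is.finite(molecular_weight) || molecular_weight <= 0) {
    stop("`molecular_weight` must be a single positive number (g/mol)",
         call. = FALSE)
  }
  structure(
    list(name = name, molecular_weight = as.numeric(molecular_weight),
         note = note),
    class = "protein_spec"
  )
}

#' @export
print.protein_spec <- function(x, ...) {
  cat(sprintf("<protein_spec> %s, MW = %g g/mol\n", x$name,
              x$molecular_weight))
  invisible(x)
}

#' PEG precipitant specification
#'
#' Describes the polyethylene glycol species used as precipitant. The default
#' is PEG with a median molecular mass of 6000 g/mol. The solution density is
#' needed to convert % (w/w) to mol/L; the default of 1.0 g/mL is the
#' dilute-aqueous assumption and can be overridden (or set in the run config).
#'
#' @param molecular_weight PEG molecular weight, g/mol.
#' @param solution_density Solution density in g/mL used in the % (w/w)
#'   conversion.
#'
#' @return An object of class `peg_spec`.
#' @export
peg_spec <- function(molecular_weight = 6000, solution_density = 1.0) {
  if (!is.numeric(molecular_weight) || molecular_weight <= 0 ||
      !is.finite(molecular_weight)) {
    stop("PEG `molecular_weight` must be positive", call. = FALSE)
  }
  if (!is.numeric(solution_density) || solution_density <= 0 ||
      !is.finite(solution_density)) {
    stop("`solution_density` must be positive", call. = FALSE)
  }
  structure(
    list(molecular_weight = as.numeric(molecular_weight),
         solution_density = as.numeric(solution_density)),
    class = "peg_spec"
  )
}

.mw_of <- function(spec) {
  if (inherits(spec, "protein_spec") || inherits(spec, "peg_spec")) {
    spec$molecular_weight
  } else if (is.numeric(spec) && length(spec) == 1L && spec > 0) {
    as.numeric(spec)
  } else {
    stop("expected a protein_spec/peg_spec or a positive molecular weight",
         call. = FALSE)
  }
}

#' Convert protein concentration from mg/mL to mol/L
#'
#' mg/mL is identical to g/L, so the conversion is a division by the molecular
#' weight in g/mol. Linear and zero-preserving.
#'
#' @param c Concentration(s) in mg/mL; must be non-negative.
#' @param spec A [protein_spec()] or a bare molecular weight in g/mol.
#' @return Concentration(s) in mol/L.
#' @examples
#' protein_mgml_to_molar(12, 14600)  # 8.219e-4 mol/L
#' @export
protein_mgml_to_molar <- function(c, spec) {
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("protein concentration must be finite and >= 0 (mg/mL)",
         call. = FALSE)
  }
  c / .mw_of(spec)
}

#' Convert protein concentration from mol/L to mg/mL
#'
#' Inverse of [protein_mgml_to_molar()].
#'
#' @inheritParams protein_mgml_to_molar
#' @param c Concentration(s) in mol/L; must be non-negative.
#' @return Concentration(s) in mg/mL.
#' @export
protein_molar_to_mgml <- function(c, spec) {
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("protein concentration must be finite and >= 0 (mol/L)",
         call. = FALSE)
  }
  c * .mw_of(spec)
}

#' Convert PEG concentration from % (w/w) to mol/L
#'
#' A `pct` % (w/w) solution contains `pct/100 * density * 1000` grams of PEG
#' per litre (using the configured solution density); dividing by the PEG
#' molecular weight gives mol/L. With the defaults (PEG 6000, density
#' 1.0 g/mL), 12 % (w/w) is 0.020 mol/L and 33.6 % (w/w) is 0.056 mol/L.
#'
#' @param pct Percent weight-by-weight, in `[0, 100)`.
#' @param spec A [peg_spec()]; defaults to PEG 6000 at density 1.0 g/mL.
#' @return Concentration(s) in mol/L.
#' @export
peg_ww_to_molar <- function(pct, spec = peg_spec()) {
  if (any(!is.finite(pct)) || any(pct < 0) || any(pct >= 100)) {
    stop("PEG percentage must lie in [0, 100)", call. = FALSE)
  }
  if (!inherits(spec, "peg_spec")) stop("`spec` must be a peg_spec",
                                        call. = FALSE)
  (pct / 100 * spec$solution_density * 1000) / spec$molecular_weight
}

#' Convert PEG concentration from mol/L to % (w/w)
#'
#' Inverse of [peg_ww_to_molar()].
#'
#' @param c Concentration(s) in mol/L; must be non-negative.
#' @inheritParams peg_ww_to_molar
#' @return Percent weight-by-weight.
#' @export
peg_molar_to_ww <- function(c, spec = peg_spec()) {
  if (any(!is.finite(c)) || any(c < 0)) {
    stop("PEG concentration must be finite and >= 0 (mol/L)", call. = FALSE)
  }
  if (!inherits(spec, "peg_spec")) stop("`spec` must be a peg_spec",
                                        call. = FALSE)
  c * spec$molecular_weight / (spec$solution_density * 1000) * 100
}

#' Default protein molecular-weight registry
#'
#' Named vector mapping protein labels to molecular weights in g/mol.
#' Lysozyme (14,600) and myoglobin (17,000) are the screen's reference values;
#' the BSA (66,500) and mAb (150,000) entries are conventional textbook
#' defaults intended to be edited via the run config when the actual species
#' is known.
#'
#' @return Named numeric vector of molecular weights (g/mol).
#' @export
default_protein_registry <- function() {
  c(lysozyme = 14600, myoglobin = 17000, bsa = 66500, mab = 150000)
}
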