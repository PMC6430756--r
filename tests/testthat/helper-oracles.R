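# Independent oracles and generators shared across tests.

# Brute-force sign bisection of the linear-form isotherm residual,
# written out from the model definition (no package solver code): the
# residual q^(1+n*beta) - exp(ln_k_eq) * (c_p0 - q)^n * c_peg is negative
# below the equilibrium root and positive above it.
bisect_oracle <- function(params, c_p0, c_peg, iters = 200L) {
  if (c_p0 == 0 || c_peg == 0) return(0)
  beta <- params$beta0 * exp(params$beta1 * c_peg + params$beta2 * c_p0)
  f <- function(q) {
    a <- if (q > 0) exp((1 + params$n * beta) * log(q)) else 0
    cp <- c_p0 - q
    b <- if (cp > 0) exp(params$ln_k_eq + params$n * log(cp) + log(c_peg))
         else 0
    a - b
  }
  lo <- 0; hi <- c_p0
  for (i in seq_len(iters)) {
    m <- (lo + hi) / 2
    if (f(m) >= 0) hi <- m else lo <- m
  }
  (lo + hi) / 2
}

# Random valid model instances spanning the realistic screen ranges:
# protein loads up to 1 mmol/L, PEG up to 0.06 mol/L, hydration numbers of
# the magnitude seen across the bundled parameter sets. The hydration-term
# exponents are drawn directly so the product n*beta stays in the regime
# where the linear-form residual is representable across the whole bracket.
random_instance <- function() {
  c_p0 <- exp(stats::runif(1, log(1e-5), log(1e-3)))
  c_peg <- exp(stats::runif(1, log(1e-3), log(0.06)))
  e_peg <- stats::runif(1, 0, 3)      # beta1 * c_peg
  e_prot <- stats::runif(1, 0, 1.5)   # beta2 * c_p0
  list(
    params = isotherm_parameters(
      ln_k_eq = stats::runif(1, 10, 40),
      n = stats::runif(1, 0.5, 8),
      beta0 = exp(stats::runif(1, log(1e-4), log(3e-2))),
      beta1 = e_peg / c_peg,
      beta2 = e_prot / c_p0
    ),
    c_p0 = c_p0, c_peg = c_peg
  )
}

# Noiseless single-replicate screen for one bundled parameter set, on the
# default 8 x 12 grid of that protein class.
noiseless_screen <- function(protein, seed = 1L) {
  row <- reference_parameter_table()
  row <- row[row$protein == protein, ]
  params <- builtin_isotherm_parameters(protein)
  lv <- default_screen_levels(peg_max = row$peg_max)
  d <- design_screen(lv$protein_mgml, lv$peg, replicates = 1L, seed = seed)
  simulate_screen(params, d,
                  noise = noise_model(cv = 0, outlier_rate = 0, seed = seed),
                  protein = protein_spec(protein, row$mw))
}
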