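lys <- builtin_isotherm_parameters("lysozyme")

test_that("hydration number evaluates the exponential model", {
  expect_identical(hydration_number(lys, 0, 0), lys$beta0)
  # direct scalar evaluation of the closed form with the lysozyme constants
  expect_equal(hydration_number(lys, 0.02, 1.0274e-4),
               0.054820278418052731, tolerance = 1e-12)
  # monotone in both arguments
  b <- hydration_number(lys, c(0.01, 0.02, 0.03), 1e-4)
  expect_true(all(diff(b) > 0))
  expect_gt(hydration_number(lys, 0.02, 2e-4),
            hydration_number(lys, 0.02, 1e-4))
  big <- isotherm_parameters(1, 1, 1, 1e3, 1e3)
  expect_error(hydration_number(big, 1e3, 1e3), "overflow")
})

test_that("equilibrium residual has the endpoint signs that bracket a root", {
  c_p0 <- 8.219e-4
  # q = 0: only the mass-action term survives, with a minus sign
  expect_equal(equilibrium_residual(lys, 0, c_p0, 0.04),
               -exp(lys$ln_k_eq) * c_p0^lys$n * 0.04)
  expect_lt(equilibrium_residual(lys, 0, c_p0, 0.04), 0)
  # q = c_p0: only the precipitate term survives
  expect_gt(equilibrium_residual(lys, c_p0, c_p0, 0.04), 0)
  expect_error(equilibrium_residual(lys, c_p0 * 1.01, c_p0, 0.04),
               "\\[0, c_p0\\]")
})

test_that("solve_equilibrium returns the bracketed root with mass closure", {
  st <- solve_equilibrium(lys, c_p0 = 8.219e-4, c_peg = 0.04)
  q_oracle <- bisect_oracle(lys, 8.219e-4, 0.04)
  expect_equal(st$q, q_oracle, tolerance = 1e-10)
  expect_equal(st$q + st$c_p, st$c_p0, tolerance = 1e-12)
  # degenerate inputs short-circuit to no precipitation
  expect_identical(solve_equilibrium(lys, 8.219e-4, 0)$q, 0)
  expect_identical(solve_equilibrium(lys, 0, 0.04)$q, 0)
  expect_identical(solve_equilibrium(lys, 0, 0.04)$c_p, 0)
})

test_that("solver agrees with the bisection oracle on random instances", {
  set.seed(101)
  for (i in 1:200) {
    inst <- random_instance()
    st <- solve_equilibrium(inst$params, inst$c_p0, inst$c_peg)
    q_o <- bisect_oracle(inst$params, inst$c_p0, inst$c_peg)
    expect_lt(abs(st$q - q_o) / max(q_o, 1e-300), 1e-10)
    expect_lt(abs(st$q + st$c_p - inst$c_p0) / inst$c_p0, 1e-12)
  }
})

test_that("residual is strictly increasing in q across the bracket", {
  set.seed(202)
  for (i in 1:200) {
    inst <- random_instance()
    qs <- seq(0, inst$c_p0, length.out = 300)
    f <- equilibrium_residual(inst$params, qs, inst$c_p0, inst$c_peg)
    expect_true(all(diff(f) > 0))
    # exactly one sign change
    expect_equal(sum(diff(sign(f)) != 0), 1)
  }
})

test_that("internal vectorized bisection matches the public solver", {
  # the fixed-iteration fast path resolves q to c_p0 * 2^-90 absolute;
  # roots large enough to matter for fitting also agree in relative terms
  set.seed(303)
  insts <- replicate(50, random_instance(), simplify = FALSE)
  for (inst in insts) {
    q_fast <- pegprecip:::.solve_bisect(inst$params, inst$c_p0, inst$c_peg)
    q_pub <- solve_equilibrium(inst$params, inst$c_p0, inst$c_peg)$q
    expect_lt(abs(q_fast - q_pub) / inst$c_p0, 1e-15)
    if (q_pub > 1e-8 * inst$c_p0) {
      expect_lt(abs(q_fast - q_pub) / q_pub, 1e-10)
    }
  }
})

test_that("precipitation vanishes as PEG goes to zero", {
  for (prot in reference_parameter_table()$protein) {
    p <- builtin_isotherm_parameters(prot)
    c_p0 <- protein_mgml_to_molar(12, attr(p, "mw"))
    expect_lt(solve_equilibrium(p, c_p0, 1e-12)$q, 1e-6 * c_p0)
  }
})

test_that("supernatant curves are monotone non-increasing in PEG", {
  tab <- reference_parameter_table()
  for (i in seq_len(nrow(tab))) {
    p <- builtin_isotherm_parameters(tab$protein[i])
    lv <- default_screen_levels(peg_max = tab$peg_max[i])
    for (c0 in protein_mgml_to_molar(lv$protein_mgml, tab$mw[i])) {
      cp <- predict_supernatant_curve(p, c0, lv$peg)
      expect_true(all(diff(cp) <= 0))
      q <- c0 - cp
      expect_true(all(diff(q) >= 0))
    }
  }
})

test_that("predict_supernatant_curve handles trivial grids", {
  expect_identical(predict_supernatant_curve(lys, 1e-4, numeric(0)),
                   numeric(0))
  expect_identical(predict_supernatant_curve(lys, 1e-4, 0), 1e-4)
})

test_that("Cohn baseline follows the semi-logarithmic law", {
  expect_equal(cohn_solubility(cohn_parameters(1, 0.5), 0), 10)
  expect_equal(cohn_solubility(cohn_parameters(1, 0), 50), 10)
  expect_equal(cohn_solubility(cohn_parameters(1, 0.1), 10), 1)
  # configurable log base
  expect_equal(cohn_solubility(cohn_parameters(1, 0.1), 10, base = exp(1)),
               1 / exp(0))
  expect_equal(cohn_solubility(cohn_parameters(2, 0.05), c(0, 20), base = 10),
               c(100, 10))
})

test_that("parameter constructors enforce their invariants", {
  expect_error(isotherm_parameters(1, -1, 1e-3, 0, 0), "`n`")
  expect_error(isotherm_parameters(1, 1, 0, 0, 0), "beta0")
  expect_error(isotherm_parameters(1, 1, 1e-3, -1, 0), "beta1")
  expect_error(isotherm_parameters(Inf, 1, 1e-3, 0, 0), "finite")
  expect_error(condition(-1, 0.02), "c_p0")
})
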