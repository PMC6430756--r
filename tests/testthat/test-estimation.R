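test_that("level-based split reproduces the screen's 50/46 arithmetic", {
  ds <- noiseless_screen("lysozyme")
  sp <- split_calibration_validation(ds)
  expect_equal(nrow(sp$calibration), 50)
  expect_equal(nrow(sp$validation), 46)
  expect_equal(nrow(sp$calibration) + nrow(sp$validation), nrow(ds))
  # calibration keeps only the 5 lowest protein and 10 lowest PEG levels
  lp <- sort(unique(ds$c_p0)); lg <- sort(unique(ds$c_peg))
  expect_true(all(sp$calibration$c_p0 <= lp[5]))
  expect_true(all(sp$calibration$c_peg <= lg[10]))
  expect_true(all(sp$validation$c_p0 > lp[5] | sp$validation$c_peg > lg[10]))
})

test_that("split generalizes to other grids and keeps duplicates together", {
  # 5 protein x 10 PEG: removing the top 3/2 levels leaves a 2 x 8 block
  grid <- expand.grid(c_p0 = seq(1e-4, 5e-4, length.out = 5),
                      c_peg = seq(0.005, 0.05, length.out = 10))
  df <- data.frame(grid, replicate = 1, c_supernatant = 1e-5)
  sp <- split_calibration_validation(screen_data(df))
  expect_equal(nrow(sp$calibration), 16)
  expect_equal(nrow(sp$validation), 34)
  # duplicated conditions follow their level, never straddle the split
  df2 <- rbind(df, df[c(1, 50), ])
  sp2 <- split_calibration_validation(screen_data(df2))
  expect_equal(nrow(sp2$calibration) + nrow(sp2$validation), nrow(df2))
  key <- function(d) paste(d$c_p0, d$c_peg)
  expect_length(intersect(key(sp2$calibration), key(sp2$validation)), 0)
  # too few levels is a configuration error
  few <- screen_data(data.frame(c_p0 = rep(c(1e-4, 2e-4, 3e-4), 4),
                                c_peg = rep(c(0.01, 0.02, 0.03, 0.04),
                                            each = 3),
                                replicate = 1, c_supernatant = 1e-5))
  expect_error(split_calibration_validation(few), "protein levels")
})

test_that("sse objective matches a brute-force loop and its edge cases", {
  p <- builtin_isotherm_parameters("bsa")
  ds <- noiseless_screen("bsa")
  expect_lt(sse_objective(p, ds), 1e-16)  # self-consistency at the truth
  # single record: one squared difference
  one <- data.frame(c_p0 = 3e-4, c_peg = 1e-9, c_p_obs = 2e-4)
  # with c_peg ~ 0 the prediction is ~c_p0 = 3e-4, so error is 1e-4
  expect_equal(sse_objective(p, one), 1e-8, tolerance = 1e-6)
  # multi-record value equals an explicit loop over solver calls
  m <- screen_means(ds)[seq(1, 96, by = 7), ]
  m$c_p_obs <- m$c_p_obs * 1.05
  loop <- 0
  for (i in seq_len(nrow(m))) {
    pred <- solve_equilibrium(p, m$c_p0[i], m$c_peg[i])$c_p
    loop <- loop + (m$c_p_obs[i] - pred)^2
  }
  expect_equal(sse_objective(p, m), loop, tolerance = 1e-10)
  expect_error(sse_objective(p, m[0, ]), "empty")
})

test_that("rmsep is the root mean squared prediction error", {
  p <- builtin_isotherm_parameters("myoglobin")
  ds <- noiseless_screen("myoglobin")
  expect_lt(rmsep(p, ds), 1e-8)
  # hand arithmetic: errors 3e-5 and 4e-5 -> sqrt(12.5)e-5;
  # c_peg = 0 makes the prediction exactly c_p0
  two <- data.frame(c_p0 = c(1e-4, 2e-4), c_peg = 0,
                    c_p_obs = c(1e-4 + 3e-5, 2e-4 - 4e-5))
  expect_equal(rmsep(p, two), 3.5355339059327377e-5, tolerance = 1e-12)
})

test_that("fitting recovers generating parameters from a noiseless screen", {
  ds <- noiseless_screen("lysozyme")
  sp <- split_calibration_validation(ds)
  fit <- fit_parameters(sp$calibration, seed = 1, restarts = 4,
                        sann_iter = 500)
  truth <- as.numeric(builtin_isotherm_parameters("lysozyme"))
  est <- as.numeric(fit$params)
  expect_lt(max(abs(est - truth) / abs(truth)), 0.02)
  expect_lt(fit$rmse_calibration, 1e-8)
  expect_lt(rmsep(fit$params, sp$validation), 1e-8)
})

test_that("a reduced model (n = 1, no concentration dependence) refits", {
  # ln_k_eq chosen so the grid sweeps a partial phase split (the
  # precipitated:supernatant ratio runs ~0.15 to ~1.9 across PEG levels)
  p0 <- isotherm_parameters(ln_k_eq = 3.5, n = 1, beta0 = 0.01,
                            beta1 = 0, beta2 = 0)
  lv <- default_screen_levels("small")
  d <- design_screen(lv$protein_mgml, lv$peg, replicates = 1, seed = 2)
  ds <- simulate_screen(p0, d, noise_model(cv = 0, outlier_rate = 0),
                        protein = protein_spec("lysozyme", 14600), seed = 2)
  fit <- fit_parameters(ds, seed = 3, restarts = 4, sann_iter = 500)
  expect_equal(fit$params$n, 1, tolerance = 0.02)
  # the concentration dependences collapse toward their lower bound: their
  # contribution to the hydration exponent is negligible across the grid
  expect_lt(fit$params$beta1 * max(ds$c_peg), 0.05)
  expect_lt(fit$params$beta2 * max(ds$c_p0), 0.05)
})

test_that("fitting is deterministic given its seed", {
  ds <- noiseless_screen("mab_ph7.5")
  f1 <- fit_parameters(ds, seed = 9, restarts = 2, sann_iter = 200)
  f2 <- fit_parameters(ds, seed = 9, restarts = 2, sann_iter = 200)
  expect_identical(as.numeric(f1$params), as.numeric(f2$params))
  expect_identical(f1$objective, f2$objective)
  expect_identical(f1$diagnostics$restarts, f2$diagnostics$restarts)
})

test_that("degenerate designs are rejected as non-identifiable", {
  df <- data.frame(c_p0 = rep(1e-4, 4), c_peg = c(0.01, 0.02, 0.03, 0.04),
                   replicate = 1, c_supernatant = 1e-5)
  expect_error(fit_parameters(screen_data(df)), "non-identifiable")
})

test_that("fit_screen reports the held-out RMSEP and split sizes", {
  ds <- noiseless_screen("bsa")
  fit <- fit_screen(ds, seed = 4, restarts = 3, sann_iter = 500)
  expect_equal(fit$diagnostics$n_calibration, 50)
  expect_equal(fit$diagnostics$n_validation, 46)
  expect_lt(fit$rmsep_validation, 1e-8)
})

test_that("fit reports and parameter files round-trip through JSON", {
  ds <- noiseless_screen("myoglobin")
  fit <- fit_parameters(ds, seed = 5, restarts = 2, sann_iter = 200)
  tmp <- tempfile(fileext = ".json")
  fit_report(fit, tmp)
  rep <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(rep$parameters$n, fit$params$n, tolerance = 1e-12)
  expect_equal(rep$diagnostics$seed, 5)
  expect_equal(nrow(rep$diagnostics$per_restart), 2)
  # bare parameter files
  tmp2 <- tempfile(fileext = ".json")
  write_params_json(fit$params, tmp2)
  back <- read_params_json(tmp2)
  expect_equal(as.numeric(back), as.numeric(fit$params), tolerance = 1e-15)
  # fit-report files are also accepted as parameter sources
  back2 <- read_params_json(tmp)
  expect_equal(back2$ln_k_eq, fit$params$ln_k_eq, tolerance = 1e-12)
})
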