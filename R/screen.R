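#' Replicate measurement noise model
#'
#' Describes the replicate-level error applied to simulated supernatant
#' readings. The core perturbation is multiplicative lognormal — UV-280
#' quantification after dilution produces errors that scale with the signal —
#' parameterized by its coefficient of variation and mean-corrected so the
#' expected reading equals the true concentration. A small fraction of
#' replicates can additionally be replaced by gross errors (pipetting or
#' carry-over mistakes): the reading is multiplied or divided by a factor
#' drawn uniformly from `outlier_scale`.
#'
#' @param cv Relative standard deviation of the multiplicative noise;
#'   default 0.02 (2 %).
#' @param outlier_rate Probability that a replicate becomes a gross error;
#'   in `[0, 1)`. Default 0.02.
#' @param outlier_scale Length-2 range of the gross-error factor; default
#'   `c(1.5, 3)`.
#' @param seed Optional integer seed making [simulate_screen()]
#'   deterministic.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(cv = 0.02, outlier_rate = 0.02,
                        outlier_scale = c(1.5, 3), seed = NULL) {
  if (!is.numeric(cv) || cv < 0) stop("`cv` must be >= 0", call. = FALSE)
  if (!is.numeric(outlier_rate) || outlier_rate < 0 || outlier_rate >= 1) {
    stop("`outlier_rate` must lie in [0, 1)", call. = FALSE)
  }
  if (length(outlier_scale) != 2L || any(outlier_scale < 1)) {
    stop("`outlier_scale` must be a length-2 range of factors >= 1",
         call. = FALSE)
  }
  structure(list(cv = cv, outlier_rate = outlier_rate,
                 outlier_scale = as.numeric(outlier_scale),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "noise_model")
}

#' Design a randomized precipitation screen
#'
#' Builds the full factorial grid of initial protein levels x PEG levels x
#' replicates and assigns each well a randomized position on sequentially
#' filled 96-well plates, as a liquid-handling robot would execute it.
#'
#' @param protein_levels Initial protein concentrations, mg/mL.
#' @param peg_levels PEG concentrations, mol/L.
#' @param replicates Number of replicates per condition (>= 1); default 3.
#' @param seed Integer seed for the plate randomization.
#' @return A data.frame of class `plate_design` with one row per well:
#'   `plate`, `well` (e.g. "A1"), `c_p0_mgml`, `c_peg`, `replicate`. The
#'   seed is stored as an attribute.
#' @examples
#' d <- design_screen(seq(1.5, 12, by = 1.5),
#'                    seq(0.056 / 12, 0.056, length.out = 12),
#'                    replicates = 3, seed = 7)
#' nrow(d)  # 288 wells on 3 plates
#' @export
design_screen <- function(protein_levels, peg_levels, replicates = 3L,
                          seed = 1L) {
  if (length(protein_levels) == 0L || length(peg_levels) == 0L) {
    stop("level vectors must be non-empty", call. = FALSE)
  }
  if (any(protein_levels < 0) || any(peg_levels < 0)) {
    stop("concentration levels must be >= 0", call. = FALSE)
  }
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop("`replicates` must be >= 1", call. = FALSE)

  grid <- expand.grid(c_p0_mgml = protein_levels, c_peg = peg_levels,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  perm <- .with_seed(seed, sample.int(n))
  grid <- grid[perm, , drop = FALSE]
  pos <- seq_len(n) - 1L
  grid$plate <- pos %/% 96L + 1L
  within_plate <- pos %% 96L
  grid$well <- paste0(LETTERS[within_plate %/% 12L + 1L],
                      within_plate %% 12L + 1L)
  rownames(grid) <- NULL
  grid <- grid[, c("plate", "well", "c_p0_mgml", "c_peg", "replicate")]
  attr(grid, "seed") <- as.integer(seed)
  class(grid) <- c("plate_design", "data.frame")
  grid
}

# Run code under a temporary RNG state; the caller's stream is untouched.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Simulate a high-throughput precipitation screen
#'
#' Forward-simulates supernatant measurements for every well of a
#' [design_screen()] layout: protein levels are converted to mol/L, the
#' precipitation equilibrium is solved per condition, and replicate readings
#' are perturbed according to the [noise_model()]. With `cv = 0` and
#' `outlier_rate = 0` every replicate equals the solver output exactly.
#'
#' @param params An [isotherm_parameters()] object (the generating truth).
#' @param design A [design_screen()] layout.
#' @param noise A [noise_model()]; its `seed` (or the `seed` argument)
#'   makes the simulation deterministic.
#' @param protein A [protein_spec()] supplying the molecular weight.
#' @param ph pH metadata attached to the dataset.
#' @param seed Overrides `noise$seed` when given.
#' @return A [screen_data()] object with one row per well.
#' @export
simulate_screen <- function(params, design, noise = noise_model(),
                            protein = protein_spec("lysozyme", 14600),
                            ph = NA_real_, seed = NULL) {
  stopifnot(inherits(params, "isotherm_parameters"),
            inherits(design, "plate_design"),
            inherits(noise, "noise_model"),
            inherits(protein, "protein_spec"))
  seed <- if (!is.null(seed)) as.integer(seed) else noise$seed
  if (is.null(seed)) seed <- 1L

  c_p0 <- protein_mgml_to_molar(design$c_p0_mgml, protein)
  # solve each distinct condition once
  key <- paste(format(c_p0, digits = 17), format(design$c_peg, digits = 17))
  uk <- !duplicated(key)
  st <- solve_equilibrium(params, c_p0[uk], design$c_peg[uk])
  c_p_true <- st$c_p[match(key, key[uk])]

  nwell <- nrow(design)
  obs <- .with_seed(seed, {
    if (noise$cv > 0) {
      sdlog <- sqrt(log1p(noise$cv^2))
      fac <- exp(stats::rnorm(nwell, mean = -sdlog^2 / 2, sd = sdlog))
    } else {
      fac <- rep(1, nwell)
    }
    x <- c_p_true * fac
    if (noise$outlier_rate > 0) {
      hit <- stats::runif(nwell) < noise$outlier_rate
      if (any(hit)) {
        f <- stats::runif(sum(hit), noise$outlier_scale[1],
                          noise$outlier_scale[2])
        updown <- stats::runif(sum(hit)) < 0.5
        f[updown] <- 1 / f[updown]
        x[hit] <- x[hit] * f
      }
    }
    x
  })

  df <- data.frame(
    protein = protein$name, ph = ph,
    c_p0 = c_p0, c_peg = design$c_peg,
    replicate = design$replicate, c_supernatant = obs,
    plate = design$plate, well = design$well,
    stringsAsFactors = FALSE
  )
  screen_data(df, protein_id = protein$name, ph = ph,
              source = "simulated", mw = protein$molecular_weight)
}

#' Replicate outlier filter
#'
#' Data pretreatment applied to each replicate set before averaging: the
#' percentage standard error (standard error of the mean as a percentage of
#' the mean) is computed; if it exceeds the threshold, the replicate
#' farthest from the median is dropped and the criterion re-evaluated,
#' never reducing the set below two retained values. A set still above the
#' threshold with only two values left is returned flagged.
#'
#' The percentage-standard-error reading of the 5 % rule is the default;
#' `measure = "sd"` switches to relative standard deviation.
#'
#' @param replicates Numeric vector of replicate measurements (>= 2 values).
#' @param threshold_pct Threshold on the percentage error; default 5.
#' @param measure `"sem"` (default) or `"sd"`.
#' @return A list with `retained` (values kept, original order), `dropped`
#'   (indices into the input that were removed) and `flagged` (TRUE when the
#'   criterion is still violated, or undefined because the mean is zero with
#'   nonzero spread).
#' @examples
#' triplicate_outlier_filter(c(10, 10, 16))$retained  # 10 10
#' triplicate_outlier_filter(c(10, 10.2, 9.9))$retained  # all kept
#' @export
triplicate_outlier_filter <- function(replicates, threshold_pct = 5,
                                      measure = c("sem", "sd")) {
  measure <- match.arg(measure)
  if (length(replicates) < 2L) {
    stop("need at least 2 replicates", call. = FALSE)
  }
  if (any(!is.finite(replicates))) {
    stop("replicate values must be finite", call. = FALSE)
  }
  idx <- seq_along(replicates)
  pct_err <- function(x) {
    m <- mean(x)
    s <- stats::sd(x)
    if (measure == "sem") s <- s / sqrt(length(x))
    if (m == 0) return(if (s > 0) NA_real_ else 0)
    100 * s / abs(m)
  }
  repeat {
    e <- pct_err(replicates[idx])
    if (is.na(e)) {
      return(list(retained = replicates[idx],
                  dropped = setdiff(seq_along(replicates), idx),
                  flagged = TRUE))
    }
    if (e <= threshold_pct) {
      return(list(retained = replicates[idx],
                  dropped = setdiff(seq_along(replicates), idx),
                  flagged = FALSE))
    }
    if (length(idx) <= 2L) {
      return(list(retained = replicates[idx],
                  dropped = setdiff(seq_along(replicates), idx),
                  flagged = TRUE))
    }
    med <- stats::median(replicates[idx])
    worst <- idx[which.max(abs(replicates[idx] - med))]
    idx <- setdiff(idx, worst)
  }
}
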