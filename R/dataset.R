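#' Screen dataset
#'
#' Container for a precipitation screen: one row per replicate measurement,
#' all concentrations in the model's internal molar units. Built by
#' [simulate_screen()] or [read_screen_csv()], or directly from a prepared
#' data.frame.
#'
#' @param df data.frame with columns `c_p0`, `c_peg`, `replicate`,
#'   `c_supernatant` (all mol/L except `replicate`); optional `protein`,
#'   `ph`, `plate`, `well`.
#' @param protein_id Protein label stored as metadata.
#' @param ph pH metadata.
#' @param source `"measured"` or `"simulated"`.
#' @param mw Molecular weight (g/mol) used for any mg/mL conversion;
#'   `NA` when unknown.
#' @return A data.frame of class `screen_data` with metadata attributes
#'   `protein_id`, `ph`, `source`, `mw`.
#' @export
screen_data <- function(df, protein_id = NA_character_, ph = NA_real_,
                        source = c("simulated", "measured"),
                        mw = NA_real_) {
  source <- match.arg(source)
  need <- c("c_p0", "c_peg", "replicate", "c_supernatant")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  num <- c("c_p0", "c_peg", "c_supernatant")
  for (col in num) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] < 0)
    if (length(bad) > 0L) {
      stop(sprintf("column `%s` has negative or non-finite values at row(s) %s",
                   col, paste(utils::head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    }
  }
  out <- as.data.frame(df)
  attr(out, "protein_id") <- protein_id
  attr(out, "ph") <- ph
  attr(out, "source") <- source
  attr(out, "mw") <- mw
  class(out) <- c("screen_data", "data.frame")
  out
}

#' @export
print.screen_data <- function(x, ...) {
  cat(sprintf("<screen_data> %s (%s), %d replicate rows, %d conditions\n",
              attr(x, "protein_id"), attr(x, "source"), nrow(x),
              nrow(unique(x[, c("c_p0", "c_peg")]))))
  NextMethod()
}

# Group values into distinct levels with a relative tolerance, so levels
# survive text round-trips. Returns an integer level index per value
# (1 = lowest level) and the sorted level representatives.
.level_index <- function(x, tol = 1e-9) {
  u <- sort(unique(x))
  if (length(u) > 1L) {
    scale <- max(abs(u))
    keep <- c(TRUE, diff(u) > tol * scale)
    u <- u[keep]
  }
  idx <- vapply(x, function(v) which.min(abs(u - v)), integer(1))
  list(index = idx, levels = u)
}

#' Collapse a screen to condition-level means
#'
#' Applies the replicate pretreatment ([triplicate_outlier_filter()]) to
#' each condition's replicate set and averages the retained values —
#' the per-condition mean supernatant concentrations that fitting and
#' validation operate on.
#'
#' @param data A [screen_data()] object.
#' @param threshold_pct Outlier-filter threshold; default 5 (%).
#' @param filter Apply the outlier filter (default `TRUE`); with `FALSE`
#'   plain replicate means are returned. Conditions with a single replicate
#'   are averaged as-is in either case.
#' @return data.frame with one row per condition: `c_p0`, `c_peg`,
#'   `c_p_obs` (mean retained supernatant, mol/L), `n_replicates`,
#'   `n_retained`, `flagged`.
#' @export
screen_means <- function(data, threshold_pct = 5, filter = TRUE) {
  stopifnot(inherits(data, "screen_data"))
  key <- paste(format(data$c_p0, digits = 15), format(data$c_peg, digits = 15))
  groups <- split(seq_len(nrow(data)), key)
  rows <- lapply(groups, function(ii) {
    reps <- data$c_supernatant[ii]
    if (filter && length(reps) >= 2L) {
      f <- triplicate_outlier_filter(reps, threshold_pct = threshold_pct)
      kept <- f$retained
      flagged <- f$flagged
    } else {
      kept <- reps
      flagged <- FALSE
    }
    data.frame(c_p0 = data$c_p0[ii[1]], c_peg = data$c_peg[ii[1]],
               c_p_obs = mean(kept), n_replicates = length(reps),
               n_retained = length(kept), flagged = flagged)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$c_p0, out$c_peg), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a screen dataset to CSV
#'
#' Tidy one-row-per-replicate layout with explicit unit columns
#' (`protein_unit`, `peg_unit`), written at full double precision so a
#' write/read round-trip is lossless.
#'
#' @param data A [screen_data()] object (internal molar units).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_screen_csv <- function(data, path) {
  stopifnot(inherits(data, "screen_data"))
  out <- data.frame(
    protein = if ("protein" %in% names(data)) data$protein
              else attr(data, "protein_id"),
    ph = if ("ph" %in% names(data)) data$ph else attr(data, "ph"),
    c_protein_initial = format(data$c_p0, digits = 17),
    protein_unit = "mol/L",
    c_peg = format(data$c_peg, digits = 17),
    peg_unit = "mol/L",
    replicate = data$replicate,
    c_supernatant = format(data$c_supernatant, digits = 17),
    stringsAsFactors = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a screen dataset from CSV
#'
#' Reads the tidy replicate-level layout written by [write_screen_csv()]
#' (or prepared from laboratory exports). Protein concentrations may be
#' given in `mg/mL` — then the protein must resolve to a molecular weight in
#' the config registry — or directly in `mol/L`; PEG in `mol/L` or `%w/w`.
#' All values are converted to internal molar units.
#'
#' @param path CSV file with columns `protein`, `ph`, `c_protein_initial`,
#'   `protein_unit`, `c_peg`, `peg_unit`, `replicate`, `c_supernatant`.
#' @param config A [run_config()] supplying the protein registry and the
#'   PEG specification.
#' @return A [screen_data()] object.
#' @export
read_screen_csv <- function(path, config = run_config()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("protein", "ph", "c_protein_initial", "protein_unit",
            "c_peg", "peg_unit", "replicate", "c_supernatant")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  for (col in c("c_protein_initial", "c_peg", "c_supernatant")) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]))
    if (length(bad) > 0L) {
      stop(sprintf("column `%s`: unparseable value at row %d", col, bad[1]),
           call. = FALSE)
    }
    neg <- which(v < 0)
    if (length(neg) > 0L) {
      stop(sprintf("column `%s`: negative concentration at row %d",
                   col, neg[1]), call. = FALSE)
    }
    raw[[col]] <- v
  }

  peg <- peg_spec(molecular_weight = config$units$peg_molecular_weight,
                  solution_density = config$units$peg_density)
  protein_id <- raw$protein[1]
  mw <- NA_real_

  punit <- unique(raw$protein_unit)
  if (length(punit) != 1L || !punit %in% c("mg/mL", "mol/L")) {
    stop("`protein_unit` must be uniformly 'mg/mL' or 'mol/L'",
         call. = FALSE)
  }
  if (punit == "mg/mL") {
    mw <- config$proteins[[protein_id]]
    if (is.null(mw)) {
      stop("protein '", protein_id,
           "' not in the molecular-weight registry; cannot convert mg/mL",
           call. = FALSE)
    }
    c_p0 <- protein_mgml_to_molar(raw$c_protein_initial, mw)
    c_sup <- protein_mgml_to_molar(raw$c_supernatant, mw)
  } else {
    c_p0 <- raw$c_protein_initial
    c_sup <- raw$c_supernatant
  }

  gunit <- unique(raw$peg_unit)
  if (length(gunit) != 1L || !gunit %in% c("mol/L", "%w/w")) {
    stop("`peg_unit` must be uniformly 'mol/L' or '%w/w'", call. = FALSE)
  }
  c_peg <- if (gunit == "%w/w") peg_ww_to_molar(raw$c_peg, peg) else raw$c_peg

  df <- data.frame(protein = raw$protein, ph = raw$ph, c_p0 = c_p0,
                   c_peg = c_peg, replicate = raw$replicate,
                   c_supernatant = c_sup, stringsAsFactors = FALSE)
  screen_data(df, protein_id = protein_id, ph = raw$ph[1],
              source = "measured", mw = mw)
}
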