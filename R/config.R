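#' Run configuration
#'
#' Central knobs of a run: unit conventions, solver and optimizer settings,
#' the protein molecular-weight registry, and noise defaults for
#' simulation. All arguments have working defaults; [read_run_config()]
#' builds the same object from a YAML file.
#'
#' @param units List: `peg_molecular_weight` (g/mol, default 6000),
#'   `peg_density` (g/mL, default 1.0), `cohn_log_base` (default 10).
#' @param solver List: `eps_edge` — relative bracket margin that triggers
#'   the log-substituted solve (default 1e-12).
#' @param fit List: `seed`, `restarts`, `sann_iter`, `bounds` (named list
#'   overriding [default_fit_bounds()]).
#' @param proteins Named list/vector mapping protein label to molecular
#'   weight in g/mol; defaults to [default_protein_registry()].
#' @param noise List: `cv`, `outlier_rate`, `outlier_scale`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(units = list(), solver = list(), fit = list(),
                       proteins = NULL, noise = list()) {
  merge_defaults <- function(given, defaults) {
    defaults[names(given)] <- given
    defaults
  }
  cfg <- structure(list(
    units = merge_defaults(units, list(peg_molecular_weight = 6000,
                                       peg_density = 1.0,
                                       cohn_log_base = 10)),
    solver = merge_defaults(solver, list(eps_edge = 1e-12)),
    fit = merge_defaults(fit, list(seed = 1L, restarts = 10L,
                                   sann_iter = 1000L, bounds = list())),
    proteins = if (is.null(proteins)) as.list(default_protein_registry())
               else as.list(proteins),
    noise = merge_defaults(noise, list(cv = 0.02, outlier_rate = 0.02,
                                       outlier_scale = c(1.5, 3)))
  ), class = "run_config")
  .validate_config(cfg)
  cfg
}

.validate_config <- function(cfg) {
  u <- cfg$units
  if (u$peg_molecular_weight <= 0 || u$peg_density <= 0 ||
      u$cohn_log_base <= 1) {
    stop("invalid unit settings in config", call. = FALSE)
  }
  mws <- unlist(cfg$proteins)
  if (length(mws) > 0L && (any(!is.finite(mws)) || any(mws <= 0))) {
    stop("protein registry molecular weights must be positive",
         call. = FALSE)
  }
  if (cfg$noise$cv < 0 || cfg$noise$outlier_rate < 0 ||
      cfg$noise$outlier_rate >= 1) {
    stop("invalid noise settings in config", call. = FALSE)
  }
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Fields present in the file override the defaults of [run_config()];
#' everything else keeps its default. The file is validated on load.
#'
#' @param path YAML file path.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  run_config(units = y$units %||% list(),
             solver = y$solver %||% list(),
             fit = y$fit %||% list(),
             proteins = y$proteins,
             noise = y$noise %||% list())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Short content hash of a config, for run logging.
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(cfg), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
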