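# Run configuration: defaults, YAML round-trip, validation.

#' Default run configuration
#'
#' Collects the tunable thresholds and parameters of the pipeline:
#' `pag_p = 1e-6` (all-parameters Wald threshold for PAG calling),
#' `deg_p = 0.001` (BH-adjusted threshold of the moderated test),
#' `enrich_p = 0.01` (BH-adjusted over-representation cutoff),
#' `window = 10000` (promoter half-width in bp), the interaction-effect
#' `gammas`, `n_iter = 100` robustness iterations, the link and the grade
#' mapping.
#'
#' @return Named list.
#' @export
default_config <- function() {
  list(link = "probit",
       pag_p = 1e-6,
       all_params = TRUE,
       deg_p = 0.001,
       enrich_p = 0.01,
       window = 10000,
       gammas = c(0, 1, 1, 1),
       n_iter = 100,
       seed = 1,
       grade_mapping = as.list(default_hd_mapping()))
}

.validate_config <- function(cfg) {
  for (f in c("pag_p", "deg_p", "enrich_p")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      stop("config field '", f, "' must lie in (0, 1)", call. = FALSE)
    }
  }
  if (cfg$window <= 0) stop("config field 'window' must be positive",
                            call. = FALSE)
  if (length(cfg$gammas) != 4L) stop("config field 'gammas' must have length 4",
                                     call. = FALSE)
  invisible(cfg)
}

#' Read (or write) a YAML run configuration
#'
#' Missing fields are filled from [default_config()]; thresholds are
#' validated.  `write_run_config()` followed by `read_run_config()` is the
#' identity on the stored fields.
#'
#' @param path YAML file path.
#' @return Named list (read) or `path` invisibly (write).
#' @export
read_run_config <- function(path) {
  cfg <- utils::modifyList(default_config(), yaml::read_yaml(path))
  cfg$gammas <- as.numeric(unlist(cfg$gammas))
  .validate_config(cfg)
  cfg
}

#' @rdname read_run_config
#' @param cfg Configuration list.
#' @export
write_run_config <- function(cfg, path) {
  .validate_config(utils::modifyList(default_config(), cfg))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
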