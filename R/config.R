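#' Configuration for the scale-validation pipeline
#'
#' Collects every tunable threshold of the validation workflow, with the
#' conventional defaults for dichotomous symptom scales: infit acceptance
#' band 0.91-1.09, residual-correlation threshold 0.2 with familywise alpha
#' 0.05, DIF alpha 0.05, and reliability thresholds alpha > 0.8 and
#' PSI > 0.7. Nothing in the pipeline is hard-coded to these values.
#'
#' @param n_per_sample persons in each of the calibration and validation
#'   samples.
#' @param pa_sims permuted datasets for parallel analysis.
#' @param infit_bounds length-2 acceptance band for infit mean squares.
#' @param q3_threshold residual-correlation magnitude threshold.
#' @param alpha_level significance level for local-dependence and DIF tests.
#' @param dif_covariates names of binary covariates to test for DIF.
#' @param alpha_threshold,psi_threshold reliability pass thresholds.
#' @param reliability_subsets optional named list of item-label vectors for
#'   which reliability is additionally reported (e.g. a standard diagnostic
#'   subset).
#' @param confirm_with_validation require every elimination decision to be
#'   confirmed in the validation sample (same item outside the infit band on
#'   the same side, or same pair Q3-flagged) before an item is removed.
#' @param seed integer seed driving the sample split and permutations.
#' @return A list of class `validation_config`.
#' @export
validation_config <- function(n_per_sample = 500, pa_sims = 5000,
                              infit_bounds = c(0.91, 1.09),
                              q3_threshold = 0.2, alpha_level = 0.05,
                              dif_covariates = character(),
                              alpha_threshold = 0.8, psi_threshold = 0.7,
                              reliability_subsets = NULL,
                              confirm_with_validation = TRUE, seed = 1) {
  stopifnot(n_per_sample >= 1, pa_sims >= 100,
            length(infit_bounds) == 2, infit_bounds[1] < infit_bounds[2],
            infit_bounds[1] > 0,
            q3_threshold > 0, q3_threshold < 1,
            alpha_level > 0, alpha_level < 1,
            alpha_threshold > 0, alpha_threshold < 1,
            psi_threshold > 0, psi_threshold < 1)
  structure(list(n_per_sample = n_per_sample, pa_sims = pa_sims,
                 infit_bounds = infit_bounds, q3_threshold = q3_threshold,
                 alpha_level = alpha_level, dif_covariates = dif_covariates,
                 alpha_threshold = alpha_threshold,
                 psi_threshold = psi_threshold,
                 reliability_subsets = reliability_subsets,
                 confirm_with_validation = confirm_with_validation,
                 seed = seed),
            class = "validation_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' The YAML schema mirrors [validation_config()] field for field and
#' round-trips losslessly.
#'
#' @param config a `validation_config`.
#' @param path YAML file path.
#' @return `read_validation_config()` returns a `validation_config`;
#'   `write_validation_config()` returns `path` invisibly.
#' @export
write_validation_config <- function(config, path) {
  stopifnot(inherits(config, "validation_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_validation_config
#' @export
read_validation_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$infit_bounds <- unlist(x$infit_bounds)
  x$dif_covariates <- as.character(unlist(x$dif_covariates))
  if (!is.null(x$reliability_subsets))
    x$reliability_subsets <- lapply(x$reliability_subsets, unlist)
  do.call(validation_config, x)
}

#' @export
print.validation_config <- function(x, ...) {
  cat("Scale-validation configuration:\n")
  cat(sprintf("  samples: 2 x %d persons (seed %s)\n", x$n_per_sample,
              format(x$seed)))
  cat(sprintf("  parallel analysis: %d simulations\n", x$pa_sims))
  cat(sprintf("  infit band: %.2f-%.2f; Q3: r > %.2f & Holm p <= %.2f\n",
              x$infit_bounds[1], x$infit_bounds[2], x$q3_threshold,
              x$alpha_level))
  cat(sprintf("  DIF covariates: %s (alpha %.2f)\n",
              if (length(x$dif_covariates))
                paste(x$dif_covariates, collapse = ", ") else "none",
              x$alpha_level))
  cat(sprintf("  reliability thresholds: alpha > %.2f, PSI > %.2f\n",
              x$alpha_threshold, x$psi_threshold))
  invisible(x)
}
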