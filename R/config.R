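#' Analysis configuration
#'
#' Collects every adjustable threshold, seed and naming convention of the
#' discovery pipeline in one validated object.  Defaults follow the standard
#' parameterisation of the workflow: per-stage false discovery rates
#' `fdr_mol` = 0.05 (molecular landscape), `fdr_alpha` = 0.1 (arm-specific
#' screening) and `fdr_beta` = 0.2 (predictive interaction components), a
#' minimum group size of `n_min` = 10 for any statistical test, `U` = 1000
#' treatment-label permutations and `B` = 500 bootstrap resamples.
#'
#' @param fdr_mol FDR threshold for subtype enrichment/depletion calls.
#' @param fdr_alpha FDR threshold for treatment-arm-specific biomarkers.
#' @param fdr_beta FDR threshold for predictive (interaction) components.
#' @param n_min Minimum number of patients required in every compared group
#'   (mutant/wild-type, per arm where applicable) before a model is fitted.
#' @param n_permutations Number of treatment-label permutations used for the
#'   multiplicity adjustment of subgroup treatment-effect p-values.
#' @param n_bootstrap Number of non-parametric bootstrap resamples used for
#'   the bias correction of subgroup treatment effects.
#' @param seed Integer master seed; `NULL` leaves the RNG state untouched.
#' @param endpoints Character subset of `c("OS", "PFS", "ORR")`.
#' @param covariates Names of clinical columns entering every regression
#'   model as unpenalised covariates.
#' @param subtype_schemes Names of clinical columns holding categorical
#'   tumour subtype labels (e.g. primary tumour sidedness, CMS).
#' @param custom_modules Named list of user-defined feature groupings; each
#'   element is a character vector of feature names whose union is added as
#'   one pseudo-feature (e.g. `list(RAS = c("KRAS_SV", "NRAS_SV"))`).
#' @param effect_reporting `"reciprocal"` reports every hazard/odds ratio
#'   `> 1` as its reciprocal with a direction flag so that values `< 1`
#'   always denote benefit; `"raw"` reports coefficients as estimated.
#' @param include_treatment_main Add a treatment main-effect term to the
#'   interaction model (sensitivity analysis; the default model carries only
#'   biomarker and biomarker-by-treatment terms).
#' @param add_one_permutation Use the add-one permutation p-value
#'   `(1 + sum) / (1 + U)` instead of the plain fraction.
#' @param fdr_beta_cv Relaxed interaction FDR used inside the
#'   cross-validation stability analysis.
#' @param mutex_alpha Growth threshold of the mutual-exclusivity module
#'   search: a candidate is admitted only while the module score (worst
#'   member exclusivity p-value) stays below this value.
#' @param missing_as How to resolve missing alteration values at load time:
#'   `"error"` (default) or `"zero"`.
#'
#' @return An object of class `onco_config` (a validated named list).
#' @examples
#' onco_config()
#' onco_config(fdr_alpha = 0.05, covariates = "n_met_sites")
#' @export
onco_config <- function(fdr_mol = 0.05,
                        fdr_alpha = 0.1,
                        fdr_beta = 0.2,
                        n_min = 10,
                        n_permutations = 1000,
                        n_bootstrap = 500,
                        seed = NULL,
                        endpoints = c("OS", "PFS", "ORR"),
                        covariates = character(),
                        subtype_schemes = character(),
                        custom_modules = list(),
                        effect_reporting = c("reciprocal", "raw"),
                        include_treatment_main = FALSE,
                        add_one_permutation = FALSE,
                        fdr_beta_cv = 0.3,
                        mutex_alpha = 0.05,
                        missing_as = c("error", "zero")) {
  cfg <- list(
    fdr_mol = fdr_mol, fdr_alpha = fdr_alpha, fdr_beta = fdr_beta,
    n_min = n_min, n_permutations = n_permutations,
    n_bootstrap = n_bootstrap, seed = seed, endpoints = endpoints,
    covariates = covariates, subtype_schemes = subtype_schemes,
    custom_modules = custom_modules,
    effect_reporting = match.arg(effect_reporting),
    include_treatment_main = include_treatment_main,
    add_one_permutation = add_one_permutation,
    fdr_beta_cv = fdr_beta_cv, mutex_alpha = mutex_alpha,
    missing_as = match.arg(missing_as)
  )
  validate_config(cfg)
}

#' Validate a raw configuration
#'
#' Fills defaults for absent keys, rejects unknown keys and checks every
#' value's range.  Accepts the output of [onco_config()], a plain named list
#' (e.g. parsed from YAML/JSON), or `NULL` (all defaults).
#'
#' @param config Named list of configuration values.
#' @return A validated `onco_config` object.
#' @export
validate_config <- function(config = NULL) {
  defaults <- list(
    fdr_mol = 0.05, fdr_alpha = 0.1, fdr_beta = 0.2, n_min = 10L,
    n_permutations = 1000L, n_bootstrap = 500L, seed = NULL,
    endpoints = c("OS", "PFS", "ORR"), covariates = character(),
    subtype_schemes = character(), custom_modules = list(),
    effect_reporting = "reciprocal", include_treatment_main = FALSE,
    add_one_permutation = FALSE, fdr_beta_cv = 0.3, mutex_alpha = 0.05,
    missing_as = "error"
  )
  config <- unclass(config %||% list())
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  config <- config[!vapply(config, is.null, logical(1))]
  cfg <- modifyList(defaults, config, keep.null = TRUE)
  # modifyList merges lists recursively, which mangles the module list
  if ("custom_modules" %in% names(config)) {
    cfg$custom_modules <- config$custom_modules
  }

  for (key in c("fdr_mol", "fdr_alpha", "fdr_beta", "fdr_beta_cv",
                "mutex_alpha")) {
    v <- cfg[[key]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v >= 1) {
      abort(paste0(key, " out of range: must be a fraction in (0, 1)"))
    }
  }
  if (!is.numeric(cfg$n_min) || cfg$n_min < 2) {
    abort("n_min out of range: must be an integer >= 2")
  }
  if (!is.numeric(cfg$n_permutations) || cfg$n_permutations < 1) {
    abort("n_permutations out of range: must be >= 1")
  }
  if (!is.numeric(cfg$n_bootstrap) || cfg$n_bootstrap < 1) {
    abort("n_bootstrap out of range: must be >= 1")
  }
  cfg$n_min <- as.integer(cfg$n_min)
  cfg$n_permutations <- as.integer(cfg$n_permutations)
  cfg$n_bootstrap <- as.integer(cfg$n_bootstrap)
  if (!is.null(cfg$seed)) cfg$seed <- as.integer(cfg$seed)

  bad_ep <- setdiff(cfg$endpoints, ENDPOINTS)
  if (length(bad_ep) > 0 || length(cfg$endpoints) == 0) {
    abort("endpoints must be a non-empty subset of OS, PFS, ORR")
  }
  if (!cfg$effect_reporting %in% c("reciprocal", "raw")) {
    abort("effect_reporting must be 'reciprocal' or 'raw'")
  }
  if (!cfg$missing_as %in% c("error", "zero")) {
    abort("missing_as must be 'error' or 'zero'")
  }
  if (length(cfg$custom_modules) > 0 &&
      (is.null(names(cfg$custom_modules)) ||
       any(names(cfg$custom_modules) == ""))) {
    abort("custom_modules must be a named list of feature vectors")
  }
  cfg$custom_modules <- lapply(cfg$custom_modules, as.character)
  cfg$covariates <- as.character(cfg$covariates)
  cfg$subtype_schemes <- as.character(cfg$subtype_schemes)
  cfg$include_treatment_main <- isTRUE(cfg$include_treatment_main)
  cfg$add_one_permutation <- isTRUE(cfg$add_one_permutation)
  structure(cfg, class = "onco_config")
}

#' Read a configuration file
#'
#' @param path Path to a YAML (`.yml`/`.yaml`) or JSON (`.json`) file whose
#'   keys are [onco_config()] fields.
#' @return A validated `onco_config` object.
#' @export
read_onco_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    abort("config file must be .yaml/.yml or .json")
  )
  if (!is.null(raw$custom_modules)) {
    raw$custom_modules <- lapply(raw$custom_modules, as.character)
  }
  validate_config(raw)
}

#' Write a configuration file
#'
#' @param config An `onco_config` object.
#' @param path Output path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
write_onco_config <- function(config, path) {
  config <- validate_config(config)
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  switch(ext,
    yml = ,
    yaml = yaml::write_yaml(x, path),
    json = jsonlite::write_json(x, path, auto_unbox = TRUE, null = "null",
                                pretty = TRUE, digits = NA),
    abort("config file must be .yaml/.yml or .json")
  )
  invisible(path)
}

#' @export
print.onco_config <- function(x, ...) {
  cat("<onco_config>\n")
  cat(sprintf("  FDR (landscape / screening / interaction): %s / %s / %s\n",
              x$fdr_mol, x$fdr_alpha, x$fdr_beta))
  cat(sprintf("  n_min: %d | permutations: %d | bootstraps: %d\n",
              x$n_min, x$n_permutations, x$n_bootstrap))
  cat(sprintf("  endpoints: %s\n", paste(x$endpoints, collapse = ", ")))
  if (length(x$covariates)) {
    cat(sprintf("  covariates: %s\n", paste(x$covariates, collapse = ", ")))
  }
  if (length(x$subtype_schemes)) {
    cat(sprintf("  subtype schemes: %s\n",
                paste(x$subtype_schemes, collapse = ", ")))
  }
  if (length(x$custom_modules)) {
    cat(sprintf("  custom modules: %s\n",
                paste(names(x$custom_modules), collapse = ", ")))
  }
  cat(sprintf("  effect reporting: %s\n", x$effect_reporting))
  invisible(x)
}
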