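#' Run the full discovery pipeline
#'
#' Executes the five stages in order: molecular landscape (subtype
#' enrichment, mutual-exclusivity modules, feature-set construction),
#' treatment-arm-specific screening, cross-arm interaction tests, subgroup
#' selection, and resampling (permutation multiplicity adjustment plus
#' bootstrap bias correction of the selected subgroup effects).  An empty
#' subgroup list is a valid result: the pipeline completes and reports
#' zero subgroups.
#'
#' @param trial A [trial_data] object, or `NULL` to load from files.
#' @param clinical_path,alterations_path Input files used when `trial` is
#'   `NULL` (see [load_trial()]).
#' @param config Configuration; defaults to the one attached to `trial`.
#' @param out_dir Optional output directory; when given, all result tables
#'   are written as TSV plus a JSON summary and a MANIFEST of completed
#'   stages (partial outputs are retained on error).
#' @param seed Master seed for the resampling stage (default: the
#'   configuration seed).  Permutation and bootstrap draw from separate
#'   seeds derived from it.
#' @return An object of class `onco_report`: a list with elements
#'   `enrichment`, `modules`, `screening`, `interactions`, `subgroups`,
#'   `km_curves`, `audit`, `config`, `seed`, `version`, `n_patients`.
#' @export
run_pipeline <- function(trial = NULL, clinical_path = NULL,
                         alterations_path = NULL, config = NULL,
                         out_dir = NULL, seed = NULL) {
  if (is.null(trial)) {
    trial <- load_trial(clinical_path, alterations_path,
                        config %||% onco_config())
  } else if (!is.null(config)) {
    trial <- new_trial_data(as_tibble(trial), feature_meta(trial),
                            validate_config(config))
  }
  cfg <- trial_config(trial)
  seed <- seed %||% cfg$seed
  completed <- character()
  results <- list()
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }

  stage <- function(name, expr) {
    out <- tryCatch(expr, error = function(e) {
      if (!is.null(out_dir)) {
        writeLines(c(completed, paste0("FAILED: ", name)),
                   file.path(out_dir, "MANIFEST"))
      }
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    completed <<- c(completed, name)
    out
  }

  results$enrichment <- stage("landscape_enrichment", {
    if (length(cfg$subtype_schemes) > 0) {
      test_subtype_enrichment(trial)
    } else {
      test_enrichment_placeholder()
    }
  })
  results$modules <- stage("landscape_modules", find_mutex_modules(trial))
  trial_aug <- stage("feature_set",
                     build_feature_set(trial, results$modules))
  results$screening <- stage("screening", screen_arms(trial_aug))
  results$interactions <- stage(
    "interaction",
    test_interaction(trial_aug, screen = results$screening)
  )
  subgroups <- stage("selection",
                     select_subgroups(trial_aug, results$interactions))

  found <- subgroups[which(subgroups$selected), , drop = FALSE]
  if (nrow(found) > 0) {
    sub_seeds <- derive_seeds(seed, 2)
    found <- stage("permutation", permutation_adjust(
      trial_aug, found, subgroup_search("fdr"), seed = sub_seeds[1]
    ))
    found <- stage("bootstrap", bootstrap_bias_correct(
      trial_aug, found, seed = sub_seeds[2]
    ))
    subgroups <- dplyr::left_join(
      subgroups,
      found[, c("group_id", "status", "p_adj", "gamma_corrected",
                "effect_corrected", "ci_boot_low", "ci_boot_high",
                "boot_skipped", "boot_unstable")],
      by = c("group_id", "status")
    )
  } else {
    subgroups$p_adj <- numeric(0)
    subgroups$gamma_corrected <- numeric(0)
    subgroups$effect_corrected <- numeric(0)
    subgroups$ci_boot_low <- numeric(0)
    subgroups$ci_boot_high <- numeric(0)
    subgroups$boot_skipped <- integer(0)
    subgroups$boot_unstable <- logical(0)
  }
  results$screening <- apply_reporting(results$screening, cfg,
                                       comparison = "mutant")
  subgroups <- apply_reporting(subgroups, cfg, comparison = "treatment")
  class(subgroups) <- c("onco_subgroups", class(tibble()))
  results$subgroups <- subgroups

  results$km_curves <- stage("km_curves", km_curves(trial_aug, subgroups))
  results$audit <- dplyr::bind_rows(
    attr(results$screening, "audit") %||% audit_empty(),
    attr(results$interactions, "audit") %||% audit_empty()
  )

  report <- structure(
    c(results, list(
      config = cfg, seed = seed,
      version = as.character(packageVersion("oncoscreen")),
      n_patients = nrow(trial), feature_meta = feature_meta(trial_aug)
    )),
    class = "onco_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

test_enrichment_placeholder <- function() {
  out <- tibble(feature = character(), scheme = character(),
                level = character(), direction = character(),
                k = integer(), K = integer(), n_s = integer(),
                N = integer(), p = double(), q = double(),
                significant = logical())
  class(out) <- c("onco_enrichment", class(tibble()))
  out
}

# independent substreams for the resampling stages, all below 2^31
derive_seeds <- function(seed, k) {
  if (is.null(seed)) return(rep(list(NULL), k))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, k)
}

#' Reporting convention for ratio effects
#'
#' Under the reciprocal convention any hazard/odds ratio above 1 is
#' reported as its reciprocal (CI reversed accordingly) with a direction
#' flag, so that reported ratios below 1 always read as a benefit: for
#' mutant-versus-wild-type comparisons the flag distinguishes
#' `benefit-in-mutant` from `benefit-in-wildtype`; for treatment effects,
#' `benefit-in-experimental` from `benefit-in-control`.  Stored
#' coefficients stay on the raw scale.
#'
#' @param x A result tibble with `effect`, `ci_low`, `ci_high` columns.
#' @param config An [onco_config()]; `effect_reporting = "raw"` keeps the
#'   raw scale.
#' @param comparison `"mutant"` (screening results) or `"treatment"`
#'   (subgroup effects).
#' @return `x` with `effect_reported`, `ci_reported_low`,
#'   `ci_reported_high` and `direction` columns appended.
#' @export
apply_reporting <- function(x, config,
                            comparison = c("mutant", "treatment")) {
  comparison <- match.arg(comparison)
  if (nrow(x) == 0) {
    x$effect_reported <- numeric(0)
    x$ci_reported_low <- numeric(0)
    x$ci_reported_high <- numeric(0)
    x$direction <- character(0)
    return(x)
  }
  labels <- if (comparison == "mutant") {
    c("benefit-in-mutant", "benefit-in-wildtype")
  } else {
    c("benefit-in-experimental", "benefit-in-control")
  }
  flip <- config$effect_reporting == "reciprocal" & x$effect > 1
  x$effect_reported <- ifelse(flip, 1 / x$effect, x$effect)
  x$ci_reported_low <- ifelse(flip, 1 / x$ci_high, x$ci_low)
  x$ci_reported_high <- ifelse(flip, 1 / x$ci_low, x$ci_high)
  x$direction <- ifelse(x$effect > 1, labels[2], labels[1])
  x
}

#' Kaplan-Meier coordinates for reported subgroups
#'
#' Product-limit estimates by treatment arm within each selected subgroup
#' of a survival endpoint, with 95% Greenwood bands on the log scale (the
#' `survfit` default), as plot-ready coordinates.
#'
#' @param trial A [trial_data] object.
#' @param subgroups An `onco_subgroups` tibble.
#' @return A tibble with columns `group_id`, `status`, `arm`, `time`,
#'   `n_risk`, `n_event`, `surv`, `lower`, `upper`.
#' @export
km_curves <- function(trial, subgroups) {
  data <- as_tibble(trial)
  sel <- subgroups[which(subgroups$selected), , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sel))) {
    cols <- endpoint_cols(sel$endpoint[i])
    if (cols$type != "survival") next
    want <- if (sel$status[i] == "mutant") 1 else 0
    mask <- stratum_mask(data, sel$scheme[i], sel$level[i]) &
      data[[sel$feature[i]]] == want & endpoint_rows(data, sel$endpoint[i])
    sdat <- data[mask, , drop = FALSE]
    fit <- survival::survfit(
      survival::Surv(sdat[[cols$time]], sdat[[cols$event]]) ~ sdat$treatment,
      conf.type = "log"
    )
    arms <- rep(sub(".*=", "", names(fit$strata)),
                fit$strata %||% length(fit$time))
    rows[[length(rows) + 1]] <- tibble(
      group_id = sel$group_id[i], status = sel$status[i],
      arm = as.integer(arms), time = fit$time, n_risk = fit$n.risk,
      n_event = fit$n.event, surv = fit$surv, lower = fit$lower,
      upper = fit$upper
    )
  }
  dplyr::bind_rows(c(list(tibble(
    group_id = character(), status = character(), arm = integer(),
    time = double(), n_risk = double(), n_event = double(),
    surv = double(), lower = double(), upper = double()
  )), rows))
}

#' Write a pipeline report to disk
#'
#' Emits `enrichment.tsv`, `modules.tsv` (members semicolon-joined),
#' `arm_biomarkers.tsv`, `interactions.tsv`, `subgroups_adjusted.tsv`,
#' `km_curves.tsv`, `audit.tsv`, `feature_set.tsv` metadata, a JSON
#' summary `report.json` and a `MANIFEST`.  Output is deterministic:
#' identical reports produce byte-identical files.
#'
#' @param report An `onco_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  w <- function(x, name) {
    readr::write_tsv(as_tibble(x), file.path(dir, name), progress = FALSE)
  }
  w(report$enrichment, "enrichment.tsv")
  mods <- as_tibble(report$modules)
  if (nrow(mods) > 0) {
    mods$members <- vapply(mods$members, paste, character(1),
                           collapse = ";")
  } else {
    mods$members <- character(0)
  }
  w(mods, "modules.tsv")
  w(report$screening, "arm_biomarkers.tsv")
  w(report$interactions, "interactions.tsv")
  w(report$subgroups, "subgroups_adjusted.tsv")
  w(report$km_curves, "km_curves.tsv")
  w(report$audit, "audit.tsv")
  w(report$feature_meta, "feature_set.tsv")

  found <- report$subgroups[which(report$subgroups$selected), , drop = FALSE]
  summary <- list(
    version = report$version,
    seed = report$seed,
    n_patients = report$n_patients,
    n_features = nrow(report$feature_meta),
    n_modules = nrow(report$modules),
    n_enrichment_significant = sum(report$enrichment$significant,
                                   na.rm = TRUE),
    n_screen_tests = nrow(report$screening),
    n_screen_significant = sum(report$screening$significant, na.rm = TRUE),
    n_interaction_tests = nrow(report$interactions),
    n_predictive = sum(report$interactions$predictive, na.rm = TRUE),
    n_subgroups = nrow(found),
    subgroups = found,
    config = unclass(report$config)
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, null = "null", pretty = TRUE,
                       digits = NA)
  writeLines(
    c("landscape_enrichment", "landscape_modules", "feature_set",
      "screening", "interaction", "selection", "resampling", "km_curves",
      "outputs"),
    file.path(dir, "MANIFEST")
  )
  invisible(dir)
}

#' @export
print.onco_report <- function(x, ...) {
  found <- x$subgroups[which(x$subgroups$selected), , drop = FALSE]
  cat("<onco_report>\n")
  cat(sprintf("  %d patients, %d features (%d modules)\n",
              x$n_patients, nrow(x$feature_meta), nrow(x$modules)))
  cat(sprintf("  enrichment calls: %d | screening hits: %d | predictive: %d\n",
              sum(x$enrichment$significant, na.rm = TRUE),
              sum(x$screening$significant, na.rm = TRUE),
              sum(x$interactions$predictive, na.rm = TRUE)))
  if (nrow(found) == 0) {
    cat("  no subgroup selected (empty result)\n")
  } else {
    for (i in seq_len(nrow(found))) {
      cat(sprintf(
        "  %s | %s %s | %s=%s: effect %.2f (corrected %.2f [%.2f, %.2f]), p_adj %.3g\n",
        found$endpoint[i], found$feature[i], found$status[i],
        found$scheme[i], found$level[i], found$effect[i],
        found$effect_corrected[i], exp(found$ci_boot_low[i]),
        exp(found$ci_boot_high[i]), found$p_adj[i]
      ))
    }
  }
  invisible(x)
}
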