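#' Trial dataset container
#'
#' A `trial_data` object is a tibble with one row per patient, joining the
#' clinical table (treatment indicator, endpoints, covariates, subtype
#' labels) with the binary alteration matrix.  Feature columns are tracked
#' through the attribute `feature_meta` (feature name, gene symbol,
#' alteration class) and the analysis configuration travels with the data
#' in the attribute `config`.
#'
#' @param clinical Data frame with columns `patient_id`, `treatment`
#'   (0 = control arm, 1 = experimental arm), the endpoint columns used by
#'   the configured endpoints (`os_time`/`os_event`, `pfs_time`/`pfs_event`,
#'   `orr`), plus any covariate and subtype-label columns named in `config`.
#' @param alterations Data frame with a `patient_id` column and one binary
#'   column per candidate feature.
#' @param config An [onco_config()] object.
#' @param feature_meta Optional tibble with columns `feature`, `gene`,
#'   `class`; inferred from feature names when absent (suffixes `_AMP`,
#'   `_DEL` mark copy-number classes, `MSI` the microsatellite status,
#'   everything else a somatic variant).
#'
#' @return A `trial_data` tibble (inner join on `patient_id`).
#' @export
trial_data <- function(clinical, alterations, config = onco_config(),
                       feature_meta = NULL) {
  config <- validate_config(config)
  clinical <- as_tibble(clinical)
  alterations <- as_tibble(alterations)

  check_clinical(clinical, config)
  alterations <- check_alterations(alterations, config)

  features <- setdiff(names(alterations), "patient_id")
  if (is.null(feature_meta)) feature_meta <- infer_feature_meta(features)

  dropped_clin <- setdiff(clinical$patient_id, alterations$patient_id)
  dropped_alt <- setdiff(alterations$patient_id, clinical$patient_id)
  n_dropped <- length(dropped_clin) + length(dropped_alt)
  if (n_dropped > 0) {
    warn(sprintf(
      "dropped %d patient(s) missing from one input (%s)",
      n_dropped,
      paste(head(c(dropped_clin, dropped_alt), 10), collapse = ", ")
    ))
  }
  joined <- dplyr::inner_join(clinical, alterations, by = "patient_id")
  if (nrow(joined) == 0) abort("no patients shared between the two inputs")

  for (scheme in config$subtype_schemes) {
    n_na <- sum(is.na(joined[[scheme]]))
    if (n_na > 0) {
      inform(sprintf(
        "%d patient(s) without a '%s' label are excluded from that scheme's stratified analyses",
        n_na, scheme
      ))
    }
  }
  arms <- table(factor(joined$treatment, levels = 0:1))
  if (any(arms == 0)) {
    abort("one treatment arm is empty after the join")
  }
  if (any(arms < 2)) {
    warn("a treatment arm has fewer than 2 patients; most analyses will be degenerate")
  }

  new_trial_data(joined, feature_meta, config)
}

new_trial_data <- function(data, feature_meta, config) {
  structure(
    as_tibble(data),
    feature_meta = as_tibble(feature_meta),
    config = config,
    class = c("trial_data", class(tibble()))
  )
}

check_clinical <- function(clinical, config) {
  if (!"patient_id" %in% names(clinical)) abort("clinical table needs a patient_id column")
  if (anyDuplicated(clinical$patient_id)) {
    abort(paste0("duplicate patient_id in clinical table: ",
                 clinical$patient_id[duplicated(clinical$patient_id)][1]))
  }
  if (!"treatment" %in% names(clinical)) abort("clinical table needs a treatment column")
  tr <- clinical$treatment
  if (anyNA(tr) || !all(tr %in% c(0, 1))) {
    abort("treatment must be 0 or 1 and never missing")
  }
  present <- character()
  for (ep in config$endpoints) {
    cols <- endpoint_cols(ep)
    if (cols$type == "survival") {
      if (all(c(cols$time, cols$event) %in% names(clinical))) {
        tt <- clinical[[cols$time]]
        evf <- clinical[[cols$event]]
        if (any(tt < 0, na.rm = TRUE)) abort(paste0(cols$time, " must be non-negative"))
        if (!all(evf %in% c(0, 1, NA))) abort(paste0(cols$event, " must be 0/1"))
        if (!anyNA(tt) && !anyNA(evf)) present <- c(present, ep)
      }
    } else if (cols$response %in% names(clinical)) {
      if (!all(clinical[[cols$response]] %in% c(0, 1, NA))) {
        abort("orr must be 0/1 or missing")
      }
      present <- c(present, ep)
    }
  }
  if (length(present) == 0) {
    abort("at least one configured endpoint must be present in the clinical table")
  }
  missing_cols <- setdiff(c(config$covariates, config$subtype_schemes),
                          names(clinical))
  if (length(missing_cols) > 0) {
    abort(paste0("clinical table lacks configured column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  invisible(clinical)
}

check_alterations <- function(alterations, config) {
  if (!"patient_id" %in% names(alterations)) {
    abort("alteration matrix needs a patient_id column")
  }
  if (anyDuplicated(alterations$patient_id)) {
    abort(paste0("duplicate patient_id in alteration matrix: ",
                 alterations$patient_id[duplicated(alterations$patient_id)][1]))
  }
  features <- setdiff(names(alterations), "patient_id")
  if (length(features) == 0) abort("alteration matrix has no feature columns")
  for (f in features) {
    v <- alterations[[f]]
    if (anyNA(v)) {
      if (config$missing_as == "zero") {
        v[is.na(v)] <- 0
        alterations[[f]] <- v
      } else {
        abort(sprintf(
          "missing alteration value at (%s, %s); use missing_as = 'zero' to impute",
          alterations$patient_id[which(is.na(v))[1]], f
        ))
      }
    }
    bad <- which(!v %in% c(0, 1))
    if (length(bad) > 0) {
      abort(sprintf("non-binary alteration value '%s' at (%s, %s)",
                    v[bad[1]], alterations$patient_id[bad[1]], f))
    }
    alterations[[f]] <- as.integer(v)
  }
  alterations
}

infer_feature_meta <- function(features) {
  tibble(
    feature = features,
    gene = stringr::str_remove(features, "_(SV|AMP|DEL)$"),
    class = dplyr::case_when(
      stringr::str_detect(features, "_AMP$") ~ "AMP",
      stringr::str_detect(features, "_DEL$") ~ "DEL",
      features == "MSI" ~ "MSI",
      TRUE ~ "SV"
    )
  )
}

#' Accessors for trial datasets
#'
#' @param x A `trial_data` object.
#' @return `feature_meta()` returns the per-feature metadata tibble,
#'   `feature_names()` the character vector of feature column names, and
#'   `trial_config()` the attached [onco_config()].
#' @export
feature_meta <- function(x) attr(x, "feature_meta")

#' @rdname feature_meta
#' @export
feature_names <- function(x) feature_meta(x)$feature

#' @rdname feature_meta
#' @export
trial_config <- function(x) attr(x, "config")

#' @export
`[.trial_data` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    fm <- attr(x, "feature_meta")
    out <- new_trial_data(out, fm[fm$feature %in% names(out), , drop = FALSE],
                          attr(x, "config"))
  }
  out
}

# row subset preserving attributes (hot path: no validation)
trial_slice <- function(x, idx) {
  out <- vctrs::vec_slice(as_tibble(x), idx)
  new_trial_data(out, attr(x, "feature_meta"), attr(x, "config"))
}

#' @export
print.trial_data <- function(x, ...) {
  fm <- feature_meta(x)
  cat(sprintf("<trial_data> %d patients x %d features (%s)\n",
              nrow(x), nrow(fm),
              paste(sprintf("%s: %d", names(table(fm$class)),
                            as.integer(table(fm$class))), collapse = ", ")))
  cat(sprintf("  arms: %d control / %d experimental\n",
              sum(x$treatment == 0), sum(x$treatment == 1)))
  NextMethod()
}
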