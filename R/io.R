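#' Load a trial from delimited files
#'
#' Reads the clinical table and the binary alteration matrix (TSV or CSV,
#' auto-detected from the file extension), validates both, and joins them on
#' `patient_id`.  Patients present in only one file are dropped with a
#' warning; missing subtype labels are reported per scheme.
#'
#' @param clinical_path,alterations_path Paths to delimited files with a
#'   header row.  The alteration matrix is expected patients-as-rows; set
#'   `transpose = TRUE` for genes-as-rows input.
#' @param config An [onco_config()] object (or raw list; validated).
#' @param transpose Transpose the alteration matrix after reading.
#' @inheritParams trial_data
#' @return A [trial_data] object.
#' @export
load_trial <- function(clinical_path, alterations_path,
                       config = onco_config(), transpose = FALSE,
                       feature_meta = NULL) {
  config <- validate_config(config)
  clinical <- read_delim_auto(clinical_path)
  alterations <- read_delim_auto(alterations_path)
  if (transpose) alterations <- transpose_alterations(alterations)
  trial_data(clinical, alterations, config, feature_meta = feature_meta)
}

read_delim_auto <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  ext <- tolower(tools::file_ext(path))
  delim <- switch(ext, csv = ",", tsv = "\t", txt = "\t",
                  abort(paste0("cannot infer delimiter from extension: ", path)))
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

transpose_alterations <- function(x) {
  first <- names(x)[1]
  feats <- x[[first]]
  ids <- setdiff(names(x), first)
  out <- as_tibble(t(as.matrix(x[, ids])), .name_repair = "minimal")
  names(out) <- feats
  dplyr::bind_cols(tibble(patient_id = ids), out)
}

#' Write a trial dataset to delimited files
#'
#' Emits `clinical.tsv` (clinical columns, covariates, subtype labels) and
#' `alterations.tsv` (patient by feature binary matrix) so that
#' [load_trial()] on the pair reproduces the dataset value-for-value.
#'
#' @param trial A [trial_data] object.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_trial <- function(trial, dir) {
  stopifnot(inherits(trial, "trial_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  feats <- feature_names(trial)
  clin <- as_tibble(trial)[, setdiff(names(trial), feats)]
  alt <- as_tibble(trial)[, c("patient_id", feats)]
  readr::write_tsv(clin, file.path(dir, "clinical.tsv"))
  readr::write_tsv(alt, file.path(dir, "alterations.tsv"))
  invisible(dir)
}
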