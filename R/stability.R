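#' Cross-validation stability of biomarker selection
#'
#' Repeated k-fold cross-validation of the screening and interaction
#' stages: for each of `repeats * folds` training sets (folds stratified
#' by treatment arm), the arm-specific screen and the interaction tests
#' are run with the relaxed cross-validation interaction threshold
#' (`fdr_beta_cv`, default 0.3, accounting for the reduced training-set
#' size) and the `top_k` biomarkers with the smallest interaction p-values
#' are tallied.  The resampling stage is skipped inside the loop; the
#' purpose is selection stability, not effect estimation.
#'
#' @param trial A [trial_data] object.
#' @param folds,repeats Cross-validation geometry (default 5 x 5).
#' @param top_k Number of top-ranked biomarkers tallied per training set
#'   (ranked by interaction p-value).
#' @param seed Seed for the fold assignments.
#' @return A tibble of class `onco_stability`: per
#'   (endpoint, feature, scheme, level) the count `n_selected` of training
#'   sets (out of `n_splits = folds * repeats`) in which it ranked among
#'   the top `top_k`, plus the selection frequency.
#' @export
stability_cv <- function(trial, folds = 5, repeats = 5, top_k = 10,
                         seed = NULL) {
  if (folds < 2) abort("folds must be >= 2")
  cfg <- trial_config(trial)
  seed <- seed %||% cfg$seed
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(trial)
  tally <- list()
  n_refolds <- 0L

  for (r in seq_len(repeats)) {
    assignment <- make_folds(trial$treatment, folds)
    for (k in seq_len(folds)) {
      train_idx <- which(assignment != k)
      tr <- trial_slice(trial, train_idx)
      attempt <- 0L
      while (length(unique(tr$treatment)) < 2 && attempt < 10L) {
        # degenerate arm in this fold: redraw the assignment
        n_refolds <- n_refolds + 1L
        attempt <- attempt + 1L
        assignment <- make_folds(trial$treatment, folds)
        tr <- trial_slice(trial, which(assignment != k))
      }
      scr <- suppressWarnings(screen_arms(tr))
      inter <- suppressWarnings(
        test_interaction(tr, screen = scr, fdr_beta = cfg$fdr_beta_cv)
      )
      inter <- inter[which(inter$converged), , drop = FALSE]
      if (nrow(inter) == 0) next
      top <- head(arrange(inter, .data$p_int), top_k)
      tally[[length(tally) + 1]] <-
        top[, c("endpoint", "feature", "scheme", "level")]
    }
  }

  out <- dplyr::bind_rows(c(list(tibble(
    endpoint = character(), feature = character(),
    scheme = character(), level = character()
  )), tally))
  out <- out |>
    dplyr::count(.data$endpoint, .data$feature, .data$scheme, .data$level,
                 name = "n_selected") |>
    mutate(n_splits = folds * repeats,
           frequency = .data$n_selected / .data$n_splits) |>
    arrange(desc(.data$n_selected), .data$feature)
  attr(out, "n_refolds") <- n_refolds
  class(out) <- c("onco_stability", class(tibble()))
  out
}

# arm-stratified fold labels
make_folds <- function(treatment, folds) {
  assignment <- integer(length(treatment))
  for (arm in unique(treatment)) {
    idx <- which(treatment == arm)
    assignment[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  assignment
}
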