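#' Tidy pipeline results
#'
#' Broom-style accessors.  `tidy()` returns one row per estimate with the
#' conventional `estimate` / `std.error` / `p.value` column names;
#' `glance()` returns a one-row summary of a result table or report.
#'
#' @param x A result object (`onco_screen`, `onco_interaction`,
#'   `onco_subgroups`, `onco_enrichment` or `onco_report`).
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.onco_screen <- function(x, ...) {
  as_tibble(x) |>
    mutate(term = paste0(.data$feature, " (arm ", .data$arm, ")")) |>
    select("term", "endpoint", "scheme", "level",
           estimate = "alpha1", std.error = "se", p.value = "p",
           adj.p.value = "q", "effect", conf.low = "ci_low",
           conf.high = "ci_high", "n_mut", "n_wt", "significant",
           "converged")
}

#' @rdname tidiers
#' @export
tidy.onco_interaction <- function(x, ...) {
  as_tibble(x) |>
    select(term = "feature", "endpoint", "scheme", "level",
           estimate = "beta2", std.error = "se2", p.value = "p_int",
           adj.p.value = "q_int", prognostic = "beta1", "predictive",
           "converged")
}

#' @rdname tidiers
#' @export
tidy.onco_subgroups <- function(x, ...) {
  out <- as_tibble(x) |>
    mutate(term = paste0(.data$feature, " ", .data$status)) |>
    select("term", "endpoint", "scheme", "level", estimate = "gamma1",
           std.error = "se", p.value = "p_gamma", "effect",
           conf.low = "ci_low", conf.high = "ci_high", "n0", "n1",
           "selected",
           dplyr::any_of(c("p_adj", "gamma_corrected", "effect_corrected",
                           "ci_boot_low", "ci_boot_high")))
  out
}

#' @rdname tidiers
#' @export
tidy.onco_enrichment <- function(x, ...) {
  as_tibble(x) |>
    select(term = "feature", "scheme", "level", "direction",
           overlap = "k", feature.count = "K", level.size = "n_s",
           cohort.size = "N", p.value = "p", adj.p.value = "q",
           "significant")
}

#' @rdname tidiers
#' @export
glance.onco_report <- function(x, ...) {
  tibble(
    n_patients = x$n_patients,
    n_features = nrow(x$feature_meta),
    n_modules = nrow(x$modules),
    n_enrichment_significant = sum(x$enrichment$significant, na.rm = TRUE),
    n_screen_tests = nrow(x$screening),
    n_screen_significant = sum(x$screening$significant, na.rm = TRUE),
    n_interaction_tests = nrow(x$interactions),
    n_predictive = sum(x$interactions$predictive, na.rm = TRUE),
    n_subgroups = sum(x$subgroups$selected, na.rm = TRUE),
    seed = x$seed %||% NA_integer_,
    version = x$version
  )
}

#' @rdname tidiers
#' @export
glance.onco_screen <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    n_nonconverged = sum(!x$converged, na.rm = TRUE),
    n_skipped = nrow(attr(x, "audit") %||% audit_empty())
  )
}

#' @rdname tidiers
#' @export
glance.onco_interaction <- function(x, ...) {
  tibble(
    n_tests = nrow(x),
    n_predictive = sum(x$predictive, na.rm = TRUE),
    n_nonconverged = sum(!x$converged, na.rm = TRUE),
    n_skipped = nrow(attr(x, "audit") %||% audit_empty())
  )
}

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot
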