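#' Plot methods
#'
#' Convenience ggplot2 views of the pipeline's result tables; every plot
#' is built from the same plot-ready coordinates the TSV outputs carry.
#'
#' @param object A result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name onco-plots
NULL

#' @rdname onco-plots
#' @export
autoplot.onco_enrichment <- function(object, ...) {
  df <- as_tibble(object)
  df$signed <- ifelse(df$direction == "enriched", -log10(df$p),
                      log10(df$p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level, y = .data$feature)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$k, colour = .data$signed,
                                     shape = .data$significant)) +
    ggplot2::scale_colour_gradient2(
      low = "#2166ac", mid = "grey85", high = "#b2182b", midpoint = 0,
      name = "signed -log10 p"
    ) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::facet_grid(. ~ scheme, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "subtype level", y = NULL, size = "overlap") +
    ggplot2::theme_minimal()
}

#' @rdname onco-plots
#' @export
autoplot.onco_screen <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$converged, , drop = FALSE]
  df$label <- paste0(df$feature, " | ", df$level)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$effect, y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_grid(endpoint ~ arm, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "hazard / odds ratio (mutant vs wild-type)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname onco-plots
#' @export
autoplot.onco_subgroups <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- paste0(df$feature, " ", df$status, " | ", df$level)
  has_corrected <- "gamma_corrected" %in% names(df) &&
    any(!is.na(df$gamma_corrected))
  p <- ggplot2::ggplot(df, ggplot2::aes(y = .data$label)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2, colour = "grey40"
    ) +
    ggplot2::geom_point(ggplot2::aes(x = .data$effect,
                                     shape = .data$selected), size = 2)
  if (has_corrected) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(x = .data$effect_corrected), colour = "#b2182b",
      size = 2, na.rm = TRUE
    )
  }
  p +
    ggplot2::scale_x_log10() +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 1, `TRUE` = 16)) +
    ggplot2::facet_grid(endpoint ~ ., scales = "free_y", space = "free_y") +
    ggplot2::labs(
      x = "treatment effect (experimental vs control)", y = NULL,
      caption = if (has_corrected) "red: bootstrap bias-corrected" else NULL
    ) +
    ggplot2::theme_minimal()
}

#' Oncoprint-style alteration landscape
#'
#' Patients-by-features tile view of the binary alteration matrix, with
#' patients ordered by a memo-sort style cascade (most frequent feature
#' first) and features by frequency.
#'
#' @param trial A [trial_data] object.
#' @param features Optional subset of feature columns to show.
#' @return A ggplot object.
#' @export
plot_oncoprint <- function(trial, features = NULL) {
  fm <- feature_meta(trial)
  features <- features %||% fm$feature
  mat <- as.matrix(as_tibble(trial)[, features, drop = FALSE])
  ord_f <- order(colSums(mat), decreasing = TRUE)
  mat <- mat[, ord_f, drop = FALSE]
  ord_p <- do.call(order, c(lapply(seq_len(ncol(mat)),
                                   function(j) -mat[, j]))) # memo-sort
  df <- tidyr::expand_grid(
    patient = seq_len(nrow(mat)), feature = colnames(mat)
  )
  df$altered <- as.vector(t(mat[ord_p, , drop = FALSE])) == 1
  df <- dplyr::left_join(df, fm[, c("feature", "class")], by = "feature")
  df$feature <- factor(df$feature, levels = rev(colnames(mat)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$patient, y = .data$feature)) +
    ggplot2::geom_tile(ggplot2::aes(
      fill = ifelse(.data$altered, .data$class, NA_character_)
    )) +
    ggplot2::scale_fill_brewer(palette = "Set1", na.value = "grey93",
                               name = "alteration") +
    ggplot2::labs(x = "patients", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Kaplan-Meier plot of a reported subgroup
#'
#' @param km A tibble from [km_curves()].
#' @param group_id Which subgroup to draw (default: the first).
#' @return A ggplot object.
#' @export
plot_km <- function(km, group_id = NULL) {
  group_id <- group_id %||% km$group_id[1]
  df <- km[km$group_id == group_id, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = factor(.data$arm))) +
    ggplot2::geom_step() +
    ggplot2::geom_step(ggplot2::aes(y = .data$lower), linetype = 3,
                       na.rm = TRUE) +
    ggplot2::geom_step(ggplot2::aes(y = .data$upper), linetype = 3,
                       na.rm = TRUE) +
    ggplot2::scale_colour_manual(values = c(`0` = "#2166ac",
                                            `1` = "#b2182b"),
                                 name = "arm") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = group_id, x = "months", y = "survival") +
    ggplot2::theme_minimal()
}
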