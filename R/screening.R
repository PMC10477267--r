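#' Fit one treatment-arm-specific biomarker model
#'
#' Restricts the trial to one treatment arm (and optionally one subtype
#' level) and fits the arm-specific model: a Cox proportional-hazards fit
#' (Efron ties, no intercept -- the baseline hazard absorbs it) for
#' survival endpoints, or a logistic fit for the binary response, with the
#' biomarker indicator plus the configured covariates as predictors.  The
#' reported effect is the hazard or odds ratio `exp(alpha1)` of mutant
#' versus wild-type tumours, with a two-sided Wald p-value and 95% CI.
#'
#' @param trial A [trial_data] object.
#' @param endpoint One of `"OS"`, `"PFS"`, `"ORR"`.
#' @param arm Treatment arm, 0 (control) or 1 (experimental).
#' @param feature Feature column name.
#' @param scheme,level Subtype scheme column and level restricting the
#'   analysis; both `NULL` for the unstratified fit.
#' @return A one-row tibble with the coefficient `alpha1`, its standard
#'   error, `effect = exp(alpha1)`, Wald CI and p-value, group sizes and a
#'   convergence flag -- or a zero-row tibble with the skip reason recorded
#'   in the `audit` attribute when the outcome is degenerate.
#' @export
fit_arm_model <- function(trial, endpoint, arm, feature,
                          scheme = NULL, level = NULL) {
  cfg <- trial_config(trial)
  scheme <- scheme %||% "none"
  level <- level %||% "ALL"
  mask <- stratum_mask(trial, scheme, level) &
    trial$treatment == arm & endpoint_rows(trial, endpoint)
  res <- .fit_arm(as_tibble(trial)[mask, , drop = FALSE], cfg, endpoint,
                  arm, feature, scheme, level)
  screen_result_tibble(res)
}

# core single fit; data already restricted to arm/stratum/endpoint rows
.fit_arm <- function(data, cfg, endpoint, arm, feature, scheme, level) {
  cols <- endpoint_cols(endpoint)
  x <- data[[feature]]
  base <- list(endpoint = endpoint, arm = arm, feature = feature,
               scheme = scheme, level = level,
               n = nrow(data), n_mut = sum(x == 1), n_wt = sum(x == 0))
  X <- cbind(matrix(as.numeric(x), ncol = 1,
                    dimnames = list(NULL, feature)),
             covariate_matrix(data, cfg$covariates))
  fit <- if (cols$type == "survival") {
    fit_core("survival", X, time = data[[cols$time]],
             event = data[[cols$event]])
  } else {
    fit_core("binary", X, y = data[[cols$response]])
  }
  c(base, list(fit = fit))
}

screen_result_tibble <- function(res, audit_extra = NULL) {
  fit <- res$fit
  if (!fit$ok) {
    out <- screen_empty()
    attr(out, "audit") <- tibble(
      endpoint = res$endpoint, arm = res$arm, feature = res$feature,
      scheme = res$scheme, level = res$level, reason = fit$reason
    )
    return(out)
  }
  est <- fit$coef[[fit$focal]]
  se <- fit$se[[fit$focal]]
  w <- wald_summary(est, se)
  tibble(
    endpoint = res$endpoint, arm = res$arm, feature = res$feature,
    scheme = res$scheme, level = res$level,
    n = res$n, n_mut = res$n_mut, n_wt = res$n_wt,
    n_events = fit$n_events,
    alpha0 = fit$intercept, alpha1 = est, se = se,
    effect = exp(est), ci_low = w$ci_low, ci_high = w$ci_high,
    p = w$p, q = NA_real_, significant = NA,
    converged = fit$converged,
    family_id = paste(res$endpoint, "arm", res$arm, res$scheme, sep = ":")
  )
}

screen_empty <- function() {
  tibble(
    endpoint = character(), arm = integer(), feature = character(),
    scheme = character(), level = character(), n = integer(),
    n_mut = integer(), n_wt = integer(), n_events = integer(),
    alpha0 = double(), alpha1 = double(), se = double(), effect = double(),
    ci_low = double(), ci_high = double(), p = double(), q = double(),
    significant = logical(), converged = logical(), family_id = character()
  )
}

audit_empty <- function() {
  tibble(endpoint = character(), arm = integer(), feature = character(),
         scheme = character(), level = character(), reason = character())
}

# module columns must redistribute >= n_min patients relative to every
# single member within the analysed stratum
module_redistribution_ok <- function(data, fm, feature, n_min) {
  row <- fm[fm$feature == feature, ]
  if (!row$class %in% c("MODULE", "CUSTOM")) return(TRUE)
  members <- strsplit(row$gene, ";", fixed = TRUE)[[1]]
  members <- intersect(members, names(data))
  if (length(members) == 0) return(TRUE)
  union_n <- sum(data[[feature]])
  all(union_n - vapply(members, function(m) sum(data[[m]]),
                       numeric(1)) >= n_min)
}

#' Screen all treatment-arm-specific biomarkers
#'
#' Enumerates every combination of endpoint, treatment arm, feature and
#' stratum (unstratified plus every subtype level), fits the eligible ones
#' with [fit_arm_model()]'s model, and applies Benjamini-Hochberg
#' adjustment within each (endpoint, arm, scheme) family; results with
#' `q < fdr_alpha` are flagged significant.  A combination is eligible when
#' (i) the analysed stratum-arm holds at least `n_min` mutant and `n_min`
#' wild-type patients, and (ii) a module column additionally redistributes
#' at least `n_min` patients relative to each of its members within the
#' stratum.  Skipped combinations are recorded with their reason in the
#' `audit` attribute.
#'
#' @param trial A [trial_data] object (typically after
#'   [build_feature_set()]).
#' @param fdr_alpha,n_min Overrides of the attached configuration.
#' @param endpoints Endpoints to screen (default: configured endpoints).
#' @return A tibble of class `onco_screen` (one row per fitted model) with
#'   attribute `audit` (one row per skipped combination and reason).
#' @export
screen_arms <- function(trial, fdr_alpha = NULL, n_min = NULL,
                        endpoints = NULL) {
  cfg <- trial_config(trial)
  fdr_alpha <- fdr_alpha %||% cfg$fdr_alpha
  n_min <- n_min %||% cfg$n_min
  endpoints <- endpoints %||% cfg$endpoints
  fm <- feature_meta(trial)
  feats <- fm$feature
  strata <- stratum_table(trial)
  data <- as_tibble(trial)

  rows <- list(); n_rows <- 0L
  audits <- list(); n_audits <- 0L
  push_audit <- function(ep, arm, f, sc, lv, reason) {
    n_audits <<- n_audits + 1L
    audits[[n_audits]] <<- c(ep, as.character(arm), f, sc, lv, reason)
  }

  for (si in seq_len(nrow(strata))) {
    sc <- strata$scheme[si]; lv <- strata$level[si]
    smask <- stratum_mask(data, sc, lv)
    sdata <- data[smask, , drop = FALSE]
    redis_ok <- vapply(feats, function(f) {
      module_redistribution_ok(sdata, fm, f, n_min)
    }, logical(1))
    for (ep in endpoints) {
      emask <- endpoint_rows(sdata, ep)
      for (arm in 0:1) {
        adata <- sdata[emask & sdata$treatment == arm, , drop = FALSE]
        for (fi in seq_along(feats)) {
          f <- feats[fi]
          n_mut <- sum(adata[[f]] == 1)
          n_wt <- nrow(adata) - n_mut
          if (n_mut < n_min) {
            push_audit(ep, arm, f, sc, lv, "n_mut < n_min"); next
          }
          if (n_wt < n_min) {
            push_audit(ep, arm, f, sc, lv, "n_wt < n_min"); next
          }
          if (!redis_ok[fi]) {
            push_audit(ep, arm, f, sc, lv, "module_redistribution"); next
          }
          res <- .fit_arm(adata, cfg, ep, arm, f, sc, lv)
          if (!res$fit$ok) {
            push_audit(ep, arm, f, sc, lv, res$fit$reason); next
          }
          n_rows <- n_rows + 1L
          rows[[n_rows]] <- res
        }
      }
    }
  }

  out <- screen_rows_tibble(rows)
  if (nrow(out) > 0) {
    n_nc <- sum(!out$converged)
    if (n_nc > 0) {
      warn(sprintf("%d non-converged fit(s) excluded from BH adjustment", n_nc))
    }
    out <- out |>
      group_by(.data$family_id) |>
      mutate(
        q = replace(.data$q, .data$converged,
                    p.adjust(.data$p[.data$converged], method = "BH")),
        significant = .data$converged & !is.na(.data$q) & .data$q < fdr_alpha
      ) |>
      ungroup() |>
      arrange(.data$endpoint, .data$arm, .data$scheme, .data$level, .data$p)
  }
  attr(out, "audit") <- audit_rows_tibble(audits)
  class(out) <- c("onco_screen", class(tibble()))
  out
}

# vectorised constructors for the hot enumeration paths (a tibble() call
# per fitted model dominates runtime otherwise)
audit_rows_tibble <- function(audits) {
  if (length(audits) == 0) return(audit_empty())
  m <- do.call(rbind, audits)
  tibble(endpoint = m[, 1], arm = suppressWarnings(as.integer(m[, 2])),
         feature = m[, 3], scheme = m[, 4], level = m[, 5],
         reason = m[, 6])
}

screen_rows_tibble <- function(rows) {
  if (length(rows) == 0) return(screen_empty())
  chr <- function(fld) vapply(rows, function(r) as.character(r[[fld]]), character(1))
  int <- function(fld) vapply(rows, function(r) as.integer(r[[fld]]), integer(1))
  est <- vapply(rows, function(r) r$fit$coef[[r$fit$focal]], numeric(1))
  se <- vapply(rows, function(r) r$fit$se[[r$fit$focal]], numeric(1))
  w <- wald_summary(est, se)
  endpoint <- chr("endpoint"); arm <- int("arm"); scheme <- chr("scheme")
  tibble(
    endpoint = endpoint, arm = arm, feature = chr("feature"),
    scheme = scheme, level = chr("level"),
    n = int("n"), n_mut = int("n_mut"), n_wt = int("n_wt"),
    n_events = vapply(rows, function(r) as.integer(r$fit$n_events), integer(1)),
    alpha0 = vapply(rows, function(r) r$fit$intercept, numeric(1)),
    alpha1 = est, se = se, effect = exp(est),
    ci_low = w$ci_low, ci_high = w$ci_high, p = w$p,
    q = NA_real_, significant = NA,
    converged = vapply(rows, function(r) r$fit$converged, logical(1)),
    family_id = paste(endpoint, "arm", arm, scheme, sep = ":")
  )
}
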