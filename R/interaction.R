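#' Cross-arm predictive (interaction) tests
#'
#' For every endpoint, feature and stratum (unstratified plus every subtype
#' level) with both arms represented, fits the interaction model whose
#' linear predictor carries the biomarker term `beta1 * x` (prognostic
#' component) and the biomarker-by-treatment term `beta2 * x * t`
#' (predictive component) plus configured covariates; by design there is no
#' treatment main-effect term (set `include_treatment_main = TRUE` in the
#' configuration for a sensitivity variant).  The Wald p-value of `beta2`
#' is Benjamini-Hochberg-adjusted within each (endpoint, scheme) family.
#' A biomarker is flagged `predictive` when `q_int < fdr_beta` and its
#' arm-specific screening call was significant (`q < fdr_alpha`) in at
#' least one arm for the same endpoint, feature and stratum.
#'
#' Eligibility requires at least `n_min` mutant and `n_min` wild-type
#' patients in each treatment arm of the stratum; module columns must also
#' pass the redistribution filter.  Skipped combinations are recorded in
#' the `audit` attribute.
#'
#' @param trial A [trial_data] object.
#' @param screen An `onco_screen` tibble from [screen_arms()]; required for
#'   the predictive flag (pass `NULL` to skip the screening condition).
#' @param fdr_beta,fdr_alpha,n_min Overrides of the attached configuration.
#' @param endpoints Endpoints to test (default: configured endpoints).
#' @return A tibble of class `onco_interaction`, one row per fitted
#'   interaction with `beta1`, `beta2`, `p_int`, `q_int` and the
#'   `predictive` flag.
#' @export
test_interaction <- function(trial, screen = NULL, fdr_beta = NULL,
                             fdr_alpha = NULL, n_min = NULL,
                             endpoints = NULL) {
  cfg <- trial_config(trial)
  fdr_beta <- fdr_beta %||% cfg$fdr_beta
  fdr_alpha <- fdr_alpha %||% cfg$fdr_alpha
  n_min <- n_min %||% cfg$n_min
  endpoints <- endpoints %||% cfg$endpoints
  fm <- feature_meta(trial)
  feats <- fm$feature
  strata <- stratum_table(trial)
  data <- as_tibble(trial)

  rows <- list(); n_rows <- 0L
  audits <- list(); n_audits <- 0L
  push_audit <- function(ep, f, sc, lv, reason) {
    n_audits <<- n_audits + 1L
    audits[[n_audits]] <<- c(ep, NA_character_, f, sc, lv, reason)
  }

  for (si in seq_len(nrow(strata))) {
    sc <- strata$scheme[si]; lv <- strata$level[si]
    sdata <- data[stratum_mask(data, sc, lv), , drop = FALSE]
    redis_ok <- vapply(feats, function(f) {
      module_redistribution_ok(sdata, fm, f, n_min)
    }, logical(1))
    for (ep in endpoints) {
      edata <- sdata[endpoint_rows(sdata, ep), , drop = FALSE]
      tt <- edata$treatment
      for (fi in seq_along(feats)) {
        f <- feats[fi]
        x <- edata[[f]]
        cells <- c(sum(x == 1 & tt == 0), sum(x == 0 & tt == 0),
                   sum(x == 1 & tt == 1), sum(x == 0 & tt == 1))
        if (any(cells < n_min)) {
          push_audit(ep, f, sc, lv, "group below n_min in an arm"); next
        }
        if (!redis_ok[fi]) {
          push_audit(ep, f, sc, lv, "module_redistribution"); next
        }
        res <- .fit_interaction(edata, cfg, ep, f, sc, lv)
        if (!res$fit$ok) {
          push_audit(ep, f, sc, lv, res$fit$reason); next
        }
        n_rows <- n_rows + 1L
        rows[[n_rows]] <- res
      }
    }
  }

  out <- interaction_rows_tibble(rows)
  if (nrow(out) > 0) {
    out <- out |>
      group_by(.data$family_id) |>
      mutate(
        q_int = replace(.data$q_int, .data$converged,
                        p.adjust(.data$p_int[.data$converged], method = "BH"))
      ) |>
      ungroup()
    screened <- screen_significant_keys(screen, fdr_alpha)
    key <- paste(out$endpoint, out$feature, out$scheme, out$level, sep = "\r")
    out$predictive <- out$converged & !is.na(out$q_int) &
      out$q_int < fdr_beta &
      (if (is.null(screened)) TRUE else key %in% screened)
    out <- arrange(out, .data$endpoint, .data$scheme, .data$level,
                   .data$p_int)
  }
  attr(out, "audit") <- audit_rows_tibble(audits)
  class(out) <- c("onco_interaction", class(tibble()))
  out
}

screen_significant_keys <- function(screen, fdr_alpha) {
  if (is.null(screen)) return(NULL)
  hit <- screen[!is.na(screen$q) & screen$q < fdr_alpha, , drop = FALSE]
  unique(paste(hit$endpoint, hit$feature, hit$scheme, hit$level,
               sep = "\r"))
}

.fit_interaction <- function(data, cfg, endpoint, feature, scheme, level) {
  cols <- endpoint_cols(endpoint)
  x <- as.numeric(data[[feature]])
  t <- as.numeric(data$treatment)
  X <- cbind(
    matrix(x * t, ncol = 1, dimnames = list(NULL, "x:t")),
    matrix(x, ncol = 1, dimnames = list(NULL, "x")),
    if (cfg$include_treatment_main) {
      matrix(t, ncol = 1, dimnames = list(NULL, "t"))
    },
    covariate_matrix(data, cfg$covariates)
  )
  fit <- if (cols$type == "survival") {
    fit_core("survival", X, time = data[[cols$time]],
             event = data[[cols$event]])
  } else {
    fit_core("binary", X, y = data[[cols$response]])
  }
  list(endpoint = endpoint, feature = feature, scheme = scheme,
       level = level, n = nrow(data), n_mut = sum(x == 1),
       n_wt = sum(x == 0), fit = fit)
}

interaction_rows_tibble <- function(rows) {
  if (length(rows) == 0) return(interaction_empty())
  chr <- function(fld) vapply(rows, function(r) as.character(r[[fld]]), character(1))
  int <- function(fld) vapply(rows, function(r) as.integer(r[[fld]]), integer(1))
  beta2 <- vapply(rows, function(r) r$fit$coef[["x:t"]], numeric(1))
  se2 <- vapply(rows, function(r) r$fit$se[["x:t"]], numeric(1))
  w <- wald_summary(beta2, se2)
  endpoint <- chr("endpoint"); scheme <- chr("scheme")
  tibble(
    endpoint = endpoint, feature = chr("feature"), scheme = scheme,
    level = chr("level"), n = int("n"), n_mut = int("n_mut"),
    n_wt = int("n_wt"),
    beta0 = vapply(rows, function(r) r$fit$intercept, numeric(1)),
    beta1 = vapply(rows, function(r) {
      if ("x" %in% names(r$fit$coef)) r$fit$coef[["x"]] else NA_real_
    }, numeric(1)),
    beta2 = beta2, se2 = se2, p_int = w$p, q_int = NA_real_,
    predictive = NA,
    converged = vapply(rows, function(r) r$fit$converged, logical(1)),
    family_id = paste(endpoint, scheme, sep = ":")
  )
}

interaction_empty <- function() {
  tibble(
    endpoint = character(), feature = character(), scheme = character(),
    level = character(), n = integer(), n_mut = integer(), n_wt = integer(),
    beta0 = double(), beta1 = double(), beta2 = double(), se2 = double(),
    p_int = double(), q_int = double(), predictive = logical(),
    converged = logical(), family_id = character()
  )
}

#' Estimate the treatment effect within one subgroup
#'
#' Fits the conditional-average-treatment-effect model
#' `gamma0 + gamma1 * t + covariates` within the population defined by a
#' subtype level and a biomarker status; `gamma1` is the log hazard (or
#' odds) ratio of the experimental versus the control arm in that
#' subgroup.
#'
#' @param trial A [trial_data] object.
#' @param feature Feature column name.
#' @param status `"mutant"` (feature = 1) or `"wildtype"` (feature = 0).
#' @param endpoint One of `"OS"`, `"PFS"`, `"ORR"`.
#' @param scheme,level Subtype restriction; `NULL` for unstratified.
#' @return A one-row tibble with `gamma1`, its Wald CI/p-value and the
#'   per-arm subgroup sizes.
#' @export
estimate_cate <- function(trial, feature, status = c("mutant", "wildtype"),
                          endpoint = "OS", scheme = NULL, level = NULL) {
  status <- match.arg(status)
  scheme <- scheme %||% "none"
  level <- level %||% "ALL"
  res <- .fit_cate(as_tibble(trial), trial_config(trial), endpoint, feature,
                   scheme, level, status)
  if (!res$fit$ok) {
    abort(sprintf(
      "degenerate outcome in subgroup (%s, %s, %s, %s, %s): %s",
      endpoint, feature, scheme, level, status, res$fit$reason
    ))
  }
  cate_result_tibble(res)
}

.fit_cate <- function(data, cfg, endpoint, feature, scheme, level, status) {
  cols <- endpoint_cols(endpoint)
  want <- if (status == "mutant") 1 else 0
  mask <- stratum_mask(data, scheme, level) & data[[feature]] == want &
    endpoint_rows(data, endpoint)
  sub <- data[mask, , drop = FALSE]
  t <- as.numeric(sub$treatment)
  base <- list(endpoint = endpoint, feature = feature, scheme = scheme,
               level = level, status = status, n = nrow(sub),
               n0 = sum(t == 0), n1 = sum(t == 1))
  if (base$n0 == 0 || base$n1 == 0) {
    return(c(base, list(fit = fit_failure("missing_arm"))))
  }
  X <- cbind(matrix(t, ncol = 1, dimnames = list(NULL, "t")),
             covariate_matrix(sub, cfg$covariates))
  fit <- if (cols$type == "survival") {
    fit_core("survival", X, time = sub[[cols$time]],
             event = sub[[cols$event]])
  } else {
    fit_core("binary", X, y = sub[[cols$response]])
  }
  c(base, list(fit = fit))
}

cate_result_tibble <- function(res) {
  fit <- res$fit
  est <- fit$coef[["t"]]
  se <- fit$se[["t"]]
  w <- wald_summary(est, se)
  tibble(
    endpoint = res$endpoint, feature = res$feature, scheme = res$scheme,
    level = res$level, status = res$status,
    n = res$n, n0 = res$n0, n1 = res$n1,
    gamma0 = fit$intercept, gamma1 = est, se = se,
    effect = exp(est), ci_low = w$ci_low, ci_high = w$ci_high,
    p_gamma = w$p, converged = fit$converged
  )
}

subgroup_empty <- function() {
  tibble(
    endpoint = character(), feature = character(), scheme = character(),
    level = character(), status = character(), n = integer(),
    n0 = integer(), n1 = integer(), gamma0 = double(), gamma1 = double(),
    se = double(), effect = double(), ci_low = double(), ci_high = double(),
    p_gamma = double(), converged = logical(), selected = logical(),
    group_id = character()
  )
}

#' Select the reported subgroup for each predictive biomarker
#'
#' For every interaction result flagged `predictive`, estimates the
#' treatment effect ([estimate_cate()]) in both the mutant and the
#' wild-type population of the stratum and selects the one with the larger
#' absolute `gamma1` (ties select the mutant population; if one population
#' is degenerate the other is selected with a warning).  The companion
#' population is retained with `selected = FALSE` so both subpopulations
#' can be reported side by side.
#'
#' @param trial A [trial_data] object.
#' @param interactions An `onco_interaction` tibble.
#' @return A tibble of class `onco_subgroups`; selected rows carry the
#'   subgroup whose effect the resampling stage adjusts.
#' @export
select_subgroups <- function(trial, interactions) {
  cfg <- trial_config(trial)
  data <- as_tibble(trial)
  cand <- interactions[which(interactions$predictive), , drop = FALSE]
  out <- subgroup_empty()
  if (nrow(cand) == 0) {
    class(out) <- c("onco_subgroups", class(tibble()))
    return(out)
  }
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    gid <- paste(cand$endpoint[i], cand$feature[i], cand$scheme[i],
                 cand$level[i], sep = ":")
    fits <- lapply(c("mutant", "wildtype"), function(st) {
      res <- .fit_cate(data, cfg, cand$endpoint[i], cand$feature[i],
                       cand$scheme[i], cand$level[i], st)
      if (!res$fit$ok || !res$fit$converged) return(NULL)
      cate_result_tibble(res)
    })
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) {
      warn(sprintf("both subpopulations degenerate for %s; skipped", gid))
      next
    }
    if (!all(ok)) {
      warn(sprintf("one subpopulation degenerate for %s; the other selected",
                   gid))
      sel <- which(ok)
    } else {
      g <- vapply(fits, function(f) abs(f$gamma1), numeric(1))
      sel <- if (g[1] >= g[2]) 1L else 2L # tie selects the mutant population
    }
    pair <- dplyr::bind_rows(fits[ok])
    pair$selected <- seq_len(nrow(pair)) ==
      match(c("mutant", "wildtype")[sel], pair$status)
    pair$group_id <- gid
    rows[[length(rows) + 1]] <- pair
  }
  if (length(rows) > 0) out <- dplyr::bind_rows(rows)
  class(out) <- c("onco_subgroups", class(tibble()))
  out
}
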