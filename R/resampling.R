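#' Define the subgroup search procedure
#'
#' A search procedure is the deterministic mapping from a trial dataset to
#' the list of selected subgroups with their treatment-effect p-values.  It
#' is the unit the resampling stage replays on permuted and bootstrapped
#' data so that the multiplicity adjustment accounts for the entire search
#' strategy.
#'
#' Two modes are available:
#' * `"fdr"` (default) -- the full gated pipeline: arm-specific screening,
#'   interaction tests, the predictive criterion
#'   (`q_int < fdr_beta` and screening `q < fdr_alpha` in at least one
#'   arm), then subgroup selection by larger absolute `gamma1`.
#' * `"best"` -- no significance gates: for every candidate
#'   (endpoint, feature, stratum) combination (or the explicit `candidates`
#'   table) the better of the mutant/wild-type subgroups is estimated and
#'   the single best subgroup (smallest `p_gamma`) is returned.  This is
#'   the forced-selection variant used for calibration studies.
#'
#' @param mode `"fdr"` or `"best"`.
#' @param endpoints Endpoints searched (default: the trial configuration's
#'   endpoints at run time).
#' @param candidates Optional tibble with columns `endpoint`, `feature`,
#'   `scheme`, `level` restricting the `"best"`-mode candidate set.
#' @return An object of class `subgroup_search`.
#' @seealso [run_search()], [permutation_adjust()],
#'   [bootstrap_bias_correct()]
#' @export
subgroup_search <- function(mode = c("fdr", "best"), endpoints = NULL,
                            candidates = NULL) {
  structure(
    list(mode = match.arg(mode), endpoints = endpoints,
         candidates = candidates),
    class = "subgroup_search"
  )
}

#' Run a subgroup search
#'
#' @param trial A [trial_data] object.
#' @param search A [subgroup_search()] object, or a function
#'   `trial -> tibble` with at least a `p_gamma` column (useful for
#'   testing).
#' @return An `onco_subgroups` tibble of selected subgroups (zero rows when
#'   nothing is selected -- an empty result is a valid result).
#' @export
run_search <- function(trial, search = subgroup_search()) {
  if (is.function(search)) return(search(trial))
  stopifnot(inherits(search, "subgroup_search"))
  cfg <- trial_config(trial)
  endpoints <- search$endpoints %||% cfg$endpoints
  if (search$mode == "fdr") {
    scr <- suppressWarnings(screen_arms(trial, endpoints = endpoints))
    if (!any(scr$significant, na.rm = TRUE)) return(subgroup_empty_cls())
    inter <- suppressWarnings(
      test_interaction(trial, screen = scr, endpoints = endpoints)
    )
    if (!any(inter$predictive, na.rm = TRUE)) return(subgroup_empty_cls())
    sel <- suppressWarnings(select_subgroups(trial, inter))
    out <- sel[which(sel$selected), , drop = FALSE]
    return(out)
  }
  # best mode: forced selection of the best subgroup over the candidates
  cand <- search$candidates %||% eligible_candidates(trial, endpoints)
  data <- as_tibble(trial)
  best <- NULL
  best_p <- Inf
  for (i in seq_len(nrow(cand))) {
    pair <- best_of_pair(data, cfg, cand$endpoint[i], cand$feature[i],
                         cand$scheme[i], cand$level[i])
    if (is.null(pair)) next
    p <- 2 * pnorm(-abs(pair$fit$coef[["t"]] / pair$fit$se[["t"]]))
    if (p < best_p) { best <- pair; best_p <- p }
  }
  if (is.null(best)) return(subgroup_empty_cls())
  out <- cate_result_tibble(best)
  out$selected <- TRUE
  out$group_id <- paste(out$endpoint, out$feature, out$scheme,
                        out$level, sep = ":")
  class(out) <- c("onco_subgroups", class(tibble()))
  out
}

subgroup_empty_cls <- function() {
  out <- subgroup_empty()
  class(out) <- c("onco_subgroups", class(tibble()))
  out
}

# mutant/wildtype pair -> selected fit (larger |gamma1|, tie -> mutant);
# NULL when both are degenerate
best_of_pair <- function(data, cfg, endpoint, feature, scheme, level) {
  fits <- lapply(c("mutant", "wildtype"), function(st) {
    res <- suppressWarnings(
      .fit_cate(data, cfg, endpoint, feature, scheme, level, st)
    )
    if (!res$fit$ok || !res$fit$converged) return(NULL)
    res
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) return(NULL)
  if (all(ok)) {
    g <- vapply(fits, function(r) abs(r$fit$coef[["t"]]), numeric(1))
    sel <- if (g[1] >= g[2]) 1L else 2L
  } else {
    sel <- which(ok)
  }
  fits[[sel]]
}

# all (endpoint, feature, stratum) combinations meeting the per-arm
# per-status n_min eligibility; with `ignore_arms` the treatment-free
# superset (>= 2 * n_min per status) of combinations that could be
# eligible under some relabelling of the arms
eligible_candidates <- function(trial, endpoints = NULL,
                                ignore_arms = FALSE) {
  cfg <- trial_config(trial)
  endpoints <- endpoints %||% cfg$endpoints
  data <- as_tibble(trial)
  strata <- stratum_table(trial)
  feats <- feature_names(trial)
  rows <- list()
  for (si in seq_len(nrow(strata))) {
    sc <- strata$scheme[si]; lv <- strata$level[si]
    sdata <- data[stratum_mask(data, sc, lv), , drop = FALSE]
    for (ep in endpoints) {
      edata <- sdata[endpoint_rows(sdata, ep), , drop = FALSE]
      tt <- edata$treatment
      for (f in feats) {
        x <- edata[[f]]
        ok <- if (ignore_arms) {
          sum(x == 1) >= 2 * cfg$n_min && sum(x == 0) >= 2 * cfg$n_min
        } else {
          all(c(sum(x == 1 & tt == 0), sum(x == 0 & tt == 0),
                sum(x == 1 & tt == 1), sum(x == 0 & tt == 1)) >= cfg$n_min)
        }
        if (ok) {
          rows[[length(rows) + 1]] <- tibble(endpoint = ep, feature = f,
                                             scheme = sc, level = lv)
        }
      }
    }
  }
  dplyr::bind_rows(c(list(tibble(endpoint = character(),
                                 feature = character(),
                                 scheme = character(),
                                 level = character())), rows))
}

#' Permutation-based multiplicity adjustment of subgroup p-values
#'
#' Permutes the treatment labels of the whole cohort `U` times (preserving
#' marginal arm sizes, leaving alterations and subtypes untouched), replays
#' the full search procedure on every null dataset, and records the
#' smallest subgroup treatment-effect p-value `p^(u)` per permutation (1
#' when no subgroup is selected, the conservative convention; permutations
#' whose search fails are counted the same way).  Each found subgroup's
#' adjusted p-value is the fraction of null values at or below its
#' `p_gamma`; with `add_one_permutation` the add-one estimate
#' `(1 + sum) / (1 + U)` is reported instead.
#'
#' @param trial A [trial_data] object.
#' @param found An `onco_subgroups` tibble of selected subgroups
#'   (non-empty).
#' @param search The [subgroup_search()] replayed on each null dataset.
#' @param n_permutations,seed,add_one Overrides of the attached
#'   configuration.
#' @return `found` with a `p_adj` column; the vector of null p-values is
#'   attached as attribute `null_pvalues`, failed-permutation count as
#'   `n_failed`.
#' @export
permutation_adjust <- function(trial, found, search = subgroup_search(),
                               n_permutations = NULL, seed = NULL,
                               add_one = NULL) {
  cfg <- trial_config(trial)
  U <- n_permutations %||% cfg$n_permutations
  add_one <- add_one %||% cfg$add_one_permutation
  if (U < 1) abort("n_permutations must be >= 1")
  if (nrow(found) == 0) abort("no subgroups to adjust")
  seed <- seed %||% cfg$seed
  if (!is.null(seed)) set.seed(seed)

  if (!is.function(search) && search$mode == "best") {
    nulls <- permutation_null_best(trial, search, U)
  } else {
    nulls <- permutation_null_generic(trial, search, U)
  }
  p_u <- nulls$p_u
  n_failed <- nulls$n_failed
  found$p_adj <- vapply(found$p_gamma, function(p) {
    hits <- sum(p_u <= p)
    if (add_one) (1 + hits) / (1 + U) else hits / U
  }, numeric(1))
  attr(found, "null_pvalues") <- p_u
  attr(found, "n_failed") <- n_failed
  found
}

# generic permutation null: replay the search on each null dataset
permutation_null_generic <- function(trial, search, U) {
  p_u <- numeric(U)
  n_failed <- 0L
  tr <- trial$treatment
  for (u in seq_len(U)) {
    null_trial <- trial
    null_trial$treatment <- sample(tr)
    p_u[u] <- tryCatch({
      res <- run_search(null_trial, search)
      if (nrow(res) == 0) 1 else min(res$p_gamma)
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      1
    })
  }
  list(p_u = p_u, n_failed = n_failed)
}

# fast best-mode permutation null: only the treatment column varies across
# permutations, so every candidate subpopulation (its rows, outcomes and
# covariate matrix) is precomputed once and each permutation refits the
# single-treatment-term model.  Equivalent to replaying run_search() with
# mode = "best" on each null dataset (verified by test).
permutation_null_best <- function(trial, search, U) {
  cfg <- trial_config(trial)
  endpoints <- search$endpoints %||% cfg$endpoints
  explicit <- !is.null(search$candidates)
  cand <- search$candidates %||%
    eligible_candidates(trial, endpoints, ignore_arms = TRUE)
  data <- as_tibble(trial)
  tr0 <- trial$treatment

  units <- list()
  for (i in seq_len(nrow(cand))) {
    cols <- endpoint_cols(cand$endpoint[i])
    base_mask <- stratum_mask(data, cand$scheme[i], cand$level[i]) &
      endpoint_rows(data, cand$endpoint[i])
    x_all <- data[[cand$feature[i]]]
    for (status in c("mutant", "wildtype")) {
      want <- if (status == "mutant") 1 else 0
      idx <- which(base_mask & x_all == want)
      sub <- data[idx, , drop = FALSE]
      units[[length(units) + 1]] <- list(
        cand = i, idx = idx,
        covm = covariate_matrix(sub, cfg$covariates),
        type = cols$type,
        time = if (cols$type == "survival") sub[[cols$time]],
        event = if (cols$type == "survival") sub[[cols$event]],
        y = if (cols$type == "binary") sub[[cols$response]]
      )
    }
  }

  p_u <- numeric(U)
  for (u in seq_len(U)) {
    t_perm <- sample(tr0)
    best_p <- Inf
    i <- 1L
    while (i <= length(units)) {
      pair <- units[c(i, i + 1L)]
      i <- i + 2L
      if (!explicit) {
        # re-evaluate the four-cell n_min eligibility under the permuted
        # labels, as a full re-run of the search would
        cells <- c(vapply(pair, function(un) {
          tt <- t_perm[un$idx]
          c(sum(tt == 0), sum(tt == 1))
        }, numeric(2)))
        if (any(cells < cfg$n_min)) next
      }
      g <- rep(NA_real_, 2)
      se <- rep(NA_real_, 2)
      for (j in 1:2) {
        un <- pair[[j]]
        tt <- t_perm[un$idx]
        if (length(unique(tt)) < 2) next
        X <- cbind(matrix(as.numeric(tt), ncol = 1,
                          dimnames = list(NULL, "t")), un$covm)
        fit <- tryCatch(suppressWarnings(
          if (un$type == "survival") {
            fit_core("survival", X, time = un$time, event = un$event)
          } else {
            fit_core("binary", X, y = un$y)
          }
        ), error = function(e) fit_failure("fit_error"))
        if (fit$ok && fit$converged) {
          g[j] <- fit$coef[["t"]]
          se[j] <- fit$se[["t"]]
        }
      }
      if (all(is.na(g))) next
      sel <- if (all(!is.na(g))) {
        if (abs(g[1]) >= abs(g[2])) 1L else 2L
      } else {
        which(!is.na(g))
      }
      p <- 2 * pnorm(-abs(g[sel] / se[sel]))
      if (p < best_p) best_p <- p
    }
    p_u[u] <- if (is.finite(best_p)) best_p else 1
  }
  list(p_u = p_u, n_failed = 0L)
}

#' Bootstrap bias correction of subgroup treatment effects
#'
#' A subgroup selected by the search overstates its own treatment effect
#' (winner's curse).  For each of `B` non-parametric bootstrap resamples of
#' patients, the subgroup selection (mutant versus wild-type population by
#' larger absolute `gamma1`) is replayed per originally found
#' (feature, stratum) pair, giving a resample-selected population; the
#' per-resample corrected value is
#' `gamma1(A) + gamma1(A^(b)) - gamma1^(b)(A^(b))`, combining the original
#' estimate, the original-data estimate of the resample-selected
#' population, and the resample estimate of that population.  The
#' bias-corrected estimate is the mean of these values (all arithmetic on
#' the log scale; ratios are exponentiated only at reporting) and the 95%
#' interval their 0.025/0.975 empirical quantiles.  Resamples in which
#' either candidate population is degenerate are skipped with a reduced
#' denominator; a subgroup with more than 20% skipped resamples is flagged
#' `boot_unstable`.
#'
#' @param trial A [trial_data] object.
#' @param found An `onco_subgroups` tibble of selected subgroups.
#' @param n_bootstrap,seed Overrides of the attached configuration.
#' @return `found` with columns `gamma_corrected`, `effect_corrected`,
#'   `ci_boot_low`, `ci_boot_high` (log scale), `boot_skipped`,
#'   `boot_unstable`.
#' @export
bootstrap_bias_correct <- function(trial, found, n_bootstrap = NULL,
                                   seed = NULL) {
  cfg <- trial_config(trial)
  B <- n_bootstrap %||% cfg$n_bootstrap
  if (B < 1) abort("n_bootstrap must be >= 1")
  if (nrow(found) == 0) abort("no subgroups to correct")
  seed <- seed %||% cfg$seed
  if (!is.null(seed)) set.seed(seed)

  data <- as_tibble(trial)
  n <- nrow(data)

  # original-data estimates of both candidate populations per found pair
  orig <- lapply(seq_len(nrow(found)), function(i) {
    vapply(c("mutant", "wildtype"), function(st) {
      res <- .fit_cate(data, cfg, found$endpoint[i], found$feature[i],
                       found$scheme[i], found$level[i], st)
      if (!res$fit$ok || !res$fit$converged) NA_real_
      else res$fit$coef[["t"]]
    }, numeric(1))
  })

  draws <- matrix(NA_real_, nrow = B, ncol = nrow(found))
  for (b in seq_len(B)) {
    bdata <- data[sample.int(n, n, replace = TRUE), , drop = FALSE]
    for (i in seq_len(nrow(found))) {
      est <- vapply(c("mutant", "wildtype"), function(st) {
        res <- .fit_cate(bdata, cfg, found$endpoint[i], found$feature[i],
                         found$scheme[i], found$level[i], st)
        if (!res$fit$ok || !res$fit$converged) NA_real_
        else res$fit$coef[["t"]]
      }, numeric(1))
      if (anyNA(est) || anyNA(orig[[i]])) next # degenerate resample: skip
      sel_b <- if (abs(est[1]) >= abs(est[2])) 1L else 2L
      draws[b, i] <- found$gamma1[i] + orig[[i]][sel_b] - est[sel_b]
    }
  }

  found$gamma_corrected <- NA_real_
  found$effect_corrected <- NA_real_
  found$ci_boot_low <- NA_real_
  found$ci_boot_high <- NA_real_
  found$boot_skipped <- NA_integer_
  found$boot_unstable <- NA
  for (i in seq_len(nrow(found))) {
    d <- draws[, i]
    skipped <- sum(is.na(d))
    d <- d[!is.na(d)]
    found$boot_skipped[i] <- skipped
    found$boot_unstable[i] <- skipped > 0.2 * B
    if (length(d) == 0) next
    found$gamma_corrected[i] <- mean(d)
    found$effect_corrected[i] <- exp(mean(d))
    qq <- quantile(d, c(0.025, 0.975), names = FALSE, type = 7)
    found$ci_boot_low[i] <- qq[1]
    found$ci_boot_high[i] <- qq[2]
  }
  if (any(found$boot_unstable, na.rm = TRUE)) {
    warn("bootstrap correction unstable for at least one subgroup (> 20% resamples skipped)")
  }
  found
}

# pure Eq-style helper: corrected value and quantile CI from per-resample
# components; exposed internally for exact contract tests
boot_correct_values <- function(gamma_A, gamma_orig_b, gamma_boot_b) {
  d <- gamma_A + gamma_orig_b - gamma_boot_b
  list(gamma_corrected = mean(d),
       ci = quantile(d, c(0.025, 0.975), names = FALSE, type = 7))
}
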