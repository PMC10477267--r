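# Internal regression engine.
#
# All models in the pipeline are either Cox proportional-hazards fits
# (partial likelihood, Efron ties) or maximum-likelihood logistic fits.
# The hot paths (permutation and bootstrap loops) go through
# survival::coxph.fit / stats::glm.fit directly with pre-built design
# matrices; both are numerically identical to the coxph()/glm() formula
# interfaces but avoid their formula/model-frame overhead.

# reference-coded covariate matrix; reference = most frequent level,
# computed on the rows being fitted so that stratified fits equal
# pre-filtered unstratified fits.
covariate_matrix <- function(data, covariates) {
  if (length(covariates) == 0) return(NULL)
  cols <- lapply(covariates, function(cv) {
    v <- data[[cv]]
    if (is.numeric(v)) {
      m <- matrix(as.numeric(v), ncol = 1, dimnames = list(NULL, cv))
      return(m)
    }
    v <- as.character(v)
    tab <- sort(table(v), decreasing = TRUE)
    lev <- names(tab)
    if (length(lev) < 2) return(NULL) # constant in this subset
    others <- lev[-1]
    m <- vapply(others, function(l) as.numeric(v == l), numeric(length(v)))
    m <- matrix(m, ncol = length(others),
                dimnames = list(NULL, paste0(cv, others)))
    m
  })
  cols <- cols[!vapply(cols, is.null, logical(1))]
  if (length(cols) == 0) return(NULL)
  do.call(cbind, cols)
}

# drop constant / linearly dependent columns, never the focal (first) one;
# NULL when the focal column itself is degenerate.
prune_design <- function(X, has_intercept = FALSE) {
  keep <- rep(TRUE, ncol(X))
  for (j in seq_len(ncol(X))) {
    if (max(X[, j]) == min(X[, j])) keep[j] <- FALSE
  }
  if (!keep[1]) return(NULL)
  X <- X[, keep, drop = FALSE]
  Xq <- if (has_intercept) cbind(1, X) else X
  q <- qr(Xq)
  if (q$rank < ncol(Xq)) {
    drop_idx <- sort(q$pivot[seq(q$rank + 1, ncol(Xq))])
    if (has_intercept) drop_idx <- drop_idx - 1
    if (any(drop_idx <= 1)) return(NULL)
    X <- X[, -drop_idx, drop = FALSE]
  }
  X
}

fit_failure <- function(reason) {
  list(ok = FALSE, reason = reason, converged = FALSE)
}

# type: "survival" (time/event) or "binary" (y); X: design matrix whose
# first column is the focal predictor.  Returns coefficients, SEs and
# convergence diagnostics; intercept reported for logistic fits only (the
# Cox baseline hazard absorbs it).
fit_core <- function(type, X, time = NULL, event = NULL, y = NULL) {
  focal <- colnames(X)[1]
  if (type == "survival") {
    if (sum(event) == 0) return(fit_failure("no_events"))
    X <- prune_design(X, has_intercept = FALSE)
    if (is.null(X)) return(fit_failure("constant_predictor"))
    fit <- survival::coxph.fit(
      X, survival::Surv(time, event), strata = NULL, offset = NULL,
      init = NULL, control = survival::coxph.control(), weights = NULL,
      method = "efron", rownames = NULL, resid = FALSE
    )
    beta <- fit$coefficients
    se <- sqrt(diag(as.matrix(fit$var)))
    intercept <- NA_real_
  } else {
    if (length(unique(y)) < 2) return(fit_failure("degenerate_response"))
    X <- prune_design(X, has_intercept = TRUE)
    if (is.null(X)) return(fit_failure("constant_predictor"))
    Xi <- cbind(`(Intercept)` = 1, X)
    fit <- suppressWarnings(glm.fit(Xi, y, family = binomial()))
    beta_all <- fit$coefficients
    V <- tryCatch(solve(crossprod(Xi * sqrt(fit$weights))),
                  error = function(e) NULL)
    if (is.null(V) || !fit$converged) return(fit_failure("not_converged"))
    se_all <- sqrt(diag(V))
    intercept <- beta_all[["(Intercept)"]]
    beta <- beta_all[-1]
    se <- se_all[-1]
  }
  names(se) <- names(beta)
  converged <- all(is.finite(beta)) && all(is.finite(se)) &&
    abs(beta[[focal]]) < 15 && se[[focal]] < 50
  list(
    ok = TRUE, reason = NA_character_, converged = converged,
    intercept = intercept, coef = beta, se = se, focal = focal,
    n = nrow(X), n_events = if (type == "survival") sum(event) else sum(y)
  )
}

# one focal coefficient -> Wald summary on the ratio scale
wald_summary <- function(est, se) {
  z <- est / se
  list(
    p = 2 * pnorm(-abs(z)),
    ci_low = exp(est - qnorm(0.975) * se),
    ci_high = exp(est + qnorm(0.975) * se)
  )
}

# rows of `data` usable for an endpoint (ORR-missing patients are excluded
# from ORR models only)
endpoint_rows <- function(data, endpoint) {
  cols <- endpoint_cols(endpoint)
  if (cols$type == "survival") {
    !is.na(data[[cols$time]]) & !is.na(data[[cols$event]])
  } else {
    !is.na(data[[cols$response]])
  }
}

# strata enumerated by every analysis stage: unstratified ("none"/"ALL")
# plus each level of each configured subtype scheme
stratum_table <- function(trial) {
  schemes <- trial_config(trial)$subtype_schemes
  rows <- list(tibble(scheme = "none", level = "ALL"))
  for (s in schemes) {
    lv <- sort(unique(as.character(stats::na.omit(trial[[s]]))))
    rows[[s]] <- tibble(scheme = s, level = lv)
  }
  dplyr::bind_rows(rows)
}

stratum_mask <- function(data, scheme, level) {
  if (scheme == "none") rep(TRUE, nrow(data))
  else !is.na(data[[scheme]]) & as.character(data[[scheme]]) == level
}
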