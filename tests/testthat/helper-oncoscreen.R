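# fixtures are built in code; no data files

# deterministic 3-patient pair of tables for io tests
tiny_clinical <- function(n = 6) {
  tibble::tibble(
    patient_id = paste0("p", seq_len(n)),
    treatment = rep_len(c(0L, 1L), n),
    os_time = seq(2, 2 * n, by = 2),
    os_event = rep_len(c(1L, 1L, 0L), n),
    pfs_time = seq(1, n),
    pfs_event = rep_len(c(1L, 0L), n),
    orr = rep_len(c(0L, 1L), n)
  )
}

tiny_alterations <- function(n = 6) {
  tibble::tibble(
    patient_id = paste0("p", seq_len(n)),
    KRAS = rep_len(c(1L, 0L, 0L), n),
    TP53 = rep_len(c(0L, 1L), n)
  )
}

# all-null generative design (no prognostic or predictive effects)
null_design <- function(n = 300, n_features = 20, schemes = TRUE) {
  freq <- stats::setNames(
    round(exp(seq(log(0.45), log(0.05), length.out = n_features)), 3),
    sprintf("G%02d_SV", seq_len(n_features))
  )
  trial_design(
    n_patients = n,
    feature_frequencies = freq,
    schemes = if (schemes) {
      list(side = c(left = 0.6, right = 0.4),
           cms = c(CMS1 = 0.15, CMS2 = 0.4, CMS3 = 0.15, CMS4 = 0.3))
    } else {
      list()
    },
    baseline_rate = 1 / 24, censor_rate = 1 / 96 # ~80% events
  )
}

# planted subtype-specific predictive effect: experimental-arm log HR
# `loghr` for mutants of G01_SV inside the 40% subtype level
planted_design <- function(n = 600, loghr = log(0.4), n_features = 12) {
  freq <- stats::setNames(
    round(exp(seq(log(0.40), log(0.05), length.out = n_features)), 3),
    sprintf("G%02d_SV", seq_len(n_features))
  )
  freq["G01_SV"] <- 0.30
  trial_design(
    n_patients = n,
    feature_frequencies = freq,
    schemes = list(side = c(right = 0.4, left = 0.6)),
    predictive_loghr = tibble::tibble(
      feature = "G01_SV", scheme = "side", level = "right",
      status = "mutant", loghr = loghr
    ),
    baseline_rate = 1 / 24, censor_rate = 1 / 140 # ~15% censored
  )
}

# ---- independent oracles -------------------------------------------------

# hypergeometric tail probabilities by exhaustive pmf summation
oracle_hyper_pmf <- function(x, K, ns, N) {
  choose(K, x) * choose(N - K, ns - x) / choose(N, ns)
}

oracle_hyper_upper <- function(k, K, ns, N) {
  hi <- min(K, ns)
  if (k > hi) return(0)
  sum(oracle_hyper_pmf(max(0, k):hi, K, ns, N))
}

oracle_hyper_lower <- function(k, K, ns, N) {
  lo <- max(0, ns - (N - K))
  if (k < lo) return(0)
  sum(oracle_hyper_pmf(lo:min(k, ns, K), K, ns, N))
}

# textbook Benjamini-Hochberg step-up
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  out <- numeric(m)
  out[o] <- q_sorted
  out
}

# builds a trial directly from clinical + alteration tibbles with a config
quick_trial <- function(clinical, alterations, ...) {
  suppressMessages(suppressWarnings(
    trial_data(clinical, alterations, onco_config(...))
  ))
}
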