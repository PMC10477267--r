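found_stub <- function(p_gamma = 0.5) {
  out <- tibble::tibble(
    endpoint = "OS", feature = "F1", scheme = "none", level = "ALL",
    status = "mutant", n = 100L, n0 = 50L, n1 = 50L, gamma0 = NA_real_,
    gamma1 = -0.4, se = 0.2, effect = exp(-0.4), ci_low = 0.4,
    ci_high = 1.1, p_gamma = p_gamma, converged = TRUE, selected = TRUE,
    group_id = "OS:F1:none:ALL"
  )
  class(out) <- c("onco_subgroups", class(tibble::tibble()))
  out
}

test_that("the adjusted p-value is the fraction of null values at or below p", {
  tr <- simulate_trial(null_design(n = 100, n_features = 2,
                                   schemes = FALSE), seed = 1)
  # stub searches give full control over the null distribution
  all_null_one <- function(trial) found_stub(p_gamma = 1)
  adj <- permutation_adjust(tr, found_stub(0.5), all_null_one,
                            n_permutations = 20, seed = 1)
  expect_equal(adj$p_adj, 0)

  half_small <- local({
    counter <- 0
    function(trial) {
      counter <<- counter + 1
      found_stub(p_gamma = if (counter %% 2 == 0) 0.25 else 0.75)
    }
  })
  adj <- permutation_adjust(tr, found_stub(0.5), half_small,
                            n_permutations = 20, seed = 1)
  expect_equal(adj$p_adj, 0.5)

  # add-one variant
  adj1 <- permutation_adjust(tr, found_stub(0.5), all_null_one,
                             n_permutations = 20, seed = 1, add_one = TRUE)
  expect_equal(adj1$p_adj, 1 / 21)

  # failing permutations count conservatively as p = 1
  fail_search <- function(trial) stop("boom")
  adjf <- permutation_adjust(tr, found_stub(0.5), fail_search,
                             n_permutations = 10, seed = 1)
  expect_equal(adjf$p_adj, 0)
  expect_equal(attr(adjf, "n_failed"), 10L)

  expect_error(permutation_adjust(tr, found_stub(), all_null_one,
                                  n_permutations = 0), "n_permutations")
})

test_that("p_adj lives on the permutation grid and is monotone in p_gamma", {
  tr <- simulate_trial(null_design(n = 160, n_features = 3,
                                   schemes = FALSE), seed = 7)
  srch <- subgroup_search("best", endpoints = "OS")
  found <- run_search(tr, srch)
  found <- dplyr::bind_rows(found, found, found)
  found$p_gamma <- c(0.01, 0.2, 0.9)
  U <- 50
  adj <- permutation_adjust(tr, found, srch, n_permutations = U, seed = 3)
  expect_true(all(adj$p_adj * U == round(adj$p_adj * U)))
  expect_true(all(diff(adj$p_adj) >= 0))
  # reproducibility to the last bit
  adj2 <- permutation_adjust(tr, found, srch, n_permutations = U, seed = 3)
  expect_identical(adj$p_adj, adj2$p_adj)
})

test_that("the fast best-mode permutation path equals the generic replay", {
  tr <- simulate_trial(null_design(n = 200, n_features = 4,
                                   schemes = FALSE), seed = 11)
  for (srch in list(
    subgroup_search("best", endpoints = "OS"),
    subgroup_search("best", endpoints = "OS",
                    candidates = tibble::tibble(
                      endpoint = "OS", feature = c("G01_SV", "G02_SV"),
                      scheme = "none", level = "ALL"
                    ))
  )) {
    set.seed(42)
    generic <- oncoscreen:::permutation_null_generic(tr, srch, 25)
    set.seed(42)
    fast <- oncoscreen:::permutation_null_best(tr, srch, 25)
    expect_equal(fast$p_u, generic$p_u, tolerance = 1e-12)
  }
})

test_that("landscape quantities are untouched by treatment permutation", {
  tr <- simulate_trial(null_design(n = 200, n_features = 6), seed = 13)
  dat <- tibble::as_tibble(tr)
  dat$treatment <- sample(dat$treatment)
  feats <- feature_names(tr)
  tr_perm <- trial_data(dat[, setdiff(names(dat), feats)],
                        dat[, c("patient_id", feats)], trial_config(tr))
  expect_identical(test_subtype_enrichment(tr),
                   test_subtype_enrichment(tr_perm))
  expect_identical(find_mutex_modules(tr), find_mutex_modules(tr_perm))
})

# bootstrap ------------------------------------------------------------------

test_that("the per-resample correction obeys its algebraic contracts", {
  bcv <- oncoscreen:::boot_correct_values
  # resample estimate equal to the original-data estimate for every b:
  # the correction collapses to the naive estimate
  g_orig_b <- rnorm(50)
  out <- bcv(gamma_A = -0.7, gamma_orig_b = g_orig_b, gamma_boot_b = g_orig_b)
  expect_equal(out$gamma_corrected, -0.7)

  # per-resample corrected values 1..100: the CI is their empirical
  # 2.5th / 97.5th percentile
  out <- bcv(gamma_A = 0, gamma_orig_b = 1:100, gamma_boot_b = rep(0, 100))
  expect_equal(out$gamma_corrected, mean(1:100))
  expect_equal(out$ci, quantile(1:100, c(0.025, 0.975), names = FALSE))
})

test_that("bootstrap correction is reproducible and shrinks selected effects", {
  set.seed(300)
  ratios <- replicate(25, {
    tr <- simulate_trial(null_design(n = 240, n_features = 1,
                                     schemes = FALSE),
                         seed = sample.int(1e6, 1))
    srch <- subgroup_search("best", endpoints = "OS")
    found <- run_search(tr, srch)
    adj <- bootstrap_bias_correct(tr, found, n_bootstrap = 60, seed = 9)
    c(abs(adj$gamma_corrected), abs(adj$gamma1))
  })
  expect_lt(mean(ratios[1, ]), mean(ratios[2, ]))

  tr <- simulate_trial(null_design(n = 240, n_features = 1,
                                   schemes = FALSE), seed = 2024)
  found <- run_search(tr, subgroup_search("best", endpoints = "OS"))
  a <- bootstrap_bias_correct(tr, found, n_bootstrap = 40, seed = 5)
  b <- bootstrap_bias_correct(tr, found, n_bootstrap = 40, seed = 5)
  expect_identical(a$gamma_corrected, b$gamma_corrected)
  expect_identical(a$ci_boot_low, b$ci_boot_low)
  expect_true(a$ci_boot_low <= a$ci_boot_high)
  expect_lte(a$boot_skipped, 40 * 0.2) # otherwise flagged unstable
})

test_that("bootstrap intervals cover a genuinely planted subgroup effect", {
  # loose coverage check: the quantile interval of the corrected draws
  # contains the true value in most replicates
  hits <- 0L
  n_rep <- 25L
  for (r in seq_len(n_rep)) {
    d <- trial_design(
      n_patients = 300, feature_frequencies = c(F1 = 0.5),
      predictive_loghr = tibble::tibble(feature = "F1", scheme = "none",
                                        level = "ALL", status = "mutant",
                                        loghr = -0.9),
      baseline_rate = 1 / 24, censor_rate = 1 / 140
    )
    tr <- simulate_trial(d, seed = 5000 + r)
    found <- run_search(tr, subgroup_search(
      "best", endpoints = "OS",
      candidates = tibble::tibble(endpoint = "OS", feature = "F1",
                                  scheme = "none", level = "ALL")
    ))
    adj <- bootstrap_bias_correct(tr, found, n_bootstrap = 100,
                                  seed = 6000 + r)
    if (!is.na(adj$ci_boot_low) && adj$status == "mutant" &&
        adj$ci_boot_low <= -0.9 && -0.9 <= adj$ci_boot_high) {
      hits <- hits + 1L
    }
  }
  expect_gte(hits, ceiling(0.7 * n_rep))
})
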