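# single fits ---------------------------------------------------------------

orr_trial <- function(x, y, t = NULL) {
  n <- length(x)
  clin <- tiny_clinical(n)
  clin$orr <- as.integer(y)
  if (!is.null(t)) clin$treatment <- as.integer(t)
  alt <- tibble::tibble(patient_id = clin$patient_id, F1 = as.integer(x))
  quick_trial(clin, alt)
}

test_that("a saturated 2x2 logistic fit reproduces the closed-form odds ratio", {
  # mutants 10/20 responders vs wild-type 5/20: OR = (10*15)/(10*5) = 3
  x <- rep(c(1, 0), each = 20)
  y <- c(rep(1, 10), rep(0, 10), rep(1, 5), rep(0, 15))
  tr <- orr_trial(x, y)
  res <- fit_arm_model(tr, "ORR", arm = 0, feature = "F1")
  res1 <- fit_arm_model(tr, "ORR", arm = 1, feature = "F1")
  pooled_or <- exp(c(res$alpha1[res$converged], res1$alpha1))
  # per-arm tables are saturated too; check both against their own tables
  for (arm in 0:1) {
    d <- tibble::as_tibble(tr)[tr$treatment == arm, ]
    tab <- table(factor(d$F1, 0:1), factor(d$orr, 0:1))
    or <- (tab[2, 2] * tab[1, 1]) / (tab[2, 1] * tab[1, 2])
    res_arm <- fit_arm_model(tr, "ORR", arm = arm, feature = "F1")
    expect_equal(res_arm$effect, or, tolerance = 1e-6)
    expect_equal(res_arm$alpha1, log(or), tolerance = 1e-6)
  }
})

test_that("fits with no events are skipped with the reason recorded", {
  clin <- tiny_clinical(30)
  clin$os_event <- 0L
  clin$os_time <- 12
  tr <- quick_trial(clin, tibble::tibble(patient_id = clin$patient_id,
                                         F1 = rep_len(c(1L, 0L), 30)))
  res <- fit_arm_model(tr, "OS", arm = 0, feature = "F1")
  expect_equal(nrow(res), 0)
  expect_equal(attr(res, "audit")$reason, "no_events")
})

test_that("the Cox fit recovers a planted log-hazard ratio at large n", {
  d <- trial_design(n_patients = 2000,
                    feature_frequencies = c(F1 = 0.4),
                    prognostic_loghr = c(F1 = log(2)),
                    baseline_rate = 1 / 24, censor_rate = 1 / 1e6)
  tr <- simulate_trial(d, seed = 21)
  res <- fit_arm_model(tr, "OS", arm = 0, feature = "F1")
  expect_true(res$converged)
  expect_lt(abs(res$alpha1 - log(2)), 0.15)

  # dual route: the formula interface of the reference survival package
  d0 <- tibble::as_tibble(tr)[tr$treatment == 0, ]
  ref <- survival::coxph(survival::Surv(os_time, os_event) ~ F1, data = d0,
                         ties = "efron")
  expect_equal(res$alpha1, unname(coef(ref)), tolerance = 1e-8)
  expect_equal(res$se, sqrt(unname(vcov(ref)[1, 1])), tolerance = 1e-8)
})

# enumeration / eligibility -------------------------------------------------

screen_fixture <- function(n = 240, seed = 17) {
  # 3 features x 2 levels x 2 arms, all eligible by construction
  set.seed(seed)
  i <- seq_len(n)
  clin <- tiny_clinical(n)
  clin$treatment <- rep_len(c(0L, 1L), n)
  clin$os_time <- rexp(n, 1 / 20)
  clin$os_event <- rbinom(n, 1, 0.9)
  clin$side <- rep_len(c("L", "L", "R"), n)
  alt <- tibble::tibble(
    patient_id = clin$patient_id,
    A = as.integer(i %% 5 < 2),
    B = as.integer(i %% 7 < 3),
    C = as.integer(i %% 11 < 5)
  )
  quick_trial(clin, alt, subtype_schemes = "side", endpoints = "OS")
}

test_that("screening enumerates exactly the eligible combinations", {
  tr <- screen_fixture()
  scr <- screen_arms(tr)
  # 3 features x (ALL + 2 levels) x 2 arms x 1 endpoint = 18 results
  expect_equal(nrow(scr), 18)
  expect_setequal(unique(scr$level), c("ALL", "L", "R"))
  # matches a brute-force enumeration of the combination grid
  grid <- expand.grid(feature = c("A", "B", "C"), arm = 0:1,
                      level = c("ALL", "L", "R"),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(dplyr::distinct(scr[, c("feature", "arm", "level")])),
               nrow(grid))
})

test_that("groups below n_min are audited, not fitted", {
  tr <- screen_fixture()
  # make feature A rare: 9 mutants in arm 1 only
  dat <- tibble::as_tibble(tr)
  dat$A <- 0L
  dat$A[which(dat$treatment == 1)[1:9]] <- 1L
  tr2 <- quick_trial(dat[, c("patient_id", "treatment", "os_time",
                             "os_event", "pfs_time", "pfs_event", "orr",
                             "side")],
                     dat[, c("patient_id", "A", "B", "C")],
                     subtype_schemes = "side", endpoints = "OS")
  scr <- screen_arms(tr2)
  expect_false(any(scr$feature == "A"))
  audit <- attr(scr, "audit")
  expect_true(all(audit$reason[audit$feature == "A"] %in%
                  c("n_mut < n_min", "n_wt < n_min")))
})

test_that("module columns require n_min redistributed patients", {
  n <- 100
  clin <- tiny_clinical(n)
  set.seed(3)
  clin$os_time <- rexp(n, 1 / 20); clin$os_event <- 1L
  # module adds only 5 patients over member A: filtered everywhere
  a <- c(rep(1L, 30), rep(0L, 70))
  b <- c(rep(1L, 25), rep(0L, 50), rep(1L, 5), rep(0L, 20))
  tr <- quick_trial(clin, tibble::tibble(patient_id = clin$patient_id,
                                         A = a, B = b),
                    custom_modules = list(AB = c("A", "B")),
                    endpoints = "OS")
  aug <- build_feature_set(tr)
  scr <- screen_arms(aug)
  expect_false(any(scr$feature == "AB"))
  audit <- attr(scr, "audit")
  expect_true(all(audit$reason[audit$feature == "AB"] ==
                  "module_redistribution"))
})

test_that("BH families use the step-up formula and the fdr_alpha flag", {
  expect_equal(oracle_bh(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  tr <- screen_fixture()
  scr <- screen_arms(tr)
  for (fam in split(scr, scr$family_id)) {
    expect_equal(fam$q, oracle_bh(fam$p), tolerance = 1e-12)
  }
  expect_equal(scr$significant, !is.na(scr$q) & scr$q < 0.1)
})

# invariants ----------------------------------------------------------------

test_that("flipping the feature coding negates the coefficient", {
  tr <- screen_fixture()
  scr <- screen_arms(tr)
  dat <- tibble::as_tibble(tr)
  dat$A <- 1L - dat$A
  tr_flip <- quick_trial(dat[, c("patient_id", "treatment", "os_time",
                                 "os_event", "pfs_time", "pfs_event",
                                 "orr", "side")],
                         dat[, c("patient_id", "A", "B", "C")],
                         subtype_schemes = "side", endpoints = "OS")
  scr_flip <- screen_arms(tr_flip)
  a <- scr[scr$feature == "A", ]
  af <- scr_flip[scr_flip$feature == "A", ]
  key <- paste(a$arm, a$level)
  af <- af[match(key, paste(af$arm, af$level)), ]
  expect_equal(af$alpha1, -a$alpha1, tolerance = 1e-8)
  expect_equal(af$effect, 1 / a$effect, tolerance = 1e-8)
  expect_equal(af$ci_low, 1 / a$ci_high, tolerance = 1e-8)
})

test_that("stratified results equal unstratified results on pre-filtered data", {
  tr <- screen_fixture()
  scr <- screen_arms(tr)
  sub <- trial_data(
    tibble::as_tibble(tr)[tr$side == "L",
                          c("patient_id", "treatment", "os_time",
                            "os_event", "pfs_time", "pfs_event", "orr")],
    tibble::as_tibble(tr)[tr$side == "L", c("patient_id", "A", "B", "C")],
    onco_config(endpoints = "OS")
  )
  scr_sub <- screen_arms(sub)
  a <- scr[scr$level == "L", ]
  b <- scr_sub[scr_sub$level == "ALL", ]
  b <- b[match(paste(a$feature, a$arm), paste(b$feature, b$arm)), ]
  expect_equal(a$alpha1, b$alpha1, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("null screening p-values are calibrated", {
  # pooled across simulated null trials, the rejection rate at 0.05 is 0.05
  ps <- c()
  for (seed in 1:60) {
    tr <- simulate_trial(null_design(n = 150, n_features = 5,
                                     schemes = FALSE), seed = 1000 + seed)
    scr <- suppressWarnings(screen_arms(tr, endpoints = "OS"))
    ps <- c(ps, scr$p[scr$converged])
  }
  frac <- mean(ps < 0.05)
  tol <- 3 * sqrt(0.05 * 0.95 / length(ps))
  expect_gt(length(ps), 300)
  expect_lt(abs(frac - 0.05), tol + 0.01)
})
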