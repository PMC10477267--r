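# enrichment ---------------------------------------------------------------

make_enrichment_trial <- function(labels, x, scheme = "side") {
  n <- length(labels)
  clin <- tiny_clinical(n)
  clin[[scheme]] <- labels
  alt <- tibble::tibble(patient_id = clin$patient_id, F1 = as.integer(x))
  quick_trial(clin, alt, subtype_schemes = scheme)
}

test_that("enrichment p-values equal direct binomial-coefficient arithmetic", {
  # N = 6, K = 3, n_s = 3, k = 3: C(3,3) C(3,0) / C(6,3) = 1/20
  tr <- make_enrichment_trial(rep(c("L", "R"), each = 3),
                              c(1, 1, 1, 0, 0, 0))
  enr <- test_subtype_enrichment(tr, n_min = 2)
  hit <- enr[enr$level == "L" & enr$direction == "enriched", ]
  expect_equal(hit$p, 1 / 20)
  expect_equal(hit[, c("k", "K", "n_s", "N")],
               tibble::tibble(k = 3L, K = 3L, n_s = 3L, N = 6L),
               ignore_attr = TRUE)
})

test_that("a feature altered in everyone has enrichment p = 1 everywhere", {
  tr <- make_enrichment_trial(rep(c("L", "R"), 5), rep(1, 10))
  enr <- test_subtype_enrichment(tr, n_min = 2)
  expect_true(all(enr$p[enr$direction == "enriched"] == 1))
})

test_that("tail probabilities match exhaustive pmf summation", {
  # the documented instance N = 100, K = 50, n_s = 10, k = 5 ...
  set.seed(41)
  labels <- c(rep("A", 10), rep("B", 90))
  x <- integer(100)
  x[c(1:5, sample(11:100, 45))] <- 1L
  tr <- make_enrichment_trial(labels, x)
  enr <- test_subtype_enrichment(tr, n_min = 2)
  hit <- enr[enr$level == "A" & enr$direction == "enriched", ]
  expect_equal(hit$k, 5L)
  expect_equal(hit$p, oracle_hyper_upper(5, 50, 10, 100), tolerance = 1e-14)

  # ... and every record of random instances with N <= 200
  for (seed in 1:10) {
    set.seed(seed)
    N <- sample(20:200, 1)
    labels <- sample(c("A", "B", "C"), N, replace = TRUE)
    x <- rbinom(N, 1, runif(1, 0.1, 0.6))
    tr <- make_enrichment_trial(labels, x)
    enr <- test_subtype_enrichment(tr, n_min = 2)
    for (i in seq_len(nrow(enr))) {
      oracle <- if (enr$direction[i] == "enriched") {
        oracle_hyper_upper(enr$k[i], enr$K[i], enr$n_s[i], enr$N[i])
      } else {
        oracle_hyper_lower(enr$k[i], enr$K[i], enr$n_s[i], enr$N[i])
      }
      expect_equal(enr$p[i], oracle, tolerance = 1e-12)
    }
    # the two tails overlap at k
    both <- tidyr::pivot_wider(enr[, c("feature", "level", "direction", "p")],
                               names_from = "direction", values_from = "p")
    expect_true(all(both$enriched + both$depleted >= 1 - 1e-12))
  }
})

test_that("BH adjustment within families matches the step-up formula", {
  tr <- simulate_trial(null_design(n = 200, n_features = 8), seed = 2)
  enr <- test_subtype_enrichment(tr)
  for (fam in split(enr, paste(enr$scheme, enr$direction))) {
    expect_equal(fam$q, oracle_bh(fam$p), tolerance = 1e-12)
    expect_true(all(fam$q >= fam$p - 1e-12))
    expect_true(all(fam$q >= 0 & fam$q <= 1))
  }
})

test_that("degenerate schemes are rejected", {
  tr <- make_enrichment_trial(rep("L", 6), c(1, 1, 1, 0, 0, 0))
  expect_error(test_subtype_enrichment(tr, n_min = 2), "single level")
})

# mutual exclusivity --------------------------------------------------------

mutex_trial <- function(cols) {
  n <- nrow(cols)
  quick_trial(tiny_clinical(n),
              dplyr::bind_cols(tibble::tibble(patient_id = paste0("p", 1:n)),
                               cols))
}

test_that("disjoint features form a module, identical features do not", {
  n <- 100
  a <- integer(n); a[1:30] <- 1L
  b <- integer(n); b[31:65] <- 1L
  tr <- mutex_trial(tibble::tibble(A = a, B = b))
  mods <- find_mutex_modules(tr, n_min = 10)
  expect_equal(nrow(mods), 1)
  expect_equal(mods$members[[1]], c("A", "B"))
  expect_equal(mods$union_count, 65L)
  # the member test is the hypergeometric lower tail on the overlap
  expect_equal(mods$score, oracle_hyper_lower(0, 30, 35, 100),
               tolerance = 1e-12)

  tr2 <- mutex_trial(tibble::tibble(A = a, B = a))
  expect_equal(nrow(find_mutex_modules(tr2, n_min = 10)), 0)

  # exclusivity of small supports is not statistically surprising: zero
  # overlap between 10 and 12 of 100 has tail probability ~ 0.27 > 0.05
  a2 <- integer(n); a2[1:10] <- 1L
  b2 <- integer(n); b2[11:22] <- 1L
  tr3 <- mutex_trial(tibble::tibble(A = a2, B = b2))
  expect_equal(nrow(find_mutex_modules(tr3, n_min = 10)), 0)
})

test_that("the greedy search recovers the exhaustively best subset", {
  set.seed(9)
  n <- 120
  # three mutually disjoint features plus one co-occurring with all
  a <- integer(n); a[1:40] <- 1L
  b <- integer(n); b[41:80] <- 1L
  c_ <- integer(n); c_[81:115] <- 1L
  d <- integer(n); d[c(1:12, 41:52, 81:92)] <- 1L
  tr <- mutex_trial(tibble::tibble(A = a, B = b, C = c_, D = d))
  mods <- find_mutex_modules(tr, n_min = 10)
  expect_equal(mods$members[[1]], c("A", "B", "C"))
  expect_false(any(vapply(mods$members, function(m) "D" %in% m, logical(1))))

  # oracle: exhaustive scoring of all subsets of size <= 4 with
  # brute-force hypergeometric member tests
  feats <- c("A", "B", "C", "D")
  mat <- cbind(A = a, B = b, C = c_, D = d)
  score_subset <- function(members) {
    max(vapply(members, function(m) {
      u <- rowSums(mat[, setdiff(members, m), drop = FALSE]) > 0
      k <- sum(mat[, m] == 1 & u)
      oracle_hyper_lower(k, sum(mat[, m]), sum(u), n)
    }, numeric(1)))
  }
  subsets <- unlist(lapply(2:4, function(s) combn(feats, s, simplify = FALSE)),
                    recursive = FALSE)
  scores <- vapply(subsets, score_subset, numeric(1))
  best <- subsets[[which.min(scores)]]
  expect_equal(mods$members[[1]], sort(best))
  expect_equal(mods$score[1], min(scores), tolerance = 1e-12)
})

test_that("reported modules never point in the co-occurrence direction", {
  tr <- simulate_trial(fire3_like_design(), seed = 8)
  mods <- find_mutex_modules(tr)
  mat <- as.matrix(tibble::as_tibble(tr)[, feature_names(tr)])
  for (members in mods$members) {
    for (m in members) {
      u <- rowSums(mat[, setdiff(members, m), drop = FALSE]) > 0
      expect_lte(sum(mat[, m] == 1 & u), sum(mat[, m]) * sum(u) / nrow(mat))
    }
  }
})

test_that("fewer than two eligible features yields an empty module list", {
  n <- 50
  tr <- mutex_trial(tibble::tibble(A = c(rep(1L, 12), rep(0L, n - 12)),
                                   B = c(rep(1L, 3), rep(0L, n - 3))))
  expect_equal(nrow(find_mutex_modules(tr, n_min = 10)), 0)
})

# feature set --------------------------------------------------------------

test_that("module unions are boolean ORs and custom modules are added", {
  n <- 30
  a <- c(rep(1L, 10), rep(0L, 20))
  b <- c(rep(0L, 10), rep(1L, 10), rep(0L, 10))
  clin <- tiny_clinical(n)
  alt <- tibble::tibble(patient_id = clin$patient_id, KRAS = a, NRAS = b,
                        TP53 = rep_len(c(1L, 0L), n))
  tr <- quick_trial(clin, alt, custom_modules = list(RAS = c("KRAS", "NRAS")))
  mods <- find_mutex_modules(tr, n_min = 10)
  aug <- build_feature_set(tr, mods)
  expect_true("RAS" %in% feature_names(aug))
  expect_equal(aug$RAS, as.integer(a | b))
  expect_equal(feature_meta(aug)$class[feature_meta(aug)$feature == "RAS"],
               "CUSTOM")

  # empty module list leaves the matrix unchanged (custom modules aside)
  tr_plain <- quick_trial(clin, alt)
  aug_plain <- build_feature_set(tr_plain, NULL)
  expect_identical(as.data.frame(aug_plain), as.data.frame(tr_plain))
})

test_that("a custom module naming an unknown feature errors", {
  tr <- quick_trial(tiny_clinical(6), tiny_alterations(6),
                    custom_modules = list(BAD = c("KRAS", "NOPE")))
  expect_error(build_feature_set(tr), "unknown feature")
})
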