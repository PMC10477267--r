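#' Feature-subtype enrichment and depletion
#'
#' Tests every sufficiently frequent feature for enrichment and depletion in
#' every level of every configured subtype scheme with one-sided
#' hypergeometric tests: with `N` labelled patients, `K` of them altered,
#' and `k` altered among the `n_s` patients of a level, the enrichment
#' p-value is the upper tail `P(X >= k)` and the depletion p-value the lower
#' tail `P(X <= k)`.  Benjamini-Hochberg adjustment is applied within each
#' (scheme, direction) family and calls with `q < fdr_mol` are flagged.
#'
#' @param trial A [trial_data] object.
#' @param fdr_mol,n_min Overrides of the corresponding [onco_config()]
#'   values attached to `trial`.
#' @return A tibble of class `onco_enrichment`: one row per
#'   (feature, scheme, level, direction) with counts `k`, `K`, `n_s`, `N`,
#'   tail probability `p`, BH-adjusted `q` and a `significant` flag.
#' @export
test_subtype_enrichment <- function(trial, fdr_mol = NULL, n_min = NULL) {
  cfg <- trial_config(trial)
  fdr_mol <- fdr_mol %||% cfg$fdr_mol
  n_min <- n_min %||% cfg$n_min
  schemes <- cfg$subtype_schemes
  if (length(schemes) == 0) abort("no subtype schemes configured")
  feats <- feature_names(trial)

  rows <- list()
  for (scheme in schemes) {
    labels <- as.character(trial[[scheme]])
    keep <- !is.na(labels)
    labels <- labels[keep]
    levels <- sort(unique(labels))
    if (length(levels) < 2) {
      abort(sprintf("scheme '%s' has a single level", scheme))
    }
    N <- length(labels)
    for (f in feats) {
      x <- trial[[f]][keep]
      K <- sum(x)
      if (K < n_min) next
      for (lv in levels) {
        in_level <- labels == lv
        n_s <- sum(in_level)
        if (n_s == 0) {
          warn(sprintf("empty level '%s' in scheme '%s' skipped", lv, scheme))
          next
        }
        k <- sum(x[in_level])
        p_enrich <- phyper(k - 1, K, N - K, n_s, lower.tail = FALSE)
        p_deplete <- phyper(k, K, N - K, n_s, lower.tail = TRUE)
        rows[[length(rows) + 1]] <- tibble(
          feature = f, scheme = scheme, level = lv,
          direction = c("enriched", "depleted"),
          k = k, K = K, n_s = n_s, N = N,
          p = c(p_enrich, p_deplete)
        )
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(feature = character(), scheme = character(),
                  level = character(), direction = character(),
                  k = integer(), K = integer(), n_s = integer(),
                  N = integer(), p = double(), q = double(),
                  significant = logical())
  } else {
    out <- out |>
      group_by(.data$scheme, .data$direction) |>
      mutate(q = p.adjust(.data$p, method = "BH")) |>
      ungroup() |>
      mutate(significant = .data$q < fdr_mol) |>
      arrange(.data$scheme, .data$direction, .data$p)
  }
  class(out) <- c("onco_enrichment", class(tibble()))
  out
}

# one-sided exclusivity p-value of a member against the union of the other
# members: hypergeometric lower tail on the co-occurrence count
# (under-representation of overlap).
member_exclusivity_p <- function(x, others_union, N) {
  a <- sum(x)
  u <- sum(others_union)
  k <- sum(x & others_union)
  phyper(k, a, N - a, u, lower.tail = TRUE)
}

module_score <- function(mat, members) {
  N <- nrow(mat)
  ps <- vapply(members, function(m) {
    others <- members[members != m]
    u <- rowSums(mat[, others, drop = FALSE]) > 0
    member_exclusivity_p(mat[, m] == 1, u, N)
  }, numeric(1))
  max(ps)
}

# every member must co-occur with the union of the others at most as often
# as expected under independence (the one-sided direction is exclusivity)
module_exclusive_direction <- function(mat, members) {
  N <- nrow(mat)
  all(vapply(members, function(m) {
    others <- members[members != m]
    u <- rowSums(mat[, others, drop = FALSE]) > 0
    x <- mat[, m] == 1
    sum(x & u) <= sum(x) * sum(u) / N
  }, logical(1)))
}

#' Mutual-exclusivity module search
#'
#' Groups features whose alterations rarely co-occur into candidate modules
#' with a network-free greedy search.  Starting from every eligible seed
#' feature, the candidate minimising the module score is added while the
#' score stays below `alpha`; the score is the worst member exclusivity
#' p-value, where a member is tested one-sidedly (hypergeometric lower tail)
#' for under-representation of co-occurrence against the union of the other
#' members.  Ties are broken towards larger union coverage, then
#' lexicographic feature name.  Duplicate member sets are removed and
#' modules are sorted by score.
#'
#' @param trial A [trial_data] object.
#' @param n_min Minimum number of altered patients for a candidate feature.
#' @param alpha Growth threshold on the module score.
#' @return A tibble of class `onco_modules`: one row per module with a
#'   `members` list-column, the patient count of the member union and the
#'   module score.  Empty (zero-row) when fewer than two features are
#'   eligible or no exclusive pair exists.
#' @export
find_mutex_modules <- function(trial, n_min = NULL, alpha = NULL) {
  cfg <- trial_config(trial)
  n_min <- n_min %||% cfg$n_min
  alpha <- alpha %||% cfg$mutex_alpha
  feats <- feature_names(trial)
  counts <- vapply(feats, function(f) sum(trial[[f]]), integer(1))
  cand <- feats[counts >= n_min]

  empty <- tibble(label = character(), members = list(),
                  n_members = integer(), union_count = integer(),
                  score = double())
  class(empty) <- c("onco_modules", class(tibble()))
  if (length(cand) < 2) return(empty)

  mat <- as.matrix(as_tibble(trial)[, cand])
  storage.mode(mat) <- "integer"

  grow_module <- function(seed) {
    members <- seed
    score <- Inf
    repeat {
      pool <- setdiff(cand, members)
      if (length(pool) == 0) break
      trials_ <- lapply(pool, function(p) {
        new_members <- c(members, p)
        if (!module_exclusive_direction(mat, new_members)) return(NULL)
        list(member = p, score = module_score(mat, new_members),
             coverage = sum(rowSums(mat[, new_members, drop = FALSE]) > 0))
      })
      trials_ <- trials_[!vapply(trials_, is.null, logical(1))]
      trials_ <- Filter(function(t) t$score < alpha, trials_)
      if (length(trials_) == 0) break
      scores <- vapply(trials_, `[[`, numeric(1), "score")
      coverages <- vapply(trials_, `[[`, numeric(1), "coverage")
      nms <- vapply(trials_, `[[`, character(1), "member")
      ord <- order(scores, -coverages, nms)
      best <- trials_[[ord[1]]]
      members <- c(members, best$member)
      score <- best$score
    }
    if (length(members) < 2) return(NULL)
    list(members = sort(members), score = score)
  }

  mods <- lapply(cand, grow_module)
  mods <- mods[!vapply(mods, is.null, logical(1))]
  if (length(mods) == 0) return(empty)

  keys <- vapply(mods, function(m) paste(m$members, collapse = ";"),
                 character(1))
  mods <- mods[!duplicated(keys)]
  out <- tibble(
    label = vapply(mods, function(m) paste(m$members, collapse = "."),
                   character(1)),
    members = lapply(mods, `[[`, "members"),
    n_members = vapply(mods, function(m) length(m$members), integer(1)),
    union_count = vapply(mods, function(m) {
      sum(rowSums(mat[, m$members, drop = FALSE]) > 0)
    }, integer(1)),
    score = vapply(mods, `[[`, numeric(1), "score")
  ) |>
    arrange(.data$score, .data$label)
  class(out) <- c("onco_modules", class(tibble()))
  out
}

#' Augment a trial with module union pseudo-features
#'
#' Adds one binary column per detected module and per configured custom
#' module (1 iff any member is altered).  Original feature columns are
#' retained; the feature metadata gains rows of class `MODULE` (detected)
#' or `CUSTOM` (user-supplied).
#'
#' @param trial A [trial_data] object.
#' @param modules An `onco_modules` tibble from [find_mutex_modules()]
#'   (or `NULL` for custom modules only).
#' @return A [trial_data] object with the augmented feature set.
#' @export
build_feature_set <- function(trial, modules = NULL) {
  cfg <- trial_config(trial)
  fm <- feature_meta(trial)
  data <- as_tibble(trial)

  add_union <- function(data, fm, name, members, class) {
    unknown <- setdiff(members, fm$feature)
    if (length(unknown) > 0) {
      abort(sprintf("module '%s' references unknown feature(s): %s",
                    name, paste(unknown, collapse = ", ")))
    }
    if (name %in% names(data)) return(list(data = data, fm = fm))
    u <- as.integer(rowSums(as.matrix(data[, members, drop = FALSE])) > 0)
    data[[name]] <- u
    fm <- dplyr::bind_rows(fm, tibble(
      feature = name, gene = paste(members, collapse = ";"), class = class
    ))
    list(data = data, fm = fm)
  }

  if (!is.null(modules) && nrow(modules) > 0) {
    for (i in seq_len(nrow(modules))) {
      res <- add_union(data, fm, modules$label[i], modules$members[[i]],
                       "MODULE")
      data <- res$data; fm <- res$fm
    }
  }
  for (name in names(cfg$custom_modules)) {
    res <- add_union(data, fm, name, cfg$custom_modules[[name]], "CUSTOM")
    data <- res$data; fm <- res$fm
  }
  new_trial_data(data, fm, cfg)
}
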