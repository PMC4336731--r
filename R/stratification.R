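# Enumeration of patient subgroups and classification trees, joint feature-set
# and operating-point selection, and aggregation of leaf performances into
# tree performance. The selection objective is
#   max over (i, j, theta_R, p, q, theta_H) of NPV(T_R^{i,j}, theta_R)
#                                            + PPV(T_H^{p,q}, theta_H)
# evaluated by resubstitution on the training fold. Because the two summands
# share no free variables, the joint argmax is found by maximizing each test
# separately; tests verify equivalence against a brute-force scan of the full
# cross product.
#
# Sign convention: a prediction is *positive* when the predicted probability
# is at or above the threshold (P_k >= theta_k) and *negative* below it;
# a negative first test suggests BMS.

SPLIT_VARS <- c("age", "sex", "diabetes")
SPLIT_LEVELS <- list(age = c("LE60", "GT60"),
                     sex = c("FEMALE", "MALE"),
                     diabetes = c("NO", "YES"))

#' Enumerate all leaf-level patient subgroups
#'
#' All conjunctions of \{unconstrained, level 1, level 2\} over age, sex and
#' diabetes: 3^3 = 27 distinct subgroups, in a fixed deterministic order
#' (diabetes varying slowest).
#'
#' @return List of 27 [subgroup_spec()] objects.
#' @export
enumerate_subgroups <- function() {
  grid <- expand.grid(age = c("ALL", "LE60", "GT60"),
                      sex = c("ALL", "FEMALE", "MALE"),
                      diabetes = c("ALL", "NO", "YES"),
                      stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    subgroup_spec(grid$age[i], grid$sex[i], grid$diabetes[i])
  })
}

# ---------------------------------------------------------------------------
# Classification trees

tree_leaf <- function(spec) list(type = "leaf", spec = spec)

tree_leaves <- function(tree) {
  if (tree$type == "leaf") return(list(tree$spec))
  c(tree_leaves(tree$left), tree_leaves(tree$right))
}

partition_key <- function(tree) {
  ids <- vapply(tree_leaves(tree), subgroup_id, character(1))
  paste(sort(ids), collapse = "|")
}

constrain <- function(spec, var, level) {
  s <- unclass(spec); s[[var]] <- level
  do.call(subgroup_spec, s)
}

gen_trees <- function(avail, spec) {
  out <- list(tree_leaf(spec))
  for (v in avail) {
    rest <- setdiff(avail, v)
    lv <- gen_trees(rest, constrain(spec, v, SPLIT_LEVELS[[v]][1]))
    rv <- gen_trees(rest, constrain(spec, v, SPLIT_LEVELS[[v]][2]))
    for (l in lv) for (r in rv) {
      out[[length(out) + 1L]] <- list(type = "split", var = v, left = l, right = r)
    }
  }
  out
}

#' Enumerate all candidate classification trees
#'
#' Trees split on age, sex and diabetes, each variable at most once per
#' root-to-leaf path, children split independently, with a leaf allowed at
#' any node (maximum depth four levels: three splits plus the leaf). The raw
#' enumeration of tree shapes is de-duplicated by the induced leaf-subgroup
#' partition, so each distinct partitioning of the population appears exactly
#' once, in deterministic order. The single-leaf tree (no splits) and the
#' full 8-leaf tree are always included.
#'
#' @param vars Split variables to use (default all three; restricting the
#'   set is mainly useful for validating the enumeration).
#' @return List of trees; each tree is a nested list of `split`/`leaf` nodes,
#'   leaves carrying their [subgroup_spec()].
#' @export
enumerate_trees <- function(vars = SPLIT_VARS) {
  raw <- gen_trees(vars, subgroup_spec())
  keys <- vapply(raw, partition_key, character(1))
  raw[!duplicated(keys)]
}

#' Route cohort rows to the leaves of a tree
#'
#' The leaves of every enumerated tree partition the population, so each
#' record matches exactly one leaf.
#'
#' @param tree A tree from [enumerate_trees()].
#' @param cohort Cohort data frame.
#' @return Integer vector of leaf indices (into `tree_leaves(tree)` order).
#' @export
route_to_leaf <- function(tree, cohort) {
  leaves <- tree_leaves(tree)
  idx <- rep(NA_integer_, nrow(cohort))
  for (i in seq_along(leaves)) {
    m <- subgroup_membership(cohort, leaves[[i]])
    idx[m] <- i
  }
  if (anyNA(idx)) stop("tree leaves do not cover the cohort")
  idx
}

# ---------------------------------------------------------------------------
# Operating points and confusion matrices

#' Thresholds realizing a grid of specificity levels
#'
#' For each level of the grid (5% to 95% in 5% steps; the trivial 0% and
#' 100% specificity operating points are excluded), returns the smallest
#' candidate threshold whose achieved specificity on the given scores is at
#' least the level, along with that achieved specificity. Candidate
#' thresholds are the observed score values plus a sentinel above the
#' maximum.
#'
#' @param scores Numeric predicted probabilities.
#' @param labels 0/1 labels; at least one negative required.
#' @param levels Specificity grid (default `seq(0.05, 0.95, by = 0.05)`).
#' @return Data frame with columns `level`, `threshold`, `achieved_spec`.
#' @export
thresholds_at_specificity <- function(scores, labels,
                                      levels = seq(0.05, 0.95, by = 0.05)) {
  stopifnot(length(scores) == length(labels))
  neg <- scores[labels == 0]
  if (length(neg) == 0) stop("at least one negative sample is required")
  cands <- c(sort(unique(scores)), max(scores) + 1)
  spec_at <- vapply(cands, function(t) mean(neg < t), numeric(1))
  thr <- numeric(length(levels)); ach <- numeric(length(levels))
  for (i in seq_along(levels)) {
    k <- which(spec_at >= levels[i] - 1e-12)[1]
    thr[i] <- cands[k]; ach[i] <- spec_at[k]
  }
  data.frame(level = levels, threshold = thr, achieved_spec = ach)
}

#' Confusion matrix at a decision threshold
#'
#' Predictions are positive iff `score >= threshold`.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold.
#' @return Object of class `confusion_matrix` with fields `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold) {
  pred <- scores >= threshold
  structure(list(tp = sum(pred & labels == 1),
                 fp = sum(pred & labels == 0),
                 fn = sum(!pred & labels == 1),
                 tn = sum(!pred & labels == 0)),
            class = "confusion_matrix")
}

confusion_add <- function(a, b) {
  structure(list(tp = a$tp + b$tp, fp = a$fp + b$fp,
                 fn = a$fn + b$fn, tn = a$tn + b$tn),
            class = "confusion_matrix")
}

confusion_total <- function(cm) cm$tp + cm$fp + cm$fn + cm$tn

#' Sensitivity, specificity, predictive values and prevalence
#'
#' @param cm A `confusion_matrix`.
#' @return List with `sens`, `spec`, `ppv`, `npv`, `prevalence`, `n`;
#'   entries are `NA` where the defining denominator is zero.
#' @export
classifier_performance <- function(cm) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  n <- confusion_total(cm)
  list(sens = div(cm$tp, cm$tp + cm$fn),
       spec = div(cm$tn, cm$tn + cm$fp),
       ppv = div(cm$tp, cm$tp + cm$fp),
       npv = div(cm$tn, cm$tn + cm$fn),
       prevalence = div(cm$tp + cm$fn, n),
       n = n)
}

# ---------------------------------------------------------------------------
# Candidate feature-set pairs and the exhaustive selection search

#' Candidate (clinical set, biomarker set) pairs for one test
#'
#' The four clinical options (C1, C2, C3, none) crossed with the four
#' biomarker options (B1, B2, B3, none): 16 pairs per test, hence at most
#' 16 x 27 = 432 classifiers per endpoint across all subgroups.
#'
#' @return Data frame with columns `clinical` and `biomarker`.
#' @export
candidate_pairs <- function() {
  expand.grid(clinical = c(CLINICAL_SET_IDS, "NONE"),
              biomarker = c(BIOMARKER_SET_IDS, "NONE"),
              stringsAsFactors = FALSE)
}

#' Size of the exhaustive feature-set and operating-point search
#'
#' Each candidate feature-set pair of each test contributes one evaluation
#' per threshold of the 19-level specificity grid; with a single pair per
#' test the search visits 2 x 19 = 38 cells, with all 16 pairs available per
#' test 2 x 19 x 16 = 608.
#'
#' @param n_pairs_r,n_pairs_h Number of candidate pairs for the restenosis
#'   and hazard test, respectively.
#' @param n_levels Number of specificity-grid levels (default 19).
#' @return Total number of (candidate, threshold) evaluations.
#' @export
selection_search_size <- function(n_pairs_r = 16L, n_pairs_h = 16L,
                                  n_levels = 19L) {
  n_levels * n_pairs_r + n_levels * n_pairs_h
}

set_index <- function(set_id, family_ids) {
  if (set_id == "NONE") 0L else match(set_id, family_ids)
}

# Exhaustive search over candidate pairs and thresholds for one test.
# `metric` is "npv" for the restenosis test, "ppv" for the hazard test.
# Candidates whose metric denominator is zero are excluded. Ties are broken
# by fewer total features, then lower (clinical, biomarker) set indices
# (none = 0), then lower grid level.
select_test_candidate <- function(cohort, spec, arm, endpoint, metric,
                                  catalog, penalty = 0.01,
                                  min_n = 100L, min_pos = 10L) {
  pairs <- candidate_pairs()
  best <- NULL
  n_candidates <- 0L
  n_evaluations <- 0L
  for (k in seq_len(nrow(pairs))) {
    cl <- pairs$clinical[k]; bm <- pairs$biomarker[k]
    sample <- filter_eligible(cohort, spec, cl, bm, arm, endpoint, catalog,
                              min_n = min_n, min_pos = min_pos)
    if (is.null(sample)) next
    model <- tryCatch(
      suppressWarnings(fit_l2_logistic(sample, penalty = penalty, catalog = catalog)),
      error = function(e) NULL)
    if (is.null(model)) {
      warning("skipping candidate (", cl, ", ", bm, ") for ",
              subgroup_id(spec), ": fit failed")
      next
    }
    n_candidates <- n_candidates + 1L
    scores <- predict_prob(model, sample$data, catalog)
    grid <- thresholds_at_specificity(scores, sample$y)
    n_evaluations <- n_evaluations + nrow(grid)
    n_feat <- length(sample$data)
    key_idx <- c(set_index(cl, CLINICAL_SET_IDS), set_index(bm, BIOMARKER_SET_IDS))
    for (g in seq_len(nrow(grid))) {
      cm <- confusion_at_threshold(scores, sample$y, grid$threshold[g])
      perf <- classifier_performance(cm)
      value <- perf[[metric]]
      if (is.na(value)) next
      cand <- list(model = model, threshold = grid$threshold[g],
                   level = grid$level[g], achieved_spec = grid$achieved_spec[g],
                   cm = cm, value = value, clinical_set = cl, biomarker_set = bm,
                   n_features = n_feat, key_idx = key_idx)
      if (is.null(best) || candidate_better(cand, best)) best <- cand
    }
  }
  if (is.null(best)) return(NULL)
  best$n_candidates <- n_candidates
  best$n_evaluations <- n_evaluations
  best
}

candidate_better <- function(a, b) {
  if (a$value != b$value) return(a$value > b$value)
  if (a$n_features != b$n_features) return(a$n_features < b$n_features)
  if (a$key_idx[1] != b$key_idx[1]) return(a$key_idx[1] < b$key_idx[1])
  if (a$key_idx[2] != b$key_idx[2]) return(a$key_idx[2] < b$key_idx[2])
  a$level < b$level
}

#' Select feature sets and operating points for one subgroup
#'
#' Trains restenosis-test candidates on the subgroup's BMS arm and
#' hazard-test candidates on its DES arm for every eligible feature-set
#' pair, evaluates every threshold of the specificity grid on the training
#' scores, and returns the pair of tests maximizing NPV(T_R) + PPV(T_H).
#' Since the two summands are optimized over disjoint variables, each test
#' is maximized independently; the result equals a brute-force scan of the
#' full cross product.
#'
#' @param spec A [subgroup_spec()].
#' @param cohort Training cohort data frame (training folds only).
#' @param endpoint_r Restenosis endpoint column for the first test.
#' @param endpoint_h Hazard endpoint column for the second test.
#' @param catalog A [feature_catalog()].
#' @param penalty Ridge penalty for every leaf model (default 0.01).
#' @param min_n,min_pos Eligibility thresholds.
#' @return Object of class `leaf_pair` (fitted models, thresholds, training
#'   confusion matrices, objective value, evaluation counts), or `NULL` when
#'   no eligible candidate exists for either test.
#' @export
select_pair_for_subgroup <- function(spec, cohort, endpoint_r, endpoint_h,
                                     catalog = feature_catalog(),
                                     penalty = 0.01,
                                     min_n = 100L, min_pos = 10L) {
  r <- select_test_candidate(cohort, spec, "BMS", endpoint_r, "npv",
                             catalog, penalty, min_n, min_pos)
  h <- select_test_candidate(cohort, spec, "DES", endpoint_h, "ppv",
                             catalog, penalty, min_n, min_pos)
  if (is.null(r) || is.null(h)) return(NULL)
  structure(
    list(subgroup = spec,
         model_R = r$model, theta_R = r$threshold, level_R = r$level,
         cm_R = r$cm, npv_R = r$value,
         model_H = h$model, theta_H = h$threshold, level_H = h$level,
         cm_H = h$cm, ppv_H = h$value,
         objective = r$value + h$value,
         n_candidates = c(R = r$n_candidates, H = h$n_candidates),
         n_evaluations = r$n_evaluations + h$n_evaluations),
    class = "leaf_pair"
  )
}

# ---------------------------------------------------------------------------
# Tree aggregation and selection

#' Aggregate leaf performances into tree performance
#'
#' Element-wise sums of the leaves' training confusion matrices, separately
#' for the restenosis and the hazard test; the tree objective is the NPV of
#' the aggregated restenosis matrix plus the PPV of the aggregated hazard
#' matrix. Trees with any leaf lacking a fitted pair are discarded
#' (signalled by returning `NULL`, not an error).
#'
#' @param tree A tree from [enumerate_trees()].
#' @param leaf_pairs Named list mapping [subgroup_id()] to `leaf_pair`
#'   objects (entries may be `NULL` for ineligible subgroups).
#' @return List with `tree`, `leaf_ids`, `cm_R`, `cm_H`, `objective`,
#'   `n_leaves`, or `NULL` if a leaf is missing.
#' @export
aggregate_tree <- function(tree, leaf_pairs) {
  leaves <- tree_leaves(tree)
  ids <- vapply(leaves, subgroup_id, character(1))
  pairs <- leaf_pairs[ids]
  if (any(vapply(pairs, is.null, logical(1)))) return(NULL)
  cm_R <- Reduce(confusion_add, lapply(pairs, `[[`, "cm_R"))
  cm_H <- Reduce(confusion_add, lapply(pairs, `[[`, "cm_H"))
  npv <- classifier_performance(cm_R)$npv
  ppv <- classifier_performance(cm_H)$ppv
  if (is.na(npv) || is.na(ppv)) return(NULL)
  list(tree = tree, leaf_ids = ids, cm_R = cm_R, cm_H = cm_H,
       objective = npv + ppv, n_leaves = length(ids))
}

#' Pick the best classification tree
#'
#' Maximal aggregated objective; ties broken by fewer leaves, then by
#' enumeration order.
#'
#' @param aggregates List of non-`NULL` results of [aggregate_tree()].
#' @return The winning element of `aggregates`.
#' @export
select_best_tree <- function(aggregates) {
  if (length(aggregates) == 0) stop("no valid classification tree")
  best <- 1L
  for (i in seq_along(aggregates)[-1]) {
    a <- aggregates[[i]]; b <- aggregates[[best]]
    if (a$objective > b$objective ||
        (a$objective == b$objective && a$n_leaves < b$n_leaves)) {
      best <- i
    }
  }
  aggregates[[best]]
}

#' Train the full two-test cascade on a training cohort
#'
#' Fits subgroup-specific leaf pairs for every subgroup with eligible data,
#' scores every candidate classification tree by its aggregated training
#' objective, and returns the winning tree with its leaf models. In
#' `global_mode` no partitioning is performed: only the universal subgroup
#' and the single-leaf tree are used, yielding a conventional population-wide
#' pair of classifiers.
#'
#' @param cohort Training cohort data frame.
#' @param endpoint_r,endpoint_h Endpoint columns for the two tests.
#' @param catalog A [feature_catalog()].
#' @param penalty Ridge penalty (default 0.01).
#' @param min_n,min_pos Eligibility thresholds.
#' @param global_mode Logical; fit a single population-wide pair instead of
#'   subgroup-specific ones.
#' @return Object of class `fitted_cascade`: the selected tree, its leaf
#'   specs and `leaf_pair`s, aggregated training confusion matrices, the
#'   objective, and the count of leaf classifiers fitted across all
#'   subgroups.
#' @export
train_cascade <- function(cohort, endpoint_r, endpoint_h,
                          catalog = feature_catalog(), penalty = 0.01,
                          min_n = 100L, min_pos = 10L, global_mode = FALSE) {
  subgroups <- if (global_mode) list(subgroup_spec()) else enumerate_subgroups()
  leaf_pairs <- list()
  for (sg in subgroups) {
    leaf_pairs[[subgroup_id(sg)]] <-
      select_pair_for_subgroup(sg, cohort, endpoint_r, endpoint_h, catalog,
                               penalty, min_n, min_pos)
  }
  trees <- if (global_mode) list(tree_leaf(subgroup_spec())) else enumerate_trees()
  aggregates <- list()
  for (tr in trees) {
    agg <- aggregate_tree(tr, leaf_pairs)
    if (!is.null(agg)) aggregates[[length(aggregates) + 1L]] <- agg
  }
  best <- select_best_tree(aggregates)
  fitted <- vapply(leaf_pairs, Negate(is.null), logical(1))
  structure(
    list(tree = best$tree,
         leaf_ids = best$leaf_ids,
         leaf_pairs = leaf_pairs[best$leaf_ids],
         cm_R = best$cm_R, cm_H = best$cm_H,
         objective = best$objective,
         endpoint_r = endpoint_r, endpoint_h = endpoint_h,
         penalty = penalty, global_mode = global_mode,
         n_trees_compared = length(aggregates),
         n_subgroups_fitted = sum(fitted),
         n_leaf_classifiers = sum(vapply(
           leaf_pairs[fitted], function(p) sum(p$n_candidates), numeric(1)))),
    class = "fitted_cascade"
  )
}

#' @export
print.fitted_cascade <- function(x, ...) {
  cat("<fitted cascade:", length(x$leaf_ids), "leaves [",
      paste(x$leaf_ids, collapse = "; "), "], objective =",
      round(x$objective, 4), ">\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Cascade serialization

tree_to_list <- function(tree) {
  if (tree$type == "leaf") {
    list(type = "leaf", spec = unclass(tree$spec))
  } else {
    list(type = "split", var = tree$var,
         left = tree_to_list(tree$left), right = tree_to_list(tree$right))
  }
}

tree_from_list <- function(x) {
  if (x$type == "leaf") {
    tree_leaf(do.call(subgroup_spec, x$spec))
  } else {
    list(type = "split", var = x$var,
         left = tree_from_list(x$left), right = tree_from_list(x$right))
  }
}

leaf_pair_to_list <- function(p) {
  list(subgroup = unclass(p$subgroup),
       model_R = model_to_list(p$model_R), theta_R = p$theta_R,
       level_R = p$level_R, cm_R = unclass(p$cm_R), npv_R = p$npv_R,
       model_H = model_to_list(p$model_H), theta_H = p$theta_H,
       level_H = p$level_H, cm_H = unclass(p$cm_H), ppv_H = p$ppv_H,
       objective = p$objective)
}

leaf_pair_from_list <- function(x) {
  structure(
    list(subgroup = do.call(subgroup_spec, x$subgroup),
         model_R = model_from_list(x$model_R), theta_R = x$theta_R,
         level_R = x$level_R,
         cm_R = structure(x$cm_R, class = "confusion_matrix"), npv_R = x$npv_R,
         model_H = model_from_list(x$model_H), theta_H = x$theta_H,
         level_H = x$level_H,
         cm_H = structure(x$cm_H, class = "confusion_matrix"), ppv_H = x$ppv_H,
         objective = x$objective),
    class = "leaf_pair"
  )
}

#' Serialize a fitted cascade to JSON
#' @param cascade A `fitted_cascade`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cascade_json <- function(cascade, path) {
  x <- list(tree = tree_to_list(cascade$tree),
            leaf_ids = cascade$leaf_ids,
            leaf_pairs = lapply(cascade$leaf_pairs, leaf_pair_to_list),
            cm_R = unclass(cascade$cm_R), cm_H = unclass(cascade$cm_H),
            objective = cascade$objective,
            endpoint_r = cascade$endpoint_r, endpoint_h = cascade$endpoint_h,
            penalty = cascade$penalty, global_mode = cascade$global_mode)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a cascade serialized with [write_cascade_json()]
#' @param path JSON file path.
#' @return A `fitted_cascade`.
#' @export
read_cascade_json <- function(path) {
  x <- jsonlite::read_json(path)
  structure(
    list(tree = tree_from_list(x$tree),
         leaf_ids = unlist(x$leaf_ids),
         leaf_pairs = setNames(lapply(x$leaf_pairs, leaf_pair_from_list),
                               names(x$leaf_pairs)),
         cm_R = structure(x$cm_R, class = "confusion_matrix"),
         cm_H = structure(x$cm_H, class = "confusion_matrix"),
         objective = x$objective,
         endpoint_r = x$endpoint_r, endpoint_h = x$endpoint_h,
         penalty = x$penalty, global_mode = x$global_mode),
    class = "fitted_cascade"
  )
}
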