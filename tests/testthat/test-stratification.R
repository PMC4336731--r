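test_that("subgroup enumeration yields 27 distinct subgroups including the universal one", {
  sgs <- enumerate_subgroups()
  expect_length(sgs, 27L)
  ids <- vapply(sgs, subgroup_id, character(1))
  expect_false(any(duplicated(ids)))
  expect_true("ALL/ALL/ALL" %in% ids)
})

# Independent oracle for the tree enumeration: enumerate ALL set partitions of
# the eight fully-specified cells and keep those realizable by hierarchical
# guillotine splits (either the whole cube, or some variable separates every
# block and both halves are recursively realizable). This characterization
# never builds a tree, so it is structurally independent of the enumerator.
guillotine_partitions <- function(vars) {
  cells <- do.call(expand.grid, c(lapply(vars, function(v) c(1L, 2L)),
                                  list(stringsAsFactors = FALSE)))
  names(cells) <- vars
  cell_ids <- seq_len(nrow(cells))
  set_partitions <- function(elems) {
    if (length(elems) == 0) return(list(list()))
    first <- elems[1]
    out <- list()
    for (p in set_partitions(elems[-1])) {
      for (i in seq_along(p)) {
        q <- p; q[[i]] <- c(first, q[[i]])
        out[[length(out) + 1L]] <- q
      }
      out[[length(out) + 1L]] <- c(p, list(first))
    }
    out
  }
  valid <- function(blocks, scope, avail) {
    if (length(blocks) == 1 && setequal(blocks[[1]], scope)) return(TRUE)
    for (v in avail) {
      h1 <- scope[cells[[v]][match(scope, cell_ids)] == 1L]
      h2 <- setdiff(scope, h1)
      in1 <- vapply(blocks, function(b) all(b %in% h1), logical(1))
      in2 <- vapply(blocks, function(b) all(b %in% h2), logical(1))
      if (all(in1 | in2) &&
          valid(blocks[in1], h1, setdiff(avail, v)) &&
          valid(blocks[in2], h2, setdiff(avail, v))) return(TRUE)
    }
    FALSE
  }
  parts <- set_partitions(cell_ids)
  keep <- vapply(parts, valid, logical(1), scope = cell_ids, avail = vars)
  parts <- parts[keep]
  canon <- vapply(parts, function(p) {
    paste(sort(vapply(p, function(b) paste(sort(b), collapse = ","),
                      character(1))), collapse = "|")
  }, character(1))
  sort(canon)
}

# canonical cell-partition key of a tree, for comparison with the oracle
tree_cell_key <- function(tree, vars) {
  cells <- do.call(expand.grid, c(lapply(vars, function(v) c(1L, 2L)),
                                  list(stringsAsFactors = FALSE)))
  names(cells) <- vars
  lv1 <- list(age = "LE60", sex = "FEMALE", diabetes = "NO")
  blocks <- vapply(stentstrat:::tree_leaves(tree), function(spec) {
    keep <- rep(TRUE, nrow(cells))
    for (v in vars) {
      if (spec[[v]] != "ALL") {
        keep <- keep & (cells[[v]] == (if (spec[[v]] == lv1[[v]]) 1L else 2L))
      }
    }
    paste(sort(which(keep)), collapse = ",")
  }, character(1))
  paste(sort(blocks), collapse = "|")
}

test_that("tree enumeration matches the brute-force guillotine-partition oracle", {
  trees2 <- enumerate_trees(vars = c("age", "sex"))
  expect_length(trees2, 8L)
  expect_setequal(vapply(trees2, tree_cell_key, character(1), vars = c("age", "sex")),
                  guillotine_partitions(c("age", "sex")))
  trees3 <- enumerate_trees()
  oracle3 <- guillotine_partitions(c("age", "sex", "diabetes"))
  expect_length(trees3, length(oracle3))
  expect_setequal(vapply(trees3, tree_cell_key, character(1),
                         vars = c("age", "sex", "diabetes")), oracle3)
  n_leaves <- vapply(trees3, function(t) length(stentstrat:::tree_leaves(t)),
                     integer(1))
  expect_true(any(n_leaves == 1L))  # the no-split tree
  expect_true(any(n_leaves == 8L))  # the full three-split tree
})

test_that("every enumerated tree partitions an arbitrary cohort (exactly one leaf per record)", {
  set.seed(11)
  co <- toy_cohort(40, age = runif(40, 30, 90))
  co$sex <- sample(c("female", "male"), 40, replace = TRUE)
  co$diabetes <- sample(c("no", "yes"), 40, replace = TRUE)
  for (tr in enumerate_trees()) {
    leaves <- stentstrat:::tree_leaves(tr)
    hits <- rowSums(sapply(leaves, function(sg) subgroup_membership(co, sg)))
    expect_true(all(hits == 1))
  }
})

test_that("the specificity grid has 19 levels with correct smallest thresholds", {
  set.seed(12)
  neg <- sort(runif(20))  # 20 distinct negative scores
  scores <- c(neg, 0.99)
  labels <- c(rep(0, 20), 1)
  grid <- thresholds_at_specificity(scores, labels)
  expect_equal(nrow(grid), 19L)
  expect_equal(grid$level, seq(0.05, 0.95, by = 0.05))
  row50 <- grid[grid$level == 0.5, ]
  # smallest threshold with >= 50% of negatives below it: just above the
  # 10th smallest negative, i.e. the 11th
  expect_equal(row50$threshold, neg[11])
  expect_equal(row50$achieved_spec, 0.5)
  expect_error(thresholds_at_specificity(c(0.1, 0.9), c(1, 1)), "negative")
})

test_that("tied negative scores collapse every level to one threshold with specificity 1", {
  grid <- thresholds_at_specificity(rep(0.3, 15), rep(0, 15))
  expect_equal(unique(grid$threshold), 1.3)
  expect_true(all(grid$achieved_spec == 1))
})

test_that("achieved specificity dominates its level and thresholds are monotone", {
  set.seed(13)
  for (i in 1:20) {
    scores <- round(runif(50), 2)  # forces ties
    labels <- rep_len(c(0, 0, 1), 50)
    grid <- thresholds_at_specificity(scores, labels)
    expect_true(all(grid$achieved_spec >= grid$level - 1e-12))
    expect_true(all(diff(grid$threshold) >= 0))
  }
})

test_that("confusion matrices tabulate the >= threshold rule", {
  cm <- confusion_at_threshold(c(0.2, 0.6, 0.7), c(0, 1, 0), 0.5)
  expect_equal(unclass(cm)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 0L, tn = 1L))
  all_pos <- confusion_at_threshold(c(0.2, 0.6), c(1, 0), 0)
  expect_equal(all_pos$fn + all_pos$tn, 0L)
  all_neg <- confusion_at_threshold(c(0.2, 0.6), c(1, 0), 0.61)
  expect_equal(all_neg$tp + all_neg$fp, 0L)
  perf <- classifier_performance(cm)
  expect_equal(perf$prevalence, 1 / 3)
  expect_equal(perf$n, 3L)
})

test_that("the candidate search space matches its documented combinatorics", {
  expect_equal(nrow(candidate_pairs()), 16L)
  expect_equal(length(enumerate_subgroups()) * nrow(candidate_pairs()), 432L)
  expect_equal(selection_search_size(1, 1), 38L)
  expect_equal(selection_search_size(16, 16), 608L)
})

test_that("pair selection equals a brute-force scan over every (candidate, threshold) cell", {
  co <- fully_observed_cohort(120, 120, seed = 14)
  sg <- subgroup_spec()
  got <- select_pair_for_subgroup(sg, co, "angio_restenosis_6m", "hazard_1y")
  expect_s3_class(got, "leaf_pair")
  r_cells <- brute_force_cells(co, sg, "BMS", "angio_restenosis_6m", "npv")
  h_cells <- brute_force_cells(co, sg, "DES", "hazard_1y", "ppv")
  expect_gt(nrow(r_cells), 19)  # more than one candidate pair was eligible
  best_joint <- max(outer(r_cells$value, h_cells$value, "+"))
  expect_equal(got$objective, best_joint, tolerance = 1e-12)
  expect_equal(got$npv_R, max(r_cells$value), tolerance = 1e-12)
  expect_equal(got$ppv_H, max(h_cells$value), tolerance = 1e-12)

  # the implementation's evaluation count matches the visited cells plus the
  # excluded zero-denominator cells it also visited
  expect_equal(got$n_evaluations,
               19L * (got$n_candidates[["R"]] + got$n_candidates[["H"]]))

  # tie-break oracle on the restenosis side: among value ties, fewer
  # features, then lower set indices (none = 0), then lower level
  idx <- function(set, fam) ifelse(set == "NONE", 0L, match(set, fam))
  rr <- r_cells[r_cells$value == max(r_cells$value), ]
  rr <- rr[order(rr$n_features, idx(rr$clinical, c("C1", "C2", "C3")),
                 idx(rr$biomarker, c("B1", "B2", "B3")), rr$level), ]
  expect_equal(got$model_R$clinical_set, rr$clinical[1])
  expect_equal(got$model_R$biomarker_set, rr$biomarker[1])
  expect_equal(got$theta_R, rr$threshold[1])
})

test_that("a perfectly predictive feature drives the selected restenosis test to NPV 1", {
  co <- fully_observed_cohort(150, 150, seed = 15)
  co$angio_restenosis_6m <- as.integer(co$crp > 0.8)  # deterministic outcome
  got <- select_pair_for_subgroup(subgroup_spec(), co,
                                  "angio_restenosis_6m", "hazard_1y")
  expect_equal(got$npv_R, 1)
  expect_equal(got$cm_R$fn, 0L)
})

test_that("tree aggregation sums leaf confusion matrices element-wise", {
  mk_cm <- function(tp, fp, fn, tn) {
    structure(list(tp = tp, fp = fp, fn = fn, tn = tn),
              class = "confusion_matrix")
  }
  mk_pair <- function(cm_r, cm_h) {
    structure(list(cm_R = cm_r, cm_H = cm_h), class = "leaf_pair")
  }
  leaf_pairs <- list(
    "LE60/ALL/ALL" = mk_pair(mk_cm(5, 1, 2, 10), mk_cm(2, 2, 1, 9)),
    "GT60/ALL/ALL" = mk_pair(mk_cm(3, 2, 1, 8), mk_cm(1, 1, 2, 7)),
    "ALL/ALL/ALL" = mk_pair(mk_cm(9, 9, 9, 9), mk_cm(3, 1, 1, 3))
  )
  split_tree <- list(type = "split", var = "age",
                     left = stentstrat:::tree_leaf(subgroup_spec("LE60")),
                     right = stentstrat:::tree_leaf(subgroup_spec("GT60")))
  agg <- aggregate_tree(split_tree, leaf_pairs)
  expect_equal(unclass(agg$cm_R)[c("tp", "fp", "fn", "tn")],
               list(tp = 8, fp = 3, fn = 3, tn = 18))
  expect_equal(stentstrat:::confusion_total(agg$cm_R),
               stentstrat:::confusion_total(leaf_pairs[[1]]$cm_R) +
                 stentstrat:::confusion_total(leaf_pairs[[2]]$cm_R))
  expect_equal(agg$objective, 18 / (18 + 3) + 3 / (3 + 3))

  single <- stentstrat:::tree_leaf(subgroup_spec())
  agg1 <- aggregate_tree(single, leaf_pairs)
  expect_equal(agg1$cm_R, leaf_pairs[["ALL/ALL/ALL"]]$cm_R)

  # a missing leaf discards the tree without raising
  expect_null(aggregate_tree(split_tree, leaf_pairs["ALL/ALL/ALL"]))
})

test_that("tree selection maximizes the aggregated objective with documented tie-breaks", {
  mk_agg <- function(obj, n_leaves, id) {
    list(objective = obj, n_leaves = n_leaves, id = id)
  }
  aggs <- list(mk_agg(1.3, 1, "a"), mk_agg(1.5, 4, "b"), mk_agg(1.2, 2, "c"))
  expect_equal(select_best_tree(aggs)$id, "b")
  expect_equal(select_best_tree(aggs[1])$id, "a")
  # tie: fewer leaves wins, then enumeration order
  tied <- list(mk_agg(1.5, 4, "x"), mk_agg(1.5, 2, "y"), mk_agg(1.5, 2, "z"))
  expect_equal(select_best_tree(tied)$id, "y")
  expect_error(select_best_tree(list()), "no valid")
  # brute-force re-evaluation agreement
  objs <- vapply(aggs, `[[`, numeric(1), "objective")
  expect_equal(select_best_tree(aggs)$objective, max(objs))
})
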