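# Repeated stratified k-fold cross-validation of the full pipeline.
# Training (leaf fitting, feature-set and operating-point selection, tree
# selection) happens strictly on the training folds of each iteration;
# held-out predictions are pooled across the k folds of a repetition
# (micro-pooling) before effectiveness and cost estimation. Confidence
# intervals are empirical percentiles across repetitions.

#' The four endpoint pairings analysed by the pipeline
#'
#' Restenosis outcome for the first test paired with the hazard horizon of
#' the second: angiographic restenosis at 6 months with 1- or 3-year
#' hazardous events, and clinical restenosis (target lesion
#' revascularization) at the matching 1- or 3-year horizon.
#'
#' @return Data frame with columns `label`, `endpoint_r`, `endpoint_h`.
#' @export
endpoint_pairs <- function() {
  data.frame(
    label = c("angio6m_hazard1y", "angio6m_hazard3y",
              "clin1y_hazard1y", "clin3y_hazard3y"),
    endpoint_r = c("angio_restenosis_6m", "angio_restenosis_6m",
                   "clin_restenosis_1y", "clin_restenosis_3y"),
    endpoint_h = c("hazard_1y", "hazard_3y", "hazard_1y", "hazard_3y"),
    stringsAsFactors = FALSE
  )
}

#' Cross-validation analysis configuration
#'
#' @param endpoint_r,endpoint_h Endpoint columns for the two tests (see
#'   [endpoint_pairs()]).
#' @param k Number of folds (default 10).
#' @param repetitions Number of repeated CV runs (300 for CI-quality
#'   estimates; smaller values keep exploratory runs fast).
#' @param seed Integer seed governing every random split.
#' @param constants A [literature_constants()].
#' @param costs A [cost_table()].
#' @param penalty Ridge penalty for all leaf models (default 0.01).
#' @param min_n,min_pos Eligibility thresholds.
#' @param global_mode Fit a single population-wide classifier pair instead
#'   of subgroup-specific ones.
#' @return Object of class `analysis_config`.
#' @export
analysis_config <- function(endpoint_r = "angio_restenosis_6m",
                            endpoint_h = "hazard_1y",
                            k = 10L, repetitions = 10L, seed = 1L,
                            constants = literature_constants(),
                            costs = cost_table(),
                            penalty = 0.01, min_n = 100L, min_pos = 10L,
                            global_mode = FALSE) {
  stopifnot(k >= 2, repetitions >= 1,
            endpoint_r %in% RESTENOSIS_ENDPOINTS,
            endpoint_h %in% HAZARD_ENDPOINTS)
  structure(
    list(endpoint_r = endpoint_r, endpoint_h = endpoint_h,
         k = as.integer(k), repetitions = as.integer(repetitions),
         seed = as.integer(seed), constants = constants, costs = costs,
         penalty = penalty, min_n = min_n, min_pos = min_pos,
         global_mode = global_mode),
    class = "analysis_config"
  )
}

#' Empirical percentile confidence interval
#'
#' 2.5th and 97.5th percentiles (for the default 95% level) of the
#' repetition distribution, using the linear-interpolation quantile
#' convention (type 7, the R default).
#'
#' @param values Numeric vector, at least two values.
#' @param level Confidence level (default 0.95).
#' @return Named vector `c(low, high)`.
#' @export
percentile_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("at least two values are required")
  a <- (1 - level) / 2
  q <- quantile(values, c(a, 1 - a), type = 7, names = FALSE)
  c(low = q[1], high = q[2])
}

# Stratified fold assignment: endpoint label within treatment arm (BMS
# records by the restenosis label, DES records by the hazard label, with
# missing labels as their own stratum) so small subgroups keep both classes
# in every fold where possible.
stratified_folds <- function(cohort, k, endpoint_r, endpoint_h) {
  label <- ifelse(cohort$treatment == "BMS",
                  cohort[[endpoint_r]], cohort[[endpoint_h]])
  strata <- paste(cohort$treatment, ifelse(is.na(label), "na", label))
  folds <- integer(nrow(cohort))
  for (s in unique(strata)) {
    rows <- which(strata == s)
    folds[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  folds
}

#' Repeated k-fold cross-validation of the stratification pipeline
#'
#' Per repetition: a fresh stratified k-fold split; per fold, the cascade is
#' trained on the other folds (leaf fitting, selection and tree choice use
#' training data only) and applied to the held-out fold; held-out
#' predictions are pooled across folds and summarized into AUCs,
#' effectiveness estimates, baseline comparison and costs. Deterministic
#' given `config$seed`.
#'
#' @param cohort Cohort data frame.
#' @param config An [analysis_config()].
#' @param catalog A [feature_catalog()].
#' @return Object of class `cv_result`: data frame `repetitions` (one row
#'   per repetition) and list `summary` (per metric: median and 95%
#'   percentile CI).
#' @export
repeated_cv <- function(cohort, config = analysis_config(),
                        catalog = feature_catalog()) {
  set.seed(config$seed)
  rep_seeds <- sample.int(.Machine$integer.max, config$repetitions)
  rows <- vector("list", config$repetitions)
  for (r in seq_len(config$repetitions)) {
    set.seed(rep_seeds[r])
    folds <- stratified_folds(cohort, config$k, config$endpoint_r,
                              config$endpoint_h)
    sugg_all <- NULL; test_all <- NULL
    tree_keys <- character(config$k)
    n_classifiers <- 0
    for (j in seq_len(config$k)) {
      train <- cohort[folds != j, , drop = FALSE]
      test <- cohort[folds == j, , drop = FALSE]
      cascade <- train_cascade(train, config$endpoint_r, config$endpoint_h,
                               catalog, config$penalty, config$min_n,
                               config$min_pos, config$global_mode)
      tree_keys[j] <- paste(sort(cascade$leaf_ids), collapse = "|")
      n_classifiers <- n_classifiers + cascade$n_leaf_classifiers
      sugg <- suppressWarnings(suggest_treatment(cascade, test, catalog))
      sugg_all <- rbind(sugg_all, sugg)
      test_all <- rbind(test_all, test)
    }
    ev <- evaluate_from_suggestions(sugg_all, test_all, config$endpoint_r,
                                    config$endpoint_h, config$constants)
    costs <- tryCatch(estimate_costs(ev, config$costs), error = function(e) NULL)
    cmp <- if (is.null(ev$proposed) || is.null(ev$baseline)) NULL else
      compare_workflows(ev$proposed$p_adverse, ev$baseline$p_adverse)
    rows[[r]] <- data.frame(
      repetition = r,
      auc_r = ev$auc_r, auc_h = ev$auc_h,
      p_sbms = ev$p_treat[["sBMS"]], p_sdes = ev$p_treat[["sDES"]],
      p_scabg = ev$p_treat[["sCABG"]],
      p_restenosis = null_na(ev$proposed, "p_restenosis"),
      p_hazard = null_na(ev$proposed, "p_hazard"),
      p_adverse_proposed = null_na(ev$proposed, "p_adverse"),
      p_adverse_baseline = null_na(ev$baseline, "p_adverse"),
      delta_adverse = if (is.null(cmp)) NA_real_ else cmp$absolute_delta,
      relative_reduction = if (is.null(cmp)) NA_real_ else cmp$relative_reduction,
      initial_proposed = null_na(costs, "initial_proposed"),
      corrective_proposed = null_na(costs, "corrective_proposed"),
      initial_baseline = null_na(costs, "initial_baseline"),
      corrective_baseline = null_na(costs, "corrective_baseline"),
      total_savings = null_na(costs, "total_savings"),
      savings_pct = null_na(costs, "savings_pct"),
      n_eval = ev$n_eval,
      n_leaf_classifiers = n_classifiers,
      tree_id = names(sort(table(tree_keys), decreasing = TRUE))[1],
      stringsAsFactors = FALSE
    )
  }
  reps <- do.call(rbind, rows)
  metrics <- setdiff(names(reps), c("repetition", "tree_id"))
  summary <- lapply(setNames(metrics, metrics), function(m) {
    v <- reps[[m]][!is.na(reps[[m]])]
    if (length(v) == 0) return(list(median = NA_real_, ci = c(low = NA_real_, high = NA_real_)))
    list(median = median(v),
         ci = if (length(v) >= 2) percentile_ci(v) else c(low = v, high = v))
  })
  structure(list(repetitions = reps, summary = summary, config = config),
            class = "cv_result")
}

null_na <- function(x, field) if (is.null(x)) NA_real_ else x[[field]]

# Pooled-evaluation core shared by evaluate_cascade (single split) and
# repeated_cv (micro-pooled folds): computes everything downstream of the
# per-record scores and suggestions.
evaluate_from_suggestions <- function(sugg, cohort, ep_r, ep_h,
                                      constants = literature_constants()) {
  bms_rows <- !is.na(cohort$treatment) & cohort$treatment == "BMS" &
    !is.na(cohort[[ep_r]]) & sugg$scoreable_r
  des_rows <- !is.na(cohort$treatment) & cohort$treatment == "DES" &
    !is.na(cohort[[ep_h]]) & sugg$scoreable_h
  cm_r <- confusion_from_rows(sugg$p_r[bms_rows], cohort[[ep_r]][bms_rows],
                              sugg$theta_r[bms_rows])
  cm_h <- confusion_from_rows(sugg$p_h[des_rows], cohort[[ep_h]][des_rows],
                              sugg$theta_h[des_rows])
  perf_r <- classifier_performance(cm_r)
  perf_h <- classifier_performance(cm_h)
  # AUC per leaf classifier, then the median: scores from different leaf
  # models live on different scales, so pooling them into one ranking would
  # conflate calibration with discrimination
  auc_r <- median_leaf_auc(sugg$p_r[bms_rows], cohort[[ep_r]][bms_rows],
                           sugg$leaf_id[bms_rows])
  auc_h <- median_leaf_auc(sugg$p_h[des_rows], cohort[[ep_h]][des_rows],
                           sugg$leaf_id[des_rows])
  p_sbms <- est_with_na(est_p_sbms, perf_r$prevalence, perf_r$sens, perf_r$spec)
  p_sdes <- if (is.na(p_sbms)) NA_real_ else
    est_with_na(est_p_sdes, p_sbms, perf_h$prevalence, perf_h$sens, perf_h$spec)
  p_scabg <- if (is.na(p_sbms) || is.na(p_sdes)) NA_real_ else
    est_p_scabg(p_sbms, p_sdes)
  p_treat <- c(sBMS = p_sbms, sDES = p_sdes, sCABG = p_scabg)
  counted <- c(sBMS = mean(sugg$suggestion == "sBMS"),
               sDES = mean(sugg$suggestion == "sDES"),
               sCABG = mean(sugg$suggestion == "sCABG"))
  conds <- conditional_adverse_estimates(perf_r, perf_h, sugg, cohort, ep_r, ep_h)
  proposed <- if (anyNA(p_treat)) NULL else
    tryCatch(total_adverse(p_treat, conds, constants), error = function(e) NULL)
  des_arm <- !is.na(cohort$treatment) & cohort$treatment == "DES"
  p_rest_des <- rate_or_na(cohort[[ep_r]][des_arm])
  p_haz_des <- rate_or_na(cohort[[ep_h]][des_arm])
  tv_rate <- rate_or_na(as.numeric(cohort$three_vessel == "yes"))
  baseline <- if (anyNA(c(p_rest_des, p_haz_des, tv_rate))) NULL else
    baseline_effectiveness(p_rest_des, p_haz_des, tv_rate, constants)
  structure(
    list(auc_r = auc_r, auc_h = auc_h,
         cm_r = cm_r, cm_h = cm_h, perf_r = perf_r, perf_h = perf_h,
         p_treat = p_treat, p_treat_counted = counted,
         conditionals = conds, proposed = proposed, baseline = baseline,
         p_rest_des = p_rest_des, p_haz_des = p_haz_des,
         three_vessel_rate = tv_rate,
         n_eval = nrow(cohort), n_bms_scored = sum(bms_rows),
         n_des_scored = sum(des_rows), suggestions = sugg,
         endpoint_r = ep_r, endpoint_h = ep_h),
    class = "cascade_evaluation"
  )
}

median_leaf_auc <- function(scores, labels, leaf_ids) {
  vals <- c()
  for (id in unique(leaf_ids)) {
    rows <- leaf_ids == id
    if (length(unique(labels[rows])) == 2) {
      vals <- c(vals, roc_auc(scores[rows], labels[rows]))
    }
  }
  if (length(vals) == 0) NA_real_ else median(vals)
}

#' Compare proposed and baseline workflow effectiveness
#'
#' @param proposed_adverse,baseline_adverse Adverse-effect probabilities of
#'   the two workflows on the same evaluation population.
#' @return List with `absolute_delta` (baseline minus proposed),
#'   `relative_reduction` (delta over baseline; `NA` with
#'   `relative_defined = FALSE` when the baseline is zero).
#' @export
compare_workflows <- function(proposed_adverse, baseline_adverse) {
  check_prob(proposed_adverse, baseline_adverse)
  delta <- baseline_adverse - proposed_adverse
  if (baseline_adverse == 0) {
    return(list(absolute_delta = delta, relative_reduction = NA_real_,
                relative_defined = delta == 0))
  }
  list(absolute_delta = delta, relative_reduction = delta / baseline_adverse,
       relative_defined = TRUE)
}

#' Subgroup-specific versus population-wide discrimination
#'
#' Focused experiment contrasting the two modelling modes on one endpoint
#' and arm with a fixed feature list: eight leaf-subgroup models versus one
#' global model, trained on a stratified split and compared by held-out
#' AUC. Leaves whose training data lack either class are dropped from both
#' AUCs so the comparison covers the same records.
#'
#' @param cohort Cohort data frame.
#' @param endpoint Endpoint column.
#' @param arm Treatment arm providing the labels.
#' @param features Feature columns used by every model.
#' @param train_frac Fraction of records used for training (default 0.7).
#' @param penalty Ridge penalty.
#' @param seed Seed for the split.
#' @param catalog A [feature_catalog()].
#' @return List with `auc_subgroup`, `auc_global`, `n_train`, `n_test`.
#' @export
compare_subgroup_global <- function(cohort, endpoint, arm, features,
                                    train_frac = 0.7, penalty = 0.01,
                                    seed = 1L, catalog = feature_catalog()) {
  set.seed(seed)
  usable <- !is.na(cohort$treatment) & cohort$treatment == arm &
    !is.na(cohort[[endpoint]]) &
    rowSums(is.na(cohort[, features, drop = FALSE])) == 0
  data <- cohort[usable, , drop = FALSE]
  y <- data[[endpoint]]
  strat <- paste(y)
  train_idx <- logical(nrow(data))
  for (s in unique(strat)) {
    rows <- which(strat == s)
    n_tr <- round(train_frac * length(rows))
    train_idx[sample(rows, n_tr)] <- TRUE
  }
  train <- data[train_idx, , drop = FALSE]
  test <- data[!train_idx, , drop = FALSE]
  fit_on <- function(rows_df) {
    fit_l2_logistic(list(data = rows_df[, features, drop = FALSE],
                         y = rows_df[[endpoint]]),
                    penalty = penalty, catalog = catalog)
  }
  global <- fit_on(train)
  scores_sub <- rep(NA_real_, nrow(test))
  keep <- rep(TRUE, nrow(test))
  for (sg in LEAF_SUBGROUPS) {
    tr_rows <- subgroup_membership(train, sg)
    te_rows <- subgroup_membership(test, sg)
    if (!any(te_rows)) next
    if (length(unique(train[[endpoint]][tr_rows])) < 2) {
      keep[te_rows] <- FALSE
      next
    }
    m <- fit_on(train[tr_rows, , drop = FALSE])
    scores_sub[te_rows] <- predict_prob(m, test[te_rows, , drop = FALSE], catalog)
  }
  scores_glob <- predict_prob(global, test, catalog)
  list(auc_subgroup = safe_auc(scores_sub[keep], test[[endpoint]][keep]),
       auc_global = safe_auc(scores_glob[keep], test[[endpoint]][keep]),
       n_train = nrow(train), n_test = sum(keep))
}
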