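# Fixture builders shared across the suite. Everything is generated in code;
# no data files.

CAT <- feature_catalog()

# A cohort data frame with constant metadata and any feature columns passed
# via `...` (recycled to n); all other catalogue features are missing.
toy_cohort <- function(n, age = 50, sex = "male", diabetes = "no",
                       treatment = "BMS", era_tag = "era1",
                       three_vessel = "no", followed_up = TRUE, ...) {
  co <- data.frame(record_id = sprintf("R%04d", seq_len(n)),
                   patient_id = sprintf("P%04d", seq_len(n)),
                   age = rep_len(age, n), sex = rep_len(sex, n),
                   diabetes = rep_len(diabetes, n),
                   era_tag = rep_len(era_tag, n),
                   treatment = rep_len(treatment, n),
                   three_vessel = rep_len(three_vessel, n),
                   followed_up = rep_len(followed_up, n),
                   stringsAsFactors = FALSE)
  for (ep in stentstrat:::ENDPOINTS) co[[ep]] <- NA_integer_
  feats <- list(...)
  for (f in catalog_features(CAT)) {
    if (f %in% names(feats)) {
      co[[f]] <- rep_len(feats[[f]], n)
    } else {
      type <- stentstrat:::catalog_entry(CAT, f)$type
      co[[f]] <- switch(type, continuous = NA_real_, binary = NA_integer_,
                        categorical = NA_character_)
    }
  }
  co
}

# One-feature eligible-sample-like list for direct fitting.
one_feature_sample <- function(x, y, feature = "crp") {
  df <- data.frame(x)
  names(df) <- feature
  list(data = df, y = as.integer(y))
}

# Independent penalized log-likelihood (oracle used against the fitter).
pen_loglik <- function(b0, b1, x, y, penalty) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta))) - penalty * b1^2
}

# Cohort in which every feature is observed so many feature-set pairs are
# eligible; labels depend on crp (restenosis) and troponin_t (hazard).
fully_observed_cohort <- function(n_bms, n_des, seed) {
  set.seed(seed)
  n <- n_bms + n_des
  feats <- list()
  for (f in catalog_features(CAT)) {
    entry <- stentstrat:::catalog_entry(CAT, f)
    feats[[f]] <- switch(entry$type,
                         continuous = rnorm(n),
                         binary = as.integer(runif(n) < 0.4),
                         categorical = sample(entry$levels[[1]], n, replace = TRUE))
  }
  co <- do.call(toy_cohort, c(list(n), feats))
  co$age <- runif(n, 35, 85)
  co$sex <- sample(c("female", "male"), n, replace = TRUE)
  co$diabetes <- sample(c("no", "yes"), n, replace = TRUE)
  co$treatment <- c(rep("BMS", n_bms), rep("DES", n_des))
  co$angio_restenosis_6m <- as.integer(runif(n) < plogis(-1 + 1.5 * co$crp))
  co$hazard_1y <- as.integer(runif(n) < plogis(-1 + 1.5 * co$troponin_t))
  co
}

# Independent scan of every (feature-set pair, threshold) cell of one test,
# with its own confusion arithmetic; used as the selection oracle.
brute_force_cells <- function(co, sg, arm, ep, metric) {
  pairs <- candidate_pairs()
  cells <- list()
  for (k in seq_len(nrow(pairs))) {
    s <- filter_eligible(co, sg, pairs$clinical[k], pairs$biomarker[k], arm, ep)
    if (is.null(s)) next
    m <- fit_l2_logistic(s)
    sc <- predict_prob(m, s$data)
    grid <- thresholds_at_specificity(sc, s$y)
    for (g in seq_len(nrow(grid))) {
      pred <- sc >= grid$threshold[g]
      tp <- sum(pred & s$y == 1); fp <- sum(pred & s$y == 0)
      fn <- sum(!pred & s$y == 1); tn <- sum(!pred & s$y == 0)
      val <- if (metric == "npv") {
        if (tn + fn == 0) NA_real_ else tn / (tn + fn)
      } else {
        if (tp + fp == 0) NA_real_ else tp / (tp + fp)
      }
      if (is.na(val)) next
      cells[[length(cells) + 1L]] <- data.frame(
        clinical = pairs$clinical[k], biomarker = pairs$biomarker[k],
        threshold = grid$threshold[g], level = grid$level[g], value = val,
        n_features = ncol(s$data), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, cells)
}

# Small generated cohort cache so several tests can share one draw.
.cohort_cache <- new.env()
cached_cohort <- function(key, config, seed) {
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- generate_cohort(config, seed = seed)
  }
  .cohort_cache[[key]]
}
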