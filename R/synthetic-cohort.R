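# Synthetic cohort generator. Emulates the statistical structure the
# stratification pipeline assumes: subgroup-heterogeneous logistic outcome
# models over the eight fully-specified age/sex/diabetes leaf subgroups,
# era-dependent feature availability (each collection era records one
# clinical set and one biomarker set), observational BMS/DES assignment,
# endpoint prevalences calibrated per arm by bisection on the intercept, and
# loss to follow-up. Outcome labels are generated for BOTH potential
# treatments; only the assigned arm's label is exposed in the cohort table,
# while the counterfactual is retained in the planted-truth sidecar for
# oracle evaluation only. Restenosis and hazard are drawn independently
# (their pathophysiologies differ; they are treated as competing,
# independent risks), and 3-year indicators are supersets of their 1-year
# counterparts by construction (a single latent uniform per endpoint
# family).

LEAF_SUBGROUPS <- local({
  grid <- expand.grid(age = c("LE60", "GT60"), sex = c("FEMALE", "MALE"),
                      diabetes = c("NO", "YES"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    subgroup_spec(grid$age[i], grid$sex[i], grid$diabetes[i])
  })
})

# Marginal distributions used for feature synthesis (continuous: mean/sd;
# binary: event probability; categorical: level probabilities). Magnitudes
# are typical of interventional-cardiology cohorts.
FEATURE_MARGINALS <- list(
  continuous = list(
    bmi = c(27, 4), ejection_fraction = c(55, 10), lesion_length = c(14, 6),
    min_lumen_diameter = c(1.0, 0.35), reference_diameter = c(3.0, 0.5),
    height = c(171, 9), weight = c(79, 14), n_stents = c(1.4, 0.7),
    vessels_affected = c(1.8, 0.8),
    cholesterol = c(200, 40), creatine_kinase = c(120, 60), ck_mb = c(15, 8),
    creatinine = c(1.0, 0.3), crp = c(5, 4), hdl = c(48, 13), ldl = c(125, 35),
    nt_probnp = c(600, 500), triglycerides = c(150, 70),
    troponin_t = c(0.05, 0.08), hs_troponin_t = c(0.02, 0.03)
  ),
  binary = c(angina = 0.6, hypercholesterolemia = 0.55, dissection = 0.12,
             eccentric_lesion = 0.4, family_history = 0.25,
             history_bypass = 0.08, history_intervention = 0.2,
             history_mi = 0.3, hypertension = 0.6, smoker = 0.35,
             plaques = 0.5, st_elevation = 0.1, thrombus = 0.05,
             tortuosity = 0.15, angulation = 0.2),
  categorical = list(
    aha_lesion_class = c(A = 0.15, B1 = 0.35, B2 = 0.3, C = 0.2),
    ccs_grade = c(I = 0.3, II = 0.35, III = 0.25, IV = 0.1),
    nyha_class = c(I = 0.4, II = 0.35, III = 0.18, IV = 0.07),
    stenosis_type = c(de_novo = 0.85, restenotic = 0.15),
    timi_rating = c(`0` = 0.05, `1` = 0.08, `2` = 0.17, `3` = 0.7),
    lv_function = c(normal = 0.55, mild = 0.25, moderate = 0.15, severe = 0.05)
  )
)

#' Planted per-subgroup outcome coefficients
#'
#' Coefficient vectors (on the z-score scale of the continuous features,
#' full catalogue dimension with zeros outside the support) and the support
#' restricted to features recorded in every collection era, so leaf models
#' are estimable in all eras. In the heterogeneous default, coefficients
#' flip sign between diabetes strata and scale in magnitude between age
#' strata (0.8 for age <= 60, 1.3 for age > 60, mild 1.1 factor for
#' females), so a single population-wide model is misspecified while
#' subgroup-specific models are well-specified. With
#' `heterogeneous = FALSE` every leaf shares the same coefficients.
#'
#' @param heterogeneous Logical (default `TRUE`).
#' @param catalog A [feature_catalog()].
#' @return Named list over the eight leaf [subgroup_id()]s; each element has
#'   `coef_r` and `coef_h` (named numeric over the full catalogue).
#' @export
default_subgroup_truth <- function(heterogeneous = TRUE,
                                   catalog = feature_catalog()) {
  all_feats <- catalog_features(catalog)
  base_r <- c(lesion_length = 0.9, min_lumen_diameter = -0.9,
              ejection_fraction = -0.5, crp = 0.7, reference_diameter = -0.4,
              bmi = 0.3)
  base_h <- c(troponin_t = 1.0, ejection_fraction = -0.9, crp = 0.6,
              lesion_length = 0.5)
  expand <- function(v) {
    out <- setNames(rep(0, length(all_feats)), all_feats)
    out[names(v)] <- v
    out
  }
  truth <- list()
  for (sg in LEAF_SUBGROUPS) {
    if (heterogeneous) {
      mag <- if (sg$age == "LE60") 0.8 else 1.3
      mag <- mag * if (sg$sex == "FEMALE") 1.1 else 1.0
      sgn <- if (sg$diabetes == "YES") -1 else 1
    } else {
      mag <- 1; sgn <- 1
    }
    truth[[subgroup_id(sg)]] <- list(coef_r = expand(sgn * mag * base_r),
                                     coef_h = expand(sgn * mag * base_h))
  }
  truth
}

#' Default per-arm endpoint prevalence targets
#'
#' Event-rate targets used to calibrate the generator's intercepts. The
#' restenosis targets follow the documented clinical ranges (20-30% under
#' BMS, 4-8% under DES; midpoints used), clinical restenosis accrues from
#' one to three years, and hazardous-event rates are similar across stent
#' types. These are calibration choices of the generator, not published
#' per-arm counts.
#'
#' @return Named list `BMS`/`DES`, each a named vector over the five
#'   endpoints.
#' @export
default_target_prevalences <- function() {
  list(BMS = c(angio_restenosis_6m = 0.25, clin_restenosis_1y = 0.20,
               clin_restenosis_3y = 0.28, hazard_1y = 0.04, hazard_3y = 0.09),
       DES = c(angio_restenosis_6m = 0.06, clin_restenosis_1y = 0.05,
               clin_restenosis_3y = 0.08, hazard_1y = 0.04, hazard_3y = 0.09))
}

#' Synthetic cohort generator configuration
#'
#' Defaults mirror the study conditions of a two-study interventional
#' cohort: 2,733 interventions, 34.2% DES usage, loss to follow-up 913/2733,
#' era weights (0.4, 0.3, 0.3) over the three feature-collection eras, and
#' the heterogeneous planted truth of [default_subgroup_truth()].
#'
#' @param n_interventions Number of records.
#' @param des_fraction Probability of DES assignment.
#' @param era_weights Probabilities of the three collection eras (era k
#'   records clinical set Ck and biomarker set Bk).
#' @param subgroup_truth Planted coefficients, see [default_subgroup_truth()].
#' @param target_prevalences Per-arm endpoint targets, see
#'   [default_target_prevalences()].
#' @param three_vessel_rate Probability of three-vessel disease.
#' @param lost_followup_rate Probability a record has no follow-up (all
#'   endpoints missing).
#' @param feature_missing_rate Extra per-cell missingness among recorded
#'   features.
#' @param female_rate,diabetes_rate Demographic Bernoulli rates.
#' @param age_mean,age_sd,age_min Truncated-normal age distribution (years).
#' @param feature_correlation Exchangeable correlation of continuous
#'   features within each family block.
#' @param seed Default seed used when [generate_cohort()] is called without
#'   one.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_interventions = 2733L,
                             des_fraction = 0.342,
                             era_weights = c(0.4, 0.3, 0.3),
                             subgroup_truth = default_subgroup_truth(),
                             target_prevalences = default_target_prevalences(),
                             three_vessel_rate = 0.25,
                             lost_followup_rate = 913 / 2733,
                             feature_missing_rate = 0.005,
                             female_rate = 0.24,
                             diabetes_rate = 0.28,
                             age_mean = 65, age_sd = 10, age_min = 18,
                             feature_correlation = 0.2,
                             seed = 1L) {
  cfg <- structure(
    list(n_interventions = as.integer(n_interventions),
         des_fraction = des_fraction, era_weights = era_weights,
         subgroup_truth = subgroup_truth,
         target_prevalences = target_prevalences,
         three_vessel_rate = three_vessel_rate,
         lost_followup_rate = lost_followup_rate,
         feature_missing_rate = feature_missing_rate,
         female_rate = female_rate, diabetes_rate = diabetes_rate,
         age_mean = age_mean, age_sd = age_sd, age_min = age_min,
         feature_correlation = feature_correlation,
         seed = as.integer(seed)),
    class = "generator_config"
  )
  validate_generator_config(cfg)
  cfg
}

#' Validate a generator configuration
#' @param cfg A `generator_config`.
#' @param catalog A [feature_catalog()].
#' @return `cfg`, invisibly; stops on violation.
#' @export
validate_generator_config <- function(cfg, catalog = feature_catalog()) {
  probs <- c(cfg$des_fraction, cfg$era_weights, cfg$three_vessel_rate,
             cfg$lost_followup_rate, cfg$feature_missing_rate,
             cfg$female_rate, cfg$diabetes_rate,
             unlist(cfg$target_prevalences))
  if (any(probs < 0 | probs > 1)) stop("all probabilities must lie in [0, 1]")
  if (abs(sum(cfg$era_weights) - 1) > 1e-9) stop("era_weights must sum to 1")
  if (cfg$n_interventions < 1) stop("n_interventions must be positive")
  all_feats <- catalog_features(catalog)
  cont <- names(FEATURE_MARGINALS$continuous)
  expected <- vapply(LEAF_SUBGROUPS, subgroup_id, character(1))
  if (!setequal(names(cfg$subgroup_truth), expected)) {
    stop("subgroup_truth must cover exactly the 8 fully-specified leaf subgroups")
  }
  for (tr in cfg$subgroup_truth) {
    for (v in list(tr$coef_r, tr$coef_h)) {
      if (!setequal(names(v), all_feats)) {
        stop("truth coefficient vectors must be dimensioned to the full catalogue")
      }
      nz <- names(v)[v != 0]
      if (!all(nz %in% cont)) {
        stop("planted coefficients must be supported on continuous features")
      }
    }
  }
  invisible(cfg)
}

# Bisection on the intercept shift so the mean event probability over the
# arm's linear predictors hits the target.
calibrate_intercept <- function(lp, target) {
  if (target <= 0 || target >= 1) {
    stop("target prevalence must lie strictly in (0, 1) to be calibratable")
  }
  lo <- -40; hi <- 40
  f <- function(d) mean(plogis(lp + d)) - target
  if (f(lo) > 0 || f(hi) < 0) stop("prevalence target not reachable")
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

rtruncnorm_min <- function(n, mean, sd, lower) {
  p_lo <- pnorm(lower, mean, sd)
  qnorm(p_lo + runif(n) * (1 - p_lo), mean, sd)
}

#' Generate a synthetic cohort with planted truth
#'
#' Draws demographics, correlated continuous features (z-scores kept
#' internally as the scale the planted coefficients act on), binary and
#' categorical features, treatment assignment, era-dependent feature
#' masking, and endpoint labels from the subgroup-specific logistic truth
#' with per-arm intercepts calibrated by bisection so realized prevalences
#' match the targets. A fixed seed makes the output byte-identical across
#' calls.
#'
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @param catalog A [feature_catalog()].
#' @return List with `cohort` (data frame, one row per intervention) and
#'   `truth` (class `planted_truth`: planted coefficients, calibrated
#'   intercepts, per-record linear predictors, event probabilities and
#'   counterfactual labels under both arms). The truth sidecar is for
#'   oracle evaluation only and is never consumed by the fitting pipeline.
#' @export
generate_cohort <- function(config = generator_config(), seed = config$seed,
                            catalog = feature_catalog()) {
  validate_generator_config(config, catalog)
  set.seed(seed)
  n <- config$n_interventions
  n_patients <- max(1L, round(n * 2377 / 2733))
  patient_id <- sprintf("P%05d", sample.int(n_patients, n, replace = TRUE))
  age <- rtruncnorm_min(n, config$age_mean, config$age_sd, config$age_min)
  sex <- ifelse(runif(n) < config$female_rate, "female", "male")
  diabetes <- ifelse(runif(n) < config$diabetes_rate, "yes", "no")
  era_tag <- paste0("era", sample.int(3, n, replace = TRUE,
                                      prob = config$era_weights))
  treatment <- ifelse(runif(n) < config$des_fraction, "DES", "BMS")
  three_vessel <- ifelse(runif(n) < config$three_vessel_rate, "yes", "no")
  followed_up <- runif(n) >= config$lost_followup_rate

  # correlated z-scores per family block (exchangeable correlation)
  cont_names <- names(FEATURE_MARGINALS$continuous)
  clin_cont <- intersect(catalog$clinical$name, cont_names)
  bio_cont <- intersect(catalog$biomarker$name, cont_names)
  rho <- config$feature_correlation
  draw_block <- function(feats) {
    common <- rnorm(n)
    z <- sapply(feats, function(f) sqrt(rho) * common + sqrt(1 - rho) * rnorm(n))
    if (length(feats) == 1) z <- matrix(z, ncol = 1, dimnames = list(NULL, feats))
    z
  }
  Z <- cbind(draw_block(clin_cont), draw_block(bio_cont))

  features <- list()
  for (f in cont_names) {
    m <- FEATURE_MARGINALS$continuous[[f]]
    features[[f]] <- m[1] + m[2] * Z[, f]
  }
  for (f in names(FEATURE_MARGINALS$binary)) {
    features[[f]] <- as.integer(runif(n) < FEATURE_MARGINALS$binary[[f]])
  }
  for (f in names(FEATURE_MARGINALS$categorical)) {
    p <- FEATURE_MARGINALS$categorical[[f]]
    features[[f]] <- sample(names(p), n, replace = TRUE, prob = p)
  }

  # leaf subgroup of each record and its planted linear predictors
  leaf_key <- paste(ifelse(age <= 60, "LE60", "GT60"),
                    toupper(sex), toupper(diabetes), sep = "/")
  lp_r <- numeric(n); lp_h <- numeric(n)
  for (key in unique(leaf_key)) {
    rows <- leaf_key == key
    tr <- config$subgroup_truth[[key]]
    support_r <- names(tr$coef_r)[tr$coef_r != 0]
    support_h <- names(tr$coef_h)[tr$coef_h != 0]
    if (length(support_r) > 0) {
      lp_r[rows] <- Z[rows, support_r, drop = FALSE] %*% tr$coef_r[support_r]
    }
    if (length(support_h) > 0) {
      lp_h[rows] <- Z[rows, support_h, drop = FALSE] %*% tr$coef_h[support_h]
    }
  }

  # per-arm intercept calibration and counterfactual labels; one latent
  # uniform per endpoint family keeps 3-year events supersets of 1-year ones
  targets <- config$target_prevalences
  intercepts <- list()
  probs <- list(); labels <- list()
  u_angio <- runif(n); u_clin <- runif(n); u_haz <- runif(n)
  latent <- list(angio_restenosis_6m = u_angio, clin_restenosis_1y = u_clin,
                 clin_restenosis_3y = u_clin, hazard_1y = u_haz,
                 hazard_3y = u_haz)
  for (arm in c("BMS", "DES")) {
    in_arm <- treatment == arm
    intercepts[[arm]] <- numeric(0)
    for (ep in ENDPOINTS) {
      lp <- if (ep %in% RESTENOSIS_ENDPOINTS) lp_r else lp_h
      d <- calibrate_intercept(lp[in_arm], targets[[arm]][[ep]])
      intercepts[[arm]][[ep]] <- d
      p <- plogis(lp + d)
      probs[[arm]][[ep]] <- p
      labels[[arm]][[ep]] <- as.integer(latent[[ep]] < p)
    }
  }

  cohort <- data.frame(record_id = sprintf("R%05d", seq_len(n)),
                       patient_id = patient_id,
                       age = age, sex = sex, diabetes = diabetes,
                       era_tag = era_tag, treatment = treatment,
                       three_vessel = three_vessel, followed_up = followed_up,
                       stringsAsFactors = FALSE)
  for (ep in ENDPOINTS) {
    obs <- ifelse(treatment == "DES", labels$DES[[ep]], labels$BMS[[ep]])
    obs[!followed_up] <- NA_integer_
    cohort[[ep]] <- as.integer(obs)
  }
  # era-dependent availability + sporadic missingness
  era_sets <- list(era1 = c("C1", "B1"), era2 = c("C2", "B2"),
                   era3 = c("C3", "B3"))
  all_feats <- catalog_features(catalog)
  for (f in all_feats) cohort[[f]] <- features[[f]]
  for (era in names(era_sets)) {
    avail <- unlist(lapply(era_sets[[era]], feature_set, catalog = catalog))
    rows <- cohort$era_tag == era
    for (f in setdiff(all_feats, avail)) cohort[[f]][rows] <- NA
  }
  if (config$feature_missing_rate > 0) {
    for (f in all_feats) {
      drop <- runif(n) < config$feature_missing_rate
      cohort[[f]][drop] <- NA
    }
  }

  truth <- structure(
    list(subgroup_truth = config$subgroup_truth,
         intercepts = intercepts, lp_r = lp_r, lp_h = lp_h,
         probs = probs, counterfactual_labels = labels,
         leaf_key = leaf_key, z_scores = Z, seed = seed),
    class = "planted_truth"
  )
  list(cohort = cohort, truth = truth)
}

#' Oracle AUC of the planted truth
#'
#' Discrimination achievable by the true event probabilities themselves,
#' computed from the planted truth (no fitting): either the leaf-specific
#' truth (`mode = "leaf"`) or a single population-wide linear predictor
#' obtained by using one common coefficient vector (`mode = "global"`, the
#' pooled least-squares average of the leaf coefficients, i.e. what a
#' correctly-fitted but unpartitioned linear score converges to).
#'
#' @param result Output of [generate_cohort()].
#' @param endpoint Endpoint column name.
#' @param arm Treatment arm whose labels are scored.
#' @param mode `"leaf"` or `"global"`.
#' @return AUC of the oracle score for the arm's counterfactual labels.
#' @export
oracle_auc <- function(result, endpoint, arm = c("BMS", "DES"),
                       mode = c("leaf", "global")) {
  arm <- match.arg(arm); mode <- match.arg(mode)
  truth <- result$truth
  labels <- truth$counterfactual_labels[[arm]][[endpoint]]
  fam <- if (endpoint %in% RESTENOSIS_ENDPOINTS) "coef_r" else "coef_h"
  if (mode == "leaf") {
    scores <- if (fam == "coef_r") truth$lp_r else truth$lp_h
  } else {
    coefs <- sapply(truth$subgroup_truth, `[[`, fam)
    avg <- rowMeans(coefs)
    support <- names(avg)[avg != 0]
    scores <- if (length(support) == 0) rep(0, length(labels)) else
      drop(truth$z_scores[, support, drop = FALSE] %*% avg[support])
  }
  roc_auc(scores, labels)
}

#' Heterogeneous default configuration
#'
#' Convenience wrapper: the default [generator_config()] with planted
#' subgroup heterogeneity (sign flips across diabetes strata, magnitude
#' differences across age strata), under which a global classifier is
#' misspecified while leaf classifiers are well-specified.
#'
#' @param ... Overrides passed to [generator_config()].
#' @return A `generator_config`.
#' @export
default_heterogeneous_config <- function(...) {
  generator_config(subgroup_truth = default_subgroup_truth(heterogeneous = TRUE),
                   ...)
}

#' Write / read a planted-truth sidecar
#' @param truth A `planted_truth`.
#' @param path JSON file path.
#' @return `path`, invisibly.
#' @export
write_planted_truth <- function(truth, path) {
  x <- list(subgroup_truth = lapply(truth$subgroup_truth, function(tr)
    list(coef_r = as.list(tr$coef_r), coef_h = as.list(tr$coef_h))),
    intercepts = truth$intercepts, seed = truth$seed)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
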