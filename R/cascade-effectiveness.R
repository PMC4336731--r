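# The two-test cascade and the closed-form effectiveness estimators.
#
# A record is first scored by the restenosis test of its leaf subgroup:
# a negative result (P_R < theta_R) suggests BMS. Positive records are scored
# by the hazard test: a negative result (P_H < theta_H) suggests DES,
# otherwise CABG. Treatment probabilities are estimated from the tests'
# pooled evaluation performance:
#   P(sBMS)  = Prev_R (1 - Sens_R) + (1 - Prev_R) Spec_R
#   P(sDES)  = (1 - P(sBMS)) [Prev_H (1 - Sens_H) + (1 - Prev_H) Spec_H]
#   P(sCABG) = 1 - P(sBMS) - P(sDES)
# assuming independence of the two tests. Adverse effects decompose as
# P(Adverse) = P(Restenosis) + P(Hazard), each a probability-weighted sum of
# per-treatment conditionals; conditionals carry a "hat" provenance when they
# come from classifier performance (1 - NPV) and a "tilde" provenance when
# counted directly from follow-up labels or taken from literature.

#' Literature-derived constants for the CABG arm and the grey zone
#'
#' Event rates after bypass surgery are not estimable from a PCI cohort and
#' are taken from published values: 8.56% hazardous events and 1.9%
#' restenosis. `lambda_grey` is the fraction of three-vessel-disease patients
#' with low-complexity lesions who are eligible for either DES or CABG
#' (0.21, the fraction of SYNTAX-score <= 22 lesions reported in trial data).
#'
#' @param p_hazard_scabg,p_restenosis_scabg CABG event probabilities.
#' @param lambda_grey Grey-zone fraction among three-vessel disease.
#' @return Object of class `literature_constants`.
#' @export
literature_constants <- function(p_hazard_scabg = 0.0856,
                                 p_restenosis_scabg = 0.019,
                                 lambda_grey = 0.21) {
  vals <- c(p_hazard_scabg, p_restenosis_scabg, lambda_grey)
  if (any(vals < 0 | vals > 1)) stop("constants must lie in [0, 1]")
  structure(list(p_hazard_scabg = p_hazard_scabg,
                 p_restenosis_scabg = p_restenosis_scabg,
                 lambda_grey = lambda_grey),
            class = "literature_constants")
}

#' Apply the two-test cascade to suggest treatments
#'
#' Routes each record to its leaf subgroup of the fitted tree and thresholds
#' the two predicted probabilities. Records that cannot be scored (missing
#' features for their leaf's model) default to the baseline-dominant
#' treatment, DES, with a warning.
#'
#' @param cascade A `fitted_cascade`.
#' @param cohort Data frame of records to score.
#' @param catalog A [feature_catalog()].
#' @return Data frame with one row per record: `leaf_id`, `p_r`, `p_h`,
#'   `theta_r`, `theta_h`, `scoreable_r`, `scoreable_h`, and `suggestion`
#'   (`"sBMS"`, `"sDES"` or `"sCABG"`).
#' @export
suggest_treatment <- function(cascade, cohort, catalog = feature_catalog()) {
  n <- nrow(cohort)
  leaf_idx <- route_to_leaf(cascade$tree, cohort)
  out <- data.frame(leaf_id = cascade$leaf_ids[leaf_idx],
                    p_r = NA_real_, p_h = NA_real_,
                    theta_r = NA_real_, theta_h = NA_real_,
                    scoreable_r = FALSE, scoreable_h = FALSE,
                    suggestion = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(cascade$leaf_ids)) {
    rows <- which(leaf_idx == i)
    if (length(rows) == 0) next
    pair <- cascade$leaf_pairs[[i]]
    out$theta_r[rows] <- pair$theta_R
    out$theta_h[rows] <- pair$theta_H
    ok_r <- rows[rowSums(is.na(cohort[rows, pair$model_R$features, drop = FALSE])) == 0]
    if (length(ok_r) > 0) {
      out$p_r[ok_r] <- predict_prob(pair$model_R, cohort[ok_r, , drop = FALSE], catalog)
      out$scoreable_r[ok_r] <- TRUE
    }
    ok_h <- rows[rowSums(is.na(cohort[rows, pair$model_H$features, drop = FALSE])) == 0]
    if (length(ok_h) > 0) {
      out$p_h[ok_h] <- predict_prob(pair$model_H, cohort[ok_h, , drop = FALSE], catalog)
      out$scoreable_h[ok_h] <- TRUE
    }
  }
  neg_r <- out$scoreable_r & out$p_r < out$theta_r
  pos_r <- out$scoreable_r & out$p_r >= out$theta_r
  out$suggestion[neg_r] <- "sBMS"
  out$suggestion[pos_r & out$scoreable_h & out$p_h < out$theta_h] <- "sDES"
  out$suggestion[pos_r & out$scoreable_h & out$p_h >= out$theta_h] <- "sCABG"
  unscored <- is.na(out$suggestion)
  if (any(unscored)) {
    warning(sum(unscored), " record(s) not scoreable by their leaf models; ",
            "defaulting to sDES")
    out$suggestion[unscored] <- "sDES"
  }
  out
}

# ---------------------------------------------------------------------------
# Closed-form treatment-probability estimators

check_prob <- function(...) {
  vals <- c(...)
  if (any(is.na(vals)) || any(vals < 0 | vals > 1)) {
    stop("all arguments must be probabilities in [0, 1]")
  }
  invisible(vals)
}

#' Estimated probability that the cascade suggests BMS
#'
#' The probability of a negative first test: `prev * (1 - sens) +
#' (1 - prev) * spec`, with prevalence, sensitivity and specificity of the
#' restenosis test taken from the evaluation population's BMS arm.
#'
#' @param prev Prevalence of restenosis among BMS-treated patients.
#' @param sens,spec Sensitivity and specificity of the restenosis test.
#' @return Probability of suggestion sBMS.
#' @export
est_p_sbms <- function(prev, sens, spec) {
  check_prob(prev, sens, spec)
  prev * (1 - sens) + (1 - prev) * spec
}

#' Estimated probability that the cascade suggests DES
#'
#' A positive first test followed by a negative second test, assuming
#' independence: `(1 - p_sbms) * [prev_h * (1 - sens_h) +
#' (1 - prev_h) * spec_h]`.
#'
#' @param p_sbms Output of [est_p_sbms()].
#' @param prev_h Prevalence of hazardous events among DES-treated patients.
#' @param sens_h,spec_h Sensitivity and specificity of the hazard test.
#' @return Probability of suggestion sDES.
#' @export
est_p_sdes <- function(p_sbms, prev_h, sens_h, spec_h) {
  check_prob(p_sbms, prev_h, sens_h, spec_h)
  (1 - p_sbms) * (prev_h * (1 - sens_h) + (1 - prev_h) * spec_h)
}

#' Estimated probability that the cascade suggests CABG
#'
#' The complement of the other two suggestions.
#'
#' @param p_sbms,p_sdes Outputs of [est_p_sbms()] and [est_p_sdes()].
#' @return Probability of suggestion sCABG.
#' @export
est_p_scabg <- function(p_sbms, p_sdes) {
  check_prob(p_sbms, p_sdes)
  if (any(p_sbms + p_sdes > 1 + 1e-12)) stop("p_sbms + p_sdes must not exceed 1")
  1 - p_sbms - p_sdes
}

#' Conditional adverse-effect estimates for the suggested treatments
#'
#' The classifier-based ("hat") conditionals are 1 - NPV of the respective
#' test; the counted ("tilde") conditionals are observed event rates among
#' records routed to the suggestion, retrieved from follow-up labels. A
#' counted rate must reflect the outcome *under the suggested treatment*, and
#' in observational data that label exists only for records actually treated
#' with the matching stent, so the tilde conditionals are counted among
#' arm-matched records (hazard under sBMS from BMS-treated T_R-negatives,
#' restenosis under sDES from DES-treated records routed to sDES). Empty
#' denominators yield `NA` with `defined = FALSE`.
#'
#' @param perf_r,perf_h [classifier_performance()] of the pooled evaluation
#'   confusion matrices of the two tests.
#' @param suggestions Result of [suggest_treatment()] on the evaluation set.
#' @param cohort The evaluation cohort the suggestions refer to.
#' @param endpoint_r,endpoint_h Endpoint columns of the two tests.
#' @return List of four conditionals (`rest_sbms_hat`, `haz_sdes_hat`,
#'   `haz_sbms_tilde`, `rest_sdes_tilde`), each with `value`, `defined` and
#'   `provenance`.
#' @export
conditional_adverse_estimates <- function(perf_r, perf_h, suggestions, cohort,
                                          endpoint_r, endpoint_h) {
  counted <- function(sugg, arm, endpoint) {
    rows <- suggestions$suggestion == sugg & !is.na(cohort[[endpoint]]) &
      !is.na(cohort$treatment) & cohort$treatment == arm
    if (!any(rows)) return(list(value = NA_real_, defined = FALSE,
                                provenance = "tilde"))
    list(value = mean(cohort[[endpoint]][rows]), defined = TRUE,
         provenance = "tilde")
  }
  hat <- function(npv) {
    list(value = if (is.na(npv)) NA_real_ else 1 - npv,
         defined = !is.na(npv), provenance = "hat")
  }
  list(rest_sbms_hat = hat(perf_r$npv),
       haz_sdes_hat = hat(perf_h$npv),
       haz_sbms_tilde = counted("sBMS", "BMS", endpoint_h),
       rest_sdes_tilde = counted("sDES", "DES", endpoint_r))
}

#' Total adverse-effect probability of the proposed workflow
#'
#' `P(Restenosis)` and `P(Hazard)` as probability-weighted sums of the
#' per-treatment conditionals over \{sBMS, sDES, sCABG\} (CABG conditionals
#' from [literature_constants()]); `P(Adverse) = P(Restenosis) + P(Hazard)`.
#'
#' @param p_treat Named numeric vector with elements `sBMS`, `sDES`, `sCABG`
#'   summing to one.
#' @param conditionals Output of [conditional_adverse_estimates()].
#' @param constants A [literature_constants()].
#' @return List with `p_restenosis`, `p_hazard`, `p_adverse` and the
#'   per-treatment conditional vectors used.
#' @export
total_adverse <- function(p_treat, conditionals, constants = literature_constants()) {
  stopifnot(all(c("sBMS", "sDES", "sCABG") %in% names(p_treat)))
  rest <- c(sBMS = conditionals$rest_sbms_hat$value,
            sDES = conditionals$rest_sdes_tilde$value,
            sCABG = constants$p_restenosis_scabg)
  haz <- c(sBMS = conditionals$haz_sbms_tilde$value,
           sDES = conditionals$haz_sdes_hat$value,
           sCABG = constants$p_hazard_scabg)
  for (t in names(p_treat)) {
    if (p_treat[[t]] > 0 && (is.na(rest[[t]]) || is.na(haz[[t]]))) {
      stop("undefined conditional for treatment '", t, "' with nonzero weight")
    }
  }
  wsum <- function(cond) sum(ifelse(p_treat > 0, p_treat * cond, 0))
  p_rest <- wsum(rest[names(p_treat)])
  p_haz <- wsum(haz[names(p_treat)])
  list(p_restenosis = p_rest, p_hazard = p_haz,
       p_adverse = p_rest + p_haz,
       restenosis_conditionals = rest, hazard_conditionals = haz)
}

#' Effectiveness of the baseline (DES-dominant) workflow
#'
#' In the baseline workflow every patient receives DES except a grey-zone
#' fraction `omega = lambda * P(3-vessel disease)` treated half with DES and
#' half with CABG. Event probabilities are the correspondingly weighted sums
#' of the empirical DES rates (counted from follow-up) and the literature
#' CABG rates.
#'
#' @param p_rest_des,p_haz_des Empirical restenosis and hazard rates in the
#'   evaluation DES arm.
#' @param three_vessel_rate Fraction of the evaluation population with
#'   three-vessel disease.
#' @param constants A [literature_constants()].
#' @return List with `omega`, `p_restenosis`, `p_hazard`, `p_adverse`.
#' @export
baseline_effectiveness <- function(p_rest_des, p_haz_des, three_vessel_rate,
                                   constants = literature_constants()) {
  check_prob(p_rest_des, p_haz_des, three_vessel_rate)
  omega <- constants$lambda_grey * three_vessel_rate
  p_rest <- (1 - omega) * p_rest_des +
    0.5 * omega * (p_rest_des + constants$p_restenosis_scabg)
  p_haz <- (1 - omega) * p_haz_des +
    0.5 * omega * (p_haz_des + constants$p_hazard_scabg)
  list(omega = omega, p_restenosis = p_rest, p_hazard = p_haz,
       p_adverse = p_rest + p_haz)
}

# ---------------------------------------------------------------------------
# Full held-out evaluation of a fitted cascade

#' Evaluate a fitted cascade on held-out records
#'
#' Pools per-leaf predictions into evaluation confusion matrices for both
#' tests (restenosis test on scoreable BMS-arm records with a known
#' restenosis label, hazard test on scoreable DES-arm records with a known
#' hazard label), computes treatment suggestions for every record, the
#' closed-form treatment probabilities, the adverse-effect decomposition,
#' and the baseline workflow's effectiveness on the same population.
#' Prevalences, sensitivities and specificities entering the estimators all
#' come from the pooled evaluation confusion matrices.
#'
#' @param cascade A `fitted_cascade`.
#' @param cohort Held-out evaluation cohort.
#' @param catalog A [feature_catalog()].
#' @param constants A [literature_constants()].
#' @return Object of class `cascade_evaluation`: AUCs, pooled performances,
#'   treatment probabilities (formula-based and counted), conditionals,
#'   proposed and baseline adverse-effect estimates, and their difference.
#' @export
evaluate_cascade <- function(cascade, cohort, catalog = feature_catalog(),
                             constants = literature_constants()) {
  sugg <- suppressWarnings(suggest_treatment(cascade, cohort, catalog))
  evaluate_from_suggestions(sugg, cohort, cascade$endpoint_r,
                            cascade$endpoint_h, constants)
}

confusion_from_rows <- function(scores, labels, thresholds) {
  pred <- scores >= thresholds
  structure(list(tp = sum(pred & labels == 1),
                 fp = sum(pred & labels == 0),
                 fn = sum(!pred & labels == 1),
                 tn = sum(!pred & labels == 0)),
            class = "confusion_matrix")
}

safe_auc <- function(scores, labels) {
  if (length(labels) == 0 || length(unique(labels)) < 2) return(NA_real_)
  roc_auc(scores, labels)
}

rate_or_na <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) NA_real_ else mean(x)
}

est_with_na <- function(f, ...) {
  args <- list(...)
  if (anyNA(unlist(args))) return(NA_real_)
  do.call(f, args)
}
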