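# A hand-made single-leaf cascade whose two models depend only on crp and
# troponin_t through known monotone links, so routing outcomes are exactly
# controllable.
make_const_cascade <- function(theta_r, theta_h) {
  mk_model <- function(feature, arm, ep) {
    structure(
      list(intercept = 0,
           coefficients = setNames(1, feature),
           standardizer = structure(list(center = setNames(0, feature),
                                         scale = setNames(1, feature),
                                         zero_var = character(0)),
                                    class = "standardizer"),
           encoder = list(features = feature, reference = list()),
           features = feature, clinical_set = "NONE", biomarker_set = "B1",
           subgroup = subgroup_spec(), arm = arm, endpoint = ep,
           penalty = 0.01, n = 0L, n_pos = 0L),
      class = "logistic_model")
  }
  structure(
    list(tree = stentstrat:::tree_leaf(subgroup_spec()),
         leaf_ids = "ALL/ALL/ALL",
         leaf_pairs = list("ALL/ALL/ALL" = structure(
           list(subgroup = subgroup_spec(),
                model_R = mk_model("crp", "BMS", "angio_restenosis_6m"),
                theta_R = theta_r,
                model_H = mk_model("troponin_t", "DES", "hazard_1y"),
                theta_H = theta_h),
           class = "leaf_pair")),
         endpoint_r = "angio_restenosis_6m", endpoint_h = "hazard_1y",
         penalty = 0.01, global_mode = TRUE),
    class = "fitted_cascade")
}

test_that("the cascade routes records by thresholding P_R then P_H", {
  casc <- make_const_cascade(theta_r = 0.5, theta_h = 0.5)
  # qlogis inputs chosen so P_R/P_H are exactly the intended probabilities
  co <- toy_cohort(3, crp = qlogis(c(0.01, 0.9, 0.9)),
                   troponin_t = qlogis(c(0.5, 0.01, 0.9)))
  sugg <- suggest_treatment(casc, co)
  expect_equal(sugg$suggestion, c("sBMS", "sDES", "sCABG"))
  expect_equal(sugg$p_r, c(0.01, 0.9, 0.9), tolerance = 1e-12)
})

test_that("unscoreable records default to DES with a warning", {
  casc <- make_const_cascade(0.5, 0.5)
  co <- toy_cohort(2, crp = c(NA, qlogis(0.9)), troponin_t = c(1, NA))
  expect_warning(sugg <- suggest_treatment(casc, co), "sDES")
  expect_equal(sugg$suggestion, c("sDES", "sDES"))
  expect_false(sugg$scoreable_r[1])
})

test_that("est_p_sbms matches a toy population tabulated by hand", {
  expect_equal(est_p_sbms(0, 0.5, 1), 1)
  expect_equal(est_p_sbms(1, 1, 0.5), 0)
  # 40 records: 10 events (8 detected), 30 non-events (18 true negatives)
  # => 2 + 18 = 20 predicted negative of 40
  scores <- c(rep(1, 8), rep(0, 2), rep(1, 12), rep(0, 18))
  labels <- c(rep(1, 10), rep(0, 30))
  cm <- confusion_at_threshold(scores, labels, 0.5)
  perf <- classifier_performance(cm)
  expect_equal(perf$prevalence, 0.25)
  expect_equal(perf$sens, 0.8)
  expect_equal(perf$spec, 0.6)
  expect_equal(est_p_sbms(perf$prevalence, perf$sens, perf$spec), 0.5)
  expect_equal(est_p_sbms(perf$prevalence, perf$sens, perf$spec),
               mean(scores < 0.5))
  expect_error(est_p_sbms(1.2, 0.5, 0.5), "probabilities")
})

test_that("est_p_sdes and est_p_scabg follow the cascade algebra", {
  expect_equal(est_p_sdes(1, 0.3, 0.5, 0.5), 0)
  expect_equal(est_p_sdes(0, 0, 0.5, 1), 1)
  expect_equal(est_p_sdes(0.5, 0.2, 0.75, 0.5), 0.5 * (0.05 + 0.4))
  expect_equal(est_p_scabg(0.2, 0.7), 0.1)
  expect_equal(est_p_scabg(1, 0), 0)
  expect_equal(est_p_scabg(0.097, 0.818), 0.085)
  expect_error(est_p_scabg(0.7, 0.7), "exceed")
})

test_that("treatment probabilities sum to one across a randomized sweep", {
  set.seed(30)
  out <- t(vapply(1:2000, function(i) {
    v <- runif(6)
    p1 <- est_p_sbms(v[1], v[2], v[3])
    p2 <- est_p_sdes(p1, v[4], v[5], v[6])
    c(p1, p2, est_p_scabg(p1, p2))
  }, numeric(3)))
  expect_lt(max(abs(rowSums(out) - 1)), 1e-12)
  expect_true(all(out >= -1e-15 & out <= 1 + 1e-15))
})

test_that("est_p_sbms is monotone: increasing in spec, decreasing in sens when prev > 0", {
  set.seed(31)
  ok <- vapply(1:200, function(i) {
    prev <- runif(1, 0.05, 0.95); sens <- runif(1); spec <- runif(1)
    eps <- 0.01
    est_p_sbms(prev, sens, min(spec + eps, 1)) >= est_p_sbms(prev, sens, spec) &&
      est_p_sbms(prev, min(sens + eps, 1), spec) <= est_p_sbms(prev, sens, spec)
  }, logical(1))
  expect_true(all(ok))
})

test_that("formula-based treatment probabilities equal counted fractions on the same set", {
  set.seed(32)
  n <- 500
  p_r <- runif(n); p_h <- runif(n)
  y_r <- rbinom(n, 1, 0.3); y_h <- rbinom(n, 1, 0.2)
  theta_r <- 0.55; theta_h <- 0.7
  cm_r <- confusion_at_threshold(p_r, y_r, theta_r)
  perf_r <- classifier_performance(cm_r)
  p_sbms <- est_p_sbms(perf_r$prevalence, perf_r$sens, perf_r$spec)
  expect_equal(p_sbms, mean(p_r < theta_r), tolerance = 1e-12)
  # hazard-test performance computed among first-test positives, the same
  # population whose routed fractions are counted
  pos1 <- p_r >= theta_r
  cm_h <- confusion_at_threshold(p_h[pos1], y_h[pos1], theta_h)
  perf_h <- classifier_performance(cm_h)
  p_sdes <- est_p_sdes(p_sbms, perf_h$prevalence, perf_h$sens, perf_h$spec)
  expect_equal(p_sdes, mean(pos1 & p_h < theta_h), tolerance = 1e-12)
  expect_equal(est_p_scabg(p_sbms, p_sdes), mean(pos1 & p_h >= theta_h),
               tolerance = 1e-12)
})

test_that("conditional adverse estimates combine classifier and counted provenance", {
  perf_r <- list(npv = 1); perf_h <- list(npv = 0.9)
  co <- toy_cohort(12, treatment = c("BMS", "BMS", rep("DES", 10)))
  co$angio_restenosis_6m <- c(rep(0L, 2), rep(c(1L, 0L, 0L, 0L, 0L), 2))
  co$hazard_1y <- rep(0L, 12)
  sugg <- data.frame(suggestion = c(rep("sCABG", 2), rep("sDES", 10)),
                     stringsAsFactors = FALSE)
  # a BMS-treated record routed to sDES must not contaminate the DES-arm rate
  co <- rbind(co, co[3, ])
  co$treatment[13] <- "BMS"; co$angio_restenosis_6m[13] <- 1L
  sugg <- rbind(sugg, data.frame(suggestion = "sDES"))
  conds <- conditional_adverse_estimates(perf_r, perf_h, sugg, co,
                                         "angio_restenosis_6m", "hazard_1y")
  expect_equal(conds$rest_sbms_hat$value, 0)  # NPV 1 => zero restenosis
  expect_equal(conds$haz_sdes_hat$value, 0.1, tolerance = 1e-12)
  expect_equal(conds$rest_sdes_tilde$value, 0.2)  # 2 events in 10 sDES
  expect_false(conds$haz_sbms_tilde$defined)  # no sBMS records
})

test_that("total adverse effect is the weighted decomposition and the hazard+restenosis sum", {
  conds <- list(rest_sbms_hat = list(value = 0.1, defined = TRUE),
                rest_sdes_tilde = list(value = 0.2, defined = TRUE),
                haz_sbms_tilde = list(value = 0, defined = TRUE),
                haz_sdes_hat = list(value = 0, defined = TRUE))
  out <- total_adverse(c(sBMS = 0.5, sDES = 0.5, sCABG = 0), conds,
                       literature_constants())
  expect_equal(out$p_restenosis, 0.15)
  expect_equal(out$p_adverse, out$p_restenosis + out$p_hazard)
  zero <- list(rest_sbms_hat = list(value = 0), rest_sdes_tilde = list(value = 0),
               haz_sbms_tilde = list(value = 0), haz_sdes_hat = list(value = 0))
  out0 <- total_adverse(c(sBMS = 0.3, sDES = 0.7, sCABG = 0), zero,
                        literature_constants(p_hazard_scabg = 0,
                                             p_restenosis_scabg = 0))
  expect_equal(out0$p_adverse, 0)
  und <- conds; und$rest_sdes_tilde <- list(value = NA_real_, defined = FALSE)
  expect_error(total_adverse(c(sBMS = 0.5, sDES = 0.5, sCABG = 0), und),
               "undefined")
})

test_that("baseline effectiveness weights the grey zone as documented", {
  cst <- literature_constants()
  b0 <- baseline_effectiveness(0.08, 0.05, 0, cst)
  expect_equal(b0$omega, 0)
  expect_equal(b0$p_restenosis, 0.08)
  expect_equal(b0$p_hazard, 0.05)
  expect_equal(baseline_effectiveness(0.1, 0.1, 0.5, cst)$omega, 0.105)
  b <- baseline_effectiveness(0.08, 0, 0.2 / cst$lambda_grey,
                              literature_constants(p_restenosis_scabg = 0.019,
                                                   p_hazard_scabg = 0))
  expect_equal(b$p_restenosis, 0.8 * 0.08 + 0.1 * (0.08 + 0.019))
})

test_that("cascade serialization round-trips predictions and structure", {
  casc <- make_const_cascade(0.4, 0.6)
  path <- withr::local_tempfile(fileext = ".json")
  write_cascade_json(casc, path)
  back <- read_cascade_json(path)
  co <- toy_cohort(5, crp = qlogis(seq(0.1, 0.9, by = 0.2)),
                   troponin_t = qlogis(rep(0.5, 5)))
  expect_equal(suggest_treatment(back, co), suggest_treatment(casc, co))
  expect_equal(back$leaf_ids, casc$leaf_ids)
})
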