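test_that("cohort CSV round-trips exactly, with blanks read as missing", {
  co <- toy_cohort(3, crp = c(2.5, NA, 4.1), troponin_t = 0.04,
                   bmi = c(24, 31, 27), smoker = c(1L, 0L, 1L),
                   aha_lesion_class = c("A", "B2", "C"))
  co$angio_restenosis_6m <- c(1L, 0L, NA)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  back <- read_cohort(path)
  expect_equal(nrow(back), 3L)
  expect_identical(sum(is.na(back$crp)), 1L)
  expect_equal(back, co[, names(back)], tolerance = 1e-12)
})

test_that("reading a file without the treatment column names the column", {
  co <- toy_cohort(2)
  co$treatment <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(co, path, row.names = FALSE, na = "NA")
  expect_error(read_cohort(path), "treatment")
})

test_that("unparseable cells become missing with a warning, count preserved", {
  co <- toy_cohort(3, crp = c(1, 2, 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, path)
  txt <- readLines(path)
  txt[2] <- sub("^\"R0001\",\"P0001\",50", "\"R0001\",\"P0001\",fifty", txt[2])
  writeLines(txt, path)
  expect_warning(back <- read_cohort(path), "age")
  expect_equal(nrow(back), 3L)
  expect_true(is.na(back$age[1]))
})

test_that("subgroup membership follows the conjunction with an inclusive age-60 boundary", {
  co <- toy_cohort(3, age = c(60, 61, 61))
  co$sex <- c("male", "female", "female")
  co$diabetes <- c("no", "yes", "yes")
  expect_identical(subgroup_membership(co, subgroup_spec("LE60")),
                   c(TRUE, FALSE, FALSE))
  expect_true(all(subgroup_membership(co, subgroup_spec())))
  # age 61, female, diabetic against LE60/FEMALE/YES: age constraint fails
  expect_false(subgroup_membership(co, subgroup_spec("LE60", "FEMALE", "YES"))[2])
  co$age[1] <- NA
  expect_error(subgroup_membership(co, subgroup_spec()), "mandatory")
})

test_that("eligibility requires 100 complete records and 10 positives", {
  base <- function(n, n_pos) {
    co <- toy_cohort(n, crp = rnorm(n, 5), troponin_t = rnorm(n, 0.05),
                     creatinine = rnorm(n, 1), ck_mb = rnorm(n, 15),
                     creatine_kinase = rnorm(n, 120), era_tag = "era2")
    co$hazard_1y <- NULL
    co$hazard_1y <- rep(0L, n); co$hazard_1y[seq_len(n_pos)] <- 1L
    co
  }
  set.seed(1)
  co <- base(150, 12)
  s <- filter_eligible(co, subgroup_spec(), "NONE", "B2", "BMS", "hazard_1y")
  expect_s3_class(s, "eligible_sample")
  expect_equal(s$n, 150L)
  expect_false(anyNA(s$data))
  expect_null(filter_eligible(base(99, 12), subgroup_spec(), "NONE", "B2",
                              "BMS", "hazard_1y"))
  expect_null(filter_eligible(base(150, 9), subgroup_spec(), "NONE", "B2",
                              "BMS", "hazard_1y"))
  # both set ids NONE -> empty design matrix, never eligible
  expect_null(filter_eligible(base(150, 12), subgroup_spec(), "NONE", "NONE",
                              "BMS", "hazard_1y"))
})

test_that("eligible row count is non-increasing in the feature union and filters drop the right rows", {
  set.seed(2)
  n <- 260
  c3 <- feature_set(CAT, "C3")
  feats <- list()
  for (f in c3) {
    entry <- stentstrat:::catalog_entry(CAT, f)
    feats[[f]] <- switch(entry$type,
                         continuous = rnorm(n),
                         binary = rep_len(c(0L, 1L), n),
                         categorical = rep_len(entry$levels[[1]], n))
  }
  feats$crp <- rnorm(n); feats$troponin_t <- rnorm(n)
  feats$creatinine <- rnorm(n); feats$ck_mb <- rnorm(n)
  feats$creatine_kinase <- rnorm(n)
  co <- do.call(toy_cohort, c(list(n), feats))
  co$hazard_1y <- rep_len(c(1L, 0L, 0L, 0L), n)
  co$treatment[1:30] <- "DES"
  co$hazard_1y[31:40] <- NA_integer_
  co$creatinine[50] <- NA  # one extra incomplete BMS row
  co$bmi[51] <- NA         # lost only once clinical features enter the union
  small <- filter_eligible(co, subgroup_spec(), "NONE", "B2", "BMS", "hazard_1y")
  big <- filter_eligible(co, subgroup_spec(), "C3", "B2", "BMS", "hazard_1y")
  # counted by hand: 260 - 30 DES - 10 unlabeled - 1 missing creatinine
  expect_equal(small$n, 260L - 30L - 10L - 1L)
  expect_equal(big$n, small$n - 1L)
  expect_false(anyNA(big$data))
})

test_that("standardization is train-anchored, idempotent, and flags constant columns", {
  X <- cbind(crp = c(1, 2, 3), troponin_t = c(5, 5, 5))
  expect_warning(p <- standardize(X, c("crp", "troponin_t")), "troponin_t")
  Xs <- apply_standardization(p, X)
  expect_equal(mean(Xs[, "crp"]), 0)
  expect_equal(sd(Xs[, "crp"]), 1)
  expect_equal(Xs[, "troponin_t"], c(0, 0, 0), ignore_attr = TRUE)
  # test data transformed with the *training* center, not its own
  Xtest <- cbind(crp = c(10, 20), troponin_t = c(7, 7))
  Xt <- apply_standardization(p, Xtest)
  expect_equal(Xt[, "crp"], (c(10, 20) - 2) / 1, ignore_attr = TRUE)
  # idempotence: standardizing the standardized training matrix is a no-op
  p2 <- suppressWarnings(standardize(Xs, c("crp", "troponin_t")))
  expect_equal(apply_standardization(p2, Xs), Xs)
  expect_error(standardize(X[0, , drop = FALSE], "crp"), "empty")
})

test_that("one-hot encoding uses the most frequent training level as reference and transfers to new data", {
  df <- data.frame(aha_lesion_class = c("A", "B1", "B1", "C"),
                   crp = c(1, 2, 3, 4), stringsAsFactors = FALSE)
  enc <- encode_design(df, CAT)
  expect_equal(enc$encoder$reference$aha_lesion_class, "B1")
  expect_setequal(colnames(enc$X),
                  c("aha_lesion_class=A", "aha_lesion_class=B2",
                    "aha_lesion_class=C", "crp"))
  new <- data.frame(aha_lesion_class = "C", crp = 9, stringsAsFactors = FALSE)
  enc2 <- encode_design(new, CAT, encoder = enc$encoder)
  expect_identical(colnames(enc2$X), colnames(enc$X))
  expect_equal(enc2$X[1, "aha_lesion_class=C"], 1, ignore_attr = TRUE)
})

test_that("feature catalogue matches the documented set sizes", {
  expect_length(feature_set(CAT, "C1"), 29L)
  expect_length(feature_set(CAT, "C2"), 26L)
  expect_length(feature_set(CAT, "C3"), 23L)
  expect_length(feature_set(CAT, "B1"), 8L)
  expect_length(feature_set(CAT, "B2"), 5L)
  expect_length(feature_set(CAT, "B3"), 5L)
  expect_length(feature_set(CAT, "NONE"), 0L)
  expect_length(catalog_features(CAT), 41L)
})
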