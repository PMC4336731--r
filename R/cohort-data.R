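#' @importFrom stats median plogis pnorm qnorm quantile rbinom rnorm runif sd setNames
#' @importFrom utils read.csv write.csv
NULL

# Endpoint columns carried by every cohort table. Restenosis endpoints are the
# targets of the first test (T_R, fitted on the BMS arm), hazard endpoints of
# the second test (T_H, fitted on the DES arm).
ENDPOINTS <- c("angio_restenosis_6m", "clin_restenosis_1y", "clin_restenosis_3y",
               "hazard_1y", "hazard_3y")

RESTENOSIS_ENDPOINTS <- c("angio_restenosis_6m", "clin_restenosis_1y",
                          "clin_restenosis_3y")
HAZARD_ENDPOINTS <- c("hazard_1y", "hazard_3y")

CLINICAL_SET_IDS <- c("C1", "C2", "C3")
BIOMARKER_SET_IDS <- c("B1", "B2", "B3")

# Non-feature columns of a cohort table, in canonical order.
COHORT_META_COLS <- c("record_id", "patient_id", "age", "sex", "diabetes",
                      "era_tag", "treatment", "three_vessel", "followed_up",
                      ENDPOINTS)

.catalog_cache <- new.env(parent = emptyenv())

#' Load the predictive-variable catalogue
#'
#' Reads the packaged catalogue of clinical variables (era-linked sets C1, C2,
#' C3) and in vitro diagnostic biomarkers (sets B1, B2, B3), including each
#' variable's measurement type and, for categorical variables, its levels.
#' A user-supplied JSON file with the same structure may be given instead.
#'
#' @param path Optional path to an alternative catalogue JSON file.
#' @return An object of class `feature_catalog`: a list with data frames
#'   `clinical` and `biomarker` (columns `name`, `label`, `type`, `levels`,
#'   `sets`).
#' @export
feature_catalog <- function(path = NULL) {
  key <- if (is.null(path)) ".default" else normalizePath(path)
  if (!is.null(.catalog_cache[[key]])) return(.catalog_cache[[key]])
  if (is.null(path)) {
    path <- system.file("extdata", "feature_catalog.json", package = "stentstrat")
  }
  raw <- jsonlite::read_json(path)
  parse_family <- function(entries) {
    data.frame(
      name = vapply(entries, `[[`, "", "name"),
      label = vapply(entries, `[[`, "", "label"),
      type = vapply(entries, `[[`, "", "type"),
      levels = I(lapply(entries, function(e) unlist(e$levels))),
      sets = I(lapply(entries, function(e) unlist(e$sets))),
      stringsAsFactors = FALSE
    )
  }
  cat_obj <- structure(
    list(clinical = parse_family(raw$clinical),
         biomarker = parse_family(raw$biomarker)),
    class = "feature_catalog"
  )
  stopifnot(
    length(feature_set(cat_obj, "B1")) == 8L,
    length(feature_set(cat_obj, "B2")) == 5L,
    length(feature_set(cat_obj, "B3")) == 5L
  )
  .catalog_cache[[key]] <- cat_obj
  cat_obj
}

#' Feature names belonging to a feature set
#'
#' @param catalog A [feature_catalog()].
#' @param set_id One of `"C1"`, `"C2"`, `"C3"`, `"B1"`, `"B2"`, `"B3"`, or
#'   `"NONE"` (the empty set of either family).
#' @return Character vector of feature names (empty for `"NONE"`).
#' @export
feature_set <- function(catalog, set_id) {
  if (identical(set_id, "NONE")) return(character(0))
  fam <- if (set_id %in% CLINICAL_SET_IDS) catalog$clinical else
    if (set_id %in% BIOMARKER_SET_IDS) catalog$biomarker else
      stop("unknown feature set id: ", set_id)
  fam$name[vapply(fam$sets, function(s) set_id %in% s, logical(1))]
}

#' All feature names in the catalogue
#' @param catalog A [feature_catalog()].
#' @return Character vector: clinical variables followed by biomarkers.
#' @export
catalog_features <- function(catalog) {
  c(catalog$clinical$name, catalog$biomarker$name)
}

catalog_entry <- function(catalog, feature) {
  for (fam in list(catalog$clinical, catalog$biomarker)) {
    i <- match(feature, fam$name)
    if (!is.na(i)) return(fam[i, ])
  }
  stop("feature not in catalogue: ", feature)
}

# ---------------------------------------------------------------------------
# Subgroup specifications

#' Construct a patient subgroup specification
#'
#' A subgroup is a conjunction of constraints over the three partitioning
#' variables: age (split at 60 years, inclusive on the young side), sex and
#' diabetes indication. `"ALL"` leaves a variable unconstrained.
#'
#' @param age One of `"ALL"`, `"LE60"` (age <= 60), `"GT60"` (age > 60).
#' @param sex One of `"ALL"`, `"FEMALE"`, `"MALE"`.
#' @param diabetes One of `"ALL"`, `"NO"`, `"YES"`.
#' @return An object of class `subgroup_spec`.
#' @export
subgroup_spec <- function(age = "ALL", sex = "ALL", diabetes = "ALL") {
  age <- match.arg(age, c("ALL", "LE60", "GT60"))
  sex <- match.arg(sex, c("ALL", "FEMALE", "MALE"))
  diabetes <- match.arg(diabetes, c("ALL", "NO", "YES"))
  structure(list(age = age, sex = sex, diabetes = diabetes),
            class = "subgroup_spec")
}

#' @export
format.subgroup_spec <- function(x, ...) {
  paste(x$age, x$sex, x$diabetes, sep = "/")
}

#' @export
print.subgroup_spec <- function(x, ...) {
  cat("<subgroup:", format(x), ">\n")
  invisible(x)
}

#' Identifier string for a subgroup specification
#' @param spec A [subgroup_spec()].
#' @return A string such as `"LE60/FEMALE/ALL"`.
#' @export
subgroup_id <- function(spec) format.subgroup_spec(spec)

#' Test subgroup membership
#'
#' A record belongs to a subgroup iff it satisfies every non-`"ALL"`
#' constraint; `LE60` means age <= 60 and `GT60` means age > 60.
#'
#' @param cohort A cohort data frame (see [read_cohort()]); may have any
#'   number of rows.
#' @param spec A [subgroup_spec()].
#' @return Logical vector, one element per row of `cohort`.
#' @export
subgroup_membership <- function(cohort, spec) {
  if (any(is.na(cohort$age)) || any(is.na(cohort$sex)) || any(is.na(cohort$diabetes))) {
    stop("age, sex and diabetes are mandatory and must not be missing")
  }
  keep <- rep(TRUE, nrow(cohort))
  if (spec$age == "LE60") keep <- keep & cohort$age <= 60
  if (spec$age == "GT60") keep <- keep & cohort$age > 60
  if (spec$sex != "ALL") keep <- keep & cohort$sex == tolower(spec$sex)
  if (spec$diabetes != "ALL") keep <- keep & cohort$diabetes == tolower(spec$diabetes)
  keep
}

# ---------------------------------------------------------------------------
# Cohort CSV I/O

#' Read a cohort table from CSV
#'
#' One row per intervention. The file must contain a header row and at least
#' the mandatory columns `age`, `sex`, `diabetes` and `treatment`; the
#' remaining metadata columns (`record_id`, `patient_id`, `era_tag`,
#' `three_vessel`, `followed_up`, the five endpoint columns) and any feature
#' columns named as in the catalogue are optional and filled with missing
#' values when absent. Unparseable cells become missing values with a warning;
#' both empty cells and `"NA"` are read as missing.
#'
#' @param path Path to a UTF-8, comma-separated file with a header row.
#' @param catalog A [feature_catalog()]; feature columns not in the catalogue
#'   are rejected.
#' @return A cohort data frame with typed columns (endpoints and binary
#'   features as 0/1 integers, `followed_up` logical).
#' @export
read_cohort <- function(path, catalog = feature_catalog()) {
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"),
                 colClasses = "character")
  mandatory <- c("age", "sex", "diabetes", "treatment")
  miss <- setdiff(mandatory, names(df))
  if (length(miss) > 0) {
    stop("cohort file is missing mandatory column(s): ", paste(miss, collapse = ", "))
  }
  known <- c(COHORT_META_COLS, catalog_features(catalog))
  unknown <- setdiff(names(df), known)
  if (length(unknown) > 0) {
    stop("cohort file has columns not in the catalogue: ",
         paste(unknown, collapse = ", "))
  }
  n <- nrow(df)
  for (col in setdiff(COHORT_META_COLS, names(df))) df[[col]] <- NA
  num_warn <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(out)
    if (any(bad)) warning(sum(bad), " unparseable value(s) in column '", col,
                          "' set to missing")
    out
  }
  lvl_warn <- function(x, col, levels) {
    x <- tolower(x)
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      warning(sum(bad), " unexpected value(s) in column '", col, "' set to missing")
      x[bad] <- NA
    }
    x
  }
  df$age <- num_warn(df$age, "age")
  df$sex <- lvl_warn(df$sex, "sex", c("female", "male"))
  df$diabetes <- lvl_warn(df$diabetes, "diabetes", c("no", "yes"))
  df$treatment <- toupper(df$treatment)
  bad_trt <- !is.na(df$treatment) & !(df$treatment %in% c("BMS", "DES"))
  if (any(bad_trt)) {
    warning(sum(bad_trt), " unexpected value(s) in column 'treatment' set to missing")
    df$treatment[bad_trt] <- NA
  }
  df$three_vessel <- lvl_warn(as.character(df$three_vessel), "three_vessel", c("no", "yes"))
  fu <- toupper(as.character(df$followed_up))
  df$followed_up <- ifelse(is.na(fu), NA, fu %in% c("TRUE", "1", "T", "YES"))
  for (ep in ENDPOINTS) {
    x <- as.character(df[[ep]])
    x[x %in% c("event")] <- "1"
    x[x %in% c("no_event")] <- "0"
    v <- num_warn(x, ep)
    bad <- !is.na(v) & !(v %in% c(0, 1))
    if (any(bad)) {
      warning(sum(bad), " non-binary value(s) in endpoint '", ep, "' set to missing")
      v[bad] <- NA
    }
    df[[ep]] <- as.integer(v)
  }
  # not followed up -> no endpoint can be known
  lost <- !is.na(df$followed_up) & !df$followed_up
  for (ep in ENDPOINTS) {
    if (any(lost & !is.na(df[[ep]]))) {
      warning("endpoint '", ep, "' present for records not followed up; set to missing")
      df[[ep]][lost] <- NA_integer_
    }
  }
  for (feat in intersect(catalog_features(catalog), names(df))) {
    entry <- catalog_entry(catalog, feat)
    if (entry$type == "categorical") {
      df[[feat]] <- lvl_warn_case(df[[feat]], feat, entry$levels[[1]])
    } else {
      v <- num_warn(df[[feat]], feat)
      if (entry$type == "binary") {
        bad <- !is.na(v) & !(v %in% c(0, 1))
        if (any(bad)) {
          warning(sum(bad), " non-binary value(s) in feature '", feat, "' set to missing")
          v[bad] <- NA
        }
        v <- as.integer(v)
      }
      df[[feat]] <- v
    }
  }
  stopifnot(nrow(df) == n)
  df[, c(COHORT_META_COLS, intersect(catalog_features(catalog), names(df)))]
}

# categorical parser that preserves level case (levels like "B1" or "I")
lvl_warn_case <- function(x, col, levels) {
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    warning(sum(bad), " unexpected level(s) in column '", col, "' set to missing")
    x[bad] <- NA
  }
  x
}

#' Write a cohort table to CSV
#'
#' Missing values are written as `"NA"`; [read_cohort()] of the result
#' reproduces the cohort exactly.
#'
#' @param cohort A cohort data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "NA")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Eligibility filtering

#' Extract the eligible modelling sample for one subgroup and feature pair
#'
#' Keeps records that belong to the subgroup, received the given treatment,
#' have a known endpoint label, and have no missing value among the selected
#' features (union of a clinical and a biomarker set, either possibly
#' `"NONE"`). Incomplete rows are discarded, never imputed. The sample is
#' eligible only if it has at least `min_n` records and at least `min_pos`
#' event-positive records.
#'
#' @param cohort A cohort data frame.
#' @param spec A [subgroup_spec()].
#' @param clinical_set,biomarker_set Set ids (`"C1"`..`"C3"`/`"B1"`..`"B3"`)
#'   or `"NONE"`; both `"NONE"` is never eligible (empty design matrix).
#' @param arm Treatment arm, `"BMS"` or `"DES"`.
#' @param endpoint One of the five endpoint column names.
#' @param catalog A [feature_catalog()].
#' @param min_n,min_pos Eligibility thresholds (defaults 100 and 10).
#' @return An object of class `eligible_sample` (fields `data`, `y`,
#'   `subgroup`, `clinical_set`, `biomarker_set`, `arm`, `endpoint`, `n`,
#'   `n_pos`), or `NULL` when the sample is ineligible.
#' @export
filter_eligible <- function(cohort, spec, clinical_set, biomarker_set,
                            arm, endpoint, catalog = feature_catalog(),
                            min_n = 100L, min_pos = 10L) {
  stopifnot(arm %in% c("BMS", "DES"), endpoint %in% ENDPOINTS)
  feats <- c(feature_set(catalog, clinical_set), feature_set(catalog, biomarker_set))
  if (length(feats) == 0) return(NULL)
  keep <- subgroup_membership(cohort, spec) &
    !is.na(cohort$treatment) & cohort$treatment == arm &
    !is.na(cohort[[endpoint]])
  sub <- cohort[keep, , drop = FALSE]
  if (nrow(sub) > 0) {
    complete <- rowSums(is.na(sub[, feats, drop = FALSE])) == 0
    sub <- sub[complete, , drop = FALSE]
  }
  y <- sub[[endpoint]]
  if (nrow(sub) < min_n || sum(y) < min_pos) return(NULL)
  structure(
    list(data = sub[, feats, drop = FALSE], y = as.integer(y),
         subgroup = spec, clinical_set = clinical_set,
         biomarker_set = biomarker_set, arm = arm, endpoint = endpoint,
         n = nrow(sub), n_pos = sum(y)),
    class = "eligible_sample"
  )
}

# ---------------------------------------------------------------------------
# Encoding and standardization

#' Encode raw features into a numeric design matrix
#'
#' Continuous features pass through as numeric columns; binary features as
#' 0/1; categorical features are one-hot encoded against the most frequent
#' training level as reference (columns named `feature=level`). When
#' `encoder` is supplied (prediction on new data) its reference levels are
#' reused so the column layout matches the training matrix.
#'
#' @param data Data frame of raw feature columns (no missing values).
#' @param catalog A [feature_catalog()].
#' @param encoder Encoder returned by a previous call, or `NULL` to build one.
#' @return List with `X` (numeric matrix) and `encoder`.
#' @export
encode_design <- function(data, catalog = feature_catalog(), encoder = NULL) {
  feats <- if (is.null(encoder)) names(data) else encoder$features
  build <- is.null(encoder)
  if (build) encoder <- list(features = feats, reference = list())
  cols <- list()
  for (feat in feats) {
    if (!feat %in% names(data)) stop("feature '", feat, "' absent from data")
    entry <- catalog_entry(catalog, feat)
    x <- data[[feat]]
    if (entry$type == "categorical") {
      levels <- entry$levels[[1]]
      if (build) {
        counts <- table(factor(x, levels = levels))
        encoder$reference[[feat]] <- names(counts)[which.max(counts)]
      }
      ref <- encoder$reference[[feat]]
      for (lv in setdiff(levels, ref)) {
        cols[[paste0(feat, "=", lv)]] <- as.numeric(x == lv)
      }
    } else {
      cols[[feat]] <- as.numeric(x)
    }
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) X <- matrix(numeric(0), nrow = nrow(data), ncol = 0)
  colnames(X) <- names(cols)
  list(X = X, encoder = encoder)
}

continuous_columns <- function(catalog, colnames) {
  cont <- c(catalog$clinical$name[catalog$clinical$type == "continuous"],
            catalog$biomarker$name[catalog$biomarker$type == "continuous"])
  intersect(colnames, cont)
}

#' Fit standardization parameters on a training design matrix
#'
#' Continuous columns are centred to mean zero and scaled to unit variance;
#' one-hot and binary columns are left untouched. Zero-variance continuous
#' columns are mapped to all-zero with a warning (they carry no information
#' but would otherwise divide by zero).
#'
#' @param X Numeric training design matrix.
#' @param continuous Character vector naming the columns of `X` to scale.
#' @return An object of class `standardizer` with `center`, `scale` and
#'   `zero_var` fields.
#' @export
standardize <- function(X, continuous) {
  if (nrow(X) == 0) stop("cannot standardize an empty matrix")
  continuous <- intersect(continuous, colnames(X))
  center <- vapply(continuous, function(cn) mean(X[, cn]), numeric(1))
  scale <- vapply(continuous, function(cn) sd(X[, cn]), numeric(1))
  zero_var <- names(scale)[!is.na(scale) & scale == 0]
  if (length(zero_var) > 0) {
    warning("zero-variance column(s) mapped to 0: ", paste(zero_var, collapse = ", "))
    scale[zero_var] <- 1
  }
  structure(list(center = center, scale = scale, zero_var = zero_var),
            class = "standardizer")
}

#' Apply fitted standardization parameters to a design matrix
#'
#' @param params A `standardizer` from [standardize()]; training means and
#'   scales are used, never recomputed on `X`.
#' @param X Numeric design matrix with the training column layout.
#' @return The transformed matrix.
#' @export
apply_standardization <- function(params, X) {
  for (cn in names(params$center)) {
    X[, cn] <- (X[, cn] - params$center[[cn]]) / params$scale[[cn]]
  }
  if (length(params$zero_var) > 0) X[, params$zero_var] <- 0
  X
}
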