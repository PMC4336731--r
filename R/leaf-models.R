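# Base learner of every leaf: logistic regression with an l2 (ridge) penalty
# on the slope coefficients. The penalized log-likelihood is
#   l(b0, b) - penalty * ||b||^2
# with the intercept b0 unpenalized and the penalty applied exactly as the
# coefficient of ||b||^2 (no 1/n scaling), so fits are comparable across
# sample sizes. Fitting is deterministic: Newton iterations from a zero start
# with step-halving, run to a gradient norm below `tol`.

#' Fit an l2-regularized logistic regression on an eligible sample
#'
#' Encodes the raw features of `sample` (one-hot for categoricals),
#' standardizes continuous columns on the training data, and maximizes the
#' penalized log-likelihood by Newton's method from a zero start. The fitted
#' object stores everything needed to score a raw record: encoder, training
#' standardization parameters, coefficients and metadata.
#'
#' @param sample An `eligible_sample` from [filter_eligible()], or any list
#'   with `data` (raw feature data frame) and `y` (0/1 vector). Both classes
#'   must be present.
#' @param penalty Non-negative ridge penalty; default 0.01, the value fixed
#'   for every model in the cross-validation scheme.
#' @param catalog A [feature_catalog()].
#' @param max_iter Maximum Newton iterations.
#' @param tol Convergence tolerance on the Euclidean norm of the penalized
#'   score vector (default 1e-6).
#' @return An object of class `logistic_model`.
#' @export
fit_l2_logistic <- function(sample, penalty = 0.01, catalog = feature_catalog(),
                            max_iter = 100L, tol = 1e-6) {
  y <- as.numeric(sample$y)
  stopifnot(all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("both classes must be present to fit")
  enc <- encode_design(sample$data, catalog)
  std <- standardize(enc$X, continuous_columns(catalog, colnames(enc$X)))
  Xs <- apply_standardization(std, enc$X)
  X <- cbind(`(Intercept)` = 1, Xs)
  p_dim <- ncol(X)
  pen_mask <- c(0, rep(1, p_dim - 1L))  # intercept unpenalized

  obj <- function(beta, eta) {
    # penalized log-likelihood; log1p(exp()) guarded for large |eta|
    ll <- sum(y * eta - ifelse(eta > 30, eta, log1p(exp(eta))))
    ll - penalty * sum((beta * pen_mask)^2)
  }
  beta <- rep(0, p_dim)
  eta <- drop(X %*% beta)
  f <- obj(beta, eta)
  grad_norm <- Inf
  for (iter in seq_len(max_iter)) {
    p <- plogis(eta)
    grad <- drop(crossprod(X, y - p)) - 2 * penalty * beta * pen_mask
    grad_norm <- sqrt(sum(grad^2))
    if (grad_norm <= tol) break
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(X * w, X)
    diag(H) <- diag(H) + 2 * penalty * pen_mask
    step <- solve(H, grad)
    # step-halving keeps the penalized log-likelihood non-decreasing
    t_step <- 1
    repeat {
      beta_new <- beta + t_step * step
      eta_new <- drop(X %*% beta_new)
      f_new <- obj(beta_new, eta_new)
      if (f_new >= f - 1e-12 || t_step < 1e-8) break
      t_step <- t_step / 2
    }
    beta <- beta_new; eta <- eta_new; f <- f_new
  }
  if (grad_norm > tol) {
    # final check (gradient recomputed at the accepted iterate)
    p <- plogis(eta)
    grad <- drop(crossprod(X, y - p)) - 2 * penalty * beta * pen_mask
    grad_norm <- sqrt(sum(grad^2))
    if (grad_norm > tol) {
      stop(sprintf("l2-logistic fit did not converge: gradient norm %.3e after %d iterations",
                   grad_norm, max_iter))
    }
  }
  structure(
    list(intercept = unname(beta[1]),
         coefficients = setNames(beta[-1], colnames(Xs)),
         standardizer = std,
         encoder = enc$encoder,
         features = names(sample$data),
         clinical_set = sample$clinical_set,
         biomarker_set = sample$biomarker_set,
         subgroup = sample$subgroup,
         arm = sample$arm,
         endpoint = sample$endpoint,
         penalty = penalty,
         n = length(y), n_pos = sum(y),
         iterations = iter, grad_norm = grad_norm,
         loglik_penalized = f),
    class = "logistic_model"
  )
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("<l2-logistic model:", length(x$coefficients), "coefficients, n =", x$n,
      ", penalty =", x$penalty, ">\n")
  invisible(x)
}

#' Predicted event probability for raw records
#'
#' Applies the model's stored encoding and training standardization, then the
#' logistic link. Every feature the model uses must be present and
#' non-missing.
#'
#' @param model A `logistic_model`.
#' @param newdata Data frame of raw records (cohort rows or feature columns).
#' @param catalog A [feature_catalog()].
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict_prob <- function(model, newdata, catalog = feature_catalog()) {
  miss_col <- setdiff(model$features, names(newdata))
  if (length(miss_col) > 0) {
    stop("missing required feature(s): ", paste(miss_col, collapse = ", "))
  }
  feat_df <- newdata[, model$features, drop = FALSE]
  has_na <- vapply(model$features, function(f) anyNA(feat_df[[f]]), logical(1))
  if (any(has_na)) {
    stop("missing required feature(s): ",
         paste(model$features[has_na], collapse = ", "))
  }
  enc <- encode_design(feat_df, catalog, encoder = model$encoder)
  Xs <- apply_standardization(model$standardizer, enc$X)
  plogis(model$intercept + drop(Xs %*% model$coefficients[colnames(Xs)]))
}

#' Area under the ROC curve (midrank convention)
#'
#' The probability that a randomly chosen event outscores a randomly chosen
#' non-event, with ties counted one half (Mann-Whitney statistic).
#'
#' @param scores Numeric scores (higher = more event-like).
#' @param labels 0/1 labels, both classes present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present to compute AUC")
  r <- rank(scores)  # midranks
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# ---------------------------------------------------------------------------
# JSON serialization (audit / reload)

model_to_list <- function(model) {
  list(intercept = model$intercept,
       coefficients = as.list(model$coefficients),
       standardizer = list(center = as.list(model$standardizer$center),
                           scale = as.list(model$standardizer$scale),
                           zero_var = model$standardizer$zero_var),
       encoder = model$encoder,
       features = model$features,
       clinical_set = model$clinical_set,
       biomarker_set = model$biomarker_set,
       subgroup = unclass(model$subgroup),
       arm = model$arm, endpoint = model$endpoint,
       penalty = model$penalty, n = model$n, n_pos = model$n_pos)
}

model_from_list <- function(x) {
  structure(
    list(intercept = x$intercept,
         coefficients = unlist(x$coefficients),
         standardizer = structure(
           list(center = unlist(x$standardizer$center),
                scale = unlist(x$standardizer$scale),
                zero_var = as.character(unlist(x$standardizer$zero_var))),
           class = "standardizer"),
         encoder = x$encoder,
         features = unlist(x$features),
         clinical_set = x$clinical_set,
         biomarker_set = x$biomarker_set,
         subgroup = do.call(subgroup_spec, x$subgroup),
         arm = x$arm, endpoint = x$endpoint,
         penalty = x$penalty, n = x$n, n_pos = x$n_pos),
    class = "logistic_model"
  )
}

#' Serialize a fitted leaf model to JSON
#' @param model A `logistic_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(model_to_list(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Reload a leaf model serialized with [write_model_json()]
#' @param path JSON file path.
#' @return A `logistic_model`.
#' @export
read_model_json <- function(path) {
  model_from_list(jsonlite::read_json(path))
}
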