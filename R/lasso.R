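# L1-penalized logistic regression: coordinate descent over a decreasing
# lambda path (via glmnet) with stratified cross-validated lambda
# selection.

# Muffle glmnet advisories that are structural here: clinical group sizes
# put < 8 of a class in CV folds by design, and unconverged path-tail
# lambdas under near-separation are never the CV optimum.
quiet_glmnet <- function(expr) {
  withCallingHandlers(
    expr,
    warning = function(w) {
      if (grepl("fewer than 8|Convergence for .*lambda|collapsing to unique",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
}

# Binary word indicators are deliberately NOT standardized (a common 0/1
# scale keeps |beta| comparable across words for the ranking criteria);
# continuous covariates are z-scored before entry.

#' Stratified fold assignment
#'
#' Shuffles within each class and deals folds cyclically, so every fold
#' holds both classes whenever each class has at least k members.
#' @param y Binary outcome (0/1 or two-level factor).
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer fold id per row.
#' @export
make_stratified_folds <- function(y, k, seed) {
  y <- as.integer(factor(y)) - 1L
  folds <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

#' Fit an L1-penalized logistic regression with CV lambda selection
#'
#' Solves the penalized binomial likelihood over a decreasing lambda path
#' by coordinate descent and selects the lambda minimizing the mean
#' cross-validated binomial deviance (ties resolved toward the larger,
#' more parsimonious lambda). Constant columns are dropped first (and
#' recorded); the penalty keeps coefficients finite even under complete
#' separation. The final model is refit on all rows at the selected
#' lambda.
#'
#' @param x Predictor matrix (binary indicators, optionally with z-scored
#'   continuous columns appended).
#' @param y Binary outcome (0/1 or two-level factor; second level = 1).
#' @param cv_folds Number of CV folds (default 4); reduced with a warning
#'   when the smaller class has fewer members.
#' @param seed Seed for the stratified fold assignment.
#' @param thresh Coordinate-descent convergence threshold (tighten for
#'   near-unpenalized fits).
#' @param lambda Optional fixed penalty: skips cross-validation and fits at
#'   exactly this lambda (0 gives the unpenalized logistic fit on
#'   non-separable data; very large values give the null model).
#' @return A `lasso_fit`: `intercept`, `beta` (named vector over retained
#'   columns), `selected` (names with nonzero beta), `lambda`,
#'   `lambda_path`, `cv_deviance`, `cv_folds`, `seed`,
#'   `dropped_constant`.
#' @export
fit_lasso_logistic <- function(x, y, cv_folds = 4L, seed = 1L,
                               thresh = 1e-8, lambda = NULL) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  yf <- factor(y)
  if (nlevels(yf) != 2L) stop_pre("y must have exactly two classes")
  yi <- as.integer(yf) - 1L
  keep <- apply(x, 2, function(col) length(unique(col)) > 1L)
  dropped <- colnames(x)[!keep]
  x <- x[, keep, drop = FALSE]
  if (ncol(x) == 0L) stop_pre("no non-constant predictor columns")
  if (min(table(yi)) < 2L) {
    stop_pre("each class needs at least 2 observations")
  }
  if (!is.null(lambda)) {
    # fixed-penalty fit, no cross-validation
    padded <- ncol(x) == 1L
    xg <- if (padded) cbind(x, ".pad" = 0) else x
    # a decreasing path ending at the requested lambda stabilizes the
    # coordinate-descent warm starts
    lam_seq <- sort(unique(c(lambda, exp(seq(log(max(lambda, 1e-4) * 1e3),
                                             log(max(lambda, 1e-8)),
                                             length.out = 60)))),
                    decreasing = TRUE)
    fit <- quiet_glmnet(
      glmnet::glmnet(xg, yi, family = "binomial", lambda = lam_seq,
                     standardize = FALSE, thresh = thresh))
    cf <- as.matrix(stats::coef(fit, s = lambda, exact = FALSE))
    beta <- cf[-1L, 1L]
    if (padded) beta <- beta[names(beta) != ".pad"]
    return(structure(
      list(intercept = unname(cf[1L, 1L]), beta = beta,
           selected = names(beta)[beta != 0], lambda = lambda,
           lambda_path = lam_seq, cv_deviance = NULL, cv_folds = NA_integer_,
           seed = seed, dropped_constant = dropped, classes = levels(yf)),
      class = "lasso_fit"))
  }
  n_min <- min(table(yi))
  if (n_min < 3L) {
    # a class of 1-2 members cannot survive any CV split; fall back to a
    # fixed moderate penalty (a tenth of lambda_max) rather than fail
    warning("smallest class has ", n_min,
            " members; too few for cross-validation, fitting at ",
            "lambda = 0.1 * lambda_max", call. = FALSE)
    l0 <- max(abs(crossprod(x, yi - mean(yi)))) / length(yi)
    out <- fit_lasso_logistic(x, yf, seed = seed, thresh = thresh,
                              lambda = max(0.1 * l0, 1e-4))
    out$dropped_constant <- dropped
    return(out)
  }
  k <- as.integer(cv_folds)
  if (n_min < k) {
    k <- max(3L, n_min)  # glmnet's CV needs at least three folds
    warning("smallest class has ", n_min, " members; reducing CV folds to ",
            k, call. = FALSE)
  }
  foldid <- make_stratified_folds(yi, k, seed)
  # glmnet requires >= 2 columns; pad with an all-zero dummy if needed
  # (constant columns are unpenalized no-ops with standardize = FALSE).
  padded <- ncol(x) == 1L
  xg <- if (padded) cbind(x, ".pad" = 0) else x
  # With very few predictors a fold's auto-generated lambda path can
  # degenerate to a single value and break CV; supply an explicit grid.
  lam_grid <- if (ncol(xg) <= 2L) {
    l0 <- max(max(abs(crossprod(xg, yi - mean(yi)))) / length(yi), 1e-3)
    exp(seq(log(l0 * 1.1), log(l0 * 1e-4), length.out = 60))
  } else NULL
  cvfit <- quiet_glmnet(
    glmnet::cv.glmnet(xg, yi, family = "binomial", foldid = foldid,
                      standardize = FALSE, type.measure = "deviance",
                      thresh = thresh, lambda = lam_grid))
  lambda <- cvfit$lambda.min  # first (largest) lambda attaining min cvm
  cf <- as.matrix(stats::coef(cvfit$glmnet.fit, s = lambda, exact = FALSE))
  beta <- cf[-1L, 1L]
  if (padded) beta <- beta[names(beta) != ".pad"]
  structure(
    list(intercept = unname(cf[1L, 1L]), beta = beta,
         selected = names(beta)[beta != 0], lambda = lambda,
         lambda_path = cvfit$lambda, cv_deviance = cvfit$cvm,
         cv_folds = k, seed = seed, dropped_constant = dropped,
         classes = levels(yf)),
    class = "lasso_fit"
  )
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat("L1-penalized logistic fit: lambda =", signif(x$lambda, 4), "|",
      length(x$selected), "of", length(x$beta), "predictors selected\n")
  invisible(x)
}

#' Predict from a `lasso_fit`
#'
#' @param object A `lasso_fit`.
#' @param newdata Matrix containing the fitted predictor columns.
#' @param type `"response"` (probability of the second class), `"class"`
#'   (0.5 threshold) or `"link"`.
#' @param ... Unused.
#' @export
predict.lasso_fit <- function(object, newdata, type = c("response", "class",
                                                        "link"), ...) {
  type <- match.arg(type)
  m <- as.matrix(newdata)[, names(object$beta), drop = FALSE]
  eta <- drop(object$intercept + m %*% object$beta)
  switch(type,
         link = eta,
         response = stats::plogis(eta),
         class = as.integer(stats::plogis(eta) > 0.5))
}
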