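#' Standardize a biomarker matrix
#'
#' Centers and scales each column to mean 0, SD 1 (denominator `n - 1`),
#' retaining the scaling parameters so new samples can be scored on the
#' training scale. Constant columns cannot be scaled; they are excluded
#' with a warning.
#'
#' @param x Numeric matrix or data.frame (subjects x biomarkers).
#' @return A list of class `standardizer`: `x` (the standardized matrix),
#'   `center`, `scale` (named vectors) and `dropped` (constant columns).
#' @export
standardize <- function(x) {
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  dropped <- colnames(x)[scl == 0 | is.na(scl)]
  if (length(dropped)) {
    warning("constant column(s) excluded: ", paste(dropped, collapse = ", "))
    keep <- setdiff(colnames(x), dropped)
    x <- x[, keep, drop = FALSE]
    ctr <- ctr[keep]; scl <- scl[keep]
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, `/`)
  structure(list(x = z, center = ctr, scale = scl, dropped = dropped),
            class = "standardizer")
}

#' Apply stored scaling parameters to new data
#'
#' @param params A `standardizer` (or list with `center` and `scale`).
#' @param x New data with at least the trained columns.
#' @return The matrix scaled with the stored parameters (column means of
#'   the result need not be 0).
#' @export
apply_standardization <- function(params, x) {
  x <- as.matrix(x)
  nm <- names(params$center)
  miss <- setdiff(nm, colnames(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  sweep(sweep(x[, nm, drop = FALSE], 2, params$center), 2, params$scale, `/`)
}

# AUC of scores against binary labels by the rank-sum (Mann-Whitney)
# identity, ties by average rank
.auc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# elastic-net lambda grid: lambda_max down 4 decades, log-spaced
.lambda_grid <- function(x, y, alpha, nlambda = 50, decades = 4) {
  yc <- y - mean(y)
  lmax <- max(abs(crossprod(x, yc))) / (nrow(x) * max(alpha, 1e-3))
  exp(seq(log(lmax), log(lmax) - decades * log(10), length.out = nlambda))
}

#' Leave-one-out cross-validated AUC over a penalty grid
#'
#' For each left-out subject the elastic net is refit on the remainder over
#' the whole `lambda` path and the subject's predicted probability is
#' recorded; the AUC at each penalty is then computed over the held-out
#' predictions against the arm labels. A fold whose training set lacks one
#' arm is skipped with a warning.
#'
#' @param x Standardized biomarker matrix.
#' @param y Binary arm label (0/1 or two-level factor).
#' @param alpha Elastic-net mixing parameter (default 0.5).
#' @param lambda_grid Decreasing penalty sequence; by default 50 log-spaced
#'   values spanning 4 decades below the data-driven maximum.
#' @return A list: `lambda`, `auc` (per penalty), `best_lambda` (maximum
#'   AUC, ties broken toward the larger penalty, i.e. the sparser model),
#'   `best_auc`, and `heldout` (subjects x penalties prediction matrix).
#' @export
loo_cv_auc <- function(x, y, alpha = 0.5, lambda_grid = NULL) {
  x <- as.matrix(x)
  y <- .as01(y)
  n <- nrow(x)
  if (n < 10) stop("need n >= 10 for leave-one-out cross-validation")
  if (is.null(lambda_grid)) lambda_grid <- .lambda_grid(x, y, alpha)
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  preds <- matrix(NA_real_, n, length(lambda_grid))
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2) {
      warning("fold ", i, " skipped: one arm absent from training set")
      next
    }
    fit <- glmnet::glmnet(x[-i, , drop = FALSE], yi, family = "binomial",
                          alpha = alpha, lambda = lambda_grid,
                          standardize = FALSE)
    preds[i, ] <- predict(fit, x[i, , drop = FALSE], type = "response",
                          s = lambda_grid, exact = FALSE)
  }
  ok <- !is.na(preds[, 1])
  aucs <- apply(preds[ok, , drop = FALSE], 2, .auc, y = y[ok])
  best <- which(aucs == max(aucs))[1]   # grid is decreasing: first = largest
  list(lambda = lambda_grid, auc = aucs,
       best_lambda = lambda_grid[best], best_auc = aucs[best],
       heldout = preds)
}

.as01 <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.character(y)) y <- as.integer(factor(y)) - 1L
  if (!all(y %in% c(0, 1))) stop("arm label must be binary")
  as.numeric(y)
}

#' Fit a treatment-response biomarker signature
#'
#' Regresses the treatment-arm label on the standardized biomarkers by
#' elastic-net penalized logistic regression (mixing parameter `alpha`,
#' default 0.5), selecting the penalty by leave-one-out cross-validated
#' AUC. The biomarkers with nonzero coefficients, and those coefficients
#' as weights, form the signature; the signature score of a sample is the
#' weighted sum of its standardized biomarker values.
#'
#' @param trial A `sim_trial`, or a list with elements `x` (biomarker
#'   matrix) and `arm`.
#' @param alpha Elastic-net mixing parameter in (0, 1]; 0.5 by default.
#' @param lambda Optional fixed penalty (> 0); skips cross-validation.
#' @param visit Which visit's biomarker levels to model for a `sim_trial`
#'   (default the final visit; `"change"` for final minus baseline).
#' @param lambda_grid Optional penalty grid for cross-validation.
#' @return An object of class `signature_model`: `biomarkers` and `weights`
#'   (the nonzero-coefficient terms), `alpha`, `lambda`, `cv_auc`,
#'   `scaling` (training center/scale), `cv` (the per-penalty AUC table)
#'   and `fit_names` (all candidate biomarkers).
#' @export
fit_signature <- function(trial, alpha = 0.5, lambda = NULL, visit = NULL,
                          lambda_grid = NULL) {
  tb <- if (inherits(trial, "sim_trial")) trial_biomarkers(trial, visit)
        else trial
  y <- .as01(tb$arm)
  std <- standardize(tb$x)
  x <- std$x
  if (!is.null(lambda) && lambda <= 0)
    stop("lambda must be > 0: the unpenalized fit is refused ",
         "(complete separation is possible)")
  cv <- NULL
  cv_auc <- NA_real_
  if (is.null(lambda)) {
    cv <- loo_cv_auc(x, y, alpha = alpha, lambda_grid = lambda_grid)
    lambda <- cv$best_lambda
    cv_auc <- cv$best_auc
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-12)
  cf <- as.vector(coef(fit, s = lambda))[-1]   # drop intercept
  names(cf) <- colnames(x)
  w <- cf[cf != 0]
  structure(list(biomarkers = names(w), weights = w,
                 alpha = alpha, lambda = lambda, cv_auc = cv_auc,
                 intercept = as.vector(coef(fit, s = lambda))[1],
                 scaling = list(center = std$center, scale = std$scale),
                 cv = if (!is.null(cv)) data.frame(lambda = cv$lambda,
                                                   auc = cv$auc),
                 fit_names = colnames(x), coefficients = cf),
            class = "signature_model")
}

#' Construct a signature model from explicit weights
#'
#' @param weights Named numeric vector of biomarker weights.
#' @param alpha,lambda,cv_auc Optional provenance fields.
#' @return A `signature_model`.
#' @export
signature_model <- function(weights, alpha = 0.5, lambda = NA_real_,
                            cv_auc = NA_real_) {
  stopifnot(!is.null(names(weights)), all(is.finite(weights)))
  structure(list(biomarkers = names(weights), weights = weights,
                 alpha = alpha, lambda = lambda, cv_auc = cv_auc,
                 intercept = 0,
                 scaling = NULL, cv = NULL, fit_names = names(weights),
                 coefficients = weights),
            class = "signature_model")
}

#' The published 20-term signature
#'
#' Returns the printed signature exactly as reported: 18 proteins and two
#' sex hormones with their elastic-net coefficients as weights. The score
#' of a sample is the weighted sum of its standardized biomarker values.
#'
#' @return A `signature_model` with 20 weights and the reported
#'   cross-validated AUC (0.61).
#' @export
published_signature <- function() {
  w <- c(testosterone = 0.21, SHBG = 0.21, CA1 = 0.007, CCL5 = -0.23,
         LTBP2 = -0.14, F11 = -0.13, COMP = -0.004, CA4 = 0.08,
         MBL2 = 0.04, CD46 = 0.01, REG1A = 0.27, FCN2 = -0.03,
         PRSS2 = -0.35, CNDP1 = -0.18, THBS4 = -0.15, TGFBR3 = -0.11,
         DEFA1 = 0.27, APOM = -0.25, LCN2 = -0.025, PLA2G7 = -0.14)
  signature_model(w, alpha = 0.5, cv_auc = 0.61)
}

#' Score samples with a signature
#'
#' `score_i = sum_k w_k x_ik` over the signature's biomarkers; inputs are
#' expected on the standardized scale (see [apply_standardization()]).
#'
#' @param signature A `signature_model`.
#' @param x Standardized biomarker matrix/data.frame containing every
#'   signature biomarker as a column.
#' @return Numeric vector of per-subject scores.
#' @export
score <- function(signature, x) {
  stopifnot(inherits(signature, "signature_model"))
  x <- as.matrix(x)
  miss <- setdiff(signature$biomarkers, colnames(x))
  if (length(miss))
    stop("missing biomarker column(s): ", paste(miss, collapse = ", "))
  as.vector(x[, signature$biomarkers, drop = FALSE] %*% signature$weights)
}

#' @export
coef.signature_model <- function(object, ...) object$weights

#' @export
#' @param object,newdata,standardize `predict` arguments: new biomarker
#'   data and whether to apply the stored training scaling first.
#' @rdname score
predict.signature_model <- function(object, newdata,
                                    standardize = FALSE, ...) {
  if (standardize) {
    if (is.null(object$scaling)) stop("model carries no scaling parameters")
    newdata <- apply_standardization(object$scaling, newdata)
  }
  score(object, newdata)
}

#' @export
print.signature_model <- function(x, ...) {
  cat("Biomarker signature:", length(x$weights), "terms (alpha =",
      x$alpha, ", lambda =", signif(x$lambda, 3), ")\n")
  if (!is.na(x$cv_auc)) cat("LOO-CV AUC:", round(x$cv_auc, 3), "\n")
  w <- sort(x$weights, decreasing = TRUE)
  cat(paste0(names(w), "*", signif(w, 3), collapse = " + "), "\n")
  invisible(x)
}

#' Permutation test of signature coefficients
#'
#' Shuffles the treatment labels and refits the elastic net `B` times at
#' the observed model's penalty, producing a reference coefficient
#' distribution under no treatment-biomarker association. The empirical
#' p-value per biomarker is the proportion of permutations in which the
#' absolute refitted coefficient is at least the observed absolute
#' coefficient.
#'
#' @param trial A `sim_trial` or list with `x` and `arm`.
#' @param model The observed `signature_model` (refit if omitted).
#' @param B Number of permutations (default 500).
#' @param seed Integer seed; results are deterministic given it.
#' @param visit Passed to [trial_biomarkers()] for `sim_trial` input.
#' @return A data.frame of class `permutation_result`: `biomarker`,
#'   `coef` (observed), `p_empirical`, with attribute `B`.
#' @export
permutation_test <- function(trial, model = NULL, B = 500, seed = 1,
                             visit = NULL) {
  if (B < 1) stop("B must be >= 1")
  tb <- if (inherits(trial, "sim_trial")) trial_biomarkers(trial, visit)
        else trial
  y <- .as01(tb$arm)
  if (is.null(model)) model <- fit_signature(tb)
  x <- standardize(tb$x)$x
  obs <- model$coefficients[colnames(x)]
  set.seed(seed)
  exceed <- numeric(ncol(x))
  for (b in seq_len(B)) {
    yp <- sample(y)
    fit <- glmnet::glmnet(x, yp, family = "binomial", alpha = model$alpha,
                          lambda = model$lambda, standardize = FALSE)
    cfp <- as.vector(coef(fit, s = model$lambda))[-1]
    exceed <- exceed + (abs(cfp) >= abs(obs))
  }
  out <- data.frame(biomarker = colnames(x), coef = unname(obs),
                    p_empirical = exceed / B, stringsAsFactors = FALSE)
  attr(out, "B") <- B
  class(out) <- c("permutation_result", "data.frame")
  out
}

#' Selection stability across leave-one-out folds
#'
#' Refits the elastic net at the model's penalty with each subject left
#' out in turn and tabulates, per biomarker, how often it is selected
#' (nonzero coefficient), the corresponding percentage, and how often its
#' coefficient sign agrees with the full-data signature.
#'
#' @inheritParams permutation_test
#' @return A data.frame of class `stability_table`: `biomarker`,
#'   `selected`, `pct`, `sign_consistent`, `n_folds`.
#' @export
stability_table <- function(trial, model = NULL, visit = NULL) {
  tb <- if (inherits(trial, "sim_trial")) trial_biomarkers(trial, visit)
        else trial
  y <- .as01(tb$arm)
  if (is.null(model)) model <- fit_signature(tb)
  x <- standardize(tb$x)$x
  obs_sign <- sign(model$coefficients[colnames(x)])
  n <- nrow(x)
  sel <- consist <- numeric(ncol(x))
  folds <- 0L
  for (i in seq_len(n)) {
    yi <- y[-i]
    if (length(unique(yi)) < 2) next
    fit <- glmnet::glmnet(x[-i, , drop = FALSE], yi, family = "binomial",
                          alpha = model$alpha, lambda = model$lambda,
                          standardize = FALSE)
    cf <- as.vector(coef(fit, s = model$lambda))[-1]
    sel <- sel + (cf != 0)
    consist <- consist + (cf != 0 & sign(cf) == obs_sign)
    folds <- folds + 1L
  }
  out <- data.frame(biomarker = colnames(x), selected = sel,
                    pct = 100 * sel / folds, sign_consistent = consist,
                    n_folds = folds, stringsAsFactors = FALSE)
  class(out) <- c("stability_table", "data.frame")
  out
}
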