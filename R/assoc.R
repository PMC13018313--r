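new_assoc_result <- function(outcome, estimate, se, p, n, family) {
  data.frame(outcome = outcome, estimate = estimate, se = se,
             or = if (family == "logistic") exp(estimate) else NA_real_,
             ci_low = estimate - 1.96 * se, ci_high = estimate + 1.96 * se,
             p = p, q = NA_real_, n = n, stringsAsFactors = FALSE)
}

#' Covariate-adjusted logistic association
#'
#' Maximum-likelihood logistic regression of a binary outcome on a
#' standardized exposure plus pass-through covariates; reported as the
#' log-OR (and OR) per SD of exposure with a Wald CI.
#'
#' @param data Data.frame holding all columns.
#' @param outcome Binary outcome column name.
#' @param exposure Exposure column name (SD scale).
#' @param covariates Optional covariate column names.
#' @return A one-row `AssociationResult` data.frame: `outcome`,
#'   `estimate` (log-OR), `se`, `or`, `ci_low`, `ci_high`, `p`, `q`
#'   (NA until [bh_fdr()] is applied across a family), `n`.
#' @export
logistic_assoc <- function(data, outcome, exposure, covariates = NULL) {
  y <- data[[outcome]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1")
  form <- paste(outcome, "~", exposure)
  if (!is.null(covariates))
    form <- paste(form, "+", paste(covariates, collapse = " + "))
  fit <- glm(stats::as.formula(form), data = data, family = binomial())
  if (!fit$converged) stop("logistic fit did not converge (deviance ",
                           signif(fit$deviance, 6), ")")
  mu <- fitted(fit)
  if (any(mu > 1 - 1e-8) || any(mu < 1e-8))
    warning("possible separation: fitted probabilities at the boundary")
  cf <- summary(fit)$coefficients[exposure, ]
  new_assoc_result(outcome, cf[1], cf[2], cf[4], nrow(data), "logistic")
}

#' Covariate-adjusted linear association
#'
#' OLS regression of a continuous outcome (SD units) on a standardized
#' exposure plus covariates, with an optional heteroskedasticity-robust
#' (HC1) standard error.
#'
#' @inheritParams logistic_assoc
#' @param robust Use the HC1 sandwich SE instead of the model-based one.
#' @return A one-row `AssociationResult` data.frame.
#' @export
linear_assoc <- function(data, outcome, exposure, covariates = NULL,
                         robust = FALSE) {
  form <- paste(outcome, "~", exposure)
  if (!is.null(covariates))
    form <- paste(form, "+", paste(covariates, collapse = " + "))
  mf <- stats::model.frame(stats::as.formula(form), data = data)
  X <- stats::model.matrix(stats::as.formula(form), data = data)
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  fit <- lm(stats::as.formula(form), data = data)
  est <- coef(fit)[exposure]
  if (robust) {
    # HC1 sandwich
    e <- stats::residuals(fit)
    n <- nrow(X); k <- ncol(X)
    XtXi <- solve(crossprod(X))
    meat <- crossprod(X * e)
    V <- n / (n - k) * XtXi %*% meat %*% XtXi
    se <- sqrt(diag(V))[colnames(X) == exposure]
    p <- 2 * pt(-abs(est / se), fit$df.residual)
  } else {
    se <- summary(fit)$coefficients[exposure, 2]
    p <- summary(fit)$coefficients[exposure, 4]
  }
  new_assoc_result(outcome, unname(est), unname(se), unname(p),
                   nrow(mf), "linear")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment with enforced monotonicity, capped at 1.
#'
#' @param pvals Numeric p-values in (0, 1].
#' @return The BH-adjusted q-values, in the input order.
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1))
    stop("p-values must lie in (0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Multi-source panel screen with direction consistency
#'
#' Combines trial effects, observational associations and MR estimates
#' over a shared outcome panel. FDR is applied within each result family
#' (observational; MR) separately; an outcome is flagged iff both
#' families are significant at `alpha` after adjustment and all three
#' effect directions agree.
#'
#' @param trial_effects Data.frame with `outcome` and `estimate` columns
#'   (trial-scale effects).
#' @param obs_results Data.frame of association results (`outcome`,
#'   `estimate`, `p`).
#' @param mr_results Data.frame of MR results (`outcome`, `estimate`/
#'   `beta`, `p`).
#' @param alpha FDR threshold (default 0.05).
#' @return A data.frame of class `panel_screen`: per outcome the three
#'   directions, the two q-values and the consistency `flag`.
#' @export
panel_screen <- function(trial_effects, obs_results, mr_results,
                         alpha = 0.05) {
  if (!is.null(mr_results$beta) && is.null(mr_results$estimate))
    mr_results$estimate <- mr_results$beta
  nms <- trial_effects$outcome
  miss <- c(setdiff(nms, obs_results$outcome),
            setdiff(nms, mr_results$outcome))
  if (length(miss))
    stop("outcome(s) missing from a result set: ",
         paste(unique(miss), collapse = ", "))
  obs <- obs_results[match(nms, obs_results$outcome), ]
  mr <- mr_results[match(nms, mr_results$outcome), ]
  obs_q <- bh_fdr(obs$p)
  mr_q <- bh_fdr(mr$p)
  dir_agree <- sign(trial_effects$estimate) == sign(obs$estimate) &
    sign(obs$estimate) == sign(mr$estimate)
  out <- data.frame(outcome = nms,
                    trial_direction = sign(trial_effects$estimate),
                    obs_estimate = obs$estimate, obs_q = obs_q,
                    mr_estimate = mr$estimate, mr_q = mr_q,
                    flag = obs_q < alpha & mr_q < alpha & dir_agree,
                    stringsAsFactors = FALSE)
  class(out) <- c("panel_screen", "data.frame")
  out
}
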