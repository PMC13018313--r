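new_mr_estimate <- function(method, beta, se, p, n_snp, ...) {
  structure(list(method = method, beta = beta, se = se,
                 ci = beta + c(-1, 1) * 1.96 * se, p = p, n_snp = n_snp,
                 ...),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: beta %.4f (SE %.4f, 95%% CI %.4f, %.4f), OR %.3f, p = %.3g [%d SNPs]\n",
              x$method, x$beta, x$se, x$ci[1], x$ci[2], exp(x$beta), x$p,
              x$n_snp))
  if (!is.null(x$egger_intercept))
    cat(sprintf("  Egger intercept %.4f (p = %.3g)\n", x$egger_intercept,
                x$egger_intercept_p))
  if (!is.null(x$q_stat))
    cat(sprintf("  Cochran's Q = %.2f on %d df\n", x$q_stat, x$n_snp - 1L))
  invisible(x)
}

#' @export
coef.mr_estimate <- function(object, ...) {
  setNames(object$beta, object$method)
}

#' Wald ratio causal estimate for a single variant
#'
#' The per-variant causal estimate is the variant's outcome association
#' divided by its exposure association; the default standard error is the
#' first-order delta approximation `|se_out / beta_exp|`, with a
#' second-order option that also propagates the exposure uncertainty.
#'
#' @param beta_exp,se_exp Exposure association and SE.
#' @param beta_out,se_out Outcome association and SE.
#' @param second_order Use the second-order delta SE.
#' @return An `mr_estimate`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       second_order = FALSE) {
  if (beta_exp == 0) stop("exposure association is zero: ratio undefined")
  theta <- beta_out / beta_exp
  se <- if (second_order) {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  } else {
    abs(se_out / beta_exp)
  }
  new_mr_estimate("Wald ratio", theta, se, 2 * pnorm(-abs(theta / se)), 1L)
}

.ratios <- function(pairs) {
  list(theta = pairs$beta_out / pairs$beta_exp,
       se = abs(pairs$se_out / pairs$beta_exp))
}

#' Inverse-variance-weighted meta-analysis of Wald ratios
#'
#' Combines the per-variant ratio estimates with weights
#' `w_j = beta_exp_j^2 / se_out_j^2`, equivalent to the zero-intercept
#' weighted least-squares regression of outcome betas on exposure betas
#' with weights `1/se_out^2`. The multiplicative random-effects model
#' (default when more than 3 instruments) inflates the fixed-effect SE by
#' `sqrt(Q/(J-1))` when Cochran's Q exceeds its degrees of freedom.
#'
#' @param pairs An `mr_pairs` data.frame.
#' @param model `"auto"` (random when J > 3), `"fixed"` or `"random"`.
#' @return An `mr_estimate` with `q_stat` (Cochran's Q) in its extras.
#' @export
mr_ivw <- function(pairs, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  J <- nrow(pairs)
  if (J < 1) stop("need at least one harmonized pair")
  r <- .ratios(pairs)
  w <- pairs$beta_exp^2 / pairs$se_out^2
  theta <- sum(w * r$theta) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  Q <- sum(w * (r$theta - theta)^2)
  use_random <- switch(model, fixed = FALSE, random = TRUE, auto = J > 3)
  se <- if (use_random && J > 1) se_fixed * max(1, sqrt(Q / (J - 1)))
        else se_fixed
  new_mr_estimate(if (use_random) "IVW (mult. random effects)" else "IVW (fixed)",
                  theta, se, 2 * pnorm(-abs(theta / se)), J,
                  q_stat = Q, q_p = if (J > 1) pchisq(Q, J - 1, lower.tail = FALSE)
                                    else NA_real_)
}

.weighted_median_point <- function(theta, w) {
  o <- order(theta)
  theta <- theta[o]; w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (any(abs(s - 0.5) < 1e-15)) return(theta[which.min(abs(s - 0.5))])
  below <- which(s < 0.5)
  if (length(below) == 0) return(theta[1])
  j <- max(below)
  if (j == length(theta)) return(theta[length(theta)])
  theta[j] + (theta[j + 1] - theta[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

#' Weighted-median causal estimate
#'
#' Orders the per-variant ratio estimates and takes the value at which the
#' normalized cumulative inverse-variance weight crosses one half, with
#' linear interpolation between adjacent ratios; consistent when up to
#' half of the weight comes from invalid instruments. The SE comes from a
#' parametric bootstrap resampling the exposure and outcome betas from
#' normal distributions.
#'
#' @param pairs An `mr_pairs` data.frame (at least 3 pairs).
#' @param n_boot Bootstrap draws for the SE (default 1000).
#' @param seed Integer seed.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed = 1) {
  J <- nrow(pairs)
  if (J < 3) stop("weighted median needs at least 3 pairs")
  r <- .ratios(pairs)
  w <- 1 / r$se^2
  theta <- .weighted_median_point(r$theta, w)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    be <- rnorm(J, pairs$beta_exp, pairs$se_exp)
    bo <- rnorm(J, pairs$beta_out, pairs$se_out)
    th <- bo / be
    .weighted_median_point(th, be^2 / pairs$se_out^2)
  }, numeric(1))
  se <- sd(boots)
  new_mr_estimate("Weighted median", theta, se,
                  2 * pnorm(-abs(theta / se)), J)
}

.mode_bandwidth <- function(theta, phi) {
  J <- length(theta)
  s <- 0.9 * min(sd(theta), mad(theta)) * J^(-1 / 5)
  phi * s
}

.weighted_mode_point <- function(theta, w, h) {
  if (h <= 0 || length(unique(theta)) == 1) return(theta[which.max(w)])
  f <- function(x) {
    vapply(x, function(xi) sum(w * dnorm(xi, theta, h)), numeric(1))
  }
  grid <- seq(min(theta) - 3 * h, max(theta) + 3 * h, length.out = 512)
  fx <- f(grid)
  i <- which.max(fx)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)$maximum
}

#' Weighted-mode causal estimate
#'
#' The mode of the inverse-variance-weighted normal-kernel density over
#' the per-variant ratio estimates; consistent when the largest group of
#' instruments sharing a causal estimate (a plurality) is valid. The
#' bandwidth is `phi` times the modified Silverman scale
#' `0.9 min(sd, mad) J^(-1/5)` of the ratios; SE by parametric bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param phi Bandwidth multiplier (default 1).
#' @return An `mr_estimate`.
#' @export
mr_weighted_mode <- function(pairs, phi = 1, n_boot = 1000, seed = 1) {
  J <- nrow(pairs)
  if (J < 3) stop("weighted mode needs at least 3 pairs")
  r <- .ratios(pairs)
  w <- 1 / r$se^2
  h <- .mode_bandwidth(r$theta, phi)
  theta <- .weighted_mode_point(r$theta, w, h)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    be <- rnorm(J, pairs$beta_exp, pairs$se_exp)
    bo <- rnorm(J, pairs$beta_out, pairs$se_out)
    th <- bo / be
    sb <- abs(pairs$se_out / be)
    hb <- .mode_bandwidth(th, phi)
    .weighted_mode_point(th, 1 / sb^2, hb)
  }, numeric(1))
  se <- sd(boots)
  new_mr_estimate("Weighted mode", theta, se,
                  2 * pnorm(-abs(theta / se)), J)
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with a
#' free intercept (weights `1/se_out^2`), after orienting all exposure
#' betas to be non-negative. The slope is the causal estimate; a nonzero
#' intercept indicates directional pleiotropy. Standard errors use a
#' multiplicative overdispersion factor bounded below by 1 and p-values
#' the t distribution on J - 2 degrees of freedom.
#'
#' @param pairs An `mr_pairs` data.frame (at least 3 pairs).
#' @return An `mr_estimate` with `egger_intercept`,
#'   `egger_intercept_se` and `egger_intercept_p` extras.
#' @export
mr_egger <- function(pairs) {
  J <- nrow(pairs)
  if (J < 3) stop("MR-Egger needs at least 3 pairs")
  flip <- sign(pairs$beta_exp)
  flip[flip == 0] <- 1
  x <- pairs$beta_exp * flip
  y <- pairs$beta_out * flip
  w <- 1 / pairs$se_out^2
  # weighted least squares with intercept via normal equations
  sw <- sum(w); sx <- sum(w * x); sxx <- sum(w * x^2)
  sy <- sum(w * y); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  b0 <- (sxx * sy - sx * sxy) / det
  b1 <- (sw * sxy - sx * sy) / det
  resid <- y - b0 - b1 * x
  sigma2 <- sum(w * resid^2) / (J - 2)
  scale <- max(1, sigma2)
  se0 <- sqrt(scale * sxx / det)
  se1 <- sqrt(scale * sw / det)
  p1 <- 2 * pt(-abs(b1 / se1), J - 2)
  p0 <- 2 * pt(-abs(b0 / se0), J - 2)
  new_mr_estimate("MR-Egger", b1, se1, p1, J,
                  egger_intercept = b0, egger_intercept_se = se0,
                  egger_intercept_p = p0)
}
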