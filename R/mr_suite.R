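#' Two-sample Mendelian randomization estimator suite
#'
#' Runs the requested estimators on harmonized exposure/outcome pairs (or
#' harmonizes two summary files first) and collects the estimates in one
#' object.
#'
#' @param exposure An `mr_pairs` data.frame, or an exposure `gwas_summary`
#'   (then `outcome` must be supplied and the two are harmonized).
#' @param outcome Optional outcome `gwas_summary`.
#' @param methods Subset of `c("ivw", "median", "mode", "egger",
#'   "presso")`.
#' @param n_boot Bootstrap draws for median/mode SEs.
#' @param seed Integer seed for the resampling-based methods.
#' @param ... Passed to [harmonize()] when two summaries are given.
#' @return A list of class `mr_result`: `estimates` (named list of
#'   `mr_estimate`s), `presso` (a `presso_result` when run) and `pairs`.
#' @export
mr_two_sample <- function(exposure, outcome = NULL,
                          methods = c("ivw", "median", "mode", "egger",
                                      "presso"),
                          n_boot = 1000, seed = 1, ...) {
  methods <- match.arg(methods, several.ok = TRUE)
  pairs <- if (inherits(exposure, "mr_pairs")) exposure
           else harmonize(exposure, outcome, ...)
  J <- nrow(pairs)
  est <- list()
  presso <- NULL
  if ("ivw" %in% methods)
    est$ivw <- if (J == 1) wald_ratio(pairs$beta_exp, pairs$se_exp,
                                      pairs$beta_out, pairs$se_out)
               else mr_ivw(pairs)
  if ("median" %in% methods && J >= 3)
    est$median <- mr_weighted_median(pairs, n_boot = n_boot, seed = seed)
  if ("mode" %in% methods && J >= 3)
    est$mode <- mr_weighted_mode(pairs, n_boot = n_boot, seed = seed)
  if ("egger" %in% methods && J >= 3)
    est$egger <- mr_egger(pairs)
  if ("presso" %in% methods && J >= 4) {
    presso <- mr_presso(pairs, seed = seed)
    if (!is.null(presso$corrected)) {
      est$presso <- presso$corrected
      est$presso$method <- "MR-PRESSO (outlier-corrected)"
    }
  }
  structure(list(estimates = est, presso = presso, pairs = pairs),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat("Two-sample MR on", nrow(x$pairs), "harmonized variants\n")
  for (e in x$estimates) print(e)
  if (!is.null(x$presso) && length(x$presso$outliers))
    cat("MR-PRESSO outliers removed:",
        paste(x$presso$outliers, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mr_result <- function(object, ...) as.data.frame(object)

#' Tabulate an `mr_result`
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return A data.frame with one row per method: `method`, `beta`, `se`,
#'   `ci_low`, `ci_high`, `p`, `n_snps`, `intercept`, `intercept_p`,
#'   `q_stat`, `outliers`.
#' @export
as.data.frame.mr_result <- function(x, ...) {
  rows <- lapply(x$estimates, function(e) {
    data.frame(method = e$method, beta = e$beta, se = e$se,
               ci_low = e$ci[1], ci_high = e$ci[2], p = e$p,
               n_snps = e$n_snp,
               intercept = if (is.null(e$egger_intercept)) NA_real_
                           else e$egger_intercept,
               intercept_p = if (is.null(e$egger_intercept_p)) NA_real_
                             else e$egger_intercept_p,
               q_stat = if (is.null(e$q_stat)) NA_real_ else e$q_stat,
               outliers = if (is.null(x$presso)) ""
                          else paste(x$presso$outliers, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' One-sample Mendelian randomization via a genetic score
#'
#' Builds a per-subject score as the weighted sum of instrument dosages
#' (weights from an exposure GWAS, or allele counts when unweighted),
#' standardizes it to SD 1, and fits a logistic regression of the binary
#' outcome on the score plus covariates; reported as OR per SD of score.
#'
#' @param cohort A `sim_cohort`, or a list with `genotypes` and `data`.
#' @param instruments Variant ids (or an `instrument_set`).
#' @param weights Named per-variant weights; `NULL` for an unweighted
#'   allele-count score. All-zero weights are refused.
#' @param outcome Name of the binary outcome column (default "outcome").
#' @param covariates Optional covariate column names.
#' @return An `mr_estimate` (log-OR per SD of score) with an `or` extra.
#' @export
one_sample_mr <- function(cohort, instruments, weights = NULL,
                          outcome = "outcome", covariates = NULL) {
  ids <- if (inherits(instruments, "data.frame")) instruments$variant_id
         else instruments
  G <- cohort$genotypes
  miss <- setdiff(ids, colnames(G))
  if (length(miss))
    stop("instrument dosage column(s) missing: ", paste(miss, collapse = ", "))
  if (is.null(weights)) weights <- setNames(rep(1, length(ids)), ids)
  w <- weights[ids]
  if (all(w == 0)) stop("all instrument weights are zero: degenerate score")
  s <- as.vector(G[, ids, drop = FALSE] %*% w)
  s <- (s - mean(s)) / sd(s)
  dat <- cohort$data
  df <- data.frame(y = dat[[outcome]], score = s)
  form <- "y ~ score"
  if (!is.null(covariates)) {
    df <- cbind(df, dat[, covariates, drop = FALSE])
    form <- paste("y ~ score +", paste(covariates, collapse = " + "))
  }
  fit <- glm(stats::as.formula(form), data = df, family = binomial())
  cf <- summary(fit)$coefficients["score", ]
  new_mr_estimate("One-sample MR (genetic score)", cf[1], cf[2], cf[4],
                  length(ids), or = exp(cf[1]),
                  or_ci = exp(cf[1] + c(-1, 1) * 1.96 * cf[2]))
}

#' Bi-directional two-sample Mendelian randomization
#'
#' Runs the estimator suite in both directions between two traits, with
#' direction-specific instrument selection: instruments for each exposure
#' are its genome-wide-significant variants clumped at that direction's
#' r-squared threshold (0.01 forward, 0.001 reverse by default). A
#' direction with no selectable instruments is skipped with a warning.
#'
#' @param summary_a,summary_b `gwas_summary` files for the two traits
#'   (forward = a on b, reverse = b on a).
#' @param genotypes Reference dosage matrix for clumping.
#' @param p_threshold Instrument significance threshold (default 5e-8).
#' @param r2_forward,r2_reverse Clumping thresholds per direction.
#' @param window_bp Clumping window.
#' @param methods,seed Passed to [mr_two_sample()].
#' @return A list of class `mr_bidirectional` with `forward` and
#'   `reverse` `mr_result`s (either may be `NULL`).
#' @export
bidirectional <- function(summary_a, summary_b, genotypes,
                          p_threshold = 5e-8,
                          r2_forward = 0.01, r2_reverse = 0.001,
                          window_bp = 1e6,
                          methods = c("ivw", "median", "mode", "egger",
                                      "presso"),
                          seed = 1) {
  run_dir <- function(exp_sum, out_sum, r2) {
    inst <- suppressWarnings(clump(exp_sum, genotypes, p_threshold, r2,
                                   window_bp))
    if (nrow(inst) == 0) {
      warning("no instruments in one direction: skipped")
      return(NULL)
    }
    exp_sub <- exp_sum[exp_sum$variant_id %in% inst$variant_id, ]
    mr_two_sample(exp_sub, out_sum, methods = methods, seed = seed)
  }
  structure(list(forward = run_dir(summary_a, summary_b, r2_forward),
                 reverse = run_dir(summary_b, summary_a, r2_reverse)),
            class = "mr_bidirectional")
}

#' @export
print.mr_bidirectional <- function(x, ...) {
  cat("== Forward direction ==\n")
  if (is.null(x$forward)) cat("(skipped)\n") else print(x$forward)
  cat("== Reverse direction ==\n")
  if (is.null(x$reverse)) cat("(skipped)\n") else print(x$reverse)
  invisible(x)
}
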