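#' Classify one biomarker as candidate mediator, off-target or null
#'
#' Applies direction-consistency rules to one biomarker-outcome evidence
#' row. A biomarker is a `candidate_mediator` iff (a) its signature
#' correlation sign and observational disease association are opposed in
#' the beneficial pairing - negatively correlated with the signature and
#' associated with higher risk, or positively correlated and associated
#' with lower risk; (b) the observational association is FDR-significant
#' (`q < alpha`); and (c) the MR estimate has the same direction as the
#' observational one (sign agreement only; MR significance is not
#' required). The reverse pairing with observational significance is
#' `off_target`; anything else is `not_significant`.
#'
#' @param biomarker Biomarker name.
#' @param weight_sign Sign of the biomarker's signature weight (+1/-1), the
#'   biomarker's correlation direction with the signature.
#' @param obs_logor Observational log-OR for the outcome.
#' @param obs_q BH-adjusted observational p-value.
#' @param mr_beta MR estimate (log-OR); may be `NA` (classified on the
#'   observational rules with a flag in the rationale).
#' @param outcome Outcome name carried into the call.
#' @param alpha FDR threshold (default 0.05).
#' @return A one-row data.frame (`MediatorCall`): `biomarker`, `outcome`,
#'   `category` in \{candidate_mediator, off_target, not_significant\},
#'   `rationale`.
#' @export
classify_biomarker <- function(biomarker, weight_sign, obs_logor, obs_q,
                               mr_beta = NA_real_, outcome = "outcome",
                               alpha = 0.05) {
  stopifnot(weight_sign %in% c(-1, 1))
  mr_missing <- is.na(mr_beta)
  mr_consistent <- if (mr_missing) TRUE else sign(mr_beta) == sign(obs_logor)
  beneficial_pairing <- (weight_sign < 0 & obs_logor > 0) |
    (weight_sign > 0 & obs_logor < 0)
  if (obs_q < alpha && beneficial_pairing && mr_consistent) {
    cat_ <- "candidate_mediator"
    why <- sprintf("signature %s, obs log-OR %.3f (q=%.3g), MR direction %s",
                   if (weight_sign > 0) "positive" else "negative",
                   obs_logor, obs_q,
                   if (mr_missing) "unavailable (observational rules only)"
                   else "consistent")
  } else if (obs_q < alpha && !beneficial_pairing) {
    cat_ <- "off_target"
    why <- sprintf("signature %s but obs log-OR %.3f (q=%.3g): reverse pairing",
                   if (weight_sign > 0) "positive" else "negative",
                   obs_logor, obs_q)
  } else {
    cat_ <- "not_significant"
    why <- if (obs_q >= alpha)
      sprintf("obs q=%.3g above threshold", obs_q)
    else "MR direction inconsistent with observational association"
  }
  if (mr_missing && cat_ == "candidate_mediator")
    why <- paste(why, "[no MR estimate]")
  data.frame(biomarker = biomarker, outcome = outcome, category = cat_,
             rationale = why, stringsAsFactors = FALSE)
}

#' Screen a biomarker panel for candidate mediators
#'
#' Applies [classify_biomarker()] to every row of an evidence panel for a
#' given outcome. Candidates are returned first, sorted by observational
#' q-value.
#'
#' @param evidence Data.frame with one row per signature biomarker:
#'   `biomarker`, `weight_sign` (or a `weight` column whose sign is
#'   taken), `obs_logor`, `obs_q`, `mr_beta` (optionally `NA`).
#' @param outcome Outcome name.
#' @param alpha FDR threshold.
#' @return A data.frame of class `mediator_calls` with one call per
#'   biomarker.
#' @export
select_mediators <- function(evidence, outcome = "outcome", alpha = 0.05) {
  if (anyDuplicated(evidence$biomarker))
    stop("duplicate biomarker rows in the evidence panel")
  ws <- if (!is.null(evidence$weight_sign)) evidence$weight_sign
        else sign(evidence$weight)
  mr <- if (is.null(evidence$mr_beta)) rep(NA_real_, nrow(evidence))
        else evidence$mr_beta
  calls <- do.call(rbind, lapply(seq_len(nrow(evidence)), function(i) {
    classify_biomarker(evidence$biomarker[i], ws[i],
                       evidence$obs_logor[i], evidence$obs_q[i],
                       mr[i], outcome = outcome, alpha = alpha)
  }))
  qv <- evidence$obs_q
  is_cand <- calls$category == "candidate_mediator"
  ord <- c(which(is_cand)[order(qv[is_cand])], which(!is_cand))
  out <- calls[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mediator_calls", "data.frame")
  out
}

#' @export
print.mediator_calls <- function(x, ...) {
  n_cand <- sum(x$category == "candidate_mediator")
  cat("Mediator screen:", nrow(x), "biomarkers,", n_cand,
      "candidate mediator(s)\n")
  if (n_cand)
    cat(" ", paste(x$biomarker[x$category == "candidate_mediator"],
                   collapse = ", "), "\n")
  invisible(x)
}
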