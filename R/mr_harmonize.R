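.complement <- function(a) chartr("ACGT", "TGCA", toupper(a))

.is_palindromic <- function(ea, oa) .complement(ea) == toupper(oa)

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns the two studies to the same effect allele per variant. Alleles
#' matching directly (or after strand complement) are kept; when the
#' effect/other alleles are swapped between studies the outcome beta is
#' negated and its EAF reflected. Palindromic (A/T, C/G) variants, whose
#' strand cannot be resolved from alleles, are aligned by allele frequency
#' unless both EAFs fall inside the ambiguity band, in which case they are
#' dropped. Irreconcilable allele pairs are dropped with a log entry.
#'
#' @param exposure,outcome `gwas_summary` data.frames sharing variant ids.
#' @param palindrome_eaf_band EAF interval within which a palindromic
#'   variant is considered ambiguous (default (0.42, 0.58)).
#' @return A data.frame of class `mr_pairs` with one row per kept variant:
#'   `variant_id`, `beta_exp`, `se_exp`, `beta_out`, `se_out`,
#'   `effect_allele`, `other_allele`, `eaf_exp`, `eaf_out`, `action`.
#'   The attribute `log` records every shared variant with its action
#'   (`kept`, `flipped`, `dropped-palindromic`, `dropped-incompatible`).
#' @export
harmonize <- function(exposure, outcome,
                      palindrome_eaf_band = c(0.42, 0.58)) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0) stop("no shared variant ids")
  if (anyDuplicated(shared)) stop("duplicate variant ids")
  e <- exposure[match(shared, exposure$variant_id), ]
  o <- outcome[match(shared, outcome$variant_id), ]

  ea_e <- toupper(e$effect_allele); oa_e <- toupper(e$other_allele)
  ea_o <- toupper(o$effect_allele); oa_o <- toupper(o$other_allele)

  action <- character(length(shared))
  flip <- logical(length(shared))
  pal <- .is_palindromic(ea_e, oa_e)

  same <- ea_o == ea_e & oa_o == oa_e
  swap <- ea_o == oa_e & oa_o == ea_e
  csame <- ea_o == .complement(ea_e) & oa_o == .complement(oa_e)
  cswap <- ea_o == .complement(oa_e) & oa_o == .complement(ea_e)

  for (k in seq_along(shared)) {
    if (pal[k]) {
      if (!(same[k] || swap[k] || csame[k] || cswap[k])) {
        action[k] <- "dropped-incompatible"
      } else if (!is.na(e$eaf[k]) && !is.na(o$eaf[k]) &&
                 e$eaf[k] > palindrome_eaf_band[1] &&
                 e$eaf[k] < palindrome_eaf_band[2] &&
                 o$eaf[k] > palindrome_eaf_band[1] &&
                 o$eaf[k] < palindrome_eaf_band[2]) {
        action[k] <- "dropped-palindromic"
      } else {
        # align by frequency: minor alleles should correspond
        flip[k] <- (e$eaf[k] < 0.5) != (o$eaf[k] < 0.5)
        action[k] <- if (flip[k]) "flipped" else "kept"
      }
    } else if (same[k] || csame[k]) {
      action[k] <- "kept"
    } else if (swap[k] || cswap[k]) {
      flip[k] <- TRUE
      action[k] <- "flipped"
    } else {
      action[k] <- "dropped-incompatible"
    }
  }

  beta_out <- ifelse(flip, -o$beta, o$beta)
  eaf_out <- ifelse(flip, 1 - o$eaf, o$eaf)
  keep <- action %in% c("kept", "flipped")
  out <- data.frame(variant_id = shared,
                    beta_exp = e$beta, se_exp = e$se,
                    beta_out = beta_out, se_out = o$se,
                    effect_allele = ea_e, other_allele = oa_e,
                    eaf_exp = e$eaf, eaf_out = eaf_out,
                    action = action,
                    stringsAsFactors = FALSE)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "log") <- data.frame(variant_id = shared, action = action,
                                 stringsAsFactors = FALSE)
  class(out) <- c("mr_pairs", "data.frame")
  out
}

#' Construct harmonized pairs directly from aligned effect estimates
#'
#' Convenience constructor for estimator inputs that are already on a
#' common effect allele (e.g. simulated instrument sets).
#'
#' @param beta_exp,se_exp,beta_out,se_out Aligned per-variant effects and
#'   standard errors.
#' @param variant_id Optional ids.
#' @return An `mr_pairs` data.frame.
#' @export
mr_pairs <- function(beta_exp, se_exp, beta_out, se_out,
                     variant_id = NULL) {
  J <- length(beta_exp)
  stopifnot(length(se_exp) == J, length(beta_out) == J, length(se_out) == J,
            all(se_exp > 0), all(se_out > 0))
  if (is.null(variant_id)) variant_id <- sprintf("v%03d", seq_len(J))
  out <- data.frame(variant_id = variant_id,
                    beta_exp = beta_exp, se_exp = se_exp,
                    beta_out = beta_out, se_out = se_out,
                    effect_allele = "A", other_allele = "G",
                    eaf_exp = NA_real_, eaf_out = NA_real_,
                    action = "kept", stringsAsFactors = FALSE)
  class(out) <- c("mr_pairs", "data.frame")
  out
}
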