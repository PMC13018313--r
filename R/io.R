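#' Write / read a GWAS summary-statistics table
#'
#' Tab-delimited with the fixed column order `variant_id`, `chrom`,
#' `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `p`, `n`.
#'
#' @param x A `gwas_summary` data.frame.
#' @param path File path.
#' @return `read_gwas` returns a `gwas_summary` data.frame.
#' @export
write_gwas <- function(x, path) {
  cols <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "p", "n")
  utils::write.table(x[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_gwas
#' @export
read_gwas <- function(path) {
  x <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  need <- c("variant_id", "chrom", "pos", "effect_allele", "other_allele",
            "eaf", "beta", "se", "p", "n")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  class(x) <- c("gwas_summary", "data.frame")
  x
}

#' Write / read a signature model as JSON
#'
#' Stores biomarker names, weights, the mixing parameter, penalty and
#' cross-validated AUC.
#'
#' @param model A `signature_model`.
#' @param path File path.
#' @return `read_signature` returns a `signature_model`.
#' @export
write_signature <- function(model, path) {
  jsonlite::write_json(list(biomarkers = model$biomarkers,
                            weights = unname(model$weights),
                            alpha = model$alpha, lambda = model$lambda,
                            cv_auc = model$cv_auc),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  signature_model(setNames(x$weights, x$biomarkers), alpha = x$alpha,
                  lambda = if (is.null(x$lambda)) NA_real_ else x$lambda,
                  cv_auc = if (is.null(x$cv_auc)) NA_real_ else x$cv_auc)
}

#' Write / read a long trial table
#'
#' @param trial A `sim_trial` (its `data` is written) or a data.frame.
#' @param path File path.
#' @return `read_trial` returns the long data.frame with `arm` and
#'   `visit` as factors.
#' @export
write_trial <- function(trial, path) {
  dat <- if (inherits(trial, "sim_trial")) trial$data else trial
  utils::write.table(dat, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  dat$arm <- factor(dat$arm, levels = c("control", "treated"))
  dat$visit <- factor(dat$visit, levels = unique(dat$visit))
  dat
}

#' Write a genotype dosage matrix as TSV
#'
#' Rows are individuals, columns variant ids.
#'
#' @param dosage Integer dosage matrix with variant-id column names.
#' @param path File path.
#' @export
write_dosage <- function(dosage, path) {
  utils::write.table(dosage, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
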