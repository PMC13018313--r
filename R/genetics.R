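#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact conditional test of HWE for a biallelic variant: given the allele
#' counts, the p-value is the sum of the probabilities of all genotype
#' tables whose conditional probability does not exceed that of the
#' observed table.
#'
#' @param nAA,nAa,naa Genotype counts (non-negative integers).
#' @return The exact p-value in `[0, 1]`.
#' @export
hwe_exact_p <- function(nAA, nAa, naa) {
  stopifnot(nAA >= 0, nAa >= 0, naa >= 0)
  n <- nAA + nAa + naa
  if (n < 1) stop("total genotype count must be >= 1")
  nA <- 2L * nAA + nAa            # minor/major labelling is irrelevant
  nB <- 2L * naa + nAa
  rare <- min(nA, nB)
  # heterozygote count shares the parity of the rare allele count
  hets <- seq(rare %% 2L, rare, by = 2L)
  # log P(nAa = h | allele counts) up to a constant
  lp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((nB - hets) / 2 + 1) + hets * log(2)
  pr <- exp(lp - max(lp))
  pr <- pr / sum(pr)
  obs <- pr[match(nAa, hets)]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Variant quality-control filter
#'
#' Keeps a variant iff it passes all four rules: imputation INFO score at
#' least `info_min`, missing genotype rate at most `missing_max`, minor
#' allele frequency at least `maf_min`, and HWE exact p-value at least
#' `hwe_min`. Each excluded variant is logged with the first failing rule
#' (in that order).
#'
#' @param variants Data.frame with columns `id`, `eaf`, `info`, `callrate`
#'   and either `hwe_p` or genotypes from which to compute it.
#' @param genotypes Optional dosage matrix (columns named by variant id)
#'   used to compute HWE p-values and missing rates when not supplied as
#'   columns.
#' @param info_min,missing_max,maf_min,hwe_min Thresholds (defaults 0.7,
#'   0.10, 0.01, 1e-15).
#' @return A list with `kept` (the passing subset of `variants`) and
#'   `excluded` (data.frame `id`, `rule`).
#' @export
qc_filter <- function(variants, genotypes = NULL,
                      info_min = 0.7, missing_max = 0.10,
                      maf_min = 0.01, hwe_min = 1e-15) {
  v <- variants
  if (is.null(v$hwe_p)) {
    if (is.null(genotypes)) {
      v$hwe_p <- 1
    } else {
      v$hwe_p <- vapply(v$id, function(id) {
        g <- genotypes[, id]
        hwe_exact_p(sum(g == 2, na.rm = TRUE), sum(g == 1, na.rm = TRUE),
                    sum(g == 0, na.rm = TRUE))
      }, numeric(1))
    }
  }
  if (is.null(v$callrate) && !is.null(genotypes))
    v$callrate <- colMeans(!is.na(genotypes[, v$id, drop = FALSE]))
  maf <- pmin(v$eaf, 1 - v$eaf)
  rule <- rep(NA_character_, nrow(v))
  rule[is.na(rule) & v$info < info_min] <- "info"
  rule[is.na(rule) & (1 - v$callrate) > missing_max] <- "missing"
  rule[is.na(rule) & maf < maf_min] <- "maf"
  rule[is.na(rule) & v$hwe_p < hwe_min] <- "hwe"
  keep <- is.na(rule)
  list(kept = v[keep, , drop = FALSE],
       excluded = data.frame(id = v$id[!keep], rule = rule[!keep],
                             stringsAsFactors = FALSE))
}

#' Inverse rank-normal transformation
#'
#' Maps values through their (tie-averaged) ranks to normal quantiles with
#' the Blom offset: `z_i = qnorm((r_i - 3/8) / (n + 1/4))`.
#'
#' @param x Numeric vector, length at least 2, no missing values.
#' @return The transformed vector.
#' @export
inverse_rank_normalize <- function(x) {
  if (anyNA(x)) stop("missing values must be handled upstream")
  n <- length(x)
  if (n < 2) stop("need at least 2 observations")
  if (length(unique(x)) == 1) stop("all values equal: ranks undefined")
  r <- rank(x, ties.method = "average")
  qnorm((r - 3 / 8) / (n + 1 / 4))
}

# residualize columns of m on the covariate design (with intercept)
.residualize <- function(m, qr_x) {
  m - qr.fitted(qr_x, m)
}

#' Per-variant association scan
#'
#' Regresses a phenotype on each variant's dosage with optional covariate
#' adjustment. The linear family uses exact closed-form OLS after
#' projecting out the covariates (Frisch-Waugh); the logistic family runs
#' per-variant maximum-likelihood fits (vectorized Newton iterations when
#' there are no covariates). Missing dosages are mean-imputed per variant.
#'
#' @param phenotype Numeric vector (binary 0/1 for `family = "logistic"`).
#' @param genotypes Dosage matrix, individuals x variants.
#' @param covariates Optional numeric matrix/data.frame of covariates.
#' @param family `"linear"` or `"logistic"`.
#' @param variants Optional metadata data.frame (id, chrom, pos, alleles,
#'   eaf) merged into the output.
#' @return A data.frame of class `gwas_summary` with columns `variant_id`,
#'   `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`, `se`,
#'   `p`, `n`.
#' @export
gwas_scan <- function(phenotype, genotypes, covariates = NULL,
                      family = c("linear", "logistic"), variants = NULL) {
  family <- match.arg(family)
  G <- as.matrix(genotypes)
  n <- length(phenotype)
  stopifnot(nrow(G) == n)
  # mean-impute missing dosages per variant (keeps n constant)
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    idx <- which(is.na(G), arr.ind = TRUE)
    G[idx] <- mu[idx[, 2]]
  }
  X <- cbind(`(Intercept)` = rep(1, n))
  if (!is.null(covariates)) {
    C <- as.matrix(covariates)
    X <- cbind(X, C)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
      stop("collinear covariates: ", paste(bad, collapse = ", "))
    }
  }
  p_cov <- ncol(X)

  if (family == "linear") {
    qx <- qr(X)
    ry <- as.vector(.residualize(matrix(phenotype, ncol = 1), qx))
    RG <- .residualize(G, qx)
    sgg <- colSums(RG^2)
    sgy <- as.vector(crossprod(RG, ry))
    beta <- sgy / sgg
    df <- n - p_cov - 1
    rss <- sum(ry^2) - beta^2 * sgg
    se <- sqrt(pmax(rss, 0) / df / sgg)
    tval <- beta / se
    pval <- 2 * pt(-abs(tval), df)
  } else {
    y <- phenotype
    if (!all(y %in% c(0, 1))) stop("logistic family needs a 0/1 phenotype")
    if (is.null(covariates)) {
      m <- ncol(G)
      b0 <- rep(qlogis(mean(y)), m)
      b1 <- rep(0, m)
      for (it in 1:25) {
        eta <- matrix(b0, n, m, byrow = TRUE) +
          sweep(G, 2, b1, `*`)
        mu <- plogis(eta)
        w <- mu * (1 - mu)
        r <- y - mu
        S0 <- colSums(w); S1 <- colSums(w * G); S2 <- colSums(w * G^2)
        U0 <- colSums(r); U1 <- colSums(r * G)
        det <- S0 * S2 - S1^2
        d0 <- (S2 * U0 - S1 * U1) / det
        d1 <- (S0 * U1 - S1 * U0) / det
        b0 <- b0 + d0; b1 <- b1 + d1
        if (max(abs(c(d0, d1))) < 1e-10) break
      }
      eta <- matrix(b0, n, m, byrow = TRUE) + sweep(G, 2, b1, `*`)
      mu <- plogis(eta); w <- mu * (1 - mu)
      S0 <- colSums(w); S1 <- colSums(w * G); S2 <- colSums(w * G^2)
      det <- S0 * S2 - S1^2
      beta <- b1
      se <- sqrt(S0 / det)
    } else {
      m <- ncol(G)
      beta <- se <- numeric(m)
      for (j in seq_len(m)) {
        fit <- glm.fit(cbind(X, g = G[, j]), y, family = binomial())
        cf <- fit$coefficients
        # Wald SE from the final IRLS weights
        W <- fit$weights
        XX <- cbind(X, g = G[, j])
        V <- tryCatch(solve(crossprod(XX * sqrt(W))),
                      error = function(e) matrix(NA, ncol(XX), ncol(XX)))
        beta[j] <- cf["g"]
        se[j] <- sqrt(V[ncol(XX), ncol(XX)])
      }
    }
    z <- beta / se
    pval <- 2 * pnorm(-abs(z))
  }

  out <- data.frame(variant_id = colnames(G), stringsAsFactors = FALSE)
  if (!is.null(variants)) {
    idx <- match(out$variant_id, variants$id)
    out$chrom <- variants$chrom[idx]
    out$pos <- variants$pos[idx]
    out$effect_allele <- variants$effect_allele[idx]
    out$other_allele <- variants$other_allele[idx]
    out$eaf <- variants$eaf[idx]
  } else {
    out$chrom <- 1L
    out$pos <- seq_len(ncol(G))
    out$effect_allele <- "A"
    out$other_allele <- "G"
    out$eaf <- colMeans(G) / 2
  }
  out$beta <- beta
  out$se <- se
  out$p <- pmin(pmax(pval, .Machine$double.xmin), 1)
  out$n <- n
  class(out) <- c("gwas_summary", "data.frame")
  out
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of two dosage vectors over their shared
#' non-missing individuals.
#'
#' @param genotypes Dosage matrix.
#' @param i,j Column indices or variant ids.
#' @return r-squared in `[0, 1]`, or `NA` (with attribute
#'   `monomorphic = TRUE`) when either variant has zero variance.
#' @export
ld_r2 <- function(genotypes, i, j) {
  gi <- genotypes[, i]
  gj <- genotypes[, j]
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < 10) stop("need >= 10 overlapping non-missing individuals")
  gi <- gi[ok]; gj <- gj[ok]
  if (var(gi) == 0 || var(gj) == 0)
    return(structure(NA_real_, monomorphic = TRUE))
  cor(gi, gj)^2
}

#' Greedy LD clumping of a summary-statistics file
#'
#' Sorts variants passing `p_threshold` by ascending p-value, accepts the
#' best, and discards any remaining variant on the same chromosome within
#' `window_bp` whose dosage r-squared with an accepted variant exceeds
#' `r2_threshold`; repeats until the list is exhausted. P-value ties break
#' toward the smaller position.
#'
#' @param summary A `gwas_summary` data.frame.
#' @param genotypes Reference dosage matrix covering the significant
#'   variants (columns named by variant id).
#' @param p_threshold Significance threshold (default genome-wide, 5e-8).
#' @param r2_threshold LD threshold (e.g. 0.01 exposure-side, 0.001
#'   disease-side).
#' @param window_bp Clumping window in base pairs (default 1 Mb).
#' @return A data.frame of class `instrument_set`: the retained rows of
#'   `summary`, with attributes `p_threshold`, `r2_threshold`, `window_bp`
#'   and `discarded` (id of each discarded variant and its index variant).
#' @export
clump <- function(summary, genotypes, p_threshold = 5e-8,
                  r2_threshold = 0.01, window_bp = 1e6) {
  sig <- summary[summary$p < p_threshold, , drop = FALSE]
  if (nrow(sig) == 0) {
    warning("no variant passes the significance threshold")
    out <- summary[0, , drop = FALSE]
  } else {
    sig <- sig[order(sig$p, sig$pos), , drop = FALSE]
    kept <- integer(0)
    discarded <- data.frame(id = character(0), index = character(0),
                            stringsAsFactors = FALSE)
    active <- rep(TRUE, nrow(sig))
    for (k in seq_len(nrow(sig))) {
      if (!active[k]) next
      kept <- c(kept, k)
      active[k] <- FALSE
      cand <- which(active & sig$chrom == sig$chrom[k] &
                      abs(sig$pos - sig$pos[k]) <= window_bp)
      if (length(cand)) {
        gk <- genotypes[, sig$variant_id[k]]
        r2 <- suppressWarnings(
          cor(gk, genotypes[, sig$variant_id[cand], drop = FALSE])^2)
        drop <- cand[!is.na(r2) & r2 > r2_threshold]
        if (length(drop)) {
          active[drop] <- FALSE
          discarded <- rbind(discarded,
                             data.frame(id = sig$variant_id[drop],
                                        index = sig$variant_id[k],
                                        stringsAsFactors = FALSE))
        }
      }
    }
    out <- sig[kept, , drop = FALSE]
    attr(out, "discarded") <- discarded
  }
  attr(out, "p_threshold") <- p_threshold
  attr(out, "r2_threshold") <- r2_threshold
  attr(out, "window_bp") <- window_bp
  class(out) <- c("instrument_set", "data.frame")
  out
}

#' Restrict variants to a cis region around a gene
#'
#' Keeps variants on the gene's chromosome with
#' `gene_start - flank <= pos <= gene_end + flank` (1-based, inclusive at
#' both flanks).
#'
#' @param variants Data.frame with `chrom` and `pos` columns.
#' @param gene_chrom,gene_start,gene_end Gene coordinates (1-based,
#'   inclusive).
#' @param flank Flank width in bp (default 100 kb).
#' @return The subset of `variants` in the cis window.
#' @export
cis_filter <- function(variants, gene_chrom, gene_start, gene_end,
                       flank = 100000) {
  if (gene_start > gene_end) stop("gene_start must be <= gene_end")
  keep <- variants$chrom == gene_chrom &
    variants$pos >= gene_start - flank &
    variants$pos <= gene_end + flank
  variants[keep, , drop = FALSE]
}
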