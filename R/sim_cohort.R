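#' Configuration for a simulated genotyped cohort
#'
#' Study conditions for [simulate_genotypes()], [simulate_cohort()] and
#' [make_two_sample()]: a cohort with Hardy-Weinberg genotypes arranged in
#' LD blocks, a signature-like quantitative exposure with a genetic
#' component scaled to heritability `h2`, an optional shared confounder,
#' and a binary outcome from a logistic model in which one SD of the
#' exposure carries log-odds `causal_logOR`.
#'
#' @param n_individuals Cohort size.
#' @param n_variants Number of variants.
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param ld_block_size Variants per LD block.
#' @param ld_rho Latent AR(1) correlation within a block, in `[0, 1)`.
#' @param variant_effects Per-variant relative effect on the exposure; the
#'   overall scale is set by `h2`. Default: alternating-sign effects of
#'   graded magnitude on all variants.
#' @param h2 Fraction of exposure variance explained by genetics, in (0,1).
#' @param causal_logOR Log-odds effect of 1 SD of exposure on the outcome.
#' @param baseline_prev Marginal outcome prevalence in (0,1); the logistic
#'   intercept is solved by bisection to match it.
#' @param n_pleiotropic Number of variants with direct outcome effects.
#' @param pleiotropy_effect Per-allele direct log-odds effect of each
#'   pleiotropic variant (recycled; give a vector for heterogeneous or
#'   balanced direct effects).
#' @param confounder_strength Loading of a shared standard-normal confounder
#'   on both the exposure (SD units) and the outcome (log-odds).
#' @param seed Integer seed.
#'
#' @return An object of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_individuals = 10000L,
                              n_variants = 50L,
                              maf_range = c(0.05, 0.5),
                              ld_block_size = 5L,
                              ld_rho = 0.3,
                              variant_effects = NULL,
                              h2 = 0.3,
                              causal_logOR = -0.16,
                              baseline_prev = 0.10,
                              n_pleiotropic = 0L,
                              pleiotropy_effect = 0,
                              confounder_strength = 0,
                              seed = 1L) {
  if (ld_rho >= 1 || ld_rho < 0) stop("ld_rho must be in [0,1)")
  if (h2 <= 0 || h2 >= 1) stop("h2 must be in (0,1)")
  if (baseline_prev <= 0 || baseline_prev >= 1) stop("baseline_prev must be in (0,1)")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (n_pleiotropic > n_variants)
    stop("pleiotropic variants must be a subset of the variant set")
  if (is.null(variant_effects)) {
    variant_effects <- rep(c(1, -1), length.out = n_variants) *
      seq(0.5, 1.5, length.out = n_variants)
  }
  if (length(variant_effects) != n_variants)
    stop("variant_effects must have length n_variants")
  if (h2 + confounder_strength^2 >= 1)
    stop("h2 + confounder_strength^2 must be < 1")
  structure(list(n_individuals = as.integer(n_individuals),
                 n_variants = as.integer(n_variants),
                 maf_range = maf_range,
                 ld_block_size = as.integer(ld_block_size),
                 ld_rho = ld_rho,
                 variant_effects = variant_effects,
                 h2 = h2, causal_logOR = causal_logOR,
                 baseline_prev = baseline_prev,
                 n_pleiotropic = as.integer(n_pleiotropic),
                 pleiotropy_effect = pleiotropy_effect,
                 confounder_strength = confounder_strength,
                 seed = as.integer(seed)),
            class = "sim_cohort_config")
}

# one haplotype matrix: latent block-AR(ld_rho) Gaussian thresholded at the
# MAF quantile; HWE holds because the two haplotypes are independent draws
.haplotypes <- function(n, mafs, block_size, rho) {
  m <- length(mafs)
  z <- matrix(rnorm(n * m), n, m)
  if (rho > 0 && m > 1) {
    for (j in 2:m) {
      if ((j - 1) %% block_size != 0) {   # stays within the block
        z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
      }
    }
  }
  thr <- qnorm(mafs)
  (z < matrix(thr, n, m, byrow = TRUE)) + 0L
}

#' Simulate HWE genotype dosages in LD blocks
#'
#' Dosages in \{0,1,2\} are formed as the sum of two independent haplotype
#' draws per individual; each haplotype thresholds a block-AR(`ld_rho`)
#' latent Gaussian at the MAF-matched quantile, so per-variant genotype
#' frequencies follow Hardy-Weinberg equilibrium while adjacent variants in
#' a block are correlated.
#'
#' @param cfg A [sim_cohort_config()].
#' @return A list with `dosage` (n x m integer matrix, columns named by
#'   variant id), `variants` (metadata data.frame: id, chrom, pos,
#'   effect_allele, other_allele, eaf, info, callrate, block) and `mafs`
#'   (the generating frequencies).
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_cohort_config"))
  set.seed(cfg$seed)
  m <- cfg$n_variants
  n <- cfg$n_individuals
  mafs <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  G <- .haplotypes(n, mafs, cfg$ld_block_size, cfg$ld_rho) +
    .haplotypes(n, mafs, cfg$ld_block_size, cfg$ld_rho)
  ids <- sprintf("rs%05d", seq_len(m))
  colnames(G) <- ids
  variants <- data.frame(id = ids, chrom = 1L, pos = seq_len(m) * 50000L,
                         effect_allele = "A", other_allele = "G",
                         eaf = colMeans(G) / 2, info = 1, callrate = 1,
                         block = (seq_len(m) - 1L) %/% cfg$ld_block_size + 1L,
                         stringsAsFactors = FALSE)
  list(dosage = G, variants = variants, mafs = mafs)
}

# solve the logistic intercept so marginal prevalence matches the target
.solve_intercept <- function(eta_rest, prev, tol = 1e-4) {
  f <- function(a) mean(plogis(a + eta_rest)) - prev
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0)
    stop("requested prevalence is unattainable for this linear predictor")
  while (hi - lo > 1e-10) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
    if (abs(f(mid)) < tol * 1e-2) break
  }
  (lo + hi) / 2
}

#' Simulate a genotyped cohort with exposure and binary outcome
#'
#' The exposure is `sqrt(h2)`-scaled genetic score (from `variant_effects`)
#' plus a shared confounder and Gaussian noise, scaled to unit variance.
#' The binary outcome follows a logistic model with the exposure effect
#' `causal_logOR` per SD, optional direct (pleiotropic) variant effects and
#' the confounder; the intercept is solved numerically so the marginal
#' prevalence matches `baseline_prev` to within 1e-4.
#'
#' @param cfg A [sim_cohort_config()].
#' @return A list of class `sim_cohort`: `genotypes`, `variants`, `data`
#'   (data.frame with `exposure`, `outcome` and numeric covariate columns),
#'   `truth` (scaled variant effects, pleiotropic indices, causal_logOR,
#'   intercept) and `config`.
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_cohort_config"))
  gt <- simulate_genotypes(cfg)   # reseeds from cfg$seed
  n <- cfg$n_individuals
  G <- gt$dosage
  g_raw <- as.vector(G %*% cfg$variant_effects)
  vg <- var(g_raw)
  if (vg <= 0) stop("genetic score has zero variance")
  a <- sqrt(cfg$h2 / vg)
  U <- rnorm(n)
  noise_var <- 1 - cfg$h2 - cfg$confounder_strength^2
  exposure <- a * g_raw + cfg$confounder_strength * U +
    sqrt(noise_var) * rnorm(n)

  pleio_idx <- integer(0)
  eta_pleio <- 0
  if (cfg$n_pleiotropic > 0) {
    pleio_idx <- seq_len(cfg$n_pleiotropic)
    pe <- rep_len(cfg$pleiotropy_effect, cfg$n_pleiotropic)
    eta_pleio <- as.vector(G[, pleio_idx, drop = FALSE] %*% pe)
  }
  eta_rest <- cfg$causal_logOR * exposure + eta_pleio +
    cfg$confounder_strength * U
  alpha <- .solve_intercept(eta_rest, cfg$baseline_prev)
  outcome <- rbinom(n, 1, plogis(alpha + eta_rest))

  covars <- data.frame(age = rnorm(n, 56.5, 8),
                       ethnicity = rnorm(n), smoking = rnorm(n),
                       townsend = rnorm(n), education = rnorm(n),
                       activity = rnorm(n))
  dat <- cbind(data.frame(id = seq_len(n), exposure = exposure,
                          outcome = outcome), covars)
  truth <- list(variant_effects = a * cfg$variant_effects,
                raw_variant_effects = cfg$variant_effects,
                h2 = cfg$h2, causal_logOR = cfg$causal_logOR,
                pleiotropic = pleio_idx,
                pleiotropy_effect = cfg$pleiotropy_effect,
                confounder_strength = cfg$confounder_strength,
                intercept = alpha, confounder = U,
                genetic_score = a * g_raw, seed = cfg$seed)
  structure(list(genotypes = G, variants = gt$variants, data = dat,
                 truth = truth, config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Simulated cohort:", nrow(x$data), "individuals,",
      ncol(x$genotypes), "variants; outcome prevalence",
      round(mean(x$data$outcome), 3), "\n")
  invisible(x)
}

#' Paired non-overlapping exposure/outcome summary statistics
#'
#' Simulates two independent cohorts from the same variant truth: the
#' exposure summary file comes from a linear scan of the exposure in cohort
#' A, the outcome file from a logistic scan of the binary outcome in cohort
#' B, emulating a two-sample design with no sample overlap.
#'
#' @param cfg A [sim_cohort_config()]; `cfg$seed` seeds cohort A, a derived
#'   seed cohort B.
#' @return A list of class `sim_two_sample`: `exposure` and `outcome`
#'   (`gwas_summary` data.frames), `truth`, and the two cohorts.
#' @export
make_two_sample <- function(cfg) {
  stopifnot(inherits(cfg, "sim_cohort_config"))
  cfg_b <- cfg
  cfg_b$seed <- (cfg$seed + 1000003L) %% .Machine$integer.max
  coh_a <- simulate_cohort(cfg)
  coh_b <- simulate_cohort(cfg_b)
  exposure <- gwas_scan(coh_a$data$exposure, coh_a$genotypes,
                        family = "linear", variants = coh_a$variants)
  outcome <- gwas_scan(coh_b$data$outcome, coh_b$genotypes,
                       family = "logistic", variants = coh_b$variants)
  structure(list(exposure = exposure, outcome = outcome,
                 truth = coh_a$truth, cohort_a = coh_a, cohort_b = coh_b),
            class = "sim_two_sample")
}

#' Flip the allele coding of selected rows of a summary file
#'
#' Swaps effect/other alleles, negates beta and reflects the EAF for the
#' given variants: the association content is unchanged, only its coding.
#' Useful to exercise harmonization.
#'
#' @param summary A `gwas_summary` data.frame.
#' @param idx Row indices (or variant ids) to flip.
#' @return The recoded summary data.frame.
#' @export
flip_alleles <- function(summary, idx) {
  if (is.character(idx)) idx <- match(idx, summary$variant_id)
  ea <- summary$effect_allele[idx]
  summary$effect_allele[idx] <- summary$other_allele[idx]
  summary$other_allele[idx] <- ea
  summary$beta[idx] <- -summary$beta[idx]
  summary$eaf[idx] <- 1 - summary$eaf[idx]
  summary
}
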