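#' End-to-end synthetic study: trial to mediator calls
#'
#' Runs the whole inference chain on synthetic data with known truth:
#' simulate a randomized biomarker trial and fit the treatment-response
#' signature; simulate two independent genotyped cohorts in which each
#' biomarker has its own LD block of causal variants and a planted subset
#' of treatment-responsive biomarkers (the mediators) directly drives the
#' binary outcome in the beneficial direction; score the signature in the
#' cohorts; run the exposure GWAS (inverse-rank-normalized score), QC and
#' LD clumping to select instruments; estimate the signature-outcome
#' effect by observational logistic regression, one-sample genetic-score
#' MR and the two-sample estimator suite; and classify each signature
#' biomarker with the direction-consistency mediator rules.
#'
#' @param seed Integer seed driving every stage.
#' @param n_trial Trial size (default 84, 1:1 arms, 4 dropouts).
#' @param n_biomarkers Biomarkers measured in trial and cohorts.
#' @param n_mediators Biomarkers that both respond to treatment and drive
#'   the outcome (planted truth).
#' @param n_responders Biomarkers with a treatment effect in the trial
#'   (includes the mediators).
#' @param n_cohort Individuals per cohort (two cohorts are simulated).
#' @param variants_per_biomarker Causal variants in each biomarker's LD
#'   block.
#' @param h2_biomarker Variance fraction of each biomarker explained by
#'   its block.
#' @param delta Absolute log-odds effect of each mediator biomarker (SD
#'   units) on the outcome; its sign opposes the biomarker's treatment
#'   response, so the signature is protective.
#' @param prevalence Marginal outcome prevalence.
#' @param ld_rho Within-block latent LD correlation.
#' @param n_boot Bootstrap draws inside the two-sample estimators.
#' @return A list of class `trialmr_pipeline`: the fitted `signature`,
#'   `instruments`, `obs` (observational association), `one_sample`,
#'   `two_sample` (an `mr_result`), `mediators` (calls), `evidence`,
#'   `truth` (planted mediators and effects) and `recovery` (fraction of
#'   planted mediators called candidate_mediator).
#' @export
run_pipeline <- function(seed = 1, n_trial = 84, n_biomarkers = 20,
                         n_mediators = 4, n_responders = 8,
                         n_cohort = 10000, variants_per_biomarker = 4,
                         h2_biomarker = 0.15, delta = 0.35,
                         prevalence = 0.10, ld_rho = 0.3, n_boot = 200) {
  stopifnot(n_mediators <= n_responders, n_responders <= n_biomarkers)
  K <- n_biomarkers
  v <- variants_per_biomarker
  m <- K * v
  bm_names <- sprintf("bm%02d", seq_len(K))

  # planted truth: mediators respond to treatment AND drive the outcome
  eff <- numeric(K)
  mag <- c(rep(1.0, n_mediators), rep(0.8, n_responders - n_mediators))
  eff[seq_len(n_responders)] <- rep(c(1, -1),
                                    length.out = n_responders) * mag
  mediators <- bm_names[seq_len(n_mediators)]
  delta_k <- numeric(K)
  delta_k[seq_len(n_mediators)] <- -delta * sign(eff[seq_len(n_mediators)])

  # trial and signature
  cfg_trial <- sim_trial_config(n_subjects = n_trial, n_biomarkers = K,
                                effect_vector = eff, seed = seed + 11L)
  trial <- simulate_trial(cfg_trial)
  sig <- fit_signature(trial)

  # shared variant truth for the two cohorts
  set.seed(seed + 23L)
  mafs <- runif(m, 0.1, 0.5)
  b_var <- runif(m, 0.5, 1.5) * rep(c(1, -1), length.out = m)
  block_of <- rep(seq_len(K), each = v)
  variants <- data.frame(id = sprintf("rs%05d", seq_len(m)), chrom = 1L,
                         pos = seq_len(m) * 50000L,
                         effect_allele = "A", other_allele = "G",
                         eaf = NA_real_, info = 1, callrate = 1,
                         block = block_of, stringsAsFactors = FALSE)

  gen_cohort <- function(sub_seed) {
    set.seed(sub_seed)
    G <- .haplotypes(n_cohort, mafs, v, ld_rho) +
      .haplotypes(n_cohort, mafs, v, ld_rho)
    colnames(G) <- variants$id
    B <- matrix(NA_real_, n_cohort, K, dimnames = list(NULL, bm_names))
    for (k in seq_len(K)) {
      idx <- which(block_of == k)
      gscore <- as.vector(G[, idx, drop = FALSE] %*% b_var[idx])
      gz <- (gscore - mean(gscore)) / sd(gscore)
      B[, k] <- sqrt(h2_biomarker) * gz +
        sqrt(1 - h2_biomarker) * rnorm(n_cohort)
    }
    Bz <- scale(B)
    eta_rest <- as.vector(Bz %*% delta_k)
    alpha <- .solve_intercept(eta_rest, prevalence)
    y <- rbinom(n_cohort, 1, plogis(alpha + eta_rest))
    covars <- data.frame(age = rnorm(n_cohort, 56.5, 8),
                         townsend = rnorm(n_cohort))
    list(G = G, B = B, Bz = Bz, outcome = y, covars = covars)
  }
  coh_a <- gen_cohort(seed + 101L)
  coh_b <- gen_cohort(seed + 202L)
  variants$eaf <- colMeans(coh_a$G) / 2

  # cohort scoring on the cohort's own scale, then the exposure GWAS
  score_a <- score(sig, apply_standardization(
    list(center = colMeans(coh_a$B), scale = apply(coh_a$B, 2, sd)),
    coh_a$B))
  phen_a <- inverse_rank_normalize(score_a)
  exposure_gwas <- gwas_scan(phen_a, coh_a$G, family = "linear",
                             variants = variants)
  qc <- qc_filter(exposure_gwas_variants(exposure_gwas, variants), coh_a$G)
  exposure_gwas <- exposure_gwas[exposure_gwas$variant_id %in% qc$kept$id, ]
  instruments <- suppressWarnings(
    clump(exposure_gwas, coh_a$G, p_threshold = 5e-8, r2_threshold = 0.01))

  outcome_gwas <- gwas_scan(coh_b$outcome, coh_b$G, family = "logistic",
                            variants = variants)

  # observational association of the signature score with the outcome
  dat_a <- cbind(data.frame(outcome = coh_a$outcome,
                            sig_score = as.vector(scale(score_a))),
                 coh_a$covars)
  obs <- logistic_assoc(dat_a, "outcome", "sig_score",
                        covariates = c("age", "townsend"))

  one_sample <- NULL
  two_sample <- NULL
  if (nrow(instruments) >= 1) {
    w <- setNames(exposure_gwas$beta[match(instruments$variant_id,
                                           exposure_gwas$variant_id)],
                  instruments$variant_id)
    one_sample <- one_sample_mr(list(genotypes = coh_a$G,
                                     data = data.frame(outcome = coh_a$outcome)),
                                instruments$variant_id, weights = w)
    exp_sub <- exposure_gwas[exposure_gwas$variant_id %in%
                               instruments$variant_id, ]
    two_sample <- mr_two_sample(exp_sub, outcome_gwas, n_boot = n_boot,
                                seed = seed)
  }

  # per-biomarker evidence for the mediator screen (signature members)
  sel <- sig$biomarkers
  evidence <- NULL
  med_calls <- NULL
  if (length(sel) >= 1) {
    obs_rows <- lapply(sel, function(bk) {
      d <- cbind(data.frame(outcome = coh_a$outcome,
                            x = coh_a$Bz[, bk]), coh_a$covars)
      logistic_assoc(d, "outcome", "x", covariates = c("age", "townsend"))
    })
    obs_logor <- vapply(obs_rows, function(r) r$estimate, numeric(1))
    obs_p <- vapply(obs_rows, function(r) r$p, numeric(1))
    obs_q <- bh_fdr(obs_p)
    mr_beta <- vapply(sel, function(bk) {
      idx <- which(block_of == match(bk, bm_names))
      ex <- gwas_scan(coh_a$Bz[, bk], coh_a$G[, idx, drop = FALSE],
                      family = "linear",
                      variants = variants[idx, , drop = FALSE])
      ou <- outcome_gwas[match(ex$variant_id, outcome_gwas$variant_id), ]
      mr_ivw(mr_pairs(ex$beta, ex$se, ou$beta, ou$se, ex$variant_id))$beta
    }, numeric(1))
    evidence <- data.frame(biomarker = sel,
                           weight_sign = sign(sig$weights[sel]),
                           obs_logor = obs_logor, obs_q = obs_q,
                           mr_beta = mr_beta, stringsAsFactors = FALSE)
    med_calls <- select_mediators(evidence, outcome = "disease")
  }

  planted_in_panel <- mediators
  recovered <- if (is.null(med_calls)) character(0)
               else med_calls$biomarker[med_calls$category ==
                                          "candidate_mediator"]
  recovery <- mean(planted_in_panel %in% recovered)

  structure(list(trial = trial, signature = sig,
                 exposure_gwas = exposure_gwas, outcome_gwas = outcome_gwas,
                 instruments = instruments, obs = obs,
                 one_sample = one_sample, two_sample = two_sample,
                 evidence = evidence, mediators = med_calls,
                 truth = list(effect_vector = eff, mediators = mediators,
                              delta = delta_k, seed = seed),
                 recovery = recovery),
            class = "trialmr_pipeline")
}

# attach QC columns expected by qc_filter to a scan's variant list
exposure_gwas_variants <- function(gwas, variants) {
  v <- variants[match(gwas$variant_id, variants$id), ]
  v
}

#' @export
print.trialmr_pipeline <- function(x, ...) {
  cat("End-to-end synthetic study (seed", x$truth$seed, ")\n")
  cat("Signature terms:", length(x$signature$weights),
      "| LOO-CV AUC:", round(x$signature$cv_auc, 3), "\n")
  cat("Instruments after clumping:", nrow(x$instruments), "\n")
  cat(sprintf("Observational OR per SD: %.3f (p = %.3g)\n",
              exp(x$obs$estimate), x$obs$p))
  if (!is.null(x$one_sample))
    cat(sprintf("One-sample MR OR per SD: %.3f (p = %.3g)\n",
                exp(x$one_sample$beta), x$one_sample$p))
  if (!is.null(x$two_sample)) {
    ivw <- x$two_sample$estimates$ivw
    cat(sprintf("Two-sample IVW OR: %.3f (p = %.3g)\n", exp(ivw$beta),
                ivw$p))
  }
  cat(sprintf("Planted mediators recovered: %.0f%%\n", 100 * x$recovery))
  invisible(x)
}
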