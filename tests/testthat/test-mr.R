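make_summary <- function(id, ea, oa, eaf, beta, se = 0.05, pos = NULL) {
  n <- length(id)
  data.frame(variant_id = id, chrom = 1L,
             pos = if (is.null(pos)) seq_len(n) * 1000L else pos,
             effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se,
             p = 2 * pnorm(-abs(beta / se)), n = 1000L,
             stringsAsFactors = FALSE)
}

test_that("harmonization aligns alleles, flips swapped coding, drops ambiguous palindromes", {
  ex <- make_summary(c("a", "b", "c", "d"), c("A", "A", "A", "C"),
                     c("G", "G", "T", "T"), c(0.2, 0.2, 0.5, 0.3),
                     c(0.1, 0.2, 0.3, 0.4))
  # b swapped, c palindromic with ambiguous EAF, d strand-complemented
  ou <- make_summary(c("a", "b", "c", "d"), c("A", "G", "A", "G"),
                     c("G", "A", "T", "A"), c(0.2, 0.8, 0.5, 0.3),
                     c(0.05, -0.07, 0.2, 0.09))
  h <- harmonize(ex, ou)
  expect_identical(h$action[h$variant_id == "a"], "kept")
  expect_equal(h$beta_out[h$variant_id == "a"], 0.05)
  expect_identical(h$action[h$variant_id == "b"], "flipped")
  expect_equal(h$beta_out[h$variant_id == "b"], 0.07)
  expect_equal(h$eaf_out[h$variant_id == "b"], 0.2)
  expect_false("c" %in% h$variant_id)
  lg <- attr(h, "log")
  expect_identical(lg$action[lg$variant_id == "c"], "dropped-palindromic")
  expect_identical(h$action[h$variant_id == "d"], "kept")
  # irreconcilable alleles are dropped with a log entry
  ou2 <- ou
  ou2$effect_allele[1] <- "C"
  h2 <- harmonize(ex, ou2)
  expect_false("a" %in% h2$variant_id)
  expect_identical(attr(h2, "log")$action[1], "dropped-incompatible")
})

test_that("harmonization is idempotent", {
  ex <- make_summary(c("a", "b"), c("A", "A"), c("G", "G"), c(0.2, 0.3),
                     c(0.1, 0.2))
  ou <- make_summary(c("a", "b"), c("G", "A"), c("A", "G"), c(0.8, 0.3),
                     c(-0.05, 0.07))
  h1 <- harmonize(ex, ou)
  # rebuild an outcome summary from the harmonized pairs and re-harmonize
  ou_h <- make_summary(h1$variant_id, h1$effect_allele, h1$other_allele,
                       h1$eaf_out, h1$beta_out, h1$se_out)
  h2 <- harmonize(ex, ou_h)
  expect_equal(h1$beta_out, h2$beta_out)
  expect_equal(h1$eaf_out, h2$eaf_out)
  expect_true(all(h2$action == "kept"))
})

test_that("Wald ratio arithmetic, sign rule and zero guard", {
  w <- wald_ratio(0.5, 0.01, 0.1, 0.05)
  expect_equal(w$beta, 0.2)
  expect_equal(w$se, 0.1)
  expect_equal(wald_ratio(0.5, 0.01, 0, 0.05)$beta, 0)
  expect_equal(sign(wald_ratio(-0.5, 0.01, 0.1, 0.05)$beta),
               sign(-0.5) * sign(0.1))
  expect_error(wald_ratio(0, 0.01, 0.1, 0.05), "zero")
  # second-order delta SE is larger
  expect_gt(wald_ratio(0.5, 0.1, 0.1, 0.05, second_order = TRUE)$se, 0.1)
})

test_that("IVW: single pair equals the Wald ratio; duplicated pair halves the variance", {
  p1 <- mr_pairs(0.2, 0.01, 0.05, 0.02)
  expect_equal(mr_ivw(p1, model = "fixed")$beta,
               wald_ratio(0.2, 0.01, 0.05, 0.02)$beta)
  expect_equal(mr_ivw(p1, model = "fixed")$se,
               wald_ratio(0.2, 0.01, 0.05, 0.02)$se)
  p2 <- mr_pairs(c(0.2, 0.2), c(0.01, 0.01), c(0.05, 0.05), c(0.02, 0.02))
  expect_equal(mr_ivw(p2, model = "fixed")$beta, mr_ivw(p1)$beta)
  expect_equal(mr_ivw(p2, model = "fixed")$se,
               mr_ivw(p1, model = "fixed")$se / sqrt(2), tolerance = 1e-12)
  expect_error(mr_ivw(p1[0, ]), "at least one")
})

test_that("IVW equals the zero-intercept WLS oracle and Egger the with-intercept oracle", {
  for (s in 1:5) {
    pr <- random_pairs(sample(4:12, 1), seed = 100 + s)
    w <- 1 / pr$se_out^2
    o <- oracle_wls_origin(pr$beta_exp, pr$beta_out, w)
    fit <- mr_ivw(pr, model = "fixed")
    expect_equal(fit$beta, o$beta, tolerance = 1e-10)
    expect_equal(fit$se, o$se, tolerance = 1e-10)

    flip <- sign(pr$beta_exp)
    oe <- oracle_wls_intercept(pr$beta_exp * flip, pr$beta_out * flip, w)
    eg <- mr_egger(pr)
    expect_equal(eg$beta, oe$slope, tolerance = 1e-10)
    expect_equal(eg$egger_intercept, oe$intercept, tolerance = 1e-10)
  }
  expect_error(mr_egger(random_pairs(2, 1)), "at least 3")
})

test_that("Egger with its intercept constrained to zero is fixed-effect IVW", {
  pr <- random_pairs(8, seed = 7)
  w <- 1 / pr$se_out^2
  flip <- sign(pr$beta_exp)
  o <- oracle_wls_origin(pr$beta_exp * flip, pr$beta_out * flip, w)
  expect_equal(mr_ivw(pr, model = "fixed")$beta, o$beta, tolerance = 1e-12)
})

test_that("weighted median: unweighted middle value, hand instance, interpolation oracle", {
  p3 <- mr_pairs(rep(1, 3), rep(0.01, 3), c(0.1, 0.3, 0.9), rep(0.1, 3))
  expect_equal(mr_weighted_median(p3, n_boot = 10)$beta, 0.3)

  # constructed 5-pair instance checked step by step
  p5 <- mr_pairs(c(1, 1, 1, 1, 1), rep(0.01, 5),
                 c(0.10, 0.20, 0.30, 0.40, 0.80),
                 c(0.10, 0.05, 0.20, 0.10, 0.40))
  w <- (1 / abs(p5$se_out / p5$beta_exp))^2
  expect_equal(mr_weighted_median(p5, n_boot = 10)$beta,
               oracle_weighted_median(p5$beta_out / p5$beta_exp, w),
               tolerance = 1e-12)
  for (s in 1:10) {
    pr <- random_pairs(sample(3:15, 1), seed = 200 + s)
    th <- pr$beta_out / pr$beta_exp
    w <- (pr$beta_exp / pr$se_out)^2
    expect_equal(mr_weighted_median(pr, n_boot = 5)$beta,
                 oracle_weighted_median(th, w), tolerance = 1e-12)
  }
  expect_error(mr_weighted_median(random_pairs(2, 1)), "at least 3")
})

test_that("weighted mode: degenerate and plurality cases, dense-grid oracle", {
  pd <- mr_pairs(rep(1, 4), rep(0.01, 4), rep(0.25, 4), rep(0.05, 4))
  expect_equal(mr_weighted_mode(pd, n_boot = 20)$beta, 0.25,
               tolerance = 1e-9)

  # 7 ratios near 0.2 and 2 near 1.0 with comparable weights
  pc <- mr_pairs(rep(1, 9), rep(0.01, 9),
                 c(0.18, 0.19, 0.20, 0.20, 0.21, 0.22, 0.20, 1.0, 1.02),
                 rep(0.05, 9))
  est <- mr_weighted_mode(pc, n_boot = 20)$beta
  expect_lt(abs(est - 0.2), 0.05)

  # mode equals a dense grid evaluation of the weighted kernel density
  pr <- random_pairs(8, seed = 17)
  th <- pr$beta_out / pr$beta_exp
  se_th <- abs(pr$se_out / pr$beta_exp)
  w <- 1 / se_th^2
  h <- 0.9 * min(sd(th), mad(th)) * length(th)^(-1 / 5)
  grid <- seq(min(th) - 3 * h, max(th) + 3 * h, length.out = 100000)
  dens <- sapply(grid, function(x) sum(w * dnorm(x, th, h)))
  expect_lt(abs(mr_weighted_mode(pr, n_boot = 5)$beta -
                  grid[which.max(dens)]),
            (grid[2] - grid[1]) * 2)
})

test_that("every estimator is scale-equivariant in the exposure units", {
  pr <- random_pairs(10, seed = 23)
  pr_scaled <- pr
  c0 <- 2.5
  pr_scaled$beta_exp <- pr$beta_exp * c0
  pr_scaled$se_exp <- pr$se_exp * c0
  expect_equal(mr_ivw(pr_scaled)$beta, mr_ivw(pr)$beta / c0,
               tolerance = 1e-12)
  expect_equal(mr_egger(pr_scaled)$beta, mr_egger(pr)$beta / c0,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(pr_scaled, n_boot = 5, seed = 2)$beta,
               mr_weighted_median(pr, n_boot = 5, seed = 2)$beta / c0,
               tolerance = 1e-10)
  expect_equal(mr_weighted_mode(pr_scaled, n_boot = 5, seed = 2)$beta,
               mr_weighted_mode(pr, n_boot = 5, seed = 2)$beta / c0,
               tolerance = 1e-6)
})

test_that("bootstrap-based estimators are deterministic given the seed", {
  pr <- random_pairs(8, seed = 31)
  a <- mr_weighted_median(pr, n_boot = 50, seed = 5)
  b <- mr_weighted_median(pr, n_boot = 50, seed = 5)
  expect_identical(a$se, b$se)
  c1 <- mr_weighted_mode(pr, n_boot = 50, seed = 5)
  c2 <- mr_weighted_mode(pr, n_boot = 50, seed = 5)
  expect_identical(c1$se, c2$se)
})

test_that("one-sample MR: zero weights refused, null calibrated, planted effect directional", {
  co <- simulate_cohort(sim_cohort_config(n_individuals = 5000,
                                          n_variants = 10,
                                          causal_logOR = -0.5, seed = 43))
  ids <- colnames(co$genotypes)
  expect_error(one_sample_mr(co, ids, weights = setNames(rep(0, 10), ids)),
               "degenerate")
  est <- one_sample_mr(co, ids,
                       weights = setNames(co$truth$variant_effects, ids))
  expect_lt(est$beta, 0)
  expect_lt(est$p, 0.05)
  expect_error(one_sample_mr(co, c(ids, "nope")), "missing")
})

test_that("bi-directional analysis recovers the causal asymmetry and swaps panels", {
  cfg <- sim_cohort_config(n_individuals = 15000, n_variants = 30,
                           h2 = 0.4, causal_logOR = -0.6, seed = 47,
                           ld_rho = 0)
  ts <- make_two_sample(cfg)
  bi <- suppressWarnings(
    bidirectional(ts$exposure, ts$outcome, ts$cohort_a$genotypes,
                  methods = "ivw", seed = 1))
  expect_false(is.null(bi$forward))
  fw <- bi$forward$estimates$ivw
  expect_lt(fw$ci[2], 0)   # forward CI excludes 0
  # reverse: outcome instruments are sparse under a forward-only model;
  # if any exist the reverse CI should cover 0
  if (!is.null(bi$reverse)) {
    rv <- bi$reverse$estimates$ivw
    expect_true(rv$ci[1] < 0 && rv$ci[2] > 0)
  }
  # swapping the files swaps the panel labels exactly (same thresholds in
  # both directions so the instrument sets coincide)
  biA <- suppressWarnings(
    bidirectional(ts$exposure, ts$outcome, ts$cohort_a$genotypes,
                  r2_forward = 0.01, r2_reverse = 0.01,
                  methods = "ivw", seed = 1))
  biB <- suppressWarnings(
    bidirectional(ts$outcome, ts$exposure, ts$cohort_a$genotypes,
                  r2_forward = 0.01, r2_reverse = 0.01,
                  methods = "ivw", seed = 1))
  expect_equal(biA$forward$estimates$ivw$beta,
               biB$reverse$estimates$ivw$beta)
})
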