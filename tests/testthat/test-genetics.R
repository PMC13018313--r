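test_that("HWE exact test: monomorphic case, allele symmetry, enumeration oracle", {
  expect_identical(hwe_exact_p(50, 0, 0), 1)
  expect_equal(hwe_exact_p(10, 10, 10), oracle_hwe(10, 10, 10),
               tolerance = 1e-12)
  expect_equal(hwe_exact_p(3, 40, 2), hwe_exact_p(2, 40, 3),
               tolerance = 1e-14)
  set.seed(11)
  for (i in 1:20) {
    cnt <- c(sample(0:40, 1), sample(0:40, 1), sample(0:40, 1))
    if (sum(cnt) == 0) cnt <- c(1, 0, 0)
    expect_equal(hwe_exact_p(cnt[1], cnt[2], cnt[3]),
                 oracle_hwe(cnt[1], cnt[2], cnt[3]), tolerance = 1e-12)
  }
})

test_that("QC rules match their thresholds and a hand-enumerated pattern", {
  v <- data.frame(id = sprintf("v%02d", 1:10),
                  eaf = c(0.3, 0.005, 0.3, 0.3, 0.995, 0.2, 0.4, 0.009,
                          0.25, 0.35),
                  info = c(0.65, 0.9, 0.9, 0.71, 0.9, 0.69, 1, 0.9, 0.9,
                           0.9),
                  callrate = c(1, 1, 0.85, 1, 1, 1, 0.95, 1, 0.9, 1),
                  hwe_p = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1e-16),
                  stringsAsFactors = FALSE)
  res <- qc_filter(v)
  # hand enumeration: v01 info, v02 maf, v03 missing, v05 maf (eaf .995),
  # v06 info, v08 maf, v10 hwe -> kept v04, v07, v09
  expect_identical(res$kept$id, c("v04", "v07", "v09"))
  expect_identical(res$excluded$rule[res$excluded$id == "v01"], "info")
  expect_identical(res$excluded$rule[res$excluded$id == "v02"], "maf")
  expect_identical(res$excluded$rule[res$excluded$id == "v03"], "missing")
  expect_identical(res$excluded$rule[res$excluded$id == "v10"], "hwe")
  # order independence
  perm <- sample(nrow(v))
  res2 <- qc_filter(v[perm, ])
  expect_setequal(res2$kept$id, res$kept$id)
})

test_that("inverse rank-normal transform follows the Blom formula and is rank-invariant", {
  expect_equal(inverse_rank_normalize(c(3, 1, 9))[1], 0)  # middle of n = 3
  z <- inverse_rank_normalize(c(5, 1, 9))
  expect_equal(z, qnorm((c(2, 1, 3) - 3 / 8) / 3.25), tolerance = 1e-14)
  x <- rnorm(50)
  expect_equal(inverse_rank_normalize(x), inverse_rank_normalize(exp(x)),
               tolerance = 1e-14)
  expect_error(inverse_rank_normalize(rep(1, 5)), "equal")
  expect_error(inverse_rank_normalize(c(1, NA, 2)), "missing")
})

test_that("linear scan equals closed-form OLS and recovers a planted effect", {
  set.seed(21)
  g <- matrix(rbinom(500 * 4, 2, 0.3), 500, 4,
              dimnames = list(NULL, paste0("v", 1:4)))
  y <- rnorm(500) + 0.2 * g[, 2]
  sc <- gwas_scan(y, g, family = "linear")
  for (j in 1:4) {
    expect_equal(sc$beta[j], cov(y, g[, j]) / var(g[, j]),
                 tolerance = 1e-10)
  }
  # planted 0.1 SD/allele at n = 20,000
  cfg <- sim_cohort_config(n_individuals = 20000, n_variants = 5,
                           ld_rho = 0, maf_range = c(0.3, 0.3), seed = 22)
  gt <- simulate_genotypes(cfg)
  set.seed(23)
  y2 <- 0.1 * gt$dosage[, 1] + rnorm(20000)
  sc2 <- gwas_scan(y2, gt$dosage, family = "linear")
  expect_lt(abs(sc2$beta[1] - 0.1), 0.02)
})

test_that("logistic scan matches glm and a balanced 2x3 table's IRLS slope", {
  set.seed(31)
  g <- matrix(rbinom(400 * 3, 2, 0.4), 400, 3,
              dimnames = list(NULL, paste0("v", 1:3)))
  y <- rbinom(400, 1, plogis(-1 + 0.4 * g[, 1]))
  sc <- gwas_scan(y, g, family = "logistic")
  for (j in 1:3) {
    f <- glm(y ~ g[, j], family = binomial())
    expect_equal(sc$beta[j], unname(coef(f)[2]), tolerance = 1e-7)
    expect_equal(sc$se[j], unname(sqrt(diag(vcov(f)))[2]), tolerance = 1e-6)
  }
  # covariate-adjusted path agrees with glm too
  cv <- data.frame(age = rnorm(400))
  sca <- gwas_scan(y, g, covariates = cv, family = "logistic")
  fa <- glm(y ~ cv$age + g[, 2], family = binomial())
  expect_equal(sca$beta[2], unname(coef(fa)[3]), tolerance = 1e-6)
  expect_error(gwas_scan(y, g, covariates = cbind(a = cv$age, b = cv$age)),
               "collinear")
})

test_that("missing dosages are mean-imputed so n stays constant", {
  set.seed(41)
  g <- matrix(rbinom(200 * 2, 2, 0.3), 200, 2,
              dimnames = list(NULL, c("v1", "v2")))
  gm <- g
  gm[1:10, 1] <- NA
  sc <- gwas_scan(rnorm(200), gm, family = "linear")
  expect_identical(sc$n, rep(200L, 2))
  gi <- gm
  gi[1:10, 1] <- mean(gm[, 1], na.rm = TRUE)
  sc2 <- gwas_scan(rnorm(200), gi, family = "linear")  # same shape, no NA
  expect_false(anyNA(sc$beta))
})

test_that("ld_r2: identical columns, independent variants, two-pass oracle, monomorphic flag", {
  set.seed(51)
  g <- matrix(rbinom(50000 * 2, 2, 0.3), 50000, 2)
  g <- cbind(g, g[, 1], 1)
  colnames(g) <- paste0("v", 1:4)
  expect_equal(ld_r2(g, 1, 3), 1, tolerance = 1e-12)
  expect_lt(ld_r2(g, 1, 2), 0.01)
  # independent two-pass arithmetic oracle
  x <- g[, 1]; y <- g[, 2]
  mx <- mean(x); my <- mean(y)
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  expect_equal(as.numeric(ld_r2(g, 1, 2)), r^2, tolerance = 1e-12)
  flagged <- ld_r2(g, 1, 4)
  expect_true(is.na(flagged))
  expect_true(attr(flagged, "monomorphic"))
  expect_error(ld_r2(g[1:5, ], 1, 2), ">= 10")
})

test_that("clumping keeps one of a perfectly correlated pair and handles trivial cases", {
  set.seed(61)
  g1 <- rbinom(500, 2, 0.3)
  g <- cbind(v1 = g1, v2 = g1, v3 = rbinom(500, 2, 0.3))
  sm <- data.frame(variant_id = c("v1", "v2", "v3"), chrom = 1,
                   pos = c(100, 200, 5000),
                   effect_allele = "A", other_allele = "G", eaf = 0.3,
                   beta = c(0.5, 0.4, 0.3), se = 0.01,
                   p = c(1e-10, 2e-10, 1e-9), n = 500)
  res <- clump(sm, g, r2_threshold = 0.5, window_bp = 1e6)
  expect_identical(res$variant_id, c("v1", "v3"))
  # only one variant passes the threshold
  sm2 <- sm; sm2$p <- c(1e-10, 0.5, 0.5)
  expect_identical(clump(sm2, g)$variant_id, "v1")
  sm3 <- sm; sm3$p <- rep(0.5, 3)
  expect_warning(res3 <- clump(sm3, g), "no variant")
  expect_identical(nrow(res3), 0L)
  # p-value tie between the duplicated pair breaks to the smaller position
  sm4 <- sm; sm4$p <- c(1e-10, 1e-10, 0.5)
  expect_identical(clump(sm4, g, r2_threshold = 0.5)$variant_id, "v1")
})

test_that("cis filter bounds are inclusive at both flanks", {
  v <- data.frame(id = paste0("v", 1:5), chrom = c(1, 1, 1, 1, 2),
                  pos = c(1000, 900, 51000 + 100000, 51000 + 100001, 20000))
  out <- cis_filter(v, gene_chrom = 1, gene_start = 1000, gene_end = 51000)
  expect_setequal(out$id, c("v1", "v2", "v3"))  # v4 is 1 bp past the flank
  expect_error(cis_filter(v, 1, 100, 50), "gene_start")
})
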