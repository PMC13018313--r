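test_that("standardization: symmetric case, idempotence, stored parameters, constant columns", {
  s <- standardize(matrix(c(1, 2, 3), ncol = 1,
                          dimnames = list(NULL, "a")))
  expect_equal(as.vector(s$x), c(-1, 0, 1))

  z <- s$x
  s2 <- standardize(z)
  expect_equal(s2$x, z, tolerance = 1e-12)

  # new cohort scored with trial scaling: means need not be 0
  new <- matrix(c(10, 11, 14), ncol = 1, dimnames = list(NULL, "a"))
  zz <- apply_standardization(s, new)
  expect_equal(as.vector(zz), (c(10, 11, 14) - 2) / 1)  # center 2, sd 1
  expect_gt(abs(mean(zz)), 1)

  xc <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  expect_warning(sc <- standardize(xc), "constant")
  expect_identical(colnames(sc$x), "a")
  expect_error(apply_standardization(s, matrix(1, 1, 1,
                                               dimnames = list(NULL, "zz"))),
               "missing column")
})

test_that("published signature reproduces the printed formula", {
  sig <- published_signature()
  expect_length(sig$weights, 20)
  expect_identical(unname(sig$weights["SHBG"]), 0.21)
  expect_identical(unname(sig$weights["CCL5"]), -0.23)
  x0 <- matrix(0, 1, 20, dimnames = list(NULL, sig$biomarkers))
  expect_identical(score(sig, x0), 0)
  x1 <- x0; x1[1, "testosterone"] <- 1
  expect_equal(score(sig, x1), 0.21)
  x2 <- x0; x2[1, "PRSS2"] <- 1
  expect_equal(score(sig, x2), -0.35)
  # all 20 inputs at 1: independently summed printed coefficients
  printed_sum <- sum(c(0.21, 0.21, 0.007, -0.23, -0.14, -0.13, -0.004,
                       0.08, 0.04, 0.01, 0.27, -0.03, -0.35, -0.18,
                       -0.15, -0.11, 0.27, -0.25, -0.025, -0.14))
  xall <- x0 + 1
  expect_equal(score(sig, xall), printed_sum)
  expect_error(score(sig, x0[, -1, drop = FALSE]), "testosterone")
})

test_that("scoring is linear in its input", {
  sig <- published_signature()
  set.seed(4)
  x <- matrix(rnorm(60), 3, 20, dimnames = list(NULL, sig$biomarkers))
  y <- matrix(rnorm(60), 3, 20, dimnames = list(NULL, sig$biomarkers))
  expect_equal(score(sig, 2 * x + 3 * y),
               2 * score(sig, x) + 3 * score(sig, y), tolerance = 1e-12)
})

test_that("full shrinkage zeroes every weight and lambda = 0 is refused", {
  tr <- simulate_trial(sim_trial_config(n_subjects = 40, n_biomarkers = 10,
                                        seed = 6))
  m <- fit_signature(tr, lambda = 10)
  expect_length(m$weights, 0)
  expect_error(fit_signature(tr, lambda = 0), "refused|> 0")
})

test_that("penalized fit satisfies the KKT optimality conditions", {
  tr <- simulate_trial(sim_trial_config(n_subjects = 60, n_biomarkers = 8,
                                        seed = 13))
  tb <- trial_biomarkers(tr)
  m <- fit_signature(tb, lambda = 0.05)
  x <- standardize(tb$x)$x
  y <- as.numeric(tb$arm == "treated")
  beta <- m$coefficients
  eta <- m$intercept + as.vector(x %*% beta)
  grad <- -crossprod(x, y - plogis(eta)) / nrow(x)   # d(-loglik/n)/dbeta
  lam <- 0.05; alp <- m$alpha
  for (k in seq_along(beta)) {
    if (beta[k] == 0) {
      expect_lte(abs(grad[k]), lam * alp + 1e-6)
    } else {
      # stationarity: grad + lam*(1-alp)*beta + lam*alp*sign(beta) = 0
      expect_lt(abs(grad[k] + lam * (1 - alp) * beta[k] +
                      lam * alp * sign(beta[k])), 1e-6)
    }
  }
})

test_that("LOO-CV AUC: null labels near 0.5, separable biomarker near 1, rank-sum identity", {
  set.seed(17)
  x <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("b", 1:5)))
  y <- rep(c(0, 1), 100)
  cv <- loo_cv_auc(x, y)
  # leave-one-out CV AUC is pessimistic under the null (the held-out fit is
  # anti-correlated with the left-out label), so the guarantee that matters
  # is the absence of optimistic bias at the selected penalty
  expect_lt(cv$best_auc, 0.5 + 0.08)

  x2 <- x
  x2[, 1] <- y + rnorm(200, sd = 0.05)
  cv2 <- loo_cv_auc(x2, y)
  expect_gte(cv2$best_auc, 0.95)

  # held-out AUC equals the brute-force pairwise-count computation
  held <- cv2$heldout[, which.max(cv2$auc)]
  expect_equal(trialmr:::.auc(held, y), oracle_auc(held, y),
               tolerance = 1e-12)
})

test_that("fitted signature recovers planted responders on a strong trial", {
  tr <- simulate_trial(sim_trial_config(seed = 29))
  sig <- fit_signature(tr)
  planted <- sprintf("bm%02d", 1:4)    # the largest planted effects
  expect_true(all(planted %in% sig$biomarkers))
  expect_equal(unname(sign(sig$weights[planted])),
               sign(tr$truth$effect_vector[1:4]))
  expect_gt(sig$cv_auc, 0.6)
})

test_that("permutation p-values follow their definition", {
  tr <- simulate_trial(sim_trial_config(n_subjects = 40, n_biomarkers = 8,
                                        effect_vector = rep(0, 8),
                                        dropout = 0, seed = 23))
  tb <- trial_biomarkers(tr)
  m <- fit_signature(tb, lambda = 0.08)
  pr <- permutation_test(tb, m, B = 50, seed = 1)
  expect_true(all(pr$p_empirical >= 0) && all(pr$p_empirical <= 1))
  expect_true(all(abs(pr$p_empirical * 50 - round(pr$p_empirical * 50)) <
                    1e-12))
  # biomarkers with observed coefficient 0 must get p = 1
  zero <- pr$biomarker[pr$coef == 0]
  if (length(zero))
    expect_true(all(pr$p_empirical[pr$biomarker %in% zero] == 1))
  # deterministic given seed
  pr2 <- permutation_test(tb, m, B = 50, seed = 1)
  expect_identical(pr, pr2)
  expect_error(permutation_test(tb, m, B = 0), "B")
})

test_that("stability table counts selections and sign consistency across folds", {
  tr <- simulate_trial(sim_trial_config(n_subjects = 60, n_biomarkers = 8,
                                        effect_vector = c(1.5, rep(0, 7)),
                                        dropout = 0, seed = 31))
  tb <- trial_biomarkers(tr)
  m <- fit_signature(tb)
  st <- stability_table(tb, m)
  expect_true(all(st$sign_consistent <= st$selected))
  expect_true(all(st$selected <= st$n_folds))
  # the strongly planted biomarker is selected in >= 90% of folds
  expect_gte(st$pct[st$biomarker == "bm01"], 90)
})
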