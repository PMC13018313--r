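# Independent oracle implementations used to cross-check the package.
# Each is written from the definition, not from the package code path.

# zero-intercept weighted least squares by explicit normal equations
oracle_wls_origin <- function(x, y, w) {
  beta <- sum(w * x * y) / sum(w * x^2)
  se <- sqrt(1 / sum(w * x^2))
  list(beta = beta, se = se)
}

# weighted least squares with intercept by solving the 2x2 normal equations
oracle_wls_intercept <- function(x, y, w) {
  A <- matrix(c(sum(w), sum(w * x), sum(w * x), sum(w * x^2)), 2, 2)
  b <- c(sum(w * y), sum(w * x * y))
  sol <- solve(A, b)
  list(intercept = sol[1], slope = sol[2])
}

# weighted median by the interpolation rule, step by step
oracle_weighted_median <- function(theta, w) {
  o <- order(theta)
  th <- theta[o]
  ww <- w[o] / sum(w)
  s <- cumsum(ww) - ww / 2
  if (min(abs(s - 0.5)) < 1e-15) return(th[which.min(abs(s - 0.5))])
  j <- findInterval(0.5, s)
  if (j == 0) return(th[1])
  if (j >= length(th)) return(th[length(th)])
  th[j] + (th[j + 1] - th[j]) * (0.5 - s[j]) / (s[j + 1] - s[j])
}

# Benjamini-Hochberg by the brute-force definition:
# q_(i) = min_{k >= i} m p_(k) / k, capped at 1, mapped back to input order
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# exact HWE p by full enumeration with factorial probabilities (choose())
oracle_hwe <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  nB <- 2 * n - nA
  hets <- seq(min(nA, nB) %% 2, min(nA, nB), by = 2)
  prob <- sapply(hets, function(h) {
    aa <- (nA - h) / 2
    bb <- (nB - h) / 2
    exp(lfactorial(n) - lfactorial(aa) - lfactorial(h) - lfactorial(bb) +
          h * log(2) + lfactorial(nA) + lfactorial(nB) - lfactorial(2 * n))
  })
  prob <- prob / sum(prob)  # guard accumulated rounding
  obs <- prob[hets == nAa]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

# AUC by exhaustive pairwise comparison (ties count 1/2)
oracle_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# greedy clumping by an exhaustive, index-at-a-time reimplementation
oracle_clump <- function(df, r2mat, p_threshold, r2_threshold, window_bp) {
  df <- df[df$p < p_threshold, , drop = FALSE]
  if (nrow(df) == 0) return(character(0))
  df <- df[order(df$p, df$pos), , drop = FALSE]
  kept <- character(0)
  avail <- df$variant_id
  while (length(avail)) {
    best <- avail[1]
    kept <- c(kept, best)
    row_best <- df[df$variant_id == best, ]
    drop <- sapply(avail, function(v) {
      if (v == best) return(TRUE)
      rv <- df[df$variant_id == v, ]
      rv$chrom == row_best$chrom &&
        abs(rv$pos - row_best$pos) <= window_bp &&
        r2mat[best, v] > r2_threshold
    })
    avail <- avail[!drop]
  }
  kept
}

# penalized logistic objective of the elastic net (intercept unpenalized)
enet_objective <- function(b0, beta, x, y, lambda, alpha) {
  eta <- b0 + as.vector(x %*% beta)
  ll <- sum(y * eta - log(1 + exp(eta)))
  -ll / length(y) +
    lambda * (alpha * sum(abs(beta)) + (1 - alpha) / 2 * sum(beta^2))
}

# grid minimizer of the elastic-net objective for 1-2 active coefficients
# (others held at zero); staged grid refinement down to 1e-5 resolution,
# profiling the unpenalized intercept by 1-D optimization at each point
oracle_enet_grid <- function(x, y, lambda, alpha, active) {
  p <- ncol(x)
  eval_point <- function(b) {
    beta <- numeric(p); beta[active] <- b
    op <- optimize(function(b0) enet_objective(b0, beta, x, y, lambda, alpha),
                   c(-5, 5), tol = 1e-9)
    op$objective
  }
  k <- length(active)
  centre <- rep(0, k)
  width <- 2
  step <- if (k == 1) 0.02 else 0.05
  best <- NULL
  for (stage in 1:4) {
    grids <- lapply(seq_len(k), function(i)
      seq(centre[i] - width, centre[i] + width, by = step))
    combos <- as.matrix(expand.grid(grids))
    vals <- apply(combos, 1, eval_point)
    i <- which.min(vals)
    centre <- combos[i, ]
    best <- list(val = vals[i], beta = unname(centre))
    width <- step
    step <- step / 10
  }
  best
}

# random harmonized pairs for estimator cross-checks
random_pairs <- function(J, seed) {
  set.seed(seed)
  mr_pairs(beta_exp = runif(J, 0.05, 0.3) * sample(c(-1, 1), J, TRUE),
           se_exp = runif(J, 0.005, 0.02),
           beta_out = rnorm(J, 0, 0.05),
           se_out = runif(J, 0.01, 0.05))
}
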