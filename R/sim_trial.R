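#' Configuration for a simulated two-arm randomized trial
#'
#' Defines the study conditions for [simulate_trial()]: a 1:1 randomized,
#' placebo-controlled trial of 84 men with 94 standardized biomarkers
#' (92 proteomic analytes plus two sex hormones) measured at baseline and
#' two post-baseline visits, with 4 subjects lost to follow-up. The
#' defaults mirror that design; every field is overridable.
#'
#' @param n_subjects Number of randomized subjects (default 84).
#' @param alloc_ratio Proportion allocated to the treated arm (default 0.5).
#' @param n_biomarkers Number of biomarkers measured (default 94).
#' @param effect_vector Per-biomarker treatment effect in SD units at
#'   post-baseline visits. Sparse by default: 10 of the biomarkers carry
#'   effects of 0.4-0.8 SD with mixed signs, the rest are null.
#' @param biomarker_corr Exchangeable correlation among biomarkers, in
#'   `[0, 1)`.
#' @param n_visits Number of visits (default 3: baseline, week 8, week 12).
#' @param dropout Number of subjects lost after baseline (default 4).
#' @param subject_icc Within-subject correlation of a biomarker across
#'   visits (default 0.5).
#' @param outcome_effects Named treatment effects (SD units) on the three
#'   clinical outcomes carried by the trial: total cholesterol, fasting
#'   glucose and LDL-cholesterol. Defaults are the trial-scale effects
#'   -0.45, -0.59 and -0.39 SD.
#' @param seed Integer seed; the simulation is deterministic given the
#'   config.
#'
#' @return An object of class `sim_trial_config` (a validated list).
#' @export
sim_trial_config <- function(n_subjects = 84L,
                             alloc_ratio = 0.5,
                             n_biomarkers = 94L,
                             effect_vector = NULL,
                             biomarker_corr = 0.2,
                             n_visits = 3L,
                             dropout = 4L,
                             subject_icc = 0.5,
                             outcome_effects = c(total_cholesterol = -0.45,
                                                 fasting_glucose = -0.59,
                                                 ldl_cholesterol = -0.39),
                             seed = 1L) {
  if (n_subjects < 4) stop("n_subjects must be >= 4")
  if (alloc_ratio <= 0 || alloc_ratio >= 1) stop("alloc_ratio must be in (0,1)")
  if (is.null(effect_vector)) {
    effect_vector <- numeric(n_biomarkers)
    k <- min(10L, n_biomarkers)
    mags <- rep(c(0.8, -0.7, 0.6, -0.6, 0.5, -0.5, 0.45, -0.45, 0.4, -0.4),
                length.out = k)
    effect_vector[seq_len(k)] <- mags
  }
  if (length(effect_vector) != n_biomarkers)
    stop("effect_vector must have length n_biomarkers")
  # exchangeable correlation is PSD iff rho > -1/(K-1); the config further
  # restricts to [0, 1)
  if (biomarker_corr < 0 || biomarker_corr >= 1)
    stop("biomarker_corr must be in [0,1): requested correlation matrix is ",
         "not an admissible exchangeable structure")
  if (subject_icc < 0 || subject_icc >= 1) stop("subject_icc must be in [0,1)")
  if (n_visits < 1) stop("n_visits must be >= 1")
  if (dropout < 0 || dropout >= n_subjects) stop("invalid dropout count")
  structure(list(n_subjects = as.integer(n_subjects),
                 alloc_ratio = alloc_ratio,
                 n_biomarkers = as.integer(n_biomarkers),
                 effect_vector = effect_vector,
                 biomarker_corr = biomarker_corr,
                 n_visits = as.integer(n_visits),
                 dropout = as.integer(dropout),
                 subject_icc = subject_icc,
                 outcome_effects = outcome_effects,
                 seed = as.integer(seed)),
            class = "sim_trial_config")
}

#' Simulate a two-arm randomized biomarker trial
#'
#' Draws a 1:1 (or `alloc_ratio`) randomized trial with Gaussian biomarkers
#' under an exchangeable between-biomarker correlation and a subject-level
#' intraclass correlation across visits. The treated arm is shifted by
#' `effect_vector` (SD units) at post-baseline visits; clinical outcomes are
#' shifted by `outcome_effects`. `dropout` subjects lose their post-baseline
#' visits, mirroring completers-only follow-up.
#'
#' @param cfg A [sim_trial_config()].
#' @return A list of class `sim_trial` with elements `data` (long
#'   data.frame: `subject`, `arm`, `visit`, biomarker columns `bm*`, and the
#'   three clinical outcome columns) and `truth` (the planted effects).
#' @export
simulate_trial <- function(cfg) {
  stopifnot(inherits(cfg, "sim_trial_config"))
  set.seed(cfg$seed)
  n <- cfg$n_subjects
  K <- cfg$n_biomarkers
  V <- cfg$n_visits
  rho <- cfg$biomarker_corr
  icc <- cfg$subject_icc

  n_treat <- round(n * cfg$alloc_ratio)
  arm <- sample(rep(c("treated", "control"), c(n_treat, n - n_treat)))

  visits <- c("baseline", "wk8", "wk12", paste0("v", seq_len(max(0, V - 3L)) + 3L))[seq_len(V)]
  post <- visits != "baseline"

  # subject-level biomarker latents with exchangeable correlation rho
  f <- rnorm(n)                                   # shared factor
  a <- sqrt(rho) * matrix(f, n, K) + sqrt(1 - rho) * matrix(rnorm(n * K), n, K)

  rows <- vector("list", V)
  bm_names <- sprintf("bm%02d", seq_len(K))
  for (v in seq_len(V)) {
    e <- matrix(rnorm(n * K), n, K)
    x <- sqrt(icc) * a + sqrt(1 - icc) * e
    if (post[v]) {
      x[arm == "treated", ] <- sweep(x[arm == "treated", , drop = FALSE], 2,
                                     cfg$effect_vector, `+`)
    }
    colnames(x) <- bm_names
    rows[[v]] <- data.frame(subject = seq_len(n), arm = arm, visit = visits[v],
                            x, check.names = FALSE)
  }

  # clinical outcomes: same ICC structure, treatment effect post-baseline
  oc_names <- names(cfg$outcome_effects)
  oa <- matrix(rnorm(n * length(oc_names)), n, length(oc_names))
  for (v in seq_len(V)) {
    y <- sqrt(icc) * oa +
      sqrt(1 - icc) * matrix(rnorm(n * length(oc_names)), n, length(oc_names))
    if (post[v]) {
      y[arm == "treated", ] <- sweep(y[arm == "treated", , drop = FALSE], 2,
                                     cfg$outcome_effects, `+`)
    }
    colnames(y) <- oc_names
    rows[[v]] <- cbind(rows[[v]], y)
  }

  dat <- do.call(rbind, rows)
  dat$visit <- factor(dat$visit, levels = visits)
  dat$arm <- factor(dat$arm, levels = c("control", "treated"))

  dropped <- integer(0)
  if (cfg$dropout > 0) {
    dropped <- sort(sample(n, cfg$dropout))
    dat <- dat[!(dat$subject %in% dropped & dat$visit != "baseline"), ]
  }
  rownames(dat) <- NULL

  truth <- list(effect_vector = cfg$effect_vector,
                outcome_effects = cfg$outcome_effects,
                arm = arm, dropped = dropped, seed = cfg$seed)
  structure(list(data = dat, truth = truth, config = cfg),
            class = "sim_trial")
}

#' @export
print.sim_trial <- function(x, ...) {
  cfg <- x$config
  cat("Simulated randomized trial:", cfg$n_subjects, "subjects (",
      sum(x$truth$arm == "treated"), "treated),", cfg$n_biomarkers,
      "biomarkers,", cfg$n_visits, "visits,", length(x$truth$dropped),
      "dropouts\n")
  invisible(x)
}

#' Extract the per-subject biomarker matrix from a trial at one visit
#'
#' @param trial A `sim_trial` or a long trial data.frame.
#' @param visit Which visit to extract (default the last one present), or
#'   `"change"` for final visit minus baseline (completers only).
#' @return A list with `x` (subjects x biomarkers matrix), `arm` (factor)
#'   and `subject` ids.
#' @export
trial_biomarkers <- function(trial, visit = NULL) {
  dat <- if (inherits(trial, "sim_trial")) trial$data else trial
  bm <- grep("^bm", names(dat), value = TRUE)
  if (length(bm) == 0)
    bm <- setdiff(names(dat), c("subject", "arm", "visit",
                                "total_cholesterol", "fasting_glucose",
                                "ldl_cholesterol"))
  lv <- levels(factor(dat$visit))
  if (is.null(visit)) visit <- lv[length(lv)]
  if (identical(visit, "change")) {
    last <- lv[length(lv)]
    d1 <- dat[dat$visit == last, ]
    d0 <- dat[dat$visit == lv[1], ]
    keep <- intersect(d1$subject, d0$subject)
    d1 <- d1[match(keep, d1$subject), ]
    d0 <- d0[match(keep, d0$subject), ]
    x <- as.matrix(d1[, bm]) - as.matrix(d0[, bm])
    return(list(x = x, arm = d1$arm, subject = keep))
  }
  d <- dat[dat$visit == visit, ]
  list(x = as.matrix(d[, bm]), arm = d$arm, subject = d$subject)
}
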