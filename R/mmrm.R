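# Mixed model for repeated measures: marginal multivariate-normal model on
# change from baseline with categorical time, baseline and baseline-by-time
# covariates, treatment-by-time effects, and an unstructured T x T
# within-subject covariance fit by REML on the log-Cholesky scale. Subject
# weights enter as precision: Cov(y_i) = Sigma[V_i, V_i] / w_i.

#' Assemble the analysis dataset for the longitudinal model
#'
#' Converts a long-format observation table to the change-from-baseline
#' response of the repeated-measures model: one row per subject and
#' post-baseline visit, with the week-0 total as the baseline covariate. The
#' weight column is 1 for the reference (unweighted) analysis or the
#' propensity-derived weight when scores are supplied. Subjects with no
#' post-baseline observation are dropped and counted.
#'
#' @param data long-format observations (`subject_id`, `arm`, `visit_week`,
#'   `total_score`).
#' @param scores optional [predict_propensity()] result; must cover every
#'   retained subject (intention-to-treat completeness) or an error is
#'   raised.
#' @return data frame (`subject_id`, `arm`, `visit_week`, `change`,
#'   `baseline`, `weight`) with attribute `n_dropped` (subjects with no
#'   post-baseline data).
#' @export
prepare_long_dataset <- function(data, scores = NULL) {
  bsl <- data[data$visit_week == 0, c("subject_id", "total_score")]
  if (anyDuplicated(bsl$subject_id)) stop("duplicate baseline rows")
  post <- data[data$visit_week > 0, c("subject_id", "arm", "visit_week", "total_score")]
  m <- match(post$subject_id, bsl$subject_id)
  if (anyNA(m)) stop("post-baseline rows for subjects without a baseline")
  out <- data.frame(
    subject_id = post$subject_id,
    arm = post$arm,
    visit_week = post$visit_week,
    change = post$total_score - bsl$total_score[m],
    baseline = bsl$total_score[m],
    stringsAsFactors = FALSE
  )
  all_ids <- unique(data$subject_id)
  dropped <- setdiff(all_ids, unique(out$subject_id))
  if (is.null(scores)) {
    out$weight <- 1
  } else {
    sm <- match(out$subject_id, scores$subject_id)
    if (anyNA(sm)) {
      stop(
        "propensity scores missing for ",
        length(unique(out$subject_id[is.na(sm)])),
        " retained subject(s); the weighted analysis requires full coverage"
      )
    }
    out$weight <- scores$w[sm]
  }
  out <- out[order(out$subject_id, out$visit_week), ]
  rownames(out) <- NULL
  structure(out, n_dropped = length(dropped), dropped_ids = dropped)
}

# ---- log-Cholesky parameterization -------------------------------------

theta_to_chol <- function(theta, T) {
  L <- matrix(0, T, T)
  L[lower.tri(L, diag = TRUE)] <- theta
  diag(L) <- exp(diag(L))
  L
}

sigma_to_theta <- function(Sigma) {
  L <- t(chol(Sigma))
  diag(L) <- log(diag(L))
  L[lower.tri(L, diag = TRUE)]
}

# design matrix: visit cell means + baseline-by-visit + treatment-by-visit
mmrm_design <- function(long, visits, arms, placebo_arm) {
  T <- length(visits)
  vi <- match(long$visit_week, visits)
  p <- 2 * T + (length(arms) - 1) * T
  X <- matrix(0, nrow(long), p)
  cn <- c(
    sprintf("visit_%g", visits),
    sprintf("bsl_x_visit_%g", visits),
    as.vector(outer(visits, setdiff(arms, placebo_arm),
      function(v, a) sprintf("%s_x_visit_%g", a, v)
    ))
  )
  X[cbind(seq_len(nrow(long)), vi)] <- 1
  X[cbind(seq_len(nrow(long)), T + vi)] <- long$baseline
  act <- setdiff(arms, placebo_arm)
  for (k in seq_along(act)) {
    rows <- long$arm == act[k]
    X[cbind(which(rows), 2 * T + (k - 1) * T + vi[rows])] <- 1
  }
  colnames(X) <- cn
  X
}

# group subjects by observed-visit pattern; precompute per-visit row blocks
mmrm_patterns <- function(long, X, visits) {
  vi <- match(long$visit_week, visits)
  sid <- long$subject_id
  subj <- unique(sid)
  pat_key <- vapply(
    split(vi, factor(sid, levels = subj)),
    function(v) paste(sort(v), collapse = ","), character(1)
  )
  w_subj <- vapply(
    split(long$weight, factor(sid, levels = subj)),
    function(w) w[1], numeric(1)
  )
  patterns <- list()
  for (key in unique(pat_key)) {
    ids <- subj[pat_key == key]
    vidx <- as.integer(strsplit(key, ",")[[1]])
    rows_by_visit <- lapply(vidx, function(j) {
      which(sid %in% ids & vi == j)[order(sid[sid %in% ids & vi == j])]
    })
    # order consistently by subject within each visit block
    Xv <- lapply(rows_by_visit, function(r) X[r, , drop = FALSE])
    yv <- lapply(rows_by_visit, function(r) long$change[r])
    wS <- w_subj[match(ids[order(ids)], subj)]
    patterns[[length(patterns) + 1]] <- list(
      vidx = vidx, Xv = Xv, yv = yv, w = wS, n = length(ids)
    )
  }
  patterns
}

# -2 * restricted log-likelihood (up to an additive constant); also returns
# beta and the information matrix when requested
mmrm_objective <- function(theta, patterns, T, p, return_fit = FALSE) {
  L <- theta_to_chol(theta, T)
  Sigma <- tcrossprod(L)
  A <- matrix(0, p, p)
  bvec <- numeric(p)
  ld <- 0
  Ks <- vector("list", length(patterns))
  for (g in seq_along(patterns)) {
    pat <- patterns[[g]]
    Sp <- Sigma[pat$vidx, pat$vidx, drop = FALSE]
    cp <- tryCatch(chol(Sp), error = function(e) NULL)
    if (is.null(cp)) {
      return(if (return_fit) NULL else 1e10)
    }
    K <- chol2inv(cp)
    Ks[[g]] <- K
    tn <- length(pat$vidx)
    ld <- ld + pat$n * 2 * sum(log(diag(cp))) - tn * sum(log(pat$w))
    for (j in seq_len(tn)) {
      Xwj <- pat$Xv[[j]] * pat$w
      for (k in seq_len(tn)) {
        A <- A + K[j, k] * crossprod(Xwj, pat$Xv[[k]])
        bvec <- bvec + K[j, k] * crossprod(Xwj, pat$yv[[k]])
      }
    }
  }
  ch_A <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch_A)) {
    return(if (return_fit) NULL else 1e10)
  }
  beta <- backsolve(ch_A, forwardsolve(t(ch_A), bvec))
  quad <- 0
  for (g in seq_along(patterns)) {
    pat <- patterns[[g]]
    K <- Ks[[g]]
    tn <- length(pat$vidx)
    r <- lapply(seq_len(tn), function(j) pat$yv[[j]] - pat$Xv[[j]] %*% beta)
    for (j in seq_len(tn)) {
      rwj <- pat$w * r[[j]]
      for (k in seq_len(tn)) {
        quad <- quad + K[j, k] * sum(rwj * r[[k]])
      }
    }
  }
  obj <- ld + 2 * sum(log(diag(ch_A))) + quad
  if (!is.finite(obj)) {
    return(if (return_fit) NULL else 1e10)
  }
  if (return_fit) {
    # empirical (sandwich) covariance: A^-1 B A^-1 with B the outer product
    # of per-subject weighted score contributions
    cov_model <- chol2inv(ch_A)
    B <- matrix(0, p, p)
    for (g in seq_along(patterns)) {
      pat <- patterns[[g]]
      K <- Ks[[g]]
      tn <- length(pat$vidx)
      R <- vapply(seq_len(tn), function(j) {
        as.numeric(pat$yv[[j]] - pat$Xv[[j]] %*% beta)
      }, numeric(pat$n))
      if (pat$n == 1) R <- matrix(R, 1)
      C <- R %*% K
      U <- matrix(0, pat$n, p)
      for (j in seq_len(tn)) {
        U <- U + pat$Xv[[j]] * (pat$w * C[, j])
      }
      B <- B + crossprod(U)
    }
    m <- sum(vapply(patterns, function(pat) pat$n, numeric(1)))
    list(
      objective = obj, beta = as.numeric(beta),
      cov_beta = cov_model,
      # m/(m-1) small-sample factor, the usual cluster-robust correction
      cov_beta_empirical = (m / (m - 1)) * cov_model %*% B %*% cov_model,
      Sigma = Sigma, quad = quad
    )
  } else {
    obj
  }
}

# starting covariance: weighted pairwise covariance of independence-fit
# residuals, eigenvalue-floored to be safely positive definite
mmrm_start_sigma <- function(long, X, visits) {
  w <- long$weight
  sw <- sqrt(w)
  fit0 <- stats::lm.fit(X * sw, long$change * sw)
  beta0 <- fit0$coefficients
  beta0[is.na(beta0)] <- 0
  r <- as.numeric(long$change - X %*% beta0)
  T <- length(visits)
  vi <- match(long$visit_week, visits)
  sid <- long$subject_id
  S <- matrix(0, T, T)
  cnt <- matrix(0, T, T)
  rs <- split(data.frame(vi = vi, r = r, w = w), sid)
  for (d in rs) {
    for (a in seq_len(nrow(d))) {
      for (b in seq_len(nrow(d))) {
        S[d$vi[a], d$vi[b]] <- S[d$vi[a], d$vi[b]] + d$w[a] * d$r[a] * d$r[b]
        cnt[d$vi[a], d$vi[b]] <- cnt[d$vi[a], d$vi[b]] + d$w[a]
      }
    }
  }
  S <- S / pmax(cnt, 1)
  # fill never-jointly-observed cells with 0 and floor the spectrum
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  floor_v <- max(mean(diag(S)), 1e-6) * 1e-3
  e$values <- pmax(e$values, floor_v)
  e$vectors %*% (e$values * t(e$vectors))
}

#' Fit the (optionally weighted) mixed model for repeated measures
#'
#' REML fit of the marginal model `change ~ visit + baseline:visit +
#' arm:visit` with an unstructured within-subject covariance, where subject
#' `i`, observing visit set `V_i` with weight `w_i`, has covariance
#' `Sigma[V_i, V_i] / w_i` (the precision-weight convention of standard
#' mixed-model software). Weights are normalized to mean 1 internally — a
#' pure reparameterization of `Sigma` that makes every reported quantity,
#' including the pooled SD, exactly invariant to rescaling all weights by a
#' constant. Missing visits contribute nothing (direct-likelihood
#' missing-at-random handling); no imputation is performed.
#'
#' @param long a [prepare_long_dataset()] result.
#' @param placebo_arm reference arm label.
#' @param df_method `"satterthwaite"` (default) or `"residual"` degrees of
#'   freedom for Wald tests (with few visits and these sample sizes the two
#'   are nearly identical).
#' @param vcov_method `"model"` (default) uses the model-based fixed-effect
#'   covariance `(X' Omega^-1 X)^-1`; `"empirical"` uses the sandwich
#'   covariance clustered by subject. Estimated inverse-propensity weights
#'   are working precision weights, not true inverse variances, so the
#'   model-based covariance understates the sampling variance of the
#'   weighted estimator by about `sqrt(1 + Var(w))`; the empirical
#'   covariance is consistent regardless. Wald tests for `"empirical"` use
#'   between-subject degrees of freedom (subjects minus arms).
#' @param reltol relative convergence tolerance of the REML objective.
#' @param maxit optimizer iteration cap.
#' @return an object of class `mmrm_fit`: fixed effects, their covariance,
#'   the fitted `Sigma`, visit/arm metadata, the REML criterion and
#'   convergence flag.
#' @export
fit_mmrm <- function(long, placebo_arm = "placebo",
                     df_method = c("satterthwaite", "residual"),
                     vcov_method = c("model", "empirical"),
                     reltol = 1e-12, maxit = 500) {
  df_method <- match.arg(df_method)
  vcov_method <- match.arg(vcov_method)
  arms_all <- unique(long$arm)
  if (!placebo_arm %in% arms_all) stop("placebo arm '", placebo_arm, "' not in data")
  if (length(arms_all) < 2) stop("need at least two arms")
  tab <- table(unique(long[, c("subject_id", "arm")])$arm)
  if (any(tab < 2)) stop("need at least two subjects per arm")
  wrng <- tapply(long$weight, long$subject_id, function(w) diff(range(w)))
  if (any(wrng > 0)) stop("weights must be constant within subject")
  if (any(long$weight <= 0)) stop("weights must be positive")
  if (any(long$visit_week <= 0)) stop("response rows must be post-baseline")

  # mean-1 weight normalization (see Details)
  subj <- unique(long$subject_id)
  w_subj <- long$weight[match(subj, long$subject_id)]
  long$weight <- long$weight / mean(w_subj)

  visits <- sort(unique(long$visit_week))
  arms <- c(placebo_arm, setdiff(arms_all, placebo_arm))
  T <- length(visits)
  X <- mmrm_design(long, visits, arms, placebo_arm)
  p <- ncol(X)
  patterns <- mmrm_patterns(long, X, visits)

  Sigma0 <- mmrm_start_sigma(long, X, visits)
  theta0 <- sigma_to_theta(Sigma0)
  obj <- function(th) mmrm_objective(th, patterns, T, p)
  opt <- stats::optim(theta0, obj,
    method = "BFGS", control = list(maxit = maxit, reltol = reltol)
  )
  if (opt$value >= 1e10) {
    stop("MMRM did not reach a positive-definite covariance; try fewer visits")
  }
  fit <- mmrm_objective(opt$par, patterns, T, p, return_fit = TRUE)
  if (is.null(fit)) stop("MMRM evaluation failed at the optimum")
  # analytic polish of the free variance scale: for fixed correlation shape
  # the REML-optimal scale is quad/(n_obs - p); exact for a single visit
  s <- fit$quad / (nrow(long) - p)
  if (is.finite(s) && s > 0 && abs(log(s)) > 1e-14) {
    Lp <- theta_to_chol(opt$par, T) * sqrt(s)
    diag(Lp) <- log(diag(Lp))
    theta_p <- Lp[lower.tri(Lp, diag = TRUE)]
    fit_p <- mmrm_objective(theta_p, patterns, T, p, return_fit = TRUE)
    if (!is.null(fit_p) && fit_p$objective <= fit$objective + 1e-10) {
      opt$par <- theta_p
      fit <- fit_p
    }
  }
  names(fit$beta) <- colnames(X)
  cov_beta <- if (vcov_method == "empirical") fit$cov_beta_empirical else fit$cov_beta
  dimnames(cov_beta) <- list(colnames(X), colnames(X))
  dimnames(fit$Sigma) <- list(sprintf("wk%g", visits), sprintf("wk%g", visits))

  env <- new.env(parent = emptyenv()) # lazy Satterthwaite cache
  structure(
    list(
      beta = fit$beta, cov_beta = cov_beta,
      cov_beta_model = fit$cov_beta, Sigma = fit$Sigma,
      theta = opt$par, reml_criterion = fit$objective,
      converged = opt$convergence == 0,
      visits = visits, arms = arms, placebo_arm = placebo_arm,
      baseline_mean = mean(long$baseline[match(subj, long$subject_id)]),
      n_subjects = length(subj), n_obs = nrow(long), p = p,
      df_method = df_method, vcov_method = vcov_method,
      patterns = patterns, cache = env
    ),
    class = "mmrm_fit"
  )
}

#' @export
print.mmrm_fit <- function(x, ...) {
  cat(sprintf(
    "<mmrm_fit> %d subjects, %d obs, %d visits, %d arms; REML criterion %.3f%s\n",
    x$n_subjects, x$n_obs, length(x$visits), length(x$arms),
    x$reml_criterion, if (x$converged) "" else " (not converged)"
  ))
  invisible(x)
}

# contrast row for the LS mean of `arm` at `visit` (baseline at its mean)
lsmean_row <- function(fit, arm, visit) {
  T <- length(fit$visits)
  j <- match(visit, fit$visits)
  if (is.na(j)) stop("visit ", visit, " not in the fitted schedule")
  L <- numeric(fit$p)
  L[j] <- 1
  L[T + j] <- fit$baseline_mean
  act <- setdiff(fit$arms, fit$placebo_arm)
  k <- match(arm, act)
  if (!is.na(k)) L[2 * T + (k - 1) * T + j] <- 1
  L
}

satterthwaite_df <- function(fit, L) {
  vfun <- function(theta) {
    f <- mmrm_objective(theta, fit$patterns, length(fit$visits), fit$p,
      return_fit = TRUE
    )
    if (is.null(f)) return(NA_real_)
    as.numeric(L %*% f$cov_beta %*% L)
  }
  v0 <- as.numeric(L %*% fit$cov_beta %*% L)
  q <- length(fit$theta)
  h <- 1e-4 * (1 + abs(fit$theta))
  g <- vapply(seq_len(q), function(j) {
    tp <- fit$theta
    tm <- fit$theta
    tp[j] <- tp[j] + h[j]
    tm[j] <- tm[j] - h[j]
    (vfun(tp) - vfun(tm)) / (2 * h[j])
  }, numeric(1))
  H <- fit$cache$hessian
  if (is.null(H)) {
    f0 <- fit$reml_criterion
    fe <- function(th) mmrm_objective(th, fit$patterns, length(fit$visits), fit$p)
    H <- matrix(0, q, q)
    fp <- fm <- numeric(q)
    for (j in seq_len(q)) {
      tp <- fit$theta
      tm <- fit$theta
      tp[j] <- tp[j] + h[j]
      tm[j] <- tm[j] - h[j]
      fp[j] <- fe(tp)
      fm[j] <- fe(tm)
      H[j, j] <- (fp[j] - 2 * f0 + fm[j]) / h[j]^2
    }
    for (j in seq_len(q)) {
      for (k in seq_len(q)) {
        if (j < k) {
          tpp <- fit$theta
          tpp[c(j, k)] <- tpp[c(j, k)] + h[c(j, k)]
          fpp <- fe(tpp)
          H[j, k] <- H[k, j] <- (fpp - fp[j] - fp[k] + f0) / (h[j] * h[k])
        }
      }
    }
    fit$cache$hessian <- H
  }
  cov_theta <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(cov_theta) || anyNA(g)) {
    return(fit$n_obs - fit$p)
  }
  den <- as.numeric(g %*% cov_theta %*% g)
  if (!is.finite(den) || den <= 0) {
    return(fit$n_obs - fit$p)
  }
  df <- 2 * v0^2 / den
  min(max(df, 1), fit$n_obs - fit$p)
}

contrast_df <- function(fit, L) {
  if (fit$vcov_method == "empirical") {
    # between-subject df for the cluster-robust covariance
    fit$n_subjects - length(fit$arms)
  } else if (fit$df_method == "residual") {
    fit$n_obs - fit$p
  } else {
    satterthwaite_df(fit, L)
  }
}

#' Least-squares (adjusted) arm means
#'
#' Model-based arm means at the requested visit(s), evaluated at the overall
#' mean baseline, with delta-method standard errors from the fixed-effect
#' covariance.
#'
#' @param fit an [fit_mmrm()] result.
#' @param visits visit weeks to evaluate (default: all fitted visits).
#' @return data frame with `arm`, `visit_week`, `lsmean`, `se`.
#' @export
ls_means <- function(fit, visits = fit$visits) {
  out <- expand.grid(
    arm = fit$arms, visit_week = visits,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  est <- t(apply(out, 1, function(row) {
    L <- lsmean_row(fit, row[["arm"]], as.numeric(row[["visit_week"]]))
    c(sum(L * fit$beta), sqrt(as.numeric(L %*% fit$cov_beta %*% L)))
  }))
  out$lsmean <- est[, 1]
  out$se <- est[, 2]
  out
}

#' Tukey multiplicity adjustment
#'
#' Adjusted p-value of a two-sided pairwise t-statistic under the
#' studentized-range (Tukey) family with `n_means` groups: the probability
#' that the studentized range of `n_means` means exceeds `sqrt(2) |t|`. With
#' two groups this reduces to the unadjusted two-sided t-test.
#'
#' @param statistic t-statistic(s) of the pairwise comparison(s).
#' @param df degrees of freedom (recycled).
#' @param n_means number of group means in the family (the number of arms).
#' @return adjusted p-value(s) in (0, 1\], never below the unadjusted p.
#' @export
tukey_adjust <- function(statistic, df, n_means) {
  pmin(stats::ptukey(sqrt(2) * abs(statistic), n_means, df, lower.tail = FALSE), 1)
}

#' Between-group effect size
#'
#' Absolute LS-mean difference divided by the model-estimated pooled SD.
#'
#' @param te treatment effect (LS-mean difference, points).
#' @param pooled_sd model-estimated pooled SD (points), > 0.
#' @return standardized effect size.
#' @examples
#' effect_size(4.104, 7.990) # 0.514
#' @export
effect_size <- function(te, pooled_sd) {
  if (any(pooled_sd <= 0)) stop("pooled SD must be positive")
  abs(te) / pooled_sd
}

#' Treatment effects at end of study
#'
#' One row per active arm versus placebo: the LS-mean difference at the
#' end-of-study visit (positive when the active arm improves more than
#' placebo, i.e. placebo minus active on the change scale), its standard
#' error, the Tukey-adjusted p-value over the all-pairwise family of
#' `length(fit$arms)` means, the model pooled SD (square root of the
#' end-of-study diagonal of the fitted covariance), and the standardized
#' effect size.
#'
#' @param fit an [fit_mmrm()] result.
#' @param eos_week end-of-study visit week.
#' @return data frame of class `treatment_comparisons` with columns
#'   `comparison`, `te`, `std_err`, `df`, `p_unadjusted`, `p_adjusted`,
#'   `pooled_sd`, `effect_size`.
#' @export
treatment_effects <- function(fit, eos_week) {
  if (!eos_week %in% fit$visits) stop("end-of-study week not in the fitted schedule")
  j <- match(eos_week, fit$visits)
  pooled_sd <- sqrt(fit$Sigma[j, j])
  act <- setdiff(fit$arms, fit$placebo_arm)
  rows <- lapply(act, function(a) {
    L <- lsmean_row(fit, fit$placebo_arm, eos_week) - lsmean_row(fit, a, eos_week)
    te <- sum(L * fit$beta)
    se <- sqrt(as.numeric(L %*% fit$cov_beta %*% L))
    df <- contrast_df(fit, L)
    tval <- te / se
    data.frame(
      comparison = sprintf("%s vs. %s", fit$placebo_arm, a),
      te = te, std_err = se, df = df,
      p_unadjusted = 2 * stats::pt(-abs(tval), df),
      p_adjusted = tukey_adjust(tval, df, length(fit$arms)),
      pooled_sd = pooled_sd,
      effect_size = effect_size(te, pooled_sd),
      stringsAsFactors = FALSE
    )
  })
  structure(do.call(rbind, rows), class = c("treatment_comparisons", "data.frame"))
}
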