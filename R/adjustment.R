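#' Fit a probabilistic index model on pairwise pseudo-observations
#'
#' Fits the logit-link PIM
#' \deqn{P(Y_i \preceq Y_j \mid A_i, A_j, X_i, X_j) =
#'   expit(\tau_A (A_j - A_i) + \tau_X^T (X_j - X_i))}
#' by solving the estimating equations
#' \deqn{\sum_{i \ne j} d_{ij}\,(S_{ij} - expit(\beta^T d_{ij})) = 0, \quad
#'   d_{ij} = (A_j - A_i, (X_j - X_i)^T)^T}
#' over all n(n-1) ordered pairs — equivalent to logistic-regression
#' estimating equations in the n(n-1) pseudo-observations with fractional
#' responses \{0, 1/2, 1\}; ties enter as 1/2 directly, with no
#' tie-breaking. There is no intercept. Fisher scoring starts at
#' \eqn{\beta = 0} (unless `init` is given), accumulates score and
#' information across pairs without materializing the pair-level design
#' (memory O(p^2)), and stops when the maximum absolute score component is
#' at most `tol` or the step norm falls below 1e-10.
#'
#' With no covariates the solution is \eqn{\hat\tau_A =
#' logit(\hat\nu_{direct})}: pairs within an arm drop out of the treatment
#' equation and the score collapses to
#' \eqn{2 N_0 N_1 (\hat\nu_{direct} - expit(\tau_A))}.
#'
#' @inheritParams win_statistics
#' @param covariates numeric matrix of baseline covariates (n x p) or
#'   `NULL` for the covariate-free model.
#' @param tol convergence tolerance on the maximum absolute component of
#'   the estimating equations (default 1e-8).
#' @param max_iter Fisher-scoring iteration cap (default 100).
#' @param guard coefficient bound beyond which separation is declared
#'   (default 30 on the logit scale).
#' @param init optional starting coefficient vector (tau_A first).
#' @return object of class `"pim_fit"` with `tau_A`, `tau_X`, `n_iter`,
#'   `converged`, `max_score`.
#' @export
fit_pim <- function(scores, arm, covariates = NULL, tol = 1e-8,
                    max_iter = 100L, guard = 30, init = NULL) {
  check_scores_arm(scores, arm)
  X <- check_covariates(covariates, length(arm))
  Z <- cbind(A = as.numeric(arm), X)
  check_pair_rank(Z)
  if (nrow(Z) < ncol(Z) + 1) {
    stop("too few subjects (", nrow(Z), ") for ", ncol(Z) - 1,
         " covariates", call. = FALSE)
  }
  if (is.null(init)) init <- rep(0, ncol(Z))
  fit <- cpp_pim_fit(scores, Z, tol, as.integer(max_iter), guard,
                     as.numeric(init))
  finish_pim(fit, X, tol, max_iter)
}

finish_pim <- function(fit, X, tol, max_iter) {
  if (fit$separated) {
    stop("PIM fitting diverged (coefficient beyond the separation guard); ",
         "the pairwise responses are likely separable in the design",
         call. = FALSE)
  }
  if (fit$singular) {
    stop("singular information matrix in PIM fitting; check for ",
         "collinear or constant covariates", call. = FALSE)
  }
  if (!fit$converged) {
    stop(sprintf(paste0("PIM fitting did not converge in %d iterations ",
                        "(max |score| = %.3e, tolerance %.1e)"),
                 max_iter, fit$max_score, tol), call. = FALSE)
  }
  beta <- fit$beta
  p <- if (is.null(X)) 0L else ncol(X)
  tau_X <- if (p > 0) beta[-1] else numeric(0)
  names(tau_X) <- colnames(X)
  structure(list(tau_A = beta[1], tau_X = tau_X, n_iter = fit$n_iter,
                 converged = fit$converged, max_score = fit$max_score,
                 tol = tol),
            class = "pim_fit")
}

#' @export
print.pim_fit <- function(x, ...) {
  cat("probabilistic index model (logit link, no intercept)\n")
  cat(sprintf("  tau_A = %.6f\n", x$tau_A))
  if (length(x$tau_X) > 0) {
    cat("  tau_X:\n")
    print(round(x$tau_X, 6))
  }
  cat(sprintf("  converged in %d Fisher-scoring iterations (max |score| %.2e)\n",
              x$n_iter, x$max_score))
  invisible(x)
}

check_covariates <- function(covariates, n) {
  if (is.null(covariates)) return(NULL)
  X <- as.matrix(covariates)
  if (ncol(X) == 0) return(NULL)
  if (nrow(X) != n) {
    stop("covariate matrix has ", nrow(X), " rows but there are ", n,
         " subjects", call. = FALSE)
  }
  if (!is.numeric(X) || anyNA(X)) {
    stop("covariates must be numeric and complete; encode categorical ",
         "covariates as 0/1 indicator columns and impute or drop missing ",
         "values upstream", call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("X", seq_len(ncol(X)))
  X
}

# The PIM design lives on pairwise differences z_j - z_i, so constants are
# absorbed: the design is rank-deficient iff the centered Z is.
check_pair_rank <- function(Z) {
  Zc <- scale(Z, center = TRUE, scale = FALSE)
  if (qr(Zc)$rank < ncol(Z)) {
    bad <- colnames(Z)[apply(Zc, 2, function(v) all(abs(v) < 1e-12))]
    if (length(bad) > 0) {
      stop("constant column(s) in the pairwise design: ",
           paste(bad, collapse = ", "),
           " (a constant covariate carries no pairwise information)",
           call. = FALSE)
    }
    stop("covariate matrix is rank-deficient on pairwise differences",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Standardization estimator of the MPI
#'
#' Averages the fitted conditional probabilistic index over the empirical
#' covariate-pair distribution, plugging in the treated-vs-control arm
#' contrast for every pair:
#' \deqn{\hat\nu_{stand} = \frac{1}{n(n-1)} \sum_{i \ne j}
#'   expit(\hat\tau_A + \hat\tau_X^T (X_j - X_i)).}
#'
#' @param pim a [fit_pim()] fit.
#' @param covariates the covariate matrix the PIM was fitted with (or
#'   `NULL` for the covariate-free model, where the estimator reduces to
#'   `expit(tau_A)`).
#' @param n number of subjects; only needed when `covariates` is `NULL`.
#' @return the scalar standardization estimate of \eqn{\nu}.
#' @export
standardize_pim <- function(pim, covariates = NULL, n = NULL) {
  stopifnot(inherits(pim, "pim_fit"))
  if (is.null(covariates) || ncol(as.matrix(covariates)) == 0) {
    return(expit(pim$tau_A))
  }
  X <- as.matrix(covariates)
  v <- as.numeric(X %*% pim$tau_X)
  n <- nrow(X)
  E <- expit(pim$tau_A + matrix(v, n, n, byrow = TRUE) - matrix(v, n, n))
  (sum(E) - sum(diag(E))) / (n * (n - 1))
}

#' Augmentation estimator of the MPI
#'
#' Adds to the direct estimator an asymptotically mean-zero augmentation
#' term built from a covariate function \eqn{H(X_i, X_j)}:
#' \deqn{\hat\nu_{aug} = \hat\nu_{direct} + \sum_{i \ne j}
#'   \left[\frac{1}{n(n-1)} - \frac{(1-A_i) A_j}{N_0 N_1}\right]
#'   H(X_i, X_j).}
#' With the optimal \eqn{H^*}, estimated by the fitted PIM
#' \eqn{expit(\hat\tau_A + \hat\tau_X^T(X_j - X_i))}, the result equals the
#' standardization estimator — a property specific to the logit link and
#' the pairwise estimating equations. The bracketed weights sum to zero, so
#' a constant `H` leaves the direct estimator unchanged.
#'
#' @inheritParams fit_pim
#' @param pim a [fit_pim()] fit (ignored when `H` is supplied).
#' @param H optional n x n matrix overriding the fitted
#'   \eqn{H(X_i, X_j)}, e.g. for sensitivity checks.
#' @return the scalar augmentation estimate of \eqn{\nu}.
#' @export
augment_pim <- function(scores, arm, pim = NULL, covariates = NULL,
                        H = NULL) {
  check_scores_arm(scores, arm)
  n <- length(arm)
  if (is.null(H)) {
    stopifnot(inherits(pim, "pim_fit"))
    v <- if (is.null(covariates) || length(pim$tau_X) == 0) {
      rep(0, n)
    } else {
      as.numeric(as.matrix(covariates) %*% pim$tau_X)
    }
    H <- expit(pim$tau_A + matrix(v, n, n, byrow = TRUE) - matrix(v, n, n))
  }
  stats <- win_statistics(scores, arm)
  a <- as.numeric(arm)
  W <- 1 / (n * (n - 1)) - outer(1 - a, a) / (stats$n0 * stats$n1)
  diag(W) <- 0
  stats$nu_direct + sum(W * H)
}

#' Projection (Hajek) sandwich variance of the adjusted MPI estimator
#'
#' Variance estimator for the augmented/standardized estimator, built from
#' the order-2 U-statistic representation. With \eqn{\hat p_a = N_a / n},
#' \eqn{\hat H_{ij} = expit(\hat\tau_A + \hat\tau_X^T (X_j - X_i))} and
#' kernel
#' \deqn{h_{ij} = \frac{(1-A_i) A_j (S_{ij} - \hat H_{ij})}{\hat p_0
#'   \hat p_1} + \hat H_{ij},}
#' the per-subject projections are \eqn{\hat g_k = \frac{1}{2(n-1)}
#' \sum_{j \ne k} (h_{kj} + h_{jk})} and
#' \eqn{\hat\sigma^2_\nu = (4/n)\,\widehat{Var}(\hat g)}. Because the
#' augmentation term has mean zero for any fixed \eqn{H}, estimation of the
#' PIM coefficients is first-order ignorable and does not enter the
#' variance.
#'
#' @inheritParams augment_pim
#' @return the scalar variance estimate, with attribute `degenerate = TRUE`
#'   when the projection variance is exactly zero.
#' @export
sandwich_variance <- function(scores, arm, pim, covariates = NULL) {
  check_scores_arm(scores, arm)
  stopifnot(inherits(pim, "pim_fit"))
  n <- length(arm)
  v <- if (is.null(covariates) || length(pim$tau_X) == 0) {
    rep(0, n)
  } else {
    as.numeric(as.matrix(covariates) %*% pim$tau_X)
  }
  core <- cpp_adjusted_core(scores, as.integer(arm), pim$tau_A, v)
  out <- core$var_nu
  if (out == 0) attr(out, "degenerate") <- TRUE
  out
}

#' Covariate-adjusted win-odds inference
#'
#' End-to-end adjusted analysis: pairwise score matrix, PIM fit on the
#' n(n-1) pseudo-observations, standardization/augmentation point estimate
#' (their equality is asserted), projection sandwich (or subject-resampling
#' bootstrap) standard error, and Wald inference on the \eqn{\nu} scale
#' mapped to the win-odds and \eqn{\log\theta} scales as in
#' [direct_inference()].
#'
#' @param data trial data frame (see [read_trial_csv()]).
#' @param covariates character vector naming covariate columns of `data`
#'   (possibly `character(0)` for an adjusted analysis with an empty
#'   adjustment set, which reproduces the direct point estimate).
#' @param rule win/loss/tie rule; default the built-in hierarchical rule.
#' @param alpha two-sided significance level (default 0.05).
#' @param variance `"sandwich"` (default) or `"bootstrap"` (within-arm
#'   subject resampling of the full estimator).
#' @param boot_reps bootstrap resamples (default 500).
#' @param boot_seed optional seed for the bootstrap resampling.
#' @param engine `"auto"` (dense pairwise matrix up to `dense_limit`
#'   subjects, then streaming), `"dense"`, or `"streaming"`. The streaming
#'   engine recomputes pairwise scores on the fly in row blocks and never
#'   stores the n x n matrix; it supports only the built-in rule.
#' @param dense_limit subject count above which `engine = "auto"` switches
#'   to streaming (default 5000).
#' @param tol,max_iter passed to [fit_pim()].
#' @return object of class `"win_odds_result"` with the fitted `"pim_fit"`
#'   in `$pim` and both point-estimate forms in `$nu_stand`, `$nu_aug`.
#' @export
adjusted_inference <- function(data, covariates = character(),
                               rule = hierarchical_rule(), alpha = 0.05,
                               variance = c("sandwich", "bootstrap"),
                               boot_reps = 500L, boot_seed = NULL,
                               engine = c("auto", "dense", "streaming"),
                               dense_limit = 5000L, tol = 1e-8,
                               max_iter = 100L) {
  variance <- match.arg(variance)
  engine <- match.arg(engine)
  data <- validate_trial_data(data, covariates = covariates)
  n <- nrow(data)
  arm <- data$arm
  X <- if (length(covariates) > 0) {
    as.matrix(data[, covariates, drop = FALSE])
  } else {
    NULL
  }
  if (engine == "auto") {
    engine <- if (n <= dense_limit) "dense" else "streaming"
  }
  if (engine == "streaming" && !isTRUE(rule$builtin)) {
    stop("the streaming engine supports only the built-in hierarchical ",
         "rule; use engine = \"dense\"", call. = FALSE)
  }

  if (engine == "dense") {
    S <- score_matrix(data, rule)
    pim <- fit_pim(S, arm, X, tol = tol, max_iter = max_iter)
    v <- linear_score(pim, X, n)
    core <- cpp_adjusted_core(S, as.integer(arm), pim$tau_A, v)
  } else {
    Z <- cbind(A = as.numeric(arm), check_covariates(X, n))
    check_pair_rank(Z)
    fit <- cpp_pim_fit_stream(data$time_death,
                              as.integer(data$event_death),
                              data$time_nonfatal,
                              as.integer(data$event_nonfatal),
                              Z, tol, as.integer(max_iter), 30,
                              rep(0, ncol(Z)))
    pim <- finish_pim(fit, X, tol, max_iter)
    v <- linear_score(pim, X, n)
    core <- cpp_adjusted_core_stream(data$time_death,
                                     as.integer(data$event_death),
                                     data$time_nonfatal,
                                     as.integer(data$event_nonfatal),
                                     as.integer(arm), pim$tau_A, v)
  }
  if (abs(core$nu_stand - core$nu_aug) > 1e-6) {
    stop(sprintf(paste0("standardization (%.10f) and augmentation (%.10f) ",
                        "estimates disagree; the PIM fit is unreliable"),
                 core$nu_stand, core$nu_aug), call. = FALSE)
  }
  nu <- core$nu_stand
  if (variance == "sandwich") {
    var_nu <- core$var_nu
    if (var_nu == 0 && nu != 0.5) {
      stop("degenerate (zero) projection variance", call. = FALSE)
    }
    se_nu <- sqrt(var_nu)
  } else {
    se_nu <- bootstrap_se(data, covariates, rule, boot_reps, boot_seed,
                          pim = pim,
                          S = if (engine == "dense") S else NULL)
  }
  stats <- if (engine == "dense") win_statistics(S, arm) else NULL
  res <- build_result(nu = nu, se_nu = se_nu, alpha = alpha,
                      method = "adjusted", stats = stats,
                      adjustment = covariates, pim = pim,
                      nu_stand = core$nu_stand, nu_aug = core$nu_aug,
                      variance_method = variance)
  res
}

linear_score <- function(pim, X, n) {
  if (is.null(X) || length(pim$tau_X) == 0) {
    rep(0, n)
  } else {
    as.numeric(X %*% pim$tau_X)
  }
}

# Within-arm subject-resampling bootstrap of the adjusted point estimate.
# Resampled score matrices are index subsets of the original (pairwise
# scores depend only on the two outcomes), so comparisons are not redone;
# refits warm-start at the original coefficients.
bootstrap_se <- function(data, covariates, rule, boot_reps, boot_seed,
                         pim = NULL, S = NULL) {
  if (!is.null(boot_seed)) set.seed(boot_seed)
  n <- nrow(data)
  arm <- data$arm
  if (is.null(S)) S <- score_matrix(data, rule)
  X <- if (length(covariates) > 0) {
    as.matrix(data[, covariates, drop = FALSE])
  } else {
    NULL
  }
  i0 <- which(arm == 0)
  i1 <- which(arm == 1)
  init <- if (is.null(pim)) NULL else c(pim$tau_A, pim$tau_X)
  est <- vapply(seq_len(boot_reps), function(b) {
    idx <- c(sample(i0, replace = TRUE), sample(i1, replace = TRUE))
    Sb <- S[idx, idx]
    diag(Sb) <- 0.5 # repeated subjects compare as ties off the diagonal too
    Xb <- if (is.null(X)) NULL else X[idx, , drop = FALSE]
    fit <- fit_pim(Sb, arm[idx], Xb, init = init)
    standardize_pim(fit, Xb, n = n)
  }, numeric(1))
  sd(est)
}

#' Win-odds analysis of a trial dataset
#'
#' The main entry point: runs the direct (unadjusted) analysis when
#' `covariates` is `NULL`, and the covariate-adjusted analysis otherwise
#' (including the empty adjustment set `character(0)`, whose point estimate
#' collapses to the direct one).
#'
#' @inheritParams adjusted_inference
#' @param covariates `NULL` for the unadjusted analysis, or a character
#'   vector of covariate column names.
#' @param ... passed to [adjusted_inference()].
#' @return object of class `"win_odds_result"`.
#' @examples
#' trial <- simulate_trial(200, scenario = "A", seed = 7)
#' win_odds(trial)                       # unadjusted
#' win_odds(trial, covariates = c("X1", "X2"))  # adjusted
#' @export
win_odds <- function(data, covariates = NULL, rule = hierarchical_rule(),
                     alpha = 0.05, ...) {
  if (is.null(covariates)) {
    data <- validate_trial_data(data)
    S <- score_matrix(data, rule)
    direct_inference(S, data$arm, alpha = alpha)
  } else {
    adjusted_inference(data, covariates = covariates, rule = rule,
                       alpha = alpha, ...)
  }
}
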