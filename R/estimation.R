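#' Win/loss/tie counts and the direct MPI estimator
#'
#' Tallies wins, losses and ties over all treatment-vs-control comparisons
#' and computes the direct (unadjusted) estimator of the marginal
#' probabilistic index,
#' \deqn{\hat\nu_{direct} = (\#wins + 0.5\,\#ties) / (N_0 N_1),}
#' together with the net benefit \eqn{\hat\Delta = (\#wins - \#losses) /
#' (N_0 N_1)} and the win odds \eqn{\hat\theta = \hat\nu / (1 - \hat\nu)
#' = (1 + \hat\Delta) / (1 - \hat\Delta)}. "Win" means a win for the
#' treated subject of the pair.
#'
#' @param scores pairwise score matrix from [score_matrix()].
#' @param arm binary treatment vector (0 = control, 1 = treated).
#' @return object of class `"win_statistics"`: a list with `n_wins`,
#'   `n_losses`, `n_ties`, `n0`, `n1`, `nu_direct`, `delta`, `theta`
#'   (`Inf` when every comparison is a treated win).
#' @export
win_statistics <- function(scores, arm) {
  check_scores_arm(scores, arm)
  core <- cpp_direct_core(scores, as.integer(arm))
  nu <- (core$n_wins + 0.5 * core$n_ties) / (core$n0 * core$n1)
  delta <- (core$n_wins - core$n_losses) / (core$n0 * core$n1)
  structure(list(n_wins = core$n_wins, n_losses = core$n_losses,
                 n_ties = core$n_ties, n0 = core$n0, n1 = core$n1,
                 nu_direct = nu, delta = delta,
                 theta = if (delta < 1) nu / (1 - nu) else Inf),
            class = "win_statistics")
}

#' @export
print.win_statistics <- function(x, ...) {
  cat(sprintf("pairwise comparisons: %d treated x %d control = %d pairs\n",
              as.integer(x$n1), as.integer(x$n0),
              as.integer(x$n0 * x$n1)))
  cat(sprintf("  wins %d | ties %d | losses %d (for treated)\n",
              as.integer(x$n_wins), as.integer(x$n_ties),
              as.integer(x$n_losses)))
  cat(sprintf("  nu = %.6f, net benefit = %.6f, win odds = %.6f\n",
              x$nu_direct, x$delta, x$theta))
  invisible(x)
}

check_scores_arm <- function(scores, arm) {
  if (!is.matrix(scores) || nrow(scores) != ncol(scores)) {
    stop("'scores' must be a square pairwise score matrix", call. = FALSE)
  }
  if (length(arm) != nrow(scores)) {
    stop("'arm' length does not match the score matrix", call. = FALSE)
  }
  if (!all(arm %in% c(0, 1))) {
    stop("'arm' must be a 0/1 vector", call. = FALSE)
  }
  if (length(unique(arm)) < 2) {
    stop("both arms must be non-empty", call. = FALSE)
  }
  invisible(TRUE)
}

#' Unadjusted win-odds inference
#'
#' Wald inference for the direct estimator based on the two-sample
#' U-statistic (projection) variance of the net benefit \eqn{\hat\Delta}:
#' with kernel \eqn{K = +1/0/-1} for a treated win/tie/loss,
#' \eqn{\hat\zeta_{10}} is the sample variance over control subjects of
#' their kernel row means, \eqn{\hat\zeta_{01}} the sample variance over
#' treated subjects of their column means, and
#' \eqn{\widehat{Var}(\hat\Delta) = \hat\zeta_{10}/N_0 + \hat\zeta_{01}/N_1}.
#' Since \eqn{\nu = (1 + \Delta)/2}, \eqn{\hat\sigma_\nu =
#' \sqrt{\widehat{Var}(\hat\Delta)}/2}. The Wald test of
#' \eqn{H_0: \nu = 1/2} (equivalently \eqn{\theta = 1}) is performed on the
#' \eqn{\nu} scale; the confidence interval is mapped to the win-odds scale
#' through the increasing map \eqn{\nu \mapsto \nu/(1-\nu)}, and
#' delta-method results on the \eqn{\log\theta} scale
#' (\eqn{\hat\sigma_{\log\theta} = \hat\sigma_\nu / (\hat\nu(1-\hat\nu))})
#' are also reported.
#'
#' @inheritParams win_statistics
#' @param alpha two-sided significance level for the confidence intervals
#'   (default 0.05; the corresponding one-sided test of
#'   \eqn{H_0: \theta \le 1} has level `alpha/2`).
#' @return object of class `"win_odds_result"`; see [win_odds()].
#' @export
direct_inference <- function(scores, arm, alpha = 0.05) {
  check_scores_arm(scores, arm)
  stats <- win_statistics(scores, arm)
  if (stats$n0 < 2 || stats$n1 < 2) {
    stop("need at least 2 subjects per arm for variance estimation",
         call. = FALSE)
  }
  core <- cpp_direct_core(scores, as.integer(arm))
  kmean <- core$kmean
  zeta10 <- var(kmean[arm == 0])
  zeta01 <- var(kmean[arm == 1])
  var_delta <- zeta10 / stats$n0 + zeta01 / stats$n1
  se_nu <- sqrt(var_delta) / 2
  build_result(nu = stats$nu_direct, se_nu = se_nu, alpha = alpha,
               method = "direct", stats = stats)
}

# Shared Wald machinery on the nu scale, with the theta and log-theta
# transforms. nu in {0, 1} raises the boundary flag (no intervals); zero
# variance away from nu = 1/2 is a degenerate-data error.
build_result <- function(nu, se_nu, alpha, method, stats = NULL,
                         adjustment = NULL, pim = NULL, nu_stand = NULL,
                         nu_aug = NULL, variance_method = "u-statistic") {
  boundary <- nu %in% c(0, 1)
  degenerate <- !boundary && se_nu == 0
  if (degenerate && nu != 0.5) {
    stop("estimated variance is zero while nu = ", nu,
         "; data are degenerate (e.g. one arm uniformly wins)",
         call. = FALSE)
  }
  zc <- qnorm(1 - alpha / 2)
  if (boundary) {
    z <- NA_real_
    p2 <- p1 <- NA_real_
    ci_nu <- ci_theta <- ci_log_theta <- c(NA_real_, NA_real_)
    theta <- if (nu == 1) Inf else 0
    log_theta <- se_log_theta <- NA_real_
    p2l <- p1l <- NA_real_
  } else if (degenerate) {
    # all comparisons tied: no evidence either way
    z <- 0
    p2 <- 1
    p1 <- 0.5
    ci_nu <- c(nu, nu)
    theta <- 1
    ci_theta <- c(1, 1)
    log_theta <- 0
    se_log_theta <- 0
    ci_log_theta <- c(0, 0)
    p2l <- 1
    p1l <- 0.5
  } else {
    z <- (nu - 0.5) / se_nu
    p2 <- 2 * pnorm(-abs(z))
    p1 <- pnorm(z, lower.tail = FALSE) # H0: theta <= 1
    ci_nu <- nu + c(-1, 1) * zc * se_nu
    theta <- nu / (1 - nu)
    ci_theta <- nu_to_theta(ci_nu)
    log_theta <- log(theta)
    se_log_theta <- se_nu / (nu * (1 - nu))
    ci_log_theta <- log_theta + c(-1, 1) * zc * se_log_theta
    zl <- log_theta / se_log_theta
    p2l <- 2 * pnorm(-abs(zl))
    p1l <- pnorm(zl, lower.tail = FALSE)
  }
  structure(list(method = method, adjustment = adjustment, alpha = alpha,
                 nu = nu, se_nu = se_nu, theta = theta, z = z,
                 p_two_sided = p2, p_one_sided = p1,
                 ci_nu = ci_nu, ci_theta = ci_theta,
                 log_theta = log_theta, se_log_theta = se_log_theta,
                 ci_log_theta = ci_log_theta,
                 p_two_sided_log_theta = p2l, p_one_sided_log_theta = p1l,
                 boundary = boundary, degenerate = degenerate,
                 stats = stats, pim = pim, nu_stand = nu_stand,
                 nu_aug = nu_aug, variance_method = variance_method),
            class = "win_odds_result")
}

# map a nu-scale interval to the win-odds scale, clamping at the boundary
nu_to_theta <- function(nu) {
  nu <- pmin(pmax(nu, 0), 1)
  ifelse(nu >= 1, Inf, nu / (1 - nu))
}

#' @export
print.win_odds_result <- function(x, digits = 6, ...) {
  cat(sprintf("win odds (%s%s)\n", x$method,
              if (!is.null(x$adjustment) && length(x$adjustment) > 0) {
                paste0(", adjusted for ", paste(x$adjustment,
                                                collapse = ", "))
              } else if (identical(x$method, "adjusted")) {
                ", empty adjustment set"
              } else ""))
  if (x$boundary) {
    cat(sprintf("  nu = %s at the boundary; no interval or test reported\n",
                format(x$nu)))
    return(invisible(x))
  }
  cat(sprintf("  nu      = %.*f (SE %.*f)\n", digits, x$nu, digits,
              x$se_nu))
  cat(sprintf("  theta   = %.*f, %d%% CI (%.*f, %.*f)\n", digits, x$theta,
              round(100 * (1 - x$alpha)), 4, x$ci_theta[1], 4,
              x$ci_theta[2]))
  cat(sprintf("  p (two-sided, H0: theta = 1)  = %.*f\n", digits,
              x$p_two_sided))
  cat(sprintf("  p (one-sided, H0: theta <= 1) = %.*f\n", digits,
              x$p_one_sided))
  invisible(x)
}

#' Flatten a win-odds result to a one-row data frame
#'
#' @param x a `"win_odds_result"`.
#' @param row.names,optional,... passed through for compatibility.
#' @export
as.data.frame.win_odds_result <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(method = x$method,
             adjustment = if (is.null(x$adjustment)) "" else
               paste(x$adjustment, collapse = "+"),
             nu = x$nu, se_nu = x$se_nu, theta = x$theta,
             ci_theta_lower = x$ci_theta[1], ci_theta_upper = x$ci_theta[2],
             p_two_sided = x$p_two_sided, p_one_sided = x$p_one_sided,
             n_wins = if (is.null(x$stats)) NA else x$stats$n_wins,
             n_ties = if (is.null(x$stats)) NA else x$stats$n_ties,
             n_losses = if (is.null(x$stats)) NA else x$stats$n_losses,
             alpha = x$alpha, variance_method = x$variance_method,
             stringsAsFactors = FALSE, row.names = row.names)
}
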