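#' Operating characteristics of the win-odds tests
#'
#' Monte-Carlo estimation of the empirical rejection rate of the one-sided
#' null hypothesis \eqn{H_0: \theta \le 1} for the unadjusted and
#' covariate-adjusted win-odds tests, over a grid of scenarios, sample
#' sizes and adjustment sets. Each replication simulates one trial from
#' the latent failure-time model ([simulate_trial()]); under
#' `null = TRUE` the treatment labels are then re-drawn independently of
#' the outcomes ([flip_treatment()]), so the data satisfy the null while
#' the outcome marginals are untouched.
#'
#' Per-replication seeds are derived from the master `seed` by a fixed
#' counter scheme (one pre-drawn seed per replication and cell), so the
#' result is deterministic and replications are independent of any
#' execution order. Replications whose adjusted fit fails (e.g.
#' non-convergence) are counted in `n_fail` and excluded from the rate
#' denominator of that method only.
#'
#' @param scenarios character vector of scenario labels (see
#'   [scenario_coefficients()]).
#' @param n vector of per-dataset sample sizes.
#' @param n_reps replications per cell (default 1000; the reference
#'   operating-characteristics study used 10000 and more).
#' @param adjust list describing the analyses to run in each replication:
#'   the string `"unadjusted"` for the direct test, an integer `k` for
#'   adjustment on `X1, ..., Xk`, or a character vector of covariate
#'   names.
#' @param null if `TRUE`, flip treatment to generate null-consistent data.
#' @param alpha one-sided significance level (default 0.025).
#' @param treatment_effect,censor_quantile,allocation passed to
#'   [simulate_trial()].
#' @param seed master seed (required for reproducibility).
#' @return data frame of class `"oc_result"` with one row per (scenario,
#'   n, method) cell: rejections, failures, rejection `rate`, binomial
#'   Monte-Carlo standard error `mc_se` and 95% half-width `mc_half`. The
#'   per-replication rejection indicators are attached as attribute
#'   `"rejections"` (a named list of logical matrices, one per scenario-n
#'   cell) so that paired method contrasts can be formed.
#' @examples
#' oc <- run_operating_characteristics("A", n = 100, n_reps = 20,
#'                                     adjust = list("unadjusted", 1),
#'                                     seed = 1)
#' oc
#' @export
run_operating_characteristics <- function(scenarios = "A", n = 500,
                                          n_reps = 1000L,
                                          adjust = list("unadjusted", 1, 10),
                                          null = FALSE, alpha = 0.025,
                                          treatment_effect = 0.3,
                                          censor_quantile = 0.35,
                                          allocation = 0.5, seed = 1L) {
  stopifnot(n_reps >= 1, length(adjust) >= 1)
  labels <- vapply(adjust, adjust_label, character(1))
  set.seed(seed)
  rows <- list()
  rejlist <- list()
  for (sc in scenarios) {
    for (nn in n) {
      rep_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
      rej <- matrix(NA, n_reps, length(adjust),
                    dimnames = list(NULL, labels))
      for (r in seq_len(n_reps)) {
        set.seed(rep_seeds[r])
        dat <- simulate_trial(nn, scenario = sc,
                              treatment_effect = treatment_effect,
                              censor_quantile = censor_quantile,
                              allocation = allocation)
        if (null) dat <- flip_treatment(dat)
        S <- try(score_matrix(dat), silent = TRUE)
        if (inherits(S, "try-error")) next
        for (m in seq_along(adjust)) {
          rej[r, m] <- tryCatch({
            res <- run_one_method(S, dat, adjust[[m]], alpha)
            res$p_one_sided < alpha
          }, error = function(e) NA)
        }
      }
      cell <- sprintf("%s_n%d", sc, nn)
      rejlist[[cell]] <- rej
      for (m in seq_along(adjust)) {
        ok <- !is.na(rej[, m])
        rate <- mean(rej[ok, m])
        mc_se <- sqrt(rate * (1 - rate) / sum(ok))
        rows[[length(rows) + 1]] <- data.frame(
          scenario = sc, n = nn, method = labels[m],
          n_reps = n_reps, n_fail = sum(!ok),
          rejections = sum(rej[ok, m]), rate = rate,
          mc_se = mc_se, mc_half = 1.96 * mc_se,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "rejections") <- rejlist
  attr(out, "alpha") <- alpha
  attr(out, "null") <- null
  attr(out, "seed") <- seed
  class(out) <- c("oc_result", "data.frame")
  out
}

adjust_label <- function(a) {
  if (identical(a, "unadjusted")) return("unadjusted")
  if (is.numeric(a) && length(a) == 1) {
    if (a == 0) return("adjusted:none")
    if (a == 1) return("adjusted:X1")
    return(sprintf("adjusted:X1..X%d", as.integer(a)))
  }
  paste0("adjusted:", paste(a, collapse = "+"))
}

run_one_method <- function(S, dat, a, alpha) {
  if (identical(a, "unadjusted")) {
    return(direct_inference(S, dat$arm, alpha = 2 * alpha))
  }
  covs <- if (is.numeric(a) && length(a) == 1) {
    if (a == 0) character(0) else paste0("X", seq_len(a))
  } else {
    a
  }
  X <- if (length(covs) > 0) as.matrix(dat[, covs, drop = FALSE]) else NULL
  pim <- fit_pim(S, dat$arm, X)
  v <- linear_score(pim, X, nrow(dat))
  core <- cpp_adjusted_core(S, as.integer(dat$arm), pim$tau_A, v)
  build_result(nu = core$nu_stand, se_nu = sqrt(core$var_nu),
               alpha = 2 * alpha, method = "adjusted", adjustment = covs,
               pim = pim, nu_stand = core$nu_stand, nu_aug = core$nu_aug,
               variance_method = "sandwich")
}

#' @export
print.oc_result <- function(x, ...) {
  cat(sprintf("operating characteristics (%s, one-sided alpha = %g)\n",
              if (isTRUE(attr(x, "null"))) "null: flipped treatment"
              else "alternative", attr(x, "alpha")))
  df <- as.data.frame(x)
  df$rate <- sprintf("%.4f", df$rate)
  df$mc_half <- sprintf("%.4f", df$mc_half)
  print(df[, c("scenario", "n", "method", "n_reps", "n_fail",
               "rejections", "rate", "mc_half")], row.names = FALSE)
  invisible(x)
}
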