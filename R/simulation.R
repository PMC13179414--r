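#' Covariate-influence patterns for the simulation scenarios
#'
#' Returns the length-10 coefficient vector \eqn{\gamma} of the latent
#' failure-time model for the built-in scenarios:
#' \itemize{
#'   \item `"A"` — equal influence: \eqn{\gamma_j = 1/\sqrt{10}}.
#'   \item `"B"` — linearly decreasing influence: \eqn{\delta_j = 1 -
#'     (j-1)/10}, \eqn{\gamma = \delta / \|\delta\|_2}.
#'   \item `"C"` — rapidly decreasing influence concentrated on the first
#'     five covariates: \eqn{\delta_j = 1/j^2} for \eqn{j \le 5}, 0 for
#'     \eqn{j \ge 6}, \eqn{\gamma = \delta / \|\delta\|_2}.
#' }
#' All scenarios are normalized so that \eqn{\sum_j \gamma_j^2 = 1}, which
#' makes \eqn{\gamma^T X \sim N(0, 1)} and hence the marginal outcome
#' distribution identical across scenarios.
#'
#' @param scenario `"A"`, `"B"` or `"C"`.
#' @return numeric vector of length 10 with unit sum of squares.
#' @export
scenario_coefficients <- function(scenario) {
  delta <- switch(as.character(scenario),
    A = rep(1, 10),
    B = 1 - (seq_len(10) - 1) / 10,
    C = c(1 / (1:5)^2, rep(0, 5)),
    stop("unknown scenario '", scenario, "'; use \"A\", \"B\" or \"C\"",
         call. = FALSE)
  )
  delta / sqrt(sum(delta^2))
}

#' Empirical-quantile censoring of latent event times
#'
#' Applies the within-dataset administrative censoring rule: the censoring
#' time is the empirical `q`-quantile (type 1, i.e. the
#' `ceiling(q * n)`-th order statistic) of `min(T1, T2)`, so that a
#' fraction `q` of subjects has reached at least one event by the censoring
#' time. Events are observed iff strictly before the censoring time, and
#' the nonfatal event only if also strictly before death:
#' \deqn{Y = (\min(T_1, T_{cens}), \min(T_2, T_1, T_{cens}),
#'   I(T_1 < T_{cens}), I(T_2 < \min(T_1, T_{cens}))).}
#'
#' @param time_death,time_nonfatal latent (uncensored) event-time vectors
#'   `T1` (death) and `T2` (first nonfatal event).
#' @param q target event fraction in (0, 1).
#' @return list with `t_cens` (the censoring time) and `data` (a data
#'   frame with the observed columns `time_death`, `event_death`,
#'   `time_nonfatal`, `event_nonfatal`).
#' @export
apply_censoring <- function(time_death, time_nonfatal, q = 0.35) {
  stopifnot(length(time_death) == length(time_nonfatal),
            q > 0, q < 1)
  n <- length(time_death)
  first <- pmin(time_death, time_nonfatal)
  t_cens <- sort(first)[ceiling(q * n)]
  obs_death <- pmin(time_death, t_cens)
  d1 <- as.integer(time_death < t_cens)
  obs_nonfatal <- pmin(time_nonfatal, time_death, t_cens)
  d2 <- as.integer(time_nonfatal < pmin(time_death, t_cens))
  list(t_cens = t_cens,
       data = data.frame(time_death = obs_death, event_death = d1,
                         time_nonfatal = obs_nonfatal, event_nonfatal = d2))
}

#' Simulate a two-arm trial with a hierarchical composite endpoint
#'
#' Generates subject-level data from the latent failure-time model
#' \deqn{X_1, \dots, X_{10} \sim N(0,1), \quad A \sim Bern(allocation),
#'   \quad T_1^0, T_2^0 \sim Exp(1),}
#' \deqn{T_k = scale \cdot \exp(effect \cdot A + \gamma^T X) \cdot T_k^0,
#'   \quad k = 1, 2,}
#' i.e. both the death time \eqn{T_1} and the first-nonfatal-event time
#' \eqn{T_2} are conditionally exponential, consistent with a proportional
#' hazards model linear in treatment and covariates (hazard ratio
#' \eqn{e^{-effect}} for treatment: positive `treatment_effect` prolongs
#' event times). Within-dataset empirical-quantile censoring
#' ([apply_censoring()]) is then applied so that a fraction
#' `censor_quantile` of subjects has at least one event in view.
#'
#' @param n number of subjects (at least 4).
#' @param scenario covariate-influence pattern, see
#'   [scenario_coefficients()]; ignored when `gamma` is given.
#' @param gamma optional custom coefficient vector (any length p; the
#'   generator then draws p standard-normal covariates).
#' @param treatment_effect log-scale effect of treatment on both event
#'   times (default 0.3; 0 gives exchangeable arms).
#' @param scale baseline time multiplier in study-time units (default
#'   7500, calibrated so cumulative incidence resembles cardiovascular
#'   outcomes trials).
#' @param censor_quantile target fraction of subjects with at least one
#'   event (default 0.35).
#' @param allocation treatment assignment probability (default 0.5).
#' @param seed optional integer seed for reproducibility.
#' @return data frame with columns `subject_id`, `arm`, covariates
#'   `X1...Xp`, and the observed outcome columns `time_death`,
#'   `event_death`, `time_nonfatal`, `event_nonfatal`. The censoring time,
#'   `gamma`, the generator settings and the latent (uncensored) event
#'   times (attribute `"latent"`) are attached as attributes.
#' @examples
#' trial <- simulate_trial(500, scenario = "A", seed = 1)
#' mean(trial$event_death == 1 | trial$event_nonfatal == 1) # ~ 0.35
#' @export
simulate_trial <- function(n, scenario = "A", gamma = NULL,
                           treatment_effect = 0.3, scale = 7500,
                           censor_quantile = 0.35, allocation = 0.5,
                           seed = NULL) {
  stopifnot(n >= 4, scale > 0, censor_quantile > 0, censor_quantile < 1,
            allocation > 0, allocation < 1)
  if (!is.null(seed)) set.seed(seed)
  gamma <- if (is.null(gamma)) scenario_coefficients(scenario) else
    as.numeric(gamma)
  p <- length(gamma)
  X <- matrix(rnorm(n * p), n, p)
  colnames(X) <- paste0("X", seq_len(p))
  A <- rbinom(n, 1, allocation)
  lp <- as.numeric(treatment_effect * A + X %*% gamma)
  T1 <- scale * exp(lp) * rexp(n)
  T2 <- scale * exp(lp) * rexp(n)
  cens <- apply_censoring(T1, T2, censor_quantile)
  out <- cbind(data.frame(subject_id = seq_len(n), arm = A), X, cens$data)
  attr(out, "t_cens") <- cens$t_cens
  attr(out, "latent") <- data.frame(T1 = T1, T2 = T2)
  attr(out, "gamma") <- gamma
  attr(out, "scenario") <- if (is.null(gamma)) scenario else "custom"
  attr(out, "allocation") <- allocation
  attr(out, "treatment_effect") <- treatment_effect
  out
}

#' Sever the treatment-outcome association (null construction)
#'
#' Re-assigns treatment independently of outcomes and covariates, producing
#' data that satisfy the null hypothesis \eqn{\theta = 1} while preserving
#' the outcome and covariate marginals. The default redraws each
#' assignment as an independent Bernoulli with the original allocation
#' probability; `method = "permute"` instead permutes the existing labels
#' (preserving the realized group sizes).
#'
#' @param data trial data frame.
#' @param allocation assignment probability for `method = "redraw"`;
#'   defaults to the generator's allocation attribute, else 0.5.
#' @param method `"redraw"` (default) or `"permute"`.
#' @param seed optional integer seed.
#' @return the data frame with a new `arm` column.
#' @export
flip_treatment <- function(data, allocation = NULL,
                           method = c("redraw", "permute"), seed = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(data)
  if (is.null(allocation)) {
    allocation <- attr(data, "allocation")
    if (is.null(allocation)) allocation <- 0.5
  }
  data$arm <- if (method == "redraw") {
    rbinom(n, 1, allocation)
  } else {
    sample(data$arm)
  }
  data
}
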