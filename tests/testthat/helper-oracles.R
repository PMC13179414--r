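# Naive reference implementations used as independent oracles. Everything
# here is a literal transcription of the estimator definitions as double
# loops over subjects/pairs, with none of the package's algebraic or
# compiled shortcuts.

expit_ <- function(x) 1 / (1 + exp(-x))

# literal two-layer verdict (+1 = b wins), written against the formal rule
oracle_verdict <- function(a, b) {
  if (a$event_death == 1 && a$time_death < b$time_death) return(1)
  if (b$event_death == 1 && b$time_death < a$time_death) return(-1)
  tau <- min(a$time_death, b$time_death)
  a_has <- a$event_nonfatal == 1 && a$time_nonfatal < tau
  b_has <- b$event_nonfatal == 1 && b$time_nonfatal < tau
  if (a_has && !(b$event_nonfatal == 1 && b$time_nonfatal <= a$time_nonfatal))
    return(1)
  if (b_has && !(a$event_nonfatal == 1 && a$time_nonfatal <= b$time_nonfatal))
    return(-1)
  0
}

oracle_score_matrix <- function(data) {
  n <- nrow(data)
  S <- matrix(0.5, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- as.list(data[i, ])
      b <- as.list(data[j, ])
      S[i, j] <- (oracle_verdict(a, b) + 1) / 2
    }
  }
  S
}

oracle_win_stats <- function(S, arm) {
  wins <- ties <- losses <- 0
  n <- length(arm)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || arm[i] != 0 || arm[j] != 1) next
      if (S[i, j] == 1) wins <- wins + 1
      else if (S[i, j] == 0.5) ties <- ties + 1
      else losses <- losses + 1
    }
  }
  n0 <- sum(arm == 0); n1 <- sum(arm == 1)
  list(wins = wins, ties = ties, losses = losses,
       nu = (wins + 0.5 * ties) / (n0 * n1))
}

oracle_nu_stand <- function(tau_A, tau_X, X) {
  n <- nrow(X)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      acc <- acc + expit_(tau_A + sum(tau_X * (X[j, ] - X[i, ])))
    }
  }
  acc / (n * (n - 1))
}

oracle_nu_aug <- function(S, arm, tau_A, tau_X, X) {
  n <- length(arm)
  n0 <- sum(arm == 0); n1 <- sum(arm == 1)
  wins <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && arm[i] == 0 && arm[j] == 1) wins <- wins + S[i, j]
    }
  }
  nu_direct <- wins / (n0 * n1)
  acc <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      H <- expit_(tau_A + sum(tau_X * (X[j, ] - X[i, ])))
      w <- 1 / (n * (n - 1)) - (1 - arm[i]) * arm[j] / (n0 * n1)
      acc <- acc + w * H
    }
  }
  nu_direct + acc
}

# pseudo-observation logistic fit via glm: the same estimating equations,
# solved by an entirely different code path
glm_pim <- function(S, arm, X = NULL) {
  n <- length(arm)
  idx <- which(row(S) != col(S), arr.ind = TRUE)
  i <- idx[, 1]; j <- idx[, 2]
  df <- data.frame(y = S[idx], dA = arm[j] - arm[i])
  if (!is.null(X)) {
    dX <- X[j, , drop = FALSE] - X[i, , drop = FALSE]
    colnames(dX) <- paste0("d", seq_len(ncol(dX)))
    df <- cbind(df, dX)
  }
  fml <- stats::as.formula(paste("y ~ 0 +",
                                 paste(setdiff(names(df), "y"),
                                       collapse = " + ")))
  stats::coef(stats::glm(fml, family = stats::quasibinomial(), data = df))
}

random_trial <- function(n, seed, effect = 0.3, scenario = "A") {
  simulate_trial(n, scenario = scenario, treatment_effect = effect,
                 seed = seed)
}

# a tiny valid hand-built dataset
toy_records <- function() {
  data.frame(
    arm           = c(1, 0, 1, 0, 1, 0),
    time_death    = c(50, 100, 100, 80, 120, 90),
    event_death   = c(1, 0, 1, 0, 0, 1),
    time_nonfatal = c(50, 40, 30, 20, 120, 90),
    event_nonfatal = c(0, 1, 1, 1, 0, 0))
}
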