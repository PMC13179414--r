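#' Hierarchical death-then-nonfatal comparison of two composite outcomes
#'
#' Compares two censored composite outcomes with the two-layer rule used in
#' cardiovascular outcomes trials: deaths are compared first, and only if
#' neither death is decisive are first nonfatal events compared within the
#' shared follow-up window.
#'
#' Layer 1 (death): subject `b` wins if `a` died and `b` is known to be at
#' risk strictly beyond `a`'s death time (and symmetrically for `a`). A death
#' is therefore not decisive against a subject who left observation earlier,
#' and equal observed death times fall through to layer 2.
#'
#' Layer 2 (nonfatal): with shared window `tau = min(terminal_a, terminal_b)`
#' (both death and censoring truncate the window), `b` wins if `a` had a
#' nonfatal event strictly before `tau` and `b` did not have one at the same
#' time or earlier. Nonfatal events at identical times tie.
#'
#' @param a,b lists (or one-row data frames) with numeric fields
#'   `time_death`, `event_death` (0/1), `time_nonfatal`, `event_nonfatal`
#'   (0/1). `time_death` is time to death or censoring; `time_nonfatal` is
#'   time to the first nonfatal event, equal to `time_death` when none was
#'   observed.
#' @return integer verdict: `+1` if `b` wins, `-1` if `a` wins, `0` on a tie.
#' @examples
#' a <- list(time_death = 100, event_death = 1,
#'           time_nonfatal = 100, event_nonfatal = 0)
#' b <- list(time_death = 200, event_death = 0,
#'           time_nonfatal = 200, event_nonfatal = 0)
#' compare_hierarchical(a, b) # +1: b outlives a's death
#' @export
compare_hierarchical <- function(a, b) {
  check_outcome(a, "a")
  check_outcome(b, "b")
  # layer 1: deaths, decisive only beyond the other subject's follow-up
  if (a$event_death == 1 && a$time_death < b$time_death) return(1L)
  if (b$event_death == 1 && b$time_death < a$time_death) return(-1L)
  # layer 2: first nonfatal event within the shared follow-up window
  tau <- min(a$time_death, b$time_death)
  if (a$event_nonfatal == 1 && a$time_nonfatal < tau &&
      !(b$event_nonfatal == 1 && b$time_nonfatal <= a$time_nonfatal)) {
    return(1L)
  }
  if (b$event_nonfatal == 1 && b$time_nonfatal < tau &&
      !(a$event_nonfatal == 1 && a$time_nonfatal <= b$time_nonfatal)) {
    return(-1L)
  }
  0L
}

check_outcome <- function(x, label) {
  need <- c("time_death", "event_death", "time_nonfatal", "event_nonfatal")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("outcome '", label, "' is missing field(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!is.finite(x$time_death) || x$time_death <= 0 ||
      !is.finite(x$time_nonfatal) || x$time_nonfatal <= 0) {
    stop("outcome '", label, "' has non-positive or non-finite times",
         call. = FALSE)
  }
  if (x$time_nonfatal > x$time_death) {
    stop("outcome '", label, "': time_nonfatal exceeds time_death",
         call. = FALSE)
  }
  if (!x$event_death %in% c(0, 1) || !x$event_nonfatal %in% c(0, 1)) {
    stop("outcome '", label, "': event indicators must be 0 or 1",
         call. = FALSE)
  }
  invisible(x)
}

#' Win/loss/tie rules
#'
#' A rule is a deterministic function mapping an ordered pair of outcomes to
#' a verdict in `{-1, 0, +1}` (`+1` = second subject wins) and must satisfy
#' the antisymmetry contract `rule(a, b) == -rule(b, a)` and
#' `rule(a, a) == 0`. `hierarchical_rule()` is the built-in two-layer
#' death-then-nonfatal rule (evaluated in compiled code inside
#' [score_matrix()]); `comparison_rule()` wraps any user function with that
#' contract, e.g. rules with additional hierarchy layers.
#'
#' @param compare function of two outcome records returning -1, 0 or +1.
#' @param name label used in printing.
#' @return an object of class `"win_rule"`.
#' @examples
#' # pure survival comparison, ignoring nonfatal events
#' surv_rule <- comparison_rule(function(a, b) {
#'   if (a$event_death == 1 && a$time_death < b$time_death) return(1)
#'   if (b$event_death == 1 && b$time_death < a$time_death) return(-1)
#'   0
#' }, name = "survival-only")
#' @export
comparison_rule <- function(compare, name = "custom") {
  stopifnot(is.function(compare))
  structure(list(compare = compare, name = name, builtin = FALSE),
            class = "win_rule")
}

#' @rdname comparison_rule
#' @export
hierarchical_rule <- function() {
  structure(list(compare = compare_hierarchical,
                 name = "hierarchical (death, then first nonfatal event)",
                 builtin = TRUE),
            class = "win_rule")
}

#' @export
print.win_rule <- function(x, ...) {
  cat("win/loss/tie rule:", x$name,
      if (x$builtin) "[built-in, vectorized]" else "[user-supplied]", "\n")
  invisible(x)
}

#' Pairwise win/tie score matrix
#'
#' Evaluates a win/loss/tie rule on every unordered pair of subjects and
#' returns the n x n score matrix `S` with
#' `S[i, j] = I(Y_i < Y_j) + 0.5 * I(Y_i ~ Y_j)`, i.e. 1 when subject `j`
#' wins against subject `i`, 0 when `i` wins, and 0.5 on a tie.
#' Antisymmetry `S[i, j] + S[j, i] == 1` holds by construction (each
#' unordered pair is evaluated once); the diagonal is set to 0.5 and is
#' excluded from every estimator sum.
#'
#' @param data trial data frame with columns `time_death`, `event_death`,
#'   `time_nonfatal`, `event_nonfatal` (see [read_trial_csv()]).
#' @param rule a `"win_rule"`; default the built-in hierarchical rule.
#' @param check for user-supplied rules, also evaluate the reversed pair and
#'   error if the rule violates antisymmetry (doubles the rule evaluations).
#' @return numeric n x n matrix of pairwise scores.
#' @export
score_matrix <- function(data, rule = hierarchical_rule(), check = TRUE) {
  data <- validate_trial_data(data, require_arm = FALSE)
  n <- nrow(data)
  if (n < 2) stop("need at least 2 subjects", call. = FALSE)
  if (isTRUE(rule$builtin)) {
    return(cpp_score_matrix(data$time_death, as.integer(data$event_death),
                            data$time_nonfatal,
                            as.integer(data$event_nonfatal)))
  }
  recs <- lapply(seq_len(n), function(i) as.list(data[i, , drop = FALSE]))
  S <- matrix(0.5, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- rule$compare(recs[[i]], recs[[j]])
      if (!v %in% c(-1, 0, 1)) {
        stop("rule returned ", v, " for pair (", i, ", ", j,
             "); verdicts must be -1, 0 or +1", call. = FALSE)
      }
      if (check) {
        v_rev <- rule$compare(recs[[j]], recs[[i]])
        if (!isTRUE(all.equal(v_rev, -v))) {
          stop("rule violates antisymmetry on pair (", i, ", ", j, "): ",
               "rule(i, j) = ", v, " but rule(j, i) = ", v_rev,
               call. = FALSE)
        }
      }
      S[i, j] <- (v + 1) / 2
      S[j, i] <- 1 - S[i, j]
    }
  }
  if (check && rule$compare(recs[[1]], recs[[1]]) != 0) {
    stop("rule violates rule(a, a) == 0", call. = FALSE)
  }
  S
}
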