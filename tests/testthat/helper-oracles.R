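# Independent oracles used to check the package's closed forms and
# vectorized algorithms.  Deliberately brute-force and written along
# different code paths than the implementation.

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins.
oracle_fisher_2x2 <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- dhyper(xs, r1, n - r1, c1)
  p_obs <- dhyper(a, r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Unit-elasticity price found as the root of a numerically
# differentiated elasticity (central differences on log10 axes).
oracle_pmax <- function(q0, alpha, k, tol = 1e-13) {
  el <- function(lc) {
    h <- 1e-6
    (opdemand::predict_log_consumption(q0, alpha, k, 10^(lc + h)) -
     opdemand::predict_log_consumption(q0, alpha, k, 10^(lc - h))) / (2 * h)
  }
  # elasticity falls from 0 through -1 on the inelastic limb; bracket the
  # first crossing, before the slope's turning point at u = 1
  lc_turn <- log10(1 / (alpha * q0))
  10^uniroot(function(lc) el(lc) + 1, c(lc_turn - 12, lc_turn),
             tol = tol)$root
}

# Peak expenditure by golden-section search on the log10-price axis
# over a fixed wide bracket (independent of the closed form).
oracle_omax <- function(q0, alpha, k) {
  expend <- function(lc) {
    cc <- 10^lc
    cc * 10^opdemand::predict_log_consumption(q0, alpha, k, cc)
  }
  opt <- optimize(expend, interval = log10(1 / (alpha * q0)) + c(-12, 0),
                  maximum = TRUE, tol = 1e-11)
  opt$objective
}

# Brute-force window-by-window acquisition classification with explicit
# loops (the implementation uses cumulative sums).
oracle_classify <- function(sessions, bounds) {
  s <- sessions[order(sessions$session_index), ]
  S <- nrow(s)
  status <- character(0)
  for (e in 3:S) {
    w <- (e - 2):e
    a <- mean(s$active_responses[w])
    i <- mean(s$inactive_responses[w])
    f <- mean(s$infusions[w])
    b <- bounds[as.character(e)]
    status[as.character(e)] <-
      if (is.na(b)) "not_evaluable"
      else if (a >= 2 * i && a > 0 && f > b) "met"
      else "not_met"
  }
  status
}

# Brute-force demand-phase re-check over every 3-session window.
oracle_recheck <- function(active, inactive) {
  n <- length(active)
  if (n < 3) return(NA)
  for (st in 1:(n - 2)) {
    a <- mean(active[st:(st + 2)])
    i <- mean(inactive[st:(st + 2)])
    if (a >= 2 * i && a > 0) return(TRUE)
  }
  FALSE
}

# Noise-free demand series straight from the model equation.
make_exact_series <- function(q0, alpha, k, prices, ...) {
  opdemand::demand_series(
    prices, 10^opdemand::predict_log_consumption(q0, alpha, k, prices), ...)
}

# Random acquisition-phase session table for one subject.
random_subject_sessions <- function(n_sessions = 14, id = "s1") {
  data.frame(subject_id = id, strain = "Wistar", sex = "male",
             unit_dose_ug_kg = 30,
             phase = rep(c("FR1_acq", "FR2_acq"),
                         c(7, n_sessions - 7))[1:n_sessions],
             session_index = seq_len(n_sessions),
             fr_value = rep(c(1L, 2L), c(7, n_sessions - 7))[1:n_sessions],
             active_responses = rpois(n_sessions, 25),
             inactive_responses = rpois(n_sessions, 12),
             infusions = rpois(n_sessions, 15),
             stringsAsFactors = FALSE)
}
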