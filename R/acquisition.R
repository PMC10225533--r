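# Two-part acquisition criterion, evaluated over sliding 3-session
# windows starting at session 3: (1) mean active >= 2 x mean inactive
# lever responding, and (2) mean infusions strictly above the upper
# bound of the saline controls' 95% CI over the same window.

.window <- 3L

# trailing window means; x[s] is session s, result[s] = mean over
# sessions (s-2):s, NA for s < 3
.roll_mean <- function(x, w = .window) {
  n <- length(x)
  if (n < w) return(rep(NA_real_, n))
  cs <- cumsum(c(0, x))
  out <- rep(NA_real_, n)
  out[w:n] <- (cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w
  out
}

#' Saline-control confidence bound for a session window
#'
#' 95% t-interval on the mean of per-subject mean infusions across a
#' 3-session window of saline controls:
#' `mean +/- t(0.975, n-1) * sd/sqrt(n)`.  Nicotine subjects acquire
#' only when their own window mean lies strictly above `ci_upper`.
#'
#' @param saline_means Per-subject mean infusions over the window (one
#'   value per saline control; at least 2).
#' @param window Optional `(first, last)` session pair, recorded for
#'   bookkeeping.
#' @param conf Confidence level (default 0.95).
#' @return Object of class `"saline_reference"`: list with
#'   `n_subjects`, `mean_infusions`, `ci_lower`, `ci_upper`, `window`.
#' @examples
#' saline_reference(c(10, 14, 12))$ci_upper  # about 16.97
#' @export
saline_reference <- function(saline_means, window = NULL, conf = 0.95) {
  n <- length(saline_means)
  if (n < 2)
    stop("saline reference needs at least 2 control subjects ",
         "(CI undefined for n < 2)")
  m <- mean(saline_means)
  sem <- stats::sd(saline_means) / sqrt(n)
  tcrit <- stats::qt(1 - (1 - conf) / 2, df = n - 1)
  structure(list(window = window, n_subjects = n, mean_infusions = m,
                 ci_lower = m - tcrit * sem, ci_upper = m + tcrit * sem),
            class = "saline_reference")
}

#' @export
print.saline_reference <- function(x, digits = 4, ...) {
  cat("Saline reference",
      if (!is.null(x$window)) sprintf("(sessions %s-%s)",
                                      x$window[1], x$window[2]), "\n")
  cat(sprintf("  n = %d, mean = %s, 95%% CI [%s, %s]\n", x$n_subjects,
              format(x$mean_infusions, digits = digits),
              format(x$ci_lower, digits = digits),
              format(x$ci_upper, digits = digits)))
  invisible(x)
}

#' Lever discrimination criterion (2:1 active:inactive)
#'
#' Division-free form: met iff mean active responding is at least twice
#' mean inactive responding *and* there is some active responding.  The
#' 2:1 boundary is inclusive; zero responding on both levers is not
#' discrimination.
#'
#' @param active_window_mean,inactive_window_mean Non-negative window
#'   means of lever responses.  Vectorized.
#' @return Logical.
#' @export
lever_discrimination_met <- function(active_window_mean,
                                     inactive_window_mean) {
  stopifnot(all(active_window_mean >= 0, na.rm = TRUE),
            all(inactive_window_mean >= 0, na.rm = TRUE))
  active_window_mean >= 2 * inactive_window_mean & active_window_mean > 0
}

#' Classify acquisition for one subject
#'
#' Evaluates both acquisition criteria at every session from 3 on, over
#' the trailing 3-session window (windows may span the FR 1 to FR 2
#' transition since the acquisition phase is analyzed as one sequence).
#' Status is `"met"` when the 2:1 lever discrimination holds and window
#' mean infusions strictly exceed the saline bound, `"not_evaluable"`
#' when the saline bound is missing for that window, else `"not_met"`.
#'
#' @param subject_sessions One subject's acquisition-phase session
#'   records, sessions 1..S contiguous, S >= 3.
#' @param saline_ci_upper Saline `ci_upper` per window: either a single
#'   number applied to every window or a numeric vector named by window
#'   end session (`"3"`, `"4"`, ...); `NA` for unavailable windows.
#' @return Object of class `"acquisition_result"`: list with
#'   `subject_id`, `per_session_status` (named character vector, sessions
#'   3..S), `first_session_met` (or `NA`), `acquired_in_demand`
#'   (initialized `NA`; see [demand_phase_recheck()]).
#' @export
classify_acquisition <- function(subject_sessions, saline_ci_upper) {
  s <- subject_sessions[order(subject_sessions$session_index), , drop = FALSE]
  idx <- s$session_index
  S <- max(idx)
  if (!identical(as.integer(idx), seq_len(S)))
    stop("session indices must be contiguous 1..S (subject ",
         s$subject_id[1], ")")
  if (S < .window) stop("need at least 3 sessions to classify")

  act <- .roll_mean(s$active_responses)
  inact <- .roll_mean(s$inactive_responses)
  inf <- .roll_mean(s$infusions)
  ends <- .window:S

  bound <- if (length(saline_ci_upper) == 1 && is.null(names(saline_ci_upper)))
    rep(saline_ci_upper, length(ends))
  else as.numeric(saline_ci_upper[as.character(ends)])

  disc <- lever_discrimination_met(act[ends], inact[ends])
  status <- ifelse(is.na(bound), "not_evaluable",
                   ifelse(disc & inf[ends] > bound, "met", "not_met"))
  names(status) <- as.character(ends)
  first <- if (any(status == "met")) ends[which(status == "met")[1]]
           else NA_integer_
  structure(list(subject_id = as.character(s$subject_id[1]),
                 per_session_status = status,
                 first_session_met = first,
                 acquired_in_demand = NA),
            class = "acquisition_result")
}

#' @export
print.acquisition_result <- function(x, ...) {
  cat("Acquisition result for subject", x$subject_id, "\n")
  cat("  first session met:",
      if (is.na(x$first_session_met)) "never" else x$first_session_met, "\n")
  met <- names(x$per_session_status)[x$per_session_status == "met"]
  cat("  sessions met:", if (length(met)) paste(met, collapse = " ")
      else "none", "\n")
  invisible(x)
}

#' Demand-phase lever-discrimination re-check
#'
#' A subject that never met the full acquisition criterion can still
#' count as acquired if the 2:1 active:inactive criterion is met over
#' any 3 consecutive demand-phase sessions (intake is already evidenced
#' by earning infusions at escalating prices, so the saline bound is not
#' re-applied here).
#'
#' @param demand_sessions One subject's demand-phase session records in
#'   session order.
#' @return `TRUE`/`FALSE`, or `NA` when fewer than 3 demand sessions are
#'   available (not evaluable).
#' @export
demand_phase_recheck <- function(demand_sessions) {
  n <- nrow(demand_sessions)
  if (n < .window) return(NA)
  act <- .roll_mean(demand_sessions$active_responses)
  inact <- .roll_mean(demand_sessions$inactive_responses)
  ok <- lever_discrimination_met(act, inact)
  any(ok, na.rm = TRUE)
}

#' Classify acquisition across a cohort
#'
#' Builds window-wise saline references (per strain by default, both
#' strains having saline controls; pooled on request) and classifies
#' every nicotine-dose subject, applying the demand-phase re-check where
#' demand sessions exist.
#'
#' @param sessions Validated session table for the whole cohort.
#' @param saline_scope `"strain"` (match saline controls by strain) or
#'   `"pooled"`.
#' @return Data frame of class `"acquisition_table"`: one row per
#'   nicotine subject with `subject_id, strain, sex, unit_dose_ug_kg,
#'   first_session_met, acquired_criteria, acquired_in_demand, acquired`
#'   and per-session status columns `s3 ... sS`.
#' @export
classify_cohort <- function(sessions, saline_scope = c("strain", "pooled")) {
  saline_scope <- match.arg(saline_scope)
  validate_sessions(sessions)
  acq <- sessions[sessions$phase %in% c("FR1_acq", "FR2_acq"), , drop = FALSE]
  dem <- sessions[sessions$phase == "demand", , drop = FALSE]
  if (nrow(acq) == 0) stop("no acquisition-phase sessions in table")
  S <- max(acq$session_index)
  ends <- .window:S

  saline_bounds <- function(rows) {
    ids <- unique(rows$subject_id)
    if (length(ids) < 2) return(stats::setNames(rep(NA_real_, length(ends)),
                                                as.character(ends)))
    vapply(stats::setNames(ends, as.character(ends)), function(e) {
      win <- (e - .window + 1):e
      means <- vapply(ids, function(id) {
        x <- rows$infusions[rows$subject_id == id & rows$session_index %in% win]
        if (length(x) < .window) NA_real_ else mean(x)
      }, numeric(1))
      means <- means[!is.na(means)]
      if (length(means) < 2) NA_real_
      else saline_reference(means, window = range(win))$ci_upper
    }, numeric(1))
  }
  sal <- acq[acq$unit_dose_ug_kg == 0, , drop = FALSE]
  bounds <- if (saline_scope == "pooled")
    list(pooled = saline_bounds(sal))
  else lapply(split(sal, sal$strain), saline_bounds)

  nic <- acq[acq$unit_dose_ug_kg > 0, , drop = FALSE]
  ids <- unique(nic$subject_id)
  if (length(ids) == 0) stop("no nicotine-dose subjects to classify")
  rows <- lapply(ids, function(id) {
    ss <- nic[nic$subject_id == id, , drop = FALSE]
    b <- if (saline_scope == "pooled") bounds[["pooled"]]
         else bounds[[ss$strain[1]]]
    if (is.null(b)) b <- stats::setNames(rep(NA_real_, length(ends)),
                                         as.character(ends))
    res <- classify_acquisition(ss, b)
    ds <- dem[dem$subject_id == id, , drop = FALSE]
    recheck <- if (nrow(ds) > 0) demand_phase_recheck(ds) else NA
    met_crit <- !is.na(res$first_session_met)
    status <- as.list(res$per_session_status)
    names(status) <- paste0("s", names(status))
    cbind(data.frame(subject_id = id, strain = ss$strain[1],
                     sex = ss$sex[1],
                     unit_dose_ug_kg = ss$unit_dose_ug_kg[1],
                     first_session_met = res$first_session_met,
                     acquired_criteria = met_crit,
                     acquired_in_demand = recheck,
                     acquired = met_crit | isTRUE(recheck),
                     stringsAsFactors = FALSE),
          as.data.frame(status, stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("acquisition_table", "data.frame")
  out
}

#' Per-session acquisition proportions
#'
#' Proportion of subjects per group meeting the acquisition criterion at
#' each session.  The default cumulative convention counts a subject as
#' met at every session from its first met window onward (monotone
#' non-decreasing curves); `cumulative = FALSE` uses the raw per-window
#' status instead.
#'
#' @param results An `"acquisition_table"` from [classify_cohort()].
#' @param by Grouping column (default `"strain"`).
#' @param cumulative Use the cumulative convention (default `TRUE`).
#' @return Data frame with `group, session, n, n_met, proportion`.
#' @export
acquisition_proportions <- function(results, by = "strain",
                                    cumulative = TRUE) {
  stopifnot(by %in% names(results))
  scols <- grep("^s[0-9]+$", names(results), value = TRUE)
  sess <- as.integer(sub("^s", "", scols))
  groups <- split(results, results[[by]])
  out <- do.call(rbind, lapply(names(groups), function(g) {
    r <- groups[[g]]
    if (nrow(r) == 0) stop("empty group: ", g)
    n_met <- vapply(seq_along(scols), function(i) {
      if (cumulative)
        sum(!is.na(r$first_session_met) & r$first_session_met <= sess[i])
      else sum(r[[scols[i]]] == "met", na.rm = TRUE)
    }, numeric(1))
    data.frame(group = g, session = sess, n = nrow(r), n_met = n_met,
               proportion = n_met / nrow(r))
  }))
  rownames(out) <- NULL
  out
}

#' Fisher's exact test for a 2x2 table
#'
#' Exact conditional two-sided p-value (sum of hypergeometric table
#' probabilities no larger than that of the observed table) for a
#' group-by-outcome table such as strain x acquired.
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise:
#'   `rbind(c(a, b), c(c, d))`.
#' @return Two-sided p-value.
#' @seealso [bonferroni_significant()] for the corrected threshold used
#'   when testing the final session of each FR phase.
#' @examples
#' fisher_exact_2x2(5, 0, 0, 5)  # 2/252
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("cell counts must be non-negative integers")
  if (sum(counts) == 0) stop("at least one margin must be nonzero")
  stats::fisher.test(matrix(counts, nrow = 2, byrow = TRUE))$p.value
}

#' Bonferroni-corrected significance decision
#'
#' Significance at `alpha / n_tests`; with the default two tests (one
#' per FR phase of acquisition) the threshold is 0.025.
#'
#' @param p P-value(s).
#' @param n_tests Number of tests corrected across (default 2).
#' @param alpha Family-wise level (default 0.05).
#' @return Logical.
#' @export
bonferroni_significant <- function(p, n_tests = 2, alpha = 0.05) {
  p < alpha / n_tests
}
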