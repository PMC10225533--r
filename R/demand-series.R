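#' Construct a demand series
#'
#' A demand series is one subject's consumption at each unit price of an
#' FR-escalation phase, ordered by ascending price.  A terminal session
#' with zero infusions is retained with consumption replaced by 0.01
#' mg/kg (zero is undefined on the log scale; 0.01 is one log-unit below
#' a single infusion at a 0.03 mg/kg unit dose) and flagged via
#' `replaced_zero`.
#'
#' @param price Strictly increasing unit prices (FR per mg/kg).
#' @param consumption Non-negative consumption (mg/kg) per price.
#' @param replaced_zero Logical flags; `TRUE` only allowed for the last
#'   observation, whose consumption must then be 0.01.
#' @param subject_id Optional subject identifier.
#' @param unit_dose_mg_kg Optional unit dose used to build the series.
#' @return A `demand_series`: a data frame with columns `price`,
#'   `consumption`, `replaced_zero` and attributes `subject_id`,
#'   `unit_dose_mg_kg`.
#' @seealso [prepare_demand_series()] to build one from session records.
#' @export
demand_series <- function(price, consumption,
                          replaced_zero = rep(FALSE, length(price)),
                          subject_id = NA_character_,
                          unit_dose_mg_kg = NA_real_) {
  n <- length(price)
  stopifnot(length(consumption) == n, length(replaced_zero) == n)
  if (n > 0) {
    if (any(price <= 0)) stop("unit prices must be positive")
    if (any(diff(price) <= 0)) stop("unit prices must be strictly increasing")
    if (any(consumption < 0)) stop("consumption must be non-negative")
    if (sum(replaced_zero) > 1)
      stop("at most one replaced-zero observation is allowed")
    if (any(replaced_zero) && which(replaced_zero) != n)
      stop("a replaced-zero observation must be the last one")
    if (any(replaced_zero) && consumption[n] != 0.01)
      stop("a replaced-zero observation must have consumption 0.01 mg/kg")
    if (any(consumption[seq_len(n - 1)] == 0))
      stop("interior zero consumption violates the stopping rule")
  }
  out <- data.frame(price = as.numeric(price),
                    consumption = as.numeric(consumption),
                    replaced_zero = as.logical(replaced_zero))
  attr(out, "subject_id") <- subject_id
  attr(out, "unit_dose_mg_kg") <- unit_dose_mg_kg
  class(out) <- c("demand_series", "data.frame")
  out
}

#' Build a demand series from demand-phase session records
#'
#' Converts one subject's demand-phase sessions (escalating FR) into
#' (unit price, consumption) pairs.  The terminal zero-infusion session,
#' if present, becomes a 0.01 mg/kg observation flagged `replaced_zero`;
#' that point participates in individual curve fitting (it completes the
#' demand function), unlike the group-curve zero padding which is
#' illustration-only.
#'
#' @param demand_sessions Data frame of session records (one subject,
#'   `phase == "demand"`) with columns `fr_value` and `infusions`,
#'   ordered by escalating FR.
#' @param unit_dose_mg_kg Positive unit dose in mg/kg.
#' @return A [demand_series()].
#' @examples
#' s <- data.frame(fr_value = c(3, 6, 9), infusions = c(40, 25, 0))
#' prepare_demand_series(s, 0.03)
#' @export
prepare_demand_series <- function(demand_sessions, unit_dose_mg_kg) {
  stopifnot(is.data.frame(demand_sessions),
            all(c("fr_value", "infusions") %in% names(demand_sessions)))
  if (unit_dose_mg_kg <= 0) stop("'unit_dose_mg_kg' must be positive")
  fr <- demand_sessions$fr_value
  inf <- demand_sessions$infusions
  n <- length(fr)
  if (n == 0) stop("no demand-phase sessions supplied")
  if (any(diff(fr) <= 0)) stop("FR values must escalate strictly")
  zero <- inf == 0
  if (any(zero[seq_len(n - 1)])) {
    bad <- which(zero[seq_len(n - 1)])[1]
    stop(sprintf(
      "zero infusions at interior FR %s: demand phases stop at the first zero",
      fr[bad]))
  }
  q <- consumption_mg_kg(inf, unit_dose_mg_kg)
  replaced <- rep(FALSE, n)
  if (zero[n]) {
    q[n] <- 0.01
    replaced[n] <- TRUE
  }
  sid <- if ("subject_id" %in% names(demand_sessions))
    as.character(demand_sessions$subject_id[1]) else NA_character_
  demand_series(unit_price(fr, unit_dose_mg_kg), q, replaced,
                subject_id = sid, unit_dose_mg_kg = unit_dose_mg_kg)
}
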