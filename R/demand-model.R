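#' Unit price of a drug reinforcer
#'
#' Behavioral-economic unit price: the response requirement (fixed-ratio
#' value) divided by the unit dose, i.e. responses per mg/kg of drug.
#'
#' @param fr_value Positive fixed-ratio requirement (responses per infusion).
#' @param unit_dose_mg_kg Positive unit dose in mg/kg per infusion.
#' @return Numeric unit price in FR per mg/kg.
#' @examples
#' unit_price(3, 0.03)   # 100 responses per mg/kg
#' @export
unit_price <- function(fr_value, unit_dose_mg_kg) {
  if (any(!is.finite(unit_dose_mg_kg)) || any(unit_dose_mg_kg <= 0))
    stop("'unit_dose_mg_kg' must be positive")
  if (any(!is.finite(fr_value)) || any(fr_value <= 0))
    stop("'fr_value' must be positive")
  fr_value / unit_dose_mg_kg
}

#' Drug consumption in mg/kg
#'
#' Session consumption is the number of infusions earned times the unit
#' dose; infusions (not reinforced-response counts) are the canonical
#' intake measure.
#'
#' @param infusions Non-negative infusion count.
#' @param unit_dose_mg_kg Positive unit dose in mg/kg per infusion.
#' @return Consumption in mg/kg per session.
#' @examples
#' consumption_mg_kg(10, 0.03)  # 0.3 mg/kg
#' @export
consumption_mg_kg <- function(infusions, unit_dose_mg_kg) {
  if (any(unit_dose_mg_kg <= 0)) stop("'unit_dose_mg_kg' must be positive")
  if (any(infusions < 0)) stop("'infusions' must be non-negative")
  infusions * unit_dose_mg_kg
}

#' Exponential demand prediction on the log10 scale
#'
#' The exponential demand equation of Hursh and Silberberg:
#' \deqn{\log_{10} Q = \log_{10} Q_0 + k\,(e^{-\alpha Q_0 C} - 1)}
#' where `C` is unit price, `Q0` is demand intensity (consumption at zero
#' price), `alpha` is demand elasticity and `k` fixes the log10 range of
#' the function (consumption spans `Q0` down to `Q0 * 10^-k`).
#'
#' @param q0 Demand intensity, mg/kg (> 0).
#' @param alpha Demand elasticity (> 0).
#' @param k Range constant in log10 units (> 0).
#' @param price Unit price(s), FR per mg/kg (>= 0).
#' @return `log10` predicted consumption, same length as `price`.
#' @examples
#' predict_log_consumption(1.85, 0.000362, 2.218, c(0, 100, 1000))
#' @export
predict_log_consumption <- function(q0, alpha, k, price) {
  stopifnot(q0 > 0, alpha > 0, k > 0, all(price >= 0))
  log10(q0) + k * (exp(-alpha * q0 * price) - 1)
}

#' Point elasticity of the exponential demand curve
#'
#' Slope of log10 consumption against log10 price,
#' `d log10(Q) / d log10(C) = -k ln(10) * alpha * Q0 * C * exp(-alpha*Q0*C)`.
#' Demand is inelastic (slope > -1) at low prices and elastic beyond Pmax.
#'
#' @inheritParams predict_log_consumption
#' @return Elasticity at `price` (non-positive).
#' @export
demand_elasticity <- function(q0, alpha, k, price) {
  stopifnot(q0 > 0, alpha > 0, k > 0, all(price >= 0))
  u <- alpha * q0 * price
  -k * log(10) * u * exp(-u)
}

# Principal-branch Lambert W on (-1/e, 0]; Halley iteration.
# Only this range is needed: the unit-elasticity condition gives
# u = -W0(-1/(k ln 10)).
lambert_w0 <- function(x) {
  stopifnot(all(x > -exp(-1)), all(x <= 0))
  w <- x * (1 - x)            # series start, adequate on (-1/e, 0]
  for (i in 1:50) {
    ew <- exp(w)
    f <- w * ew - x
    step <- f / (ew * (w + 1) - (w + 2) * f / (2 * w + 2))
    w <- w - step
    if (all(abs(step) <= 1e-15 * pmax(abs(w), 1e-300))) break
  }
  w
}

# u* = alpha*Q0*Pmax solving u e^{-u} = 1/(k ln 10); smaller root,
# the first crossing of elasticity = -1. Requires k > e/ln(10).
.unit_elasticity_u <- function(k) {
  if (any(k <= exp(1) / log(10)))
    stop("no unit-elasticity point: 'k' must exceed e/ln(10) (~1.181)")
  -lambert_w0(-1 / (k * log(10)))
}

#' Exact Pmax: unit price of unit elasticity
#'
#' The unit price at which the exponential demand curve has point
#' elasticity -1 (the transition from inelastic to elastic demand, and
#' the price of peak expenditure).  Solves
#' `u e^{-u} = 1/(k ln 10)` for `u = alpha*Q0*Pmax` via the principal
#' Lambert-W branch, so `Pmax = u*/(alpha*Q0)`.
#'
#' @inheritParams predict_log_consumption
#' @return Unit price (FR per mg/kg).  Vectorized over `q0`/`alpha`.
#' @seealso [pmax_approx()] for the legacy spreadsheet approximation,
#'   [omax()] for peak responding.
#' @examples
#' pmax_exact(1.45, 0.000161, 2.218)  # about 1079
#' @export
pmax_exact <- function(q0, alpha, k) {
  stopifnot(all(q0 > 0), all(alpha > 0), all(k > 0))
  .unit_elasticity_u(k) / (alpha * q0)
}

#' Approximate Pmax (legacy spreadsheet formula)
#'
#' Analytic approximation used by the widely circulated Excel demand-curve
#' template: `Pmax = (0.084 k + 0.65) / (Q0 alpha k^1.5)`.  Provided for
#' cross-reference with published tables; [pmax_exact()] is canonical.
#'
#' @inheritParams predict_log_consumption
#' @return Unit price (FR per mg/kg).
#' @export
pmax_approx <- function(q0, alpha, k) {
  stopifnot(all(q0 > 0), all(alpha > 0), all(k > 0))
  (0.084 * k + 0.65) / (q0 * alpha * k^1.5)
}

#' Omax: maximum output (peak responding)
#'
#' Maximum expenditure `C * Q(C)` over unit price under the exponential
#' demand equation, i.e. peak responses per session, attained at
#' [pmax_exact()].  In closed form
#' `Omax = (u*/alpha) * 10^(k (e^{-u*} - 1))` with `u*` the
#' unit-elasticity root, so `Omax * alpha` is constant at fixed `k`.
#'
#' @inheritParams predict_log_consumption
#' @return Responses per session.  Vectorized over `q0`/`alpha`.
#' @examples
#' omax(1.32, 0.001, 2.218)   # about 80.8 responses
#' @export
omax <- function(q0, alpha, k) {
  stopifnot(all(q0 > 0), all(alpha > 0), all(k > 0))
  u <- .unit_elasticity_u(k)
  (u / alpha) * 10^(k * (exp(-u) - 1))
}
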