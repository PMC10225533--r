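# Nonlinear least squares for the exponential demand equation, in
# log10-consumption space.  Parameterized internally as
# p = (log10 Q0, log alpha) so both free parameters are unconstrained in
# scale and alpha stays positive.

.demand_sse <- function(par, price, y, k) {
  q0 <- 10^par[1]
  a <- exp(par[2])
  r <- par[1] + k * (exp(-a * q0 * price) - 1) - y
  sum(r * r)
}

.demand_sse_grad <- function(par, price, y, k) {
  q0 <- 10^par[1]
  a <- exp(par[2])
  u <- a * q0 * price
  E <- exp(-u)
  r <- par[1] + k * (E - 1) - y
  2 * c(sum(r * (1 - k * E * u * log(10))),
        sum(r * (-k * E * u)))
}

#' Fit the exponential demand equation to one subject
#'
#' Least-squares fit of `log10 Q = log10 Q0 + k (e^{-alpha Q0 C} - 1)` to
#' a subject's consumption-by-price series, with `k` held fixed.  The
#' loss is squared error on log10 consumption, the scale on which the
#' model is stated and on which the terminal zero is replaced by 0.01.
#' The optimizer is multi-start (Q0 started at maximal observed
#' consumption, alpha on a log grid from 1e-5 to 1e-2) because the
#' likelihood surface has local minima in alpha; L-BFGS-B with an
#' analytic gradient polishes each start.
#'
#' @param series A [demand_series()], or a data frame with columns
#'   `price` and `consumption` (positive; replaced zeros included).
#' @param k Fixed range constant (log10 units).  Use 2.218 to replicate
#'   the published two-strain adolescent nicotine analysis, or estimate
#'   a shared value with [fit_shared_k()].
#' @param alpha_bounds Search bounds for alpha (defaults `1e-8`–`1`).  A
#'   solution at the lower bound (flat, near-constant consumption) is
#'   flagged `boundary = TRUE` and should be treated as low-confidence.
#' @param alpha_starts Multi-start grid for alpha.
#' @return An object of class `"demand_fit"` with components
#'   `coefficients` (named `q0`, `alpha`), `k`, `data`, `fitted.values`
#'   (log10 scale), `residuals`, `sse`, `r2`, `n`, `derived` (named
#'   `pmax_exact`, `pmax_approx`, `omax`), and `boundary`.
#' @examples
#' pr <- c(100, 200, 300, 500, 1000, 2000)
#' q  <- 10^predict_log_consumption(1.85, 0.000362, 2.218, pr)
#' fit <- fit_demand(demand_series(pr, q), k = 2.218)
#' coef(fit)
#' summary(fit)
#' @export
fit_demand <- function(series, k,
                       alpha_bounds = c(1e-8, 1),
                       alpha_starts = 10^seq(-5, -2, by = 0.5)) {
  stopifnot(is.data.frame(series),
            all(c("price", "consumption") %in% names(series)),
            length(k) == 1, k > 0,
            length(alpha_bounds) == 2, all(alpha_bounds > 0))
  price <- series$price
  q <- series$consumption
  keep <- q > 0
  if (sum(keep) < 3)
    stop("need at least 3 observations with positive consumption")
  price <- price[keep]
  q <- q[keep]
  y <- log10(q)

  lq0_start <- log10(max(q))
  lower <- c(lq0_start - 2, log(alpha_bounds[1]))
  upper <- c(lq0_start + 2, log(alpha_bounds[2]))
  starts <- lapply(alpha_starts,
                   function(a) c(lq0_start, min(max(log(a), lower[2]), upper[2])))

  best <- NULL
  for (st in starts) {
    opt <- try(stats::optim(st, .demand_sse, gr = .demand_sse_grad,
                            price = price, y = y, k = k,
                            method = "L-BFGS-B", lower = lower, upper = upper,
                            control = list(factr = 1e2, pgtol = 1e-14,
                                           maxit = 500)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best))
    stop("demand fit failed to converge from every start; ",
         "check the series for degenerate values")
  # polish once more from the winner
  opt <- stats::optim(best$par, .demand_sse, gr = .demand_sse_grad,
                      price = price, y = y, k = k,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(factr = 1e1, pgtol = 1e-15, maxit = 1000))
  if (opt$value > best$value) opt <- best

  q0 <- 10^opt$par[1]
  alpha <- exp(opt$par[2])
  boundary <- (opt$par[2] - lower[2]) < 1e-6 || (upper[2] - opt$par[2]) < 1e-6
  pred <- predict_log_consumption(q0, alpha, k, price)
  resid <- y - pred
  sse <- sum(resid^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_

  structure(list(
    coefficients = c(q0 = q0, alpha = alpha),
    k = k,
    data = data.frame(price = price, consumption = q),
    fitted.values = pred,
    residuals = resid,
    sse = sse,
    sst = sst,
    r2 = r2,
    n = length(price),
    derived = c(pmax_exact = pmax_exact(q0, alpha, k),
                pmax_approx = pmax_approx(q0, alpha, k),
                omax = omax(q0, alpha, k)),
    boundary = boundary,
    subject_id = attr(series, "subject_id"),
    call = match.call()
  ), class = "demand_fit")
}

#' @export
print.demand_fit <- function(x, digits = 4, ...) {
  cat("Exponential demand fit (k =", format(x$k, digits = digits), "fixed)\n")
  if (!is.null(x$subject_id) && !is.na(x$subject_id))
    cat("Subject:", x$subject_id, "\n")
  cat("  Q0    =", format(x$coefficients[["q0"]], digits = digits), "mg/kg\n")
  cat("  alpha =", format(x$coefficients[["alpha"]], digits = digits), "\n")
  cat("  r2    =", format(x$r2, digits = digits),
      " (n =", x$n, "price points)\n")
  if (isTRUE(x$boundary))
    cat("  NOTE: alpha at search bound; low-confidence fit\n")
  invisible(x)
}

#' @export
summary.demand_fit <- function(object, ...) {
  out <- list(
    coefficients = object$coefficients,
    k = object$k,
    derived = object$derived,
    r2 = object$r2,
    sigma = sqrt(object$sse / max(object$n - 2, 1)),
    n = object$n,
    boundary = object$boundary,
    subject_id = object$subject_id
  )
  class(out) <- "summary.demand_fit"
  out
}

#' @export
print.summary.demand_fit <- function(x, digits = 4, ...) {
  cat("Exponential demand fit summary\n")
  if (!is.null(x$subject_id) && !is.na(x$subject_id))
    cat("Subject:", x$subject_id, "\n")
  tab <- c(x$coefficients, k = x$k, x$derived,
           r2 = x$r2, sigma_log10 = x$sigma)
  print(signif(tab, digits))
  cat("n =", x$n, "price points\n")
  if (isTRUE(x$boundary)) cat("alpha at search bound (low confidence)\n")
  invisible(x)
}

#' @export
coef.demand_fit <- function(object, ...) object$coefficients

#' @export
fitted.demand_fit <- function(object, ...) object$fitted.values

#' Residuals of a demand fit
#'
#' @param object A `demand_fit`.
#' @param type `"log10"` (default; the fitting scale) or `"response"`
#'   (mg/kg).
#' @param ... Unused.
#' @export
residuals.demand_fit <- function(object, type = c("log10", "response"), ...) {
  type <- match.arg(type)
  if (type == "log10") object$residuals
  else object$data$consumption - 10^object$fitted.values
}

#' Predict consumption or expenditure from a demand fit
#'
#' @param object A `demand_fit`.
#' @param newdata Optional data frame with a `price` column; defaults to
#'   the fitted prices.
#' @param type `"log10q"` (log10 mg/kg), `"consumption"` (mg/kg) or
#'   `"expenditure"` (responses per session, `price * Q`).
#' @param ... Unused.
#' @export
predict.demand_fit <- function(object, newdata = NULL,
                               type = c("log10q", "consumption",
                                        "expenditure"), ...) {
  type <- match.arg(type)
  price <- if (is.null(newdata)) object$data$price else newdata$price
  lq <- predict_log_consumption(object$coefficients[["q0"]],
                                object$coefficients[["alpha"]],
                                object$k, price)
  switch(type,
         log10q = lq,
         consumption = 10^lq,
         expenditure = price * 10^lq)
}

#' Simulate consumption series from a fitted demand curve
#'
#' Draws replicate consumption series at the fitted prices with
#' multiplicative lognormal noise whose log10-scale standard deviation is
#' the fit's residual standard deviation.
#'
#' @param object A `demand_fit`.
#' @param nsim Number of replicate series.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return Data frame with columns `sim`, `price`, `consumption`.
#' @export
simulate.demand_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  price <- object$data$price
  mu <- object$fitted.values
  sigma <- sqrt(object$sse / max(object$n - 2, 1))
  do.call(rbind, lapply(seq_len(nsim), function(i) {
    data.frame(sim = i, price = price,
               consumption = 10^(mu + stats::rnorm(length(mu), 0, sigma)))
  }))
}

#' Plot a demand fit
#'
#' Log-log plot of consumption against unit price with the fitted curve
#' and the unit-elasticity price (Pmax) marked.
#'
#' @param x A `demand_fit`.
#' @param n_grid Curve resolution.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.demand_fit <- function(x, n_grid = 200, ...) {
  d <- x$data
  grid <- 10^seq(log10(min(d$price)), log10(max(d$price)), length.out = n_grid)
  curve_q <- 10^predict_log_consumption(x$coefficients[["q0"]],
                                        x$coefficients[["alpha"]],
                                        x$k, grid)
  graphics::plot(d$price, d$consumption, log = "xy",
                 xlab = "Unit price (FR per mg/kg)",
                 ylab = "Consumption (mg/kg)",
                 main = if (!is.null(x$subject_id) && !is.na(x$subject_id))
                   paste("Demand curve:", x$subject_id)
                 else "Demand curve", ...)
  graphics::lines(grid, curve_q)
  graphics::abline(v = x$derived[["pmax_exact"]], lty = 3)
  invisible(x)
}
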