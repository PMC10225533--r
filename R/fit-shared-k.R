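#' Fit a shared range constant k across subjects
#'
#' Joint least squares in which a single `k` is common to every subject
#' while each subject keeps its own `(Q0, alpha)`.  Because the
#' per-subject problems separate at fixed `k`, the joint solution is
#' found by profiling: `SSE(k) = sum_i min_{Q0_i, alpha_i} SSE_i(k)` is
#' minimized over `k` in `k_bounds`, and every subject is then refit at
#' the optimum, so refitting any subject at the returned `k` reproduces
#' its parameters exactly.
#'
#' @param series_list List of two or more [demand_series()] objects (or
#'   data frames with `price`/`consumption`).
#' @param k_bounds Search interval for `k` (default `c(0.5, 6)`).
#' @param tol Convergence tolerance on `k` passed to
#'   [stats::optimize()].
#' @param ... Passed on to [fit_demand()].
#' @return An object of class `"shared_k_fit"`: list with `k`, `fits`
#'   (per-subject `demand_fit`s at the shared `k`), `sse` (joint), and
#'   `n_series`.
#' @examples
#' pr <- c(100, 200, 400, 800, 1600, 3200)
#' sims <- lapply(c(0.0003, 0.0006), function(a)
#'   demand_series(pr, 10^predict_log_consumption(1.8, a, 2.5, pr)))
#' fit_shared_k(sims)$k   # recovers 2.5
#' @export
fit_shared_k <- function(series_list, k_bounds = c(0.5, 6), tol = 1e-7, ...) {
  if (!is.list(series_list) || is.data.frame(series_list))
    stop("'series_list' must be a list of demand series")
  if (length(series_list) < 2)
    stop("shared-k estimation needs at least 2 series; ",
         "use fit_demand() with a fixed k for a single subject")
  stopifnot(length(k_bounds) == 2, k_bounds[1] > 0,
            k_bounds[2] > k_bounds[1])

  profile_sse <- function(k) {
    sum(vapply(series_list,
               function(s) fit_demand(s, k = k, ...)$sse, numeric(1)))
  }
  opt <- stats::optimize(profile_sse, interval = k_bounds, tol = tol)
  k_hat <- opt$minimum
  fits <- lapply(series_list, fit_demand, k = k_hat, ...)
  structure(list(k = k_hat,
                 fits = fits,
                 sse = sum(vapply(fits, `[[`, numeric(1), "sse")),
                 n_series = length(fits),
                 call = match.call()),
            class = "shared_k_fit")
}

#' @export
print.shared_k_fit <- function(x, digits = 5, ...) {
  cat("Shared-k exponential demand fit\n")
  cat("  k =", format(x$k, digits = digits),
      "(shared across", x$n_series, "series)\n")
  cat("  joint SSE =", format(x$sse, digits = digits), "\n")
  invisible(x)
}

#' @export
coef.shared_k_fit <- function(object, ...) {
  out <- do.call(rbind, lapply(object$fits, function(f)
    data.frame(subject_id = if (is.null(f$subject_id)) NA_character_
               else f$subject_id,
               q0 = f$coefficients[["q0"]],
               alpha = f$coefficients[["alpha"]])))
  out$k <- object$k
  rownames(out) <- NULL
  out
}

#' @export
summary.shared_k_fit <- function(object, ...) {
  tab <- coef(object)
  tab$r2 <- vapply(object$fits, `[[`, numeric(1), "r2")
  tab$sse <- vapply(object$fits, `[[`, numeric(1), "sse")
  structure(list(k = object$k, table = tab, sse = object$sse),
            class = "summary.shared_k_fit")
}

#' @export
print.summary.shared_k_fit <- function(x, digits = 5, ...) {
  cat("Shared-k demand fit: k =", format(x$k, digits = digits), "\n")
  print(x$table, digits = digits)
  invisible(x)
}
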