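#' Group-level demand curve with zero padding
#'
#' Builds a group mean consumption curve across all unit prices achieved
#' by any subject.  For prices above a subject's last achieved price, the
#' replaced-zero value 0.01 mg/kg is carried forward so that early
#' terminators keep pulling the group mean down — this padding makes the
#' group curve representative of individuals but is illustration-only:
#' padded points never enter individual fits or statistics.
#'
#' @param series_list List of [demand_series()] objects.
#' @param k Optional fixed `k`; if supplied, an illustration-only
#'   [fit_demand()] to the group means is attached as attribute
#'   `"illustration_fit"`.
#' @return Data frame with columns `price`, `mean_q`, `n_contributing`,
#'   `interpolated_count` (number of padded 0.01 values entering each
#'   mean).
#' @export
group_demand_curve <- function(series_list, k = NULL) {
  if (length(series_list) < 2) stop("need at least 2 series")
  prices <- sort(unique(unlist(lapply(series_list, function(s) s$price))))
  per_subject <- vapply(series_list, function(s) {
    v <- rep(NA_real_, length(prices))
    idx <- match(s$price, prices)
    v[idx] <- s$consumption
    pad <- prices > max(s$price)
    v[pad] <- 0.01
    v
  }, numeric(length(prices)))
  padded <- vapply(series_list, function(s) prices > max(s$price),
                   logical(length(prices)))
  out <- data.frame(
    price = prices,
    mean_q = rowMeans(per_subject, na.rm = TRUE),
    n_contributing = rowSums(!is.na(per_subject)),
    interpolated_count = rowSums(padded)
  )
  if (!is.null(k)) {
    fit <- fit_demand(data.frame(price = out$price, consumption = out$mean_q),
                      k = k)
    fit$illustration_only <- TRUE
    attr(out, "illustration_fit") <- fit
  }
  out
}
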