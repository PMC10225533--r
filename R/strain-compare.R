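#' Welch's unequal-variance t-test between two groups
#'
#' Independent-samples t-test with Welch's correction
#' (Satterthwaite degrees of freedom), the test used for between-strain
#' comparison of fitted demand parameters.
#'
#' @param x,y Numeric samples, each of length >= 2, with nonzero
#'   variance in at least one.
#' @param labels Group labels, length 2.
#' @param measure Name of the compared quantity.
#' @return One-row data frame of class `"welch_comparison"`: `measure,
#'   group1, group2, n1, n2, mean1, mean2, sem1, sem2, t, df, p`.
#' @examples
#' welch_t(c(1, 2, 3), c(1, 2, 3, 4, 5))
#' @export
welch_t <- function(x, y, labels = c("x", "y"), measure = "value") {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs at least 2 observations")
  if (stats::var(x) == 0 && stats::var(y) == 0 && mean(x) == mean(y)) {
    tt <- list(statistic = c(t = 0), parameter = c(df = length(x) +
               length(y) - 2), p.value = 1)
  } else {
    if (stats::var(x) == 0 && stats::var(y) == 0)
      stop("both groups have zero variance")
    tt <- stats::t.test(x, y)
  }
  out <- data.frame(measure = measure,
                    group1 = labels[1], group2 = labels[2],
                    n1 = length(x), n2 = length(y),
                    mean1 = mean(x), mean2 = mean(y),
                    sem1 = stats::sd(x) / sqrt(length(x)),
                    sem2 = stats::sd(y) / sqrt(length(y)),
                    t = unname(tt$statistic),
                    df = unname(tt$parameter),
                    p = tt$p.value,
                    stringsAsFactors = FALSE)
  class(out) <- c("welch_comparison", "data.frame")
  out
}

#' @export
print.welch_comparison <- function(x, digits = 4, ...) {
  needed <- c("measure", "group1", "group2", "n1", "n2", "t", "df", "p")
  if (!all(needed %in% names(x))) {
    print.data.frame(x, digits = digits)
    return(invisible(x))
  }
  for (i in seq_len(nrow(x)))
    cat(sprintf(
      "%s: %s (n=%d) vs %s (n=%d): t(%.2f) = %.3f, p = %s\n",
      x$measure[i], x$group1[i], x$n1[i], x$group2[i], x$n2[i],
      x$df[i], x$t[i], format.pval(x$p[i], digits = digits)))
  invisible(x)
}

#' Compare all demand indices between groups
#'
#' Welch comparisons of the four demand measures -- log10 alpha (alpha
#' is compared only after log transform, which normalizes its
#' distribution), Q0, Pmax and Omax -- between strains (sexes pooled)
#' and, descriptively, between sexes within each strain.  No
#' multiplicity correction is applied across the four measures.
#'
#' @param param_table Data frame with columns `strain, sex, alpha, q0`
#'   and (optionally) `pmax_exact`/`pmax`, `omax`; at least 2 subjects
#'   per compared group.
#' @param k Range constant used to derive Pmax/Omax when those columns
#'   are absent (default 2.218).
#' @return Data frame of stacked [welch_t()] rows, one per measure and
#'   contrast, with a `contrast` column (`"strain"` or
#'   `"sex_within_<strain>"`).
#' @examples
#' ref <- reference_demand_parameters()
#' compare_all_parameters(ref)   # the headline null: all p > 0.05
#' @export
compare_all_parameters <- function(param_table, k = 2.218) {
  d <- param_table
  stopifnot(all(c("strain", "sex", "alpha", "q0") %in% names(d)))
  if (is.null(d[["pmax"]]) && !is.null(d[["pmax_exact"]]))
    d$pmax <- d[["pmax_exact"]]
  if (is.null(d[["pmax"]])) d$pmax <- pmax_exact(d$q0, d$alpha, k)
  if (is.null(d[["omax"]])) d$omax <- omax(d$q0, d$alpha, k)
  d$log10_alpha <- log10(d$alpha)
  measures <- c("log10_alpha", "q0", "pmax", "omax")

  strains <- unique(d$strain)
  if (length(strains) != 2) stop("need exactly 2 strains")
  if (any(table(d$strain) < 2)) stop("need at least 2 subjects per strain")

  one <- function(sub, split_col, contrast) {
    lv <- unique(sub[[split_col]])
    if (length(lv) != 2 || any(table(sub[[split_col]]) < 2)) return(NULL)
    do.call(rbind, lapply(measures, function(m) {
      r <- welch_t(sub[[m]][sub[[split_col]] == lv[1]],
                   sub[[m]][sub[[split_col]] == lv[2]],
                   labels = as.character(lv), measure = m)
      r$contrast <- contrast
      r
    }))
  }
  out <- one(d, "strain", "strain")
  for (st in strains) {
    r <- one(d[d$strain == st, , drop = FALSE], "sex",
             paste0("sex_within_", st))
    if (!is.null(r)) out <- rbind(out, r)
  }
  rownames(out) <- NULL
  class(out) <- c("welch_comparison", "data.frame")
  out
}
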