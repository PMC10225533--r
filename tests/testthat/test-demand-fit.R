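test_that("noise-free series are recovered essentially exactly", {
  prices <- c(100, 200, 300, 500, 1000, 2000, 4000, 8000, 16000)
  ds <- make_exact_series(1.85, 0.000362, 2.218, prices)
  fit <- fit_demand(ds, k = 2.218)
  expect_equal(coef(fit)[["q0"]], 1.85, tolerance = 1e-6)
  expect_equal(coef(fit)[["alpha"]], 0.000362, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
  expect_false(fit$boundary)
})

test_that("fit agrees with a brute-force grid-search oracle", {
  # series with a replaced terminal zero (realistic shape)
  s <- data.frame(fr_value = c(3, 6, 9, 15, 30, 60, 120),
                  infusions = c(44, 31, 26, 18, 11, 4, 0))
  ds <- prepare_demand_series(s, 0.03)
  fit <- fit_demand(ds, k = 2.218)

  y <- log10(ds$consumption)
  sse_at <- function(q0, a)
    sum((predict_log_consumption(q0, a, 2.218, ds$price) - y)^2)
  q0_grid <- seq(0.5, 3.5, length.out = 120)
  a_grid <- 10^seq(-4.5, -2, length.out = 160)
  grid <- expand.grid(q0 = q0_grid, a = a_grid)
  grid$sse <- mapply(sse_at, grid$q0, grid$a)
  best <- grid[which.min(grid$sse), ]

  # optimizer at least matches the best grid point, and lands within a
  # grid cell of it
  expect_lte(fit$sse, best$sse + 1e-12)
  expect_equal(coef(fit)[["q0"]], best$q0,
               tolerance = 2 * diff(q0_grid[1:2]) / best$q0)
  expect_equal(log10(coef(fit)[["alpha"]]), log10(best$a), tolerance = 0.05)
})

test_that("degenerate and invalid inputs are handled", {
  # constant consumption: alpha driven to the lower bound, flagged
  flat <- demand_series(c(100, 200, 400, 800), rep(1.2, 4))
  fit <- expect_silent(fit_demand(flat, k = 2.218))
  expect_true(fit$boundary)
  expect_equal(coef(fit)[["alpha"]], 1e-8, tolerance = 1e-3)
  expect_true(is.na(fit$r2))

  expect_error(fit_demand(demand_series(c(100, 200), c(1, 0.5)), k = 2.218),
               "at least 3")
})

test_that("fit is invariant to observation order", {
  prices <- c(100, 300, 900, 2700, 8100)
  q <- 10^predict_log_consumption(1.4, 6e-4, 2.218, prices) *
    exp(c(0.05, -0.08, 0.02, 0.06, -0.04))
  perm <- c(3, 1, 5, 2, 4)
  f1 <- fit_demand(data.frame(price = prices, consumption = q), k = 2.218)
  f2 <- fit_demand(data.frame(price = prices[perm], consumption = q[perm]),
                   k = 2.218)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-9)
  expect_equal(f1$r2, f2$r2, tolerance = 1e-9)
})

test_that("demand_fit methods are coherent", {
  prices <- c(100, 200, 400, 800, 1600, 3200)
  ds <- make_exact_series(1.85, 0.000362, 2.218, prices,
                          subject_id = "w1")
  fit <- fit_demand(ds, k = 2.218)

  expect_named(coef(fit), c("q0", "alpha"))
  expect_equal(length(residuals(fit)), fit$n)
  expect_equal(residuals(fit), log10(ds$consumption) - fitted(fit))

  nd <- data.frame(price = c(50, 500, 5000))
  lq <- predict(fit, nd)
  expect_equal(predict(fit, nd, type = "consumption"), 10^lq)
  expect_equal(predict(fit, nd, type = "expenditure"), nd$price * 10^lq)

  # derived indices agree with the standalone closed forms
  expect_equal(fit$derived[["pmax_exact"]],
               pmax_exact(coef(fit)[["q0"]], coef(fit)[["alpha"]], 2.218))
  expect_equal(fit$derived[["omax"]],
               omax(coef(fit)[["q0"]], coef(fit)[["alpha"]], 2.218))

  sim1 <- simulate(fit, nsim = 2, seed = 9)
  sim2 <- simulate(fit, nsim = 2, seed = 9)
  expect_identical(sim1, sim2)
  expect_equal(nrow(sim1), 2 * fit$n)

  expect_output(print(fit), "Q0")
  expect_output(print(summary(fit)), "pmax_exact")
})

test_that("shared-k joint fit recovers a common k and is locally optimal", {
  prices <- c(100, 200, 400, 800, 1600, 3200, 6400)
  set.seed(3)
  truth <- data.frame(q0 = runif(6, 0.8, 2.5), alpha = 10^runif(6, -4, -3))
  series <- lapply(seq_len(6), function(i)
    make_exact_series(truth$q0[i], truth$alpha[i], 2.5, prices))

  sk <- fit_shared_k(series)
  expect_equal(sk$k, 2.5, tolerance = 1e-4 / 2.5)
  cf <- coef(sk)
  expect_equal(cf$q0, truth$q0, tolerance = 1e-5)
  expect_equal(cf$alpha, truth$alpha, tolerance = 1e-5)

  # joint SSE at the solution beats +/-10% perturbations of k
  sse_at_k <- function(k) sum(vapply(series, function(s)
    fit_demand(s, k = k)$sse, numeric(1)))
  expect_lte(sk$sse, sse_at_k(sk$k * 1.1))
  expect_lte(sk$sse, sse_at_k(sk$k * 0.9))

  # refitting at the returned k reproduces the per-subject parameters
  refit <- fit_demand(series[[1]], k = sk$k)
  expect_equal(coef(refit), coef(sk$fits[[1]]))

  expect_error(fit_shared_k(series[1]), "fit_demand")
})
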