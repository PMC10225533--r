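test_that("unit price and consumption arithmetic and units", {
  expect_equal(unit_price(1, 0.03), 100 / 3)
  expect_equal(unit_price(3, 0.03), 100)
  expect_equal(unit_price(2, 0.004), 500)
  expect_error(unit_price(3, 0), "positive")
  expect_error(unit_price(3, -0.01), "positive")

  expect_equal(consumption_mg_kg(10, 0.03), 0.3)
  expect_equal(consumption_mg_kg(0, 0.03), 0)
  # one infusion at the 30 ug/kg dose: log10(0.03) = -1.52
  expect_equal(round(log10(consumption_mg_kg(1, 0.03)), 2), -1.52)
})

test_that("exponential demand prediction: anchors and limits", {
  q0 <- 1.85; a <- 0.000362; k <- 2.218
  expect_equal(predict_log_consumption(q0, a, k, 0), log10(q0))
  # horizontal asymptote at log10(Q0) - k
  expect_equal(predict_log_consumption(q0, a, k, 1e12), log10(q0) - k,
               tolerance = 1e-12)
  # frozen direct evaluation at C = 377.9 (checked against independent
  # arithmetic; the published template prints Q ~ 0.59 mg/kg here)
  expect_equal(predict_log_consumption(q0, a, k, 377.9), -0.2287596,
               tolerance = 1e-6)
  # strictly decreasing in price, bounded in (Q0*10^-k, Q0]; stay below
  # the price where the exponential term underflows double precision
  cc <- 10^seq(-2, 4, length.out = 200)
  lq <- predict_log_consumption(q0, a, k, cc)
  expect_true(all(diff(lq) < 0))
  expect_true(all(10^lq <= q0 & 10^lq > q0 * 10^(-k)))
})

test_that("Lambert W implementation matches a root-finding oracle", {
  xs <- -exp(-1) * c(0.999, 0.9, 0.5, 0.1, 0.01, 1e-6)
  w_pkg <- opdemand:::lambert_w0(xs)
  w_ora <- vapply(xs, function(x)
    uniroot(function(w) w * exp(w) - x, c(-1, 0), tol = 1e-15)$root,
    numeric(1))
  expect_equal(w_pkg, w_ora, tolerance = 1e-10)
  expect_equal(w_pkg * exp(w_pkg), xs, tolerance = 1e-12)
})

test_that("pmax_exact is the unit-elasticity price", {
  # published value for SHR male subject 16 (printed 1078.1)
  expect_equal(pmax_exact(1.45, 0.000161, 2.218), 1078.1,
               tolerance = 0.005)
  # numeric-root value for Wistar male subject 1
  expect_equal(pmax_exact(1.85, 0.000362, 2.218), 376.2, tolerance = 0.001)
  expect_equal(pmax_exact(1.85, 0.000362, 2.218),
               oracle_pmax(1.85, 0.000362, 2.218), tolerance = 1e-9)
  # scaling: Pmax = u*/(alpha*Q0)
  expect_equal(pmax_exact(1.85, 2 * 0.000362, 2.218),
               pmax_exact(1.85, 0.000362, 2.218) / 2)
  expect_error(pmax_exact(1, 0.001, 1.0), "unit-elasticity")
})

test_that("pmax_approx reproduces the template formula and tracks pmax_exact", {
  expect_equal(pmax_approx(1.85, 0.000362, 2.218), 378.047, tolerance = 1e-4)
  expect_equal(pmax_approx(2, 0.0004, 3) * 2, pmax_approx(1, 0.0004, 3))
  # the template formula tracks the exact root to within 5% over the
  # range of k where it was built to operate (it degrades below ~1.7)
  for (k in seq(1.7, 4, by = 0.2)) {
    ratio <- pmax_approx(1.5, 5e-4, k) / pmax_exact(1.5, 5e-4, k)
    expect_true(ratio > 0.95 && ratio < 1.05)
  }
})

test_that("omax matches published values and the grid-maximum oracle", {
  k <- 2.218
  expect_equal(omax(1.32, 0.001, k), 80.8, tolerance = 0.001)
  expect_equal(omax(0.85, 0.001899, k), 42.5, tolerance = 0.002)
  # omax * alpha constant at fixed k
  expect_equal(omax(1.32, 0.001, k) * 0.001,
               omax(2.96, 0.001036, k) * 0.001036)
  expect_equal(omax(1.32, 0.001, k) * 0.001, 0.0808, tolerance = 1e-3)
  expect_equal(omax(1.32, 0.001, k), oracle_omax(1.32, 0.001, k),
               tolerance = 1e-8)
})

test_that("elasticity equals -1 at pmax_exact (numeric check)", {
  set.seed(42)
  for (i in 1:25) {
    q0 <- 10^runif(1, -0.5, 0.6)
    a <- 10^runif(1, -4.5, -2.5)
    k <- runif(1, 1.3, 4)
    pm <- pmax_exact(q0, a, k)
    expect_equal(demand_elasticity(q0, a, k, pm), -1, tolerance = 1e-10)
    h <- 1e-6
    num <- (predict_log_consumption(q0, a, k, pm * 10^h) -
            predict_log_consumption(q0, a, k, pm * 10^-h)) / (2 * h)
    expect_equal(num, -1, tolerance = 1e-6)
  }
})
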