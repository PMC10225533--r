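test_that("saline reference is the t-interval on per-subject window means", {
  ref <- saline_reference(c(10, 14, 12))
  expect_equal(ref$mean_infusions, 12)
  # t(0.975, 2) = 4.3027, SEM = 1.1547
  expect_equal(ref$ci_upper, 12 + qt(0.975, 2) * 2 / sqrt(3))
  expect_equal(ref$ci_upper, 16.9683, tolerance = 1e-4)
  expect_lte(ref$ci_lower, ref$mean_infusions)

  zv <- saline_reference(c(12, 12, 12))
  expect_equal(zv$ci_upper, 12)
  expect_equal(zv$ci_lower, 12)

  expect_error(saline_reference(12), "at least 2")
})

test_that("2:1 lever discrimination: boundaries and degenerate cases", {
  expect_true(lever_discrimination_met(20, 10))   # boundary inclusive
  expect_true(lever_discrimination_met(5, 0))     # division-free
  expect_false(lever_discrimination_met(0, 0))    # no responding
  expect_false(lever_discrimination_met(19, 10))
  expect_equal(lever_discrimination_met(c(20, 19, 0), c(10, 10, 0)),
               c(TRUE, FALSE, FALSE))
})

test_that("classification of dominated and boundary subjects", {
  base <- random_subject_sessions()
  base$active_responses <- rep(30L, 14)
  base$inactive_responses <- rep(5L, 14)
  base$infusions <- rep(25L, 14)

  res <- classify_acquisition(base, saline_ci_upper = 15)
  expect_equal(res$first_session_met, 3)
  expect_true(all(res$per_session_status == "met"))

  # window mean equal to the bound: strictly-above fails
  base$infusions <- rep(15L, 14)
  res2 <- classify_acquisition(base, saline_ci_upper = 15)
  expect_true(all(res2$per_session_status == "not_met"))
  expect_true(is.na(res2$first_session_met))

  # missing saline bound -> not evaluable
  res3 <- classify_acquisition(base, saline_ci_upper = NA_real_)
  expect_true(all(res3$per_session_status == "not_evaluable"))

  # gap in the session sequence
  gap <- base[-4, ]
  expect_error(classify_acquisition(gap, 15), "contiguous")
})

test_that("a subject crossing the bound mid-phase is dated by the window mean", {
  s <- random_subject_sessions()
  s$active_responses <- rep(40L, 14)
  s$inactive_responses <- rep(5L, 14)
  # infusions jump at session 6; the window (5,7) mean sits exactly on
  # the bound (strictly-above fails) so the first met window is (6,8)
  s$infusions <- c(rep(4L, 5), rep(28L, 9))
  res <- classify_acquisition(s, saline_ci_upper = 20)
  expect_equal(res$first_session_met, 8)
  expect_identical(unname(res$per_session_status[c("7", "8")]),
                   c("not_met", "met"))
  # oracle agreement on the full status vector
  expect_equal(res$per_session_status,
               oracle_classify(s, setNames(rep(20, 12), 3:14)))
})

test_that("sliding-window classification equals the exhaustive oracle", {
  set.seed(101)
  for (rep in 1:100) {
    s <- random_subject_sessions()
    bounds <- setNames(runif(12, 5, 25), 3:14)
    res <- classify_acquisition(s, bounds)
    expect_identical(res$per_session_status, oracle_classify(s, bounds))
  }
})

test_that("met status is monotone in infusions", {
  set.seed(55)
  for (rep in 1:40) {
    s <- random_subject_sessions()
    bounds <- setNames(runif(12, 5, 25), 3:14)
    before <- classify_acquisition(s, bounds)$per_session_status
    s$infusions <- s$infusions + sample(0:10, 14, replace = TRUE)
    after <- classify_acquisition(s, bounds)$per_session_status
    expect_false(any(before == "met" & after == "not_met"))
  }
})

test_that("demand-phase re-check matches the brute-force window search", {
  d <- data.frame(active_responses = c(90, 120, 200),
                  inactive_responses = c(10, 10, 10))
  expect_true(demand_phase_recheck(d))
  d2 <- data.frame(active_responses = c(4, 4, 4),
                   inactive_responses = c(3, 3, 3))
  expect_false(demand_phase_recheck(d2))
  expect_true(is.na(demand_phase_recheck(d2[1:2, ])))

  set.seed(7)
  for (rep in 1:60) {
    n <- sample(3:12, 1)
    act <- rpois(n, 12); inact <- rpois(n, 8)
    d3 <- data.frame(active_responses = act, inactive_responses = inact)
    expect_identical(demand_phase_recheck(d3), oracle_recheck(act, inact))
  }
})

test_that("acquisition proportions: cumulative convention", {
  res <- data.frame(strain = "Wistar",
                    first_session_met = c(5L, 5L, NA, NA),
                    s3 = "not_met", s4 = "not_met", s5 = "met",
                    stringsAsFactors = FALSE)
  p <- acquisition_proportions(res)
  expect_equal(p$proportion[p$session == 5], 0.5)
  expect_equal(p$proportion[p$session == 3], 0)

  # monotone non-decreasing, reaching 1 when everyone acquires
  res2 <- data.frame(strain = "SHR",
                     first_session_met = c(3L, 4L, 6L),
                     s3 = "x", s4 = "x", s5 = "x", s6 = "x", s7 = "x",
                     stringsAsFactors = FALSE)
  p2 <- acquisition_proportions(res2)
  expect_true(all(diff(p2$proportion) >= 0))
  expect_equal(p2$proportion[p2$session >= 6], c(1, 1))

  # non-cumulative mode uses the per-window status
  p3 <- acquisition_proportions(res, cumulative = FALSE)
  expect_equal(p3$proportion, c(0, 0, 1))
})

test_that("Fisher exact p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(2, 2, 2, 2), 1)
  # symmetry under simultaneous row and column swap
  expect_equal(fisher_exact_2x2(7, 2, 3, 8), fisher_exact_2x2(8, 3, 2, 7))
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "non-negative")

  set.seed(12)
  for (rep in 1:50) {
    tb <- rpois(4, 6)
    if (sum(tb) == 0) next
    expect_equal(fisher_exact_2x2(tb[1], tb[2], tb[3], tb[4]),
                 oracle_fisher_2x2(tb[1], tb[2], tb[3], tb[4]),
                 tolerance = 1e-7)
  }

  expect_true(bonferroni_significant(0.01))
  expect_false(bonferroni_significant(0.03))   # 0.025 threshold
})
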