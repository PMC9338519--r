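# Unit tests for the core estimators: null covariate rate, stratum ECDF
# model, density ratio, matched thresholds and v-values.

test_that("null covariate rate uses the null-enriched p > 1/2 region", {
  expect_equal(estimate_null_covariate_rate(runif(20), rep(0, 20)), 0)
  expect_equal(estimate_null_covariate_rate(runif(20), rep(1, 20)), 1)
  # only the four SNPs with p > 0.5 count: q values (0, 1, 0, 1) -> 0.5
  expect_equal(
    estimate_null_covariate_rate(c(0.6, 0.7, 0.8, 0.9, 0.1),
                                 c(0, 1, 0, 1, 1)), 0.5)
  # fallback: no SNP above 1/2 -> overall fraction
  expect_equal(estimate_null_covariate_rate(c(0.1, 0.2, 0.3, 0.4),
                                            c(1, 0, 0, 0)), 0.25)
  expect_error(estimate_null_covariate_rate(numeric(0), numeric(0)),
               "empty training fold")
})

test_that("stratum ECDFs are continuity-corrected and the ratio follows", {
  # symmetric 6-SNP training set: both strata at (0.1, 0.5, 0.9),
  # null_q = marginal_q = 0.5 so both stratum constants are 1
  p <- rep(c(0.1, 0.5, 0.9), 2)
  q <- rep(0:1, each = 3)
  model <- fit_stratum_model(p, q)
  expect_equal(model$m0, 3)
  expect_equal(model$marginal_q, 0.5)
  expect_equal(model$null_q, 0.5)
  # ecdf_0(0.5) = (2 + 1)/(3 + 1) = 0.75, ratio = 0.5 * 0.5/(0.75 * 0.5)
  expect_equal(cfdr_ratio(0.5, 0, model), 2 / 3)
  # boundary: ecdf(1) = 1 so the ratio reduces to null rate / marginal
  expect_equal(cfdr_ratio(1, 0, model), 1)
  expect_equal(cfdr_ratio(1, 1, model), 1)
  # below the smallest training p the corrected ECDF is 1/(m+1) > 0
  expect_equal(cfdr_ratio(0.05, 0, model), 0.05 / 0.25)
  expect_true(is.finite(cfdr_ratio(1e-12, 1, model)))
})

test_that("ratio of an independent covariate is close to 1 at large m", {
  set.seed(31)
  m <- 1e5
  model <- fit_stratum_model(runif(m), rbinom(m, 1, 0.3))
  grid <- seq(0.2, 1, by = 0.01)
  for (s in 0:1) {
    r <- cfdr_ratio(grid, s, model)
    expect_lt(max(abs(r - 1)), 0.05)
  }
  # looser band where the ECDF is noisier
  expect_lt(max(abs(cfdr_ratio(seq(0.01, 0.2, 0.01), 0, model) - 1)), 0.15)
})

test_that("empty strata raise the degenerate-path error", {
  model <- fit_stratum_model(runif(10), rep(0, 10))
  expect_error(cfdr_ratio(0.5, 1, model), "uninformative")
  # solve falls back to the identity region instead
  reg <- solve_matched_threshold(0.3, 0, model)
  expect_equal(reg$p0, 0.3)
  expect_equal(reg$p1, 0.3)
})

test_that("symmetric strata solve to the flat end at or beyond the input
           p, matching the brute force", {
  # with identical strata and null_q = marginal_q the two ratio curves
  # coincide, so the matched threshold is the right end of the envelope
  # flat containing p: never below p (minus one knot step), and exactly
  # what the dense-grid brute force returns
  set.seed(5)
  base <- runif(25)
  p <- c(base, base)
  q <- rep(0:1, each = 25)
  model <- fit_stratum_model(p, q)
  expect_equal(model$null_q, model$marginal_q)
  step <- max(diff(sort(c(0, base, 1))))
  for (pi in c(0.05, 0.3, 0.7)) {
    reg <- solve_matched_threshold(pi, 0, model)
    expect_gte(reg$p1, pi - step)
    orac <- oracle_region(pi, 0, p, q)
    expect_lt(abs(reg$p1 - orac[["p1"]]), 2e-4)
  }
})

test_that("matched thresholds clamp to 1 when the target exceeds the
           opposite stratum's whole ratio range", {
  # q = 1 SNPs pile up at large p so null_q is high; a q = 1 query deep in
  # the sparse left tail of stratum 1 yields a huge target ratio
  p <- c(seq(0.05, 0.95, length.out = 20), 0.94, 0.96, 0.98)
  q <- c(rep(0, 20), rep(1, 3))
  model <- fit_stratum_model(p, q)
  target <- bincfdr:::envelope_ratio(model, 1, 0.9)
  expect_gt(target, cfdr_ratio(1, 0, model))  # above the whole q=0 range
  expect_equal(solve_matched_threshold(0.9, 1, model)$p0, 1)
})

test_that("matched thresholds agree with the dense-grid brute force", {
  worst <- 0
  for (s in 1:100) {
    set.seed(s)
    p <- runif(50)
    q <- rbinom(50, 1, 0.4)
    if (length(unique(q)) < 2) q[1:2] <- 0:1
    model <- fit_stratum_model(p, q)
    p_i <- runif(1)
    q_i <- rbinom(1, 1, 0.5)
    impl <- solve_matched_threshold(p_i, q_i, model)
    orac <- oracle_region(p_i, q_i, p, q)
    worst <- max(worst, abs(impl$p0 - orac[["p0"]]),
                 abs(impl$p1 - orac[["p1"]]))
  }
  expect_lt(worst, 2e-4)  # grid resolution 1e-4
})

test_that("v-values are the Eq-17 convex combination, clamped", {
  expect_equal(v_value(0.01, 0.1, 0.2), 0.028)
  expect_equal(v_value(0.3, 0.7, 0), 0.3)
  expect_equal(v_value(0.3, 0.7, 1), 0.7)
  p <- runif(10)
  expect_equal(v_value(p, p, 0.37), p)     # equal coordinates -> v = p
  expect_equal(v_value(0, 0, 0.5), .Machine$double.xmin)  # floored
  expect_error(v_value(-0.1, 0.5, 0.5))
})

test_that("BH adjustment validates and matches the step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.3, 7)), rep(0.3, 7))
  v <- runif(100)
  expect_true(all(bh_adjust(v) >= v))
  expect_error(bh_adjust(c(0.5, 0)), "outside")
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
  expect_error(bh_adjust(numeric(0)), "non-empty")
})
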