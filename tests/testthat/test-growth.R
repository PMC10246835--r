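test_that("growth AUC matches closed-form integrals and refuses extrapolation", {
  t10 <- seq(0, 16, by = 0.25)
  expect_equal(growth_auc(t10, rep(0.5, length(t10))), 7.5)
  expect_equal(growth_auc(t10, t10 / 15), 7.5)      # linear 0->1 over 15 h
  expect_error(growth_auc(seq(0, 12, 0.5), rep(1, 25)), "cover")
  expect_error(growth_auc(c(0, 0, 15), c(1, 1, 1)), "increasing")
})

test_that("growth AUC is linear in OD and invariant to added interior points", {
  tt <- c(0, 3, 7, 11, 15)
  od <- c(0.05, 0.1, 0.6, 0.9, 0.95)
  expect_equal(growth_auc(tt, 3 * od), 3 * growth_auc(tt, od))
  # refine the piecewise-linear curve: same polygon, same area
  mid <- (tt[-1] + tt[-5]) / 2
  odm <- approx(tt, od, mid)$y
  o <- order(c(tt, mid))
  expect_equal(growth_auc(c(tt, mid)[o], c(od, odm)[o]), growth_auc(tt, od))
})

test_that("the Gompertz fit recovers noiseless parameters and flags flat curves", {
  tt <- seq(0, 16, by = 1 / 6)
  od <- gompertz_od(tt, rate = 0.6, lag = 3, asymptote = 1.2, od0 = 0.02)
  fit <- fit_growth_model(tt, od)
  expect_true(fit$converged)
  expect_equal(fit$rate, 0.6, tolerance = 1e-3)
  expect_equal(fit$lag, 3, tolerance = 1e-2)
  flat <- fit_growth_model(tt, rep(0.4, length(tt)))
  expect_false(flat$converged)
  expect_error(fit_growth_model(1:5, 1:5), "at least 8")
})

test_that("rate recovery bias stays below 2% at 1% multiplicative noise", {
  tt <- seq(0, 16, by = 1 / 6)
  base <- gompertz_od(tt, rate = 0.6, lag = 3, asymptote = 1.2)
  set.seed(44)
  rates <- replicate(100, {
    od <- base * exp(rnorm(length(tt), 0, 0.01))
    fit_growth_model(tt, od)$rate
  })
  expect_lt(abs(mean(rates, na.rm = TRUE) / 0.6 - 1), 0.02)
})

test_that("IC50 fitting normalizes by the no-drug integral and hits the midpoint", {
  curves <- gen_growth_curves(ic50_true = 100, hill = 2, noise = 0, seed = 1)
  auc <- vapply(curves, function(d) growth_auc(d$times, d$od), numeric(1))
  conc <- as.numeric(names(auc))
  dr <- fit_ic50(conc, auc)
  expect_true(dr$converged && dr$reliable)
  expect_equal(dr$ic50, 100, tolerance = 0.01)
  expect_equal(unname(dr$normalized_growth[conc == 0]), 1)
  # g(IC50) = 0.5 on the fitted curve by definition
  expect_equal(1 / (1 + (dr$ic50 / dr$ic50)^dr$hill), 0.5)
  expect_error(fit_ic50(c(1, 2, 3, 4), c(1, 1, 1, 1)), "0-concentration")
  expect_error(fit_ic50(c(0, 1, 2, 3), rep(2, 4)), "all-equal")
})

test_that("monotone-increasing growth with dose is flagged unreliable", {
  conc <- c(0, 1, 10, 100, 1000)
  growth <- c(5, 5.5, 6.5, 8, 9)
  dr <- fit_ic50(conc, growth)
  expect_false(dr$reliable)
})

test_that("promoter activity and functional capacity are guarded ratios/products", {
  expect_equal(promoter_activity(2000, 0.5), 4000)
  expect_equal(promoter_activity(0, 0.5), 0)
  expect_error(promoter_activity(100, 0), "positive")
  expect_equal(functional_capacity(1.0, 8.1), 8.1)
  expect_equal(functional_capacity(0, 3), 0)
  expect_equal(functional_capacity(2, 3), 6)
  expect_error(functional_capacity(-1, 3), "non-negative")
})

test_that("polysome log ratio follows the delta-Ct arithmetic and is antisymmetric", {
  poly <- qpcr_record(25, 20, "polysomal")   # dCt = 5
  tot <- qpcr_record(23, 20, "total")        # dCt = 3
  expect_equal(polysome_log_ratio(poly, tot), -2)  # 2^-5 / 2^-3 = 0.25
  same <- polysome_log_ratio(qpcr_record(24, 20, "polysomal"),
                             qpcr_record(24, 20, "total"))
  expect_equal(same, 0)
  # lower polysomal dCt means more polysome engagement: positive ratio
  engaged <- polysome_log_ratio(qpcr_record(21, 20, "polysomal"),
                                qpcr_record(24, 20, "total"))
  expect_gt(engaged, 0)
  # swapping the fraction roles flips the sign
  a <- qpcr_record(25, 20, "polysomal"); b <- qpcr_record(23, 20, "total")
  a2 <- qpcr_record(23, 20, "polysomal"); b2 <- qpcr_record(25, 20, "total")
  expect_equal(polysome_log_ratio(a, b), -polysome_log_ratio(a2, b2))
  expect_error(polysome_log_ratio(tot, tot), "order")
})
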