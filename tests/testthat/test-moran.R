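test_that("a single variant stays at frequency 1 throughout", {
  cfg <- sim_config(c(only = 1), n_init = 1e4, n_cap = 1e6,
                    replicates = 2, total_generations = 18)
  for (tr in simulate_moran(cfg, seed = 3))
    expect_true(all(tr[, "only"] == rowSums(tr)))
})

test_that("population size follows the growth factor and dilution schedule", {
  cfg <- sim_config(c(a = 1, b = 1), n_init = 1e4, n_cap = 1e6,
                    generations_to_cap = 12, dilution_factor = 100,
                    dilution_every = 6, replicates = 1,
                    total_generations = 24)
  tr <- simulate_moran(cfg, seed = 2)[[1]]
  N <- rowSums(tr)
  expect_equal(N[1], 1e4)
  expect_equal(N[13], 1e6 / 100, tolerance = 0.01)   # cap reached, diluted
  expect_equal(N[19], 1e6 / 100, tolerance = 0.01)   # next cycle
  g <- (1e6 / 1e4)^(1 / 12)
  for (t in 2:12) expect_equal(N[t], round(N[t - 1] * g), tolerance = 1e-9)
})

test_that("identical seed and config give bit-identical trajectories", {
  cfg <- sim_config(c(a = 1, b = 2, c = 0.5), n_init = 1e4, n_cap = 1e6,
                    replicates = 3, total_generations = 20)
  expect_identical(simulate_moran(cfg, seed = 11), simulate_moran(cfg, seed = 11))
  expect_false(identical(simulate_moran(cfg, seed = 11),
                         simulate_moran(cfg, seed = 12)))
})

test_that("a 2:1 fitness ratio tracks the replicator recursion at large N", {
  cfg <- sim_config(c(a = 2, b = 1), n_init = 1e6, n_cap = 1e8,
                    replicates = 1, total_generations = 12)
  tr <- simulate_moran(cfg, seed = 7)[[1]]
  f <- tr[, "a"] / rowSums(tr)
  for (t in 1:12) {
    pred <- f[t] * 2 / (f[t] * 2 + (1 - f[t]) * 1)
    expect_lt(abs(f[t + 1] - pred), 0.01)
  }
})

test_that("neutral dynamics preserve expected frequencies", {
  cfg <- sim_config(c(a = 1, b = 1, c = 1, d = 1), n_init = 1e4,
                    n_cap = 1e6, replicates = 1, total_generations = 12)
  finals <- vapply(1:30, function(s) {
    tr <- simulate_moran(cfg, seed = s)[[1]]
    (tr[13, ] / sum(tr[13, ]))[["a"]]
  }, numeric(1))
  se <- sd(finals) / sqrt(length(finals))
  expect_lt(abs(mean(finals) - 0.25), 4 * se + 1e-12)
})

test_that("summaries normalize mean fitness to 1 at t0 and use nats for H", {
  cfg <- sim_config(c(a = 1.5, b = 1), n_init = 1e4, n_cap = 1e6,
                    replicates = 4, total_generations = 15)
  trs <- simulate_moran(cfg, seed = 5)
  s <- summarize_trajectories(trs, cfg$fitness)
  expect_equal(s$summary$w_bar_mean[1], 1)
  expect_true(all(s$summary$H_mean <= log(2) + 1e-12))
  neutral <- summarize_trajectories(
    simulate_moran(sim_config(c(a = 1, b = 1), n_init = 1e4, n_cap = 1e6,
                              replicates = 3, total_generations = 10),
                   seed = 9), c(a = 1, b = 1))
  expect_true(all(abs(unlist(lapply(neutral$per_replicate, `[[`, "w_bar")) - 1)
                  < 1e-12))
})

test_that("selection drives diversity down and mean fitness up, inversely coupled", {
  w <- c(a = 10, b = 1, c = 1, d = 1)
  cfg <- sim_config(w, n_init = 1e4, n_cap = 1e6, replicates = 20,
                    total_generations = 15)
  s <- summarize_trajectories(simulate_moran(cfg, seed = 21), w)
  # H decreases in expectation under strong selection
  expect_lt(s$summary$H_mean[16], s$summary$H_mean[1])
  corrs <- vapply(s$per_replicate, function(d)
    suppressWarnings(cor(d$w_bar, d$H)), numeric(1))
  expect_gte(mean(corrs < 0, na.rm = TRUE), 0.95)
})

test_that("outcome ranking is insensitive to initial frequency bias", {
  w <- c(a = 1, b = 1.4, c = 1.9, d = 2.6)
  biased <- c(a = 10, b = 1, c = 5, d = 1)
  biased <- biased / sum(biased)   # 10-fold initial bias against b, d
  cfg_eq <- sim_config(w, n_init = 1e4, n_cap = 1e6, replicates = 10,
                       total_generations = 18)
  cfg_bi <- sim_config(w, n_init = 1e4, n_cap = 1e6, replicates = 10,
                       total_generations = 18,
                       initial_frequencies = biased)
  tr_eq <- simulate_moran(cfg_eq, seed = 31)
  tr_bi <- simulate_moran(cfg_bi, seed = 32)
  agree <- mapply(function(x, y) {
    identical(order(x[nrow(x), ]), order(y[nrow(y), ]))
  }, tr_eq, tr_bi)
  expect_gte(mean(agree), 0.95)
})
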