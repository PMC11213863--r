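test_that("the eight variants are the subsets of {delta, theta, tau}", {
  subsets <- lapply(1:8, function(i) model_variant(i)$varies)
  expect_equal(length(unique(lapply(subsets, sort))), 8)
  expect_equal(subsets[[1]], character(0))
  expect_setequal(subsets[[8]], c("delta", "theta", "tau"))
  expect_setequal(subsets[[6]], c("delta", "tau"))
  expect_error(model_variant(9))
})

test_that("age-group assignment is deterministic and median splits evenly", {
  expect_equal(assign_age_group(18.08, 60), "YA")
  expect_equal(assign_age_group(86.83, 60), "OA")
  set.seed(8)
  for (n in c(9, 10, 25)) {
    ages <- runif(n, 18, 90)
    g <- assign_age_group(ages, median(ages))
    expect_lte(abs(sum(g == "OA") - sum(g == "YA")), 1)
  }
})

test_that("model structure produces the documented node counts", {
  sim <- quick_trials(4, seed = 61)
  thr <- median(unique(sim$trials$age))
  m1 <- build_model(1, sim$trials, age_threshold = thr)
  p1 <- sample_posterior(m1, n_chains = 2, n_iter = 24, burn_in = 4, thin = 2,
                         seed = 1)
  nodes <- dimnames(p1$draws)[[2]]
  # nothing varies: one group mean per parameter family
  expect_equal(sum(grepl("^mu_", nodes)), 3)
  expect_equal(sum(grepl("^sigma_", nodes)), 3)
  expect_equal(sum(!grepl("^(mu|sigma)_", nodes)), 4 * 3)

  m8 <- build_model(8, sim$trials, age_threshold = thr)
  p8 <- sample_posterior(m8, n_chains = 2, n_iter = 24, burn_in = 4, thin = 2,
                         seed = 1)
  nodes8 <- dimnames(p8$draws)[[2]]
  # all vary: 12 conditional-dependency cells per parameter family
  expect_equal(sum(grepl("^mu_delta", nodes8)), 12)
  expect_equal(sum(grepl("^mu_", nodes8)), 36)
  expect_equal(sum(!grepl("^(mu|sigma)_", nodes8)), 4 * 6 * 3)
})

test_that("an empty conditional-dependency cell is a configuration error naming it", {
  sim <- quick_trials(4, seed = 61)
  young <- sim$trials[sim$trials$age < 55, ]
  expect_error(build_model(8, young, age_threshold = 90), "OA")
})

test_that("retention arithmetic matches settings", {
  sim <- quick_trials(2, seed = 71)
  m <- build_model(1, sim$trials)
  p <- sample_posterior(m, n_chains = 1, n_iter = 12, burn_in = 10, thin = 2,
                        seed = 2)
  expect_equal(dim(p$draws)[1], 1)  # (12 - 10) / 2
  p2 <- sample_posterior(m, n_chains = 3, n_iter = 60, burn_in = 20, thin = 4,
                         seed = 2)
  expect_equal(p2$meta$pooled_draws, 3 * 10)
  expect_equal(dim(p2$draws), c(10, length(dimnames(p2$draws)[[2]]), 3))
})

test_that("chains are deterministic given the seed", {
  sim <- quick_trials(2, seed = 81)
  m <- build_model(1, sim$trials)
  a <- sample_posterior(m, n_chains = 2, n_iter = 100, burn_in = 20, thin = 2,
                        seed = 33)
  b <- sample_posterior(m, n_chains = 2, n_iter = 100, burn_in = 20, thin = 2,
                        seed = 33)
  expect_identical(a$draws, b$draws)
  expect_identical(a$deviance, b$deviance)
  c <- sample_posterior(m, n_chains = 2, n_iter = 100, burn_in = 20, thin = 2,
                        seed = 34)
  expect_false(identical(a$draws, c$draws))
})

test_that("proposal-scale adaptation stops at the end of burn-in", {
  fit <- cached_fit()$post
  for (log_ in fit$meta$adapt_logs) {
    post_burn <- log_$iteration > fit$meta$burn_in
    expect_true(all(log_$max_log_scale_change[post_burn] == 0))
    expect_true(any(log_$max_log_scale_change[!post_burn] > 0))
  }
})

test_that("a long single-participant fit concentrates near the generating truth", {
  set.seed(15)
  s <- simulate_wiener(2000, 1.8, 1.6, 0.35)
  trials <- data.frame(participant_id = "p1", age = 30,
                       condition = rep(c("V", "A", "AV"), length.out = 2000),
                       coherence = "HC", rt = s$rt * 1000, correct = s$correct)
  trials$coherence <- rep(c("HC", "LC"), each = 1000)
  m <- build_model(1, trials)
  p <- sample_posterior(m, n_chains = 2, n_iter = 1500, burn_in = 300,
                        thin = 2, seed = 5)
  est <- colMeans(do.call(rbind, lapply(1:2, function(ch) p$draws[, , ch])))
  expect_lt(abs(est[["delta[p1]"]] - 1.8), 0.2)
  expect_lt(abs(est[["theta[p1]"]] - 1.6), 0.12)
  expect_lt(abs(est[["tau[p1]"]] - 0.35), 0.04)
})
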