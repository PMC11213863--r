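# wrap plain chain matrices in a minimal posterior-like object
fake_post <- function(mat_list) {
  draws <- array(unlist(mat_list), dim = c(length(mat_list[[1]]), 1,
                                           length(mat_list)),
                 dimnames = list(NULL, "x", NULL))
  structure(list(draws = draws), class = "hddm_posterior")
}

test_that("Gelman-Rubin matches a hand computation on fixed arrays", {
  c1 <- c(1, 2, 3, 4)
  c2 <- c(2, 3, 4, 7)
  # by hand: n=4, W=(var(c1)+var(c2))/2, B/n=var(chain means)
  n <- 4
  W <- (var(c1) + var(c2)) / 2
  Bn <- var(c(mean(c1), mean(c2)))
  expected <- sqrt(((n - 1) / n * W + Bn) / W)
  expect_equal(gelman_rubin(fake_post(list(c1, c2)), "x"), expected)
})

test_that("well-mixed chains give a statistic near one; offset chains do not", {
  set.seed(1)
  same <- fake_post(list(rnorm(4000), rnorm(4000), rnorm(4000)))
  expect_lt(gelman_rubin(same, "x"), 1.01)
  apart <- fake_post(list(rnorm(500), rnorm(500) + 50))
  expect_gt(gelman_rubin(apart, "x"), 5)
})

test_that("the statistic agrees with coda's point estimate", {
  skip_if_not_installed("coda")
  set.seed(2)
  chains <- list(rnorm(1500), rnorm(1500, 0.05), rnorm(1500, -0.02))
  ours <- gelman_rubin(fake_post(chains), "x")
  cd <- coda::gelman.diag(coda::mcmc.list(lapply(chains, coda::mcmc)),
                          autoburnin = FALSE)$psrf[1]
  expect_lt(abs(ours - cd), 0.05)
})

test_that("the statistic is invariant to affine transformations", {
  set.seed(3)
  chains <- list(rnorm(800), rnorm(800, 0.3))
  r1 <- gelman_rubin(fake_post(chains), "x")
  r2 <- gelman_rubin(fake_post(lapply(chains, function(x) 7 - 3.2 * x)), "x")
  expect_equal(r1, r2)
})

test_that("single-chain posteriors are rejected by the diagnostic", {
  expect_error(gelman_rubin(fake_post(list(rnorm(10))), "x"), "chains")
})

test_that("the DIC identity holds exactly on the stored trace", {
  fit <- cached_fit()$post
  d <- dic(fit)
  expect_equal(d$dic, 2 * d$mean_deviance - d$deviance_at_means)
  expect_equal(d$p_d, d$mean_deviance - d$deviance_at_means)
  expect_gt(d$p_d, 0)   # a fitted hierarchical model has positive complexity
})

test_that("a posterior frozen at its means has zero effective parameters", {
  fit <- cached_fit()$post
  frozen <- fit
  means <- apply(fit$draws, 2, mean)
  for (ch in seq_len(dim(frozen$draws)[3]))
    frozen$draws[, , ch] <- matrix(means, dim(fit$draws)[1],
                                   length(means), byrow = TRUE)
  d0 <- dic(frozen)$deviance_at_means
  frozen$deviance[] <- d0
  d <- dic(frozen)
  expect_equal(d$p_d, 0)
  expect_equal(d$dic, d0)
})

test_that("model selection prefers the lowest DIC and applies the >10 rule", {
  s <- select_model(data.frame(variant = c("A", "B"), dic = c(100, 150)))
  expect_equal(s$best, "A")
  expect_true(s$substantial)
  s2 <- select_model(data.frame(variant = c("A", "B"), dic = c(100, 105)))
  expect_equal(s2$best, "A")
  expect_false(s2$substantial)
})

test_that("highest-density regions behave as specified", {
  set.seed(4)
  z <- rnorm(2e5)
  h <- hdr_interval(z, 0.90)
  expect_lt(abs(h[1] + 1.645), 0.03)
  expect_lt(abs(h[2] - 1.645), 0.03)
  # discrete tie broken toward the lower start
  expect_equal(hdr_interval(1:10, 0.9), c(1, 9))
  # full mass returns the sample range
  expect_equal(hdr_interval(z, 1), range(z))
  # width shrinks with mass
  w <- vapply(c(0.95, 0.9, 0.5, 0.2), function(m) diff(hdr_interval(z, m)),
              numeric(1))
  expect_true(all(diff(w) < 0))
})

test_that("posterior predictive checks pass for a self-consistent fit", {
  fit <- cached_fit()$post
  pc <- posterior_predictive_check(fit, n_draws = 120, seed = 9)
  expect_true(all(c("cell", "statistic", "observed", "hdr_lower",
                    "hdr_upper", "inside") %in% names(pc)))
  # posterior fitted to its own data: most statistics inside the 90% HDR
  expect_gte(mean(pc$inside), 0.8)
  # signed-RT convention: incorrect-response deciles live on the negative axis
  q10 <- pc[pc$statistic == "q10", ]
  expect_true(any(q10$observed < 0))
  expect_error(posterior_predictive_check(fit, n_draws = 1), "n_draws")
})
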