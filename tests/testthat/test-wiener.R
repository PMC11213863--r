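random_params <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(delta = runif(n, -5, 5), theta = runif(n, 0.5, 3),
             tau = runif(n, 0.1, 0.6))
}

quad_total <- function(p, boundary) {
  f <- function(t) wfpt_density(t, boundary, p)
  integrate(f, p$tau, p$tau + 40 * p$theta^2 + 5, rel.tol = 1e-10,
            subdivisions = 500L)$value
}

test_that("density vanishes at and before the non-decision time", {
  p <- wiener_params(1.2, 1.5, 0.3)
  expect_equal(wfpt_density(c(0, 0.1, 0.3), "upper", p), c(0, 0, 0))
  expect_gt(wfpt_density(0.31, "upper", p), 0)
})

test_that("joint density integrates to one over random parameter draws", {
  box <- random_params(6, seed = 2)
  for (i in seq_len(nrow(box))) {
    p <- wiener_params(box$delta[i], box$theta[i], box$tau[i])
    total <- quad_total(p, "upper") + quad_total(p, "lower")
    expect_lt(abs(total - 1), 1e-4)
  }
})

test_that("choice probability matches density quadrature to 1e-6", {
  box <- random_params(6, seed = 3)
  for (i in seq_len(nrow(box))) {
    p <- wiener_params(box$delta[i], box$theta[i], box$tau[i])
    expect_lt(abs(choice_probability(p, "upper") - quad_total(p, "upper")), 1e-6)
    expect_lt(abs(choice_probability(p, "lower") - quad_total(p, "lower")), 1e-6)
  }
})

test_that("zero drift with a midpoint start gives even odds; strong drift is decisive", {
  expect_equal(choice_probability(wiener_params(0, 1.5, 0.3), "upper"), 0.5)
  expect_gt(choice_probability(wiener_params(50, 1.5, 0.3), "upper"), 1 - 1e-6)
  p <- wiener_params(1.7, 2.1, 0.2)
  expect_equal(choice_probability(p, "upper") + choice_probability(p, "lower"), 1)
})

test_that("small-time and large-time branches agree where either applies", {
  # the error tolerance steers which series branch is evaluated at each
  # point; if the branches disagreed anywhere, tightening the tolerance
  # (which shifts the switch point) would move the result by more than the
  # tolerances themselves
  for (pars in list(c(1.5, 2, 0.2), c(-3, 1, 0.1), c(0.5, 2.8, 0.5))) {
    p <- wiener_params(pars[1], pars[2], pars[3])
    t <- seq(p$tau + 0.005, 6, by = 0.004)
    f_loose <- wfpt_density(t, "upper", p, eps = 1e-6)
    f_tight <- wfpt_density(t, "upper", p, eps = 1e-12)
    expect_true(all(f_tight >= 0))
    expect_lt(max(abs(f_loose - f_tight)), 2e-6)
  }
})

test_that("path simulation (Euler oracle) agrees with the series density", {
  # independent Euler-Maruyama simulator vs analytic CDF by quadrature
  p <- wiener_params(2, 1.5, 0.3)
  set.seed(10)
  sim <- simulate_wiener(1e5, p$delta, p$theta, p$tau, method = "euler")
  cdf <- analytic_subcdf(p, "upper", 4)
  emp <- findInterval(cdf$t, sort(sim$rt[sim$correct])) / nrow(sim)
  expect_lt(max(abs(cdf$F - emp)), 0.01)
  # boundary probabilities agree too
  expect_lt(abs(mean(sim$correct) - choice_probability(p, "upper")), 0.01)
})

test_that("the two samplers agree with each other", {
  set.seed(4)
  a <- simulate_wiener(3e4, 1, 1.2, 0.25, method = "exact")
  b <- simulate_wiener(3e4, 1, 1.2, 0.25, method = "euler")
  expect_lt(abs(mean(a$correct) - mean(b$correct)), 0.015)
  ks <- suppressWarnings(ks.test(a$rt[a$correct], b$rt[b$correct]))
  expect_lt(unname(ks$statistic), 0.015)
})

test_that("mean decision time matches the closed form for a symmetric start", {
  # E[T - tau] = (theta / (2 delta)) * tanh(delta * theta / 2)
  set.seed(5)
  s <- simulate_wiener(1e5, 2, 1.5, 0.3)
  expect_lt(abs(mean(s$rt) - 0.3 - (1.5 / 4) * tanh(1.5)), 0.005)
})

test_that("invalid parameters are rejected", {
  expect_error(wiener_params(1, 0, 0.3), "theta")
  expect_error(wiener_params(1, -2, 0.3), "theta")
  expect_error(wiener_params(1, 1, -0.1), "tau")
  expect_error(wiener_params(1, 1, 0.3, z = 1.2), "z")
  expect_error(simulate_wiener(10, 1, -1, 0.3), "theta")
})

test_that("log-likelihood reduces to its definition and handles edge cases", {
  expect_equal(log_likelihood(data.frame()[0, ], data.frame()), 0)
  pars <- data.frame(participant_id = "p1", condition = "V", coherence = "HC",
                     delta = 2, theta = 1.5, tau = 0.3)
  one <- data.frame(participant_id = "p1", condition = "V", coherence = "HC",
                    rt = 700, correct = TRUE)
  expect_equal(log_likelihood(one, pars),
               log(wfpt_density(0.7, "upper", wiener_params(2, 1.5, 0.3))))
  # rt at or below tau signals impossibility
  fast <- transform(one, rt = 250)
  expect_identical(log_likelihood(fast, pars), -Inf)
  # missing cell mapping is a configuration error
  other <- transform(one, condition = "A")
  expect_error(log_likelihood(other, pars), "no parameters")
})

test_that("likelihood is maximised near the generating drift on a grid", {
  set.seed(6)
  s <- simulate_wiener(1000, 2, 1.5, 0.3)
  trials <- data.frame(participant_id = "p1", condition = "V",
                       coherence = "HC", rt = s$rt * 1000, correct = s$correct)
  grid <- seq(0.5, 4, by = 0.25)
  ll <- vapply(grid, function(d) {
    pars <- data.frame(participant_id = "p1", condition = "V",
                       coherence = "HC", delta = d, theta = 1.5, tau = 0.3)
    log_likelihood(trials, pars)
  }, numeric(1))
  expect_lt(abs(grid[which.max(ll)] - 2), 0.5)
})
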