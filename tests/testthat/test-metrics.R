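# build an estimates table directly (cells x participants)
est_table <- function(values) {
  # values: named list participant -> named vector over V.HC.. cells for delta,
  # with theta/tau filled as constants unless provided
  rows <- list()
  for (id in names(values)) {
    v <- values[[id]]
    rows[[id]] <- data.frame(
      participant_id = id, age = v[["age"]],
      condition = rep(c("V", "A", "AV"), each = 2),
      coherence = rep(c("HC", "LC"), 3),
      delta = v[c("V.HC", "V.LC", "A.HC", "A.LC", "AV.HC", "AV.LC")],
      theta = if ("theta" %in% names(v)) v[["theta"]] else 1.5,
      tau = if ("tau" %in% names(v)) v[["tau"]] else 0.3,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

test_that("AV - V contrasts follow their definition, collapsed = mean of levels", {
  est <- est_table(list(
    p1 = c(age = 30, V.HC = 1.5, V.LC = 1.0, A.HC = 1.2, A.LC = 0.8,
           AV.HC = 2.0, AV.LC = 1.1)))
  d <- av_minus_v(est, "delta")
  expect_equal(d$HC, 0.5)
  expect_equal(d$LC, 0.1)
  expect_equal(av_minus_v(est, "delta", "collapsed")$collapsed, 0.3)
  # identical AV and V estimates give zero
  eq <- est_table(list(p1 = c(age = 40, V.HC = 1, V.LC = 1, A.HC = 2,
                              A.LC = 2, AV.HC = 1, AV.LC = 1)))
  expect_equal(av_minus_v(eq, "delta")$HC, 0)
  # collapsed equals the mean of per-coherence values on random inputs
  set.seed(5)
  for (i in 1:5) {
    r <- est_table(list(p1 = c(age = 50, setNames(runif(6, 0, 3),
      c("V.HC", "V.LC", "A.HC", "A.LC", "AV.HC", "AV.LC")))))
    pc <- av_minus_v(r, "delta")
    expect_equal(av_minus_v(r, "delta", "collapsed")$collapsed,
                 (pc$HC + pc$LC) / 2)
  }
})

test_that("optimal-combination gap is Pythagorean and matches a duplicate route", {
  expect_equal(optimal_combination_gap(5, 3, 4), 0)
  expect_equal(optimal_combination_gap(1, 0, 0), 1)
  set.seed(6)
  av <- rnorm(20); v <- rnorm(20); a <- rnorm(20)
  direct <- vapply(1:20, function(i) av[i] - sqrt(v[i]^2 + a[i]^2), numeric(1))
  expect_equal(optimal_combination_gap(av, v, a), direct)
})

test_that("inverse-effectiveness selects the optimal unisensory cell per coherence", {
  # V best at HC, A best at LC: the unisensory reference switches modality
  est <- est_table(list(p1 = c(age = 30, V.HC = 2, V.LC = 1, A.HC = 1,
                               A.LC = 2, AV.HC = 3, AV.LC = 3)))
  expect_equal(moie(est, "delta")$moie, (3 - 2) - (3 - 2))
  # all cells equal -> zero for every parameter
  eqv <- est_table(list(p1 = c(age = 30, V.HC = 1, V.LC = 1, A.HC = 1,
                               A.LC = 1, AV.HC = 1, AV.LC = 1)))
  expect_equal(moie(eqv, "delta")$moie, 0)
  # translation invariance
  base <- est_table(list(p1 = c(age = 30, V.HC = 1.3, V.LC = 0.6, A.HC = 0.9,
                                A.LC = 1.1, AV.HC = 1.8, AV.LC = 1.4)))
  shift <- base; shift$delta <- shift$delta + 2.7
  expect_equal(moie(base, "delta")$moie, moie(shift, "delta")$moie)
  # for theta/tau the optimum is the lowest cell
  th <- base
  th$theta <- c(1.2, 1.4, 1.3, 1.1, 1.25, 1.5)  # V.HC,V.LC,A.HC,A.LC,AV.HC,AV.LC
  expect_equal(moie(th, "theta")$moie, (1.5 - 1.1) - (1.25 - 1.2))
})

test_that("inverse effectiveness on generator truth equals the hand formula", {
  sim <- quick_trials(5, seed = 91)
  truth <- sim$truth
  m <- moie(truth, "delta")
  for (id in unique(truth$participant_id)) {
    g <- function(cond, coh) truth$delta[truth$participant_id == id &
      truth$condition == cond & truth$coherence == coh]
    hand <- (g("AV", "LC") - max(g("V", "LC"), g("A", "LC"))) -
      (g("AV", "HC") - max(g("V", "HC"), g("A", "HC")))
    expect_equal(m$moie[m$participant_id == id], hand)
  }
})

test_that("age correlations: exact, degenerate and null behaviour", {
  ages <- c(20, 35, 50, 65, 80)
  perf <- age_correlation(2 * ages, ages)
  expect_equal(perf$r, 1)
  # hand-computed Pearson R on fixed 5-point vectors
  v <- c(3, 1, 4, 1, 5)
  hand <- sum((v - mean(v)) * (ages - mean(ages))) /
    sqrt(sum((v - mean(v))^2) * sum((ages - mean(ages))^2))
  got <- age_correlation(v, ages)
  expect_equal(got$r, hand)
  expect_true(got$ci[1] <= got$r && got$r <= got$ci[2])
  # independent values: small R, non-significant most of the time
  set.seed(7)
  big <- age_correlation(rnorm(2000), runif(2000, 18, 90))
  expect_lt(abs(big$r), 0.07)
  expect_error(age_correlation(rep(1, 10), runif(10)), "zero variance")
  expect_error(age_correlation(c(1, 2), c(3, 4)), "pairs")
})

test_that("participant estimates and the benefit report assemble coherently", {
  fit <- cached_fit()$post
  est <- participant_estimates(fit)
  P <- nrow(fit$model$participants)
  expect_equal(nrow(est), P * 6)
  expect_true(all(est$theta > 0) && all(est$tau >= 0))
  br <- benefit_report(est)
  expect_equal(nrow(br$participants), P)
  # collapsed AV-V equals the mean of the per-coherence columns
  expect_equal(br$participants$av_v_delta_collapsed,
               (br$participants$av_v_delta_HC + br$participants$av_v_delta_LC) / 2)
  # every correlation row carries its R inside the CI
  expect_true(all(br$correlations$ci_lower <= br$correlations$r &
                    br$correlations$r <= br$correlations$ci_upper))
  # median point estimates are also available
  estm <- participant_estimates(fit, point = "median")
  expect_equal(dim(estm), dim(est))
})
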