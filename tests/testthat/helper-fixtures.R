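# shared fixtures: all synthetic, generated in code at test time

quick_trials <- function(n_participants = 6, seed = 101, drop_timeouts = TRUE) {
  sim <- simulate_dataset(design_spec(), age_generative_model(),
                          n_participants, seed = seed)
  if (drop_timeouts) sim$trials <- sim$trials[!sim$trials$timeout, ]
  sim
}

# a small fitted posterior reused across diagnostic/metric tests
cached_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- quick_trials(6, seed = 303)
      cache <<- list(
        sim = sim,
        post = fit_hddm(sim$trials, variant = 8, n_chains = 2, n_iter = 600,
                        burn_in = 100, thin = 2, seed = 303,
                        age_threshold = median(unique(sim$trials$age))))
    }
    cache
  }
})

# cumulative sub-CDF of one boundary by trapezoid quadrature on a fine grid
analytic_subcdf <- function(params, boundary, tmax, n = 2000L) {
  grid <- seq(params$tau + 1e-4, tmax, length.out = n)
  f <- wfpt_density(grid, boundary, params)
  dF <- (f[-1] + f[-n]) / 2 * diff(grid)
  list(t = grid[-1], F = cumsum(dF))
}

# hand-rolled trial table for preprocessing tests
toy_trials <- function(rts, correct = NULL, id = "p1") {
  n <- length(rts)
  if (is.null(correct)) correct <- rep(TRUE, n)
  data.frame(participant_id = rep(id, n), age = rep(30, n),
             block = rep(1L, n), trial = seq_len(n),
             condition = rep(c("V", "A", "AV"), length.out = n),
             coherence = rep(c("HC", "LC"), length.out = n),
             category = rep("face", n),
             rt = rts, response = ifelse(correct, "face", "car"),
             correct = correct,
             timeout = is.na(rts), stringsAsFactors = FALSE)
}
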