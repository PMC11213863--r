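#' Age-structured generative model for decision-process parameters
#'
#' Defines how diffusion-model parameters (drift rate delta, boundary
#' separation theta, non-decision time tau) change with age across the six
#' condition-by-coherence cells, and how much participants scatter around
#' those age trends. Unisensory (V, A) drift cells carry free intercepts and
#' per-year slopes; the audiovisual drift is derived as the optimal
#' combination of the two unisensory drifts, `sqrt(delta_V^2 + delta_A^2)`,
#' plus an age-increasing benefit applied at high coherence only. Boundary
#' and non-decision intercepts/slopes are free in all six cells.
#'
#' Default slopes encode the qualitative age structure the analysis is
#' designed to detect: drift decreasing with age in every cell; boundary
#' increasing with age in the A/LC, AV/LC and V/HC cells; non-decision time
#' increasing with age in V/LC only.
#'
#' @param delta_intercept,delta_slope named vectors over the four unisensory
#'   cells (`V.HC`, `V.LC`, `A.HC`, `A.LC`): drift at the reference age and
#'   change per year.
#' @param theta_intercept,theta_slope named vectors over all six cells.
#' @param tau_intercept,tau_slope named vectors over all six cells (seconds).
#' @param delta_spread,theta_spread,tau_spread between-participant SD added
#'   to each cell value.
#' @param delta_floor,theta_floor,tau_floor positivity floors applied after
#'   the participant-level draw.
#' @param av_benefit_slope per-year increase of the AV high-coherence drift
#'   above the optimal unisensory combination.
#' @param reference_age age (years) at which intercepts apply.
#' @param age_range admissible ages, drawn uniformly by default.
#' @return an object of class `age_generative_model`.
#' @export
age_generative_model <- function(
    delta_intercept = c(V.HC = 2.5, V.LC = 1.5, A.HC = 2.2, A.LC = 1.3),
    delta_slope = c(V.HC = -0.012, V.LC = -0.009, A.HC = -0.011, A.LC = -0.008),
    theta_intercept = c(V.HC = 1.4, V.LC = 1.5, A.HC = 1.4, A.LC = 1.5,
                        AV.HC = 1.4, AV.LC = 1.5),
    theta_slope = c(V.HC = 0.006, V.LC = 0, A.HC = 0, A.LC = 0.006,
                    AV.HC = 0, AV.LC = 0.006),
    tau_intercept = c(V.HC = 0.35, V.LC = 0.35, A.HC = 0.35, A.LC = 0.35,
                      AV.HC = 0.35, AV.LC = 0.35),
    tau_slope = c(V.HC = 0, V.LC = 0.0015, A.HC = 0, A.LC = 0,
                  AV.HC = 0, AV.LC = 0),
    delta_spread = 0.3, theta_spread = 0.15, tau_spread = 0.04,
    delta_floor = 0.05, theta_floor = 0.3, tau_floor = 0.1,
    av_benefit_slope = 0.02, reference_age = 18,
    age_range = c(18, 90)) {
  uni <- c("V.HC", "V.LC", "A.HC", "A.LC")
  all6 <- .cell6_labels()
  stopifnot(all(uni %in% names(delta_intercept)),
            all(uni %in% names(delta_slope)),
            all(all6 %in% names(theta_intercept)),
            all(all6 %in% names(theta_slope)),
            all(all6 %in% names(tau_intercept)),
            all(all6 %in% names(tau_slope)),
            delta_floor > 0, theta_floor > 0, tau_floor >= 0,
            av_benefit_slope >= 0,
            length(age_range) == 2, age_range[1] < age_range[2])
  structure(list(delta_intercept = delta_intercept[uni],
                 delta_slope = delta_slope[uni],
                 theta_intercept = theta_intercept[all6],
                 theta_slope = theta_slope[all6],
                 tau_intercept = tau_intercept[all6],
                 tau_slope = tau_slope[all6],
                 delta_spread = delta_spread, theta_spread = theta_spread,
                 tau_spread = tau_spread, delta_floor = delta_floor,
                 theta_floor = theta_floor, tau_floor = tau_floor,
                 av_benefit_slope = av_benefit_slope,
                 reference_age = reference_age, age_range = age_range),
            class = "age_generative_model")
}

# cell means implied by the generative model at a given age (before noise)
.cell_means <- function(age, gen) {
  a <- age - gen$reference_age
  d_uni <- pmax(gen$delta_intercept + gen$delta_slope * a, gen$delta_floor)
  d <- c(V.HC = unname(d_uni["V.HC"]), V.LC = unname(d_uni["V.LC"]),
         A.HC = unname(d_uni["A.HC"]), A.LC = unname(d_uni["A.LC"]),
         AV.HC = sqrt(d_uni[["V.HC"]]^2 + d_uni[["A.HC"]]^2) +
           gen$av_benefit_slope * a,
         AV.LC = sqrt(d_uni[["V.LC"]]^2 + d_uni[["A.LC"]]^2))
  th <- gen$theta_intercept + gen$theta_slope * a
  ta <- gen$tau_intercept + gen$tau_slope * a
  list(delta = d[.cell6_labels()], theta = th[.cell6_labels()],
       tau = ta[.cell6_labels()])
}

#' Draw one participant's diffusion parameters
#'
#' Evaluates the age trends of an [age_generative_model()] at the given age,
#' adds between-participant noise, and applies the positivity floors. With
#' zero spread the returned values are exactly the model's cell means, so the
#' AV high-coherence drift equals `sqrt(delta_V^2 + delta_A^2)` plus the age
#' benefit.
#'
#' @param age participant age in years; must lie inside `gen$age_range`.
#' @param gen an [age_generative_model()].
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return data frame with one row per condition-by-coherence cell and
#'   columns `condition`, `coherence`, `delta`, `theta`, `tau`.
#' @export
sample_participant_params <- function(age, gen, seed = NULL) {
  stopifnot(inherits(gen, "age_generative_model"),
            age >= gen$age_range[1], age <= gen$age_range[2])
  draw <- function() {
    m <- .cell_means(age, gen)
    lab <- .cell6_labels()
    data.frame(
      condition = rep(.conditions, each = 2),
      coherence = rep(.coherences, times = 3),
      delta = pmax(m$delta + gen$delta_spread * rnorm(6), gen$delta_floor),
      theta = pmax(m$theta + gen$theta_spread * rnorm(6), gen$theta_floor),
      tau = pmax(m$tau + gen$tau_spread * rnorm(6), gen$tau_floor),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  if (is.null(seed)) draw() else with_preserved_seed(seed, draw())
}

#' Simulate one decision-process trial
#'
#' Draws a first-passage time of the unit-variance diffusion with the given
#' parameters and reports it against the response deadline. The upper
#' boundary codes a correct response (accuracy coding).
#'
#' @param delta,theta,tau,z diffusion parameters (drift, boundary separation,
#'   non-decision time in seconds, relative start point).
#' @param deadline_ms response deadline in milliseconds.
#' @param method `"exact"` (inverse-CDF sampling from the first-passage
#'   distribution) or `"euler"` (Euler-Maruyama path with bridge-crossing
#'   correction).
#' @return list with `rt_ms` (numeric or `NA`), `correct` (logical or `NA`)
#'   and `timeout` (logical).
#' @export
simulate_trial <- function(delta, theta, tau, z = 0.5, deadline_ms = 3000,
                           method = c("exact", "euler")) {
  sim <- simulate_wiener(1L, delta, theta, tau, z, method = method)
  rt_ms <- sim$rt * 1000
  if (rt_ms > deadline_ms) {
    list(rt_ms = NA_real_, correct = NA, timeout = TRUE)
  } else {
    list(rt_ms = rt_ms, correct = sim$correct, timeout = FALSE)
  }
}

#' Simulate a full behavioural dataset with ground truth
#'
#' Composes [build_design()], [sample_participant_params()] and the trial
#' simulator under a single root seed: ages are drawn uniformly over the
#' generative model's range, each participant receives a pseudorandomised
#' balanced session, and every trial outcome is sampled from the Wiener
#' first-passage distribution of its cell's parameters. Reaction times are
#' serialised in milliseconds; first-passage times exceeding the deadline
#' are recorded as timeouts with missing RT/response/correctness.
#'
#' @param spec a [design_spec()].
#' @param gen an [age_generative_model()].
#' @param n_participants cohort size.
#' @param seed root seed; all sub-streams derive from it.
#' @return list with `trials` (one row per trial) and `truth` (one row per
#'   participant-cell with the generating `delta`, `theta`, `tau`).
#' @export
simulate_dataset <- function(spec, gen, n_participants, seed = 1L) {
  stopifnot(inherits(spec, "design_spec"), inherits(gen, "age_generative_model"))
  empty <- function() {
    list(trials = data.frame(participant_id = character(), age = numeric(),
                             block = integer(), trial = integer(),
                             condition = character(), coherence = character(),
                             category = character(), rt = numeric(),
                             response = character(), correct = logical(),
                             timeout = logical(), stringsAsFactors = FALSE),
         truth = data.frame(participant_id = character(), age = numeric(),
                            condition = character(), coherence = character(),
                            delta = numeric(), theta = numeric(),
                            tau = numeric(), stringsAsFactors = FALSE))
  }
  if (n_participants == 0) return(empty())
  with_preserved_seed(seed, {
    ages <- runif(n_participants, gen$age_range[1], gen$age_range[2])
    design <- build_design(spec, n_participants, seed = sample.int(2^30, 1))
    ids <- unique(design$participant_id)
    truth <- vector("list", n_participants)
    trial_rows <- vector("list", n_participants)
    for (i in seq_len(n_participants)) {
      pars <- sample_participant_params(ages[i], gen)
      truth[[i]] <- cbind(participant_id = ids[i], age = ages[i], pars,
                          stringsAsFactors = FALSE)
      dsub <- design[design$participant_id == ids[i], , drop = FALSE]
      dsub$age <- ages[i]
      dsub$rt <- NA_real_
      dsub$response <- NA_character_
      dsub$correct <- NA
      dsub$timeout <- FALSE
      for (r in seq_len(nrow(pars))) {
        sel <- which(dsub$condition == pars$condition[r] &
                       dsub$coherence == pars$coherence[r])
        if (!length(sel)) next
        sim <- simulate_wiener(length(sel), pars$delta[r], pars$theta[r],
                               pars$tau[r], 0.5, method = "exact")
        rt_ms <- sim$rt * 1000
        to <- rt_ms > spec$deadline_ms
        dsub$timeout[sel] <- to
        keep <- sel[!to]
        dsub$rt[keep] <- rt_ms[!to]
        dsub$correct[keep] <- sim$correct[!to]
        other <- ifelse(dsub$category[keep] == spec$categories[1],
                        spec$categories[2], spec$categories[1])
        dsub$response[keep] <- ifelse(sim$correct[!to], dsub$category[keep], other)
      }
      trial_rows[[i]] <- dsub
    }
    trials <- do.call(rbind, trial_rows)
    trials <- trials[, c("participant_id", "age", "block", "trial", "condition",
                         "coherence", "category", "rt", "response", "correct",
                         "timeout")]
    rownames(trials) <- NULL
    list(trials = trials, truth = do.call(rbind, truth))
  })
}
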