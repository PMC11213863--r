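#' Diffusion-model parameter set
#'
#' Bundles the parameters of the two-boundary Wiener diffusion with unit
#' diffusion coefficient: drift rate `delta` (evidence/s), boundary
#' separation `theta` (evidence units), non-decision time `tau` (seconds)
#' and relative starting point `z`, fixed at the unbiased midpoint 0.5
#' throughout this package.
#'
#' @param delta drift rate; may be negative.
#' @param theta boundary separation; strictly positive.
#' @param tau non-decision time in seconds; non-negative.
#' @param z relative starting point in (0, 1).
#' @return an object of class `wiener_params`.
#' @export
wiener_params <- function(delta, theta, tau, z = 0.5) {
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0")
  if (!is.finite(tau) || tau < 0) stop("tau must be >= 0")
  if (!is.finite(z) || z <= 0 || z >= 1) stop("z must lie in (0, 1)")
  structure(list(delta = delta, theta = theta, tau = tau, z = z),
            class = "wiener_params")
}

#' Wiener first-passage-time density
#'
#' Joint density of absorbing at the given boundary at clock time `t`
#' (seconds), evaluated by the dual small-time/large-time series with the
#' truncation chosen adaptively so the absolute error stays below `eps`;
#' at each point the branch needing fewer terms is used. Under accuracy
#' coding the upper boundary is the correct response. Zero for `t <= tau`.
#'
#' @param t evaluation times in seconds (vectorised).
#' @param boundary `"upper"` or `"lower"`.
#' @param params a [wiener_params()].
#' @param eps absolute error tolerance per evaluation.
#' @return density values (1/s).
#' @export
wfpt_density <- function(t, boundary = c("upper", "lower"), params,
                         eps = 1e-7) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "wiener_params"), eps > 0)
  wfpt_pdf_cpp(as.numeric(t), as.integer(boundary == "upper"),
               params$delta, params$theta, params$tau, params$z, eps)
}

#' Boundary absorption probability
#'
#' Closed-form probability that the diffusion is absorbed at the given
#' boundary; the two boundaries' probabilities sum to one.
#'
#' @inheritParams wfpt_density
#' @return a probability.
#' @export
choice_probability <- function(params, boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  stopifnot(inherits(params, "wiener_params"))
  choice_prob_cpp(params$delta, params$theta, params$z,
                  as.integer(boundary == "upper"))
}

#' Sample first-passage outcomes of the Wiener diffusion
#'
#' Two samplers are provided. `"exact"` draws the boundary from the
#' closed-form absorption probability and the passage time by inverse-CDF
#' lookup on a dense adaptive grid of the first-passage density. `"euler"`
#' simulates the diffusion path by Euler-Maruyama steps with a
#' Brownian-bridge correction for within-step boundary crossings, and is
#' fully independent of the series density (useful as a cross-check).
#'
#' @param n number of trials.
#' @param delta,theta,tau,z diffusion parameters (times in seconds).
#' @param method sampling algorithm.
#' @param dt Euler step size in seconds (`method = "euler"`).
#' @param eps density tolerance for the grid construction (`method = "exact"`).
#' @return data frame with `rt` (seconds, includes `tau`) and `correct`
#'   (logical; upper boundary).
#' @export
simulate_wiener <- function(n, delta, theta, tau, z = 0.5,
                            method = c("exact", "euler"), dt = 1e-4,
                            eps = 1e-7) {
  method <- match.arg(method)
  if (!is.finite(theta) || theta <= 0) stop("theta must be > 0")
  if (tau < 0) stop("tau must be >= 0")
  sim <- if (method == "exact") {
    sim_wiener_cdf_cpp(as.integer(n), delta, theta, tau, z, eps)
  } else {
    if (dt > 1e-4) stop("dt must be <= 1e-4 s")
    sim_wiener_em_cpp(as.integer(n), delta, theta, tau, z, dt)
  }
  data.frame(rt = sim$rt, correct = sim$upper == 1L)
}

#' Trial-table log-likelihood
#'
#' Sums the log Wiener first-passage density over a preprocessed trial table
#' (no timeouts), accuracy-coded: correct responses are evaluated at the
#' upper boundary, incorrect at the lower. Reaction times in the table are
#' in milliseconds and are converted to seconds here, at the module
#' boundary. Returns `-Inf` when any trial's RT is at or below its cell's
#' non-decision time.
#'
#' @param trials data frame with columns `participant_id`, `condition`,
#'   `coherence`, `rt` (ms), `correct`.
#' @param params data frame mapping `participant_id`, `condition`,
#'   `coherence` to `delta`, `theta`, `tau`.
#' @param z relative starting point.
#' @param eps density tolerance.
#' @return total log-likelihood (0 for an empty table).
#' @export
log_likelihood <- function(trials, params, z = 0.5, eps = 1e-7) {
  if (nrow(trials) == 0) return(0)
  key <- function(d) paste(d$participant_id, d$condition, d$coherence, sep = "|")
  idx <- match(key(trials), key(params))
  if (anyNA(idx)) {
    miss <- unique(key(trials)[is.na(idx)])
    stop("no parameters for cell(s): ", paste(miss, collapse = ", "))
  }
  ll <- wfpt_logdens_cpp(trials$rt / 1000, as.integer(trials$correct),
                         params$delta[idx], params$theta[idx],
                         params$tau[idx], z, eps)
  sum(ll)
}
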