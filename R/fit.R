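#' The eight conditional-dependency model variants
#'
#' Each variant declares which of the three diffusion parameters (drift
#' `delta`, boundary `theta`, non-decision `tau`) are free to vary across
#' the conditional-dependency cells (sensory condition x stimulus coherence
#' x age group, at most 12 cells per parameter family); the remaining
#' parameters are shared across all cells. The eight variants are the
#' 2^3 subsets, from variant 1 (nothing varies) to variant 8 (all three
#' vary).
#'
#' @param id variant id in 1..8.
#' @return object of class `model_variant` with elements `id` and `varies`.
#' @export
model_variant <- function(id) {
  stopifnot(length(id) == 1, id %in% 1:8)
  subsets <- list(character(0), "delta", "theta", "tau",
                  c("delta", "theta"), c("delta", "tau"),
                  c("theta", "tau"), c("delta", "theta", "tau"))
  structure(list(id = as.integer(id), varies = subsets[[id]]),
            class = "model_variant")
}

#' Assign participants to age groups
#'
#' Deterministic split of chronological age into younger (`YA`) and older
#' (`OA`) adults at a configurable threshold; ages at or above the threshold
#' are `OA`.
#'
#' @param age ages in years (vectorised).
#' @param threshold split age in years.
#' @return character vector of `"YA"`/`"OA"` labels.
#' @export
assign_age_group <- function(age, threshold = 60) {
  ifelse(age >= threshold, "OA", "YA")
}

#' Build the hierarchical model for a trial table
#'
#' Prepares a preprocessed trial table (no timeouts, RTs in ms) for
#' sampling: converts RTs to seconds, indexes participants and
#' condition-by-coherence cells, assigns age groups, and verifies that every
#' conditional-dependency cell required by the variant contains trials.
#' Participant-level `delta`/`theta`/`tau` nodes are drawn from group-level
#' normal distributions (mean and spread per cell, or shared when a
#' parameter does not vary), the starting point is fixed at 0.5, and
#' inter-trial variabilities are fixed at 0.
#'
#' @param variant a [model_variant()] (or an id in 1..8).
#' @param trials preprocessed trial table with `participant_id`, `age`,
#'   `condition`, `coherence`, `rt` (ms), `correct`.
#' @param age_threshold years; passed to [assign_age_group()].
#' @return object of class `hddm_model`.
#' @export
build_model <- function(variant, trials, age_threshold = 60) {
  if (!inherits(variant, "model_variant")) variant <- model_variant(variant)
  stopifnot(nrow(trials) > 0, !any(is.na(trials$rt)), !any(is.na(trials$correct)))
  participants <- unique(trials[, c("participant_id", "age")])
  if (anyDuplicated(participants$participant_id))
    stop("inconsistent ages within participant")
  participants$age_group <- assign_age_group(participants$age, age_threshold)
  pidx <- match(trials$participant_id, participants$participant_id)
  ci <- match(trials$condition, .conditions)
  hi <- match(trials$coherence, .coherences)
  if (anyNA(ci) || anyNA(hi)) stop("unknown condition/coherence labels")
  cell6 <- (ci - 1L) * 2L + (hi - 1L)

  if (length(variant$varies) > 0) {
    ag <- participants$age_group[pidx]
    have <- unique(paste(.cell6_labels()[cell6 + 1L], ag, sep = "."))
    missing <- setdiff(.cell12_labels(), have)
    if (length(missing))
      stop("no trials in conditional-dependency cell(s): ",
           paste(missing, collapse = ", "))
  }

  structure(list(
    variant = variant,
    participants = participants,
    rt = trials$rt / 1000,
    correct = as.integer(trials$correct),
    cell6 = cell6,
    pid = pidx - 1L,
    age_threshold = age_threshold,
    priors = list(mu0 = c(delta = 0, theta = 1.5, tau = 0.3),
                  sd0 = c(delta = 5, theta = 2, tau = 0.3),
                  sigma_hn = 2),
    init_scale = c(delta = 0.5, theta = 0.2, tau = 0.05)),
    class = "hddm_model")
}

# node names in the exact column order emitted by the sampler
.node_names <- function(model) {
  varies <- .conditions_vary(model$variant)
  pnames <- c("delta", "theta", "tau")
  gcells <- lapply(pnames, function(p)
    if (varies[p]) .cell12_labels() else "shared")
  mu <- unlist(lapply(1:3, function(p)
    paste0("mu_", pnames[p], "[", gcells[[p]], "]")))
  sg <- unlist(lapply(1:3, function(p)
    paste0("sigma_", pnames[p], "[", gcells[[p]], "]")))
  ids <- model$participants$participant_id
  part <- unlist(lapply(1:3, function(p) {
    cells <- if (varies[p]) .cell6_labels() else NULL
    if (is.null(cells)) paste0(pnames[p], "[", ids, "]")
    else as.vector(t(outer(ids, cells, function(i, c)
      paste0(pnames[p], "[", i, ".", c, "]"))))
  }))
  c(mu, sg, part)
}

.conditions_vary <- function(variant) {
  setNames(c("delta", "theta", "tau") %in% variant$varies,
           c("delta", "theta", "tau"))
}

#' Sample the posterior by Metropolis-within-Gibbs
#'
#' Runs independent Markov chains of single-site normal random-walk updates
#' over all participant- and group-level nodes against the exact Wiener
#' first-passage likelihood. Proposal scales adapt during burn-in only and
#' are frozen afterwards, preserving detailed balance on the retained
#' draws. The deviance (-2 log-likelihood) is recorded at every retained
#' draw. Per chain, `(n_iter - burn_in) / thin` draws are retained; the
#' defaults (5 chains of 11,000 iterations, 1,000 burn-in, thinning by 2)
#' retain 25,000 pooled draws.
#'
#' @param model an [build_model()] result.
#' @param n_chains number of independent chains.
#' @param n_iter iterations per chain.
#' @param burn_in iterations discarded at the start of each chain.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param seed root seed; per-chain streams derive from it.
#' @return object of class `hddm_posterior`: a draws array
#'   (iterations x nodes x chains), a deviance matrix, metadata, and the
#'   model.
#' @export
sample_posterior <- function(model, n_chains = 5, n_iter = 11000,
                             burn_in = 1000, thin = 2, seed = 1L) {
  stopifnot(inherits(model, "hddm_model"), n_chains >= 1,
            n_iter > burn_in, (n_iter - burn_in) %% thin == 0)
  varies <- .conditions_vary(model$variant)
  P <- nrow(model$participants)
  agegrp <- as.integer(model$participants$age_group == "OA")
  nodes <- .node_names(model)
  n_ret <- (n_iter - burn_in) / thin

  draws <- array(NA_real_, dim = c(n_ret, length(nodes), n_chains),
                 dimnames = list(NULL, nodes, paste0("chain", seq_len(n_chains))))
  deviance <- matrix(NA_real_, n_ret, n_chains)
  accept <- data.frame(chain = seq_len(n_chains), participant = NA_real_,
                       group = NA_real_)
  adapt_logs <- vector("list", n_chains)

  chain_seeds <- with_preserved_seed(seed, sample.int(2^30, n_chains))
  for (ch in seq_len(n_chains)) {
    res <- with_preserved_seed(chain_seeds[ch],
      hddm_mcmc_cpp(model$rt, model$correct, model$cell6, model$pid,
                    P, agegrp, unname(varies),
                    as.integer(n_iter), as.integer(burn_in), as.integer(thin),
                    unname(model$priors$mu0), unname(model$priors$sd0),
                    model$priors$sigma_hn, unname(model$init_scale)))
    draws[, , ch] <- res$draws
    deviance[, ch] <- res$deviance
    accept$participant[ch] <- res$accept_participant
    accept$group[ch] <- res$accept_group
    adapt_logs[[ch]] <- res$adapt_log
  }
  structure(list(
    draws = draws, deviance = deviance,
    meta = list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                thin = thin, seed = seed, variant_id = model$variant$id,
                retained_per_chain = n_ret, pooled_draws = n_ret * n_chains,
                priors = model$priors, age_threshold = model$age_threshold,
                acceptance = accept, adapt_logs = adapt_logs),
    model = model), class = "hddm_posterior")
}

#' Fit one model variant to a trial table
#'
#' Convenience wrapper: [build_model()] followed by [sample_posterior()].
#'
#' @inheritParams build_model
#' @inheritParams sample_posterior
#' @export
fit_hddm <- function(trials, variant = 8, n_chains = 5, n_iter = 11000,
                     burn_in = 1000, thin = 2, seed = 1L, age_threshold = 60) {
  model <- build_model(variant, trials, age_threshold)
  sample_posterior(model, n_chains, n_iter, burn_in, thin, seed)
}

#' @export
print.hddm_posterior <- function(x, ...) {
  cat("Hierarchical diffusion posterior (variant", x$meta$variant_id, ")\n")
  cat("  ", x$meta$n_chains, "chains x", x$meta$retained_per_chain,
      "retained draws (", x$meta$pooled_draws, "pooled )\n")
  cat("  ", dim(x$draws)[2], "nodes,",
      nrow(x$model$participants), "participants\n")
  invisible(x)
}

# pooled draws for one node across chains
node_draws <- function(posterior, node) {
  as.vector(posterior$draws[, node, ])
}

# names of group-level (mu/sigma) nodes
group_nodes <- function(posterior, means_only = FALSE) {
  nodes <- dimnames(posterior$draws)[[2]]
  pat <- if (means_only) "^mu_" else "^(mu|sigma)_"
  grep(pat, nodes, value = TRUE)
}

# names of participant-level nodes
participant_nodes <- function(posterior) {
  nodes <- dimnames(posterior$draws)[[2]]
  grep("^(mu|sigma)_", nodes, value = TRUE, invert = TRUE)
}
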