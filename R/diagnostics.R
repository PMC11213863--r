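#' Gelman-Rubin potential scale reduction
#'
#' Classic between/within-chain variance ratio computed on the retained
#' (post burn-in, thinned) draws of one node: with m chains of n draws,
#' W the mean within-chain variance and B the between-chain variance of the
#' chain means scaled by n, the statistic is
#' `sqrt(((n - 1) / n * W + B / n) / W)`. No rank-normalisation is applied.
#'
#' @param posterior an [sample_posterior()] result.
#' @param node node name (see `dimnames(posterior$draws)[[2]]`).
#' @return the scalar potential-scale-reduction statistic.
#' @export
gelman_rubin <- function(posterior, node) {
  x <- posterior$draws[, node, , drop = TRUE]
  if (is.null(dim(x)) || ncol(x) < 2) stop("Gelman-Rubin needs >= 2 chains")
  if (nrow(x) < 2) stop("Gelman-Rubin needs >= 2 retained draws per chain")
  n <- nrow(x)
  W <- mean(apply(x, 2, var))
  B_over_n <- var(colMeans(x))
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Convergence report over nodes
#'
#' Computes the Gelman-Rubin statistic for a set of nodes and compares the
#' maximum against a pass threshold (1.02 by default).
#'
#' @param posterior an [sample_posterior()] result.
#' @param nodes `"group"` (all group-level means and spreads, the default),
#'   `"group_means"`, `"all"`, or an explicit character vector of node names.
#' @param threshold pass when the maximum statistic is below this value.
#' @return list with per-node statistics (`rhat`), `max_rhat`, `threshold`
#'   and `pass`.
#' @export
convergence_report <- function(posterior, nodes = "group", threshold = 1.02) {
  nd <- if (identical(nodes, "group")) group_nodes(posterior)
        else if (identical(nodes, "group_means")) group_nodes(posterior, TRUE)
        else if (identical(nodes, "all")) dimnames(posterior$draws)[[2]]
        else nodes
  rhat <- vapply(nd, function(n) gelman_rubin(posterior, n), numeric(1))
  list(rhat = rhat, max_rhat = max(rhat), threshold = threshold,
       pass = max(rhat) < threshold)
}

#' Deviance information criterion
#'
#' Computes `DIC = Dbar + pD` from the stored deviance trace, where `Dbar`
#' is the mean posterior deviance, `pD = Dbar - D(theta_bar)` the effective
#' number of parameters, and `D(theta_bar)` the deviance at the posterior
#' means of the participant-level nodes (equivalently
#' `DIC = 2 Dbar - D(theta_bar)`).
#'
#' @param posterior an [sample_posterior()] result.
#' @return list of class `dic_result` with `dic`, `mean_deviance`,
#'   `deviance_at_means`, `p_d` and the variant id.
#' @export
dic <- function(posterior) {
  if (is.null(posterior$deviance)) stop("posterior has no deviance trace")
  dbar <- mean(posterior$deviance)
  model <- posterior$model
  est <- .participant_param_matrix(posterior)
  idx <- model$pid * 6L + model$cell6 + 1L
  ll <- wfpt_logdens_cpp(model$rt, model$correct,
                         est$delta[idx], est$theta[idx], est$tau[idx],
                         0.5, 1e-7)
  dhat <- -2 * sum(ll)
  structure(list(dic = 2 * dbar - dhat, mean_deviance = dbar,
                 deviance_at_means = dhat, p_d = dbar - dhat,
                 variant_id = posterior$meta$variant_id),
            class = "dic_result")
}

# posterior-mean participant parameters as P*6 vectors (row-major by
# participant, cell6) for delta/theta/tau
.participant_param_matrix <- function(posterior, point = "mean") {
  model <- posterior$model
  varies <- .conditions_vary(model$variant)
  P <- nrow(model$participants)
  pool <- apply(posterior$draws, 2,
                if (point == "median") median else mean)
  out <- list()
  for (p in c("delta", "theta", "tau")) {
    vals <- matrix(NA_real_, P, 6)
    if (varies[p]) {
      for (k in 1:6) {
        nm <- paste0(p, "[", model$participants$participant_id, ".",
                     .cell6_labels()[k], "]")
        vals[, k] <- pool[nm]
      }
    } else {
      nm <- paste0(p, "[", model$participants$participant_id, "]")
      vals[] <- pool[nm]
    }
    out[[p]] <- as.vector(t(vals))  # participant-major, cell-minor
  }
  out
}

#' Compare model variants by DIC
#'
#' Selects the variant with the lowest DIC and flags the selection as
#' substantial when the gap to the runner-up exceeds 10.
#'
#' @param dic_table data frame with columns `variant` and `dic` (one row
#'   per fitted variant; build from [dic()] results).
#' @return list with `best`, `dic_table` (sorted, with `delta_dic` to the
#'   best), and `substantial`.
#' @export
select_model <- function(dic_table) {
  stopifnot(nrow(dic_table) >= 2, all(c("variant", "dic") %in% names(dic_table)))
  ord <- order(dic_table$dic)
  tab <- dic_table[ord, , drop = FALSE]
  tab$delta_dic <- tab$dic - tab$dic[1]
  list(best = tab$variant[1], dic_table = tab,
       substantial = (tab$dic[2] - tab$dic[1]) > 10)
}

#' Highest-density region of a sample
#'
#' Shortest interval containing `ceiling(mass * n)` of the sorted sample
#' points; when several windows tie on width the one with the lowest start
#' is returned.
#'
#' @param samples numeric vector.
#' @param mass probability mass in (0, 1].
#' @return numeric `c(lower, upper)`.
#' @export
hdr_interval <- function(samples, mass = 0.90) {
  stopifnot(length(samples) > 0, mass > 0, mass <= 1)
  xs <- sort(samples)
  n <- length(xs)
  k <- ceiling(mass * n)
  if (k >= n) return(c(xs[1], xs[n]))
  widths <- xs[k:n] - xs[1:(n - k + 1)]
  i <- which.min(widths)   # which.min takes the first (lowest-start) tie
  c(xs[i], xs[i + k - 1])
}

#' Posterior predictive check
#'
#' For each of `n_draws` retained posterior draws, simulates a full
#' behavioural dataset from that draw's participant-level parameters over
#' the observed trial design, then compares observed per-cell statistics —
#' accuracy and signed-RT deciles (correct responses on the positive axis,
#' incorrect on the negative) — against the 90% highest-density regions of
#' the simulated statistics.
#'
#' @param posterior an [sample_posterior()] result.
#' @param n_draws posterior draws to simulate (>= 2).
#' @param seed seed for draw selection and simulation.
#' @param mass HDR mass for the reference bands.
#' @return data frame with one row per cell and statistic: `cell`,
#'   `statistic`, `observed`, `hdr_lower`, `hdr_upper`, `inside`; cells
#'   without observed trials are skipped with a note attribute.
#' @export
posterior_predictive_check <- function(posterior, n_draws = 200, seed = 1L,
                                       mass = 0.90) {
  if (n_draws < 2) stop("n_draws must be >= 2")
  model <- posterior$model
  P <- nrow(model$participants)
  varies <- .conditions_vary(model$variant)
  qs <- seq(0.1, 0.9, by = 0.1)

  cell_stats <- function(rt, correct, cell6) {
    # signed-RT deciles and accuracy per cell6
    out <- list()
    for (k in 0:5) {
      sel <- cell6 == k
      lab <- .cell6_labels()[k + 1]
      if (!any(sel)) { out[[lab]] <- NULL; next }
      signed <- ifelse(correct[sel] == 1, rt[sel], -rt[sel])
      out[[lab]] <- c(accuracy = mean(correct[sel]),
                      setNames(quantile(signed, qs, names = FALSE),
                               paste0("q", qs * 100)))
    }
    out
  }

  obs <- cell_stats(model$rt, model$correct, model$cell6)
  empty_cells <- setdiff(.cell6_labels(), names(obs))

  # per-participant trial counts per cell
  counts <- matrix(0L, P, 6)
  for (i in seq_len(nrow(counts)))
    for (k in 0:5) counts[i, k + 1] <- sum(model$pid == i - 1 & model$cell6 == k)

  draw_param <- function(node_vals, p, i, k) {
    if (varies[p]) node_vals[paste0(p, "[", model$participants$participant_id[i],
                                    ".", .cell6_labels()[k], "]")]
    else node_vals[paste0(p, "[", model$participants$participant_id[i], "]")]
  }

  n_ret <- dim(posterior$draws)[1]
  n_ch <- dim(posterior$draws)[3]
  sims <- with_preserved_seed(seed, {
    pick_it <- sample.int(n_ret, n_draws, replace = n_draws > n_ret)
    pick_ch <- sample.int(n_ch, n_draws, replace = TRUE)
    lapply(seq_len(n_draws), function(d) {
      nv <- posterior$draws[pick_it[d], , pick_ch[d]]
      rt <- numeric(0); correct <- integer(0); c6 <- integer(0)
      for (i in seq_len(P)) for (k in 1:6) {
        nk <- counts[i, k]
        if (nk == 0) next
        s <- sim_wiener_cdf_cpp(nk, draw_param(nv, "delta", i, k),
                                max(draw_param(nv, "theta", i, k), 1e-3),
                                max(draw_param(nv, "tau", i, k), 0),
                                0.5, 1e-5, 2000L)
        rt <- c(rt, s$rt); correct <- c(correct, s$upper)
        c6 <- c(c6, rep(k - 1L, nk))
      }
      cell_stats(rt, correct, c6)
    })
  })

  rows <- list()
  for (lab in names(obs)) {
    stats <- names(obs[[lab]])
    for (s in stats) {
      simvals <- vapply(sims, function(x) x[[lab]][[s]], numeric(1))
      hdr <- hdr_interval(simvals, mass)
      rows[[paste(lab, s)]] <- data.frame(
        cell = lab, statistic = s, observed = obs[[lab]][[s]],
        hdr_lower = hdr[1], hdr_upper = hdr[2],
        inside = obs[[lab]][[s]] >= hdr[1] & obs[[lab]][[s]] <= hdr[2],
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "skipped_cells") <- empty_cells
  attr(out, "mass") <- mass
  out
}
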