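#' Per-participant posterior point estimates
#'
#' Summarises the participant-level nodes of a fitted posterior into one
#' point estimate (posterior mean by default, median on request) of
#' `delta`, `theta` and `tau` for every condition-by-coherence cell;
#' parameters that do not vary in the fitted variant are replicated across
#' cells.
#'
#' @param posterior an [sample_posterior()] result.
#' @param point `"mean"` or `"median"`.
#' @return data frame with `participant_id`, `age`, `condition`,
#'   `coherence`, `delta`, `theta`, `tau`.
#' @export
participant_estimates <- function(posterior, point = c("mean", "median")) {
  point <- match.arg(point)
  model <- posterior$model
  P <- nrow(model$participants)
  m <- .participant_param_matrix(posterior, point)
  data.frame(
    participant_id = rep(model$participants$participant_id, each = 6),
    age = rep(model$participants$age, each = 6),
    condition = rep(rep(.conditions, each = 2), times = P),
    coherence = rep(.coherences, times = 3 * P),
    delta = m$delta, theta = m$theta, tau = m$tau,
    row.names = NULL, stringsAsFactors = FALSE)
}

.get_cell <- function(est, id, cond, coh, parameter) {
  v <- est[est$participant_id == id & est$condition == cond &
             est$coherence == coh, parameter]
  if (length(v) != 1 || is.na(v))
    stop("missing estimate for cell ", cond, ".", coh, " of ", id)
  v
}

#' Multisensory-minus-visual contrasts
#'
#' Difference between the audiovisual and visual cell estimate of one
#' parameter, per coherence level or collapsed (averaged) across the two
#' coherence levels.
#'
#' @param est a [participant_estimates()] table.
#' @param parameter `"delta"`, `"theta"` or `"tau"`.
#' @param mode `"per_coherence"` or `"collapsed"`.
#' @return data frame with `participant_id`, `age` and either `HC`/`LC`
#'   columns or a single `collapsed` column.
#' @export
av_minus_v <- function(est, parameter = c("delta", "theta", "tau"),
                       mode = c("per_coherence", "collapsed")) {
  parameter <- match.arg(parameter)
  mode <- match.arg(mode)
  ids <- unique(est$participant_id)
  out <- data.frame(participant_id = ids,
                    age = est$age[match(ids, est$participant_id)],
                    stringsAsFactors = FALSE)
  for (coh in .coherences) {
    out[[coh]] <- vapply(ids, function(id)
      .get_cell(est, id, "AV", coh, parameter) -
        .get_cell(est, id, "V", coh, parameter), numeric(1))
  }
  if (mode == "collapsed") {
    out$collapsed <- (out$HC + out$LC) / 2
    out$HC <- out$LC <- NULL
  }
  out
}

#' Optimal-combination drift gap
#'
#' Difference between an observed audiovisual drift rate and the optimal
#' combination of the two unisensory drifts,
#' `delta_AV - sqrt(delta_V^2 + delta_A^2)`. Positive gaps indicate
#' super-optimal multisensory evidence accumulation.
#'
#' @param delta_av,delta_v,delta_a drift rates (vectorised).
#' @return numeric gaps.
#' @export
optimal_combination_gap <- function(delta_av, delta_v, delta_a) {
  delta_av - sqrt(delta_v^2 + delta_a^2)
}

#' Per-participant optimal-combination gaps
#'
#' Applies [optimal_combination_gap()] to each participant's drift
#' estimates at both coherence levels.
#'
#' @param est a [participant_estimates()] table.
#' @return data frame with `participant_id`, `age`, `HC`, `LC` gap columns
#'   and the optimal combinations themselves (`opt_HC`, `opt_LC`).
#' @export
participant_opt_gaps <- function(est) {
  ids <- unique(est$participant_id)
  out <- data.frame(participant_id = ids,
                    age = est$age[match(ids, est$participant_id)],
                    stringsAsFactors = FALSE)
  for (coh in .coherences) {
    av <- vapply(ids, function(id) .get_cell(est, id, "AV", coh, "delta"), numeric(1))
    v <- vapply(ids, function(id) .get_cell(est, id, "V", coh, "delta"), numeric(1))
    a <- vapply(ids, function(id) .get_cell(est, id, "A", coh, "delta"), numeric(1))
    out[[paste0("opt_", coh)]] <- sqrt(v^2 + a^2)
    out[[coh]] <- optimal_combination_gap(av, v, a)
  }
  out
}

#' Measure of inverse effectiveness
#'
#' Difference-of-differences contrasting the multisensory benefit at low
#' versus high coherence: `(X_LC^MS - X_LC^US) - (X_HC^MS - X_HC^US)`,
#' where the multisensory cell (MS) is AV and the "optimal" unisensory cell
#' (US) at each coherence is the best-performing of V and A for that
#' participant — highest drift rate, lowest decision boundary, or lowest
#' non-decision time, per parameter. The unisensory modality may switch
#' between coherence levels.
#'
#' @param est a [participant_estimates()] table.
#' @param parameter `"delta"`, `"theta"` or `"tau"`.
#' @return data frame with `participant_id`, `age`, `moie`.
#' @export
moie <- function(est, parameter = c("delta", "theta", "tau")) {
  parameter <- match.arg(parameter)
  pick <- if (parameter == "delta") max else min
  ids <- unique(est$participant_id)
  val <- vapply(ids, function(id) {
    term <- vapply(.coherences, function(coh) {
      ms <- .get_cell(est, id, "AV", coh, parameter)
      us <- pick(.get_cell(est, id, "V", coh, parameter),
                 .get_cell(est, id, "A", coh, parameter))
      ms - us
    }, numeric(1))
    term[["LC"]] - term[["HC"]]
  }, numeric(1))
  data.frame(participant_id = ids,
             age = est$age[match(ids, est$participant_id)],
             moie = val, stringsAsFactors = FALSE)
}

#' Pearson correlation with age
#'
#' Pearson correlation coefficient with a two-sided p value from the t
#' transform and a 95% confidence interval from the Fisher z
#' transformation.
#'
#' @param values per-participant quantity.
#' @param ages matching ages in years.
#' @return list with `r`, `p`, `ci` (length-2), `n`.
#' @export
age_correlation <- function(values, ages) {
  ok <- is.finite(values) & is.finite(ages)
  if (sum(ok) < 3) stop("need >= 3 complete pairs")
  if (sd(values[ok]) == 0 || sd(ages[ok]) == 0)
    stop("correlation undefined: zero variance")
  ct <- cor.test(values[ok], ages[ok], method = "pearson",
                 conf.level = 0.95)
  list(r = unname(ct$estimate), p = ct$p.value,
       ci = as.numeric(ct$conf.int), n = sum(ok))
}

#' Multisensory benefit report
#'
#' Assembles the full derived-statistics table: per participant, AV-V
#' differences for each parameter (per coherence and collapsed),
#' optimal-combination drift gaps per coherence, and the measures of
#' inverse effectiveness; plus cohort-level Pearson age correlations for
#' every derived quantity.
#'
#' @param est a [participant_estimates()] table.
#' @return list of class `benefit_report` with `participants` (one row per
#'   participant) and `correlations` (one row per derived quantity: `r`,
#'   `p`, `ci_lower`, `ci_upper`, `n`).
#' @export
benefit_report <- function(est) {
  ids <- unique(est$participant_id)
  out <- data.frame(participant_id = ids,
                    age = est$age[match(ids, est$participant_id)],
                    stringsAsFactors = FALSE)
  for (p in c("delta", "theta", "tau")) {
    d <- av_minus_v(est, p, "per_coherence")
    out[[paste0("av_v_", p, "_HC")]] <- d$HC
    out[[paste0("av_v_", p, "_LC")]] <- d$LC
    out[[paste0("av_v_", p, "_collapsed")]] <- (d$HC + d$LC) / 2
    out[[paste0("moie_", p)]] <- moie(est, p)$moie
  }
  g <- participant_opt_gaps(est)
  out$opt_combination_HC <- g$opt_HC
  out$opt_combination_LC <- g$opt_LC
  out$opt_gap_HC <- g$HC
  out$opt_gap_LC <- g$LC

  quant_cols <- setdiff(names(out), c("participant_id", "age"))
  cors <- do.call(rbind, lapply(quant_cols, function(cn) {
    ac <- age_correlation(out[[cn]], out$age)
    data.frame(quantity = cn, r = ac$r, p = ac$p,
               ci_lower = ac$ci[1], ci_upper = ac$ci[2], n = ac$n,
               stringsAsFactors = FALSE)
  }))
  structure(list(participants = out, correlations = cors),
            class = "benefit_report")
}

#' @export
print.benefit_report <- function(x, ...) {
  cat("Multisensory benefit report:", nrow(x$participants), "participants\n")
  print(x$correlations, digits = 3)
  invisible(x)
}
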