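#' Default pipeline configuration
#'
#' Materialises every tunable of the end-to-end pipeline with its default,
#' so the configuration written alongside a run is complete and the run is
#' reproducible from it.
#'
#' @param ... overrides for any configuration field.
#' @return a fully populated configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_participants = 8L,
    stages = c("simulate", "preprocess", "fit", "diagnose", "ppc", "metrics"),
    design = list(n_blocks = 3L, trials_per_block = 72L, deadline_ms = 3000),
    generator = list(),                     # age_generative_model() overrides
    preprocess = list(criterion = 0.5, k = 2.5),
    fit = list(variants = 8L, n_chains = 2L, n_iter = 600L, burn_in = 100L,
               thin = 2L, age_threshold = 60),
    diagnose = list(threshold = 1.02),
    ppc = list(n_draws = 100L, mass = 0.90))
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]][names(over[[nm]])] <- over[[nm]]
    else cfg[[nm]] <- over[[nm]]
  }
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate (or load), preprocess,
#' fit the selected variants, convergence diagnostics, posterior
#' predictive check, and derived multisensory metrics — writing every
#' intermediate artifact, the resolved configuration and a MANIFEST with
#' per-file checksums into the output directory. Later stages reuse the
#' outputs of earlier ones; a failed stage leaves the MANIFEST marking
#' which stages completed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @param trials optional externally supplied trial table; used instead of
#'   simulation when the `simulate` stage is disabled.
#' @return the output directory, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, trials = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(completed = character(), files = list())
  save_json <- function(x, f) jsonlite::write_json(
    x, file.path(out_dir, f), auto_unbox = TRUE, digits = NA, pretty = TRUE,
    force = TRUE)
  save_csv <- function(x, f) write.csv(x, file.path(out_dir, f),
                                       row.names = FALSE)
  finish_stage <- function(stage, files) {
    manifest$completed <<- c(manifest$completed, stage)
    for (f in files)
      manifest$files[[f]] <<- unname(tools::md5sum(file.path(out_dir, f)))
    save_json(manifest, "MANIFEST.json")
  }
  save_json(config, "config.json")

  if ("simulate" %in% config$stages) {
    spec <- do.call(design_spec, config$design)
    gen <- do.call(age_generative_model, config$generator)
    sim <- simulate_dataset(spec, gen, config$n_participants, config$seed)
    trials <- sim$trials
    save_csv(trials, "trials.csv")
    save_csv(sim$truth, "ground_truth.csv")
    finish_stage("simulate", c("trials.csv", "ground_truth.csv"))
  }
  if (is.null(trials)) stop("no trials: enable the simulate stage or pass trials")

  if ("preprocess" %in% config$stages) {
    pp <- preprocess(trials, criterion = config$preprocess$criterion,
                     k = config$preprocess$k)
    trials <- pp$trials
    save_csv(trials, "trials_clean.csv")
    save_json(unclass(pp$report), "exclusion_report.json")
    finish_stage("preprocess", c("trials_clean.csv", "exclusion_report.json"))
  }

  posteriors <- list()
  if ("fit" %in% config$stages) {
    fc <- config$fit
    files <- character()
    for (v in fc$variants) {
      post <- fit_hddm(trials, variant = v, n_chains = fc$n_chains,
                       n_iter = fc$n_iter, burn_in = fc$burn_in,
                       thin = fc$thin, seed = config$seed + v,
                       age_threshold = fc$age_threshold)
      posteriors[[as.character(v)]] <- post
      summ <- data.frame(node = dimnames(post$draws)[[2]],
                         mean = apply(post$draws, 2, mean),
                         sd = apply(post$draws, 2, sd),
                         row.names = NULL)
      f <- sprintf("posterior_summary_variant%d.csv", v)
      save_csv(summ, f)
      files <- c(files, f)
    }
    if (length(fc$variants) >= 2) {
      dt <- data.frame(variant = fc$variants,
                       dic = vapply(posteriors, function(p) dic(p)$dic,
                                    numeric(1)))
      sel <- select_model(dt)
      save_json(list(best = sel$best, substantial = sel$substantial,
                     table = sel$dic_table), "model_selection.json")
      files <- c(files, "model_selection.json")
    }
    finish_stage("fit", files)
  }

  best <- if (length(posteriors)) posteriors[[length(posteriors)]] else NULL
  if ("diagnose" %in% config$stages && !is.null(best)) {
    cr <- convergence_report(best, threshold = config$diagnose$threshold)
    save_json(list(max_rhat = cr$max_rhat, threshold = cr$threshold,
                   pass = cr$pass, rhat = as.list(cr$rhat)),
              "convergence.json")
    finish_stage("diagnose", "convergence.json")
  }
  if ("ppc" %in% config$stages && !is.null(best)) {
    pc <- posterior_predictive_check(best, n_draws = config$ppc$n_draws,
                                     seed = config$seed,
                                     mass = config$ppc$mass)
    save_csv(pc, "ppc.csv")
    finish_stage("ppc", "ppc.csv")
  }
  if ("metrics" %in% config$stages && !is.null(best)) {
    est <- participant_estimates(best)
    rep <- benefit_report(est)
    save_csv(rep$participants, "benefit_participants.csv")
    save_csv(rep$correlations, "benefit_correlations.csv")
    finish_stage("metrics", c("benefit_participants.csv",
                              "benefit_correlations.csv"))
  }
  invisible(out_dir)
}
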