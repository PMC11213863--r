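#' Experimental design specification
#'
#' Describes the audiovisual object-categorisation session layout: blocks of
#' trials balanced over sensory condition (visual, auditory, audiovisual),
#' stimulus phase coherence (high/low) and stimulus category (face/car),
#' with a fixed response deadline. The default reproduces a 3-block,
#' 72-trials-per-block session (216 trials per participant).
#'
#' @param n_blocks number of blocks per participant.
#' @param trials_per_block trials in each block; must be divisible by the
#'   number of design cells (conditions x coherences x categories).
#' @param conditions sensory condition labels.
#' @param coherences stimulus coherence labels.
#' @param categories stimulus category labels.
#' @param deadline_ms response deadline in milliseconds; responses slower
#'   than this are timeouts.
#' @param stimulus_ms stimulus duration in milliseconds (metadata only).
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(n_blocks = 3L, trials_per_block = 72L,
                        conditions = c("V", "A", "AV"),
                        coherences = c("HC", "LC"),
                        categories = c("face", "car"),
                        deadline_ms = 3000, stimulus_ms = 300) {
  n_cells <- length(conditions) * length(coherences) * length(categories)
  if (trials_per_block %% n_cells != 0L) {
    stop("trials_per_block (", trials_per_block,
         ") is not divisible by the number of design cells (", n_cells, ")")
  }
  structure(list(n_blocks = as.integer(n_blocks),
                 trials_per_block = as.integer(trials_per_block),
                 conditions = conditions, coherences = coherences,
                 categories = categories, deadline_ms = deadline_ms,
                 stimulus_ms = stimulus_ms),
            class = "design_spec")
}

#' Build balanced trial skeletons for a cohort
#'
#' Expands a [design_spec()] into one row per trial per participant, with the
#' full cell structure (condition x coherence x category) exactly balanced
#' within every block and the trial order pseudorandomised within block under
#' the given seed. No behavioural outcomes are attached.
#'
#' @param spec a [design_spec()].
#' @param n_participants number of participants.
#' @param seed integer seed controlling the within-block shuffling.
#' @return data frame with columns `participant_id`, `block`, `trial`,
#'   `condition`, `coherence`, `category`.
#' @export
build_design <- function(spec, n_participants, seed = 1L) {
  stopifnot(inherits(spec, "design_spec"), n_participants >= 0)
  cells <- expand.grid(condition = spec$conditions, coherence = spec$coherences,
                       category = spec$categories, stringsAsFactors = FALSE)
  reps <- spec$trials_per_block / nrow(cells)
  if (n_participants == 0) {
    return(data.frame(participant_id = character(), block = integer(),
                      trial = integer(), condition = character(),
                      coherence = character(), category = character(),
                      stringsAsFactors = FALSE))
  }
  ids <- sprintf("p%03d", seq_len(n_participants))
  with_preserved_seed(seed, {
    out <- vector("list", n_participants * spec$n_blocks)
    k <- 1L
    for (i in seq_len(n_participants)) {
      for (b in seq_len(spec$n_blocks)) {
        ord <- sample.int(spec$trials_per_block)
        blk <- cells[rep(seq_len(nrow(cells)), each = reps), , drop = FALSE][ord, ]
        out[[k]] <- data.frame(participant_id = ids[i], block = b,
                               trial = seq_len(spec$trials_per_block),
                               blk, row.names = NULL,
                               stringsAsFactors = FALSE)
        k <- k + 1L
      }
    }
    do.call(rbind, out)
  })
}
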