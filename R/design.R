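#' Experimental design specification
#'
#' Describes the within-subject choice experiment: alternating short blocks of
#' perceptual and value-based decisions across sessions, four ordinal evidence
#' levels, balanced correct-response sides, and a pre/post split of sessions
#' around the stimulation.
#'
#' @param n_subjects number of subjects.
#' @param n_sessions sessions per subject (default 8).
#' @param trials_per_session trials in each session (default 32).
#' @param block_length_range admissible task-block lengths (default 7 to 9).
#' @param phase_split last pre-stimulation session; later sessions are "post"
#'   (default 4).
#' @return An object of class `design_spec`.
#' @details The full design must be exactly balanced over
#'   task x evidence level x correct-response side (16 cells), so
#'   `n_sessions * trials_per_session` must be divisible by 16 and each
#'   session must split evenly between the two tasks.
#' @examples
#' design_spec(n_subjects = 2)
#' @export
design_spec <- function(n_subjects, n_sessions = 8, trials_per_session = 32,
                        block_length_range = c(7, 9), phase_split = 4) {
  assert_scalar_num(n_subjects, "n_subjects", lower = 1)
  assert_scalar_num(n_sessions, "n_sessions", lower = 1)
  assert_scalar_num(trials_per_session, "trials_per_session", lower = 2)
  assert_scalar_num(phase_split, "phase_split", lower = 1,
                    upper = n_sessions - 1)
  total <- n_sessions * trials_per_session
  if (trials_per_session %% 2 != 0) {
    stop("`trials_per_session` must be even (half per task)", call. = FALSE)
  }
  if (total %% 16 != 0) {
    stop("total trials must be divisible by the 16 design cells",
         call. = FALSE)
  }
  if (length(block_length_range) != 2 || block_length_range[1] < 1 ||
      block_length_range[1] > block_length_range[2]) {
    stop("`block_length_range` must be an increasing pair", call. = FALSE)
  }
  half <- trials_per_session / 2
  if (is.null(block_partitions(half, block_length_range))) {
    stop("no block partition of ", half, " trials with lengths in [",
         block_length_range[1], ", ", block_length_range[2], "]",
         call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 trials_per_session = as.integer(trials_per_session),
                 tasks = c("perceptual", "value"),
                 evidence_levels = 1:4,
                 block_length_range = as.integer(block_length_range),
                 phase_split = as.integer(phase_split)),
            class = "design_spec")
}

# All compositions of `total` into the minimal number of parts within
# [range[1], range[2]]; NULL if infeasible.
block_partitions <- function(total, range) {
  nb <- ceiling(total / range[2])
  while (nb * range[1] <= total) {
    if (nb * range[2] >= total) {
      grid <- as.matrix(expand.grid(rep(list(range[1]:range[2]), nb)))
      grid <- grid[rowSums(grid) == total, , drop = FALSE]
      if (nrow(grid) > 0) return(grid)
    }
    nb <- nb + 1
  }
  NULL
}

#' Map a rating gap to an ordinal evidence level
#'
#' Trials are constructed from pairs of items whose mean ratings differ by
#' one of four admissible gaps per task: percentage gaps 5/10/15/20 for the
#' perceptual task and rating gaps 1/2/3/4 for the value task, mapped to
#' levels 1 to 4. A pair with any other gap is rejected, signalling the
#' pairing algorithm to resample.
#'
#' @param rating_a,rating_b mean ratings of the two items, on the task scale.
#' @param task `"perceptual"` or `"value"`.
#' @return Integer evidence level 1 to 4.
#' @examples
#' compute_evidence_level(70, 50, "perceptual")  # gap 20% -> level 4
#' compute_evidence_level(5, 8, "value")         # gap 3 -> level 3
#' @export
compute_evidence_level <- function(rating_a, rating_b,
                                   task = c("perceptual", "value")) {
  task <- match.arg(task)
  gap <- abs(rating_a - rating_b)
  gaps <- if (task == "perceptual") c(5, 10, 15, 20) else c(1, 2, 3, 4)
  lev <- match(TRUE, abs(gap - gaps) < 1e-9)
  if (is.na(lev)) {
    stop(sprintf("rejected pair: gap %g is not an admissible %s gap (%s)",
                 gap, task, paste(gaps, collapse = ", ")), call. = FALSE)
  }
  as.integer(lev)
}

#' Build a balanced trial table (design labels only)
#'
#' Lays out every subject's sessions as alternating perceptual/value blocks
#' (block lengths drawn from the admissible range, starting task randomised
#' per session), then deals a fully balanced multiset of
#' evidence level x correct-response side labels into each task's slots.
#' Deterministic given `seed`.
#'
#' @param spec a [design_spec()].
#' @param seed integer seed.
#' @return A data.frame with one row per trial: `subject_id`, `session`,
#'   `phase` ("pre"/"post"), `recovery` (logical, last two post sessions),
#'   `block_id`, `task`, `evidence_level`, `ev_irrelevant` (the other task's
#'   evidence level for the pair, behaviourally inert), `target` ("upper"/
#'   "lower" correct side). Outcome columns are absent until
#'   [generate_behaviour()] fills them.
#' @export
build_design <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "design_spec"))
  with_seed(derive_seed(seed, "design"), {
    half <- spec$trials_per_session / 2
    parts <- block_partitions(half, spec$block_length_range)
    res <- vector("list", spec$n_subjects)
    for (s in seq_len(spec$n_subjects)) {
      rows <- vector("list", spec$n_sessions)
      for (ses in seq_len(spec$n_sessions)) {
        lenA <- parts[sample.int(nrow(parts), 1), ]
        lenB <- parts[sample.int(nrow(parts), 1), ]
        first <- sample(spec$tasks, 1)
        tasks2 <- c(first, setdiff(spec$tasks, first))
        nb <- length(lenA)
        lens <- as.vector(rbind(lenA, lenB))
        btasks <- rep(tasks2, nb)
        rows[[ses]] <- data.frame(
          subject_id = s, session = ses,
          phase = if (ses <= spec$phase_split) "pre" else "post",
          recovery = ses > spec$n_sessions - 2,
          block_id = rep(seq_len(2 * nb), lens),
          task = rep(btasks, lens),
          stringsAsFactors = FALSE)
      }
      d <- do.call(rbind, rows)
      # balanced condition labels per task, shuffled and dealt in order
      per_task <- nrow(d) / 2
      cells <- expand.grid(evidence_level = spec$evidence_levels,
                           target = c("upper", "lower"),
                           stringsAsFactors = FALSE)
      d$evidence_level <- NA_integer_
      d$ev_irrelevant <- NA_integer_
      d$target <- NA_character_
      for (tk in spec$tasks) {
        idx <- which(d$task == tk)
        lab <- cells[rep(seq_len(nrow(cells)), each = per_task / 8), ]
        lab <- lab[sample.int(nrow(lab)), ]
        d$evidence_level[idx] <- lab$evidence_level
        d$target[idx] <- lab$target
        d$ev_irrelevant[idx] <- sample(rep(spec$evidence_levels,
                                           per_task / 4))
      }
      res[[s]] <- d
    }
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    out
  })
}
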