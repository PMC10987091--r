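POPULATIONS <- c("core", "middle", "edge")
SEXES <- c("M", "F")
PHASES <- c("initial", "reversal")
OPTIONS <- c("option1", "option2")
TRIAL_COLS <- c("bird_id", "population", "sex", "phase", "trial",
                "choice", "correct", "completed")

#' Validate a trial-record data frame
#'
#' Checks the trial-level schema: one row per presented trial with columns
#' `bird_id`, `population` (core/middle/edge), `sex` (M/F), `phase`
#' (initial/reversal), `trial` (1-based, consecutive within bird and phase),
#' `choice` (option1/option2, `NA` when incomplete), `correct` (0/1, `NA`
#' when incomplete) and `completed` (0/1). `correct` and `choice` must be
#' missing exactly on incomplete trials, and within each bird and phase the
#' choice-to-correct mapping must be consistent with a single rewarded
#' option that flips between phases.
#'
#' @param trials Data frame of trial records.
#' @return The validated data frame (invisibly), ordered by bird, phase,
#'   trial.
#' @export
validate_trials <- function(trials) {
  missing_cols <- setdiff(TRIAL_COLS, names(trials))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_enum <- function(x, levels, what) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) {
      stop("unknown ", what, " value(s): ",
           paste(unique(x[bad]), collapse = ", "), call. = FALSE)
    }
  }
  bad_enum(trials$population, POPULATIONS, "population")
  bad_enum(trials$sex, SEXES, "sex")
  bad_enum(trials$phase, PHASES, "phase")
  bad_enum(trials$choice, OPTIONS, "choice")
  if (anyNA(trials$population) || anyNA(trials$sex) || anyNA(trials$phase) ||
      anyNA(trials$trial) || anyNA(trials$completed)) {
    stop("population, sex, phase, trial and completed must be non-missing",
         call. = FALSE)
  }
  if (!all(trials$completed %in% c(0L, 1L))) {
    stop("completed must be 0/1", call. = FALSE)
  }
  if (!all(trials$correct %in% c(0L, 1L) | is.na(trials$correct))) {
    stop("correct must be 0/1 or missing", call. = FALSE)
  }
  inc <- trials$completed == 0L
  if (any(inc & !is.na(trials$correct))) {
    stop("correct must be missing on incomplete trials (completed = 0)", call. = FALSE)
  }
  if (any(!inc & is.na(trials$correct))) {
    stop("correct must be recorded on completed trials", call. = FALSE)
  }
  if (any(inc & !is.na(trials$choice)) || any(!inc & is.na(trials$choice))) {
    stop("choice must be missing exactly on incomplete trials", call. = FALSE)
  }
  trials <- trials[order(trials$bird_id, match(trials$phase, PHASES), trials$trial), ]
  key <- interaction(trials$bird_id, trials$phase, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    tr <- trials$trial[idx]
    if (anyDuplicated(tr)) {
      stop("duplicated (bird, phase, trial) rows for ", k, call. = FALSE)
    }
    if (!identical(as.integer(tr), seq_along(tr))) {
      stop("trial numbers for ", k,
           " are not consecutive from 1 (e.g. a skipped trial)", call. = FALSE)
    }
  }
  # one rewarded option per bird-phase, flipping between phases
  bkey <- unique(trials$bird_id)
  for (b in bkey) {
    rew <- rep(NA_character_, 2)
    for (p in 1:2) {
      rows <- trials[trials$bird_id == b & trials$phase == PHASES[p] &
                       trials$completed == 1L, ]
      if (nrow(rows) == 0) next
      cmap <- unique(rows[, c("choice", "correct")])
      if (anyDuplicated(cmap$choice)) {
        stop("bird ", b, " phase ", PHASES[p],
             ": the same choice is recorded both correct and incorrect", call. = FALSE)
      }
      hit <- cmap$choice[cmap$correct == 1L]
      miss <- cmap$choice[cmap$correct == 0L]
      if (length(hit) > 1) {
        stop("bird ", b, " phase ", PHASES[p],
             ": more than one rewarded option", call. = FALSE)
      }
      if (length(hit) == 1) rew[p] <- hit
      else if (length(miss) == 1) rew[p] <- setdiff(OPTIONS, miss)
    }
    if (!anyNA(rew) && rew[1] == rew[2]) {
      stop("bird ", b, ": rewarded option does not flip between phases", call. = FALSE)
    }
  }
  invisible(trials)
}

#' Read and write trial records
#'
#' CSV I/O for the trial-record schema (UTF-8, header row, comma separated,
#' explicit enum strings, 1-based trial numbering within phase). Reading
#' validates the schema and fails with an informative message on malformed
#' rows; a write followed by a read restores the records exactly.
#'
#' @param path File path.
#' @param trials Data frame of trial records (see [validate_trials()]).
#' @return `read_trials()` returns the validated data frame.
#' @export
read_trials <- function(path) {
  trials <- read.csv(path, stringsAsFactors = FALSE,
                     colClasses = c(bird_id = "character", population = "character",
                                    sex = "character", phase = "character",
                                    trial = "integer", choice = "character",
                                    correct = "integer", completed = "integer"))
  trials$choice[trials$choice == ""] <- NA_character_
  out <- validate_trials(trials)
  rownames(out) <- NULL
  out
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  trials <- validate_trials(trials)
  write.csv(trials[, TRIAL_COLS], path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Per-phase learning trajectories
#'
#' Reduces trial records to one row per bird and phase: the finish trial
#' under the chosen learning criterion and the number of choice-option
#' switches up to and including the finish trial. Incomplete trials are
#' excluded before evaluation, so `trials_to_finish` counts completed
#' trials; birds that never meet the criterion get `NA` in both columns.
#'
#' @param trials Validated trial records.
#' @param criterion `"applied"` (default), `"fixed"` or `"sliding"`.
#' @param minima_ordered Passed to the legacy criteria; ignored for
#'   `"applied"`.
#' @return Data frame with columns `bird_id`, `population`, `sex`, `phase`,
#'   `trials_to_finish`, `switches_at_finish`, `n_completed`.
#' @export
trajectories <- function(trials, criterion = c("applied", "fixed", "sliding"),
                         minima_ordered = TRUE) {
  criterion <- match.arg(criterion)
  trials <- validate_trials(trials)
  done <- trials[trials$completed == 1L, ]
  key <- unique(done[, c("bird_id", "population", "sex", "phase")])
  key <- key[order(key$bird_id, match(key$phase, PHASES)), ]
  out <- key
  out$trials_to_finish <- NA_integer_
  out$switches_at_finish <- NA_integer_
  out$n_completed <- NA_integer_
  for (r in seq_len(nrow(key))) {
    rows <- done[done$bird_id == key$bird_id[r] & done$phase == key$phase[r], ]
    rows <- rows[order(rows$trial), ]
    fin <- switch(criterion,
      applied = criterion_applied(rows$correct),
      fixed = criterion_fixed_window(rows$correct, minima_ordered),
      sliding = {
        f <- criterion_sliding_window(rows$correct, minima_ordered)
        # a pre-choice pass can point one past the recorded trials
        if (!is.na(f)) min(as.integer(f), nrow(rows)) else f
      })
    out$n_completed[r] <- nrow(rows)
    if (!is.na(fin)) {
      out$trials_to_finish[r] <- as.integer(fin)
      out$switches_at_finish[r] <- count_switches(rows$choice, upto = as.integer(fin))
    }
  }
  rownames(out) <- NULL
  out
}

#' Audit extra (post-criterion) learning trials
#'
#' Birds can remain in a phase beyond reaching criterion; downstream
#' analyses exclude those extra trials. This report lists, per bird and
#' phase, the applied-criterion finish trial (in completed trials), the
#' number of completed trials recorded, and the count of post-criterion
#' extras.
#'
#' @inheritParams trajectories
#' @return Data frame with columns `bird_id`, `population`, `sex`, `phase`,
#'   `finish_trial`, `n_completed`, `extra_trials` (`NA` when unfinished).
#' @export
audit_extra_trials <- function(trials, criterion = c("applied", "fixed", "sliding"),
                               minima_ordered = TRUE) {
  traj <- trajectories(trials, criterion, minima_ordered)
  data.frame(traj[, c("bird_id", "population", "sex", "phase")],
             finish_trial = traj$trials_to_finish,
             n_completed = traj$n_completed,
             extra_trials = traj$n_completed - traj$trials_to_finish)
}

#' Drop post-criterion trials from a trial table
#'
#' Returns the records with, per bird and phase, completed trials truncated
#' at the applied-criterion finish (incomplete trials occurring before the
#' finish are kept). Used to put all analyses on the criterion-defined
#' trial set.
#'
#' @inheritParams trajectories
#' @return Trial data frame without extra learning trials.
#' @export
exclude_extra_trials <- function(trials) {
  trials <- validate_trials(trials)
  keep <- rep(TRUE, nrow(trials))
  key <- unique(trials[, c("bird_id", "phase")])
  for (r in seq_len(nrow(key))) {
    idx <- which(trials$bird_id == key$bird_id[r] & trials$phase == key$phase[r])
    rows <- trials[idx, ]
    comp <- rows$completed == 1L
    fin <- criterion_applied(rows$correct[comp])
    if (is.na(fin)) next
    last_trial <- rows$trial[comp][fin]
    keep[idx[rows$trial > last_trial]] <- FALSE
  }
  out <- trials[keep, ]
  rownames(out) <- NULL
  out
}

#' Behavioural count outcomes for the Poisson models
#'
#' One row per bird and phase with the count response used by
#' [fit_behaviour_poisson()]: applied-criterion trials-to-finish and
#' switches-at-finish on completed trials. Birds that never finished a
#' phase (e.g. dropped early from reversal) contribute no row for that
#' phase, matching the exclusion applied in the behavioural models.
#'
#' @inheritParams trajectories
#' @return Data frame with columns `bird_id`, `population`, `sex`, `phase`,
#'   `trials`, `switches`.
#' @export
behaviour_outcomes <- function(trials) {
  traj <- trajectories(trials, criterion = "applied")
  traj <- traj[!is.na(traj$trials_to_finish), ]
  data.frame(traj[, c("bird_id", "population", "sex", "phase")],
             trials = traj$trials_to_finish,
             switches = traj$switches_at_finish)
}
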