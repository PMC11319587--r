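# Scoring of the four Box Task outcome measures. Error-class precedence:
# reopening a past-target box is always a between-search error, never a
# within-search error, so a single open never increments both counters.

check_completed_trial <- function(trial) {
  if (!inherits(trial, "trial_record")) stop("not a trial_record")
  if (length(trial$searches) != trial$spec$set_size) {
    stop("incomplete trial: ", length(trial$searches), " searches for set size ",
         trial$spec$set_size)
  }
  invisible(trial)
}

search_paths <- function(trial) {
  lapply(trial$searches, function(s) s$opens$box)
}

#' Count between-search errors in a trial
#'
#' A between-search error is opening a box that holds a target already found
#' in a strictly earlier search of the same trial. Every such re-open counts,
#' including repeated re-opens of the same box.
#'
#' @param trial a completed `"trial_record"`.
#' @return Non-negative integer count.
#' @examples
#' tr <- make_trial(4, c(1, 3, 0, 2),
#'                  list(c(0, 1), c(1, 3), c(2, 2, 0), 2))
#' count_between_search_errors(tr)  # the re-open of box 1 in search 2
#' @export
count_between_search_errors <- function(trial) {
  check_completed_trial(trial)
  paths <- search_paths(trial)
  targets <- trial$spec$target_order
  total <- 0L
  for (k in seq_along(paths)) {
    prior_targets <- targets[seq_len(k - 1L)]
    total <- total + sum(paths[[k]] %in% prior_targets)
  }
  total
}

#' Count within-search errors in a trial
#'
#' A within-search error is returning to a box already opened and found
#' empty earlier within the current search. Re-opens of past-target boxes
#' are classified as between-search errors only (class precedence), so the
#' two counters are disjoint.
#'
#' @param trial a completed `"trial_record"`.
#' @return Non-negative integer count.
#' @export
count_within_search_errors <- function(trial) {
  check_completed_trial(trial)
  paths <- search_paths(trial)
  targets <- trial$spec$target_order
  total <- 0L
  for (k in seq_along(paths)) {
    prior_targets <- targets[seq_len(k - 1L)]
    p <- paths[[k]]
    if (length(p) < 2L) next
    for (j in 2:length(p)) {
      b <- p[j]
      if (b %in% prior_targets) next         # between-search by precedence
      if (b %in% p[seq_len(j - 1L)]) total <- total + 1L
    }
  }
  total
}

#' Levenshtein edit distance between two box-index sequences
#'
#' Minimum number of single-element insertions, deletions and substitutions
#' transforming `a` into `b`, by dynamic programming. This is the primitive
#' underlying the search-path strategy score.
#'
#' @param a,b integer vectors (empty allowed).
#' @return Non-negative integer.
#' @examples
#' levenshtein_distance(c(0, 1, 2, 2, 1, 0), c(0, 2, 1, 0))
#' @export
levenshtein_distance <- function(a, b) {
  la <- length(a)
  lb <- length(b)
  if (la == 0L) return(lb)
  if (lb == 0L) return(la)
  prev <- 0:lb
  for (i in seq_len(la)) {
    cur <- integer(lb + 1L)
    cur[1L] <- i
    for (j in seq_len(lb)) {
      cost <- if (a[i] == b[j]) 0L else 1L
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L, prev[j] + cost)
    }
    prev <- cur
  }
  as.integer(prev[lb + 1L])
}

#' Search-path strategy score of a trial
#'
#' For each search k >= 2, the reference path is the path of search k-1 with
#' every occurrence of that search's target box removed, and the current path
#' is the full path of search k. The per-search score is the Levenshtein
#' distance between the two, normalised by the longer path length (0 when
#' both are empty); the trial score is the unweighted mean over searches
#' 2..set_size. Scores lie in \[0, 1\]; lower means consecutive searches
#' follow more similar paths, i.e. a more proficient, systematic strategy.
#'
#' @param trial a completed `"trial_record"` with at least 2 searches.
#' @return Real in \[0, 1\].
#' @export
strategy_score <- function(trial) {
  check_completed_trial(trial)
  paths <- search_paths(trial)
  if (length(paths) < 2L) stop("strategy score needs at least 2 searches")
  targets <- trial$spec$target_order
  per_search <- vapply(2:length(paths), function(k) {
    ref <- paths[[k - 1L]]
    ref <- ref[ref != targets[k - 1L]]
    cur <- paths[[k]]
    denom <- max(length(ref), length(cur))
    if (denom == 0L) 0 else levenshtein_distance(ref, cur) / denom
  }, numeric(1))
  mean(per_search)
}

#' Score a single trial
#'
#' Bundles the four Box Task outcome measures: between-search errors,
#' within-search errors, completion time (timestamp of the final
#' `target_found` event, i.e. seconds from trial onset) and the strategy
#' score.
#'
#' @param trial a completed `"trial_record"`.
#' @return A list with class `"trial_scores"`: `between_search_errors`,
#'   `within_search_errors`, `completion_time`, `strategy_score`.
#' @export
score_trial <- function(trial) {
  check_completed_trial(trial)
  last_search <- trial$searches[[length(trial$searches)]]
  structure(list(
    between_search_errors = count_between_search_errors(trial),
    within_search_errors = count_within_search_errors(trial),
    completion_time = last_search$opens$t[nrow(last_search$opens)],
    strategy_score = strategy_score(trial)),
    class = "trial_scores")
}

#' Score a session
#'
#' Scores the six test trials (two each at set sizes 4, 6, 8; practice
#' trials are excluded) and aggregates per set size: the mean of the two
#' trials for every measure, plus the trial-1 + trial-2 sum of the two error
#' counts (the fixed decision tree's inputs).
#'
#' @param session a valid, completed `"session_record"`.
#' @param emulate_missing_4box_t1_time if `TRUE`, the 4-box time aggregate
#'   uses trial 2 only, replicating the original study's handling of the
#'   unavailable 4-box trial-1 time.
#' @return A list with class `"score_report"`: `participant_id`, `per_trial`
#'   (data frame: `set_size`, `trial`, `between_errors`, `within_errors`,
#'   `time_seconds`, `strategy`) and `per_set_size` (data frame: `set_size`,
#'   `*_mean` for the four measures, `between_sum`, `within_sum`).
#' @export
score_session <- function(session, emulate_missing_4box_t1_time = FALSE) {
  if (!inherits(session, "session_record")) stop("not a session_record")
  test_trials <- Filter(function(tr) !isTRUE(tr$spec$is_practice),
                        session$trials)
  missing <- setdiff(rep(TEST_SET_SIZES, each = 2),
                     vapply(test_trials, function(tr) tr$spec$set_size,
                            integer(1)))
  if (length(test_trials) != 6L || length(missing) > 0L) {
    stop("incomplete session: expected two test trials each at set sizes ",
         paste(TEST_SET_SIZES, collapse = ", "),
         if (length(missing)) paste0("; missing set size(s) ",
                                     paste(unique(missing), collapse = ", ")))
  }
  per_trial <- do.call(rbind, lapply(seq_along(test_trials), function(i) {
    tr <- test_trials[[i]]
    check_completed_trial(tr)
    sc <- score_trial(tr)
    data.frame(set_size = tr$spec$set_size,
               trial = ((i - 1L) %% 2L) + 1L,
               between_errors = sc$between_search_errors,
               within_errors = sc$within_search_errors,
               time_seconds = sc$completion_time,
               strategy = sc$strategy_score)
  }))
  per_set_size <- do.call(rbind, lapply(TEST_SET_SIZES, function(n) {
    d <- per_trial[per_trial$set_size == n, ]
    time_mean <- if (n == 4L && emulate_missing_4box_t1_time) {
      d$time_seconds[d$trial == 2L]
    } else {
      mean(d$time_seconds)
    }
    data.frame(set_size = n,
               between_mean = mean(d$between_errors),
               within_mean = mean(d$within_errors),
               time_mean = time_mean,
               strategy_mean = mean(d$strategy),
               between_sum = sum(d$between_errors),
               within_sum = sum(d$within_errors))
  }))
  structure(list(participant_id = session$spec$participant_id,
                 per_trial = per_trial,
                 per_set_size = per_set_size),
            class = "score_report")
}

#' @export
print.score_report <- function(x, ...) {
  cat("Box Task scores for", x$participant_id, "\n")
  print(x$per_set_size, row.names = FALSE)
  invisible(x)
}

#' Score a list of sessions into long tables
#'
#' @param sessions list of `"session_record"` objects.
#' @param emulate_missing_4box_t1_time passed to [score_session()].
#' @return A list of two data frames: `per_trial` (one row per participant,
#'   set size and trial) and `per_set_size` (one row per participant and set
#'   size), each carrying `participant_id` and, when present in session
#'   metadata, `group`.
#' @export
score_cohort <- function(sessions, emulate_missing_4box_t1_time = FALSE) {
  reports <- lapply(sessions, score_session,
                    emulate_missing_4box_t1_time = emulate_missing_4box_t1_time)
  groups <- vapply(sessions, function(s) {
    g <- s$metadata$group
    if (is.null(g)) NA_character_ else as.character(g)
  }, character(1))
  bind_with_id <- function(field) {
    do.call(rbind, lapply(seq_along(reports), function(i) {
      d <- reports[[i]][[field]]
      cbind(data.frame(participant_id = reports[[i]]$participant_id,
                       group = groups[i], stringsAsFactors = FALSE), d)
    }))
  }
  list(per_trial = bind_with_id("per_trial"),
       per_set_size = bind_with_id("per_set_size"))
}
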