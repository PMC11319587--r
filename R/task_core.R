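#' boxtask: simulation and analysis of the Box Task
#'
#' The Box Task is a computerised self-ordered search test of visuospatial
#' working memory. Closed boxes are shown at random screen locations; the
#' participant opens boxes one by one to find a hidden target. Each found
#' target stays hidden in its box and a new target is hidden elsewhere, so a
#' trial of set size n comprises n consecutive searches over the same layout.
#' Test sessions present two practice trials of 3 boxes followed by two
#' trials each at set sizes 4, 6 and 8.
#'
#' The package provides the task state machine and session-log data model
#' (`build_session_spec()`, `open_box()`, `read_session()`), scoring of the
#' four outcome measures (`score_session()`), parametric cognitive agents and
#' cohort simulation (`simulate_cohort()`, `default_presets()`), diagnostic
#' classification (`classify_published_tree()`, `fit_chaid()`, `roc_auc()`),
#' and supporting statistics (`benjamini_hochberg()`,
#' `standardized_regression()`, `group_setsize_contrasts()`).
#'
#' @keywords internal
"_PACKAGE"

# Box indices are 0-based everywhere (internally and in all file formats);
# trial and search indices are 1-based in reports.

SESSION_SCHEMA_VERSION <- 1L
TEST_SET_SIZES <- c(4L, 6L, 8L)
SESSION_SET_SIZES <- c(3L, 3L, 4L, 4L, 6L, 6L, 8L, 8L)

#' Layout configuration for box placement
#'
#' Boxes are placed on an abstract canvas by rejection sampling subject to a
#' minimum pairwise separation. Coordinates matter only for log fidelity;
#' scoring never uses them.
#'
#' @param canvas numeric length-2, canvas width and height in abstract units.
#' @param min_separation minimum Euclidean distance between box centres.
#' @return A list with class `"layout_config"`.
#' @export
layout_config <- function(canvas = c(100, 100), min_separation = 15) {
  stopifnot(is.numeric(canvas), length(canvas) == 2, all(canvas > 0),
            is.numeric(min_separation), min_separation >= 0)
  structure(list(canvas = as.numeric(canvas),
                 min_separation = as.numeric(min_separation)),
            class = "layout_config")
}

# Rejection-sample `n` positions with the configured separation. Errors when
# the canvas cannot host the layout (configuration error, not a bug).
sample_layout <- function(n, config = layout_config()) {
  max_restarts <- 50L
  max_tries <- 200L
  for (r in seq_len(max_restarts)) {
    pos <- matrix(NA_real_, nrow = n, ncol = 2)
    ok <- TRUE
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        p <- stats::runif(2) * config$canvas
        if (i == 1L ||
            all(sqrt(rowSums((pos[seq_len(i - 1L), , drop = FALSE] -
                                matrix(p, i - 1L, 2, byrow = TRUE))^2)) >=
                config$min_separation)) {
          pos[i, ] <- p
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) {
      colnames(pos) <- c("x", "y")
      return(pos)
    }
  }
  stop("canvas too small for ", n, " boxes at minimum separation ",
       config$min_separation, call. = FALSE)
}

#' Build a session specification
#'
#' Generates the fixed session structure — two practice trials of 3 boxes
#' followed by two trials each at set sizes 4, 6 and 8 — with seeded random
#' box layouts and target orders. The target order is a permutation of the
#' boxes: each box hides exactly one target and found targets persist, so a
#' completed trial has one search per box.
#'
#' @param seed non-negative integer; the spec is a pure function of
#'   `(seed, config)`.
#' @param participant_id identifier stored in the spec.
#' @param config a [layout_config()].
#' @return A list with class `"session_spec"`: fields `participant_id`,
#'   `seed`, and `trials`, each trial holding `set_size`, `is_practice`,
#'   `positions` (matrix, row per box) and `target_order` (0-based box
#'   indices, a permutation).
#' @examples
#' spec <- build_session_spec(seed = 1)
#' vapply(spec$trials, `[[`, integer(1), "set_size")
#' @export
build_session_spec <- function(seed, participant_id = "sim",
                               config = layout_config()) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0, seed == floor(seed))
  set.seed(as.integer(seed))
  trials <- lapply(seq_along(SESSION_SET_SIZES), function(i) {
    n <- SESSION_SET_SIZES[i]
    list(trial_index = i,
         set_size = n,
         is_practice = i <= 2L,
         positions = sample_layout(n, config),
         target_order = sample.int(n) - 1L)
  })
  structure(list(participant_id = as.character(participant_id),
                 seed = as.integer(seed),
                 trials = trials),
            class = "session_spec")
}

#' @export
print.session_spec <- function(x, ...) {
  cat("Box Task session spec: participant", x$participant_id,
      "| seed", x$seed, "\n")
  cat("  set sizes:", paste(vapply(x$trials, `[[`, integer(1), "set_size"),
                            collapse = " "), "\n")
  invisible(x)
}

#' Start a trial
#'
#' Creates the in-progress state consumed by [open_box()].
#'
#' @param trial_spec one element of a [build_session_spec()]'s `trials`.
#' @return A list with class `"trial_state"`.
#' @export
start_trial <- function(trial_spec) {
  stopifnot(is.list(trial_spec), !is.null(trial_spec$set_size),
            !is.null(trial_spec$target_order))
  structure(list(spec = trial_spec,
                 search_index = 1L,
                 searches = list(),          # completed searches
                 current_opens = list(),     # opens of the current search
                 last_t = -Inf,
                 complete = FALSE),
            class = "trial_state")
}

#' Open a box
#'
#' Advances the trial state machine by one box-open event. The outcome is
#' `"target_found"` iff the opened box is the current search's target
#' (`target_order[k]` for search k); after the final target the outcome is
#' reported as `"trial_complete"`. Every event is appended to the log.
#'
#' @param state a `"trial_state"` from [start_trial()].
#' @param box_index 0-based box index.
#' @param timestamp seconds from trial onset; must exceed the previous
#'   event's timestamp.
#' @return A list with elements `state` (updated) and
#'   `outcome` (one of `"empty"`, `"target_found"`, `"trial_complete"`).
#' @export
open_box <- function(state, box_index, timestamp) {
  if (!inherits(state, "trial_state")) stop("state must be a trial_state")
  if (state$complete) stop("trial is already complete")
  n <- state$spec$set_size
  if (!is.numeric(box_index) || length(box_index) != 1 ||
      box_index != floor(box_index) || box_index < 0 || box_index >= n) {
    stop("box_index out of range [0, ", n - 1L, "]")
  }
  if (!is.numeric(timestamp) || timestamp < 0 || timestamp <= state$last_t) {
    stop("timestamp must be non-negative and strictly increasing")
  }
  k <- state$search_index
  target <- state$spec$target_order[k]
  hit <- box_index == target
  ev <- list(box = as.integer(box_index), t = as.numeric(timestamp),
             outcome = if (hit) "target_found" else "empty")
  state$current_opens[[length(state$current_opens) + 1L]] <- ev
  state$last_t <- as.numeric(timestamp)
  if (hit) {
    state$searches[[k]] <- list(search_index = k, opens = state$current_opens)
    state$current_opens <- list()
    if (k == n) {
      state$complete <- TRUE
      return(list(state = state, outcome = "trial_complete"))
    }
    state$search_index <- k + 1L
    return(list(state = state, outcome = "target_found"))
  }
  list(state = state, outcome = "empty")
}

#' Finish a trial state into a trial record
#'
#' @param state a completed `"trial_state"`.
#' @return A `"trial_record"`: list with `spec` and `searches`, each search a
#'   list with `search_index` and an `opens` data frame (`box`, `t`,
#'   `outcome`).
#' @export
as_trial_record <- function(state) {
  if (!inherits(state, "trial_state")) stop("state must be a trial_state")
  if (!state$complete) stop("trial is not complete")
  searches <- lapply(state$searches, function(s) {
    list(search_index = s$search_index,
         opens = data.frame(
           box = vapply(s$opens, `[[`, integer(1), "box"),
           t = vapply(s$opens, `[[`, numeric(1), "t"),
           outcome = vapply(s$opens, `[[`, character(1), "outcome"),
           stringsAsFactors = FALSE))
  })
  structure(list(spec = state$spec, searches = searches),
            class = "trial_record")
}

#' Construct a trial record from explicit open sequences
#'
#' Convenience constructor used in tests and examples: replays the given box
#' sequences through the engine with unit-spaced timestamps.
#'
#' @param set_size number of boxes.
#' @param target_order 0-based permutation of the boxes.
#' @param open_sequences list of integer vectors, the boxes opened in each
#'   search (the last entry of each must be that search's target).
#' @param dt spacing in seconds between consecutive opens.
#' @return A `"trial_record"`.
#' @export
make_trial <- function(set_size, target_order, open_sequences, dt = 1) {
  spec <- list(trial_index = 1L, set_size = as.integer(set_size),
               is_practice = FALSE,
               positions = NULL,
               target_order = as.integer(target_order))
  st <- start_trial(spec)
  t <- 0
  for (seq_k in open_sequences) {
    for (b in seq_k) {
      t <- t + dt
      st <- open_box(st, b, t)$state
    }
  }
  as_trial_record(st)
}

#' Construct a session record
#'
#' @param spec a `"session_spec"`.
#' @param trials list of `"trial_record"` objects aligned with `spec$trials`.
#' @param metadata free-form named list (group label, agent parameters, ...).
#' @return A `"session_record"`.
#' @export
session_record <- function(spec, trials, metadata = list()) {
  structure(list(spec = spec, trials = trials, metadata = metadata),
            class = "session_record")
}

#' @export
print.session_record <- function(x, ...) {
  cat("Box Task session: participant", x$spec$participant_id, "|",
      length(x$trials), "trials\n")
  if (!is.null(x$metadata$group)) cat("  group:", x$metadata$group, "\n")
  invisible(x)
}

#' Validate a session record
#'
#' Checks every structural invariant of the session-log data model and
#' returns violations rather than raising: trial/spec alignment, search
#' structure (non-empty, terminal `target_found`, none earlier), target
#' identity against the spec's `target_order`, box-index ranges, and strictly
#' increasing timestamps within each trial.
#'
#' @param record a `"session_record"`.
#' @return Character vector of violation descriptors; empty iff valid. Each
#'   descriptor names the trial, the search where applicable, and the rule
#'   broken.
#' @export
validate_session <- function(record) {
  v <- character(0)
  say <- function(...) v[[length(v) + 1L]] <<- paste0(...)
  if (!inherits(record, "session_record")) {
    return("record: not a session_record")
  }
  if (length(record$trials) != length(record$spec$trials)) {
    say("session: trials do not align one-to-one with spec.trials")
  }
  for (i in seq_along(record$trials)) {
    tr <- record$trials[[i]]
    spec <- tr$spec
    n <- spec$set_size
    if (length(tr$searches) != n) {
      say("trial ", i, ": TrialRecord rule broken - ", length(tr$searches),
          " searches for set size ", n)
    }
    last_t <- -Inf
    for (k in seq_along(tr$searches)) {
      s <- tr$searches[[k]]
      op <- s$opens
      if (is.null(op) || nrow(op) == 0L) {
        say("trial ", i, " search ", k, ": SearchRecord rule broken - empty search")
        next
      }
      if (op$outcome[nrow(op)] != "target_found") {
        say("trial ", i, " search ", k,
            ": SearchRecord rule broken - last open is not target_found")
      }
      if (nrow(op) > 1L && any(op$outcome[-nrow(op)] == "target_found")) {
        say("trial ", i, " search ", k,
            ": SearchRecord rule broken - target_found before final open")
      }
      if (op$outcome[nrow(op)] == "target_found" &&
          op$box[nrow(op)] != spec$target_order[k]) {
        say("trial ", i, " search ", k,
            ": TrialRecord rule broken - found box differs from target_order")
      }
      if (any(op$box < 0L | op$box >= n)) {
        say("trial ", i, " search ", k,
            ": OpenEvent rule broken - box_index out of range")
      }
      for (j in seq_len(nrow(op))) {
        if (op$t[j] <= last_t) {
          say("trial ", i, " search ", k,
              ": OpenEvent rule broken - timestamps not strictly increasing")
          break
        }
        last_t <- op$t[j]
      }
    }
  }
  v
}

#' Flatten a session to an event table
#'
#' @param record a `"session_record"`.
#' @return A data frame with one row per open event: `participant_id`,
#'   `trial_index`, `set_size`, `is_practice`, `search_index`, `open_index`,
#'   `box`, `t_seconds`, `outcome`.
#' @export
session_events <- function(record) {
  rows <- list()
  for (tr in record$trials) {
    for (s in tr$searches) {
      op <- s$opens
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = record$spec$participant_id,
        trial_index = tr$spec$trial_index,
        set_size = tr$spec$set_size,
        is_practice = tr$spec$is_practice,
        search_index = s$search_index,
        open_index = seq_len(nrow(op)),
        box = op$box,
        t_seconds = op$t,
        outcome = op$outcome,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a session record to JSON
#'
#' Serialises the full session log in the documented schema:
#' `{schema_version, participant_id, seed, trials:[{set_size, is_practice,
#' positions, target_order, searches:[{opens:[{box, t, outcome}]}]}]}`.
#'
#' @param record a valid `"session_record"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_session <- function(record, path) {
  stopifnot(inherits(record, "session_record"))
  doc <- list(
    schema_version = SESSION_SCHEMA_VERSION,
    participant_id = record$spec$participant_id,
    seed = record$spec$seed,
    metadata = record$metadata,
    trials = lapply(seq_along(record$trials), function(i) {
      tr <- record$trials[[i]]
      list(trial_index = tr$spec$trial_index,
           set_size = tr$spec$set_size,
           is_practice = tr$spec$is_practice,
           positions = if (is.null(tr$spec$positions)) NULL else
             unname(apply(tr$spec$positions, 1, function(r) as.list(r),
                          simplify = FALSE)),
           target_order = as.list(tr$spec$target_order),
           searches = lapply(tr$searches, function(s) {
             list(opens = lapply(seq_len(nrow(s$opens)), function(j) {
               list(box = s$opens$box[j], t = s$opens$t[j],
                    outcome = s$opens$outcome[j])
             }))
           }))
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = FALSE)
  invisible(path)
}

require_field <- function(x, field, where) {
  if (is.null(x[[field]])) {
    stop("parse error: missing required field \"", field, "\" in ", where,
         call. = FALSE)
  }
  x[[field]]
}

#' Read a session record from JSON
#'
#' Inverse of [write_session()]; `read_session(write_session(r))` equals `r`
#' field for field. Malformed files raise a parse error naming the missing
#' field; a schema-version mismatch is an error.
#'
#' @param path file written by [write_session()].
#' @return A `"session_record"`.
#' @export
read_session <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  ver <- require_field(doc, "schema_version", "document")
  if (!identical(as.integer(ver), SESSION_SCHEMA_VERSION)) {
    stop("schema-version mismatch: file has ", ver, ", expected ",
         SESSION_SCHEMA_VERSION, call. = FALSE)
  }
  pid <- require_field(doc, "participant_id", "document")
  seed <- require_field(doc, "seed", "document")
  trials_doc <- require_field(doc, "trials", "document")
  trials <- lapply(seq_along(trials_doc), function(i) {
    td <- trials_doc[[i]]
    where <- paste0("trials[", i, "]")
    n <- as.integer(require_field(td, "set_size", where))
    tord <- as.integer(unlist(require_field(td, "target_order", where)))
    pos <- if (is.null(td$positions)) NULL else {
      m <- do.call(rbind, lapply(td$positions, function(p) unlist(p)))
      colnames(m) <- c("x", "y")
      m
    }
    spec <- list(trial_index = as.integer(require_field(td, "trial_index", where)),
                 set_size = n,
                 is_practice = isTRUE(td$is_practice),
                 positions = pos,
                 target_order = tord)
    searches <- lapply(seq_along(td$searches), function(k) {
      opens <- td$searches[[k]]$opens
      list(search_index = k,
           opens = data.frame(
             box = vapply(opens, function(o) as.integer(o$box), integer(1)),
             t = vapply(opens, function(o) as.numeric(o$t), numeric(1)),
             outcome = vapply(opens, function(o) as.character(o$outcome),
                              character(1)),
             stringsAsFactors = FALSE))
    })
    structure(list(spec = spec, searches = searches), class = "trial_record")
  })
  spec <- structure(list(participant_id = as.character(pid),
                         seed = as.integer(seed),
                         trials = lapply(trials, `[[`, "spec")),
                    class = "session_spec")
  meta <- if (is.null(doc$metadata)) list() else doc$metadata
  session_record(spec, trials, metadata = meta)
}
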