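# End-to-end orchestration: simulate -> score -> classify -> analyse ->
# report. The package's functions are the interface; run_pipeline() wires
# them together for a one-call reproduction of the full simulated study.

#' Pipeline configuration
#'
#' @param cohort a [cohort_spec()].
#' @param output_dir directory for all artefacts (created if needed).
#' @param emulate_missing_4box_t1_time passed to [score_cohort()].
#' @param fit_chaid_tree also induce a CHAID tree on the simulated patients
#'   (ACE-III forced first), alongside the fixed published tree.
#' @param n_permutations for the group contrasts.
#' @param write_sessions write every session log as JSON (slowest artefact;
#'   disable for quick runs).
#' @return A list with class `"run_config"`.
#' @export
run_config <- function(cohort = cohort_spec(), output_dir = "boxtask_out",
                       emulate_missing_4box_t1_time = TRUE,
                       fit_chaid_tree = TRUE, n_permutations = 999L,
                       write_sessions = TRUE) {
  structure(list(cohort = cohort, output_dir = output_dir,
                 emulate_missing_4box_t1_time = emulate_missing_4box_t1_time,
                 fit_chaid_tree = fit_chaid_tree,
                 n_permutations = as.integer(n_permutations),
                 write_sessions = write_sessions),
            class = "run_config")
}

write_csv_with_header <- function(d, path, seed, config_hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# boxtask %s | seed %d | config %s",
                     as.character(utils::packageVersion("boxtask")),
                     seed, config_hash), con)
  utils::write.csv(d, con, row.names = FALSE)
}

#' Read a pipeline CSV artefact
#'
#' @param path a CSV written by [run_pipeline()] (one `#` header line with
#'   version, seed and config hash, then the table).
#' @return A data frame.
#' @export
read_artifact <- function(path) {
  utils::read.csv(path, comment.char = "#")
}

#' Run the full simulated-study pipeline
#'
#' Simulates the cohort, scores every session, applies the fixed published
#' decision tree to the patients (and optionally induces a CHAID tree),
#' computes the AUC table for AD vs bvFTD, the per-group standardised
#' regressions with the episodic-memory dissociation verdict, and the
#' permutation group contrasts, writing tidy CSVs plus a human-readable
#' summary. Identical config and seed give identical outputs. Every CSV
#' carries a header with the tool version, seed and config hash.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the in-memory results: `cohort`, `scores`,
#'   `labels`, `evaluation`, `auc`, `pattern`, `contrasts`, `chaid` (or
#'   `NULL`) and `files`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$cohort$seed
  # hash of the scientific settings only, so relocated runs compare equal
  config_hash <- rlang::hash(unclass(config)[setdiff(names(config),
                                                     "output_dir")])
  stamp <- function(msg) message(sprintf("[boxtask] %s (%.1fs)", msg,
                                         proc.time()[["elapsed"]] - t0))
  t0 <- proc.time()[["elapsed"]]

  cohort <- simulate_cohort(config$cohort)
  stamp("simulated cohort")
  if (config$write_sessions) {
    sess_dir <- file.path(out, "sessions")
    dir.create(sess_dir, showWarnings = FALSE)
    for (s in cohort$sessions) {
      write_session(s, file.path(sess_dir,
                                 paste0(s$spec$participant_id, ".json")))
    }
    stamp("wrote session logs")
  }

  scores <- score_cohort(cohort$sessions,
                         emulate_missing_4box_t1_time =
                           config$emulate_missing_4box_t1_time)
  files <- character(0)
  emit <- function(d, name) {
    p <- file.path(out, name)
    write_csv_with_header(d, p, seed, config_hash)
    files <<- c(files, p)
  }
  emit(scores$per_trial, "scores_per_trial.csv")
  emit(scores$per_set_size, "scores_per_set_size.csv")
  emit(cohort$covariates, "covariates.csv")
  stamp("scored sessions")

  # fixed published tree on the patients
  patients <- merge(
    cohort$covariates[cohort$covariates$group %in% c("AD", "bvFTD"),
                      c("participant_id", "group", "ace_total")],
    classifier_inputs(scores$per_set_size), by = "participant_id")
  patients$predicted <- classify_published_tree(
    patients$ace_total, patients$ws6_sum, patients$bs4_sum)
  evaluation <- evaluate_classifier(patients$predicted, patients$group)
  emit(patients, "fixed_tree_labels.csv")
  stamp("applied fixed decision tree")

  chaid <- NULL
  if (config$fit_chaid_tree) {
    feats <- chaid_features(scores$per_set_size)
    d <- merge(patients[, c("participant_id", "group", "ace_total")], feats,
               by = "participant_id")
    chaid <- tryCatch(
      fit_chaid(d[, setdiff(names(d), c("participant_id", "group"))],
                d$group,
                chaid_params(forced_first = "ace_total")),
      error = function(e) e)
    txt <- if (inherits(chaid, "error")) {
      msg <- paste("CHAID tree not fitted:", conditionMessage(chaid))
      chaid <- NULL
      msg
    } else {
      utils::capture.output(print(chaid))
    }
    writeLines(txt, file.path(out, "chaid_tree.txt"))
    files <- c(files, file.path(out, "chaid_tree.txt"))
    stamp("fitted CHAID tree")
  }

  auc <- auc_table(scores$per_set_size)
  emit(auc, "auc_table.csv")
  pattern <- tryCatch(
    regression_pattern_check(scores$per_set_size, cohort$covariates),
    error = function(e) e)
  if (inherits(pattern, "error")) {
    reg_rows <- data.frame(group = NA_character_, term = NA_character_,
                           note = paste("regression not run:",
                                        conditionMessage(pattern)))
    pattern <- NULL
  } else {
    reg_rows <- do.call(rbind, lapply(names(pattern$results), function(g) {
      co <- pattern$results[[g]]$coefficients
      cbind(group = g, co, r_squared = pattern$results[[g]]$r_squared)
    }))
  }
  emit(reg_rows, "regressions.csv")
  contrasts <- group_setsize_contrasts(scores$per_set_size,
                                       n_permutations = config$n_permutations,
                                       seed = seed)
  emit(contrasts, "contrasts.csv")
  stamp("ran analyses")

  summary_path <- file.path(out, "summary.txt")
  writeLines(c(
    sprintf("boxtask %s | seed %d | config %s",
            as.character(utils::packageVersion("boxtask")), seed, config_hash),
    sprintf("participants: %d (%s)", length(cohort$sessions),
            paste(sprintf("%s n=%d", names(config$cohort$n_per_group),
                          config$cohort$n_per_group), collapse = ", ")),
    "",
    "fixed decision tree (AD vs bvFTD):",
    utils::capture.output(print(evaluation)),
    "",
    sprintf("regression dissociation verdict (RCF recall predicts errors in AD only): %s",
            if (is.null(pattern)) "not run" else pattern$verdict),
    "",
    "AUC table (AD vs bvFTD):",
    utils::capture.output(print(auc, row.names = FALSE))),
    summary_path)
  files <- c(files, summary_path)
  stamp("wrote summary")

  invisible(list(cohort = cohort, scores = scores, labels = patients,
                 evaluation = evaluation, auc = auc, pattern = pattern,
                 contrasts = contrasts, chaid = chaid, files = files))
}

#' Fixed-tree classifier inputs from the score table
#'
#' @param per_set_size long score table from [score_cohort()].
#' @return Data frame `participant_id`, `ws6_sum` (6-box within-search error
#'   sum of trials 1 and 2), `bs4_sum` (4-box between-search error sum).
#' @export
classifier_inputs <- function(per_set_size) {
  w6 <- per_set_size[per_set_size$set_size == 6L,
                     c("participant_id", "within_sum")]
  b4 <- per_set_size[per_set_size$set_size == 4L,
                     c("participant_id", "between_sum")]
  names(w6)[2] <- "ws6_sum"
  names(b4)[2] <- "bs4_sum"
  merge(w6, b4, by = "participant_id")
}

# error sums at every set size, the CHAID feature set
chaid_features <- function(per_set_size) {
  out <- NULL
  for (n in sort(unique(per_set_size$set_size))) {
    d <- per_set_size[per_set_size$set_size == n,
                      c("participant_id", "between_sum", "within_sum")]
    names(d)[2:3] <- paste0(c("bs", "ws"), n, "_sum")
    out <- if (is.null(out)) d else merge(out, d, by = "participant_id")
  }
  out
}

#' Generate the miniature fixture set used by the test suite
#'
#' Builds a small cohort (3 participants per group) plus hand-constructed
#' defective session records that violate specific session-log invariants.
#' Everything is regenerated from the seed; nothing is stored on disk unless
#' a directory is given.
#'
#' @param seed integer seed.
#' @param dir optional directory; when given, session logs are written there
#'   as JSON.
#' @return A list: `cohort` (from [simulate_cohort()] with 3 per group) and
#'   `defects`, a named list of invalid `"session_record"`s
#'   (`missing_terminal_target`, `bad_timestamps`) whose names state the
#'   broken rule.
#' @export
make_fixtures <- function(seed = 0L, dir = NULL) {
  cohort <- simulate_cohort(
    cohort_spec(n_per_group = c(control = 3L, bvFTD = 3L, AD = 3L),
                seed = seed))
  good <- cohort$sessions[[1]]
  # defect 1: terminal open of a search is not target_found
  d1 <- good
  op <- d1$trials[[3]]$searches[[2]]$opens
  op$outcome[nrow(op)] <- "empty"
  d1$trials[[3]]$searches[[2]]$opens <- op
  # defect 2: non-monotone timestamps
  d2 <- good
  op <- d2$trials[[4]]$searches[[1]]$opens
  op$t[nrow(op)] <- -1
  d2$trials[[4]]$searches[[1]]$opens <- op
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (s in cohort$sessions) {
      write_session(s, file.path(dir, paste0(s$spec$participant_id, ".json")))
    }
  }
  list(cohort = cohort,
       defects = list(missing_terminal_target = d1, bad_timestamps = d2))
}
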