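# Parametric cognitive agents. The generative model is a geometric-decay
# memory: each remembered location survives each intervening open
# independently with a retention probability, separately for "this box holds
# a found target" (rho_between) and "I opened this box during the current
# search" (rho_within). Forgetting a past-target box can produce a
# between-search error; forgetting a same-search open can produce a
# within-search error. sigma_scan governs how systematically the agent scans.

#' Agent parameters
#'
#' @param rho_between per-intervening-open retention probability of
#'   "this box held a found target" memories, in (0, 1].
#' @param rho_within per-intervening-open retention probability of
#'   "opened this search" memories, in (0, 1].
#' @param sigma_scan probability of following the canonical scan order
#'   (ascending box index) at each choice, in \[0, 1\]; otherwise the next
#'   box is uniform over the believed-eligible set.
#' @param latency_mu log-scale mean of the per-open latency (seconds).
#' @param latency_sd log-scale standard deviation of the per-open latency;
#'   must be >= 0.
#' @return A list with class `"agent_params"`.
#' @export
agent_params <- function(rho_between, rho_within, sigma_scan,
                         latency_mu = log(2), latency_sd = 0.45) {
  stopifnot(rho_between > 0, rho_between <= 1,
            rho_within > 0, rho_within <= 1,
            sigma_scan >= 0, sigma_scan <= 1,
            is.numeric(latency_mu), latency_sd >= 0)
  structure(list(rho_between = rho_between, rho_within = rho_within,
                 sigma_scan = sigma_scan,
                 latency_mu = latency_mu, latency_sd = latency_sd),
            class = "agent_params")
}

#' Simulate one trial
#'
#' Plays a trial spec with the agent's choice mechanism. At every open the
#' believed-eligible set excludes (a) each past-target box, remembered
#' independently with probability `rho_between^d` (d = opens elapsed since
#' that target was found) and (b) each box opened during the current search,
#' remembered with probability `rho_within^d` (d = opens since its most
#' recent open). With probability `sigma_scan` the agent opens the
#' lowest-indexed believed-eligible box, else one uniformly at random; an
#' empty believed-eligible set resets to all boxes except the immediately
#' preceding open. Per-open latencies are log-normal and timestamps
#' cumulative. Consumes the current RNG stream; seed externally for
#' reproducibility.
#'
#' @param agent an [agent_params()].
#' @param trial_spec one element of a session spec's `trials`.
#' @return A completed `"trial_record"` that passes [validate_session()]
#'   rules.
#' @export
simulate_trial <- function(agent, trial_spec) {
  n <- trial_spec$set_size
  boxes <- 0:(n - 1L)
  st <- start_trial(trial_spec)
  t <- 0
  open_count <- 0L                   # opens so far in the trial
  found_at <- integer(0)             # open index at which each found target was found
  found_boxes <- integer(0)
  cur_last_open <- integer(0)        # most recent open index per box this search
  names(cur_last_open) <- character(0)
  last_box <- NA_integer_
  while (!st$complete) {
    # memory draws
    remembered <- integer(0)
    if (length(found_boxes)) {
      d <- open_count - found_at
      keep <- stats::runif(length(found_boxes)) < agent$rho_between^d
      remembered <- found_boxes[keep]
    }
    if (length(cur_last_open)) {
      d <- open_count - cur_last_open
      keep <- stats::runif(length(cur_last_open)) < agent$rho_within^d
      remembered <- union(remembered, as.integer(names(cur_last_open))[keep])
    }
    eligible <- setdiff(boxes, remembered)
    if (length(eligible) == 0L) eligible <- setdiff(boxes, last_box)
    choice <- if (stats::runif(1) < agent$sigma_scan) {
      min(eligible)
    } else {
      eligible[sample.int(length(eligible), 1L)]
    }
    t <- t + stats::rlnorm(1, agent$latency_mu, agent$latency_sd)
    res <- open_box(st, choice, t)
    st <- res$state
    open_count <- open_count + 1L
    last_box <- choice
    if (res$outcome == "empty") {
      cur_last_open[as.character(choice)] <- open_count
    } else {
      found_boxes <- c(found_boxes, choice)
      found_at <- c(found_at, open_count)
      cur_last_open <- integer(0)     # new search: same-search memory resets
      names(cur_last_open) <- character(0)
    }
  }
  as_trial_record(st)
}

#' Simulate a full session
#'
#' @param agent an [agent_params()].
#' @param spec a [build_session_spec()].
#' @param seed optional integer; when given, the session is a pure function
#'   of `(agent, spec, seed)`.
#' @param metadata stored on the returned record (the seed and agent
#'   parameters are always recorded, so a session is reproducible from its
#'   own metadata).
#' @return A `"session_record"`.
#' @export
simulate_session <- function(agent, spec, seed = NULL, metadata = list()) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  trials <- lapply(spec$trials, function(ts) simulate_trial(agent, ts))
  metadata$agent <- unclass(agent)
  metadata$sim_seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  session_record(spec, trials, metadata = metadata)
}

# ---- covariate generator -------------------------------------------------

COVARIATE_NAMES <- c("ace_total", "ace_visuospatial", "rcf_copy",
                     "rcf_copy_time", "rcf_recall", "sspan_forward",
                     "sspan_backward", "trails_a", "trails_b")

#' Covariate model for a simulated group
#'
#' Per-test marginal mean and SD plus a coupling weight on the participant's
#' latent severity scalar. A covariate is drawn as
#' `mean + coupling * severity + noise`, with the residual noise SD chosen so
#' the marginal SD is approximately the stated one, then truncated to the
#' instrument range. Positive couplings increase the score with severity
#' (times), negative couplings decrease it (ability scores).
#'
#' @param means,sds,couplings named numeric vectors over the covariates
#'   `ace_total`, `ace_visuospatial`, `rcf_copy`, `rcf_copy_time`,
#'   `rcf_recall`, `sspan_forward`, `sspan_backward`, `trails_a`, `trails_b`.
#' @return A list with class `"covariate_model"`.
#' @export
covariate_model <- function(means, sds, couplings) {
  stopifnot(setequal(names(means), COVARIATE_NAMES),
            setequal(names(sds), COVARIATE_NAMES),
            setequal(names(couplings), COVARIATE_NAMES),
            all(sds >= 0))
  structure(list(means = means[COVARIATE_NAMES],
                 sds = sds[COVARIATE_NAMES],
                 couplings = couplings[COVARIATE_NAMES]),
            class = "covariate_model")
}

# instrument ranges: scores /100, /16, /36; times in seconds
COVARIATE_RANGES <- list(
  ace_total = c(0, 100), ace_visuospatial = c(0, 16),
  rcf_copy = c(0, 36), rcf_copy_time = c(10, 1200), rcf_recall = c(0, 36),
  sspan_forward = c(0, 16), sspan_backward = c(0, 16),
  trails_a = c(5, 600), trails_b = c(10, 900))

#' Draw a neuropsychological profile
#'
#' Draws one participant's covariates from a group preset's covariate model
#' given the participant's latent severity scalar. The same severity scalar
#' shifts that participant's agent parameters (see [participant_agent()]),
#' which is what induces the covariate-task-error couplings. Consumes the
#' current RNG stream.
#'
#' @param preset a [group_preset()].
#' @param severity latent severity scalar (0 = group-typical).
#' @param participant_id identifier for the output row.
#' @return One-row data frame: `participant_id`, `group`, the nine
#'   covariates, `trails_b_minus_a` and `severity`.
#' @export
draw_covariates <- function(preset, severity, participant_id = "sim") {
  cm <- preset$covariate_model
  vals <- numeric(length(COVARIATE_NAMES))
  names(vals) <- COVARIATE_NAMES
  for (nm in COVARIATE_NAMES) {
    sd_total <- cm$sds[[nm]]
    resid_sd <- sqrt(max(sd_total^2 - cm$couplings[[nm]]^2, (0.2 * sd_total)^2))
    v <- cm$means[[nm]] + cm$couplings[[nm]] * severity +
      stats::rnorm(1, 0, resid_sd)
    rng <- COVARIATE_RANGES[[nm]]
    vals[[nm]] <- min(max(v, rng[1]), rng[2])
  }
  # Trails B is slower than Trails A by construction of the instruments
  if (vals[["trails_b"]] < vals[["trails_a"]]) {
    vals[["trails_b"]] <- vals[["trails_a"]] + 1
  }
  out <- data.frame(participant_id = participant_id, group = preset$group,
                    t(vals),
                    trails_b_minus_a = vals[["trails_b"]] - vals[["trails_a"]],
                    severity = severity,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Group preset
#'
#' Bundles the group's agent parameters, the spread of the per-participant
#' latent severity scalar, the severity-to-agent coupling slopes, and the
#' covariate model.
#'
#' @param group one of `"control"`, `"bvFTD"`, `"AD"`.
#' @param agent group-typical [agent_params()].
#' @param severity_sd SD of the latent severity scalar (>= 0).
#' @param sev_rho_slope logit-scale decrease of the retention probabilities
#'   per severity unit (worse memory with higher severity).
#' @param sev_latency_slope increase of `latency_mu` per severity unit.
#' @param covariate_model a [covariate_model()].
#' @return A list with class `"group_preset"`.
#' @export
group_preset <- function(group, agent, severity_sd, sev_rho_slope,
                         sev_latency_slope, covariate_model) {
  stopifnot(group %in% c("control", "bvFTD", "AD"),
            inherits(agent, "agent_params"), severity_sd >= 0,
            inherits(covariate_model, "covariate_model"))
  structure(list(group = group, agent = agent, severity_sd = severity_sd,
                 sev_rho_slope = sev_rho_slope,
                 sev_latency_slope = sev_latency_slope,
                 covariate_model = covariate_model),
            class = "group_preset")
}

#' Participant-level agent parameters
#'
#' Applies a participant's latent severity scalar to a preset's
#' group-typical agent: retention probabilities are shifted down on the
#' logit scale and the latency location up, both linearly in severity.
#'
#' @param preset a [group_preset()].
#' @param severity latent severity scalar.
#' @return An [agent_params()].
#' @export
participant_agent <- function(preset, severity) {
  a <- preset$agent
  shift_rho <- function(rho) {
    stats::plogis(stats::qlogis(min(rho, 1 - 1e-9)) -
                    preset$sev_rho_slope * severity)
  }
  agent_params(rho_between = shift_rho(a$rho_between),
               rho_within = shift_rho(a$rho_within),
               sigma_scan = a$sigma_scan,
               latency_mu = a$latency_mu + preset$sev_latency_slope * severity,
               latency_sd = a$latency_sd)
}

#' Cohort specification
#'
#' @param n_per_group named integer vector over `control`, `bvFTD`, `AD`
#'   (study defaults 32/28/28).
#' @param seed master seed for cohort generation.
#' @param presets named list of [group_preset()]s; defaults to
#'   [default_presets()].
#' @return A list with class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_per_group = c(control = 32L, bvFTD = 28L, AD = 28L),
                        seed = 42L, presets = default_presets()) {
  stopifnot(all(n_per_group >= 1),
            all(names(n_per_group) %in% names(presets)))
  structure(list(n_per_group = n_per_group, seed = as.integer(seed),
                 presets = presets),
            class = "cohort_spec")
}

#' Simulate a full cohort
#'
#' Generates `n_per_group` sessions and neuropsychological profiles per
#' group, deterministically under the cohort seed. Each participant gets a
#' latent severity scalar drawn from N(0, severity_sd^2) which shifts both
#' the agent parameters and the covariates, inducing the group-specific
#' covariate-error couplings.
#'
#' @param cohort a [cohort_spec()].
#' @return A list: `sessions` (list of `"session_record"`, metadata carrying
#'   group, severity and seeds) and `covariates` (data frame, one row per
#'   participant).
#' @export
simulate_cohort <- function(cohort = cohort_spec()) {
  stopifnot(inherits(cohort, "cohort_spec"))
  groups <- names(cohort$n_per_group)
  n_total <- sum(cohort$n_per_group)
  set.seed(cohort$seed)
  # pre-draw everything that depends on the master stream, because
  # build_session_spec / simulate_session reseed the RNG
  severities <- stats::rnorm(n_total)
  spec_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  cov_seeds <- sample.int(.Machine$integer.max - 1L, n_total)
  sessions <- vector("list", n_total)
  cov_rows <- vector("list", n_total)
  i <- 0L
  for (g in groups) {
    preset <- cohort$presets[[g]]
    for (j in seq_len(cohort$n_per_group[[g]])) {
      i <- i + 1L
      pid <- sprintf("%s_%02d", g, j)
      severity <- severities[i] * preset$severity_sd
      agent <- participant_agent(preset, severity)
      spec <- build_session_spec(spec_seeds[i], participant_id = pid)
      sessions[[i]] <- simulate_session(
        agent, spec, seed = sim_seeds[i],
        metadata = list(group = g, severity = severity,
                        spec_seed = spec_seeds[i]))
      set.seed(cov_seeds[i])
      cov_rows[[i]] <- draw_covariates(preset, severity, participant_id = pid)
    }
  }
  list(sessions = sessions, covariates = do.call(rbind, cov_rows))
}
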