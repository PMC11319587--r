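test_that("a perfect-memory systematic agent never makes an error", {
  agent <- agent_params(rho_between = 1, rho_within = 1, sigma_scan = 1)
  for (s in 1:6) {
    ses <- simulate_session(agent, build_session_spec(s), seed = s)
    expect_length(validate_session(ses), 0)
    rep <- score_session(ses)
    expect_equal(rep$per_set_size$between_mean, rep(0, 3))
    expect_equal(rep$per_set_size$within_mean, rep(0, 3))
  }
})

test_that("simulation is deterministic under a fixed seed", {
  agent <- agent_params(0.8, 0.9, 0.5)
  spec <- build_session_spec(9)
  expect_equal(simulate_session(agent, spec, seed = 5),
               simulate_session(agent, spec, seed = 5))

  co1 <- tiny_cohort(n = 3, seed = 13)
  co2 <- tiny_cohort(n = 3, seed = 13)
  expect_equal(co1$sessions, co2$sessions)
  expect_equal(co1$covariates, co2$covariates)

  # a session is reproducible from its own recorded metadata
  ses <- co1$sessions[[4]]
  agent2 <- do.call(agent_params, ses$metadata$agent)
  spec2 <- build_session_spec(ses$metadata$spec_seed,
                              participant_id = ses$spec$participant_id)
  redo <- simulate_session(agent2, spec2, seed = ses$metadata$sim_seed,
                           metadata = ses$metadata[c("group", "severity",
                                                     "spec_seed")])
  expect_equal(redo, ses)
})

test_that("weak memory produces more between-search errors at larger set sizes", {
  set.seed(7)
  agent <- agent_params(rho_between = 0.05, rho_within = 0.05, sigma_scan = 0)
  bet4 <- bet8 <- numeric(120)
  for (r in 1:120) {
    spec <- build_session_spec(sample.int(1e6, 1))
    rep <- score_session(simulate_session(agent, spec))$per_set_size
    bet4[r] <- rep$between_mean[1]
    bet8[r] <- rep$between_mean[3]
  }
  expect_gt(mean(bet8), mean(bet4))
})

test_that("between-search errors decrease with rho_between", {
  set.seed(19)
  means <- vapply(c(0.5, 0.85, 0.995), function(rho) {
    agent <- agent_params(rho, 0.98, 0.5)
    mean(vapply(1:80, function(r) {
      spec <- build_session_spec(sample.int(1e6, 1))
      score_session(simulate_session(agent, spec))$per_set_size$between_mean[2]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("a more systematic scanner has more similar consecutive paths", {
  set.seed(23)
  strat <- vapply(c(0.1, 0.9), function(sig) {
    agent <- agent_params(0.9, 0.95, sig)
    mean(vapply(1:80, function(r) {
      spec <- build_session_spec(sample.int(1e6, 1))
      mean(score_session(simulate_session(agent, spec))$per_set_size$strategy_mean)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(strat[2], strat[1])
})

test_that("covariates respect instrument ranges and track severity as coupled", {
  presets <- default_presets()
  set.seed(41)
  for (r in 1:300) {
    g <- sample(names(presets), 1)
    sev <- rnorm(1, 0, 3)    # extreme severities stress the truncation
    cov <- draw_covariates(presets[[g]], sev)
    expect_true(cov$ace_total >= 0 && cov$ace_total <= 100)
    expect_true(cov$ace_visuospatial >= 0 && cov$ace_visuospatial <= 16)
    expect_true(cov$rcf_copy >= 0 && cov$rcf_copy <= 36)
    expect_true(cov$rcf_recall >= 0 && cov$rcf_recall <= 36)
    expect_true(cov$sspan_forward >= 0 && cov$sspan_forward <= 16)
    expect_true(cov$sspan_backward >= 0 && cov$sspan_backward <= 16)
    expect_gte(cov$trails_b_minus_a, 0)
    expect_equal(cov$trails_b_minus_a, cov$trails_b - cov$trails_a)
  }

  # with couplings and severity spread zeroed, covariates are independent of
  # task errors
  p0 <- default_presets()$AD
  p0$severity_sd <- 0
  p0$covariate_model$couplings[] <- 0
  set.seed(42)
  n <- 200
  errs <- recall <- numeric(n)
  for (i in 1:n) {
    sev <- 0
    agent <- participant_agent(p0, sev)
    spec <- build_session_spec(sample.int(1e6, 1))
    rep <- score_session(simulate_session(agent, spec))$per_set_size
    errs[i] <- rep$between_mean[2]
    recall[i] <- draw_covariates(p0, sev)$rcf_recall
  }
  expect_lt(abs(cor(errs, recall)), 0.15)

  # AD preset default: RCF 3-min recall correlates negatively with 6-box
  # between-search errors (the episodic-memory coupling)
  set.seed(11)
  pAD <- default_presets()$AD
  errs <- recall <- numeric(n)
  for (i in 1:n) {
    sev <- rnorm(1) * pAD$severity_sd
    agent <- participant_agent(pAD, sev)
    spec <- build_session_spec(sample.int(1e6, 1))
    rep <- score_session(simulate_session(agent, spec))$per_set_size
    errs[i] <- rep$between_mean[2]
    recall[i] <- draw_covariates(pAD, sev)$rcf_recall
  }
  expect_lt(cor(errs, recall), -0.2)
})

test_that("the default cohort reproduces the published group structure", {
  co <- simulate_cohort(cohort_spec(seed = 42))
  expect_length(co$sessions, 88)
  expect_equal(nrow(co$covariates), 88)
  expect_equal(as.vector(table(co$covariates$group)[c("control", "bvFTD", "AD")]),
               c(32L, 28L, 28L))

  sc <- score_cohort(co$sessions, emulate_missing_4box_t1_time = TRUE)
  d <- sc$per_set_size
  gmean <- function(g, n, col) mean(d[[col]][d$group == g & d$set_size == n])

  # post-hoc orderings: AD > bvFTD > control for between-search errors and
  # time at the 4- and 6-box set sizes; patients > controls at 8-box
  for (n in c(4, 6)) {
    expect_gt(gmean("AD", n, "between_mean"), gmean("bvFTD", n, "between_mean"))
    expect_gt(gmean("bvFTD", n, "between_mean"),
              gmean("control", n, "between_mean"))
    expect_gt(gmean("AD", n, "time_mean"), gmean("bvFTD", n, "time_mean"))
    expect_gt(gmean("bvFTD", n, "time_mean"), gmean("control", n, "time_mean"))
  }
  expect_gt(gmean("AD", 8, "between_mean"), gmean("control", 8, "between_mean"))
  expect_gt(gmean("bvFTD", 8, "between_mean"),
            gmean("control", 8, "between_mean"))

  # control 4-box between-search errors are rare
  expect_lt(gmean("control", 4, "between_mean"), 1)

  # times grow with set size within every group
  for (g in c("control", "bvFTD", "AD")) {
    tt <- vapply(c(4, 6, 8), function(n) gmean(g, n, "time_mean"), numeric(1))
    expect_true(all(diff(tt) > 0))
  }
})

test_that("presets serialise to YAML and reload unchanged", {
  p <- default_presets()
  path <- tempfile(fileext = ".yaml")
  write_presets(p, path)
  back <- read_presets(path)
  expect_equal(back, p, tolerance = 1e-12)

  # calibration direction: AD retains past-target locations worse than controls
  expect_lt(p$AD$agent$rho_between, p$control$agent$rho_between)
})
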