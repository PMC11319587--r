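test_that("error counters match hand-traced cases and the brute-force oracle", {
  # worked 4-box trial: re-open of a past-target box in search 2 and a
  # same-search re-open in search 3
  tr <- make_trial(4, c(1, 3, 0, 2),
                   list(c(0, 1), c(1, 3), c(2, 2, 0), 2))
  expect_equal(count_between_search_errors(tr), 1)
  expect_equal(count_within_search_errors(tr), 1)
  expect_equal(brute_between(tr), 1)
  expect_equal(brute_within(tr), 1)

  # straight to target: no errors possible
  clean <- make_trial(4, c(2, 0, 3, 1), list(2, 0, 3, 1))
  expect_equal(count_between_search_errors(clean), 0)
  expect_equal(count_within_search_errors(clean), 0)

  # two re-opens of the same past-target box both count
  tr2 <- make_trial(4, c(1, 3, 0, 2),
                    list(1, c(1, 1, 3), 0, 2))
  expect_equal(count_between_search_errors(tr2), 2)
  expect_equal(count_between_search_errors(tr2), brute_between(tr2))
  expect_equal(count_within_search_errors(tr2), 0)  # precedence: not within

  # search opening 0,2,0,2,target has two same-search empty re-opens
  tr3 <- make_trial(4, c(3, 1, 0, 2),
                    list(3, c(0, 2, 0, 2, 1), 0, 2))
  expect_equal(count_within_search_errors(tr3), 2)
  expect_equal(count_within_search_errors(tr3), brute_within(tr3))

  # incomplete trial is a domain error
  incomplete <- tr
  incomplete$searches <- incomplete$searches[1:2]
  expect_error(count_between_search_errors(incomplete), "incomplete")
  expect_error(count_within_search_errors(incomplete), "incomplete")
})

test_that("error counters agree with the oracle on simulated trials", {
  set.seed(31)
  presets <- default_presets()
  for (r in 1:40) {
    preset <- presets[[sample(names(presets), 1)]]
    agent <- participant_agent(preset, rnorm(1))
    spec <- build_session_spec(sample.int(1e6, 1))
    tr <- simulate_trial(agent, spec$trials[[sample(3:8, 1)]])
    expect_equal(count_between_search_errors(tr), brute_between(tr))
    expect_equal(count_within_search_errors(tr), brute_within(tr))
    opens <- sum(vapply(tr$searches, function(s) nrow(s$opens), integer(1)))
    expect_lte(count_between_search_errors(tr) + count_within_search_errors(tr),
               opens - tr$spec$set_size)
  }
})

test_that("levenshtein_distance matches the recursive oracle", {
  expect_equal(levenshtein_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(levenshtein_distance(integer(0), c(4, 5)), 2)
  expect_equal(levenshtein_distance(c(0, 1, 2, 2, 1, 0), c(0, 2, 1, 0)),
               lev_recursive(c(0, 1, 2, 2, 1, 0), c(0, 2, 1, 0)))

  set.seed(17)
  for (r in 1:150) {
    a <- sample(0:3, sample(0:8, 1), replace = TRUE)
    b <- sample(0:3, sample(0:8, 1), replace = TRUE)
    d <- levenshtein_distance(a, b)
    expect_equal(d, lev_recursive(a, b))
    expect_equal(d, levenshtein_distance(b, a))          # symmetry
    expect_equal(d == 0, identical(as.integer(a), as.integer(b)))
  }

  # independent cross-check against base R's generalised edit distance
  set.seed(18)
  for (r in 1:25) {
    a <- sample(0:3, sample(1:8, 1), replace = TRUE)
    b <- sample(0:3, sample(1:8, 1), replace = TRUE)
    expect_equal(levenshtein_distance(a, b),
                 as.integer(utils::adist(paste(letters[a + 1], collapse = ""),
                                         paste(letters[b + 1], collapse = ""))))
  }
})

test_that("strategy score follows the path-similarity definition", {
  # each search repeats the previous path minus the found target: score 0
  tr <- make_trial(4, c(0, 1, 2, 3),
                   list(c(0), c(1), c(2), c(3)))
  # search k path = [k-1]; ref for k = path k-1 minus target k-1 = []
  # lev([], [k]) / 1 = 1 for all three comparisons
  expect_equal(strategy_score(tr), 1)

  tr2 <- make_trial(4, c(3, 2, 1, 0),
                    list(c(0, 1, 2, 3), c(0, 1, 2), c(0, 1), c(0)))
  # ref_2 = [0,1,2], cur_2 = [0,1,2]: 0; ref_3 = [0,1], cur_3 = [0,1]: 0; ...
  expect_equal(strategy_score(tr2), 0)

  # disjoint equal-length paths score 1 per search
  tr3 <- make_trial(8, c(2, 7, 3, 0, 1, 4, 5, 6),
                    list(c(0, 1, 2), c(5, 6, 7), c(3), c(0), c(1), c(4),
                         c(5), c(6)))
  p <- lapply(tr3$searches, function(s) s$opens$box)
  ref2 <- p[[1]][p[[1]] != 2]
  expect_equal(levenshtein_distance(ref2, p[[2]]) / 3, 1)

  # oracle composition on the worked example
  tr4 <- make_trial(4, c(1, 3, 0, 2),
                    list(c(0, 1), c(1, 3), c(2, 2, 0), 2))
  targets <- c(1, 3, 0, 2)
  paths <- lapply(tr4$searches, function(s) s$opens$box)
  expected <- mean(vapply(2:4, function(k) {
    ref <- paths[[k - 1]][paths[[k - 1]] != targets[k - 1]]
    cur <- paths[[k]]
    lev_recursive(ref, cur) / max(length(ref), length(cur))
  }, numeric(1)))
  expect_equal(strategy_score(tr4), expected)

  # fewer than 2 searches is a domain error
  one <- make_trial(1, 0, list(0))
  expect_error(strategy_score(one), "at least 2 searches")
})

test_that("strategy scores of simulated trials stay in [0, 1]", {
  set.seed(77)
  presets <- default_presets()
  for (r in 1:60) {
    preset <- presets[[sample(names(presets), 1)]]
    agent <- participant_agent(preset, rnorm(1))
    spec <- build_session_spec(sample.int(1e6, 1))
    for (ts in spec$trials[3:8]) {
      s <- strategy_score(simulate_trial(agent, ts))
      expect_gte(s, 0)
      expect_lte(s, 1)
    }
  }
})

test_that("score_trial bundles the four measures with the trial-end time", {
  tr <- make_trial(4, c(1, 3, 0, 2),
                   list(c(0, 1), c(1, 3), c(2, 2, 0), 2), dt = 2)
  sc <- score_trial(tr)
  expect_equal(sc$between_search_errors, 1)
  expect_equal(sc$within_search_errors, 1)
  expect_equal(sc$completion_time, 2 * 8)   # 8 opens, 2 s apart
  expect_equal(sc$strategy_score, strategy_score(tr))
})

test_that("score_session aggregates per set size, with the 4-box time option", {
  agent <- agent_params(1, 1, 1)
  ses <- simulate_session(agent, build_session_spec(21), seed = 3)
  rep0 <- score_session(ses)
  expect_equal(nrow(rep0$per_trial), 6)
  expect_equal(rep0$per_set_size$between_mean, rep(0, 3))
  expect_equal(rep0$per_set_size$within_mean, rep(0, 3))
  # mean and sum relations
  for (n in c(4, 6, 8)) {
    d <- rep0$per_trial[rep0$per_trial$set_size == n, ]
    agg <- rep0$per_set_size[rep0$per_set_size$set_size == n, ]
    expect_equal(agg$between_mean, mean(d$between_errors))
    expect_equal(agg$between_sum, sum(d$between_errors))
    expect_equal(agg$time_mean, mean(d$time_seconds))
    expect_equal(agg$strategy_mean, mean(d$strategy))
  }

  # the study's missing 4-box trial-1 time: aggregate = trial 2 only
  rep1 <- score_session(ses, emulate_missing_4box_t1_time = TRUE)
  t2 <- rep1$per_trial$time_seconds[rep1$per_trial$set_size == 4 &
                                      rep1$per_trial$trial == 2]
  expect_equal(rep1$per_set_size$time_mean[rep1$per_set_size$set_size == 4],
               t2)
  # other set sizes unaffected
  expect_equal(rep1$per_set_size$time_mean[-1], rep0$per_set_size$time_mean[-1])

  # incomplete session: drop a test trial
  broken <- ses
  broken$trials <- broken$trials[-8]
  broken$spec$trials <- broken$spec$trials[-8]
  expect_error(score_session(broken), "incomplete session")
})
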