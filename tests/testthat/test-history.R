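test_that("instant recording accumulates prefix counts per bracket", {
  u <- quad_universe(tiny_state())
  cnt <- edge_counts(u)
  q1 <- "e1|a1|g1|m1"; q2 <- "e2|a1|g1|m1"

  # empty active set leaves everything unchanged
  cnt <- record_instant(cnt, character(), time_index(1, 1, 1, 1))
  expect_equal(cnt$N_act, 0)

  # one quad active for 3 instants in one segment
  for (t in 2:4)
    cnt <- record_instant(cnt, q1, time_index(1, 1, 1, t))
  expect_equal(unname(cnt$act[q1]), 3)
  expect_equal(cnt$N_act, 3)

  # two quads active each instant for 2 instants: N grows by 4
  cnt2 <- edge_counts(u)
  for (t in 1:2)
    cnt2 <- record_instant(cnt2, c(q1, q2), time_index(1, 1, 1, t))
  expect_equal(cnt2$N_act, 4)

  # action-level counts reset on a new segment; task level persists
  cnt <- record_instant(cnt, q1, time_index(1, 1, 2, 5))
  expect_equal(unname(cnt$act[q1]), 1)
  expect_equal(unname(cnt$task[q1]), 4)

  expect_error(record_instant(cnt, q1, time_index(1, 1, 1, 2)),
               "time regression")
  expect_error(record_instant(cnt, "zz|zz|zz|zz", time_index(1, 1, 2, 9)),
               "universe")
})

test_that("Dirichlet smoothing recovers its limits and hand values", {
  u <- two_quad_universe()
  r1 <- u$keys[1]; r2 <- u$keys[2]

  # no evidence: exactly the base measure
  cnt <- edge_counts(u)
  sm <- smoothing_config(u, alpha = 1)
  expect_equal(smoothed_probability(cnt, "act", sm, r1), 0.5)

  # C = {r1: 3, r2: 1}, alpha = 1, uniform base over 2 quads
  for (t in 1:3) cnt <- record_instant(cnt, r1, time_index(1, 1, 1, t))
  cnt <- record_instant(cnt, r2, time_index(1, 1, 1, 4))
  expect_equal(smoothed_probability(cnt, "act", sm, r1), 0.7)
  expect_equal(smoothed_probability(cnt, "act", sm, r2), 0.3)

  # alpha -> 0 approaches the empirical frequency
  sm0 <- smoothing_config(u, alpha = 1e-10)
  expect_equal(smoothed_probability(cnt, "act", sm0, r1), 3 / 4,
               tolerance = 1e-9)

  expect_error(smoothed_probability(cnt, "act", sm, "a|b|c|d"), "base mass")
  # smoothed level histograms stay normalized over the universe
  for (lev in c("act", "task", "seq"))
    expect_equal(sum(eagmdbn:::smoothed_vector(cnt, lev, sm)), 1,
                 tolerance = 1e-9)
})

test_that("the coherence prior mixes levels and yields log-odds", {
  u <- quad_universe(lexicon_state("e1", "a1", c("g1", "g2"),
                                   c("m1", "m2")))
  cnt <- edge_counts(u)
  sm <- smoothing_config(u)

  # all levels uniform over 4 quads: pi = 1/4, psi = log(1/3)
  pr <- coherence_prior(cnt, sm)
  expect_equal(unname(pr$pi[u$keys[1]]), 0.25, tolerance = 1e-9)
  expect_equal(coherence_log_odds(pr, u$keys[1]), log(1 / 3),
               tolerance = 1e-9)

  # pi = 0.5 gives psi = 0 (two-quad universe)
  u2 <- two_quad_universe()
  pr2 <- coherence_prior(edge_counts(u2), smoothing_config(u2))
  expect_equal(coherence_log_odds(pr2, u2$keys[1]), 0, tolerance = 1e-9)

  # degenerate weights (1, 0, 0) reproduce the act-level histogram
  cnt3 <- edge_counts(u)
  for (t in 1:5) cnt3 <- record_instant(cnt3, u$keys[1],
                                        time_index(1, 1, 1, t))
  pr3 <- coherence_prior(cnt3, sm, weights = c(act = 1, task = 0, seq = 0))
  expect_equal(unname(pr3$pi),
               unname(eagmdbn:::smoothed_vector(cnt3, "act", sm)),
               tolerance = 1e-9)
  expect_error(coherence_prior(cnt3, sm, weights = c(act = 1, task = 1,
                                                     seq = 0)))
})

test_that("coherence gain rewards historically frequent candidates", {
  u <- quad_universe(tiny_state())
  cnt <- edge_counts(u)
  sm <- smoothing_config(u)
  dom <- u$keys[1]
  for (t in 1:30) cnt <- record_instant(cnt, dom, time_index(1, 1, 1, t))

  # candidate identical to the historically dominant quad
  expect_gt(coherence_gain(cnt, sm, candidate = dom), 0)

  # oracle: independent recomputation of both C_X terms for a zero-history
  # candidate over the joint set
  candidate <- u$keys[5]
  w <- c(act = 0.5, task = 0.3, seq = 0.2)
  got <- coherence_gain(cnt, sm, w, candidate = candidate,
                        active_set = dom)
  oracle <- 0
  for (lev in c("act", "task", "seq")) {
    C <- cnt[[lev]]; N <- cnt[[paste0("N_", lev)]]
    b <- sm$base; a <- sm$alpha
    set <- c(dom, candidate)
    old <- mean(log((C[set] + a * b[set]) / (N + a)))
    C2 <- C; C2[candidate] <- C2[candidate] + 1
    new <- mean(log((C2[set] + a * b[set]) / (N + 1 + a)))
    oracle <- oracle + w[[lev]] * (new - old)
  }
  expect_equal(got, oracle, tolerance = 1e-12)

  # no candidate, no change: zero gain; all-zero weights are rejected
  expect_equal(coherence_gain(cnt, sm, c(act = 1, task = 0, seq = 0),
                              candidate = NULL, active_set = dom), 0)
  expect_equal(coherence_gain(cnt, sm, candidate = NULL,
                              active_set = character()), 0)
  expect_error(coherence_gain(cnt, sm, c(act = 0, task = 0, seq = 0),
                              candidate = dom), "zero")
})

test_that("prefix causality: incremental counts equal truncated replay", {
  set.seed(21)
  u <- quad_universe(tiny_state())
  sm <- smoothing_config(u)
  trace <- lapply(1:40, function(t)
    list(t = t, active = sample(u$keys, sample(0:2, 1)),
         time = time_index(1, 1 + (t > 20), 1 + ((t - 1) %/% 10), t)))
  cnt <- edge_counts(u)
  for (t in seq_along(trace)) {
    # replay from scratch using evidence strictly before t: the smoothed
    # probabilities consulted at t must match the incremental state
    replay <- edge_counts(u)
    for (s in seq_len(t - 1))
      replay <- record_instant(replay, trace[[s]]$active, trace[[s]]$time)
    for (lev in c("act", "task", "seq"))
      expect_equal(eagmdbn:::smoothed_vector(cnt, lev, sm),
                   eagmdbn:::smoothed_vector(replay, lev, sm),
                   tolerance = 1e-12)
    cnt <- record_instant(cnt, trace[[t]]$active, trace[[t]]$time)
  }
})

test_that("repeated activation strictly concentrates the act histogram", {
  u <- quad_universe(tiny_state())
  cnt <- edge_counts(u)
  sm <- smoothing_config(u)
  prev <- smoothed_probability(cnt, "act", sm, u$keys[3])
  for (t in 1:10) {
    cnt <- record_instant(cnt, u$keys[3], time_index(1, 1, 1, t))
    cur <- smoothed_probability(cnt, "act", sm, u$keys[3])
    expect_gt(cur, prev)
    prev <- cur
  }
})

test_that("history summaries are fixed-size and correctly normalized", {
  u <- two_quad_universe()
  mk <- function(t, active, ty)
    list(time = time_index(1, 1, 1 + (t > 5), t), active = active,
         segment_type = ty)

  # single instant, one active quad: point-mass histogram
  s1 <- aggregate_history(list(mk(1, u$keys[1], "initiation")), u)
  expect_equal(unname(s1$histogram[u$keys[1]]), 1)

  # two equal-length segments with disjoint quads: (0.5, 0.5)
  tr <- c(lapply(1:5, function(t) mk(t, u$keys[1], "initiation")),
          lapply(6:10, function(t) mk(t, u$keys[2], "manipulation")))
  s2 <- aggregate_history(tr, u)
  expect_equal(unname(s2$histogram), c(0.5, 0.5))
  expect_equal(unname(s2$dwell[c("initiation", "manipulation")]), c(5, 5))

  # summary dimension is independent of trace length
  long <- lapply(1:1000, function(t)
    list(time = time_index(1, 1, 1, t),
         active = u$keys[1 + t %% 2], segment_type = "termination"))
  s3 <- aggregate_history(long, u)
  expect_equal(length(s3$histogram), length(s1$histogram))
  expect_equal(dim(s3$transitions), dim(s1$transitions))

  # empty bracket: zero histogram, flagged
  s4 <- aggregate_history(list(), u)
  expect_true(s4$empty)
  expect_equal(sum(s4$histogram), 0)

  # composition renormalizes to the same fixed dimension
  s5 <- compose_summaries(list(s1, s2))
  expect_equal(length(s5$histogram), length(s1$histogram))
  expect_equal(sum(s5$histogram), 1, tolerance = 1e-9)
})

test_that("coherence traces serialize the level histograms per instant", {
  u <- two_quad_universe()
  cnt <- edge_counts(u)
  sm <- smoothing_config(u)
  for (t in 1:3) cnt <- record_instant(cnt, u$keys[1],
                                       time_index(1, 1, 1, t))
  pr <- coherence_prior(cnt, sm)
  row <- coherence_trace_row(4, cnt, sm, pr, u$keys)
  expect_equal(nrow(row), 2)
  expect_equal(row$pi_act[1],
               smoothed_probability(cnt, "act", sm, u$keys[1]))
  p <- file.path(tempdir(), "coh.csv")
  write_coherence_trace(row, p)
  back <- utils::read.csv(p, stringsAsFactors = FALSE)
  expect_equal(back$psi, row$psi, tolerance = 1e-9)
  unlink(p)
})
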