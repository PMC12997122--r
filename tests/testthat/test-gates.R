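test_that("compatibility score is a sigmoid of summed logit terms", {
  q <- quadruple("e1", "a1", "g1", "m1")
  m0 <- compatibility_model()
  expect_equal(compatibility_score(m0, q), 0.5)

  # monotone in the base term
  m1 <- planted_compat(q, hi = 1)
  m2 <- planted_compat(q, hi = 2)
  expect_gt(compatibility_score(m2, q), compatibility_score(m1, q))

  # halving det(Sigma_kin) with alpha = 1 adds exactly log 2 to the logit
  ma <- compatibility_model(phi_kin_coeff = 1)
  k1 <- compatibility_score(ma, q, kin_uncertainty = 1)
  k2 <- compatibility_score(ma, q, kin_uncertainty = 0.5)
  expect_equal(stats::qlogis(k2) - stats::qlogis(k1), log(2),
               tolerance = 1e-12)
  expect_error(compatibility_score(ma, q, kin_uncertainty = -1),
               "determinant|positive")
})

test_that("kappa is monotone in every phi argument", {
  set.seed(31)
  q <- quadruple("e1", "a1", "g1", "m1")
  k3 <- "a1|g1|m1"; k2 <- "e1|a1"
  for (i in 1:25) {
    base <- stats::rnorm(1); view <- stats::rnorm(1)
    d <- stats::runif(1, 0.1, 2)
    m_lo <- compatibility_model(stats::setNames(base, k3),
                                stats::setNames(view, k2))
    m_hi <- compatibility_model(stats::setNames(base + d, k3),
                                stats::setNames(view, k2))
    expect_gt(compatibility_score(m_hi, q), compatibility_score(m_lo, q))
    m_foc <- compatibility_model(stats::setNames(base, k3),
                                 stats::setNames(view, k2),
                                 lambda_focus = 1)
    f <- stats::runif(1, -2, 0)
    expect_gt(compatibility_score(m_foc, q, focus_term = f + d,
                                  mqe_term = 0),
              compatibility_score(m_foc, q, focus_term = f, mqe_term = 0))
    expect_gt(compatibility_score(m_foc, q, mqe_term = d),
              compatibility_score(m_foc, q, mqe_term = 0))
  }
})

test_that("the threshold schedule hits its endpoints and hand value", {
  sch <- threshold_schedule(0.2, 0.8, p = 2)
  expect_equal(compatibility_threshold(sch, 0), 0.2)
  expect_equal(compatibility_threshold(sch, 1), 0.8)
  expect_equal(compatibility_threshold(sch, 0.5), 0.2 + 0.6 * 0.25)
  taus <- compatibility_threshold(sch, seq(0, 1, 0.05))
  expect_true(all(diff(taus) >= 0))
  expect_error(compatibility_threshold(sch, 1.2), "progress")
  expect_error(threshold_schedule(0.9, 0.5))
})

test_that("structural rules separate extension, novelty and contradiction", {
  st <- tiny_state(nE = 3, nA = 3, nG = 3, nM = 3)
  e1 <- c4_edge(quadruple("e1", "a1", "g1", "m1"), "active")
  e2 <- c4_edge(quadruple("e2", "a2", "g2", "m2"), "active")
  e1$status <- "validated"; e2$status <- "validated"
  net <- network_state(st, list(e1, e2))

  # identical to a validated edge: trivial extension under Rule 1
  r <- check_compatibility_rules(quadruple("e1", "a1", "g1", "m1"), net)
  expect_true(r$rule1_ok); expect_true(r$pass)

  # all four components novel: Rule 2
  r2 <- check_compatibility_rules(quadruple("e3", "a3", "g3", "m3"), net)
  expect_true(r2$rule2_ok); expect_true(r2$pass)

  # established (E, A, G) with a different established M: contradiction
  r3 <- check_compatibility_rules(quadruple("e1", "a1", "g1", "m2"), net)
  expect_true(r3$contradiction); expect_false(r3$pass)

  # a novel sub-meaning attached to an established context is an addition
  r4 <- check_compatibility_rules(quadruple("e1", "a1", "g1", "m3"), net)
  expect_false(r4$contradiction); expect_true(r4$pass)

  # an empty network makes every quad Rule-2 novel
  r5 <- check_compatibility_rules(quadruple("e1", "a1", "g1", "m1"),
                                  network_state(st))
  expect_true(r5$rule2_ok); expect_true(r5$pass)
})

test_that("observability gain matches exhaustive enumeration", {
  before <- tiny_state(nE = 2, nA = 2, nG = 1, nM = 2)
  after <- promote_symbol(before, symbol("G", "g2", "candidate"), 1)
  tau <- 0.6
  # one planted triple involving the new symbol clears the threshold
  cm <- compatibility_model(phi_base = c("a1|g2|m1" = 3))
  posts <- list(
    E = c(e1 = 0.6, e2 = 0.4), A = c(a1 = 0.7, a2 = 0.3),
    G = c(g1 = 0.5, g2 = 0.5), M = c(m1 = 0.8, m2 = 0.2))

  got <- observability_gain(before, after, cm, tau, posts)

  # brute-force oracle over both universes
  expect_count <- function(st) {
    tot <- 0
    for (E in st$E$codes) for (A in st$A$codes)
      for (G in st$G$codes) for (M in st$M$codes) {
        kap <- compatibility_score(cm, quadruple(E, A, G, M))
        pr <- posts$E[[E]] * posts$A[[A]] * posts$G[[G]] * posts$M[[M]]
        tot <- tot + pr * (kap > tau)
      }
    tot
  }
  oracle <- (expect_count(after) - expect_count(before)) / (2 * 2 * 2 * 2)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_gt(got, 0)

  # unchanged lexicons: exactly zero
  expect_equal(observability_gain(before, before, cm, tau, posts), 0)

  # a symbol enabling no above-threshold edge cannot gain observability
  cm_none <- compatibility_model()
  expect_lte(observability_gain(before, after, cm_none, tau, posts), 0)
})

test_that("the gate pipeline routes, short-circuits and error-lists", {
  st <- tiny_state()
  u <- quad_universe(st)
  q_good <- quadruple("e1", "a1", "g1", "m1")
  cm <- planted_compat(q_good, hi = 4)
  cnt <- edge_counts(u)
  ctx <- list(counts = cnt, smoothing = smoothing_config(u),
              weights = c(act = 0.5, task = 0.3, seq = 0.2),
              model = cm, schedule = threshold_schedule(0.5, 0.9, 2),
              progress = 0, network = network_state(st),
              active_set = character(), max_attempts = 3L)

  # empty candidate set: three empty sets
  res0 <- run_gate_pipeline(list(), ctx)
  expect_length(res0$active, 0)
  expect_length(res0$errors, 0)

  # a candidate passing all three gates becomes active
  res1 <- run_gate_pipeline(list(c4_edge(q_good)), ctx)
  expect_length(res1$active, 1)
  expect_equal(res1$active[[1]]$status, "active")
  expect_equal(res1$active[[1]]$activation_count, 1L)
  expect_equal(res1$log$route, "active")

  # forced sub-threshold kappa: refined 3 times, then the error list
  q_bad <- quadruple("e2", "a2", "g2", "m2")
  res2 <- run_gate_pipeline(list(c4_edge(q_bad)), ctx)
  expect_length(res2$errors, 1)
  expect_equal(res2$errors[[1]]$attempts, 3L)
  expect_equal(res2$log$route, c("refine", "refine", "error"))

  # short-circuit: no coherence or observability value after a
  # compatibility failure
  expect_true(all(is.na(res2$log$delta_C)))
  expect_true(all(is.na(res2$log$n_gain)))
  expect_false(anyNA(res1$log$delta_C))

  # refinement with posteriors rescues a candidate whose view term is
  # wrong: the E layer is re-symbolized to its next-best symbol
  cm_view <- compatibility_model(phi_base = c("a1|g1|m1" = 2),
                                 phi_view = c("e1|a1" = 2))
  ctx3 <- ctx
  ctx3$model <- cm_view
  ctx3$progress <- 1            # tau = 0.9 so plogis(2) fails, plogis(4) passes
  posts <- list(E = point_posterior("E", st$E$codes, "e1"),
                A = point_posterior("A", st$A$codes, "a1"),
                G = point_posterior("G", st$G$codes, "g1"),
                M = point_posterior("M", st$M$codes, "m1"))
  posts$E$probs <- c(e1 = 0.6, e2 = 0.4)
  ctx3$posteriors <- posts
  res3 <- run_gate_pipeline(list(c4_edge(quadruple("e2", "a1", "g1",
                                                   "m1"))), ctx3)
  expect_length(res3$active, 1)
  expect_equal(quad_key(res3$active[[1]]$quad), "e1|a1|g1|m1")
  expect_equal(res3$log$route, c("refine", "active"))
})

test_that("fewer candidates clear compatibility as progress advances", {
  set.seed(32)
  sch <- threshold_schedule(0.3, 0.9, p = 2)
  kappas <- stats::runif(200)
  passing <- vapply(seq(0, 1, 0.1), function(pr)
    sum(kappas > compatibility_threshold(sch, pr)), numeric(1))
  expect_true(all(diff(passing) <= 0))
})

test_that("error-list feedback down-weights base mass in the prior", {
  u <- quad_universe(tiny_state())
  sm <- smoothing_config(u)
  bad <- u$keys[2]
  sm2 <- apply_error_feedback(sm, bad, factor = 0.5)
  expect_lt(sm2$base[[bad]], sm$base[[bad]])
  expect_equal(sum(sm2$base), 1, tolerance = 1e-12)
  # and the smoothed prior of the error-listed quad drops accordingly
  cnt <- edge_counts(u)
  expect_lt(smoothed_probability(cnt, "act", sm2, bad),
            smoothed_probability(cnt, "act", sm, bad))
})

test_that("the validation gate combines confidence with review scores", {
  q <- quadruple("e1", "a1", "g1", "m1")
  e <- c4_edge(q, status = "active", activation_count = 10,
               confidence = 1, iters_active = 5)

  cfg0 <- validation_config(lambda_conf = 0, lambda_val = 0,
                            delta_period = 1)
  expect_equal(validation_gate(e, 0.7, cfg0)$probability, 0.5)

  cfg2 <- validation_config(lambda_conf = 2, lambda_val = 2,
                            delta_period = 1)
  g <- validation_gate(e, 1, cfg2)
  expect_equal(g$probability, stats::plogis(4), tolerance = 1e-9)
  expect_equal(g$decision, 1L)

  # a zero review score silences an arbitrarily large lambda_val
  cfgv <- validation_config(lambda_conf = 0, lambda_val = 100,
                            delta_period = 1)
  expect_equal(validation_gate(e, 0, cfgv)$probability, 0.5)

  # premature review and non-active edges are rejected
  young <- c4_edge(q, status = "active", confidence = 0.5,
                   iters_active = 0)
  expect_error(validation_gate(young, 0.9,
                               validation_config(delta_period = 3)),
               "premature")
  expect_error(validation_gate(c4_edge(q), 0.9, cfg2), "active")
})

test_that("edge confidence saturates monotonically in [0, 1)", {
  n <- 0:50
  conf <- edge_confidence(n, c_half = 5)
  expect_true(all(diff(conf) > 0))
  expect_true(all(conf >= 0 & conf < 1))
  expect_equal(edge_confidence(5, 5), 0.5)
})
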