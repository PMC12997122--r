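test_that("span-consistent MAP decoding equals exhaustive enumeration", {
  set.seed(61)
  labels <- c("x", "y")
  Psi <- matrix(c(3, 1, 1, 3), 2, 2, dimnames = list(labels, labels))
  for (rep in 1:8) {
    ev <- matrix(stats::rgamma(10, 1.5), 5, 2,
                 dimnames = list(NULL, labels))
    props <- list(span_proposal(2, 4, "y", stats::runif(1)))
    got <- segment_decode(ev, Psi, props)
    oracle <- decode_oracle(ev, Psi, props)
    expect_equal(unname(got$map), unname(oracle$map))
    expect_equal(got$marginals, oracle$marginals, tolerance = 1e-9)
  }
  # multiple spans, including one touching the boundary
  ev <- matrix(stats::rgamma(10, 1.5), 5, 2,
               dimnames = list(NULL, labels))
  props <- list(span_proposal(1, 2, "x", 0.8),
                span_proposal(4, 5, "y", 0.6))
  got <- segment_decode(ev, Psi, props)
  oracle <- decode_oracle(ev, Psi, props)
  expect_equal(unname(got$map), unname(oracle$map))
  expect_equal(got$marginals, oracle$marginals, tolerance = 1e-9)

  expect_error(segment_decode(ev, Psi, list(span_proposal(1, 3, "x", 0.5),
                                            span_proposal(3, 5, "y", 0.5))),
               "overlap")
  expect_error(segment_decode(ev, Psi, list(span_proposal(4, 9, "x", 0.5))),
               "beyond")
})

test_that("zero-confidence spans degenerate to span-free decoding", {
  set.seed(62)
  labels <- segment_types()
  Psi <- default_transition_prior()
  ev <- matrix(stats::rgamma(4 * 12, 1), 12, 4,
               dimnames = list(NULL, labels))
  props <- list(span_proposal(2, 5, "manipulation", 0),
                span_proposal(7, 10, "release", 0))
  with_spans <- segment_decode(ev, Psi, props)
  span_free <- segment_decode(ev, Psi, list())
  expect_equal(with_spans$map, span_free$map)
  expect_equal(with_spans$marginals, span_free$marginals,
               tolerance = 1e-9)
})

test_that("confident spans pin labels and drop in-span entropy", {
  # 90 frames; the segmenter proposes frames 30:60 as hand pre-shaping
  # with confidence 0.9; a stretch of contrary frame evidence sits inside
  # the span.  The defection cost is the span penalty log(1 / (1 - pi))
  # plus two ordering-prior switches, so moderate local contradiction
  # cannot break the span but overwhelming evidence can.
  labels <- c("preshape", "other")
  Psi <- matrix(c(6, 1, 1, 6), 2, 2, dimnames = list(labels, labels))
  ev <- matrix(1, 90, 2, dimnames = list(NULL, labels))
  ev[30:60, "preshape"] <- 1.2    # mild support for the proposed type
  ev[40:46, "other"] <- 1.6       # moderate contrary stretch in-span
  sp_hi <- list(span_proposal(30, 60, "preshape", 0.9))
  dec_hi <- segment_decode(ev, Psi, sp_hi)
  dec_no <- segment_decode(ev, Psi, list())

  # the confident span wins against the moderate contradiction
  expect_true(all(dec_hi$map[30:60] == "preshape"))
  # ... but overwhelmingly contradictory evidence overrides it
  ev2 <- ev
  ev2[40:46, "other"] <- 60
  dec_hi2 <- segment_decode(ev2, Psi, sp_hi)
  expect_true(all(dec_hi2$map[40:46] == "other"))

  # per-frame label entropy inside the span is strictly lower with the
  # confident proposal than without it
  h <- function(m, rows) mean(apply(m[rows, , drop = FALSE], 1,
                                    entropy_bits))
  expect_lt(h(dec_hi$marginals, 30:60), h(dec_no$marginals, 30:60))
})

test_that("cumulative-logit ratings reproduce hand-computed values", {
  m <- ordinal_model(c(-1, 0, 1), c(1, 1))
  p <- subgoal_rating_probs(m, c(0, 0))   # eta = 0
  cum <- stats::plogis(c(-1, 0, 1))
  expect_equal(unname(p),
               c(cum[1], cum[2] - cum[1], cum[3] - cum[2], 1 - cum[3]),
               tolerance = 1e-12)
  expect_equal(unname(p), c(0.2689, 0.2311, 0.2311, 0.2689),
               tolerance = 1e-3)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # extreme latent scores pin the rating at the scale ends
  expect_equal(unname(subgoal_rating_probs(m, c(30, 30))["3"]), 1,
               tolerance = 1e-9)
  expect_equal(unname(subgoal_rating_probs(m, c(-30, -30))["0"]), 1,
               tolerance = 1e-9)

  # exercise-level model: same functional form
  me <- ordinal_model(c(0, 0.5, 1), c(1))
  pe <- exercise_rating_probs(me, 0.5)
  expect_equal(unname(cumsum(pe)[1:3]),
               unname(stats::plogis(c(0, 0.5, 1) - 0.5)),
               tolerance = 1e-12)
  expect_equal(unname(cumsum(pe)[1:3]), c(0.3775, 0.5, 0.6225),
               tolerance = 1e-4)
  expect_equal(subgoal_rating_probs(me, 0.5), exercise_rating_probs(me, 0.5))

  expect_error(ordinal_model(c(0, 0, 1), c(1)), "increasing")
})

test_that("cumulative probabilities stay monotone and classes sum to 1", {
  set.seed(64)
  m <- ordinal_model(c(-0.8, 0.1, 1.4), c(0.7, -1.2, 0.4))
  for (i in 1:50) {
    p <- subgoal_rating_probs(m, stats::rnorm(3, sd = 3))
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_true(all(diff(cumsum(p)) >= -1e-12))
  }
})

test_that("the ordinal fitter recovers planted parameters", {
  set.seed(65)
  n <- 2000
  gamma <- c(-1, 0.2, 1.3)
  u <- c(1.2, -0.8, 0.5)
  h <- matrix(stats::rnorm(n * 3), n, 3)
  lat <- as.numeric(h %*% u) + stats::rlogis(n)
  y <- vapply(lat, function(l) sum(l > gamma), numeric(1))
  fit <- fit_ordinal_model(h, y)

  expect_true(all(abs(fit$thresholds - gamma) <= 0.15))
  cosine <- sum(fit$weights * u) /
    sqrt(sum(fit$weights^2) * sum(u^2))
  expect_gte(cosine, 0.95)

  # independent cross-check: our class probabilities equal polr's predict
  df <- as.data.frame(h); names(df) <- paste0("x", 1:3)
  df$y <- factor(y, levels = 0:3, ordered = TRUE)
  pf <- MASS::polr(y ~ ., data = df, method = "logistic")
  newx <- h[1:5, , drop = FALSE]
  ours <- t(apply(newx, 1, function(r) subgoal_rating_probs(fit, r)))
  theirs <- stats::predict(pf, newdata = stats::setNames(
    as.data.frame(newx), paste0("x", 1:3)), type = "probs")
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-6)
})

test_that("MQE probabilities and focused edge compatibility behave", {
  mm <- mqe_model(list(trunk = list(w = c(0, 0), b = 0),
                       aperture = list(w = c(1, 1), b = 0)))
  expect_equal(mqe_probability(mm, "trunk", c(5, -3)), 0.5)
  expect_equal(mqe_probability(mm, "aperture", c(1, 1)),
               stats::plogis(2), tolerance = 1e-12)
  expect_equal(stats::plogis(2), 0.8808, tolerance = 1e-4)
  expect_lt(mqe_probability(mm, "aperture", c(-40, 0)), 1e-6)
  expect_error(mqe_probability(mm, "unknown", c(0, 0)), "unknown")

  fp <- focus_prior(list(initiation = c("trunk", "aperture")))
  expect_equal(focus_weight(fp, "trunk", "initiation"), 0.5)
  expect_error(focus_weight(fp, "smoothness", "initiation"), "focus set")

  cm <- compatibility_model(lambda_focus = 1)
  q <- quadruple("e1", "initiation", "g1", "mqe1")
  k_uniform <- mqe_edge_compatibility(cm, q, NULL, fp, "trunk", 0.5)
  # uniform focus over |F| = 2 contributes log(0.5) for both MQEs
  expect_equal(k_uniform,
               mqe_edge_compatibility(cm, q, NULL, fp, "aperture", 0.5))
  # doubling one MQE's focus weight (renormalized) raises its kappa
  fp2 <- focus_prior(list(initiation = c("trunk", "aperture")),
                     weights = list(initiation = c(trunk = 2,
                                                   aperture = 1)))
  expect_gt(mqe_edge_compatibility(cm, q, NULL, fp2, "trunk", 0.5),
            k_uniform)

  # full five-term compatibility against a hand-summed logit oracle
  cm5 <- compatibility_model(
    phi_base = c("initiation|g1|mqe1" = 0.8),
    phi_view = c("e1|initiation" = 0.4),
    phi_kin_coeff = 1, lambda_focus = 0.7)
  phat <- 0.75
  got <- mqe_edge_compatibility(cm5, q, kin_uncertainty = 0.5, fp,
                                "trunk", phat)
  oracle <- stats::plogis(0.8 + 0.4 + (-1) * log(0.5) +
                          0.7 * log(0.5) + stats::qlogis(phat))
  expect_equal(got, oracle, tolerance = 1e-12)
})

test_that("logit fusion honors agreement, degeneracy and hand values", {
  expect_equal(fuse_logits(0.8, 0.8, 0.5), 0.8, tolerance = 1e-12)
  expect_equal(fuse_logits(0.9, 0.5, 1), 0.9, tolerance = 1e-12)
  expect_equal(fuse_logits(0.9, 0.5, 0.5),
               stats::plogis(0.5 * stats::qlogis(0.9)),
               tolerance = 1e-12)
  expect_equal(fuse_logits(0.9, 0.5, 0.5), 0.7502, tolerance = 1e-3)
  d <- fuse_ordinal(c(0.7, 0.2, 0.05, 0.05), c(0.5, 0.3, 0.1, 0.1), 0.5)
  expect_equal(sum(d), 1, tolerance = 1e-12)
})

test_that("fusing two calibrated raters preserves calibration", {
  set.seed(66)
  n <- 4000
  p_true <- stats::rbeta(n, 2, 2)
  jitter <- function(p, sd) stats::plogis(stats::qlogis(p) +
                                          stats::rnorm(n, sd = sd))
  p1 <- jitter(p_true, 0.4)
  p2 <- jitter(p_true, 0.6)
  y <- stats::rbinom(n, 1, p_true)
  reliability <- function(p) {
    bins <- cut(p, seq(0, 1, 0.1), include.lowest = TRUE)
    mean(abs(tapply(p, bins, mean) - tapply(y, bins, mean)), na.rm = TRUE)
  }
  fused <- fuse_logits(p1, p2, 0.5)
  expect_lte(reliability(fused),
             max(reliability(p1), reliability(p2)) + 0.02)
})

test_that("session scores sum the 19 exercise ratings within 0-57", {
  mk <- function(ratings) arat_session(lapply(ratings, function(r)
    list(rating = r)))
  expect_equal(total_arat_score(mk(rep(3, 19))), 57)
  expect_equal(total_arat_score(mk(rep(0, 19))), 0)
  expect_equal(total_arat_score(mk(c(rep(3, 10), rep(2, 5), rep(1, 4)))),
               44)
  expect_error(total_arat_score(mk(rep(2, 18))), "19")
  expect_error(total_arat_score(mk(c(rep(2, 18), 5))), "0..3")
  bad <- mk(rep(1, 19)); bad$exercises[[4]]$rating <- NA
  expect_error(total_arat_score(bad), "missing")
})

test_that("embedding pooling reduces by mean or max", {
  hs <- rbind(c(1, 2), c(3, 4))
  expect_equal(pool_embeddings(hs), c(2, 3))
  expect_equal(pool_embeddings(hs, "max"), c(3, 4))
  expect_equal(pool_embeddings(list(c(1, 2), c(3, 4))), c(2, 3))
})
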