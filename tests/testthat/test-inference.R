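test_that("the top-down prior averages the kernel over the previous belief", {
  pairs <- c("g1|m1", "g2|m2")
  prev <- orientation_state(pairs, c(0.5, 0.5))

  K_id <- diag(2); dimnames(K_id) <- list(pairs, pairs)
  tm_id <- transition_model(K_id)
  expect_equal(top_down_prior(tm_id, prev)$probs, prev$probs)

  K_unif <- matrix(0.5, 2, 2, dimnames = list(pairs, pairs))
  skewed <- orientation_state(pairs, c(0.9, 0.1))
  expect_equal(unname(top_down_prior(transition_model(K_unif),
                                     skewed)$probs), c(0.5, 0.5))

  K <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE,
              dimnames = list(pairs, pairs))
  got <- top_down_prior(transition_model(K), prev)
  expect_equal(unname(got$probs), c(0.55, 0.45), tolerance = 1e-12)

  expect_error(transition_model(matrix(c(1, 1, 0, 1), 2, 2,
                                       dimnames = list(pairs, pairs))),
               "sum to 1")
})

test_that("step likelihood multiplies symbol and edge Bernoulli factors", {
  u <- quad_universe(lexicon_state("e1", "a1", c("g1", "g2"), "m1"))
  # success probabilities exactly 0.7 and 0.4 (psi = 0 leaves kappa alone)
  em <- edge_factor_model(u, kappa = stats::setNames(c(0.7, 0.4), u$keys),
                          psi = stats::setNames(c(0, 0), u$keys))
  posts <- list(E = point_posterior("E", "e1", "e1"),
                A = point_posterior("A", "a1", "a1"),
                G = point_posterior("G", c("g1", "g2"), "g1"),
                M = point_posterior("M", "m1", "m1"))
  L <- step_likelihood(posts, em,
                       list(symbols = c(E = "e1", A = "a1", G = "g1",
                                        M = "m1"),
                            active = u$keys[1]))
  expect_equal(as.numeric(L), 0.7 * 0.6, tolerance = 1e-9)

  # a zero-probability realized symbol annihilates the likelihood
  posts0 <- posts
  posts0$G <- point_posterior("G", c("g1", "g2"), "g2")
  L0 <- step_likelihood(posts0, em,
                        list(symbols = c(E = "e1", A = "a1", G = "g1",
                                         M = "m1"),
                             active = character()))
  expect_equal(as.numeric(L0), 0)
  expect_true(isTRUE(attr(L0, "zero_symbol")))
})

test_that("the joint posterior matches brute-force enumeration", {
  st <- tiny_state()
  u <- quad_universe(st)
  pairs <- c("g1|m1", "g2|m2")
  prior <- orientation_state(pairs, c(0.6, 0.4))
  set.seed(41)
  kap <- stats::setNames(stats::runif(u$n, 0.2, 0.9), u$keys)
  psi <- stats::setNames(stats::rnorm(u$n, 0, 0.5), u$keys)
  em <- edge_factor_model(u, kap, psi, p0 = 0.05)
  posts <- list(E = uniform_posterior("E", st$E$codes),
                A = uniform_posterior("A", st$A$codes),
                G = uniform_posterior("G", st$G$codes),
                M = uniform_posterior("M", st$M$codes))
  posts$A$probs <- c(a1 = 0.7, a2 = 0.3)
  active <- u$keys[c(1, 6)]

  jp <- joint_posterior(prior, posts, em, active)
  expect_equal(sum(jp$prob), 1, tolerance = 1e-9)

  # oracle: enumerate every (orientation, symbol) outcome from scratch
  p_act <- stats::plogis(stats::qlogis(kap) + psi)
  for (row in sample(nrow(jp), 24)) {
    o <- jp$orientation[row]
    w <- prior$probs[[o]] *
      posts$E$probs[[jp$E[row]]] * posts$A$probs[[jp$A[row]]] *
      posts$G$probs[[jp$G[row]]] * posts$M$probs[[jp$M[row]]]
    for (i in seq_len(u$n)) {
      pr <- if (u$gm[i] == o) p_act[i] else 0.05
      w <- w * (if (u$keys[i] %in% active) pr else 1 - pr)
    }
    # total mass: same enumeration over all outcomes
    Z <- 0
    for (o2 in pairs) {
      edge_f <- 1
      for (i in seq_len(u$n)) {
        pr <- if (u$gm[i] == o2) p_act[i] else 0.05
        edge_f <- edge_f * (if (u$keys[i] %in% active) pr else 1 - pr)
      }
      Z <- Z + prior$probs[[o2]] * edge_f   # symbol factors sum to 1
    }
    expect_equal(jp$prob[row], unname(w / Z), tolerance = 1e-9)
  }

  # uniform prior and flat evidence give the uniform joint
  em_flat <- edge_factor_model(u, stats::setNames(rep(0.5, u$n), u$keys),
                               stats::setNames(rep(0, u$n), u$keys),
                               p0 = 0.5)
  jp2 <- joint_posterior(orientation_state(pairs), lapply(posts, function(p) {
    p$probs[] <- 1 / length(p$probs); p
  }), em_flat, character())
  expect_equal(max(jp2$prob) - min(jp2$prob), 0, tolerance = 1e-12)
})

test_that("orientation posterior applies Bayes with documented tie-breaks", {
  u <- quad_universe(lexicon_state("e1", "a1", c("g1", "g2"),
                                   c("m1", "m2")))
  pairs <- c("g1|m1", "g2|m2")
  prior <- orientation_state(pairs)

  # an orientation-independent edge factor leaves the prior untouched
  em_flat <- edge_factor_model(u, stats::setNames(rep(0.3, u$n), u$keys),
                               stats::setNames(rep(0, u$n), u$keys),
                               p0 = 0.3)
  up <- orientation_posterior(prior, NULL, u$keys[1], em_flat)
  expect_equal(up$state$probs, prior$probs, tolerance = 1e-12)

  # likelihood ratio 3:1 from one active edge: posterior (0.75, 0.25).
  # The consistent orientation explains the activation at p_act while the
  # other treats it as background AND must explain its own quad's silence:
  # lr = (p_act / p0) * ((1 - p0) / (1 - p_act)) = 1.8 * 5/3 = 3
  kap <- stats::setNames(rep(0.6, u$n), u$keys)
  em <- edge_factor_model(u, kap, stats::setNames(rep(0, u$n), u$keys),
                          p0 = 1 / 3)
  active <- u$keys[u$gm == "g1|m1"][1]
  up2 <- orientation_posterior(prior, NULL, active, em)
  lr <- (0.6 / (1 / 3)) * ((1 - 1 / 3) / (1 - 0.6))
  expect_equal(lr, 3, tolerance = 1e-12)
  expect_equal(unname(up2$state$probs["g1|m1"]), 0.75, tolerance = 1e-9)

  # exact tie: lexicographically smallest pair wins
  up3 <- orientation_posterior(prior, NULL, character(), em_flat)
  expect_equal(up3$map, "g1|m1")
})

test_that("entropy deltas are computed in bits with sign preserved", {
  u4 <- orientation_state(paste0("g", 1:4, "|m"), rep(0.25, 4))
  point <- orientation_state(paste0("g", 1:4, "|m"), c(1, 0, 0, 0))
  skew <- orientation_state(paste0("g", 1:4, "|m"), c(0.7, 0.1, 0.1, 0.1))

  expect_equal(entropy_delta(u4, u4), 0)
  expect_equal(entropy_delta(u4, point), 2)
  h_skew <- -(0.7 * log2(0.7) + 3 * 0.1 * log2(0.1))
  expect_equal(entropy_delta(u4, skew), 2 - h_skew, tolerance = 1e-9)
  expect_equal(entropy_delta(u4, skew), 0.643, tolerance = 1e-3)
  expect_lt(entropy_delta(point, u4), 0)
})

test_that("incremental filtering equals brute-force joint enumeration", {
  # 2 symbols per layer, 2 orientations, 3 instants
  st <- tiny_state()
  u <- quad_universe(st)
  pairs <- c("g1|m1", "g2|m2")
  K <- matrix(c(0.85, 0.15, 0.25, 0.75), 2, 2, byrow = TRUE,
              dimnames = list(pairs, pairs))
  tm <- transition_model(K)
  set.seed(42)
  kap <- stats::setNames(stats::runif(u$n, 0.3, 0.9), u$keys)
  psi <- stats::setNames(stats::rnorm(u$n, 0, 1), u$keys)
  em <- edge_factor_model(u, kap, psi, p0 = 0.1)
  actives <- list(u$keys[u$gm == "g1|m1"][1],
                  u$keys[u$gm == "g1|m1"][2],
                  u$keys[u$gm == "g2|m2"][1])
  init <- orientation_state(pairs, c(0.5, 0.5))

  got <- orientation_filter(tm, init, actives, em)

  # oracle: enumerate all 8 orientation paths
  p_act <- stats::plogis(stats::qlogis(kap) + psi)
  lik <- function(o, act) {
    l <- 1
    for (i in seq_len(u$n)) {
      pr <- if (u$gm[i] == o) p_act[i] else 0.1
      l <- l * (if (u$keys[i] %in% act) pr else 1 - pr)
    }
    l
  }
  paths <- expand.grid(o1 = pairs, o2 = pairs, o3 = pairs,
                       stringsAsFactors = FALSE)
  w <- numeric(nrow(paths))
  for (r in seq_len(nrow(paths))) {
    o <- unlist(paths[r, ])
    # the first prediction mixes the initial belief through the kernel
    w[r] <- (init$probs %*% K[, o[1]])[1] * lik(o[1], actives[[1]]) *
      K[o[1], o[2]] * lik(o[2], actives[[2]]) *
      K[o[2], o[3]] * lik(o[3], actives[[3]])
  }
  marg3 <- tapply(w, paths$o3, sum)
  marg3 <- marg3 / sum(marg3)
  expect_equal(unname(got$states[[3]]$probs[pairs]),
               as.numeric(marg3[pairs]), tolerance = 1e-9)

  # every filtered state stays normalized
  for (s in got$states)
    expect_equal(sum(s$probs), 1, tolerance = 1e-9)
})
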