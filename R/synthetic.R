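# Seeded generators for planted EAGM networks, ARAT-style session streams
# with known ground truth, and a noisy synthetic expert, so that every stage
# of the pipeline is testable without external data.

#' Planted-network configuration
#'
#' The study conditions of the synthetic benchmark.  Defaults: a
#' 3 x 4 x 3 x 3 quadruple universe with 6 planted true c4 quadruples,
#' moderate observation noise (Gaussian sd 0.6 against symbol locations
#' separated by 1.5), and high per-quad activation rates.
#'
#' @param lexicon_sizes Named integer vector `c(E=, A=, G=, M=)`.
#' @param n_true Number of planted quadruples `K` (drawn without
#'   replacement; their (G, M) pairs are distinct so each orientation has
#'   one canonical quadruple).
#' @param separation Distance scale between symbol locations.
#' @param noise_sd Observation noise standard deviation.
#' @param activation_rate Per-instant probability in (0, 1] that the
#'   orientation's quadruple is genuinely in effect.
#' @param phi_true,phi_false Base compatibility logits for planted /
#'   non-planted (A, G, M) triples.
#' @param view_bonus,view_penalty View-preference logits for planted /
#'   non-planted (E, A) pairs.
#' @param kin_uncertainty Shared kinematic-uncertainty scalar proxy.
#' @param feature_dim Embedding dimension for sub-action feature vectors.
#' @param gamma,delta Sub-goal and exercise rating thresholds (strictly
#'   increasing, length 3).
#' @param rating_weights True weight direction for the ordinal raters.
#' @param mqes Named list: MQE id -> `list(w=, b=)` true scorer parameters.
#' @param focus_sets Segment type -> focused MQE ids.
#' @export
network_config <- function(lexicon_sizes = c(E = 3L, A = 4L, G = 3L, M = 3L),
                           n_true = 6L,
                           separation = 1.5, noise_sd = 0.6,
                           activation_rate = 0.95,
                           phi_true = 2.5, phi_false = -2.5,
                           view_bonus = 1, view_penalty = -1,
                           kin_uncertainty = 1,
                           feature_dim = 3L,
                           gamma = c(-1, 0, 1), delta = c(-1, 0, 1),
                           rating_weights = c(1.2, -0.8, 0.5),
                           mqes = NULL, focus_sets = NULL) {
  stopifnot(all(lexicon_sizes >= 1L), n_true >= 0L,
            activation_rate > 0, activation_rate <= 1)
  if (is.null(mqes))
    mqes <- list(trunk_compensation = list(w = c(0.9, 0.4, 0), b = 0),
                 hand_aperture = list(w = c(0, 0.8, 0.6), b = 0.2),
                 smoothness = list(w = c(0.5, 0, 0.9), b = -0.2),
                 wrist_orientation = list(w = c(-0.4, 0.7, 0.3), b = 0))
  if (is.null(focus_sets))
    focus_sets <- list(initiation = c("trunk_compensation", "smoothness"),
                       manipulation = c("hand_aperture", "wrist_orientation"),
                       termination = c("smoothness", "hand_aperture"),
                       release = c("wrist_orientation", "trunk_compensation"))
  list(lexicon_sizes = lexicon_sizes, n_true = as.integer(n_true),
       separation = separation, noise_sd = noise_sd,
       activation_rate = activation_rate,
       phi_true = phi_true, phi_false = phi_false,
       view_bonus = view_bonus, view_penalty = view_penalty,
       kin_uncertainty = kin_uncertainty,
       feature_dim = as.integer(feature_dim),
       gamma = gamma, delta = delta, rating_weights = rating_weights,
       mqes = mqes, focus_sets = focus_sets)
}

simplex_means <- function(codes, separation) {
  n <- length(codes)
  m <- diag(separation, n)
  rownames(m) <- codes
  m
}

#' Generate a planted EAGM network
#'
#' Builds the ground truth of a synthetic study: per-layer lexicons, `K`
#' distinct planted c4 quadruples with distinct (G, M) orientations, the
#' compatibility tables that make planted structure score high, the
#' Gaussian observation model, and two probe actions (an overview action
#' and a focus action with sharper G/M channels at a higher execution
#' time).  Fully reproducible from the seed.
#'
#' @param config A [network_config()].
#' @param seed Integer seed.
#' @return An object of class `planted_network`.
#' @export
generate_network <- function(config = network_config(), seed = 1L) {
  set.seed(seed)
  sz <- config$lexicon_sizes
  codes <- lapply(layer_ids(), function(L)
    paste0(L, seq_len(sz[[L]])))
  names(codes) <- layer_ids()
  lex <- lexicon_state(codes$E, codes$A, codes$G, codes$M)
  uni <- quad_universe(lex)
  n_gm <- sz[["G"]] * sz[["M"]]
  if (config$n_true > n_gm)
    stop("n_true exceeds the number of distinct (G, M) pairs (", n_gm, ")",
         call. = FALSE)
  # distinct (G, M) orientations and distinct (E, A) contexts: a planted
  # world in which one context never asserts two opposed goal/meaning
  # pairs, i.e. truth the compatibility rules themselves can express
  gm_grid <- expand.grid(G = codes$G, M = codes$M,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ea_grid <- expand.grid(E = codes$E, A = codes$A,
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (config$n_true > nrow(ea_grid))
    stop("n_true exceeds the number of distinct (E, A) contexts",
         call. = FALSE)
  pick <- sample.int(nrow(gm_grid), config$n_true)
  pick_ea <- sample.int(nrow(ea_grid), config$n_true)
  true_quads <- lapply(seq_len(config$n_true), function(i)
    quadruple(ea_grid$E[pick_ea[i]], ea_grid$A[pick_ea[i]],
              gm_grid$G[pick[i]], gm_grid$M[pick[i]]))
  true_keys <- vapply(true_quads, quad_key, "")
  # compatibility tables: planted triples/pairs high, everything else low
  k3 <- unique(paste(uni$A, uni$G, uni$M, sep = "|"))
  phi_base <- stats::setNames(rep(config$phi_false, length(k3)), k3)
  k2 <- unique(paste(uni$E, uni$A, sep = "|"))
  phi_view <- stats::setNames(rep(config$view_penalty, length(k2)), k2)
  for (q in true_quads) {
    phi_base[paste(q[["A"]], q[["G"]], q[["M"]], sep = "|")] <- config$phi_true
    phi_view[paste(q[["E"]], q[["A"]], sep = "|")] <- config$view_bonus
  }
  compat <- compatibility_model(phi_base, phi_view, phi_kin_coeff = 1,
                                lambda_focus = 0)
  obs_model <- observation_model(lapply(codes, function(cs)
    list(mean = simplex_means(cs, config$separation),
         sd = config$noise_sd)))
  actions <- list(
    overview = probe_action("overview",
                            channels = list(E = codes$E),
                            execution_time = 1),
    focus = probe_action("focus",
                         channels = list(E = codes$E, G = codes$G,
                                         M = codes$M),
                         execution_time = 1.5))
  noise_factors <- list(
    overview = c(E = 1, A = 1, G = 1, M = 1),
    focus = c(E = 1.1, A = 1.1, G = 0.7, M = 0.7))
  subgoal <- ordinal_model(config$gamma, config$rating_weights)
  exercise <- ordinal_model(config$delta, config$rating_weights)
  structure(list(config = config, seed = seed,
                 lexicon_state = lex, universe = uni,
                 true_quads = true_quads, true_keys = true_keys,
                 orientation_pairs = sort(unique(
                   vapply(true_quads, function(q)
                     paste(q[["G"]], q[["M"]], sep = "|"), ""))),
                 compat_model = compat, obs_model = obs_model,
                 actions = actions, noise_factors = noise_factors,
                 subgoal_model = subgoal, exercise_model = exercise,
                 mqe_model = mqe_model(config$mqes),
                 focus_prior = focus_prior(config$focus_sets)),
            class = "planted_network")
}

#' @export
print.planted_network <- function(x, ...) {
  cat(sprintf("<planted network: universe %d, %d true quads, seed %d>\n",
              x$universe$n, length(x$true_keys), x$seed))
  invisible(x)
}

#' Write the planted ground truth to JSON
#'
#' @param network A [generate_network()] result.
#' @param path Output file.
#' @export
ground_truth_json <- function(network, path = NULL) {
  obj <- list(seed = network$seed,
              lexicon_sizes = as.list(network$config$lexicon_sizes),
              true_quads = as.list(network$true_keys),
              orientation_pairs = as.list(network$orientation_pairs))
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(s, path)
  invisible(as.character(s))
}

#' ARAT session specification
#'
#' Structure of one synthetic assessment session: 19 exercises, each with
#' the four canonical segment types in order, and a uniform 3-5 instants
#' per segment (desk-scale runs finish in minutes at these sizes).
#'
#' @param n_exercises Exercises per session (default 19).
#' @param segments Character segment types per exercise, canonical order.
#' @param instants_range Inclusive range for instants per segment.
#' @param orientation_stay Self-transition probability of the generative
#'   orientation chain (default 0.9: sticky, temporally coherent).
#' @param span_jitter Max absolute jitter (instants) applied to proposal
#'   boundaries.
#' @param span_type_acc Probability a proposal carries the true segment
#'   type.
#' @export
session_spec <- function(n_exercises = 19L, segments = segment_types(),
                         instants_range = c(3L, 5L),
                         orientation_stay = 0.9,
                         span_jitter = 1L, span_type_acc = 0.9) {
  stopifnot(n_exercises >= 1L, length(segments) >= 1L,
            instants_range[1] >= 1L,
            instants_range[2] >= instants_range[1])
  list(n_exercises = as.integer(n_exercises), segments = segments,
       instants_range = as.integer(instants_range),
       orientation_stay = orientation_stay,
       span_jitter = as.integer(span_jitter),
       span_type_acc = span_type_acc)
}

#' Generate synthetic ARAT sessions from a planted network
#'
#' The generative story per session: a sticky Markov chain over the planted
#' (goal, meaning) orientations; at each instant the orientation's planted
#' quadruple is in effect (active with the configured activation rate) and
#' emits per-layer features from the observation model under each probe
#' action's noise factors; per segment, a latent embedding drives the
#' cumulative-logit sub-goal rating and the Bernoulli MQE statuses; pooled
#' embeddings drive the exercise rating; span proposals are the true spans
#' with jittered boundaries, mostly-correct types and Beta-distributed
#' confidences (Beta(9, 1) when the type is right, Beta(2, 2) for wrong-type
#' distractors).
#'
#' @param network A [generate_network()] result.
#' @param spec A [session_spec()].
#' @param n_sessions Number of sessions.
#' @param seed Integer seed (independent of the network seed).
#' @return List of `arat_session_data` objects; each has `$instants` (a
#'   data.frame with the time index, true symbols, orientation and active
#'   flag), `$features` (per action, per layer, instants x dim matrices),
#'   `$segments`, `$exercises`, `$spans`, `$evidence` (per-frame segment
#'   label scores per exercise).
#' @export
generate_sessions <- function(network, spec = session_spec(),
                              n_sessions = 1L, seed = 1L) {
  set.seed(seed)
  cfg <- network$config
  pairs <- network$orientation_pairs
  # a null network (no planted quads): orientations wander uniformly over
  # the full (G, M) grid and no edge is ever truly in effect
  null_network <- length(pairs) == 0L
  if (null_network)
    pairs <- sort(unique(network$universe$gm))
  K <- sticky_kernel(pairs, spec$orientation_stay)
  quad_of_gm <- stats::setNames(network$true_keys,
                                vapply(network$true_quads, function(q)
                                  paste(q[["G"]], q[["M"]], sep = "|"), ""))
  lapply(seq_len(n_sessions), function(s_idx) {
    rows <- list(); seg_rows <- list(); ex_rows <- list()
    span_rows <- list(); evid <- list()
    feats <- lapply(network$actions, function(a)
      lapply(network$obs_model, function(m) NULL))
    o <- sample(pairs, 1)
    k_global <- 0L
    for (ex in seq_len(spec$n_exercises)) {
      hs <- NULL
      t_in_ex <- 0L
      ex_types <- spec$segments
      n_inst <- sample(seq(spec$instants_range[1], spec$instants_range[2]),
                       length(ex_types), replace = TRUE)
      bounds <- cumsum(n_inst)
      starts <- c(1L, utils::head(bounds, -1) + 1L)
      for (sg in seq_along(ex_types)) {
        k_global <- k_global + 1L
        ty <- ex_types[sg]
        # segment embedding and expert-facing truth
        h <- stats::rnorm(cfg$feature_dim)
        eta <- sum(network$subgoal_model$weights * h)
        lat <- eta + stats::rlogis(1)
        y <- sum(lat > network$subgoal_model$thresholds)
        mq <- vapply(names(cfg$mqes), function(q)
          stats::rbinom(1, 1, mqe_probability(network$mqe_model, q, h)),
          integer(1))
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
          exercise = ex, segment = sg, type = ty, rating = y,
          t(stats::setNames(h, paste0("h", seq_along(h)))),
          t(stats::setNames(mq, paste0("mqe_", names(mq)))),
          stringsAsFactors = FALSE)
        for (i in seq_len(n_inst[sg])) {
          t_in_ex <- t_in_ex + 1L
          if (length(pairs) > 1L)
            o <- sample(pairs, 1, prob = K[o, ])
          if (null_network) {
            gmp <- strsplit(o, "|", fixed = TRUE)[[1]]
            q <- quadruple(sample(network$lexicon_state$E$codes, 1),
                           sample(network$lexicon_state$A$codes, 1),
                           gmp[1], gmp[2])
            act <- FALSE
          } else {
            q <- quad_from_key(quad_of_gm[[o]])
            act <- stats::runif(1) < cfg$activation_rate
          }
          rows[[length(rows) + 1L]] <- data.frame(
            session = s_idx, exercise = ex, segment = sg,
            segment_type = ty, k = k_global, t_in_exercise = t_in_ex,
            pos = i, seg_len = n_inst[sg],
            sE = q[["E"]], sA = q[["A"]], sG = q[["G"]], sM = q[["M"]],
            orientation = o, active = act, stringsAsFactors = FALSE)
          for (a in names(network$actions)) {
            nf <- network$noise_factors[[a]]
            for (L in layer_ids()) {
              m <- network$obs_model[[L]]
              mu <- m$mean[q[[L]], ]
              x <- mu + stats::rnorm(length(mu),
                                     sd = m$sd[q[[L]], ] * nf[[L]])
              feats[[a]][[L]] <- rbind(feats[[a]][[L]], x)
            }
          }
        }
      }
      # exercise-level truth from pooled embeddings
      hmat <- do.call(rbind, lapply(
        seg_rows[(length(seg_rows) - length(ex_types) + 1):length(seg_rows)],
        function(r) unlist(r[paste0("h", seq_len(cfg$feature_dim))],
                           use.names = FALSE)))
      H <- pool_embeddings(hmat)
      etaT <- sum(network$exercise_model$weights * H)
      yT <- sum(etaT + stats::rlogis(1) > network$exercise_model$thresholds)
      ex_rows[[length(ex_rows) + 1L]] <- data.frame(
        exercise = ex, rating = yT,
        t(stats::setNames(H, paste0("H", seq_along(H)))),
        stringsAsFactors = FALSE)
      # frame evidence and span proposals for the decoder
      Tn <- sum(n_inst)
      th <- matrix(0.5, Tn, length(spec$segments),
                   dimnames = list(NULL, spec$segments))
      truth_lab <- rep(ex_types, n_inst)
      for (t in seq_len(Tn))
        th[t, ] <- th[t, ] + 2 * (colnames(th) == truth_lab[t]) +
          stats::rnorm(ncol(th), sd = 0.5)
      th <- exp(th) / rowSums(exp(th))
      evid[[ex]] <- th
      # jitter the boundaries between consecutive segments (a shared
      # shift keeps the proposals a partition, never overlapping)
      n_seg <- length(ex_types)
      jb <- bounds
      if (spec$span_jitter > 0L && n_seg > 1L) {
        for (sg in seq_len(n_seg - 1L)) {
          d <- sample(seq(-spec$span_jitter, spec$span_jitter), 1)
          lo <- if (sg == 1L) 1L else jb[sg - 1L] + 1L
          jb[sg] <- clamp(bounds[sg] + d, lo, bounds[sg + 1L] - 1L)
        }
      }
      starts_p <- c(1L, utils::head(jb, -1) + 1L)
      for (sg in seq_len(n_seg)) {
        correct <- stats::runif(1) < spec$span_type_acc
        ty_p <- if (correct) ex_types[sg]
                else sample(setdiff(spec$segments, ex_types[sg]), 1)
        conf <- if (correct) stats::rbeta(1, 9, 1) else stats::rbeta(1, 2, 2)
        span_rows[[length(span_rows) + 1L]] <- data.frame(
          exercise = ex, segment = sg,
          true_start = starts[sg], true_end = bounds[sg],
          start = starts_p[sg], end = jb[sg],
          true_type = ex_types[sg], type = ty_p, confidence = conf,
          stringsAsFactors = FALSE)
      }
    }
    structure(list(session = s_idx,
                   instants = do.call(rbind, rows),
                   features = lapply(feats, function(af)
                     lapply(af, function(m) {
                       rownames(m) <- NULL
                       m
                     })),
                   segments = do.call(rbind, seg_rows),
                   exercises = do.call(rbind, ex_rows),
                   spans = do.call(rbind, span_rows),
                   evidence = evid),
              class = "arat_session_data")
  })
}

#' Synthetic noisy expert
#'
#' Emulates inter-rater variability: ordinal ratings suffer off-by-one
#' errors with a configured probability (split up/down, clamped at the
#' scale ends), binary MQE statuses flip at a small rate, and validation
#' review scores are Beta draws whose means differ by the configured gap
#' between true planted edges and everything else.
#'
#' @param off_by_one Probability of an off-by-one ordinal error (default
#'   0.15).
#' @param mqe_flip MQE flip rate in `[0, 0.5)` (default 0.1).
#' @param val_true,val_false Beta shape pairs for validation scores of true
#'   / false edges (defaults mean 0.85 and 0.45: a 0.4 gap).
#' @return An object of class `synthetic_expert`.
#' @export
synthetic_expert <- function(off_by_one = 0.15, mqe_flip = 0.1,
                             val_true = c(17, 3), val_false = c(9, 11)) {
  stopifnot(off_by_one >= 0, off_by_one < 1, mqe_flip >= 0, mqe_flip < 0.5)
  structure(list(off_by_one = off_by_one, mqe_flip = mqe_flip,
                 val_true = val_true, val_false = val_false),
            class = "synthetic_expert")
}

#' Noisy expert labels for synthetic truth
#'
#' @param expert A [synthetic_expert()].
#' @param ratings Integer vector of true ordinal ratings (0-3).
#' @param mqe Optional 0/1 matrix of true MQE statuses.
#' @param seed Integer seed (independent of the generator seeds).
#' @return List with `ratings` (noisy), `mqe` (flipped matrix or NULL).
#' @export
label_with_expert <- function(expert, ratings, mqe = NULL, seed = 1L) {
  set.seed(seed)
  n <- length(ratings)
  err <- stats::runif(n) < expert$off_by_one
  dir <- sample(c(-1L, 1L), n, replace = TRUE)
  noisy <- ratings + ifelse(err, dir, 0L)
  noisy <- pmin(pmax(noisy, 0L), 3L)
  out_mqe <- NULL
  if (!is.null(mqe)) {
    flip <- matrix(stats::runif(length(mqe)) < expert$mqe_flip,
                   nrow(mqe), ncol(mqe))
    out_mqe <- abs(mqe - flip * 1L)
    dimnames(out_mqe) <- dimnames(mqe)
  }
  list(ratings = as.integer(noisy), mqe = out_mqe)
}

#' Validation review scores from the synthetic expert
#'
#' Scores are biased toward 1 for planted true edges and toward 0 for
#' everything else; draws are deterministic given the seed and the key
#' order.
#'
#' @param expert A [synthetic_expert()].
#' @param quad_keys Character quad keys under review.
#' @param true_keys Character keys of the planted edges.
#' @param seed Integer seed.
#' @return Named numeric scores in `[0, 1]`.
#' @export
expert_validation_scores <- function(expert, quad_keys, true_keys,
                                     seed = 1L) {
  set.seed(seed)
  is_true <- quad_keys %in% true_keys
  v <- numeric(length(quad_keys))
  for (i in seq_along(quad_keys)) {
    sh <- if (is_true[i]) expert$val_true else expert$val_false
    v[i] <- stats::rbeta(1, sh[1], sh[2])
  }
  stats::setNames(v, quad_keys)
}
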