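# Planted-structure experiment: how much does promoting a genuinely missing
# symbol sharpen the orientation posterior?  One run plants a small network,
# hides one true Goal symbol from the inference model, lets the proposal
# mechanism surface a candidate from co-occurrence clusters of partial
# tuples, promotes it through the validation gate, and compares the mean
# orientation entropy before and after the vocabulary update.

reduce_lexicon <- function(model, layer, code) {
  lex <- model$lexicon_state
  lx <- lex[[layer]]
  lx$codes <- setdiff(lx$codes, code)
  lex[[layer]] <- lx
  om <- model$obs_model
  m <- om[[layer]]
  keep <- setdiff(rownames(m$mean), code)
  m$mean <- m$mean[keep, , drop = FALSE]
  m$sd <- m$sd[keep, , drop = FALSE]
  m$prior <- m$prior[keep] / sum(m$prior[keep])
  om[[layer]] <- m
  list(lexicon_state = lex, obs_model = om)
}

#' Missing-symbol promotion experiment
#'
#' Generates a planted network whose three true quadruples use three
#' distinct Goal symbols, hides one of them from the inference model, and
#' runs the processing cycle on one synthetic session.  While the symbol is
#' missing, the affected orientation cannot be represented and its instants
#' leave the posterior diffuse; the co-occurrence trigger accumulates the
#' unexplained partial tuple (E, A, *, M), proposes a candidate Goal code,
#' the validation gate accepts it, and the promoted code (with a
#' class-conditional fitted from the trigger's retained features) is added
#' to the lexicon, observation model and compatibility tables.  The run is
#' then repeated with the augmented model on the same session.
#'
#' @param seed Integer seed.
#' @param n_exercises Exercises in the probe session (default 5).
#' @param posterior_floor Co-occurrence trigger floor on the best completing
#'   Goal [explanation_score()] (default 0.5; the closed-world posterior
#'   alone stays confident between the remaining classes, so the
#'   density-calibrated score is what exposes the unexplained instants).
#' @param cooccur_threshold Sightings required to fire the proposal
#'   (default 10).
#' @return List with `delta_H` (mean orientation entropy before minus
#'   after over the affected instants — those the trigger flagged as
#'   unexplained — in bits), `delta_H_run` (the same difference over the
#'   whole run; this conflates the enhancement's effect with the larger
#'   support's higher baseline entropy on unaffected instants), `proposed`
#'   (the candidate code), `n_gain` (the observability gain of the
#'   augmentation), `accepted` (validation decision), and the two entropy
#'   trajectories.
#' @export
missing_symbol_experiment <- function(seed = 1L, n_exercises = 12L,
                                      posterior_floor = 0.5,
                                      cooccur_threshold = 10L) {
  cfg <- network_config(lexicon_sizes = c(E = 2L, A = 2L, G = 3L, M = 2L),
                        n_true = 3L, noise_sd = 0.5)
  # require three distinct true Goal symbols so one can be hidden cleanly
  offset <- 0L
  repeat {
    network <- generate_network(cfg, seed + offset * 100003L)
    gs <- vapply(network$true_quads, function(q) q[["G"]], "")
    if (length(unique(gs)) == 3L) break
    offset <- offset + 1L
  }
  q_star <- network$true_quads[[1]]
  g_star <- q_star[["G"]]
  sessions <- generate_sessions(network,
                                session_spec(n_exercises = n_exercises,
                                             instants_range = c(3L, 4L)),
                                1L, seed + 1L)
  config <- run_config(policy = "fixed")
  red <- reduce_lexicon(as_dbn_model(network), "G", g_star)
  model_red <- as_dbn_model(network, lexicon_state = red$lexicon_state,
                            obs_model = red$obs_model)
  run_before <- dbn_run(model_red, sessions, config)

  # --- proposal from co-occurrence clusters of partial tuples
  trigger <- proposal_trigger_state(window = 400L)
  feats <- sessions[[1]]$features[[1]]
  flagged <- integer(0)
  for (i in seq_len(nrow(sessions[[1]]$instants))) {
    posts <- lapply(layer_ids(), function(L)
      symbolize_layer(feats[[L]][i, ], red$obs_model, L))
    names(posts) <- layer_ids()
    expl <- explanation_score(feats$G[i, ], red$obs_model, "G")
    if (expl$score < posterior_floor) {
      flagged <- c(flagged, i)
      map_of <- function(L) names(which.max(posts[[L]]$probs))
      trigger <- update_trigger(trigger, partial = list(
        key = paste(map_of("E"), map_of("A"), "*", map_of("M"), sep = "|"),
        free_layer = "G", best_posterior = expl$score,
        features = feats$G[i, ]))
    }
  }
  pc <- proposal_config(cooccur_threshold = cooccur_threshold,
                        posterior_floor = posterior_floor)
  props <- propose_symbols(trigger, red$lexicon_state, pc)
  if (length(props) == 0L)
    return(list(delta_H = 0, delta_H_run = 0, proposed = NA_character_,
                accepted = 0L, n_gain = NA_real_,
                H_before = run_before$logs$instants$entropy_bits,
                H_after = run_before$logs$instants$entropy_bits))
  cand <- props[[1]]
  cluster <- attr(cand, "features")

  # --- validation gate on the completed candidate edge
  src <- attr(cand, "source")
  parts <- strsplit(src, "|", fixed = TRUE)[[1]]
  cand_quad <- quadruple(parts[1], parts[2], cand$code, parts[4])
  n_seen <- length(cluster)
  edge <- c4_edge(cand_quad, status = "active", activation_count = n_seen,
                  confidence = edge_confidence(n_seen), iters_active = n_seen)
  vcfg <- validation_config(delta_period = min(n_seen, 5L))
  gate <- validation_gate(edge, validation_score = 0.9, vcfg)
  if (gate$decision != 1L)
    return(list(delta_H = 0, delta_H_run = 0, proposed = cand$code,
                accepted = 0L, n_gain = NA_real_,
                H_before = run_before$logs$instants$entropy_bits,
                H_after = run_before$logs$instants$entropy_bits))

  # --- promote and augment the model
  lex_aug <- promote_symbol(red$lexicon_state, cand, gate$decision)
  obs_aug <- extend_observation_model(red$obs_model, "G", cand$code, cluster)
  compat_aug <- network$compat_model
  compat_aug$phi_base[paste(cand_quad[["A"]], cand$code, cand_quad[["M"]],
                            sep = "|")] <- cfg$phi_true
  # observability gain of the augmentation under post-promotion posteriors
  i0 <- which.min(vapply(seq_len(nrow(sessions[[1]]$instants)), function(i)
    max(symbolize_layer(feats$G[i, ], red$obs_model, "G")$probs),
    numeric(1)))
  posts_aug <- lapply(layer_ids(), function(L)
    symbolize_layer(feats[[L]][i0, ], obs_aug, L))
  names(posts_aug) <- layer_ids()
  ngain <- observability_gain(
    red$lexicon_state, lex_aug, compat_aug,
    tau = compatibility_threshold(config$schedule, 0.5),
    posteriors = lapply(posts_aug, function(p) p$probs),
    kin_uncertainty = network$config$kin_uncertainty)

  model_aug <- as_dbn_model(network, lexicon_state = lex_aug,
                            obs_model = obs_aug, compat_model = compat_aug)
  run_after <- dbn_run(model_aug, sessions, config)
  H_before <- run_before$logs$instants$entropy_bits
  H_after <- run_after$logs$instants$entropy_bits
  list(delta_H = mean(H_before[flagged]) - mean(H_after[flagged]),
       delta_H_run = mean(H_before) - mean(H_after),
       proposed = cand$code, accepted = gate$decision, n_gain = ngain,
       flagged = flagged, H_before = H_before, H_after = H_after)
}

#' Edge-discovery recovery study
#'
#' Runs the full discovery pipeline under the default study conditions
#' (K = 6 planted quadruples in a 3 x 4 x 3 x 3 universe, 30 synthetic
#' sessions, moderate observation noise) once per seed and scores the
#' validated edge set against the planted truth.
#'
#' @param seeds Integer seeds, one run per seed.
#' @param n_sessions Sessions per run (default 30).
#' @param config A [network_config()] (default study conditions).
#' @param run_cfg A [run_config()].
#' @return data.frame with seed, precision, recall, n_validated,
#'   n_instants.
#' @export
edge_discovery_study <- function(seeds = 1:10, n_sessions = 30L,
                                 config = network_config(),
                                 run_cfg = run_config()) {
  rows <- lapply(seeds, function(seed) {
    net <- generate_network(config, seed = seed)
    ss <- generate_sessions(net, session_spec(), n_sessions,
                            seed = seed + 1000L)
    scores <- expert_validation_scores(synthetic_expert(),
                                       net$universe$keys, net$true_keys,
                                       seed = seed + 2000L)
    run <- dbn_run(net, ss, run_cfg, validation_scores = scores)
    m <- edge_metrics(run$validated, net$true_keys)
    data.frame(seed = seed, precision = m$precision, recall = m$recall,
               n_validated = m$n_predicted,
               n_instants = nrow(run$logs$instants))
  })
  do.call(rbind, rows)
}
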