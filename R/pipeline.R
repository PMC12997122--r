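# End-to-end driver: configuration, the per-instant processing cycle
# (top-down prediction, probe-action selection, symbolization, gated c4
# discovery, history update, orientation update, periodic validation),
# reporting, and reproducible simulation output.

#' Runner configuration
#'
#' All tunable parameters of the processing cycle, with package defaults.
#'
#' @param alpha Dirichlet concentration of the coherence smoothing.
#' @param weights Level mixture weights `c(act=, task=, seq=)`.
#' @param tau_min,tau_max,tau_p Compatibility threshold schedule.
#' @param max_attempts Refinement attempts before the error list.
#' @param p0 Background edge rate of the orientation edge factor.
#' @param orientation_stay Self-transition probability of the top-down
#'   kernel.
#' @param policy `"eig"` (information-seeking probe selection) or
#'   `"fixed"` (always the first action).
#' @param c_tau,c_dev_max,n_half,exchange_rate Action-cost parameters.
#' @param lambda_conf,lambda_val,confidence_threshold,delta_period,
#'   decision_threshold,c_half Validation-gate parameters.  The runner's
#'   decision threshold (0.95) sits well above the sigmoid's 0.5 floor so
#'   the gate discriminates between well-supported and weakly supported
#'   edges.
#' @param error_feedback Multiplicative base-measure down-weight for
#'   error-listed quads.
#' @param disable Character subset of
#'   `c("compat", "coherence", "obs", "validation")` for ablations.
#' @export
run_config <- function(alpha = 1,
                       weights = c(act = 0.5, task = 0.3, seq = 0.2),
                       tau_min = 0.5, tau_max = 0.9, tau_p = 2,
                       max_attempts = 3L, p0 = 0.02,
                       orientation_stay = 0.9, policy = c("eig", "fixed"),
                       c_tau = 0.1, c_dev_max = 1, n_half = 100,
                       exchange_rate = 1,
                       lambda_conf = 1, lambda_val = 4,
                       confidence_threshold = 0.6, delta_period = 50L,
                       decision_threshold = 0.97, c_half = 5,
                       error_feedback = 0.5, disable = character()) {
  policy <- match.arg(policy)
  list(alpha = alpha, weights = weights,
       schedule = threshold_schedule(tau_min, tau_max, tau_p),
       max_attempts = as.integer(max_attempts), p0 = p0,
       orientation_stay = orientation_stay, policy = policy,
       cost = cost_model(c_tau, c_dev_max, n_half),
       exchange_rate = exchange_rate,
       validation = validation_config(lambda_conf, lambda_val,
                                      confidence_threshold,
                                      delta_period, decision_threshold,
                                      c_half),
       error_feedback = error_feedback, disable = disable)
}

#' Extract the inference-facing model from a planted network
#'
#' The runner never sees the planted truth: only the lexicons, the
#' compatibility tables, the observation model and the probe actions.
#' Components can be overridden (e.g. to run with a reduced lexicon).
#'
#' @param network A [generate_network()] result.
#' @param ... Named overrides (`lexicon_state`, `obs_model`,
#'   `compat_model`, `actions`, `kin_uncertainty`).
#' @export
as_dbn_model <- function(network, ...) {
  model <- list(lexicon_state = network$lexicon_state,
                obs_model = network$obs_model,
                compat_model = network$compat_model,
                actions = network$actions,
                kin_uncertainty = network$config$kin_uncertainty)
  over <- list(...)
  model[names(over)] <- over
  structure(model, class = "dbn_model")
}

# analytic symbol-identification channel for one probe action: probability
# that MAP symbolization of the (G, M) layers recovers the true orientation,
# from the pairwise error rate of equally separated Gaussian classes
orientation_channel <- function(model, network_noise, action_id, pairs) {
  q_layer <- function(L) {
    m <- model$obs_model[[L]]
    sep <- sqrt(sum((m$mean[1, ] - m$mean[min(2, nrow(m$mean)), ])^2))
    if (nrow(m$mean) < 2) return(1)
    sdv <- mean(m$sd) * network_noise[[action_id]][[L]]
    p_err <- stats::pnorm(-sep / (2 * sdv))
    max(1 - (nrow(m$mean) - 1) * p_err, 1 / nrow(m$mean))
  }
  q <- q_layer("G") * q_layer("M")
  n <- length(pairs)
  ch <- matrix((1 - q) / max(n - 1, 1), n, n,
               dimnames = list(pairs, pairs))
  diag(ch) <- if (n > 1) q else 1
  ch
}

#' Run the bidirectional processing cycle over synthetic sessions
#'
#' For every instant: form the coherence prior from the activation history,
#' predict orientation top-down, select a probe action (expected
#' information gain minus cost), symbolize the action-conditioned features,
#' assemble the MAP candidate quadruple, pass it through the gated pipeline
#' (with refinement and error routing), record activations into the
#' hierarchical counts, update the orientation posterior bottom-up, and at
#' review epochs put well-supported active edges through the validation
#' gate.  Validated edges update the permanent network; persistently
#' failing quads join the error list, which down-weights their base mass in
#' the coherence prior.
#'
#' @param model A [as_dbn_model()] (or a `planted_network`, converted
#'   automatically).
#' @param sessions Sessions from [generate_sessions()].
#' @param config A [run_config()].
#' @param validation_scores Named review scores per quad key (e.g. from
#'   [expert_validation_scores()]); `NULL` disables validation, in which
#'   case no edge is ever validated and active edges simply persist.
#' @return An object of class `dbn_run` with the final `network`
#'   ([network_state()]), `validated` keys, `error_list`, the `counts`, and
#'   `logs` (`$instants`, `$gates`).
#' @export
dbn_run <- function(model, sessions, config = run_config(),
                    validation_scores = NULL) {
  if (inherits(model, "planted_network")) {
    noise_factors <- model$noise_factors
    model <- as_dbn_model(model)
  } else {
    noise_factors <- attr(model, "noise_factors")
  }
  uni <- quad_universe(model$lexicon_state)
  kap <- kappa_vector(model$compat_model, uni, model$kin_uncertainty)
  counts <- edge_counts(uni)
  smoothing <- smoothing_config(uni, config$alpha)
  pairs <- sort(unique(uni$gm))
  tm <- transition_model(sticky_kernel(pairs, config$orientation_stay))
  orient <- orientation_state(pairs)
  network <- network_state(model$lexicon_state)
  registry <- new.env(parent = emptyenv())
  error_list <- integer()
  action_ids <- names(model$actions)
  # probe-policy precomputation
  supp_idx <- lapply(model$actions, function(a) {
    which(uni$E %in% (a$channels$E %||% character()))
  })
  channels <- NULL
  if (config$policy == "eig" && !is.null(noise_factors))
    channels <- lapply(action_ids, function(a)
      orientation_channel(model, noise_factors, a, pairs))
  if (!is.null(channels)) names(channels) <- action_ids

  n_total <- sum(vapply(sessions, function(s) nrow(s$instants), 0L))
  log_t <- integer(n_total); log_session <- integer(n_total)
  log_action <- character(n_total); log_map <- character(n_total)
  log_H <- numeric(n_total); log_dH <- numeric(n_total)
  log_nact <- integer(n_total)
  gate_logs <- vector("list", n_total)
  validated <- character()
  t_global <- 0L
  last_review <- 0L

  for (sess in sessions) {
    inst <- sess$instants
    for (i in seq_len(nrow(inst))) {
      t_global <- t_global + 1L
      prior_coh <- coherence_prior(counts, smoothing, config$weights)
      pred <- top_down_prior(tm, orient)
      # --- probe-action selection
      if (config$policy == "eig" && !is.null(channels)) {
        om <- pred$probs[uni$gm]
        om[is.na(om)] <- 0
        raw <- vapply(action_ids, function(a)
          sum(prior_coh$pi[supp_idx[[a]]] * om[supp_idx[[a]]]), numeric(1))
        pi_exp <- if (sum(raw) > 0) raw / sum(raw) else raw
        eig <- vapply(action_ids, function(a)
          expected_information_gain(pred, channels[[a]]), numeric(1))
        costs <- vapply(action_ids, function(a)
          action_cost(config$cost, model$actions[[a]], pi_exp[[a]],
                      n_eff = t_global), numeric(1))
        act_id <- select_action(model$actions, eig, costs,
                                config$exchange_rate)$id
      } else {
        act_id <- action_ids[1]
      }
      # --- symbolization under the chosen action
      posts <- lapply(layer_ids(), function(L)
        symbolize_layer(sess$features[[act_id]][[L]][i, ], model$obs_model,
                        L))
      names(posts) <- layer_ids()
      map_sym <- vapply(posts, function(p)
        names(p$probs)[which.max(p$probs)], "")
      cand_quad <- quadruple(map_sym[["E"]], map_sym[["A"]],
                             map_sym[["G"]], map_sym[["M"]])
      cand_key <- quad_key(cand_quad)
      time <- time_index(inst$session[i], inst$exercise[i], inst$k[i],
                         t_global)
      progress <- if (inst$seg_len[i] > 1)
        (inst$pos[i] - 1) / (inst$seg_len[i] - 1) else 1
      active_keys <- character()
      if (cand_key %in% validated) {
        active_keys <- cand_key
      } else if (!cand_key %in% names(error_list)) {
        res <- run_gate_pipeline(
          list(c4_edge(cand_quad)),
          list(counts = counts, smoothing = smoothing,
               weights = config$weights, model = model$compat_model,
               schedule = config$schedule, progress = progress,
               network = network, active_set = character(),
               kin_uncertainty = model$kin_uncertainty,
               posteriors = posts, max_attempts = config$max_attempts,
               disable = config$disable))
        gate_logs[[t_global]] <- cbind(t = t_global, res$log)
        for (e in res$active) {
          k <- quad_key(e$quad)
          if (k %in% validated) { active_keys <- c(active_keys, k); next }
          rec <- registry[[k]]
          if (is.null(rec))
            rec <- list(edge = c4_edge(e$quad), last_review = 0L)
          rec$edge <- transition_edge(rec$edge, "pass_all_gates",
                                      c_half = config$validation$c_half)
          registry[[k]] <- rec
          active_keys <- c(active_keys, k)
        }
        for (e in res$errors) {
          k <- quad_key(e$quad)
          if (!k %in% names(error_list)) {
            error_list[k] <- e$attempts
            smoothing <- apply_error_feedback(smoothing, k,
                                              config$error_feedback)
          }
        }
      }
      counts <- record_instant(counts, active_keys, time)
      for (k in ls(registry)) {
        rec <- registry[[k]]
        if (rec$edge$status == "active") {
          rec$edge$iters_active <- rec$edge$iters_active + 1L
          registry[[k]] <- rec
        }
      }
      # --- bottom-up orientation update
      em <- edge_factor_model(uni, kap, prior_coh$psi, config$p0)
      up <- orientation_posterior(pred, NULL, active_keys, em)
      log_dH[t_global] <- entropy_delta(pred, up$state)
      orient <- up$state
      log_t[t_global] <- t_global
      log_session[t_global] <- inst$session[i]
      log_action[t_global] <- act_id
      log_map[t_global] <- up$map
      log_H[t_global] <- orient$entropy_bits
      log_nact[t_global] <- length(active_keys)
      # --- periodic validation review
      if (!is.null(validation_scores) &&
          !"validation" %in% config$disable &&
          t_global - last_review >= config$validation$delta_period) {
        last_review <- t_global
        for (k in ls(registry)) {
          rec <- registry[[k]]
          e <- rec$edge
          if (e$status != "active") next
          if (e$confidence < config$validation$confidence_threshold) next
          if (e$iters_active < config$validation$delta_period) next
          if (rec$last_review > 0L &&
              t_global - rec$last_review < config$validation$delta_period)
            next
          v <- validation_scores[k]
          if (is.na(v)) next
          g <- validation_gate(e, unname(v), config$validation)
          rec$last_review <- t_global
          if (g$decision == 1L) {
            e <- transition_edge(e, "validate")
            validated <- c(validated, k)
            network$validated_edges <-
              c(network$validated_edges, list(e))
            rm(list = k, envir = registry)
          } else {
            registry[[k]] <- rec
          }
        }
      }
    }
  }
  network$error_list <- error_list
  gates <- Filter(Negate(is.null), gate_logs)
  structure(list(network = network, validated = sort(validated),
                 error_list = error_list, counts = counts,
                 registry = as.list(registry),
                 logs = list(
                   instants = data.frame(
                     t = log_t, session = log_session,
                     action = log_action, map_orientation = log_map,
                     entropy_bits = log_H, delta_H = log_dH,
                     n_active = log_nact, stringsAsFactors = FALSE),
                   gates = if (length(gates)) do.call(rbind, gates)
                           else NULL)),
            class = "dbn_run")
}

#' @export
print.dbn_run <- function(x, ...) {
  cat(sprintf(
    "<dbn run: %d instants, %d validated edges, %d error-listed>\n",
    nrow(x$logs$instants), length(x$validated), length(x$error_list)))
  invisible(x)
}

#' Precision / recall of a discovered edge set
#'
#' @param predicted Character keys of discovered (validated) edges.
#' @param truth Character keys of the planted edges.
#' @return List with `precision` (NA when nothing was predicted, reported
#'   with `n_predicted = 0`), `recall`, `tp`, `n_predicted`, `n_truth`.
#' @export
edge_metrics <- function(predicted, truth) {
  tp <- length(intersect(predicted, truth))
  list(precision = if (length(predicted) == 0L) NA_real_
                   else tp / length(predicted),
       recall = if (length(truth) == 0L) NA_real_ else tp / length(truth),
       tp = tp, n_predicted = length(predicted), n_truth = length(truth))
}

#' Summarize a run against planted truth
#'
#' @param run A [dbn_run()] result.
#' @param network The [generate_network()] truth (or a character vector of
#'   true quad keys).
#' @return List with the edge metrics, the entropy trajectory summary
#'   (mean entropy, mean per-instant entropy reduction), and gate
#'   statistics (routes table, mean coherence gain among evaluated
#'   candidates).
#' @export
dbn_report <- function(run, network) {
  truth <- if (is.character(network)) network else network$true_keys
  m <- edge_metrics(run$validated, truth)
  gl <- run$logs$gates
  list(edges = m,
       mean_entropy_bits = mean(run$logs$instants$entropy_bits),
       mean_delta_H = mean(run$logs$instants$delta_H),
       gate_routes = if (!is.null(gl)) table(gl$route) else table(character()),
       mean_delta_C = if (!is.null(gl)) mean(gl$delta_C, na.rm = TRUE)
                      else NA_real_)
}

#' Simulate a complete synthetic study to disk
#'
#' Generates a planted network, sessions and noisy expert labels, and
#' writes ground truth (JSON), span proposals and expert labels (CSV) plus
#' a manifest of MD5 hashes; identical configuration and seed reproduce
#' byte-identical files.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A [network_config()].
#' @param spec A [session_spec()].
#' @param n_sessions Number of sessions.
#' @param seed Root seed; generator stages consume fixed offsets of it so
#'   stages stay independent.
#' @return Invisibly, the manifest data.frame.
#' @export
dbn_simulate <- function(out_dir, config = network_config(),
                         spec = session_spec(), n_sessions = 3L,
                         seed = 1L) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  network <- generate_network(config, seed)
  sessions <- generate_sessions(network, spec, n_sessions, seed + 1L)
  expert <- synthetic_expert()
  ground_truth_json(network, file.path(out_dir, "ground_truth.json"))
  spans <- do.call(rbind, lapply(sessions, function(s)
    cbind(session = s$session, s$spans)))
  utils::write.csv(spans, file.path(out_dir, "spans.csv"),
                   row.names = FALSE)
  segs <- do.call(rbind, lapply(sessions, function(s)
    cbind(session = s$session,
          s$segments[c("exercise", "segment", "type", "rating")])))
  lab <- label_with_expert(expert, segs$rating, seed = seed + 2L)
  segs$expert_rating <- lab$ratings
  utils::write.csv(segs, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  files <- c("ground_truth.json", "spans.csv", "labels.csv")
  manifest <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(out_dir, files))),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
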