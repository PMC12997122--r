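# The gated pipeline: compatibility scoring with a scheduled threshold and
# the two structural compatibility rules, the observability gain, sequential
# gate evaluation with refinement and error routing, and the
# confidence-plus-expert validation gate.

DET_CLAMP <- 1e-12

#' Compatibility model
#'
#' Holds the additive logit terms of the compatibility score: a base table
#' over (A, G, M) triples, a view-preference table over (E, A) pairs, the
#' kinematic evidence-quality coefficient (`phi_kin = -alpha * log det
#' Sigma_kin`), the focus-prior weight, and the map from predicted movement
#' quality evidence to a logit contribution.  Missing table entries
#' contribute 0.
#'
#' @param phi_base Named numeric, keys `"sA|sG|sM"`.
#' @param phi_view Named numeric, keys `"sE|sA"`.
#' @param phi_kin_coeff Positive kinematic coefficient (default 1).
#' @param lambda_focus Nonnegative focus-prior weight (default 0).
#' @param phi_mqe Function mapping a predicted MQE probability in (0,1) to a
#'   real logit term (default: the logit itself, clamped).
#' @return An object of class `compatibility_model`.
#' @export
compatibility_model <- function(phi_base = numeric(), phi_view = numeric(),
                                phi_kin_coeff = 1, lambda_focus = 0,
                                phi_mqe = NULL) {
  stopifnot(phi_kin_coeff > 0, lambda_focus >= 0)
  if (is.null(phi_mqe))
    phi_mqe <- function(p) stats::qlogis(clamp(p, 1e-6, 1 - 1e-6))
  structure(list(phi_base = phi_base, phi_view = phi_view,
                 phi_kin_coeff = phi_kin_coeff, lambda_focus = lambda_focus,
                 phi_mqe = phi_mqe),
            class = "compatibility_model")
}

phi_kin_term <- function(model, kin_uncertainty) {
  if (is.null(kin_uncertainty)) return(0)
  d <- if (is.matrix(kin_uncertainty)) det(kin_uncertainty)
       else as.numeric(kin_uncertainty)
  if (d <= 0) stop("non-positive determinant of kin_uncertainty",
                   call. = FALSE)
  -model$phi_kin_coeff * log(max(d, DET_CLAMP))
}

#' Compatibility score of a quadruple
#'
#' `kappa = sigmoid(phi0(A,G,M) + phi_view(E,A) + phi_kin + lambda_focus *
#' focus_term + mqe_term)`, monotone increasing in every term; absent terms
#' contribute 0.
#'
#' @param model A [compatibility_model()].
#' @param quad A `quadruple`.
#' @param kin_uncertainty Positive-definite matrix or positive scalar, or
#'   `NULL` to omit the kinematic term.
#' @param focus_term `log pi_focus(m | sA)` (or 0 when no focus prior
#'   applies); weighted by `lambda_focus`.
#' @param mqe_term Precomputed MQE evidence logit (or 0).
#' @return `kappa` in (0, 1).
#' @export
compatibility_score <- function(model, quad, kin_uncertainty = NULL,
                                focus_term = 0, mqe_term = 0) {
  k3 <- paste(quad[["A"]], quad[["G"]], quad[["M"]], sep = "|")
  k2 <- paste(quad[["E"]], quad[["A"]], sep = "|")
  phi0 <- unname(model$phi_base[k3]); if (is.na(phi0)) phi0 <- 0
  phiv <- unname(model$phi_view[k2]); if (is.na(phiv)) phiv <- 0
  stats::plogis(phi0 + phiv + phi_kin_term(model, kin_uncertainty) +
                model$lambda_focus * focus_term + mqe_term)
}

# vectorized kappa over a universe (kin shared)
kappa_vector <- function(model, universe, kin_uncertainty = NULL,
                         focus_terms = 0, mqe_terms = 0) {
  k3 <- paste(universe$A, universe$G, universe$M, sep = "|")
  k2 <- paste(universe$E, universe$A, sep = "|")
  phi0 <- model$phi_base[k3]; phi0[is.na(phi0)] <- 0
  phiv <- model$phi_view[k2]; phiv[is.na(phiv)] <- 0
  p <- stats::plogis(unname(phi0) + unname(phiv) +
                     phi_kin_term(model, kin_uncertainty) +
                     model$lambda_focus * focus_terms + mqe_terms)
  stats::setNames(p, universe$keys)
}

#' Scheduled compatibility threshold
#'
#' `tau(progress) = tau_min + (tau_max - tau_min) * progress^p`: permissive
#' early in an action segment (exploration), selective late (exploitation);
#' nondecreasing in progress.
#'
#' @param tau_min,tau_max Threshold endpoints, `0 < tau_min <= tau_max < 1`.
#' @param p Schedule exponent `>= 1` (default 2).
#' @return `threshold_schedule()` returns a schedule object;
#'   `compatibility_threshold()` evaluates it.
#' @export
threshold_schedule <- function(tau_min = 0.5, tau_max = 0.9, p = 2) {
  stopifnot(tau_min > 0, tau_min <= tau_max, tau_max < 1, p >= 1)
  structure(list(tau_min = tau_min, tau_max = tau_max, p = p),
            class = "threshold_schedule")
}

#' @rdname threshold_schedule
#' @param schedule A `threshold_schedule`.
#' @param progress Normalized progress within the current action segment,
#'   in `[0, 1]`.
#' @export
compatibility_threshold <- function(schedule, progress) {
  if (any(progress < 0 | progress > 1))
    stop("progress outside [0, 1]", call. = FALSE)
  schedule$tau_min + (schedule$tau_max - schedule$tau_min) *
    progress^schedule$p
}

#' Structural compatibility rules
#'
#' Rule 1 (novel elements compatible with existing connectivity): the quad
#' extends the validated network — it shares at least one symbol with a
#' validated edge — without contradicting it.  Rule 2 (novel four-layer
#' connectivity): all four components are novel relative to the validated
#' edges, proposing a genuinely new interpretation.  A contradiction arises
#' when the quad pairs an established (E, A) context with a *replacing*
#' established G or M: the context's validated goals/meanings are opposed
#' rather than extended (novel sub-goal / sub-meaning symbols are additions
#' and remain compatible).  A network without validated edges makes every
#' quad Rule-2 novel.
#'
#' @param quad A `quadruple`.
#' @param network A [network_state()].
#' @return List with `rule1_ok`, `rule2_ok`, `contradiction`, and `pass`
#'   (`(rule1_ok || rule2_ok) && !contradiction`).
#' @export
check_compatibility_rules <- function(quad, network) {
  edges <- network$validated_edges
  if (length(edges) == 0L) {
    return(list(rule1_ok = FALSE, rule2_ok = TRUE, contradiction = FALSE,
                pass = TRUE))
  }
  vq <- lapply(edges, function(e) e$quad)
  est <- lapply(layer_ids(), function(L)
    unique(vapply(vq, function(q) q[[L]], "")))
  names(est) <- layer_ids()
  novel <- vapply(layer_ids(), function(L) !(quad[[L]] %in% est[[L]]), TRUE)
  rule2 <- all(novel)
  # established (E, A) context?
  ea <- paste(quad[["E"]], quad[["A"]], sep = "|")
  ctx_edges <- Filter(function(q)
    paste(q[["E"]], q[["A"]], sep = "|") == ea, vq)
  contradiction <- FALSE
  if (length(ctx_edges) > 0L) {
    gm_ok <- any(vapply(ctx_edges, function(q)
      q[["G"]] == quad[["G"]] && q[["M"]] == quad[["M"]], TRUE))
    if (!gm_ok) {
      # replacing an established G or M under this context contradicts it;
      # attaching a novel sub-goal / sub-meaning does not
      ctx_g <- unique(vapply(ctx_edges, function(q) q[["G"]], ""))
      ctx_m <- unique(vapply(ctx_edges, function(q) q[["M"]], ""))
      g_replaces <- !(quad[["G"]] %in% ctx_g) && !novel[["G"]]
      m_replaces <- !(quad[["M"]] %in% ctx_m) && !novel[["M"]]
      contradiction <- g_replaces || m_replaces
    }
  }
  shares <- any(!novel)
  rule1 <- shares && !contradiction
  list(rule1_ok = rule1, rule2_ok = rule2, contradiction = contradiction,
       pass = (rule1 || rule2) && !contradiction)
}

#' Observability gain of a lexicon augmentation
#'
#' `nGain = (E[|Rc4| | new lexicons] - E[|Rc4| | old lexicons]) /
#' max(|E||A||G||M|, 1)` where the expectation is the sum, over the
#' quadruple universe, of the probability that the quad clears the
#' compatibility threshold under the current symbol posteriors:
#' `E[|Rc4|] = sum_r P(r) 1{kappa(r) > tau}` with `P(r)` the product of the
#' per-layer posterior masses of `r`'s components.  The observability gate
#' passes iff `nGain > 0`; with unchanged lexicons the gain is exactly 0.
#'
#' @param lexicon_before,lexicon_after [lexicon_state()]s differing by at
#'   most the candidate symbol(s).
#' @param kappa_model A [compatibility_model()].
#' @param tau Compatibility threshold used for the indicator.
#' @param posteriors Named list (per layer) of named posterior probability
#'   vectors covering the *after* vocabularies.
#' @param kin_uncertainty Optional shared kinematic uncertainty.
#' @return The scalar `nGain`.
#' @export
observability_gain <- function(lexicon_before, lexicon_after, kappa_model,
                               tau, posteriors, kin_uncertainty = NULL) {
  same <- all(vapply(layer_ids(), function(L)
    identical(lexicon_before[[L]]$codes, lexicon_after[[L]]$codes), TRUE))
  if (same) return(0)
  expect_edges <- function(state) {
    u <- quad_universe(state)
    kap <- kappa_vector(kappa_model, u, kin_uncertainty)
    pr <- posteriors$E[u$E] * posteriors$A[u$A] *
      posteriors$G[u$G] * posteriors$M[u$M]
    if (anyNA(pr)) stop("posteriors must cover the augmented vocabularies",
                        call. = FALSE)
    sum(pr * (kap > tau))
  }
  u_after <- prod(vapply(layer_ids(), function(L)
    length(lexicon_after[[L]]$codes), numeric(1)))
  (expect_edges(lexicon_after) - expect_edges(lexicon_before)) /
    max(u_after, 1)
}

# ---- the sequential pipeline ------------------------------------------------

#' Run candidates through the three-gate pipeline
#'
#' Each candidate passes sequentially through (1) the compatibility check
#' `kappa > tau` plus the structural rules, (2) the coherence gate
#' `DeltaC > 0`, and (3) the observability gate (`nGain > 0` for candidates
#' that augment a lexicon; vacuous for candidates built entirely from
#' established symbols, logged as `NA`).  Gates short-circuit: a later gate
#' is never evaluated after an earlier failure, which is observable as `NA`
#' in the gate log.  Failing candidates are refined — one layer per attempt,
#' in E, A, G, M order, replaced by the next-best posterior symbol — and
#' re-queued until they pass or exhaust `max_attempts`, after which they
#' join the error list.
#'
#' @param candidates List of `c4_edge` objects (status `candidate` or
#'   `refining`).
#' @param context List with `counts`, `smoothing`, `weights`, `model`
#'   (compatibility), `schedule`, `progress`, `network`, `active_set`
#'   (current active keys), and optionally `kin_uncertainty`, `focus_terms`
#'   / `mqe_terms` (named by quad key), `posteriors` (per-layer
#'   `symbol_posterior`s, enabling refinement), `posteriors_prob` and
#'   `lexicon_after` (for the observability gate when a candidate carries
#'   new symbols), `max_attempts`
#'   (default 3), `disable` (character subset of
#'   `c("compat","coherence","obs")` for ablation).
#' @return List with `active`, `refining`, `errors` (lists of edges), and
#'   `log`: a data.frame with columns quad, kappa, tau, delta_C, n_gain,
#'   route (short-circuited gates are `NA`).
#' @export
run_gate_pipeline <- function(candidates, context) {
  ctx <- context
  max_attempts <- ctx$max_attempts %||% 3L
  disable <- ctx$disable %||% character()
  tau <- compatibility_threshold(ctx$schedule, ctx$progress)
  active <- list(); refining <- list(); errors <- list()
  log_rows <- list()
  queue <- candidates
  while (length(queue) > 0L) {
    edge <- queue[[1]]; queue <- queue[-1]
    key <- quad_key(edge$quad)
    term_of <- function(v) {
      if (is.null(v)) return(0)
      x <- unname(v[key])
      if (length(x) == 0L || is.na(x)) 0 else x
    }
    kap <- compatibility_score(ctx$model, edge$quad,
                               ctx$kin_uncertainty %||% NULL,
                               focus_term = term_of(ctx$focus_terms),
                               mqe_term = term_of(ctx$mqe_terms))
    edge$kappa <- kap
    rules <- check_compatibility_rules(edge$quad, ctx$network)
    pass1 <- if ("compat" %in% disable) TRUE
             else (kap > tau) && rules$pass
    dC <- NA_real_; pass2 <- NA
    ngain <- NA_real_; pass3 <- NA
    if (pass1) {
      dC <- coherence_gain(ctx$counts, ctx$smoothing, ctx$weights,
                           candidate = key,
                           active_set = ctx$active_set %||% character())
      pass2 <- if ("coherence" %in% disable) TRUE else dC > 0
      if (pass2) {
        new_syms <- attr(edge$quad, "new_symbols")
        if (is.null(new_syms) || length(new_syms) == 0L ||
            "obs" %in% disable) {
          pass3 <- TRUE        # no vocabulary change: gate is vacuous
        } else {
          ngain <- observability_gain(ctx$network$lexicon_state,
                                      ctx$lexicon_after, ctx$model, tau,
                                      ctx$posteriors_prob,
                                      ctx$kin_uncertainty %||% NULL)
          pass3 <- ngain > 0
        }
      }
    }
    route <- if (isTRUE(pass1) && isTRUE(pass2) && isTRUE(pass3)) "active"
             else if (edge$attempts + 1L >= max_attempts &&
                      !(isTRUE(pass1) && isTRUE(pass2) && isTRUE(pass3)))
               "error" else "refine"
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      quad = key, kappa = kap, tau = tau, delta_C = dC, n_gain = ngain,
      route = route, stringsAsFactors = FALSE)
    if (route == "active") {
      edge <- transition_edge(edge, "pass_all_gates",
                              max_attempts = max_attempts)
      active[[length(active) + 1L]] <- edge
    } else {
      edge <- transition_edge(edge, "fail_gate", max_attempts = max_attempts)
      if (edge$status == "error") {
        errors[[length(errors) + 1L]] <- edge
      } else {
        # refinement: perturb one layer (E -> A -> G -> M round-robin) to
        # the next-best posterior symbol, then re-queue for re-evaluation
        if (!is.null(ctx$posteriors)) {
          L <- layer_ids()[((edge$attempts - 1L) %% 4L) + 1L]
          p <- ctx$posteriors[[L]]$probs
          ord <- names(sort(p, decreasing = TRUE))
          alt <- setdiff(ord, edge$quad[[L]])
          if (length(alt) > 0L) {
            q <- edge$quad
            q[[L]] <- alt[1]
            attr(q, "new_symbols") <- attr(edge$quad, "new_symbols")
            edge$quad <- q
          }
        }
        queue[[length(queue) + 1L]] <- edge
      }
    }
  }
  list(active = active, refining = refining, errors = errors,
       log = if (length(log_rows)) do.call(rbind, log_rows)
             else data.frame(quad = character(), kappa = numeric(),
                             tau = numeric(), delta_C = numeric(),
                             n_gain = numeric(), route = character()))
}

# ---- validation -------------------------------------------------------------

#' Validation gate configuration
#'
#' @param lambda_conf,lambda_val Nonnegative weights on accumulated
#'   confidence and on the expert validation score.
#' @param confidence_threshold Confidence required before an edge is put up
#'   for review.
#' @param delta_period Review iterations an edge must have been observed
#'   active before the gate may be called (`>= 1`).
#' @param decision_threshold Probability above which the decision is 1
#'   (default 0.5).
#' @param c_half Confidence half-count, see [edge_confidence()].
#' @export
validation_config <- function(lambda_conf = 2, lambda_val = 2,
                              confidence_threshold = 0.5,
                              delta_period = 1L,
                              decision_threshold = 0.5, c_half = 5) {
  stopifnot(lambda_conf >= 0, lambda_val >= 0, delta_period >= 1)
  structure(list(lambda_conf = lambda_conf, lambda_val = lambda_val,
                 confidence_threshold = confidence_threshold,
                 delta_period = as.integer(delta_period),
                 decision_threshold = decision_threshold, c_half = c_half),
            class = "validation_config")
}

#' The validation gate
#'
#' Combines accumulated activation confidence with the expert/developer
#' review score: `Pr[u = 1] = sigmoid(lambda_conf * Conf + lambda_val *
#' val)`.  The decision is 1 iff the probability reaches the decision
#' threshold; a positive decision is what triggers the permanent network
#' update.
#'
#' @param edge An active `c4_edge` observed for at least `delta_period`
#'   review iterations.
#' @param validation_score Review score in `[0, 1]`.
#' @param config A [validation_config()].
#' @return List with `probability` and `decision` (0/1).
#' @export
validation_gate <- function(edge, validation_score, config) {
  stopifnot(inherits(edge, "c4_edge"))
  if (edge$status != "active")
    stop("validation gate requires an active edge", call. = FALSE)
  if (edge$iters_active < config$delta_period)
    stop("premature validation: edge observed for fewer than delta_period ",
         "iterations", call. = FALSE)
  stopifnot(validation_score >= 0, validation_score <= 1)
  p <- stats::plogis(config$lambda_conf * edge$confidence +
                     config$lambda_val * validation_score)
  list(probability = p,
       decision = as.integer(p >= config$decision_threshold))
}
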