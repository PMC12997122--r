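# Symbolizers: calibrated maps from probe-action-conditioned layer
# observations to distributions over the layer's established vocabulary,
# plus the proposal mechanism that surfaces candidate codes when the current
# vocabulary explains observations poorly.

#' Shannon entropy in bits
#'
#' @param p Numeric probability vector (need not be named).
#' @return `-sum(p * log2(p))` over positive entries.
#' @export
entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Class-conditional observation model
#'
#' One diagonal-covariance Gaussian per (layer, symbol): a location vector and
#' a spread per feature dimension, plus per-symbol prior weights.  The
#' Gaussian family is closed-form, calibratable and seedable; spreads may be
#' scalar (shared over dimensions).
#'
#' @param layers Named list (names in `layer_ids()`).  Each element is a list
#'   with `mean` (matrix, one row per symbol, rownames = codes), `sd`
#'   (matrix like `mean`, or scalar), and optional `prior` (named weights,
#'   normalized internally; default uniform).
#' @return An object of class `observation_model`.
#' @export
observation_model <- function(layers) {
  stopifnot(is.list(layers), all(names(layers) %in% layer_ids()))
  out <- lapply(layers, function(m) {
    mu <- as.matrix(m$mean)
    stopifnot(!is.null(rownames(mu)))
    sd <- m$sd %||% 1
    if (length(sd) == 1L) sd <- matrix(sd, nrow(mu), ncol(mu),
                                       dimnames = dimnames(mu))
    sd <- as.matrix(sd)
    stopifnot(all(sd > 0), all(dim(sd) == dim(mu)))
    prior <- m$prior %||% stats::setNames(rep(1, nrow(mu)), rownames(mu))
    prior <- prior[rownames(mu)]
    prior <- prior / sum(prior)
    list(mean = mu, sd = sd, prior = prior)
  })
  structure(out, class = "observation_model")
}

#' Per-instant observation bundle
#'
#' The features revealed at one instant under a chosen probe action, with the
#' kinematic-uncertainty proxy that feeds the compatibility score's evidence
#' quality term.
#'
#' @param time A [time_index()].
#' @param probe_action Identifier of the probe action that produced the
#'   observation.
#' @param features Named list of per-layer numeric vectors (finite).
#' @param kin_uncertainty Symmetric positive-definite matrix or positive
#'   scalar proxy for the kinematic covariance.
#' @return An object of class `observation_bundle`.
#' @export
observation_bundle <- function(time, probe_action, features,
                               kin_uncertainty = 1) {
  stopifnot(is.list(features), all(names(features) %in% layer_ids()))
  for (f in features)
    if (!all(is.finite(f))) stop("non-finite features", call. = FALSE)
  if (is.matrix(kin_uncertainty)) {
    if (det(kin_uncertainty) <= 0)
      stop("kin_uncertainty must be positive definite", call. = FALSE)
  } else if (kin_uncertainty <= 0) {
    stop("kin_uncertainty must be positive", call. = FALSE)
  }
  structure(list(time = time, probe_action = probe_action,
                 features = features, kin_uncertainty = kin_uncertainty),
            class = "observation_bundle")
}

#' Symbolize one layer's observation
#'
#' Bayes update of the layer's symbol prior with the class-conditional
#' likelihood of the observed feature vector; the posterior is normalized and
#' its entropy reported in bits.  Deterministic: identical bundle and model
#' give an identical posterior.
#'
#' @param obs An [observation_bundle()] (or a bare numeric feature vector).
#' @param model An [observation_model()] covering every established symbol of
#'   the layer.
#' @param layer One of `layer_ids()`.
#' @return A `symbol_posterior`: list with `layer`, `probs` (named, sums to
#'   1), `entropy_bits`.
#' @export
symbolize_layer <- function(obs, model, layer) {
  assert_layer(layer)
  m <- model[[layer]]
  if (is.null(m) || nrow(m$mean) == 0L)
    stop("empty lexicon / no observation model for layer ", layer,
         call. = FALSE)
  x <- if (inherits(obs, "observation_bundle")) obs$features[[layer]] else obs
  if (is.null(x) || !all(is.finite(x)))
    stop("non-finite or missing features for layer ", layer, call. = FALSE)
  stopifnot(length(x) == ncol(m$mean))
  ll <- vapply(seq_len(nrow(m$mean)), function(i)
    sum(stats::dnorm(x, m$mean[i, ], m$sd[i, ], log = TRUE)), numeric(1))
  lp <- ll + log(m$prior)
  lp <- lp - max(lp)
  p <- exp(lp)
  p <- p / sum(p)
  names(p) <- rownames(m$mean)
  structure(list(layer = layer, probs = p, entropy_bits = entropy_bits(p)),
            class = "symbol_posterior")
}

# ---- proposal mechanism -----------------------------------------------------

#' Proposal trigger state
#'
#' Rolling evidence that the current vocabularies explain observations
#' poorly: a bounded window of near-miss compatibility flags (each attributed
#' to the layer with the weakest posterior at that instant) and co-occurrence
#' counts of partial tuples (some layers fixed, the free layers starred) whose
#' completions never clear the posterior floor.
#'
#' @param window Window length in instants (default 50).
#' @return An object of class `proposal_trigger_state`.
#' @export
proposal_trigger_state <- function(window = 50L) {
  structure(list(window = as.integer(window),
                 near_miss = logical(0), miss_layer = character(0),
                 cooccur = list()),
            class = "proposal_trigger_state")
}

#' @rdname proposal_trigger_state
#' @param trigger A `proposal_trigger_state`.
#' @param near_miss Logical: was this instant's best candidate a near miss
#'   (compatibility in `[tau - delta, tau)`)?
#' @param miss_layer Layer blamed for the near miss (weakest posterior).
#' @param partial Optional list recording a partial-tuple observation:
#'   `key` (e.g. `"E1|A2|*|*"`), `free_layer`, `best_posterior` (best
#'   posterior among completions of `free_layer`), and `features` (the free
#'   layer's feature vector, retained so a promoted code can be fitted).
#' @export
update_trigger <- function(trigger, near_miss = FALSE, miss_layer = NA_character_,
                           partial = NULL) {
  n <- trigger$window
  trigger$near_miss <- utils::tail(c(trigger$near_miss, near_miss), n)
  trigger$miss_layer <- utils::tail(c(trigger$miss_layer, miss_layer), n)
  if (!is.null(partial)) {
    k <- partial$key
    rec <- trigger$cooccur[[k]] %||%
      list(count = 0L, free_layer = partial$free_layer,
           best_posterior = numeric(0), features = list())
    rec$count <- rec$count + 1L
    rec$best_posterior <- utils::tail(c(rec$best_posterior,
                                        partial$best_posterior), n)
    if (!is.null(partial$features))
      rec$features <- utils::tail(c(rec$features, list(partial$features)), n)
    trigger$cooccur[[k]] <- rec
  }
  trigger
}

#' Proposal configuration
#'
#' @param residual_threshold Fraction of the window that must be near misses
#'   for the residual trigger to fire (inclusive boundary; default 0.3).
#' @param delta Near-miss band below the compatibility threshold (default
#'   0.1); consumed by the caller when flagging near misses.
#' @param cooccur_threshold Consecutive partial-tuple sightings required for
#'   the co-occurrence trigger (default 25).
#' @param posterior_floor A free layer is "unexplained" when its best
#'   completing posterior stays below this floor (default 0.2).
#' @export
proposal_config <- function(residual_threshold = 0.3, delta = 0.1,
                            cooccur_threshold = 25L, posterior_floor = 0.2) {
  list(residual_threshold = residual_threshold, delta = delta,
       cooccur_threshold = as.integer(cooccur_threshold),
       posterior_floor = posterior_floor)
}

next_auto_code <- function(lex, layer) {
  pat <- paste0("^", layer, "_auto([0-9]+)$")
  existing <- c(lex$codes, lex$shadow)
  hits <- regmatches(existing, regexec(pat, existing))
  ns <- vapply(hits, function(h) if (length(h) == 2L) as.integer(h[2]) else 0L,
               integer(1))
  paste0(layer, "_auto", (if (length(ns)) max(ns) else 0L) + 1L)
}

#' Propose candidate symbols
#'
#' Deterministically returns candidate codes (named `"<layer>_autoN"`) for any
#' layer where either (a) the near-miss fraction of the residual window
#' reaches the residual threshold, or (b) a partial tuple has co-occurred at
#' least `cooccur_threshold` times while no completing symbol of its free
#' layer cleared the posterior floor.  An empty set is a valid result.
#'
#' @param trigger A [proposal_trigger_state()].
#' @param state The current [lexicon_state()].
#' @param config A [proposal_config()].
#' @return List of `eagm_symbol` candidates (possibly empty).  Each carries a
#'   `"source"` attribute (`"residual"` or the partial-tuple key) and, for
#'   co-occurrence proposals, a `"features"` attribute with the retained free
#'   layer feature vectors.
#' @export
propose_symbols <- function(trigger, state, config = proposal_config()) {
  out <- list()
  taken <- character(0)
  propose_for <- function(layer, source, features = NULL) {
    lx <- state[[layer]]
    code <- next_auto_code(lx, layer)
    while (code %in% taken) {
      # bump the counter past codes proposed earlier in this same call
      n <- as.integer(sub(paste0("^", layer, "_auto"), "", code))
      code <- paste0(layer, "_auto", n + 1L)
    }
    taken <<- c(taken, code)
    s <- symbol(layer, code, "candidate")
    attr(s, "source") <- source
    if (!is.null(features)) attr(s, "features") <- features
    s
  }
  # (a) residual trigger: near-miss fraction at or above threshold
  if (length(trigger$near_miss) > 0L) {
    frac <- mean(trigger$near_miss)
    if (frac >= config$residual_threshold && any(trigger$near_miss)) {
      blamed <- trigger$miss_layer[trigger$near_miss]
      blamed <- blamed[!is.na(blamed)]
      if (length(blamed) > 0L) {
        layer <- names(sort(table(blamed), decreasing = TRUE))[1]
        out <- c(out, list(propose_for(layer, "residual")))
      }
    }
  }
  # (b) co-occurrence trigger, in insertion order of the partial keys
  for (k in names(trigger$cooccur)) {
    rec <- trigger$cooccur[[k]]
    if (rec$count >= config$cooccur_threshold &&
        (length(rec$best_posterior) == 0L ||
         max(rec$best_posterior) < config$posterior_floor)) {
      feats <- if (length(rec$features)) rec$features else NULL
      out <- c(out, list(propose_for(rec$free_layer, k, feats)))
    }
  }
  out
}

#' Fit a class-conditional for a newly promoted symbol
#'
#' Estimates the location (feature mean) and spread (pooled sd, floored) of a
#' promoted code from the feature vectors retained by the co-occurrence
#' trigger, and extends the observation model so the symbolizer can assign
#' calibrated mass to the new code.
#'
#' @param model An [observation_model()].
#' @param layer Layer of the new code.
#' @param code New symbol code.
#' @param features List of feature vectors (from the trigger record).
#' @param sd_floor Minimum spread (default 0.1).
#' @return The extended `observation_model`.
#' @export
extend_observation_model <- function(model, layer, code, features,
                                     sd_floor = 0.1) {
  assert_layer(layer)
  m <- model[[layer]]
  X <- do.call(rbind, features)
  mu <- colMeans(X)
  sd <- if (nrow(X) > 1L) pmax(apply(X, 2, stats::sd), sd_floor)
        else rep(mean(m$sd), ncol(X))
  m$mean <- rbind(m$mean, matrix(mu, 1))
  rownames(m$mean)[nrow(m$mean)] <- code
  m$sd <- rbind(m$sd, matrix(sd, 1))
  rownames(m$sd) <- rownames(m$mean)
  k <- nrow(m$mean)
  m$prior <- stats::setNames(rep(1 / k, k), rownames(m$mean))
  model[[layer]] <- m
  model
}

#' Calibrated explanation score of an observation
#'
#' How well the established vocabulary explains an observation.  A closed-
#' world posterior is always confident between the available classes, even
#' for observations far from all of them, so the proposal trigger needs the
#' class-conditional density as well: the score is the best symbol's
#' posterior damped by the Mahalanobis tail of its class-conditional,
#' `max_s p(s | x) * exp(-(d2_min - q_ref) / 2)` with `d2_min` the smallest
#' squared standardized distance to any class location and `q_ref` the
#' `ref_quantile` chi-square quantile at the feature dimension.  In-class
#' observations score near their posterior; out-of-vocabulary observations
#' score near zero.
#'
#' @param x Feature vector (or an [observation_bundle()]).
#' @param model An [observation_model()].
#' @param layer One of `layer_ids()`.
#' @param ref_quantile Chi-square reference quantile (default 0.95).
#' @return List with `score` in `[0, 1]`, `best` (the MAP code), `d2_min`.
#' @export
explanation_score <- function(x, model, layer, ref_quantile = 0.95) {
  post <- symbolize_layer(x, model, layer)
  if (inherits(x, "observation_bundle")) x <- x$features[[layer]]
  m <- model[[layer]]
  d2 <- vapply(seq_len(nrow(m$mean)), function(i)
    sum(((x - m$mean[i, ]) / m$sd[i, ])^2), numeric(1))
  d2_min <- min(d2)
  q_ref <- stats::qchisq(ref_quantile, df = length(x))
  w <- exp(-max(0, d2_min - q_ref) / 2)
  best <- names(post$probs)[which.max(post$probs)]
  list(score = unname(max(post$probs) * w), best = best, d2_min = d2_min)
}

#' Read / write an observation model as YAML
#'
#' The YAML layout mirrors the constructor: one block per layer with
#' `mean` (list of per-symbol location vectors, keyed by code), `sd`
#' (scalar or per-symbol vectors) and optional `prior`.
#'
#' @param path YAML file path.
#' @return `read_observation_model()` returns an [observation_model()];
#'   `write_observation_model()` writes and returns the path invisibly.
#' @export
read_observation_model <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  raw <- yaml::read_yaml(path)
  layers <- lapply(raw, function(m) {
    mu <- do.call(rbind, m$mean)
    sd <- if (is.list(m$sd)) do.call(rbind, m$sd)[rownames(mu), ,
                                                  drop = FALSE]
          else m$sd
    list(mean = mu, sd = sd, prior = unlist(m$prior))
  })
  observation_model(layers)
}

#' @rdname read_observation_model
#' @param model An [observation_model()].
#' @export
write_observation_model <- function(model, path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to write YAML configs")
  obj <- lapply(unclass(model), function(m) {
    list(mean = lapply(stats::setNames(rownames(m$mean), rownames(m$mean)),
                       function(cd) as.numeric(m$mean[cd, ])),
         sd = lapply(stats::setNames(rownames(m$sd), rownames(m$sd)),
                     function(cd) as.numeric(m$sd[cd, ])),
         prior = as.list(m$prior))
  })
  yaml::write_yaml(obj, path)
  invisible(path)
}
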