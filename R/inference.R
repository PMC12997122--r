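# Bidirectional inference over orientation: the top-down transition prior,
# the per-instant step likelihood, the joint posterior over orientation and
# symbols, the orientation posterior kernel with MAP estimate, and entropy
# bookkeeping.

gm_key <- function(goal, meaning) paste(goal, meaning, sep = "|")

#' Orientation belief state
#'
#' A distribution over (goal, meaning) pairs: the latent orientation the
#' top-down pass predicts and the bottom-up pass updates.
#'
#' @param pairs Character vector of `"goal|meaning"` keys (the support,
#'   a subset of the G x M cross product).
#' @param probs Numeric weights (normalized internally; default uniform).
#' @return An object of class `orientation_state` with `probs` (named, sums
#'   to 1) and `entropy_bits`.
#' @export
orientation_state <- function(pairs, probs = NULL) {
  stopifnot(length(pairs) > 0L, !anyDuplicated(pairs))
  if (is.null(probs)) probs <- rep(1 / length(pairs), length(pairs))
  stopifnot(length(probs) == length(pairs), all(probs >= 0), sum(probs) > 0)
  p <- probs / sum(probs)
  names(p) <- pairs
  structure(list(probs = p, entropy_bits = entropy_bits(p)),
            class = "orientation_state")
}

#' @export
print.orientation_state <- function(x, ...) {
  cat(sprintf("<orientation over %d pairs, H = %.3f bits>\n",
              length(x$probs), x$entropy_bits))
  invisible(x)
}

#' Top-down transition model
#'
#' Row-normalized transition kernel(s) over orientation pairs, optionally
#' indexed by a history-summary bucket (quantile bins of the dominant-quad
#' histogram mass; 3 buckets by default).
#'
#' @param kernel A row-stochastic matrix with identical row/column names
#'   (the orientation pairs), or a list of such matrices, one per bucket.
#' @param breaks Bucket breaks on the dominant-histogram mass (defaults to
#'   thirds); ignored for a single kernel.
#' @return An object of class `transition_model`.
#' @export
transition_model <- function(kernel, breaks = c(1 / 3, 2 / 3)) {
  if (is.matrix(kernel)) kernel <- list(kernel)
  for (K in kernel) {
    stopifnot(is.matrix(K), !is.null(rownames(K)),
              identical(rownames(K), colnames(K)))
    if (any(abs(rowSums(K) - 1) > 1e-9))
      stop("kernel rows must each sum to 1", call. = FALSE)
  }
  structure(list(kernel = kernel, breaks = breaks),
            class = "transition_model")
}

#' Sticky transition kernel helper
#'
#' @param pairs Orientation pair keys.
#' @param stay Self-transition probability (remainder spread uniformly).
#' @export
sticky_kernel <- function(pairs, stay = 0.9) {
  n <- length(pairs)
  off <- if (n > 1) (1 - stay) / (n - 1) else 0
  K <- matrix(off, n, n, dimnames = list(pairs, pairs))
  diag(K) <- if (n > 1) stay else 1
  K
}

summary_bucket <- function(model, summary) {
  if (length(model$kernel) == 1L || is.null(summary)) return(1L)
  m <- max(summary$histogram)
  min(findInterval(m, model$breaks) + 1L, length(model$kernel))
}

#' Top-down orientation prior
#'
#' Averages the transition kernel over the previous posterior:
#' `p_tilde(o) = sum_{o'} p_prev(o') K[o', o]`, with the kernel row block
#' selected by the history-summary bucket.  An identity kernel reproduces
#' the previous posterior; uniform rows give a uniform prior.
#'
#' @param model A [transition_model()].
#' @param prev Previous [orientation_state()].
#' @param summary Optional [aggregate_history()] summary (selects the
#'   kernel bucket).
#' @param lexicon Optional [lexicon_state()] (the support must lie inside
#'   the current G x M vocabularies when given).
#' @return The predicted `orientation_state`.
#' @export
top_down_prior <- function(model, prev, summary = NULL, lexicon = NULL) {
  K <- model$kernel[[summary_bucket(model, summary)]]
  sup <- names(prev$probs)
  if (!all(sup %in% rownames(K)))
    stop("transition kernel does not cover the orientation support",
         call. = FALSE)
  if (!is.null(lexicon)) {
    gm <- do.call(rbind, strsplit(sup, "|", fixed = TRUE))
    if (!all(gm[, 1] %in% lexicon$G$codes) ||
        !all(gm[, 2] %in% lexicon$M$codes))
      stop("orientation support outside the current lexicons", call. = FALSE)
  }
  p <- as.numeric(prev$probs %*% K[sup, sup, drop = FALSE])
  orientation_state(sup, p)
}

# ---- the c4 edge factor -----------------------------------------------------

#' Edge factor model
#'
#' Independent-Bernoulli model of the active c4 edge set over the universe:
#' each quad's success probability combines its compatibility and coherence
#' signals as `sigmoid(logit kappa + psi)`.  When conditioning on an
#' orientation, only quads whose (G, M) components agree with it keep that
#' probability; all others fall back to a small background rate `p0`, which
#' is how orientation enters the bottom-up evidence.
#'
#' @param universe A [quad_universe()].
#' @param kappa Named compatibility scores over `universe$keys`.
#' @param psi Named coherence log-odds over `universe$keys`.
#' @param p0 Background activation probability for orientation-inconsistent
#'   quads (default 0.02).
#' @return An object of class `edge_factor_model`.
#' @export
edge_factor_model <- function(universe, kappa, psi, p0 = 0.02) {
  kappa <- kappa[universe$keys]; psi <- psi[universe$keys]
  stopifnot(!anyNA(kappa), !anyNA(psi), p0 > 0, p0 < 1)
  p_act <- stats::plogis(stats::qlogis(clamp(kappa, 1e-9, 1 - 1e-9)) + psi)
  p_act <- clamp(p_act, 1e-9, 1 - 1e-9)
  structure(list(keys = universe$keys, gm = universe$gm, p = p_act, p0 = p0),
            class = "edge_factor_model")
}

# log-likelihood of the realized active set for each orientation pair:
# log L(o) = sum_{r} log Bern(p_r(o); active_r), computed as a constant
# (all-background) part plus per-(G,M)-group corrections
edge_loglik_by_orientation <- function(em, active_keys, pairs) {
  act <- em$keys %in% active_keys
  base_ll <- sum(ifelse(act, log(em$p0), log1p(-em$p0)))
  delta <- ifelse(act, log(em$p) - log(em$p0), log1p(-em$p) - log1p(-em$p0))
  grp <- rowsum(delta, em$gm)
  ll <- stats::setNames(rep(base_ll, length(pairs)), pairs)
  hit <- intersect(pairs, rownames(grp))
  ll[hit] <- ll[hit] + grp[hit, 1]
  ll
}

# orientation-free edge factor (Bernoulli product at the combined rates)
edge_loglik_plain <- function(em, active_keys) {
  act <- em$keys %in% active_keys
  sum(ifelse(act, log(em$p), log1p(-em$p)))
}

#' Per-instant step likelihood
#'
#' `L_t = prod_L p(S_t^L | Obs, Sigma) * p(Rc4 | symbols, kappa, psi)`: the
#' per-layer symbolization likelihood of the realized symbols times the
#' independent-Bernoulli edge factor matching the realized active set.  A
#' realized symbol with zero posterior mass annihilates the likelihood (the
#' result carries a `"zero_symbol"` attribute flag).
#'
#' @param symbol_posteriors Named list (per layer) of `symbol_posterior`s.
#' @param edge_model An [edge_factor_model()].
#' @param realized List with `symbols` (named E/A/G/M character) and
#'   `active` (character quad keys).
#' @return The scalar likelihood.
#' @export
step_likelihood <- function(symbol_posteriors, edge_model, realized) {
  sym <- 1
  zero <- FALSE
  for (L in names(symbol_posteriors)) {
    p <- symbol_posteriors[[L]]$probs[realized$symbols[[L]]]
    if (is.na(p)) stop("realized symbol not in lexicon for layer ", L,
                       call. = FALSE)
    if (p == 0) zero <- TRUE
    sym <- sym * unname(p)
  }
  out <- sym * exp(edge_loglik_plain(edge_model, realized$active))
  if (zero) attr(out, "zero_symbol") <- TRUE
  out
}

#' Joint posterior over orientation and symbols
#'
#' Normalized product of the top-down orientation prior, the per-layer
#' symbol posteriors and the orientation-conditioned edge factor, enumerated
#' over the full (orientation x E x A x G x M) product space.  Matches
#' brute-force enumeration on small instances by construction; an all-zero
#' unnormalized mass raises an error.
#'
#' @param prior An [orientation_state()].
#' @param symbol_posteriors Named list (per layer) of `symbol_posterior`s.
#' @param edge_model An [edge_factor_model()].
#' @param active Character keys of the realized active edge set.
#' @return A data.frame with one row per outcome (`orientation`, `E`, `A`,
#'   `G`, `M`, `prob`), normalized; class `joint_posterior` with the log
#'   normalizer in attribute `"log_Z"`.
#' @export
joint_posterior <- function(prior, symbol_posteriors, edge_model, active) {
  pairs <- names(prior$probs)
  ell <- edge_loglik_by_orientation(edge_model, active, pairs)
  grid <- expand.grid(E = names(symbol_posteriors$E$probs),
                      A = names(symbol_posteriors$A$probs),
                      G = names(symbol_posteriors$G$probs),
                      M = names(symbol_posteriors$M$probs),
                      orientation = pairs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  lw <- log(prior$probs[grid$orientation]) + ell[grid$orientation] +
    log(symbol_posteriors$E$probs[grid$E]) +
    log(symbol_posteriors$A$probs[grid$A]) +
    log(symbol_posteriors$G$probs[grid$G]) +
    log(symbol_posteriors$M$probs[grid$M])
  m <- max(lw)
  if (!is.finite(m)) stop("degenerate evidence: all-zero joint mass",
                          call. = FALSE)
  w <- exp(lw - m)
  Z <- sum(w)
  grid$prob <- as.numeric(w / Z)
  structure(grid, class = c("joint_posterior", "data.frame"),
            log_Z = m + log(Z))
}

#' Orientation posterior and MAP estimate
#'
#' Conditioned on the realized symbols and active edges:
#' `p_up(o) ∝ p_tilde(o) * p(Rc4 | symbols, kappa, psi, o)` with the
#' orientation-dependent edge factor.  The MAP pair breaks exact ties
#' lexicographically on (goal code, meaning code).
#'
#' @param prior An [orientation_state()] (the top-down prediction).
#' @param realized_symbols Named E/A/G/M character vector (currently
#'   informative only through the edge factor; may be `NULL`).
#' @param active Character keys of the realized active edge set.
#' @param edge_model An [edge_factor_model()].
#' @return List with `state` (posterior `orientation_state`) and `map` (the
#'   MAP `"goal|meaning"` key).
#' @export
orientation_posterior <- function(prior, realized_symbols = NULL, active,
                                  edge_model) {
  pairs <- names(prior$probs)
  ll <- edge_loglik_by_orientation(edge_model, active, pairs)
  lw <- log(prior$probs) + ll
  lw <- lw - max(lw)
  p <- exp(lw); p <- p / sum(p)
  st <- orientation_state(pairs, p)
  mx <- max(st$probs)
  ties <- names(st$probs)[st$probs >= mx - 1e-12]
  map <- sort(ties)[1]
  list(state = st, map = map)
}

#' Entropy change between two beliefs
#'
#' `DeltaH = H(before) - H(after)` in bits; positive when the update
#' sharpened the belief.  The sign is preserved (negative values are
#' possible; nonnegativity in expectation is a simulation property, not an
#' enforced constraint).
#'
#' @param before,after `orientation_state`s, `symbol_posterior`s, or bare
#'   probability vectors.
#' @export
entropy_delta <- function(before, after) {
  h <- function(x) {
    if (inherits(x, "orientation_state") || inherits(x, "symbol_posterior"))
      entropy_bits(x$probs)
    else entropy_bits(x)
  }
  h(before) - h(after)
}

#' Forward-filter orientation over a trace
#'
#' Alternates the top-down prior and the bottom-up orientation posterior
#' over a sequence of instants, each supplying its realized active edge set
#' (and optionally its own edge model).
#'
#' @param model A [transition_model()].
#' @param init Initial [orientation_state()].
#' @param actives List of character key vectors, one per instant.
#' @param edge_model An [edge_factor_model()] shared across instants, or a
#'   list of models (one per instant).
#' @return List with `states` (posterior per instant) and `entropies`.
#' @export
orientation_filter <- function(model, init, actives, edge_model) {
  cur <- init
  states <- vector("list", length(actives))
  for (i in seq_along(actives)) {
    em <- if (inherits(edge_model, "edge_factor_model")) edge_model
          else edge_model[[i]]
    pred <- top_down_prior(model, cur)
    cur <- orientation_posterior(pred, NULL, actives[[i]], em)$state
    states[[i]] <- cur
  }
  list(states = states,
       entropies = vapply(states, function(s) s$entropy_bits, numeric(1)))
}
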