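# ARAT instantiation: four-type segmentation with span-consistency decoding,
# focus-weighted compatibility, cumulative-logit ordinal ratings, binary
# movement quality elements (MQEs), logit-space prediction fusion, and
# 0-57 session scoring.

#' The four ARAT segment types
#'
#' Every exercise decomposes into up to four typed sub-actions, in canonical
#' order: initiation/progression, manipulation/transportation, termination,
#' and place/release.
#'
#' @return Character vector of the four segment codes.
#' @export
segment_types <- function() {
  c("initiation", "manipulation", "termination", "release")
}

#' Segment span proposal
#'
#' A proposed sub-action span from the automated segmenter: inclusive frame
#' range, segment type, and confidence `pi_A` in `[0, 1]`.  Frames are
#' 1-based; spans within one exercise must not overlap.
#'
#' @param start,end Inclusive frame indices, `start <= end`.
#' @param type One of [segment_types()] (or any label in the decoder's
#'   alphabet).
#' @param confidence Segmenter confidence in `[0, 1]`.
#' @export
span_proposal <- function(start, end, type, confidence) {
  stopifnot(start >= 1, end >= start, confidence >= 0, confidence <= 1)
  list(start = as.integer(start), end = as.integer(end),
       type = type, confidence = confidence)
}

#' Legal-progression transition prior
#'
#' Weight matrix over segment labels encoding legal orderings and
#' smoothness; illegal transitions get weight `eps`.
#'
#' @param types Label alphabet (default [segment_types()]).
#' @param self Self-transition weight (default 5: segments persist).
#' @param forward Weight of the canonical next label (default 1).
#' @param eps Weight of all other transitions (default 1e-6).
#' @return Matrix with `types` dimnames.
#' @export
default_transition_prior <- function(types = segment_types(), self = 5,
                                     forward = 1, eps = 1e-6) {
  n <- length(types)
  Psi <- matrix(eps, n, n, dimnames = list(types, types))
  diag(Psi) <- self
  for (i in seq_len(n - 1)) Psi[types[i], types[i + 1]] <- forward
  Psi
}

#' Span-consistent segmentation decoding
#'
#' Decodes a per-frame label sequence from the product of three factors:
#' per-frame evidence `theta_t[s]`, the temporal/ordering prior
#' `Psi(s', s)`, and, per proposal `j`, the span-consistency factor
#' `pi_j * 1{labels on the span all equal s_j} + (1 - pi_j)` — a soft
#' constraint that equals 1 for labelings honoring the span and `1 - pi_j`
#' otherwise.  MAP decoding and posterior marginals are exact, via dynamic
#' programming over the label state augmented with a per-span consistency
#' flag.  With all confidences 0 the result equals plain evidence +
#' transition decoding; with high confidence the labels follow the span
#' unless the frame evidence is overwhelmingly contradictory.
#'
#' @param evidence `T x L` matrix of per-frame label scores (rows need not
#'   be normalized; column names are the labels).
#' @param transition `L x L` nonnegative weight matrix (same labels).
#' @param proposals List of [span_proposal()]s (non-overlapping) or a
#'   data.frame with columns start, end, type, confidence.
#' @param init Optional initial label weights (default uniform).
#' @return List with `map` (character label per frame), `marginals`
#'   (`T x L` posterior matrix), and `log_Z`.
#' @export
segment_decode <- function(evidence, transition, proposals = list(),
                           init = NULL) {
  theta <- as.matrix(evidence)
  labels <- colnames(theta)
  stopifnot(!is.null(labels), all(theta >= 0))
  Tn <- nrow(theta); L <- length(labels)
  Psi <- as.matrix(transition)[labels, labels]
  if (is.data.frame(proposals))
    proposals <- lapply(seq_len(nrow(proposals)), function(i)
      span_proposal(proposals$start[i], proposals$end[i],
                    proposals$type[i], proposals$confidence[i]))
  # validate spans: inside the frame range, non-overlapping
  span_of <- integer(Tn)          # 0 = no span, else proposal index
  for (j in seq_along(proposals)) {
    sp <- proposals[[j]]
    if (sp$end > Tn) stop("span beyond the frame range", call. = FALSE)
    if (!sp$type %in% labels) stop("span type outside the label alphabet",
                                   call. = FALSE)
    idx <- sp$start:sp$end
    if (any(span_of[idx] != 0L)) stop("overlapping spans", call. = FALSE)
    span_of[idx] <- j
  }
  init <- init %||% rep(1 / L, L)

  # augmented state: (label, flag); the flag means "every frame of the
  # current span so far carried the span's type".  Outside spans the flag
  # slot TRUE is used and FALSE is dead.
  types <- vapply(proposals, function(sp) match(sp$type, labels), 1L)
  pis <- vapply(proposals, function(sp) sp$confidence, 1)

  # returns, for frame t, a function mapping the incoming (L x 2) weight
  # matrix to the outgoing one (before emission), in ordinary space with
  # per-step renormalization; `op` is sum (forward/backward) or max
  step_fun <- function(t, M, incoming, op) {
    # incoming: L x 2; transition by Psi over labels for each flag column
    out <- matrix(0, L, 2)
    j <- span_of[t]
    starts <- j != 0L && (t == 1L || span_of[t - 1L] != j)
    if (t == 1L) {
      base <- matrix(init, L, 1)
      if (j == 0L) {
        out[, 1] <- base
      } else {
        s <- types[j]
        out[, 1] <- base * (seq_len(L) == s)
        out[, 2] <- base * (seq_len(L) != s)
      }
      return(out)
    }
    tr <- function(v) if (identical(op, "max"))
      apply(v * Psi, 2, max) else as.numeric(v %*% Psi)
    if (j == 0L || starts) {
      inc <- if (identical(op, "max")) pmax(incoming[, 1], incoming[, 2])
             else incoming[, 1] + incoming[, 2]
      moved <- tr(inc)
      if (j == 0L) {
        out[, 1] <- moved
      } else {
        s <- types[j]
        out[, 1] <- moved * (seq_len(L) == s)
        out[, 2] <- moved * (seq_len(L) != s)
      }
    } else {
      # continuing inside span j: flag' = flag & (label == s_j)
      s <- types[j]
      m1 <- tr(incoming[, 1]); m2 <- tr(incoming[, 2])
      out[, 1] <- m1 * (seq_len(L) == s)
      bad <- m1 * (seq_len(L) != s)
      out[, 2] <- if (identical(op, "max")) pmax(m2, bad) else m2 + bad
    }
    out
  }
  end_factor <- function(t, M) {
    j <- span_of[t]
    if (j != 0L && (t == Tn || span_of[t + 1L] != j))
      M[, 2] <- M[, 2] * (1 - pis[j])
    M
  }

  # forward pass (sum)
  alphas <- vector("list", Tn)
  log_Z <- 0
  inc <- NULL
  for (t in seq_len(Tn)) {
    M <- step_fun(t, NULL, inc, "sum")
    M <- M * theta[t, ]
    M <- end_factor(t, M)
    z <- sum(M)
    if (z <= 0) stop("zero forward mass at frame ", t, call. = FALSE)
    M <- M / z
    log_Z <- log_Z + log(z)
    alphas[[t]] <- M
    inc <- M
  }
  # backward pass: mirror of forward on the reversed factor graph
  betas <- vector("list", Tn)
  beta <- matrix(1, L, 2)
  betas[[Tn]] <- beta
  for (t in rev(seq_len(Tn - 1L))) {
    tnext <- t + 1L
    j <- span_of[tnext]
    starts <- j != 0L && span_of[t] != j
    contrib <- betas[[tnext]] * theta[tnext, ]
    contrib <- end_factor(tnext, contrib)
    if (j == 0L || starts) {
      # the flag collapses across this boundary; at a span start only the
      # states consistent with the re-initialized flag are reachable
      v <- if (j == 0L) contrib[, 1]
           else ifelse(seq_len(L) == types[j], contrib[, 1], contrib[, 2])
      b1 <- as.numeric(Psi %*% v)
      beta <- cbind(b1, b1)
    } else {
      s <- types[j]
      keep <- contrib[, 1] * (seq_len(L) == s)
      broke <- contrib[, 2] * (seq_len(L) != s)
      b_true <- as.numeric(Psi %*% (keep + broke))
      b_false <- as.numeric(Psi %*% contrib[, 2])
      beta <- cbind(b_true, b_false)
    }
    beta <- beta / max(beta)
    betas[[t]] <- beta
  }
  marg <- matrix(0, Tn, L, dimnames = list(NULL, labels))
  for (t in seq_len(Tn)) {
    m <- alphas[[t]] * betas[[t]]
    marg[t, ] <- rowSums(m) / sum(m)
  }
  # Viterbi over the augmented state with backpointers
  n_states <- 2L * L
  lab_of <- rep(seq_len(L), 2); flag_of <- rep(c(1L, 2L), each = L)
  delta <- matrix(-Inf, Tn, n_states)
  back <- matrix(0L, Tn, n_states)
  lpsi <- log(Psi + .Machine$double.xmin)
  lth <- log(theta + .Machine$double.xmin)
  for (t in seq_len(Tn)) {
    j <- span_of[t]
    starts <- j != 0L && (t == 1L || span_of[t - 1L] != j)
    for (s in seq_len(n_states)) {
      l <- lab_of[s]; f <- flag_of[s]
      # flag feasibility at t
      if (j == 0L) { if (f == 2L) next
      } else if (f == 1L && l != types[j]) next
      else if (f == 2L && starts && l == types[j]) next
      if (t == 1L) {
        delta[t, s] <- log(init[l])
      } else {
        if (j == 0L || starts) {
          prev_ok <- seq_len(n_states)       # flag collapses at boundaries
        } else if (f == 1L) {
          # staying consistent requires a consistent prefix
          prev_ok <- which(flag_of == 1L)
        } else {
          # broken: already broken, or breaking now with l != s_j
          prev_ok <- which(flag_of == 2L | (flag_of == 1L & l != types[j]))
        }
        cand <- delta[t - 1L, prev_ok] + lpsi[lab_of[prev_ok], l]
        bi <- which.max(cand)
        delta[t, s] <- cand[bi]
        back[t, s] <- prev_ok[bi]
      }
      delta[t, s] <- delta[t, s] + lth[t, l]
      if (j != 0L && (t == Tn || span_of[t + 1L] != j) && f == 2L)
        delta[t, s] <- delta[t, s] + log(max(1 - pis[j],
                                             .Machine$double.xmin))
    }
  }
  s <- which.max(delta[Tn, ])
  path <- integer(Tn)
  for (t in rev(seq_len(Tn))) {
    path[t] <- lab_of[s]
    if (t > 1L) s <- back[t, s]
  }
  list(map = labels[path], marginals = marg, log_Z = log_Z)
}

# ---- ordinal ratings --------------------------------------------------------

#' Cumulative-logit ordinal rating model
#'
#' For a 0-3 ordinal rating with latent score `eta = t(weights) %*% h`:
#' `P(Y <= k) = sigmoid(thresholds[k+1] - eta)` for `k = 0, 1, 2` and
#' `P(Y <= 3) = 1`; class probabilities by adjacent differences.  The same
#' form serves segment-level sub-goal ratings (thresholds `gamma`, weights
#' `u`) and exercise-level ratings (`delta`, `v`).
#'
#' @param thresholds Strictly increasing numeric of length 3.
#' @param weights Numeric weight vector.
#' @return An object of class `ordinal_model`.
#' @export
ordinal_model <- function(thresholds, weights) {
  stopifnot(length(thresholds) == 3L)
  if (any(diff(thresholds) <= 0))
    stop("thresholds must be strictly increasing", call. = FALSE)
  structure(list(thresholds = as.numeric(thresholds),
                 weights = as.numeric(weights)),
            class = "ordinal_model")
}

#' @rdname ordinal_model
#' @param model An `ordinal_model`.
#' @param h Feature embedding vector (same length as `weights`).
#' @return `subgoal_rating_probs()` / `exercise_rating_probs()` return the
#'   named class distribution over ratings `0:3` (sums to 1; cumulative
#'   probabilities are monotone in the rating by construction).
#' @export
subgoal_rating_probs <- function(model, h) {
  eta <- sum(model$weights * h)
  cum <- stats::plogis(model$thresholds - eta)
  p <- diff(c(0, cum, 1))
  stats::setNames(p, as.character(0:3))
}

#' @rdname ordinal_model
#' @param H Pooled exercise-level embedding.
#' @export
exercise_rating_probs <- function(model, H) subgoal_rating_probs(model, H)

#' Fit a cumulative-logit rating model
#'
#' Maximum-likelihood fit of the proportional-odds model via
#' [MASS::polr()], whose parameterization `P(Y <= k) = logistic(zeta_k -
#' eta)` matches [ordinal_model()] exactly, so the fitted intercepts are the
#' thresholds and the coefficients the weight vector.
#'
#' @param h Numeric feature matrix (one row per sub-action).
#' @param y Integer ratings in `0:3`.
#' @return The fitted `ordinal_model`.
#' @export
fit_ordinal_model <- function(h, y) {
  stopifnot(nrow(h) == length(y), all(y %in% 0:3))
  df <- as.data.frame(h)
  names(df) <- paste0("x", seq_len(ncol(h)))
  df$y <- factor(y, levels = 0:3, ordered = TRUE)
  fit <- MASS::polr(y ~ ., data = df, method = "logistic", Hess = FALSE)
  ordinal_model(unname(fit$zeta), unname(stats::coef(fit)))
}

#' Pool sub-action embeddings into an exercise embedding
#'
#' @param hs Matrix of sub-action embeddings (one row per sub-action) or a
#'   list of vectors.
#' @param method `"mean"` (default) or `"max"`.
#' @export
pool_embeddings <- function(hs, method = c("mean", "max")) {
  method <- match.arg(method)
  if (is.list(hs)) hs <- do.call(rbind, hs)
  if (method == "mean") colMeans(hs) else apply(hs, 2, max)
}

# ---- movement quality elements ----------------------------------------------

#' Binary MQE model
#'
#' One logistic scorer per movement quality element `q`:
#' `p(m_q = 1 | h) = sigmoid(t(w_q) %*% h + b_q)` (1 = appropriate).
#'
#' @param params Named list, one entry per MQE, each `list(w =, b =)`.
#' @return An object of class `mqe_model`.
#' @export
mqe_model <- function(params) {
  stopifnot(is.list(params), !is.null(names(params)))
  structure(params, class = "mqe_model")
}

#' @rdname mqe_model
#' @param model An `mqe_model`.
#' @param q MQE identifier.
#' @param h Sub-action embedding.
#' @export
mqe_probability <- function(model, q, h) {
  par <- model[[q]]
  if (is.null(par)) stop("unknown MQE: ", q, call. = FALSE)
  stats::plogis(sum(par$w * h) + par$b)
}

#' Segment-focused MQE prior
#'
#' Which movement quality elements receive attention during each segment
#' type, with weights normalized within each segment's focus set.
#'
#' @param sets Named list, segment type -> character vector of focused MQEs.
#' @param weights Optional named list of weight vectors (default uniform
#'   within each set).
#' @return An object of class `focus_prior`.
#' @export
focus_prior <- function(sets, weights = NULL) {
  out <- lapply(names(sets), function(ty) {
    q <- sets[[ty]]
    w <- weights[[ty]] %||% stats::setNames(rep(1, length(q)), q)
    w <- w[q]
    w / sum(w)
  })
  names(out) <- names(sets)
  structure(list(weights = out), class = "focus_prior")
}

#' @rdname focus_prior
#' @param focus A `focus_prior`.
#' @param q MQE identifier.
#' @param segment_type Segment type whose focus set is consulted.
#' @return `focus_weight()` returns `pi_focus(q | segment_type)`; an error
#'   if `q` is outside the segment's focus set.
#' @export
focus_weight <- function(focus, q, segment_type) {
  w <- focus$weights[[segment_type]]
  if (is.null(w) || is.na(w[q]))
    stop("MQE '", q, "' outside the focus set of segment '", segment_type,
         "'", call. = FALSE)
  unname(w[q])
}

#' Per-MQE edge compatibility
#'
#' Compatibility of the per-MQE quadruple `(sE, sA, G_j, m_q)`: delegates to
#' [compatibility_score()] with the focus term `log pi_focus(q | sA)` and
#' the MQE evidence term `phi_mqe(p_hat)` from the predicted MQE
#' probability.
#'
#' @param model A [compatibility_model()] (with `lambda_focus` set).
#' @param quad The per-MQE `quadruple`.
#' @param kin_uncertainty Kinematic uncertainty (matrix or scalar).
#' @param focus A [focus_prior()].
#' @param q MQE identifier (must be in the focus set of the quad's segment
#'   type, i.e. its A component).
#' @param mqe_prob Predicted probability `p_hat(m_q = 1 | h)`.
#' @return The compatibility score in (0, 1).
#' @export
mqe_edge_compatibility <- function(model, quad, kin_uncertainty = NULL,
                                   focus, q, mqe_prob) {
  ft <- log(focus_weight(focus, q, quad[["A"]]))
  mt <- model$phi_mqe(mqe_prob)
  compatibility_score(model, quad, kin_uncertainty,
                      focus_term = ft, mqe_term = mt)
}

# ---- fusion and scoring -----------------------------------------------------

#' Fuse two probabilistic predictions in logit space
#'
#' `sigmoid(weight * logit(p1) + (1 - weight) * logit(p2))`; agreement is a
#' fixed point and `weight = 1` returns `p1`.  Boundary probabilities are
#' clamped to the open interval before the logit.
#'
#' @param p1,p2 Probabilities in (0, 1) (boundaries clamped).
#' @param weight Fusion weight in `[0, 1]`.
#' @export
fuse_logits <- function(p1, p2, weight = 0.5) {
  stopifnot(weight >= 0, weight <= 1)
  p1 <- clamp(p1, 1e-12, 1 - 1e-12)
  p2 <- clamp(p2, 1e-12, 1 - 1e-12)
  stats::plogis(weight * stats::qlogis(p1) + (1 - weight) * stats::qlogis(p2))
}

#' @rdname fuse_logits
#' @param d1,d2 Class probability vectors (e.g. ordinal rating
#'   distributions); fused per class then renormalized.
#' @export
fuse_ordinal <- function(d1, d2, weight = 0.5) {
  f <- fuse_logits(d1, d2, weight)
  f / sum(f)
}

#' Build an ARAT session record
#'
#' @param exercises List of 19 exercise records, each a list carrying at
#'   least `rating` in `0:3`.
#' @return An object of class `arat_session`.
#' @export
arat_session <- function(exercises) {
  structure(list(exercises = exercises), class = "arat_session")
}

#' Total ARAT session score
#'
#' Sums the 19 per-exercise ordinal ratings; the total lies in `[0, 57]`.
#'
#' @param session An [arat_session()] (or list with `$exercises`), all 19
#'   ratings present.
#' @return Integer total score.
#' @export
total_arat_score <- function(session) {
  ex <- session$exercises
  if (length(ex) != 19L)
    stop("an ARAT session requires exactly 19 exercises, got ", length(ex),
         call. = FALSE)
  ratings <- vapply(ex, function(e) {
    r <- e$rating
    if (is.null(r) || is.na(r)) stop("missing exercise rating",
                                     call. = FALSE)
    as.integer(r)
  }, integer(1))
  if (any(ratings < 0L | ratings > 3L))
    stop("ratings must lie in 0..3", call. = FALSE)
  sum(ratings)
}
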