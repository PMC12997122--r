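# Hierarchical activation histories: prefix counts of c4 edge activations at
# the action-segment / task / sequence levels, Dirichlet smoothing, the
# convex-mixture coherence prior and its log-odds, coherence gain, and
# fixed-size history summaries.

PI_CLAMP <- 1e-6

#' Dirichlet smoothing configuration
#'
#' Counts are converted to probabilities as `(C(r) + alpha * b(r)) / (N +
#' alpha)`, with concentration `alpha` and base measure `b` normalized over
#' the current quadruple universe.
#'
#' @param universe A [quad_universe()] (supplies the default uniform base).
#' @param alpha Positive concentration (default 1).
#' @param base Optional named base measure over `universe$keys`; normalized.
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(universe, alpha = 1, base = NULL) {
  stopifnot(alpha > 0)
  if (is.null(base)) {
    base <- stats::setNames(rep(1 / universe$n, universe$n), universe$keys)
  } else {
    base <- base[universe$keys]
    if (anyNA(base)) stop("base measure must cover the universe")
    base <- base / sum(base)
  }
  structure(list(alpha = alpha, base = base, keys = universe$keys),
            class = "smoothing_config")
}

#' Down-weight error-listed quadruples in the base measure
#'
#' The error list feeds back into the coherence prior: base-measure mass of
#' persistently failing quadruples is multiplied by `factor` and the measure
#' renormalized.
#'
#' @param smoothing A [smoothing_config()].
#' @param error_keys Character quad keys on the error list.
#' @param factor Multiplicative down-weight in `(0, 1]` (default 0.5).
#' @export
apply_error_feedback <- function(smoothing, error_keys, factor = 0.5) {
  stopifnot(factor > 0, factor <= 1)
  hit <- smoothing$keys %in% error_keys
  if (any(hit)) {
    smoothing$base[hit] <- smoothing$base[hit] * factor
    smoothing$base <- smoothing$base / sum(smoothing$base)
  }
  smoothing
}

#' Prefix counts of edge activations
#'
#' Maintains, over the enumerated quadruple universe, the activation counts
#' within the *current* action segment, task and sequence, together with
#' their totals.  The prefix property holds by construction: the counts
#' consulted at instant `t` contain evidence from instants `<= t - 1` only,
#' because [record_instant()] is called after the instant's prior was used.
#'
#' @param universe A [quad_universe()].
#' @return An object of class `edge_counts`.
#' @export
edge_counts <- function(universe) {
  z <- stats::setNames(numeric(universe$n), universe$keys)
  structure(list(keys = universe$keys,
                 act = z, task = z, seq = z,
                 N_act = 0, N_task = 0, N_seq = 0,
                 cur = list(k = NA_integer_, task = NA_integer_,
                            seq = NA_integer_),
                 last_time = NULL),
            class = "edge_counts")
}

#' Record one instant's active edge set
#'
#' Increments each active quadruple's count at all three levels for the
#' instant's action segment, task and sequence; when the instant opens a new
#' bracket the corresponding level's counts reset (they are per-bracket
#' prefix counts).  Time must strictly increase across calls.
#'
#' @param counts An [edge_counts()].
#' @param active Character vector of active quad keys (or list of
#'   `quadruple`s); may be empty.
#' @param time A [time_index()].
#' @return The updated `edge_counts`.
#' @export
record_instant <- function(counts, active, time) {
  stopifnot(inherits(counts, "edge_counts"), inherits(time, "time_index"))
  if (!is.null(counts$last_time) && !time_lt(counts$last_time, time))
    stop("time regression in record_instant", call. = FALSE)
  if (is.list(active))
    active <- vapply(active, quad_key, "")
  z <- stats::setNames(numeric(length(counts$keys)), counts$keys)
  if (!identical(counts$cur$seq, time$sequence)) {
    counts$seq <- z; counts$N_seq <- 0
    counts$cur$seq <- time$sequence
    counts$cur$task <- NA_integer_
  }
  if (!identical(counts$cur$task, time$task)) {
    counts$task <- z; counts$N_task <- 0
    counts$cur$task <- time$task
    counts$cur$k <- NA_integer_
  }
  if (!identical(counts$cur$k, time$action_segment)) {
    counts$act <- z; counts$N_act <- 0
    counts$cur$k <- time$action_segment
  }
  if (length(active) > 0L) {
    idx <- match(active, counts$keys)
    if (anyNA(idx)) stop("active quad outside the universe", call. = FALSE)
    for (i in idx) {
      counts$act[i] <- counts$act[i] + 1
      counts$task[i] <- counts$task[i] + 1
      counts$seq[i] <- counts$seq[i] + 1
    }
    counts$N_act <- counts$N_act + length(idx)
    counts$N_task <- counts$N_task + length(idx)
    counts$N_seq <- counts$N_seq + length(idx)
  }
  counts$last_time <- time
  counts
}

smoothed_vector <- function(counts, level = c("act", "task", "seq"),
                            smoothing) {
  level <- match.arg(level)
  C <- counts[[level]]
  N <- counts[[paste0("N_", level)]]
  (C + smoothing$alpha * smoothing$base) / (N + smoothing$alpha)
}

#' Dirichlet-smoothed activation probability
#'
#' `(C(r) + alpha * b(r)) / (N + alpha)` at the requested level.  With no
#' evidence this is exactly the base measure; as `alpha -> 0` with `N > 0` it
#' approaches the empirical frequency `C(r) / N`.
#'
#' @param counts An [edge_counts()].
#' @param level `"act"`, `"task"` or `"seq"`.
#' @param smoothing A [smoothing_config()].
#' @param quad A `quadruple` or quad key.
#' @return The smoothed probability.
#' @export
smoothed_probability <- function(counts, level, smoothing, quad) {
  key <- if (inherits(quad, "quadruple")) quad_key(quad) else quad
  if (!key %in% counts$keys) {
    if (is.na(smoothing$base[key]) || is.null(smoothing$base[[key]]))
      stop("unknown quad with no base mass: ", key, call. = FALSE)
  }
  v <- smoothed_vector(counts, level, smoothing)
  unname(v[key])
}

#' Coherence prior over the quadruple universe
#'
#' Convex mixture `pi = w_act * pi_act + w_task * pi_task + w_seq * pi_seq`
#' of the three smoothed level histograms, with log-odds `psi = log(pi / (1 -
#' pi))`.  The mixture is clamped to `[1e-6, 1 - 1e-6]` before the log-odds
#' so that empty histories give finite `psi`.
#'
#' @param counts An [edge_counts()].
#' @param smoothing A [smoothing_config()].
#' @param weights Named nonnegative weights `c(act=, task=, seq=)` summing
#'   to 1 (default `c(0.5, 0.3, 0.2)`).
#' @return An object of class `coherence_prior` with `pi`, `psi` (named over
#'   the universe), `weights`, `keys`.
#' @export
coherence_prior <- function(counts, smoothing,
                            weights = c(act = 0.5, task = 0.3, seq = 0.2)) {
  stopifnot(all(weights >= 0), abs(sum(weights) - 1) < 1e-9)
  pi <- weights[["act"]] * smoothed_vector(counts, "act", smoothing) +
    weights[["task"]] * smoothed_vector(counts, "task", smoothing) +
    weights[["seq"]] * smoothed_vector(counts, "seq", smoothing)
  pic <- clamp(pi, PI_CLAMP, 1 - PI_CLAMP)
  structure(list(pi = pic, psi = stats::qlogis(pic), weights = weights,
                 keys = counts$keys),
            class = "coherence_prior")
}

#' Coherence log-odds of one quadruple
#'
#' @param prior A [coherence_prior()].
#' @param quad A `quadruple` or quad key.
#' @return `log(pi / (1 - pi))` for the quad's mixture probability.
#' @export
coherence_log_odds <- function(prior, quad) {
  key <- if (inherits(quad, "quadruple")) quad_key(quad) else quad
  v <- prior$psi[key]
  if (is.na(v)) stop("quad outside the universe: ", key, call. = FALSE)
  unname(v)
}

#' Coherence gain of a candidate activation
#'
#' Measures whether admitting the candidate aligns the active edge set with
#' historically frequent patterns: at each level X, `C_X` is the mean log
#' smoothed probability of `active_set` together with the candidate, and the
#' gain compares `C_X` under counts that include the candidate's pending
#' activation against the current counts,
#' `DeltaC = sum_X w_X (C_X_new - C_X_old)`.  The coherence gate passes iff
#' `DeltaC > 0`.  With an empty active set and no candidate the gain is 0 by
#' convention.
#'
#' @param counts An [edge_counts()].
#' @param smoothing A [smoothing_config()].
#' @param weights Level weights as in [coherence_prior()] (must not be all
#'   zero).
#' @param candidate Candidate `quadruple` / key (or `NULL`).
#' @param active_set Character keys (or list of quads) currently active.
#' @param per_candidate If `TRUE`, score only the candidate rather than the
#'   whole active set (alternative operationalization, off by default).
#' @return The scalar gain `DeltaC`.
#' @export
coherence_gain <- function(counts, smoothing, weights = c(act = 0.5,
                                                          task = 0.3,
                                                          seq = 0.2),
                           candidate = NULL, active_set = character(),
                           per_candidate = FALSE) {
  if (all(weights == 0)) stop("all-zero level weights are disallowed")
  if (is.list(active_set)) active_set <- vapply(active_set, quad_key, "")
  ckey <- if (is.null(candidate)) NULL
          else if (inherits(candidate, "quadruple")) quad_key(candidate)
          else candidate
  set <- if (per_candidate && !is.null(ckey)) ckey
         else unique(c(active_set, ckey))
  if (length(set) == 0L) return(0)
  gain <- 0
  for (lev in c("act", "task", "seq")) {
    if (weights[[lev]] == 0) next
    C <- counts[[lev]]
    N <- counts[[paste0("N_", lev)]]
    b <- smoothing$base
    a <- smoothing$alpha
    old <- mean(log((C[set] + a * b[set]) / (N + a)))
    if (is.null(ckey)) {
      new <- old
    } else {
      C2 <- C
      C2[ckey] <- C2[ckey] + 1
      new <- mean(log((C2[set] + a * b[set]) / (N + 1 + a)))
    }
    gain <- gain + weights[[lev]] * (new - old)
  }
  unname(gain)
}

# ---- history summaries ------------------------------------------------------

#' Aggregate a trace bracket into a fixed-size history summary
#'
#' Pools the sufficient statistics of the instants inside one time bracket:
#' a normalized activation histogram over the quadruple universe, mean dwell
#' time (instants per run) for each segment type, and normalized
#' segment-type transition counts.  The summary dimension is fixed by the
#' universe and segment-type alphabet, independent of trace length.
#'
#' @param trace List of instant records, each a list with `time` (a
#'   [time_index()]), `active` (character quad keys) and `segment_type`.
#' @param universe A [quad_universe()].
#' @param segment_types Character alphabet of segment types (default the
#'   ARAT four, [segment_types()]).
#' @param bracket Optional list like `list(level = "task", id = 2)` selecting
#'   the instants whose bracket index matches; default uses the whole trace.
#' @return An object of class `history_summary` with `histogram`, `dwell`,
#'   `transitions`, `n_instants`, `empty` flag.
#' @export
aggregate_history <- function(trace, universe,
                              segment_types = c("initiation", "manipulation",
                                                "termination", "release"),
                              bracket = NULL) {
  if (!is.null(bracket)) {
    field <- switch(bracket$level, act = "action_segment", task = "task",
                    seq = "sequence",
                    stop("bracket level must be act/task/seq"))
    keep <- vapply(trace, function(r) r$time[[field]] == bracket$id, TRUE)
    trace <- trace[keep]
  }
  hist <- stats::setNames(numeric(universe$n), universe$keys)
  n_types <- length(segment_types)
  trans <- matrix(0, n_types, n_types,
                  dimnames = list(segment_types, segment_types))
  if (length(trace) == 0L) {
    return(structure(list(histogram = hist,
                          dwell = stats::setNames(numeric(n_types),
                                                  segment_types),
                          transitions = trans, n_instants = 0L,
                          empty = TRUE),
                     class = "history_summary"))
  }
  total <- 0
  for (r in trace) {
    for (k in r$active) {
      hist[k] <- hist[k] + 1
      total <- total + 1
    }
  }
  if (total > 0) hist <- hist / total
  types <- vapply(trace, function(r) r$segment_type %||% NA_character_, "")
  runs <- rle(types)
  dwell <- stats::setNames(numeric(n_types), segment_types)
  for (ty in segment_types) {
    len <- runs$lengths[runs$values == ty]
    dwell[ty] <- if (length(len)) mean(len) else 0
  }
  if (length(runs$values) > 1L) {
    for (i in seq_len(length(runs$values) - 1L)) {
      a <- runs$values[i]; b <- runs$values[i + 1L]
      if (a %in% segment_types && b %in% segment_types)
        trans[a, b] <- trans[a, b] + 1
    }
    if (sum(trans) > 0) trans <- trans / sum(trans)
  }
  structure(list(histogram = hist, dwell = dwell, transitions = trans,
                 n_instants = length(trace), empty = FALSE),
            class = "history_summary")
}

#' Compose child summaries into a parent summary
#'
#' Concatenates child summaries (e.g. the action-segment summaries of a
#' task) and renormalizes back to the fixed dimension: histograms are
#' averaged with weights proportional to child instant counts, dwell times
#' are count-weighted means, transition matrices are summed and
#' renormalized.
#'
#' @param summaries List of `history_summary` objects on the same universe.
#' @return A `history_summary`.
#' @export
compose_summaries <- function(summaries) {
  summaries <- Filter(function(s) !s$empty, summaries)
  if (length(summaries) == 0L) stop("no non-empty child summaries")
  w <- vapply(summaries, function(s) s$n_instants, numeric(1))
  w <- w / sum(w)
  hist <- Reduce(`+`, Map(function(s, wi) s$histogram * wi, summaries, w))
  dwell <- Reduce(`+`, Map(function(s, wi) s$dwell * wi, summaries, w))
  trans <- Reduce(`+`, lapply(summaries, function(s) s$transitions))
  if (sum(trans) > 0) trans <- trans / sum(trans)
  structure(list(histogram = hist, dwell = dwell, transitions = trans,
                 n_instants = sum(vapply(summaries,
                                         function(s) s$n_instants,
                                         numeric(1))),
                 empty = FALSE),
            class = "history_summary")
}

#' Write a per-instant coherence trace as CSV
#'
#' One row per (instant, quadruple): the three level histograms and the
#' mixture log-odds at that instant.
#'
#' @param trace data.frame accumulated by the caller with columns `t`,
#'   `quad`, `pi_act`, `pi_task`, `pi_seq`, `psi` (see
#'   [coherence_trace_row()]).
#' @param path CSV output path.
#' @export
write_coherence_trace <- function(trace, path) {
  stopifnot(all(c("t", "quad", "pi_act", "pi_task", "pi_seq", "psi") %in%
                  names(trace)))
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_coherence_trace
#' @param t Instant index.
#' @param counts An [edge_counts()].
#' @param smoothing A [smoothing_config()].
#' @param prior The instant's [coherence_prior()].
#' @param quads Quad keys to record (default: the current active set is
#'   the caller's choice).
#' @return `coherence_trace_row()` returns a data.frame row per quad.
#' @export
coherence_trace_row <- function(t, counts, smoothing, prior, quads) {
  if (length(quads) == 0L) return(NULL)
  data.frame(
    t = t, quad = quads,
    pi_act = unname(smoothed_vector(counts, "act", smoothing)[quads]),
    pi_task = unname(smoothed_vector(counts, "task", smoothing)[quads]),
    pi_seq = unname(smoothed_vector(counts, "seq", smoothing)[quads]),
    psi = unname(prior$psi[quads]),
    stringsAsFactors = FALSE)
}
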