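#' @keywords internal
"_PACKAGE"

# ---- internal utilities -----------------------------------------------------

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' The four network layers
#'
#' The nested task representation has exactly four layers: Environment (`"E"`,
#' space and tools), Activity (`"A"`, what is done), Goals (`"G"`, what is
#' aimed for) and Meaning (`"M"`, how performance is interpreted).  Every
#' symbol belongs to exactly one layer.
#'
#' @return Character vector `c("E", "A", "G", "M")`.
#' @export
layer_ids <- function() c("E", "A", "G", "M")

assert_layer <- function(layer) {
  if (!(is.character(layer) && length(layer) == 1L && layer %in% layer_ids()))
    stop("unknown layer: ", paste(layer, collapse = ","), call. = FALSE)
  layer
}

#' Create a layer symbol
#'
#' A symbol is an explicit code within one layer's vocabulary.  Candidate
#' symbols live outside the established lexicon (in its shadow) until the
#' validation gate promotes them.
#'
#' @param layer One of `layer_ids()`.
#' @param code Short character identifier (case-sensitive, no whitespace).
#' @param status `"established"` or `"candidate"`.
#' @return An object of class `eagm_symbol`.
#' @export
symbol <- function(layer, code, status = c("established", "candidate")) {
  assert_layer(layer)
  status <- match.arg(status)
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  if (grepl("[[:space:]|]", code))
    stop("symbol codes must not contain whitespace or '|'", call. = FALSE)
  structure(list(layer = layer, code = code, status = status),
            class = "eagm_symbol")
}

#' Create a single-layer lexicon
#'
#' A lexicon is the ordered, versioned vocabulary of established symbols for
#' one layer.  Versions only grow and symbols are never removed; rejected
#' candidates simply never enter.  Unpromoted candidates are held in a shadow
#' set so that likelihood factors never see them.
#'
#' @param layer One of `layer_ids()`.
#' @param codes Character vector of established symbol codes (insertion order
#'   is preserved for stable serialization).
#' @param version Nonnegative integer version.
#' @param shadow Character vector of candidate codes awaiting promotion.
#' @return An object of class `eagm_lexicon`.
#' @export
lexicon <- function(layer, codes = character(), version = 0L,
                    shadow = character()) {
  assert_layer(layer)
  codes <- as.character(codes)
  if (anyDuplicated(codes)) stop("duplicate symbol codes in lexicon")
  structure(list(layer = layer, codes = codes, shadow = as.character(shadow),
                 version = as.integer(version)),
            class = "eagm_lexicon")
}

#' @export
print.eagm_lexicon <- function(x, ...) {
  cat(sprintf("<lexicon %s v%d: %s>\n", x$layer, x$version,
              paste(x$codes, collapse = ", ")))
  invisible(x)
}

#' Bundle the four lexicons into one lexicon state
#'
#' @param E,A,G,M `eagm_lexicon` objects (or character vectors of codes, which
#'   are wrapped at version 0).
#' @param symbolizer_version,compatibility_version Integers tracking which
#'   symbolizer / compatibility tables the state was built against; they must
#'   stay consistent across a single inference step.
#' @return An object of class `eagm_lexicon_state`.
#' @export
lexicon_state <- function(E, A, G, M, symbolizer_version = 0L,
                          compatibility_version = 0L) {
  lx <- list(E = E, A = A, G = G, M = M)
  for (L in layer_ids()) {
    if (is.character(lx[[L]])) lx[[L]] <- lexicon(L, lx[[L]])
    stopifnot(inherits(lx[[L]], "eagm_lexicon"), lx[[L]]$layer == L)
  }
  structure(c(lx, list(symbolizer_version = as.integer(symbolizer_version),
                       compatibility_version = as.integer(compatibility_version))),
            class = "eagm_lexicon_state")
}

#' Promote a candidate symbol into its layer's lexicon
#'
#' Applies a validation-gate decision to a candidate code.  On acceptance the
#' layer's vocabulary becomes its union with the candidate and the lexicon
#' version increments; on rejection (or when the code is already established,
#' making the union a no-op) the state is returned unchanged.
#'
#' @param state An `eagm_lexicon_state`.
#' @param candidate An `eagm_symbol` with `status == "candidate"`.
#' @param gate_decision 0/1 (or logical) decision from the validation gate.
#' @return The updated `eagm_lexicon_state`.
#' @export
promote_symbol <- function(state, candidate, gate_decision) {
  stopifnot(inherits(state, "eagm_lexicon_state"),
            inherits(candidate, "eagm_symbol"))
  if (candidate$status != "candidate")
    stop("only candidate symbols can be promoted", call. = FALSE)
  if (!candidate$layer %in% layer_ids())
    stop("candidate's layer unknown: ", candidate$layer, call. = FALSE)
  if (!isTRUE(as.logical(gate_decision))) return(state)
  lx <- state[[candidate$layer]]
  if (candidate$code %in% lx$codes) {
    # set union with an existing element: vocabulary and version unchanged
    lx$shadow <- setdiff(lx$shadow, candidate$code)
    state[[candidate$layer]] <- lx
    return(state)
  }
  lx$codes <- c(lx$codes, candidate$code)
  lx$shadow <- setdiff(lx$shadow, candidate$code)
  lx$version <- lx$version + 1L
  state[[candidate$layer]] <- lx
  state
}

# ---- quadruples and the enumerated universe ---------------------------------

#' Create a cross-layer quadruple
#'
#' A quadruple `r = (sE, sA, sG, sM)` asserts four-layer connectivity: one
#' symbol per layer.
#'
#' @param sE,sA,sG,sM Symbol codes (character scalars).
#' @return A named character vector of class `quadruple`.
#' @export
quadruple <- function(sE, sA, sG, sM) {
  q <- c(E = as.character(sE), A = as.character(sA),
         G = as.character(sG), M = as.character(sM))
  stopifnot(all(nzchar(q)))
  structure(q, class = "quadruple")
}

#' @rdname quadruple
#' @param quad A `quadruple` (or named character vector with E/A/G/M entries).
#' @return `quad_key()` returns the canonical `"E|A|G|M"` string key.
#' @export
quad_key <- function(quad) paste(quad[c("E", "A", "G", "M")], collapse = "|")

#' @rdname quadruple
#' @param key A `"E|A|G|M"` key string.
#' @export
quad_from_key <- function(key) {
  parts <- strsplit(key, "|", fixed = TRUE)[[1]]
  stopifnot(length(parts) == 4L)
  quadruple(parts[1], parts[2], parts[3], parts[4])
}

#' Enumerate the quadruple universe of a lexicon state
#'
#' The universe is the cross product of the four established vocabularies.
#' Coherence histograms, the edge factor of the joint posterior and the
#' observability gain are all defined over this enumerable set, which is
#' recomputed whenever a lexicon version changes.
#'
#' @param state An `eagm_lexicon_state`.
#' @return A list with `keys` (character, length `|E||A||G||M|`), per-layer
#'   component vectors `E`, `A`, `G`, `M`, the `gm` pair key `"G|M"` per quad,
#'   and `n`.
#' @export
quad_universe <- function(state) {
  stopifnot(inherits(state, "eagm_lexicon_state"))
  g <- expand.grid(E = state$E$codes, A = state$A$codes,
                   G = state$G$codes, M = state$M$codes,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(g) == 0L) stop("empty lexicon: universe has no quadruples")
  keys <- paste(g$E, g$A, g$G, g$M, sep = "|")
  list(keys = keys, E = g$E, A = g$A, G = g$G, M = g$M,
       gm = paste(g$G, g$M, sep = "|"), n = nrow(g))
}

# ---- c4 edges and their lifecycle -------------------------------------------

edge_statuses <- c("candidate", "refining", "error", "active", "validated")

#' Create a c4 edge record
#'
#' Tracks a quadruple's lifecycle through the gated pipeline:
#' `candidate -> {refining}* -> {error | active} -> validated`, with
#' `validated` terminal.
#'
#' @param quad A `quadruple`.
#' @param status Lifecycle status.
#' @param kappa Compatibility score in `[0, 1]` (NA until scored).
#' @param psi_coh Coherence log-odds (NA until scored).
#' @param activation_count Number of instants the edge has been active.
#' @param confidence Accumulated confidence in `[0, 1)`.
#' @param attempts Refinement attempts consumed.
#' @param iters_active Review iterations observed while active (for the
#'   validation gate's review period).
#' @return An object of class `c4_edge`.
#' @export
c4_edge <- function(quad, status = "candidate", kappa = NA_real_,
                    psi_coh = NA_real_, activation_count = 0L,
                    confidence = 0, attempts = 0L, iters_active = 0L) {
  stopifnot(inherits(quad, "quadruple"), status %in% edge_statuses)
  structure(list(quad = quad, status = status, kappa = kappa,
                 psi_coh = psi_coh,
                 activation_count = as.integer(activation_count),
                 confidence = confidence, attempts = as.integer(attempts),
                 iters_active = as.integer(iters_active)),
            class = "c4_edge")
}

#' Accumulated-activation confidence of an edge
#'
#' Saturating map `n / (n + c_half)` from activation count to `[0, 1)`;
#' monotone in evidence.
#'
#' @param activation_count Nonnegative integer.
#' @param c_half Count at which confidence reaches 0.5 (default 5).
#' @export
edge_confidence <- function(activation_count, c_half = 5) {
  stopifnot(activation_count >= 0, c_half > 0)
  activation_count / (activation_count + c_half)
}

#' Advance a c4 edge through its lifecycle
#'
#' Legal transitions: a `candidate` or `refining` edge that passes all gates
#' becomes `active` (activation count incremented); failing a gate sends it
#' to `refining` (attempts incremented) or, when attempts are exhausted, to
#' the `error` state; an `active` edge re-activates on `pass_all_gates` and
#' becomes `validated` on `validate`.  `validated` is terminal and illegal
#' transitions raise an error.
#'
#' @param edge A `c4_edge`.
#' @param event One of `"pass_all_gates"`, `"fail_gate"`,
#'   `"exhaust_attempts"`, `"validate"`.
#' @param max_attempts Refinement attempts after which `fail_gate` routes to
#'   `error` (default 3).
#' @param c_half Confidence half-count, see [edge_confidence()].
#' @return The updated `c4_edge`.
#' @export
transition_edge <- function(edge, event = c("pass_all_gates", "fail_gate",
                                            "exhaust_attempts", "validate"),
                            max_attempts = 3L, c_half = 5) {
  stopifnot(inherits(edge, "c4_edge"))
  event <- match.arg(event)
  bad <- function() stop(sprintf("illegal transition: %s + %s",
                                 edge$status, event), call. = FALSE)
  s <- edge$status
  if (s == "validated" || s == "error") bad()
  if (event == "pass_all_gates") {
    if (!s %in% c("candidate", "refining", "active")) bad()
    edge$status <- "active"
    edge$activation_count <- edge$activation_count + 1L
    edge$confidence <- edge_confidence(edge$activation_count, c_half)
  } else if (event == "fail_gate") {
    if (!s %in% c("candidate", "refining")) bad()
    edge$attempts <- edge$attempts + 1L
    edge$status <- if (edge$attempts >= max_attempts) "error" else "refining"
  } else if (event == "exhaust_attempts") {
    if (!s %in% c("candidate", "refining")) bad()
    edge$status <- "error"
  } else if (event == "validate") {
    if (s != "active") bad()
    edge$status <- "validated"
  }
  edge
}

# ---- network state and serialization ----------------------------------------

#' Create a network state
#'
#' The permanent network: the current lexicon state, the set of validated c4
#' edges, and the error list of quadruples that persistently failed the gates
#' (with their failure counts).  The error list is disjoint from the
#' validated set.
#'
#' @param lexicon_state An `eagm_lexicon_state`.
#' @param validated_edges List of `c4_edge` objects with status `validated`.
#' @param error_list Named integer vector: quad key -> failure count.
#' @return An object of class `network_state`.
#' @export
network_state <- function(lexicon_state,
                          validated_edges = list(),
                          error_list = integer()) {
  stopifnot(inherits(lexicon_state, "eagm_lexicon_state"))
  for (e in validated_edges)
    if (!inherits(e, "c4_edge") || e$status != "validated")
      stop("validated_edges must contain only validated c4 edges")
  vkeys <- vapply(validated_edges, function(e) quad_key(e$quad), "")
  if (length(intersect(vkeys, names(error_list))) > 0L)
    stop("error list must be disjoint from validated edges")
  structure(list(lexicon_state = lexicon_state,
                 validated_edges = validated_edges,
                 error_list = error_list),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf("<network: %d validated edges, %d error-listed quads>\n",
              length(x$validated_edges), length(x$error_list)))
  invisible(x)
}

validated_keys <- function(network) {
  vapply(network$validated_edges, function(e) quad_key(e$quad), "")
}

#' Serialize / deserialize a network state as JSON
#'
#' The layout is `{layers: {E|A|G|M: {version, symbols[]}}, validated_edges[],
#' error_list[]}`.  Serialization order is insertion order and the round trip
#' is bit-exact: `network_to_json(network_from_json(s))` equals `s`.
#'
#' @param network A `network_state`.
#' @param path Optional file path; when given the JSON is also written there.
#' @return `network_to_json()` returns the JSON string (invisibly when
#'   `path` is given); `network_from_json()` returns the `network_state`.
#' @export
network_to_json <- function(network, path = NULL) {
  stopifnot(inherits(network, "network_state"))
  st <- network$lexicon_state
  layers <- lapply(layer_ids(), function(L)
    list(version = st[[L]]$version, symbols = as.list(st[[L]]$codes)))
  names(layers) <- layer_ids()
  edges <- lapply(network$validated_edges, function(e)
    list(quad = quad_key(e$quad), activation_count = e$activation_count,
         confidence = e$confidence))
  errs <- lapply(seq_along(network$error_list), function(i)
    list(quad = names(network$error_list)[i],
         failure_count = unname(network$error_list[i])))
  obj <- list(layers = layers, validated_edges = edges, error_list = errs)
  s <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(as.character(s)))
  }
  as.character(s)
}

#' @rdname network_to_json
#' @param json JSON string or path to a JSON file.
#' @export
network_from_json <- function(json) {
  if (length(json) == 1L && file.exists(json)) json <- readLines(json)
  obj <- jsonlite::fromJSON(paste(json, collapse = "\n"),
                            simplifyVector = FALSE)
  lx <- lapply(layer_ids(), function(L)
    lexicon(L, unlist(obj$layers[[L]]$symbols) %||% character(),
            version = obj$layers[[L]]$version))
  names(lx) <- layer_ids()
  st <- lexicon_state(lx$E, lx$A, lx$G, lx$M)
  edges <- lapply(obj$validated_edges, function(e) {
    q <- quad_from_key(e$quad)
    ed <- c4_edge(q, status = "active",
                  activation_count = e$activation_count,
                  confidence = e$confidence)
    ed$status <- "validated"
    ed
  })
  errs <- vapply(obj$error_list, function(e) as.integer(e$failure_count),
                 integer(1))
  names(errs) <- vapply(obj$error_list, function(e) e$quad, "")
  network_state(st, edges, errs)
}

# ---- the four-level time index ----------------------------------------------

#' Create a hierarchical time index
#'
#' Time is bracketed into four nested levels: instants partition into action
#' segments, segments into tasks, tasks into sequences.  Indices are 1-based
#' and ordered lexicographically as (sequence, task, action_segment, instant).
#'
#' @param sequence,task,action_segment,instant Positive integers.
#' @return An object of class `time_index`.
#' @export
time_index <- function(sequence, task, action_segment, instant) {
  v <- c(sequence = as.integer(sequence), task = as.integer(task),
         action_segment = as.integer(action_segment),
         instant = as.integer(instant))
  stopifnot(all(v >= 1L))
  structure(as.list(v), class = "time_index")
}

# strictly-increasing comparison in lexicographic order
time_lt <- function(a, b) {
  av <- c(a$sequence, a$task, a$action_segment, a$instant)
  bv <- c(b$sequence, b$task, b$action_segment, b$instant)
  d <- av - bv
  nz <- which(d != 0L)
  length(nz) > 0L && d[nz[1]] < 0L
}
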