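# Shared in-code fixtures: tiny lexicons, universes and models used across
# the module tests.

tiny_state <- function(nE = 2, nA = 2, nG = 2, nM = 2) {
  lexicon_state(paste0("e", seq_len(nE)), paste0("a", seq_len(nA)),
                paste0("g", seq_len(nG)), paste0("m", seq_len(nM)))
}

# a universe with exactly two quadruples (single E, A, M; two G symbols)
two_quad_universe <- function() {
  quad_universe(lexicon_state("e1", "a1", c("g1", "g2"), "m1"))
}

# observation model with one-hot symbol locations
onehot_obs_model <- function(state, sep = 3, sd = 1) {
  observation_model(lapply(stats::setNames(layer_ids(), layer_ids()),
                           function(L) {
    codes <- state[[L]]$codes
    list(mean = diag(sep, length(codes)) +
           matrix(0, length(codes), length(codes),
                  dimnames = list(codes, NULL)),
         sd = sd)
  }))
}

# a compatibility model that scores one planted quad high
planted_compat <- function(quad, hi = 3, lo = -3) {
  compatibility_model(
    phi_base = stats::setNames(hi, paste(quad[["A"]], quad[["G"]],
                                         quad[["M"]], sep = "|")),
    phi_view = stats::setNames(0, paste(quad[["E"]], quad[["A"]],
                                        sep = "|")))
}

point_posterior <- function(layer, codes, at) {
  p <- stats::setNames(rep(0, length(codes)), codes)
  p[at] <- 1
  structure(list(layer = layer, probs = p, entropy_bits = 0),
            class = "symbol_posterior")
}

uniform_posterior <- function(layer, codes) {
  p <- stats::setNames(rep(1 / length(codes), length(codes)), codes)
  structure(list(layer = layer, probs = p,
                 entropy_bits = entropy_bits(p)),
            class = "symbol_posterior")
}

# brute-force scorer for the span-consistent segmentation factor: enumerates
# every labeling and multiplies frame evidence, transition prior and span
# factors explicitly
decode_oracle <- function(evidence, transition, proposals, init = NULL) {
  labels <- colnames(evidence)
  Tn <- nrow(evidence)
  if (is.null(init)) init <- rep(1 / length(labels), length(labels))
  names(init) <- labels
  grid <- do.call(expand.grid, c(rep(list(labels), Tn),
                                 stringsAsFactors = FALSE))
  w <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    lab <- unlist(grid[r, ])
    s <- init[[lab[1]]] * evidence[1, lab[1]]
    if (Tn > 1) for (t in 2:Tn)
      s <- s * transition[lab[t - 1], lab[t]] * evidence[t, lab[t]]
    for (sp in proposals) {
      consistent <- all(lab[sp$start:sp$end] == sp$type)
      s <- s * (sp$confidence * consistent + (1 - sp$confidence))
    }
    w[r] <- s
  }
  marg <- matrix(0, Tn, length(labels), dimnames = list(NULL, labels))
  for (t in seq_len(Tn))
    for (l in labels)
      marg[t, l] <- sum(w[grid[[t]] == l])
  list(map = unlist(grid[which.max(w), ]), marginals = marg / sum(w))
}
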