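# Probe-action selection: expected information gain about the orientation
# minus a two-term action cost (execution time plus deviation from the
# historically expected connectivity).

#' Probe action
#'
#' A computational observation choice (view / zoom / feature set): which
#' observation channels it exposes per layer, and its execution time.
#'
#' @param id Action identifier (tie-breaks are by `id`).
#' @param channels Named list per layer of exposed channels (e.g. the E
#'   symbols observable under this action); at least one channel overall.
#' @param execution_time Nonnegative resource cost `tau(a)`.
#' @return An object of class `probe_action`.
#' @export
probe_action <- function(id, channels, execution_time = 1) {
  stopifnot(is.list(channels), length(unlist(channels)) > 0L,
            execution_time >= 0)
  structure(list(id = id, channels = channels,
                 execution_time = execution_time),
            class = "probe_action")
}

#' Action cost model
#'
#' `cost(a) = c_tau * tau(a) + c_dev * d(a)`.  The deviation coefficient
#' follows a saturating growth schedule in the effective history size,
#' `c_dev(n) = c_dev_max * n / (n + n_half)`: low early (exploration),
#' rising as the coherence prior stabilizes (exploitation).
#'
#' @param c_tau Nonnegative execution-time weight.
#' @param c_dev_max Nonnegative ceiling of the deviation weight.
#' @param n_half History size at which `c_dev` reaches half its ceiling
#'   (default 100 instants).
#' @return An object of class `cost_model`.
#' @export
cost_model <- function(c_tau = 0.1, c_dev_max = 1, n_half = 100) {
  stopifnot(c_tau >= 0, c_dev_max >= 0, n_half > 0)
  structure(list(c_tau = c_tau, c_dev_max = c_dev_max, n_half = n_half),
            class = "cost_model")
}

#' @rdname cost_model
#' @param cost A `cost_model`.
#' @param n_eff Effective history size in instants.
#' @return `c_dev_at()` returns the scheduled deviation coefficient.
#' @export
c_dev_at <- function(cost, n_eff) {
  cost$c_dev_max * n_eff / (n_eff + cost$n_half)
}

#' Expectation model: which quadruples each action can reveal
#'
#' @param support Named list, action id -> character vector of quad keys
#'   accessible via that action (its `supp(r)` relation).  Actions mapping
#'   to no quad are flagged exploratory.
#' @return An object of class `expectation_model`.
#' @export
expectation_model <- function(support) {
  stopifnot(is.list(support), !is.null(names(support)))
  structure(list(support = support), class = "expectation_model")
}

#' Expected-action probabilities
#'
#' For each action, sums the coherence prior mass of the quadruples it can
#' reveal, weighted by the orientation posterior mass consistent with each
#' quad's (G, M) components, then normalizes across actions so the values
#' form a probability over the action set.  An action whose raw sum is zero
#' is exploratory (`pi_exp = 0`).
#'
#' @param model An [expectation_model()].
#' @param prior A [coherence_prior()].
#' @param orientation An [orientation_state()].
#' @param actions Character action ids (default: all in the model).
#' @return Named numeric `pi_exp` per action, summing to 1 (or all zero).
#' @export
expected_action_probability <- function(model, prior, orientation,
                                        actions = names(model$support)) {
  gm_of <- function(key) {
    p <- strsplit(key, "|", fixed = TRUE)[[1]]
    paste(p[3], p[4], sep = "|")
  }
  raw <- vapply(actions, function(a) {
    keys <- model$support[[a]]
    if (is.null(keys) || length(keys) == 0L) return(0)
    pi <- prior$pi[keys]
    if (anyNA(pi)) stop("support quad outside the prior's universe",
                        call. = FALSE)
    om <- orientation$probs[vapply(keys, gm_of, "")]
    om[is.na(om)] <- 0
    sum(pi * om)
  }, numeric(1))
  tot <- sum(raw)
  if (tot > 0) raw / tot else raw
}

#' Deviation cost
#'
#' `d = -log pi_exp`, clamped at `d_max` when `pi_exp = 0` (a fully
#' off-expectation, exploratory action).
#'
#' @param pi_exp Expected-action probability in `[0, 1]`.
#' @param d_max Clamp for `pi_exp = 0` (default 10).
#' @export
deviation_cost <- function(pi_exp, d_max = 10) {
  stopifnot(all(pi_exp >= 0), all(pi_exp <= 1))
  pmin(-log(pmax(pi_exp, exp(-d_max))), d_max)
}

#' Total action cost
#'
#' `cost = c_tau * tau(a) + c_dev * d(a)`; nonnegative.
#'
#' @param cost A [cost_model()].
#' @param action A [probe_action()].
#' @param pi_exp The action's expected-action probability.
#' @param n_eff Effective history size feeding the `c_dev` schedule
#'   (default `Inf`: `c_dev` at its ceiling).
#' @param d_max Deviation clamp, see [deviation_cost()].
#' @export
action_cost <- function(cost, action, pi_exp, n_eff = Inf, d_max = 10) {
  cdev <- if (is.infinite(n_eff)) cost$c_dev_max else c_dev_at(cost, n_eff)
  cost$c_tau * action$execution_time + cdev * deviation_cost(pi_exp, d_max)
}

#' Expected information gain of a probe action
#'
#' `EIG(a) = H(orientation) - E_obs[H(orientation | obs, a)]` in bits,
#' computed exactly by enumerating the discretized observation alphabet
#' (per-layer symbol identity).  Nonnegative up to numerical error.
#'
#' @param orientation An [orientation_state()].
#' @param channel Row-stochastic matrix `p(obs | orientation)`: one row per
#'   orientation pair (rownames = the support), one column per observation
#'   outcome.
#' @return The EIG in bits.
#' @export
expected_information_gain <- function(orientation, channel) {
  stopifnot(is.matrix(channel),
            all(names(orientation$probs) %in% rownames(channel)))
  ch <- channel[names(orientation$probs), , drop = FALSE]
  if (any(abs(rowSums(ch) - 1) > 1e-9))
    stop("channel rows must sum to 1", call. = FALSE)
  p <- orientation$probs
  p_obs <- as.numeric(p %*% ch)
  h_post <- 0
  for (j in seq_len(ncol(ch))) {
    if (p_obs[j] <= 0) next
    post <- p * ch[, j] / p_obs[j]
    h_post <- h_post + p_obs[j] * entropy_bits(post)
  }
  entropy_bits(p) - h_post
}

#' Select the best probe action
#'
#' Maximizes net utility `exchange_rate * EIG - cost`; ties break
#' deterministically on the smallest action id.  An off-expectation action
#' is selected exactly when its information gain exceeds the on-expectation
#' alternatives by more than the cost gap — the signature of a novel or
#' unknown event worth a deliberate deviation.
#'
#' @param actions List of [probe_action()]s (nonempty).
#' @param eig Numeric EIG per action (same order).
#' @param costs Numeric cost per action.
#' @param exchange_rate Bits-to-cost conversion constant (default 1).
#' @return The selected `probe_action`.
#' @export
select_action <- function(actions, eig, costs, exchange_rate = 1) {
  if (length(actions) == 0L) stop("empty action set", call. = FALSE)
  stopifnot(length(eig) == length(actions), length(costs) == length(actions))
  net <- exchange_rate * eig - costs
  best <- which(net >= max(net) - 1e-12)
  ids <- vapply(actions[best], function(a) as.character(a$id), "")
  actions[[best[order(ids)[1]]]]
}
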