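#' Enumerate all binary configurations of n nodes
#'
#' States are indexed 0..2^n - 1; node j is bit j - 1 of the index, so state
#' matrices from this function line up with the implicit state indexing used
#' by [joint_distribution()].
#'
#' @param n Node count.
#' @param domain `"01"` or `"pm1"`.
#' @return An integer matrix with 2^n rows and n columns.
#' @export
ising_states <- function(n, domain = c("01", "pm1")) {
  domain <- match.arg(domain)
  if (n < 1) abort("`n` must be at least 1.")
  if (n > enum_limit()) {
    abort(sprintf(
      "%d nodes is too large to enumerate (limit %d); use sample_chain().",
      n, enum_limit()
    ))
  }
  idx <- 0:(2^n - 1)
  states <- vapply(
    seq_len(n),
    function(j) as.integer((idx %/% 2^(j - 1)) %% 2),
    integer(2^n)
  )
  if (!is.matrix(states)) states <- matrix(states, ncol = n)
  if (domain == "pm1") states <- 2L * states - 1L
  states
}

log_potential <- function(net, states) {
  # states: matrix (rows = configurations) on the network's own domain
  as.numeric(states %*% net$tau + rowSums((states %*% net$W) * states) / 2)
}

#' Probability of a single configuration under the exact Ising law
#'
#' Evaluates `exp(sum_i tau_i x_i + sum_{i<j} W_ij x_i x_j) / Z` with the
#' normalizing constant `Z` computed by full enumeration of the 2^n states
#' (each unordered pair counted once).
#'
#' @param net An `ising_network`.
#' @param state Vector of node states on the network's domain.
#' @return The state's probability.
#' @examples
#' net <- make_network(c(0, 0), matrix(0, 2, 2))
#' state_probability(net, c(1, 1)) # 0.25
#' @export
state_probability <- function(net, state) {
  assert_network(net)
  n <- n_nodes(net)
  if (length(state) != n) {
    abort(sprintf("`state` has %d entries for a %d-node network.",
                  length(state), n))
  }
  dom <- domain_values(net)
  if (!all(state %in% dom)) {
    abort(sprintf("State entries must lie in {%s}.",
                  paste(dom, collapse = ",")))
  }
  dist <- joint_distribution(net)
  lp <- log_potential(net, matrix(as.numeric(state), nrow = 1))
  exp(lp - dist$logZ)
}

#' Exact joint distribution by full state enumeration
#'
#' Enumerates all 2^n configurations and normalizes in log space
#' (log-sum-exp), so potentials far outside double range of `exp()` inputs
#' (e.g. e^36 under strong risk perturbations) do not overflow.
#'
#' @param net An `ising_network` with at most `getOption("netresil.enum_limit", 20)`
#'   nodes.
#' @return A `state_distribution`: list with `n`, `labels`, `domain`,
#'   `probs` (length 2^n, state index order of [ising_states()]), `logZ`,
#'   and `sum_scores` (active-node count per state).
#' @export
joint_distribution <- function(net) {
  assert_network(net)
  n <- n_nodes(net)
  states <- ising_states(n, net$domain)
  lp <- log_potential(net, states)
  m <- max(lp)
  logZ <- m + log(sum(exp(lp - m)))
  probs <- exp(lp - logZ)
  structure(
    list(
      n = n, labels = net$labels, domain = net$domain,
      probs = probs, logZ = logZ,
      sum_scores = as.integer(rowSums(states == 1))
    ),
    class = "state_distribution"
  )
}

#' @export
print.state_distribution <- function(x, ...) {
  cat(sprintf(
    "<state_distribution> %d nodes, %d states, logZ = %.4f\n",
    x$n, length(x$probs), x$logZ
  ))
  invisible(x)
}

#' Tidy a state distribution
#'
#' @param x A `state_distribution`.
#' @param ... Unused.
#' @return A tibble with columns `state_index` (0-based), `sum_score`, `prob`.
#' @export
tidy.state_distribution <- function(x, ...) {
  tibble(
    state_index = seq_along(x$probs) - 1L,
    sum_score = x$sum_scores,
    prob = x$probs
  )
}

#' Distribution of the symptom sum score
#'
#' Collapses a joint state distribution to the distribution of `Y`, the
#' number of active nodes: `P(Y = i)` is the total probability of all
#' configurations with exactly `i` active nodes.
#'
#' @param x A `state_distribution` from [joint_distribution()], or an
#'   `ising_network` (enumerated on the fly).
#' @return A tibble of class `sumscore_distribution` with columns
#'   `sum_score` (0..n) and `prob`; the node count is attached as
#'   attribute `n`.
#' @examples
#' net <- uniform_network(9, tau = -2, w = 0.5)
#' sumscore_distribution(net)
#' @export
sumscore_distribution <- function(x) {
  if (is_ising_network(x)) x <- joint_distribution(x)
  if (!inherits(x, "state_distribution")) {
    abort("Expected a `state_distribution` or `ising_network`.")
  }
  probs <- vapply(
    0:x$n,
    function(k) sum(x$probs[x$sum_scores == k]),
    numeric(1)
  )
  out <- tibble(sum_score = 0:x$n, prob = probs)
  attr(out, "n") <- x$n
  class(out) <- c("sumscore_distribution", class(out))
  out
}
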