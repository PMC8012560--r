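#' Fully connected network with identical parameters
#'
#' Every node gets threshold `tau` and every pair gets weight `w`. The
#' canonical nine-symptom example (`n = 9`, `tau = -2`, `w = 0.5`) mimics the
#' DSM-5 major-depression symptom set with moderate uniform coupling.
#'
#' @param n Node count (at least 1).
#' @param tau Common threshold value.
#' @param w Common edge weight.
#' @param labels Optional node labels.
#' @return An `ising_network` of density 1 (or 0 when `w = 0` or `n = 1`).
#' @examples
#' uniform_network(9, tau = -2, w = 0.5)
#' @export
uniform_network <- function(n, tau = -2, w = 0.5, labels = NULL) {
  if (n < 1) abort("`n` must be at least 1.")
  W <- matrix(w, n, n)
  diag(W) <- 0
  make_network(rep(tau, n), W, labels = labels)
}

#' Random network structure at a fixed density
#'
#' Places exactly `round(density * n(n-1)/2)` edges uniformly at random
#' without replacement, each with weight `w`; all thresholds are `tau`.
#' Reproducible under `seed` (the caller's RNG state is restored).
#'
#' @param n Node count.
#' @param density Proportion of present edges in `[0, 1]`.
#' @param tau Common threshold value.
#' @param w Common edge weight.
#' @param seed Optional integer seed.
#' @param labels Optional node labels.
#' @return An `ising_network`.
#' @examples
#' net <- random_density_network(9, density = 0.5, tau = -2, w = 0.5, seed = 1)
#' network_density(net) # 0.5
#' @export
random_density_network <- function(n, density, tau = -2, w = 0.5,
                                   seed = NULL, labels = NULL) {
  if (n < 2) abort("`n` must be at least 2 for a random structure.")
  if (!is.numeric(density) || density < 0 || density > 1) {
    abort("`density` must lie in [0, 1].")
  }
  n_pairs <- choose(n, 2)
  m <- round(density * n_pairs)
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  chosen <- with_seed_if(seed, sample.int(n_pairs, m))
  W <- matrix(0, n, n)
  W[pairs[chosen, , drop = FALSE]] <- w
  W <- W + t(W)
  make_network(rep(tau, n), W, labels = labels)
}

#' Edge density of a network
#'
#' The proportion of present (nonzero-weight) edges relative to all
#' `n(n-1)/2` possible unordered pairs.
#'
#' @param net An `ising_network` with at least 2 nodes.
#' @return Density in `[0, 1]`.
#' @export
network_density <- function(net) {
  assert_network(net)
  n <- n_nodes(net)
  if (n < 2) abort("Density is undefined for fewer than 2 nodes.")
  n_edges(net) / choose(n, 2)
}

#' Node-strength centrality
#'
#' A node's strength is the sum of the absolute weights of its incident
#' edges. Ranks run from 1 (strongest) to n; ties are broken
#' deterministically by label order (network label position), and the
#' tie-break rule is recorded in the `tie_break` attribute.
#'
#' @param net An `ising_network`.
#' @return A tibble of class `centrality_table` with columns `label`,
#'   `strength`, `z` (standardized strength; 0 when all strengths are equal)
#'   and `rank`.
#' @examples
#' node_strength(uniform_network(9, -2, 0.5)) # every node strength 4
#' @export
node_strength <- function(net) {
  assert_network(net)
  s <- rowSums(abs(net$W))
  z <- if (sd(s) > 0) (s - mean(s)) / sd(s) else rep(0, length(s))
  out <- tibble(
    label = net$labels,
    strength = unname(s),
    z = unname(z),
    rank = rank(-s, ties.method = "first")
  )
  attr(out, "tie_break") <- "label order"
  class(out) <- c("centrality_table", class(out))
  out
}

#' Select the strongest or weakest nodes
#'
#' @param x A `centrality_table` from [node_strength()], or an
#'   `ising_network` (strengths computed on the fly).
#' @param k How many nodes to select (1..n).
#' @param which `"strongest"` (default) or `"weakest"`.
#' @return Character vector of `k` node labels. Ties are broken by label
#'   order.
#' @export
select_extreme_nodes <- function(x, k, which = c("strongest", "weakest")) {
  which <- match.arg(which)
  if (is_ising_network(x)) x <- node_strength(x)
  if (!inherits(x, "centrality_table")) {
    abort("Expected a `centrality_table` or `ising_network`.")
  }
  n <- nrow(x)
  if (k < 1 || k > n) abort(sprintf("`k` must be in 1..%d.", n))
  ord <- if (which == "strongest") {
    order(-x$strength, seq_len(n))
  } else {
    order(x$strength, seq_len(n))
  }
  x$label[ord[seq_len(k)]]
}

#' Edges incident to a node set
#'
#' All present edges with at least one endpoint in `nodes` — the edge subset
#' that moderators target in strong/weak-node perturbation designs. With
#' `within = TRUE` only edges with both endpoints in the set are returned.
#'
#' @param net An `ising_network`.
#' @param nodes Character vector of node labels (may be empty).
#' @param within If `TRUE`, restrict to edges internal to the node set.
#' @return A tibble with columns `from`, `to`, `weight` (one row per
#'   unordered pair).
#' @export
incident_edges <- function(net, nodes, within = FALSE) {
  assert_network(net)
  if (length(nodes) > 0) match_labels(net, nodes) # label check
  edges <- tidy.ising_network(net)
  keep <- if (within) {
    edges$from %in% nodes & edges$to %in% nodes
  } else {
    edges$from %in% nodes | edges$to %in% nodes
  }
  edges[keep, ]
}
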