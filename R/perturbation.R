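#' The 11-constant multiplier grid
#'
#' The canonical perturbation grid: constants below 1 run from 0.5 to 1 in
#' steps of 0.1, and constants above 1 are their exact inverses
#' (1/0.9, 1/0.8, 1/0.7, 1/0.6, 1/0.5), giving a grid that is symmetric on
#' the log scale around the unperturbed baseline of 1. Values above 1 are
#' kept exact (1/0.7 = 1.428571...), not rounded to two decimals.
#'
#' @return Ascending numeric vector of length 11.
#' @examples
#' multiplier_grid()
#' @export
multiplier_grid <- function() {
  c(seq(0.5, 1, by = 0.1), 1 / seq(0.9, 0.5, by = -0.1))
}

#' Apply a risk/protective main effect to thresholds
#'
#' A main effect multiplies threshold parameters by a positive constant.
#' With the usual negative symptom thresholds, a constant below 1 makes
#' activation easier (risk) and a constant above 1 makes it harder
#' (protective). The input network is not modified.
#'
#' @param net An `ising_network`.
#' @param multiplier Positive constant.
#' @param nodes Optional character vector of node labels to target;
#'   `NULL` (default) targets every node.
#' @return A new `ising_network`.
#' @export
apply_main_effect <- function(net, multiplier, nodes = NULL) {
  assert_network(net)
  check_multiplier(multiplier)
  idx <- if (is.null(nodes)) seq_len(n_nodes(net)) else match_labels(net, nodes)
  tau <- net$tau
  tau[idx] <- tau[idx] * multiplier
  make_network(tau, net$W, labels = net$labels, domain = net$domain)
}

#' Apply a risk/protective moderator to edge weights
#'
#' A moderator multiplies edge weights by a positive constant. For positive
#' weights, a constant above 1 strengthens symptom-to-symptom spread (risk)
#' and a constant below 1 weakens it (protective). Absent edges (weight 0)
#' stay absent under any multiplier; symmetry is preserved.
#'
#' @param net An `ising_network`.
#' @param multiplier Positive constant.
#' @param edges Optional edge subset: a two-column matrix or data frame of
#'   node labels (one row per unordered pair). `NULL` (default) targets all
#'   present edges.
#' @return A new `ising_network`.
#' @export
apply_moderator <- function(net, multiplier, edges = NULL) {
  assert_network(net)
  check_multiplier(multiplier)
  W <- net$W
  if (is.null(edges)) {
    W <- W * multiplier
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) < 2) abort("`edges` needs two label columns.")
    i <- match_labels(net, edges[, 1])
    j <- match_labels(net, edges[, 2])
    if (any(i == j)) abort("Self-edges are not allowed.")
    W[cbind(i, j)] <- W[cbind(i, j)] * multiplier
    W[cbind(j, i)] <- W[cbind(j, i)] * multiplier
  }
  make_network(net$tau, W, labels = net$labels, domain = net$domain)
}

check_multiplier <- function(multiplier) {
  if (!is.numeric(multiplier) || length(multiplier) != 1 || multiplier <= 0) {
    abort("`multiplier` must be a single positive number.")
  }
}

#' Apply a perturbation to thresholds, edges, or both
#'
#' Dispatches to [apply_main_effect()], [apply_moderator()], or both with
#' the same constant; `"both"` multiplies thresholds and edge weights by the
#' one constant simultaneously.
#'
#' @inheritParams apply_main_effect
#' @param target `"thresholds"`, `"edges"`, or `"both"`.
#' @param nodes Node subset for threshold targeting (see [apply_main_effect()]).
#' @param edges Edge subset for moderator targeting (see [apply_moderator()]).
#' @return A new `ising_network`.
#' @examples
#' base <- uniform_network(9, -2, 0.5)
#' both_half <- apply_perturbation(base, 0.5, "both") # tau = -1, W = 0.25
#' @export
apply_perturbation <- function(net, multiplier,
                               target = c("thresholds", "edges", "both"),
                               nodes = NULL, edges = NULL) {
  target <- match.arg(target)
  out <- net
  if (target %in% c("thresholds", "both")) {
    out <- apply_main_effect(out, multiplier, nodes)
  }
  if (target %in% c("edges", "both")) {
    out <- apply_moderator(out, multiplier, edges)
  }
  out
}

#' Classify a perturbation as risk, protective, both, or baseline
#'
#' Sign conventions for the usual symptom-network parameterization: with
#' negative thresholds a constant below 1 is a risk main effect and above 1
#' protective; with positive weights a constant above 1 is a risk moderator
#' and below 1 protective. Simultaneous ("both") perturbations get the label
#' `"both"`, a multiplier of 1 `"baseline"`, and networks whose targeted
#' parameters have mixed signs `"mixed"`.
#'
#' @param net The base (unperturbed) `ising_network`.
#' @param target `"thresholds"`, `"edges"`, or `"both"`.
#' @param multiplier Positive constant.
#' @return One of `"baseline"`, `"risk"`, `"protective"`, `"both"`, `"mixed"`.
#' @export
rp_factor_type <- function(net, target, multiplier) {
  if (isTRUE(all.equal(multiplier, 1))) return("baseline")
  if (target == "both") return("both")
  if (target == "thresholds") {
    signs <- sign(net$tau[net$tau != 0])
    if (length(signs) == 0 || !all(signs == signs[1])) return("mixed")
    if (signs[1] < 0) {
      if (multiplier < 1) "risk" else "protective"
    } else {
      if (multiplier > 1) "risk" else "protective"
    }
  } else {
    w <- net$W[upper.tri(net$W)]
    signs <- sign(w[w != 0])
    if (length(signs) == 0 || !all(signs == signs[1])) return("mixed")
    if (signs[1] > 0) {
      if (multiplier > 1) "risk" else "protective"
    } else {
      if (multiplier < 1) "risk" else "protective"
    }
  }
}

#' Sweep a multiplier grid over perturbation targets
#'
#' For every combination of constant and target type, perturbs an independent
#' copy of the base network and computes ESA and SAS, either exactly (full
#' enumeration) or from a sampled chain for networks too large to enumerate.
#'
#' @param net The base `ising_network`.
#' @param grid Numeric vector of multipliers; defaults to [multiplier_grid()].
#' @param targets Character vector out of `"thresholds"`, `"edges"`, `"both"`.
#' @param nodes,edges Optional targeting subsets, passed to
#'   [apply_perturbation()].
#' @param mode `"exact"` (enumeration) or `"sampled"` (Gibbs chain).
#' @param iterations,burn_in,thin,n_chains Chain settings for sampled mode,
#'   passed to [sample_chain()].
#' @param seed Integer seed for sampled mode; condition `k` uses `seed + k`
#'   so conditions are independent but reproducible.
#' @return A tibble of class `resilience_sweep`: one row per
#'   (multiplier, target) with columns `target`, `multiplier`, `factor_type`,
#'   `esa`, `sas`, `degenerate`, `source`, `n_samples`, `seed`.
#' @examples
#' sweep <- perturbation_sweep(uniform_network(9, -2, 0.5))
#' dplyr::filter(sweep, multiplier %in% c(0.5, 1, 2))
#' @export
perturbation_sweep <- function(net, grid = multiplier_grid(),
                               targets = c("thresholds", "edges", "both"),
                               nodes = NULL, edges = NULL,
                               mode = c("exact", "sampled"),
                               iterations = 1000, burn_in = 0, thin = 1,
                               n_chains = 1, seed = NULL) {
  assert_network(net)
  mode <- match.arg(mode)
  targets <- match.arg(targets, c("thresholds", "edges", "both"),
                       several.ok = TRUE)
  conditions <- tidyr::expand_grid(target = targets, multiplier = grid)
  rows <- purrr::pmap(conditions, function(target, multiplier) {
    k <- which(conditions$target == target &
                 conditions$multiplier == multiplier)[1]
    pnet <- apply_perturbation(net, multiplier, target,
                               nodes = nodes, edges = edges)
    rep_row <- if (mode == "exact") {
      network_resilience(pnet)
    } else {
      cond_seed <- if (is.null(seed)) NULL else seed + k
      chain_resilience(pnet, iterations = iterations, burn_in = burn_in,
                       thin = thin, n_chains = n_chains, seed = cond_seed)
    }
    dplyr::mutate(
      rep_row,
      target = target,
      multiplier = multiplier,
      factor_type = rp_factor_type(net, target, multiplier),
      .before = 1
    )
  })
  out <- dplyr::bind_rows(rows)
  if (!"seed" %in% names(out)) out$seed <- NA_integer_
  class(out) <- c("resilience_sweep", class(out))
  out
}
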