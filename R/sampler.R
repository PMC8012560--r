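#' Sample Ising states with a single-site Metropolis-Hastings/Gibbs chain
#'
#' For networks too large to enumerate, states are simulated by a Markov
#' chain: at each iteration one node is resampled from its full conditional
#' `P(x_i = 1 | x_-i) = logistic(tau_i + sum_j W_ij x_j)`, visiting nodes in
#' a fixed sequential sweep. (Proposing the opposite response option and
#' accepting with the conditional probability — the Metropolis-Hastings
#' phrasing — coincides with this full-conditional update for a single-site
#' proposal.) The chain starts from random node values by default.
#'
#' An iteration is one single-node update (`update = "single"`, the default);
#' `update = "sweep"` makes each iteration a full sweep of n updates, useful
#' when 1,000 single-flip updates would barely move a large network.
#'
#' @param net An `ising_network` on the `{0,1}` domain.
#' @param iterations Number of iterations per chain (default 1000).
#' @param burn_in Iterations discarded from the front (default 0).
#' @param thin Keep every `thin`-th post-burn-in iteration (default 1).
#' @param n_chains Number of independent chains; kept states are stacked.
#' @param init `"random"` (each node Bernoulli(0.5)), `"zeros"`, or `"given"`
#'   with `init_state`.
#' @param init_state Binary vector used when `init = "given"`.
#' @param seed Optional integer; chains are bit-reproducible under the same
#'   seed and settings.
#' @param update `"single"` (iteration = one node update) or `"sweep"`
#'   (iteration = n updates).
#' @return A binary matrix of class `sample_matrix` (kept iterations x
#'   nodes, columns named by node label) with attributes `seed`, `burn_in`,
#'   `thin`, `update`, and `chain` (chain index per row).
#' @examples
#' net <- uniform_network(4, -1, 0.5)
#' chain <- sample_chain(net, iterations = 500, seed = 42)
#' colMeans(chain)
#' @export
sample_chain <- function(net, iterations = 1000, burn_in = 0, thin = 1,
                         n_chains = 1, init = c("random", "zeros", "given"),
                         init_state = NULL, seed = NULL,
                         update = c("single", "sweep")) {
  assert_network(net)
  init <- match.arg(init)
  update <- match.arg(update)
  if (net$domain != "01") {
    abort("Chain sampling requires the {0,1} domain; see convert_domain().")
  }
  if (iterations < 1) abort("`iterations` must be at least 1.")
  if (thin < 1) abort("`thin` must be at least 1.")
  if (burn_in < 0 || burn_in >= iterations) {
    abort("`burn_in` must be in [0, iterations).")
  }
  n <- n_nodes(net)
  if (init == "given") {
    if (is.null(init_state) || length(init_state) != n ||
        !all(init_state %in% c(0, 1))) {
      abort("`init_state` must be a binary vector of length n.")
    }
  }
  out <- with_seed_if(seed, {
    chains <- lapply(seq_len(n_chains), function(ch) {
      x0 <- switch(init,
        random = as.integer(runif(n) < 0.5),
        zeros = integer(n),
        given = as.integer(init_state)
      )
      gibbs_chain_cpp(net$tau, net$W, x0, as.integer(iterations),
                      as.integer(burn_in), as.integer(thin),
                      update == "sweep")
    })
    do.call(rbind, chains)
  })
  colnames(out) <- net$labels
  kept <- nrow(out) / n_chains
  structure(
    out,
    seed = seed, burn_in = burn_in, thin = thin, update = update,
    chain = rep(seq_len(n_chains), each = kept),
    class = c("sample_matrix", class(out))
  )
}

#' ESA and SAS from a sampled chain
#'
#' Runs [sample_chain()] and summarizes the simulated states with
#' [esa_from_samples()] and [sas_from_samples()]. With the classic settings
#' (1,000 iterations, one chain, no burn-in) this is the sampled analogue of
#' [network_resilience()] for networks beyond the enumeration limit.
#'
#' @inheritParams sample_chain
#' @param ... Further arguments passed to [sample_chain()].
#' @return A one-row tibble: `esa`, `sas`, `degenerate`, `source`
#'   (`"sampled"`), `n_samples`, `seed`.
#' @export
chain_resilience <- function(net, iterations = 1000, burn_in = 0, thin = 1,
                             n_chains = 1, seed = NULL, ...) {
  samples <- sample_chain(net, iterations = iterations, burn_in = burn_in,
                          thin = thin, n_chains = n_chains, seed = seed, ...)
  esa <- esa_from_samples(samples)
  sas <- withCallingHandlers(
    sas_from_samples(samples),
    netresil_degenerate = function(w) invokeRestart("muffleWarning")
  )
  tibble(
    esa = esa, sas = sas, degenerate = is.na(sas),
    source = "sampled", n_samples = nrow(samples),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}

#' Empirical state frequencies of a sampled chain
#'
#' Tabulates sampled configurations on the state indexing of
#' [ising_states()], for direct comparison against [joint_distribution()].
#'
#' @param samples A `sample_matrix` (or binary matrix).
#' @return Numeric vector of length 2^n of relative frequencies.
#' @export
state_frequencies <- function(samples) {
  samples <- check_sample_matrix(samples)
  n <- ncol(samples)
  idx <- as.integer(samples %*% 2^(seq_len(n) - 1))
  tabulate(idx + 1L, nbins = 2^n) / nrow(samples)
}
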