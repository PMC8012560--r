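run_metadata <- function(cfg, seed) {
  tibble(
    config_hash = rlang::hash(cfg),
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    version = as.character(utils::packageVersion("netresil"))
  )
}

#' Study design 1: density by multiplier perturbation sweeps, exact mode
#'
#' For each density, builds a 9-node network (fully connected at density 1;
#' a seeded random structure otherwise), applies every multiplier to
#' thresholds, edges, and both, and computes ESA and SAS by exact
#' enumeration. Exact-mode results do not depend on the seed except through
#' the random edge placement at densities below 1.
#'
#' @param densities Densities to run (default `c(1, 0.5, 0.3)`).
#' @param grid Multiplier grid (default [multiplier_grid()]).
#' @param n Node count (default 9).
#' @param tau,w Baseline threshold and edge weight (defaults -2, 0.5).
#' @param seed Integer seed for the random structures (density < 1).
#' @return A tibble of class `resilience_sweep`: one row per
#'   density x multiplier x target, plus run metadata columns
#'   (`config_hash`, `seed`, `version`).
#' @examples
#' res <- run_study1(densities = 1, grid = c(0.5, 1, 2))
#' @export
run_study1 <- function(densities = c(1, 0.5, 0.3), grid = multiplier_grid(),
                       n = 9, tau = -2, w = 0.5, seed = 1) {
  cfg <- list(study = "study1", densities = densities, grid = grid,
              n = n, tau = tau, w = w)
  meta <- run_metadata(cfg, seed)
  out <- purrr::map(densities, function(d) {
    net <- if (d >= 1) {
      uniform_network(n, tau, w)
    } else {
      random_density_network(n, d, tau, w, seed = seed)
    }
    sweep <- perturbation_sweep(net, grid = grid, mode = "exact")
    dplyr::mutate(sweep, density = d, .before = 1)
  })
  out <- dplyr::bind_rows(out)
  out$seed <- NULL
  out <- dplyr::bind_cols(out, meta[rep(1, nrow(out)), ])
  class(out) <- c("resilience_sweep", class(out))
  out
}

#' Study design 2: centrality-targeted perturbations with chain sampling
#'
#' Computes node-strength centrality of the supplied network, selects the
#' `k` strongest and `k` weakest nodes, and for each condition sweeps the
#' multiplier grid over thresholds, edges, and both — thresholds of the
#' selected nodes, edges incident to them — estimating ESA and SAS from a
#' Gibbs chain per condition.
#'
#' @param net The `ising_network` to analyze (e.g. an [fit_elasso()]
#'   estimate or a synthetic 27-node network).
#' @param k Number of nodes per condition (default 5).
#' @param grid Multiplier grid (default [multiplier_grid()]).
#' @param iterations,burn_in,thin,n_chains Chain settings per condition
#'   (defaults mirror the classic 1,000-iteration single chain).
#' @param within_only If `TRUE`, moderators target only edges internal to
#'   the selected node set instead of all incident edges.
#' @param seed Integer seed.
#' @return A tibble of class `resilience_sweep` with a `condition` column
#'   (`"strong_nodes"` / `"weak_nodes"`), the targeted node set in
#'   `target_nodes`, and run metadata columns.
#' @export
run_study2 <- function(net, k = 5, grid = multiplier_grid(),
                       iterations = 1000, burn_in = 0, thin = 1,
                       n_chains = 1, within_only = FALSE, seed = 1) {
  assert_network(net)
  cfg <- list(study = "study2", k = k, grid = grid, iterations = iterations,
              burn_in = burn_in, thin = thin, n_chains = n_chains,
              within_only = within_only)
  meta <- run_metadata(cfg, seed)
  strength <- node_strength(net)
  conditions <- list(
    strong_nodes = select_extreme_nodes(strength, k, "strongest"),
    weak_nodes = select_extreme_nodes(strength, k, "weakest")
  )
  out <- purrr::imap(conditions, function(nodes, cond) {
    edges <- incident_edges(net, nodes, within = within_only)
    sweep <- perturbation_sweep(
      net, grid = grid, nodes = nodes, edges = as.matrix(edges[, 1:2]),
      mode = "sampled", iterations = iterations, burn_in = burn_in,
      thin = thin, n_chains = n_chains,
      seed = seed + 1000 * match(cond, names(conditions))
    )
    dplyr::mutate(sweep, condition = cond,
                  target_nodes = paste(nodes, collapse = ";"), .before = 1)
  })
  out <- dplyr::bind_rows(out)
  out$seed <- NULL
  out <- dplyr::bind_cols(out, meta[rep(1, nrow(out)), ])
  class(out) <- c("resilience_sweep", class(out))
  out
}

#' Study design 3: conditioning a hybrid network on RP-factor scenarios
#'
#' Evaluates ESA under conditioning scenarios on a hybrid symptom +
#' RP-factor nodewise model. By default the two canonical situations are
#' run: all protective factors present with risk factors absent, and the
#' opposite. SAS is deliberately not computed in this model class — fixing
#' RP factors moves symptom means but not the variance structure, so the
#' sum-score variability no longer measures activity stability.
#'
#' @param model A `hybrid_nodewise_model` (e.g. from
#'   [generate_hybrid_dataset()]).
#' @param scenarios Named list of scenarios (named numeric vectors mapping
#'   RP factors to values); defaults to `protective_present` and
#'   `risk_present` presets.
#' @param method Propagation mode, see [condition_means()].
#' @param seed Seed recorded in the metadata (the computation itself is
#'   deterministic).
#' @return A tibble: one row per scenario (plus a baseline row) with `esa`,
#'   `delta` (change from baseline ESA), `clip_count`, and run metadata.
#' @export
run_study3 <- function(model, scenarios = NULL,
                       method = c("fixed_point", "one_step"), seed = 1) {
  method <- match.arg(method)
  if (is.null(scenarios)) {
    scenarios <- list(
      protective_present = scenario_protective_present(model),
      risk_present = scenario_risk_present(model)
    )
  }
  cfg <- list(study = "study3", scenarios = scenarios, method = method)
  meta <- run_metadata(cfg, seed)
  baseline_esa <- conditioned_esa(model$baseline_means[model$symptoms])
  rows <- purrr::imap(scenarios, function(sc, nm) {
    cm <- condition_means(model, sc, method = method)
    tibble(
      scenario = nm,
      esa = conditioned_esa(cm),
      delta = conditioned_esa(cm) - baseline_esa,
      clip_count = attr(cm, "clip_count")
    )
  })
  out <- dplyr::bind_rows(
    tibble(scenario = "baseline", esa = baseline_esa, delta = 0,
           clip_count = 0L),
    dplyr::bind_rows(rows)
  )
  dplyr::bind_cols(out, meta[rep(1, nrow(out)), ])
}
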