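test_that("the density-by-multiplier design emits the full grid", {
  res <- run_study1()
  expect_equal(nrow(res), 3 * 11 * 3) # densities x constants x targets
  expect_true(all(c("density", "target", "multiplier", "esa", "sas",
                    "config_hash", "seed", "version") %in% names(res)))

  d1 <- dplyr::filter(res, .data$density == 1)
  cell <- function(target, mult) {
    dplyr::filter(d1, .data$target == !!target,
                  abs(.data$multiplier - mult) < 1e-9)
  }
  # the fully specified density-1 column, printed at 2 d.p.
  expect_equal(round(cell("edges", 1)$esa, 2), 4.5)
  expect_equal(round(cell("edges", 1)$sas, 2), 0.34)
  expect_equal(round(cell("edges", 2)$esa, 2), 8.98)
  expect_equal(round(cell("edges", 0.5)$esa, 2), 1.46)
  expect_equal(round(cell("thresholds", 0.5)$esa, 2), 8.40)
  expect_equal(round(cell("thresholds", 2)$sas, 2), 2.26)
  expect_equal(round(cell("both", 2)$sas, 2), 0.23)
  # all density-1 simultaneous rows hold ESA at the symmetric value
  expect_true(all(abs(dplyr::filter(d1, .data$target == "both")$esa - 4.5)
                  < 1e-9))
})

test_that("a singleton grid reproduces the per-density baselines", {
  res <- run_study1(grid = 1, seed = 3)
  expect_equal(nrow(res), 9)
  for (d in unique(res$density)) {
    rows <- dplyr::filter(res, .data$density == d)
    expect_true(all(abs(rows$esa - rows$esa[1]) < 1e-12))
  }
})

test_that("exact-mode density-1 results do not depend on the seed", {
  a <- run_study1(densities = 1, seed = 1)
  b <- run_study1(densities = 1, seed = 99)
  expect_equal(a$esa, b$esa)
  expect_equal(a$sas, b$sas)
})

test_that("centrality-targeted sweeps separate strong from weak conditions", {
  net <- random_density_network(27, 0.25, tau = -1.5, w = 0.5, seed = 90)
  res <- run_study2(net, k = 5, iterations = 60000, burn_in = 5000,
                    seed = 91)
  expect_equal(nrow(res), 2 * 33)
  expect_setequal(unique(res$condition), c("strong_nodes", "weak_nodes"))

  # targeted node sets are the top/bottom of the strength ranking
  st <- node_strength(net)
  strong <- strsplit(res$target_nodes[res$condition == "strong_nodes"][1],
                     ";")[[1]]
  expect_setequal(strong, select_extreme_nodes(st, 5, "strongest"))

  # perturbing stronger nodes moves ESA through a wider range
  width <- function(cond) {
    diff(range(dplyr::filter(res, .data$condition == cond)$esa))
  }
  expect_gt(width("strong_nodes"), width("weak_nodes"))

  # unperturbed rows agree across conditions up to Monte-Carlo error
  # (six single-site chains of 55k kept states on 27 nodes: allow ~3 s.e.)
  base_rows <- dplyr::filter(res, abs(.data$multiplier - 1) < 1e-9)
  expect_lt(diff(range(base_rows$esa)), 0.75)
})

test_that("chain-based sweeps are reproducible under a fixed seed", {
  net <- random_density_network(12, 0.3, tau = -1, w = 0.5, seed = 92)
  a <- run_study2(net, k = 3, grid = c(0.5, 1, 2), iterations = 2000,
                  seed = 7)
  b <- run_study2(net, k = 3, grid = c(0.5, 1, 2), iterations = 2000,
                  seed = 7)
  expect_equal(a$esa, b$esa)
  expect_equal(a$sas, b$sas)
})

test_that("scenario conditioning runs produce signed deltas and metadata", {
  hy <- generate_hybrid_dataset(2000, seed = 93)
  res <- run_study3(hy$model)
  expect_equal(res$scenario,
               c("baseline", "protective_present", "risk_present"))
  expect_equal(res$delta[1], 0)
  expect_lt(res$delta[res$scenario == "protective_present"], 0)
  expect_gt(res$delta[res$scenario == "risk_present"], 0)
  expect_true(all(c("config_hash", "seed", "version") %in% names(res)))

  # deterministic: re-running gives identical output
  res2 <- run_study3(hy$model)
  expect_equal(res$esa, res2$esa)

  # a model with no symptom-RP effects cannot move ESA
  null <- generate_hybrid_dataset(500, effect_size = 0, seed = 94)
  res0 <- run_study3(null$model)
  expect_equal(res0$delta, rep(0, 3), tolerance = 1e-7)
})

test_that("sweep and centrality plots build without evaluation errors", {
  res <- run_study1(densities = 1, grid = c(0.5, 1, 2))
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(nrow(built$data[[1]]), 0)

  pc <- autoplot(node_strength(hub_network()))
  expect_s3_class(pc, "ggplot")
})
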