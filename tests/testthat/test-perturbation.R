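test_that("the multiplier grid is the canonical 11-constant set", {
  g <- multiplier_grid()
  expect_length(g, 11)
  expect_equal(g[6], 1)
  expect_equal(max(g), 2)
  expect_equal(g, sort(g))
  # constants above 1 are exact inverses of the sub-unit half
  expect_equal(g[7:11], 1 / rev(g[1:5]), tolerance = 1e-15)
  expect_equal(round(g, 2), c(0.5, 0.6, 0.7, 0.8, 0.9, 1,
                              1.11, 1.25, 1.43, 1.67, 2))
})

test_that("main effects scale thresholds and leave everything else alone", {
  base <- baseline_network()
  risk <- apply_main_effect(base, 0.5)
  expect_equal(unname(risk$tau), rep(-1, 9))
  expect_equal(risk$W, base$W)

  prot <- apply_main_effect(base, 2)
  expect_equal(unname(prot$tau), rep(-4, 9))

  same <- apply_main_effect(base, 1)
  expect_equal(same$tau, base$tau)
  expect_equal(unname(base$tau), rep(-2, 9)) # input not mutated

  sub <- apply_main_effect(base, 0.5, nodes = c("S1", "S3"))
  expect_equal(unname(sub$tau[c(1, 3)]), c(-1, -1))
  expect_equal(unname(sub$tau[2]), -2)
  expect_error(apply_main_effect(base, 0.5, nodes = "nope"), "Unknown")
  expect_error(apply_main_effect(base, -1), "positive")
})

test_that("moderators scale present edges and keep absent edges absent", {
  base <- baseline_network()
  risk <- apply_moderator(base, 2)
  expect_equal(unname(risk$W[1, 2]), 1.0)
  prot <- apply_moderator(base, 0.5)
  expect_equal(unname(prot$W[1, 2]), 0.25)

  sparse <- random_density_network(6, 0.4, tau = -1, w = 0.5, seed = 9)
  mod <- apply_moderator(sparse, 3)
  expect_equal(mod$W == 0, sparse$W == 0)
  expect_equal(mod$W, sparse$W * 3)

  sub <- apply_moderator(base, 2, edges = cbind("S1", "S2"))
  expect_equal(unname(sub$W[1, 2]), 1.0)
  expect_equal(unname(sub$W[2, 1]), 1.0) # symmetry preserved
  expect_equal(unname(sub$W[1, 3]), 0.5)
  expect_error(apply_moderator(base, 2, edges = cbind("S1", "zz")), "Unknown")
})

test_that("combined perturbation applies one constant to both parameter sets", {
  base <- baseline_network()
  both <- apply_perturbation(base, 0.5, "both")
  expect_equal(unname(both$tau), rep(-1, 9))
  expect_equal(unname(both$W[1, 2]), 0.25)

  both2 <- apply_perturbation(base, 2, "both")
  expect_equal(unname(both2$tau), rep(-4, 9))
  expect_equal(unname(both2$W[1, 2]), 1.0)

  id <- apply_perturbation(base, 1, "both")
  expect_equal(id$tau, base$tau)
  expect_equal(id$W, base$W)
})

test_that("perturbations compose multiplicatively", {
  net <- random_network(5, seed = 4)
  for (target in c("thresholds", "edges", "both")) {
    a <- apply_perturbation(apply_perturbation(net, 1.25, target), 0.6, target)
    b <- apply_perturbation(net, 0.75, target)
    expect_equal(a$tau, b$tau, tolerance = 1e-12)
    expect_equal(a$W, b$W, tolerance = 1e-12)
  }
})

test_that("factor type labels follow the sign conventions", {
  base <- baseline_network()
  expect_equal(rp_factor_type(base, "thresholds", 0.5), "risk")
  expect_equal(rp_factor_type(base, "thresholds", 2), "protective")
  expect_equal(rp_factor_type(base, "edges", 2), "risk")
  expect_equal(rp_factor_type(base, "edges", 0.5), "protective")
  expect_equal(rp_factor_type(base, "edges", 1), "baseline")
  expect_equal(rp_factor_type(base, "both", 2), "both")
})

test_that("exact sweeps cover the grid and reproduce reference cells", {
  base <- baseline_network()
  sweep <- perturbation_sweep(base)
  expect_equal(nrow(sweep), 33)
  expect_equal(sort(unique(sweep$target)), c("both", "edges", "thresholds"))

  cell <- function(target, mult) {
    dplyr::filter(sweep, .data$target == !!target,
                  abs(.data$multiplier - mult) < 1e-9)
  }
  expect_equal(round(cell("edges", 2)$esa, 2), 8.98)
  expect_equal(round(cell("edges", 2)$sas, 2), 6.47)
  expect_equal(round(cell("thresholds", 2)$esa, 2), 0.18)
  expect_equal(round(cell("both", 0.5)$sas, 2), 0.49)

  single <- perturbation_sweep(base, grid = 1, targets = "both")
  expect_equal(nrow(single), 1)
  expect_equal(single$esa, 4.5, tolerance = 1e-9)
})

test_that("ESA is monotone along sweep directions for the uniform family", {
  base <- baseline_network()
  sweep <- perturbation_sweep(base)
  th <- dplyr::arrange(
    dplyr::filter(sweep, .data$target == "thresholds"), .data$multiplier
  )
  # negative thresholds: larger constant = more negative tau = lower ESA
  expect_true(all(diff(th$esa) <= 1e-9))
  ed <- dplyr::arrange(
    dplyr::filter(sweep, .data$target == "edges"), .data$multiplier
  )
  expect_true(all(diff(ed$esa) >= -1e-9))
})

test_that("simultaneous sweeps pin ESA at n/2 on the symmetric baseline", {
  sweep <- perturbation_sweep(baseline_network(), targets = "both")
  expect_true(all(abs(sweep$esa - 4.5) < 1e-9))
  expect_gt(diff(range(sweep$sas)), 0.1) # SAS still varies
})
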