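test_that("exact Ising sampling is seed-deterministic and on-target", {
  net <- symptomlike_network(5, seed = 71)
  a <- sample_ising_exact(net, 200, seed = 72)
  b <- sample_ising_exact(net, 200, seed = 72)
  expect_identical(a, b)
  expect_false(identical(a, sample_ising_exact(net, 200, seed = 73)))

  single <- make_network(0, matrix(0, 1, 1))
  draws <- sample_ising_exact(single, 100000, seed = 74)
  se <- sqrt(0.25 / 100000)
  expect_lt(abs(mean(draws[[1]]) - 0.5), 3 * se)
})

test_that("exact samples reproduce the sum-score law of the baseline", {
  base <- baseline_network()
  dat <- sample_ising_exact(base, 50000, seed = 75)
  y <- rowSums(dat)
  ssd <- sumscore_distribution(base)
  sigma <- 1 / sas_exact(ssd)
  se <- sigma / sqrt(50000)
  expect_lt(abs(mean(y) - 4.5), 3 * se)
})

test_that("empirical sum-score distribution converges in total variation", {
  net <- symptomlike_network(5, seed = 76)
  dat <- sample_ising_exact(net, 100000, seed = 77)
  emp <- tabulate(rowSums(dat) + 1L, nbins = 6) / nrow(dat)
  expect_lt(0.5 * sum(abs(emp - sumscore_distribution(net)$prob)), 0.01)
})

test_that("ordinal generator respects levels and prevalence band", {
  dat <- generate_ordinal_scl(3000, n_items = 12, seed = 81)
  expect_true(all(unlist(dat) %in% 0:4))
  expect_identical(generate_ordinal_scl(50, 4, seed = 1),
                   generate_ordinal_scl(50, 4, seed = 1))

  bin <- binarize(dat)
  prev <- colMeans(bin)
  # marginal prevalence of the binarized items stays inside the band
  # (allow 3 binomial standard errors around the band edges)
  slack <- 3 * sqrt(0.4 * 0.6 / 3000)
  expect_true(all(prev > 0.05 - slack & prev < 0.40 + slack))
})

test_that("stronger latent correlation increases inter-item association", {
  mean_phi <- function(rho) {
    dat <- binarize(generate_ordinal_scl(4000, 8, latent_cor = rho,
                                         seed = 82))
    cm <- stats::cor(as.matrix(dat))
    mean(cm[upper.tri(cm)])
  }
  phis <- vapply(c(0.05, 0.3, 0.6), mean_phi, numeric(1))
  expect_true(all(diff(phis) > 0))
})

test_that("hybrid generator returns consistent data and a valid true model", {
  hy <- generate_hybrid_dataset(800, seed = 83)
  expect_named(hy, c("data", "model"))
  m <- hy$model
  expect_s3_class(m, "hybrid_nodewise_model")
  expect_equal(ncol(hy$data), length(m$labels))
  expect_true(all(diag(m$coefficients) == 0))
  lo <- m$ranges[, "min"]; hi <- m$ranges[, "max"]
  expect_true(all(m$baseline_means >= lo & m$baseline_means <= hi))
  expect_identical(generate_hybrid_dataset(100, seed = 9)$data,
                   generate_hybrid_dataset(100, seed = 9)$data)
})

test_that("planted effects leave the advertised correlation footprint", {
  # no planted symptom-RP effects: correlations center on zero
  null <- generate_hybrid_dataset(3000, effect_size = 0, seed = 84)
  cors <- stats::cor(as.matrix(null$data))[null$model$symptoms,
                                           null$model$rp_factors]
  expect_lt(max(abs(cors)), 0.08)

  # a planted protective edge shows up as a negative empirical correlation
  hy <- generate_hybrid_dataset(2000, seed = 85)
  edges <- tidy(hy$model)
  prot <- edges[edges$predictor %in%
                  names(hy$model$rp_type)[hy$model$rp_type == "protective"], ]
  prot <- prot[prot$outcome %in% hy$model$symptoms, ][1, ]
  emp <- stats::cor(hy$data[[prot$outcome]], hy$data[[prot$predictor]])
  expect_lt(emp, 0)
})

test_that("generation and estimation round-trip recovers edge signs", {
  truth <- uniform_network(5, -1, 0.8)
  dat <- sample_ising_exact(truth, 3000, seed = 86)
  fit <- fit_elasso(dat)
  est <- tidy(fit)
  expect_gt(nrow(est), 0)
  expect_true(all(est$weight > 0))
})
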