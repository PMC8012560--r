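test_that("hybrid model construction enforces its invariants", {
  m <- toy_hybrid_model()
  expect_s3_class(m, "hybrid_nodewise_model")

  bad_coef <- matrix(c(0.1, 0, 0, 0), 2, 2)
  expect_error(
    hybrid_model(c(s1 = 0, f1 = 0), bad_coef, "s1", "f1",
                 c(f1 = "risk"),
                 data.frame(min = c(0, 0), max = c(4, 4),
                            row.names = c("s1", "f1")),
                 c(s1 = 1, f1 = 1)),
    "Self-coefficients"
  )
  expect_error(
    hybrid_model(c(s1 = 0, f1 = 0), matrix(0, 2, 2), "s1", "f1",
                 c(f1 = "risk"),
                 data.frame(min = c(0, 0), max = c(4, 4),
                            row.names = c("s1", "f1")),
                 c(s1 = 9, f1 = 1)),
    "outside scale range"
  )
})

test_that("symptoms unlinked to RP factors keep their baseline means", {
  hy <- generate_hybrid_dataset(500, effect_size = 0, seed = 61)
  cm <- condition_means(hy$model, scenario_protective_present(hy$model))
  sym <- cm[cm$role == "symptom", ]
  expect_equal(sym$conditioned, sym$baseline, tolerance = 1e-8)
  expect_equal(esa_delta(hy$model, scenario_risk_present(hy$model)), 0,
               tolerance = 1e-8)
})

test_that("a single direct effect moves the symptom mean linearly", {
  m <- toy_hybrid_model(coef_sf = -0.5, f_base = 2, s_base = 1.5)
  cm <- condition_means(m, c(f1 = 3)) # raise the factor by 1
  expect_equal(cm$conditioned[cm$node == "s1"], 1.0, tolerance = 1e-10)
  one <- condition_means(m, c(f1 = 3), method = "one_step")
  expect_equal(one$conditioned[one$node == "s1"], 1.0, tolerance = 1e-10)
})

test_that("fixed-point conditioning solves the implied linear system", {
  labels <- c("s1", "s2", "f1")
  A <- matrix(0, 3, 3, dimnames = list(labels, labels))
  A["s1", "s2"] <- 0.3; A["s2", "s1"] <- 0.3
  A["s1", "f1"] <- -0.4; A["s2", "f1"] <- 0.2
  b <- c(s1 = 2, s2 = 1, f1 = 0)
  # baseline symptom means solve the nodewise system at the factor baseline,
  # as they would for a regression fit through the means
  s_base <- solve(diag(2) - A[1:2, 1:2], b[1:2] + A[1:2, "f1"] * 1)
  m <- hybrid_model(
    intercepts = b, coefficients = A,
    symptoms = c("s1", "s2"), rp_factors = "f1",
    rp_type = c(f1 = "protective"),
    ranges = data.frame(min = rep(-10, 3), max = rep(10, 3),
                        row.names = labels),
    baseline_means = c(s1 = unname(s_base[1]), s2 = unname(s_base[2]),
                       f1 = 1)
  )
  cm <- condition_means(m, c(f1 = 3), tol = 1e-12)
  closed <- solve(diag(2) - A[1:2, 1:2], b[1:2] + A[1:2, "f1"] * 3)
  expect_equal(cm$conditioned[1:2], unname(closed), tolerance = 1e-10)
  expect_equal(attr(cm, "clip_count"), 0L)
})

test_that("ESA of conditioned means is the symptom-mean sum with its bounds", {
  expect_equal(conditioned_esa(rep(4, 27)), 108)
  expect_equal(conditioned_esa(rep(0, 27)), 0)

  hy <- generate_hybrid_dataset(4000, seed = 62)
  baseline <- conditioned_esa(hy$model$baseline_means[hy$model$symptoms])
  expect_equal(baseline, sum(colMeans(hy$data[, hy$model$symptoms])),
               tolerance = 1e-10)
})

test_that("empty scenarios leave ESA unchanged; planted signs force deltas", {
  hy <- generate_hybrid_dataset(2000, seed = 63)
  expect_equal(esa_delta(hy$model, list()), 0, tolerance = 1e-7)
  expect_lt(esa_delta(hy$model, scenario_protective_present(hy$model)), 0)
  expect_gt(esa_delta(hy$model, scenario_risk_present(hy$model)), 0)
})

test_that("delta is exactly linear when symptoms are uncoupled", {
  hy <- generate_hybrid_dataset(1000, symptom_coupling = 0, seed = 64)
  m <- hy$model
  sc <- scenario_risk_present(m)
  displacement <- sc - m$baseline_means[m$rp_factors]
  closed <- sum(m$coefficients[m$symptoms, m$rp_factors] %*% displacement)
  expect_equal(esa_delta(m, sc, tol = 1e-12), closed, tolerance = 1e-8)
})

test_that("factors with no path to a symptom cannot move it", {
  labels <- c("s1", "s2", "f1")
  A <- matrix(0, 3, 3, dimnames = list(labels, labels))
  A["s1", "s2"] <- 0.3; A["s2", "s1"] <- 0.3 # f1 disconnected
  m <- hybrid_model(
    intercepts = c(s1 = 1, s2 = 1, f1 = 0), coefficients = A,
    symptoms = c("s1", "s2"), rp_factors = "f1",
    rp_type = c(f1 = "risk"),
    ranges = data.frame(min = rep(-10, 3), max = rep(10, 3),
                        row.names = labels),
    baseline_means = c(s1 = 1 / 0.7, s2 = 1 / 0.7, f1 = 1)
  )
  cm <- condition_means(m, c(f1 = 5), tol = 1e-12)
  expect_equal(cm$conditioned[1:2], cm$baseline[1:2], tolerance = 1e-9)
})

test_that("scenario validation catches unknown factors and off-scale values", {
  m <- toy_hybrid_model()
  expect_error(condition_means(m, c(nope = 1)), "unknown")
  expect_error(condition_means(m, c(f1 = 99)), "outside scale range")
})

test_that("hybrid models serialize to JSON and back", {
  hy <- generate_hybrid_dataset(300, seed = 65)
  jp <- withr::local_tempfile(fileext = ".json")
  write_hybrid_model_json(hy$model, jp)
  back <- read_hybrid_model_json(jp)
  expect_equal(back$coefficients, hy$model$coefficients)
  expect_equal(back$baseline_means, hy$model$baseline_means)
  expect_equal(back$rp_type, hy$model$rp_type)
})
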