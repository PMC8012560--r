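# Shared fixtures: all built in code, nothing stored on disk.

# The canonical nine-symptom network: fully connected, tau = -2, w = 0.5.
baseline_network <- function() uniform_network(9, tau = -2, w = 0.5)

# A dense random network with parameters across the full supported ranges.
random_network <- function(n, seed, tau_range = c(-4, 4), w_range = c(-2, 2)) {
  withr::with_seed(seed, {
    tau <- runif(n, tau_range[1], tau_range[2])
    W <- matrix(0, n, n)
    W[upper.tri(W)] <- runif(n * (n - 1) / 2, w_range[1], w_range[2])
    W <- W + t(W)
    make_network(tau, W)
  })
}

# Symptom-network-like random parameters: mostly negative thresholds,
# mostly positive moderate couplings.
symptomlike_network <- function(n, seed) {
  random_network(n, seed, tau_range = c(-1.5, 0.5), w_range = c(-0.5, 1))
}

# Closed-form sum-score law of an exchangeable fully connected network:
# P(Y = k) proportional to choose(n, k) * exp(tau k + w k (k - 1) / 2).
uniform_sumscore_closed_form <- function(n, tau, w) {
  k <- 0:n
  logp <- lchoose(n, k) + tau * k + w * k * (k - 1) / 2
  p <- exp(logp - max(logp))
  p / sum(p)
}

# Monte-Carlo standard error of a chain mean by non-overlapping batch means
# (accounts for autocorrelation).
batch_se <- function(y, n_batches = 50) {
  n <- length(y)
  b <- floor(n / n_batches)
  means <- vapply(
    seq_len(n_batches),
    function(k) mean(y[((k - 1) * b + 1):(k * b)]),
    numeric(1)
  )
  stats::sd(means) / sqrt(n_batches)
}

# A hub-and-spokes fixture: node H carries 5 strong edges, the remaining
# sparse nodes share one weak edge.
hub_network <- function() {
  labels <- c("H", paste0("P", 1:6))
  W <- matrix(0, 7, 7, dimnames = list(labels, labels))
  for (k in 2:6) {
    W["H", labels[k]] <- 1
    W[labels[k], "H"] <- 1
  }
  W["P5", "P6"] <- 0.1
  W["P6", "P5"] <- 0.1
  make_network(rep(-1, 7), W, labels = labels)
}

# Minimal hybrid model: one symptom driven by one protective factor with
# coefficient -0.5, baseline factor mean 2 on a 0-4 scale, baseline symptom
# mean 1.5.
toy_hybrid_model <- function(coef_sf = -0.5, f_base = 2, s_base = 1.5) {
  labels <- c("s1", "f1")
  coefs <- matrix(0, 2, 2, dimnames = list(labels, labels))
  coefs["s1", "f1"] <- coef_sf
  hybrid_model(
    intercepts = c(s1 = s_base - coef_sf * f_base, f1 = 0),
    coefficients = coefs,
    symptoms = "s1", rp_factors = "f1",
    rp_type = c(f1 = "protective"),
    ranges = data.frame(min = c(0, 0), max = c(9, 4),
                        row.names = labels),
    baseline_means = c(s1 = s_base, f1 = f_base)
  )
}
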