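#' Expected Symptom Activity from an exact sum-score distribution
#'
#' ESA is the expected sum score, `mu = sum_i i * P(Y = i)`: the number of
#' symptoms the network is expected to have active under its stationary law.
#' Low ESA indicates a healthy state.
#'
#' @param ssd A `sumscore_distribution` (see [sumscore_distribution()]), or
#'   an `ising_network` (enumerated on the fly).
#' @return ESA as a single number in `[0, n]`.
#' @examples
#' esa_exact(uniform_network(9, -2, 0.5)) # 4.5
#' @export
esa_exact <- function(ssd) {
  ssd <- as_sumscore(ssd)
  sum(ssd$sum_score * ssd$prob)
}

#' Symptom Activity Stability from an exact sum-score distribution
#'
#' SAS is the inverse standard deviation of the sum score,
#' `1 / sigma` with `sigma = sqrt(sum_i (i - mu)^2 P(Y = i))`. A standard
#' deviation of 1 is the reference point: SAS > 1 means activity is more
#' stable than that reference, SAS < 1 less stable. High SAS together with
#' low ESA characterizes a resilient network.
#'
#' @inheritParams esa_exact
#' @return SAS as a single positive number, or `NA` with a warning of class
#'   `netresil_degenerate` when the distribution is a point mass
#'   (`sigma = 0`), for which stability is not defined by this metric.
#' @export
sas_exact <- function(ssd) {
  ssd <- as_sumscore(ssd)
  mu <- sum(ssd$sum_score * ssd$prob)
  sigma <- sqrt(sum((ssd$sum_score - mu)^2 * ssd$prob))
  if (sigma < 1e-12) {
    warn("Degenerate sum-score distribution: sigma = 0, SAS undefined.",
         class = "netresil_degenerate")
    return(NA_real_)
  }
  1 / sigma
}

as_sumscore <- function(x) {
  if (is_ising_network(x) || inherits(x, "state_distribution")) {
    x <- sumscore_distribution(x)
  }
  if (!inherits(x, "sumscore_distribution")) {
    abort("Expected a `sumscore_distribution`, `state_distribution`, or `ising_network`.")
  }
  x
}

check_sample_matrix <- function(samples, min_rows = 1) {
  samples <- as.matrix(samples)
  if (nrow(samples) < min_rows) {
    abort(sprintf("Need at least %d sampled state(s).", min_rows))
  }
  if (!all(samples %in% c(0, 1))) {
    abort("Sampled states must be binary (0/1).")
  }
  samples
}

#' ESA from sampled or observed binary states
#'
#' The sampled counterpart of [esa_exact()]: the mean of the per-state sum
#' scores (row sums) of a chain or dataset.
#'
#' @param samples Binary matrix or data frame, one row per sampled state,
#'   one column per node.
#' @return Mean sum score.
#' @export
esa_from_samples <- function(samples) {
  samples <- check_sample_matrix(samples, min_rows = 1)
  mean(rowSums(samples))
}

#' SAS from sampled or observed binary states
#'
#' The inverse standard deviation of the per-state sum scores. The default
#' denominator is the population one (divide by N), mirroring the exact
#' definition of SAS as the inverse of a distribution's sigma.
#'
#' @inheritParams esa_from_samples
#' @param denominator `"population"` (divide by N, default) or `"sample"`
#'   (divide by N - 1).
#' @return Inverse standard deviation of the row sums, or `NA` with a
#'   `netresil_degenerate` warning when all row sums are identical.
#' @export
sas_from_samples <- function(samples, denominator = c("population", "sample")) {
  denominator <- match.arg(denominator)
  samples <- check_sample_matrix(samples, min_rows = 2)
  y <- rowSums(samples)
  n <- length(y)
  sigma2 <- sum((y - mean(y))^2) /
    (if (denominator == "population") n else n - 1)
  sigma <- sqrt(sigma2)
  if (sigma < 1e-12) {
    warn("Degenerate chain: constant sum score, SAS undefined.",
         class = "netresil_degenerate")
    return(NA_real_)
  }
  1 / sigma
}

#' Shannon entropy of a state distribution
#'
#' `-sum(p * log(p))` in nats, with `0 * log(0) = 0`. High entropy means many
#' states are nearly equally likely (unstable dynamics); low entropy means
#' the system concentrates on few states. SAS tracks the same notion of
#' stability through the sum-score margin.
#'
#' @param dist A `state_distribution` or `ising_network`.
#' @return Entropy in nats.
#' @export
distribution_entropy <- function(dist) {
  if (is_ising_network(dist)) dist <- joint_distribution(dist)
  if (!inherits(dist, "state_distribution")) {
    abort("Expected a `state_distribution` or `ising_network`.")
  }
  p <- dist$probs[dist$probs > 0]
  -sum(p * log(p))
}

#' Exact resilience report for a network
#'
#' Computes ESA and SAS by full enumeration and returns them in the one-row
#' tidy form used throughout sweep outputs.
#'
#' @param net An enumerable `ising_network`.
#' @return A one-row tibble: `esa`, `sas`, `degenerate`, `source`
#'   (`"exact"`), `n_samples` (`NA`).
#' @export
network_resilience <- function(net) {
  ssd <- sumscore_distribution(net)
  esa <- esa_exact(ssd)
  sas <- withCallingHandlers(
    sas_exact(ssd),
    netresil_degenerate = function(w) invokeRestart("muffleWarning")
  )
  tibble(
    esa = esa, sas = sas, degenerate = is.na(sas),
    source = "exact", n_samples = NA_integer_
  )
}
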