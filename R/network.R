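#' Construct an Ising symptom network
#'
#' An Ising network is parameterized by a per-node threshold vector `tau`
#' (a node's autonomous disposition toward activation; for symptoms usually
#' negative, i.e. hard to activate) and a symmetric edge-weight matrix `W`
#' with zero diagonal (pairwise interactions). Node states live either on the
#' `{0, 1}` domain (`"01"`, the default: 0 = symptom absent, 1 = present) or
#' on the spin domain `{-1, 1}` (`"pm1"`).
#'
#' @param tau Numeric vector of thresholds, one per node.
#' @param W Square symmetric numeric matrix of edge weights, zero diagonal.
#' @param labels Optional character vector of node labels; defaults to
#'   `S1..Sn`.
#' @param domain State coding, `"01"` (default) or `"pm1"`.
#' @param tol Tolerance for the symmetry / zero-diagonal checks.
#' @return An object of class `ising_network`.
#' @examples
#' net <- make_network(rep(-2, 9), matrix(0.5, 9, 9) - diag(0.5, 9))
#' net
#' @export
make_network <- function(tau, W, labels = NULL, domain = c("01", "pm1"),
                         tol = 1e-12) {
  domain <- match.arg(domain)
  tau <- as.numeric(tau)
  W <- as.matrix(W)
  if (!is.numeric(W)) abort("`W` must be a numeric matrix.")
  n <- length(tau)
  if (nrow(W) != ncol(W)) {
    abort(sprintf("`W` must be square; got %d x %d.", nrow(W), ncol(W)))
  }
  if (nrow(W) != n) {
    abort(sprintf(
      "Dimension mismatch: length(tau) = %d but W is %d x %d.",
      n, nrow(W), ncol(W)
    ))
  }
  asym <- which(abs(W - t(W)) > tol, arr.ind = TRUE)
  if (nrow(asym) > 0) {
    i <- asym[1, 1]; j <- asym[1, 2]
    abort(sprintf(
      "`W` is not symmetric: W[%d,%d] = %.6g but W[%d,%d] = %.6g.",
      i, j, W[i, j], j, i, W[j, i]
    ))
  }
  bad_diag <- which(abs(diag(W)) > tol)
  if (length(bad_diag) > 0) {
    abort(sprintf(
      "`W` must have a zero diagonal: W[%d,%d] = %.6g.",
      bad_diag[1], bad_diag[1], W[bad_diag[1], bad_diag[1]]
    ))
  }
  if (is.null(labels)) labels <- paste0("S", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) {
    abort(sprintf(
      "%d labels supplied for %d nodes.", length(labels), n
    ))
  }
  if (anyDuplicated(labels)) abort("Node labels must be unique.")
  W <- (W + t(W)) / 2 # remove sub-tolerance asymmetry
  diag(W) <- 0
  dimnames(W) <- list(labels, labels)
  names(tau) <- labels
  structure(
    list(labels = labels, tau = tau, W = W, domain = domain),
    class = "ising_network"
  )
}

#' @export
print.ising_network <- function(x, ...) {
  n <- length(x$labels)
  ne <- n_edges(x)
  cat(sprintf(
    "<ising_network> %d nodes, %d edges, domain {%s}\n",
    n, ne, if (x$domain == "01") "0,1" else "-1,1"
  ))
  cat("  tau: ", paste(format(head(x$tau, 6), digits = 3), collapse = " "),
      if (n > 6) "..." else "", "\n", sep = "")
  invisible(x)
}

n_nodes <- function(net) length(net$labels)

n_edges <- function(net) {
  sum(net$W[upper.tri(net$W)] != 0)
}

domain_values <- function(net) {
  if (net$domain == "01") c(0, 1) else c(-1, 1)
}

is_ising_network <- function(x) inherits(x, "ising_network")

assert_network <- function(net) {
  if (!is_ising_network(net)) abort("Expected an `ising_network` object.")
  invisible(net)
}

match_labels <- function(net, labels) {
  idx <- match(labels, net$labels)
  if (anyNA(idx)) {
    abort(sprintf(
      "Unknown node label(s): %s.",
      paste(labels[is.na(idx)], collapse = ", ")
    ))
  }
  idx
}

#' Tidy the edge list of an Ising network
#'
#' @param x An `ising_network`.
#' @param ... Unused.
#' @return A tibble with one row per unordered node pair with nonzero weight:
#'   columns `from`, `to`, `weight`.
#' @export
tidy.ising_network <- function(x, ...) {
  ut <- which(upper.tri(x$W) & x$W != 0, arr.ind = TRUE)
  tibble(
    from = x$labels[ut[, 1]],
    to = x$labels[ut[, 2]],
    weight = x$W[ut]
  )
}

#' One-line summary of an Ising network
#'
#' @param x An `ising_network`.
#' @param ... Unused.
#' @return A one-row tibble: node count, edge count, density, mean threshold,
#'   mean absolute edge weight, domain.
#' @export
glance.ising_network <- function(x, ...) {
  n <- n_nodes(x)
  tibble(
    n_nodes = n,
    n_edges = n_edges(x),
    density = if (n >= 2) network_density(x) else NA_real_,
    mean_threshold = mean(x$tau),
    mean_abs_weight = if (n_edges(x) > 0) {
      mean(abs(x$W[upper.tri(x$W) & x$W != 0]))
    } else 0,
    domain = x$domain
  )
}

#' Convert an Ising network between the {0,1} and {-1,1} codings
#'
#' Reparameterizes the network so that the joint law is preserved: the
#' probability of each `{0,1}` configuration equals the probability of its
#' spin image under `x = (s + 1) / 2`. The transform is an involution up to
#' floating point.
#'
#' @param net An `ising_network`.
#' @param target Target domain tag, `"01"` or `"pm1"`; must differ from the
#'   network's current domain.
#' @return The reparameterized `ising_network`.
#' @export
convert_domain <- function(net, target = c("pm1", "01")) {
  assert_network(net)
  target <- match.arg(target)
  if (identical(net$domain, target)) {
    abort("`target` domain equals the network's current domain.")
  }
  W <- net$W
  tau <- net$tau
  if (target == "pm1") {
    # x = (s+1)/2: tau.x*x + sum_{i<j} W.x*x_i*x_j collapses to
    # a_i = tau_i/2 + sum_j W_ij/4, B = W/4 (constant absorbed by Z)
    B <- W / 4
    a <- tau / 2 + rowSums(W) / 4
    make_network(a, B, labels = net$labels, domain = "pm1")
  } else {
    W01 <- 4 * W
    tau01 <- 2 * tau - 2 * rowSums(W)
    make_network(tau01, W01, labels = net$labels, domain = "01")
  }
}
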