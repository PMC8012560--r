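#' Read and write Ising networks as JSON
#'
#' The JSON schema stores `labels`, `tau`, the dense weight matrix `W`
#' (row-major list of rows), and the `domain` tag.
#'
#' @param net An `ising_network`.
#' @param path File path.
#' @return `write_network_json()` returns `net` invisibly;
#'   `read_network_json()` returns the `ising_network`.
#' @export
write_network_json <- function(net, path) {
  assert_network(net)
  obj <- list(
    labels = net$labels,
    tau = unname(net$tau),
    W = unname(apply(net$W, 1, as.numeric, simplify = FALSE)),
    domain = net$domain
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(net)
}

#' @rdname write_network_json
#' @export
read_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  W <- if (is.list(obj$W)) do.call(rbind, obj$W) else as.matrix(obj$W)
  make_network(obj$tau, W, labels = obj$labels,
               domain = if (is.null(obj$domain)) "01" else obj$domain)
}

#' Read and write Ising networks as node/edge CSV tables
#'
#' Two files: a node table (`label`, `threshold`) whose row order fixes the
#' node order, and an undirected edge table (`source`, `target`, `weight`),
#' one row per unordered pair, nodes referenced by label.
#'
#' @param net An `ising_network`.
#' @param node_path,edge_path File paths for the two tables.
#' @return `write_network_csv()` returns `net` invisibly;
#'   `read_network_csv()` returns the `ising_network`.
#' @export
write_network_csv <- function(net, node_path, edge_path) {
  assert_network(net)
  utils::write.csv(
    data.frame(label = net$labels, threshold = unname(net$tau)),
    node_path, row.names = FALSE
  )
  edges <- tidy.ising_network(net)
  utils::write.csv(
    data.frame(source = edges$from, target = edges$to,
               weight = edges$weight),
    edge_path, row.names = FALSE
  )
  invisible(net)
}

#' @rdname write_network_csv
#' @export
read_network_csv <- function(node_path, edge_path) {
  nodes <- utils::read.csv(node_path, stringsAsFactors = FALSE)
  edges <- utils::read.csv(edge_path, stringsAsFactors = FALSE)
  n <- nrow(nodes)
  W <- matrix(0, n, n, dimnames = list(nodes$label, nodes$label))
  if (nrow(edges) > 0) {
    i <- match(edges$source, nodes$label)
    j <- match(edges$target, nodes$label)
    if (anyNA(i) || anyNA(j)) abort("Edge table references unknown labels.")
    W[cbind(i, j)] <- edges$weight
    W[cbind(j, i)] <- edges$weight
  }
  make_network(nodes$threshold, W, labels = nodes$label)
}

#' Write a sampled chain to CSV with a JSON sidecar
#'
#' One row per kept iteration, columns named by node label; the sidecar
#' (`<path>.json`) records seed, burn-in, thinning, and update mode.
#'
#' @param samples A `sample_matrix` from [sample_chain()].
#' @param path CSV path.
#' @return `samples`, invisibly.
#' @export
write_sample_matrix <- function(samples, path) {
  utils::write.csv(as.data.frame(unclass(samples)[, , drop = FALSE]),
                   path, row.names = FALSE)
  side <- list(
    seed = attr(samples, "seed"),
    burn_in = attr(samples, "burn_in"),
    thin = attr(samples, "thin"),
    update = attr(samples, "update"),
    n_kept = nrow(samples)
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(samples)
}

#' Serialize a hybrid nodewise model to JSON
#'
#' @param model A `hybrid_nodewise_model`.
#' @param path File path.
#' @return `write_hybrid_model_json()` returns `model` invisibly;
#'   `read_hybrid_model_json()` returns the model.
#' @export
write_hybrid_model_json <- function(model, path) {
  obj <- list(
    symptoms = model$symptoms,
    rp_factors = model$rp_factors,
    rp_type = as.list(model$rp_type),
    intercepts = unname(model$intercepts),
    coefficients = unname(apply(model$coefficients, 1, as.numeric,
                                simplify = FALSE)),
    range_min = unname(model$ranges[, "min"]),
    range_max = unname(model$ranges[, "max"]),
    baseline_means = unname(model$baseline_means)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(model)
}

#' @rdname write_hybrid_model_json
#' @export
read_hybrid_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  labels <- c(obj$symptoms, obj$rp_factors)
  coefficients <- if (is.list(obj$coefficients)) {
    do.call(rbind, obj$coefficients)
  } else {
    as.matrix(obj$coefficients)
  }
  dimnames(coefficients) <- list(labels, labels)
  hybrid_model(
    intercepts = stats::setNames(obj$intercepts, labels),
    coefficients = coefficients,
    symptoms = obj$symptoms,
    rp_factors = obj$rp_factors,
    rp_type = unlist(obj$rp_type),
    ranges = data.frame(min = obj$range_min, max = obj$range_max,
                        row.names = labels),
    baseline_means = stats::setNames(obj$baseline_means, labels)
  )
}

#' Read a conditioning scenario from YAML
#'
#' The YAML maps RP-factor labels to fixed values; unlisted factors stay at
#' their baseline means.
#'
#' @param path YAML file path.
#' @return A named numeric vector usable as a `scenario`.
#' @export
read_scenario_yaml <- function(path) {
  sc <- yaml::read_yaml(path)
  unlist(sc)
}
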