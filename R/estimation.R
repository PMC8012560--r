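#' Binarize ordinal item responses
#'
#' Recodes 5-level ordinal items (levels 0..4 by default) to binary symptom
#' indicators: levels below the cut point indicate no or modest presence and
#' become 0, levels at or above it indicate moderate or high presence and
#' become 1. The default cut of 3 gives the rule {0,1,2} -> 0, {3,4} -> 1.
#'
#' @param data Data frame or matrix of ordinal responses, persons as rows,
#'   items as columns.
#' @param cut Smallest level recoded to 1 (default 3).
#' @param levels Admissible input levels (default `0:4`); out-of-range
#'   entries raise an error naming the offending person and item.
#' @return A tibble of 0/1 indicators with the input's column names. Items
#'   that are constant after recoding are listed in the `constant_items`
#'   attribute and flagged with a warning.
#' @examples
#' binarize(data.frame(item = c(0, 1, 2, 3, 4)))
#' @export
binarize <- function(data, cut = 3, levels = 0:4) {
  m <- as.matrix(data)
  if (is.null(colnames(m))) colnames(m) <- paste0("I", seq_len(ncol(m)))
  bad <- which(!(m %in% levels))
  if (length(bad) > 0) {
    p <- ((bad[1] - 1) %% nrow(m)) + 1
    it <- ((bad[1] - 1) %/% nrow(m)) + 1
    abort(sprintf(
      "Out-of-range response %s for person %d, item \"%s\".",
      format(m[bad[1]]), p, colnames(m)[it]
    ))
  }
  b <- (m >= cut) * 1L
  const <- colnames(b)[apply(b, 2, function(x) length(unique(x)) == 1)]
  out <- as_tibble(as.data.frame(b))
  attr(out, "constant_items") <- const
  if (length(const) > 0) {
    warn(sprintf(
      "Item(s) constant after binarization: %s.",
      paste(const, collapse = ", ")
    ), class = "netresil_constant_items")
  }
  out
}

ebic_binomial <- function(y, x, lambda_idx_fit, gamma, p_total) {
  # not exported; EBIC over a fitted glmnet path
  ll <- lambda_idx_fit$ll
  df <- lambda_idx_fit$df
  n <- length(y)
  -2 * ll + df * log(n) + 2 * gamma * df * log(p_total)
}

#' Estimate an Ising network by nodewise penalized logistic regression
#'
#' The eLasso procedure: each node is regressed on all others with
#' L1-penalized logistic regression over a path of penalty values, the
#' per-node model is chosen by minimum extended BIC
#' (`EBIC = -2 logLik + df log N + 2 gamma df log(p - 1)`), and the nodewise
#' coefficients are symmetrized into an undirected network. Under the
#' default AND rule an edge is present only if both directions retain it;
#' its weight is the mean of the two coefficients. Intercepts become
#' thresholds.
#'
#' @param data Binary dataset (persons x items), e.g. from [binarize()] or
#'   [sample_ising_exact()]. Items constant in the data are dropped with a
#'   warning.
#' @param gamma EBIC hyperparameter (default 0.25).
#' @param rule `"AND"` (default) or `"OR"` symmetrization.
#' @param nlambda Length of the penalty path (default 100), log-spaced from
#'   the smallest penalty that zeroes all coefficients down to
#'   `lambda_min_ratio` times that value.
#' @param lambda_min_ratio Ratio defining the smallest penalty (default 0.001).
#' @param combine How reciprocal coefficients are merged into one undirected
#'   weight: `"mean"` (default) or `"max"` (largest magnitude).
#' @return An object of class `elasso_fit` with elements `network` (the
#'   estimated `ising_network`), `nodewise` (per-node tibble: label,
#'   intercept, chosen lambda, EBIC, df), `gamma`, `rule`, `n_obs`, and
#'   `dropped` (constant items removed before fitting).
#' @examples
#' \donttest{
#' net <- uniform_network(5, -1, 0.6)
#' dat <- sample_ising_exact(net, 2000, seed = 1)
#' fit <- fit_elasso(dat)
#' glance(fit)
#' }
#' @export
fit_elasso <- function(data, gamma = 0.25, rule = c("AND", "OR"),
                       nlambda = 100, lambda_min_ratio = 0.001,
                       combine = c("mean", "max")) {
  rule <- match.arg(rule)
  combine <- match.arg(combine)
  if (gamma < 0) abort("`gamma` must be non-negative.")
  m <- as.matrix(data)
  if (is.null(colnames(m))) colnames(m) <- paste0("I", seq_len(ncol(m)))
  if (!all(m %in% c(0, 1))) abort("`data` must be binary (0/1).")
  keep <- apply(m, 2, function(x) length(unique(x)) > 1)
  dropped <- colnames(m)[!keep]
  if (length(dropped) > 0) {
    warn(sprintf("Dropping constant item(s): %s.",
                 paste(dropped, collapse = ", ")),
         class = "netresil_constant_items")
    m <- m[, keep, drop = FALSE]
  }
  p <- ncol(m)
  if (p < 2) abort("Need at least 2 varying items to estimate a network.")
  n <- nrow(m)
  labels <- colnames(m)

  intercepts <- numeric(p)
  betas <- matrix(0, p, p, dimnames = list(labels, labels))
  node_info <- vector("list", p)
  for (j in seq_len(p)) {
    y <- m[, j]
    x <- m[, -j, drop = FALSE]
    # glmnet requires >= 2 predictor columns; pad a constant zero column
    # (it can never enter the model) for the 2-node case
    padded <- ncol(x) == 1
    if (padded) x <- cbind(x, `..pad` = 0)
    fit <- glmnet::glmnet(
      x, y, family = "binomial",
      nlambda = nlambda, lambda.min.ratio = lambda_min_ratio
    )
    eta <- predict(fit, newx = x)
    pr <- plogis(eta)
    pr <- pmin(pmax(pr, 1e-12), 1 - 1e-12)
    ll <- colSums(y * log(pr) + (1 - y) * log(1 - pr))
    df <- fit$df
    ebic <- -2 * ll + df * log(n) + 2 * gamma * df * log(p - 1)
    best <- which.min(ebic)
    cf <- coef(fit, s = fit$lambda[best])
    intercepts[j] <- cf[1]
    cf_beta <- as.numeric(cf[-1])
    if (padded) cf_beta <- cf_beta[-length(cf_beta)]
    betas[j, -j] <- cf_beta
    node_info[[j]] <- tibble(
      label = labels[j], intercept = cf[1],
      lambda = fit$lambda[best], ebic = ebic[best], df = df[best]
    )
  }

  present <- if (rule == "AND") {
    (betas != 0) & (t(betas) != 0)
  } else {
    (betas != 0) | (t(betas) != 0)
  }
  W <- switch(combine,
    mean = (betas + t(betas)) / 2,
    max = ifelse(abs(betas) >= abs(t(betas)), betas, t(betas))
  )
  W[!present] <- 0
  diag(W) <- 0
  net <- make_network(intercepts, W, labels = labels)
  structure(
    list(
      network = net,
      nodewise = dplyr::bind_rows(node_info),
      gamma = gamma, rule = rule, combine = combine,
      n_obs = n, dropped = dropped
    ),
    class = "elasso_fit"
  )
}

#' @export
print.elasso_fit <- function(x, ...) {
  cat(sprintf(
    "<elasso_fit> %d nodes, %d edges (%s rule, gamma = %.2f, N = %d)\n",
    n_nodes(x$network), n_edges(x$network), x$rule, x$gamma, x$n_obs
  ))
  invisible(x)
}

#' Tidy the estimated edges of an eLasso fit
#'
#' @param x An `elasso_fit`.
#' @param ... Unused.
#' @return A tibble with columns `from`, `to`, `weight`.
#' @export
tidy.elasso_fit <- function(x, ...) tidy.ising_network(x$network)

#' One-row summary of an eLasso fit
#'
#' @param x An `elasso_fit`.
#' @param ... Unused.
#' @return A one-row tibble: nodes, edges, density, EBIC gamma, rule, N.
#' @export
glance.elasso_fit <- function(x, ...) {
  tibble(
    n_nodes = n_nodes(x$network),
    n_edges = n_edges(x$network),
    density = network_density(x$network),
    gamma = x$gamma,
    rule = x$rule,
    n_obs = x$n_obs,
    n_dropped = length(x$dropped)
  )
}
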