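#' Construct a hybrid nodewise-linear model of symptoms and RP factors
#'
#' The model class used for conditioning analyses: every node (symptom or
#' risk/protective factor) has an intercept and linear coefficients on all
#' other nodes, as produced by nodewise-regression estimators of mixed
#' graphical models. Ordinal variables are treated as continuous.
#'
#' @param intercepts Named numeric vector, one per node.
#' @param coefficients Square numeric matrix, `coefficients[i, j]` the effect
#'   of predictor `j` on predicted node `i`; zero diagonal.
#' @param symptoms Character vector of symptom node labels.
#' @param rp_factors Character vector of risk/protective factor labels;
#'   together with `symptoms` this must partition the node set.
#' @param rp_type Named character vector over `rp_factors` with values
#'   `"risk"` or `"protective"`.
#' @param ranges Two-column matrix or data frame (`min`, `max`) with one row
#'   per node, row names = labels: the observed scale range of each node.
#' @param baseline_means Named numeric vector of per-node baseline means,
#'   each inside its scale range.
#' @return An object of class `hybrid_nodewise_model`.
#' @export
hybrid_model <- function(intercepts, coefficients, symptoms, rp_factors,
                         rp_type, ranges, baseline_means) {
  labels <- c(symptoms, rp_factors)
  coefficients <- as.matrix(coefficients)
  if (nrow(coefficients) != ncol(coefficients)) {
    abort("`coefficients` must be square.")
  }
  if (length(labels) != nrow(coefficients)) {
    abort("Label partition does not match the coefficient matrix dimension.")
  }
  if (any(abs(diag(coefficients)) > 0)) {
    abort("Self-coefficients (nonzero diagonal) are not allowed.")
  }
  if (anyDuplicated(labels)) {
    abort("`symptoms` and `rp_factors` must be disjoint and unique.")
  }
  if (is.null(rownames(coefficients))) {
    dimnames(coefficients) <- list(labels, labels)
  } else {
    coefficients <- coefficients[labels, labels]
  }
  intercepts <- intercepts[labels]
  if (anyNA(intercepts)) abort("`intercepts` must cover every node label.")
  ranges <- as.matrix(as.data.frame(ranges)[, c("min", "max")])
  rownames(ranges) <- rownames(as.data.frame(ranges))
  ranges <- ranges[labels, , drop = FALSE]
  if (any(ranges[, "min"] >= ranges[, "max"])) {
    abort("Every scale range needs min < max.")
  }
  baseline_means <- baseline_means[labels]
  if (anyNA(baseline_means)) abort("`baseline_means` must cover every node.")
  out_of_range <- labels[baseline_means < ranges[, "min"] |
                           baseline_means > ranges[, "max"]]
  if (length(out_of_range) > 0) {
    abort(sprintf("Baseline mean outside scale range for: %s.",
                  paste(out_of_range, collapse = ", ")))
  }
  rp_type <- rp_type[rp_factors]
  if (anyNA(rp_type) || !all(rp_type %in% c("risk", "protective"))) {
    abort("`rp_type` must label every RP factor as \"risk\" or \"protective\".")
  }
  structure(
    list(
      labels = labels, symptoms = symptoms, rp_factors = rp_factors,
      rp_type = rp_type, intercepts = intercepts,
      coefficients = coefficients, ranges = ranges,
      baseline_means = baseline_means
    ),
    class = "hybrid_nodewise_model"
  )
}

#' @export
print.hybrid_nodewise_model <- function(x, ...) {
  cat(sprintf(
    "<hybrid_nodewise_model> %d symptoms, %d RP factors (%d risk, %d protective)\n",
    length(x$symptoms), length(x$rp_factors),
    sum(x$rp_type == "risk"), sum(x$rp_type == "protective")
  ))
  invisible(x)
}

#' Tidy the nonzero coefficients of a hybrid model
#'
#' @param x A `hybrid_nodewise_model`.
#' @param ... Unused.
#' @return A tibble with columns `outcome`, `predictor`, `coefficient`.
#' @export
tidy.hybrid_nodewise_model <- function(x, ...) {
  nz <- which(x$coefficients != 0, arr.ind = TRUE)
  tibble(
    outcome = x$labels[nz[, 1]],
    predictor = x$labels[nz[, 2]],
    coefficient = x$coefficients[nz]
  )
}

#' Condition symptom means on fixed RP-factor values
#'
#' Fixes the scenario's RP factors at the given values (unlisted RP factors
#' stay at their baseline means) and propagates each symptom's nodewise
#' prediction — intercept plus coefficients times the current means of its
#' predictors — to a fixed point, so that effects travel through neighboring
#' symptoms as well as direct symptom-RP edges.
#'
#' The conditioned mean is anchored at the observed baseline: it is the
#' baseline mean plus the model-implied shift (the fixed point under the
#' scenario minus the fixed point with all RP factors at baseline). When the
#' baseline means satisfy the nodewise equations — as they do for regression
#' fits, which pass through the variable means — this equals propagating the
#' predictions directly; anchoring additionally guarantees that an empty
#' scenario changes nothing. Results are clipped to each node's scale range;
#' any clipping is recorded.
#'
#' @param model A `hybrid_nodewise_model`.
#' @param scenario Named numeric vector or list mapping RP-factor labels to
#'   fixed values inside their scale ranges. May be empty.
#' @param method `"fixed_point"` (default: Jacobi iteration to tolerance) or
#'   `"one_step"` (a single prediction pass from baseline means, a
#'   sensitivity-analysis mode in which only direct effects act).
#' @param tol Fixed-point convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap (default 1000); non-convergence raises an
#'   error naming the worst-oscillating nodes.
#' @return A tibble with one row per node: `node`, `role`
#'   (symptom/risk/protective), `baseline`, `conditioned`, `clipped`; the
#'   clip count is attached as attribute `clip_count`.
#' @export
condition_means <- function(model, scenario = list(),
                            method = c("fixed_point", "one_step"),
                            tol = 1e-8, max_iter = 1000) {
  if (!inherits(model, "hybrid_nodewise_model")) {
    abort("Expected a `hybrid_nodewise_model`.")
  }
  method <- match.arg(method)
  scenario <- unlist(scenario)
  if (length(scenario) > 0) {
    unknown <- setdiff(names(scenario), model$rp_factors)
    if (length(unknown) > 0) {
      abort(sprintf("Scenario names must be RP factors; unknown: %s.",
                    paste(unknown, collapse = ", ")))
    }
    lo <- model$ranges[names(scenario), "min"]
    hi <- model$ranges[names(scenario), "max"]
    bad <- names(scenario)[scenario < lo | scenario > hi]
    if (length(bad) > 0) {
      abort(sprintf("Scenario value outside scale range for: %s.",
                    paste(bad, collapse = ", ")))
    }
  }
  sym <- model$symptoms
  A <- model$coefficients
  b <- model$intercepts

  propagate <- function(rp_values) {
    m <- model$baseline_means
    m[names(rp_values)] <- rp_values
    if (method == "one_step") {
      m[sym] <- b[sym] + as.numeric(A[sym, , drop = FALSE] %*% m)
      return(m[sym])
    }
    for (it in seq_len(max_iter)) {
      nxt <- b[sym] + as.numeric(A[sym, , drop = FALSE] %*% m)
      delta <- abs(nxt - m[sym])
      m[sym] <- nxt
      if (max(delta) < tol) return(m[sym])
    }
    worst <- sym[order(-delta)][seq_len(min(3, length(sym)))]
    abort(sprintf(
      "Fixed-point conditioning did not converge in %d iterations; worst nodes: %s.",
      max_iter, paste(worst, collapse = ", ")
    ))
  }

  s_base <- propagate(stats::setNames(numeric(0), character(0)))
  s_cond <- if (length(scenario) > 0) propagate(scenario) else s_base

  m <- model$baseline_means
  m[names(scenario)] <- scenario
  m[sym] <- model$baseline_means[sym] + (s_cond - s_base)

  lo <- model$ranges[, "min"]
  hi <- model$ranges[, "max"]
  clipped_v <- m < lo | m > hi
  m <- pmin(pmax(m, lo), hi)
  role <- ifelse(model$labels %in% sym, "symptom",
                 unname(model$rp_type[model$labels]))
  out <- tibble(
    node = model$labels,
    role = role,
    baseline = unname(model$baseline_means),
    conditioned = unname(m),
    clipped = unname(clipped_v)
  )
  attr(out, "clip_count") <- sum(clipped_v)
  class(out) <- c("conditioned_means", class(out))
  out
}

#' ESA of a set of (conditioned) symptom means
#'
#' In the ordinal hybrid setting, symptom activity is summarized by summing
#' symptom means: ESA is the sum over all symptoms of their (possibly
#' conditioned) means. With 27 items on a 0-4 scale the largest possible
#' value is 108.
#'
#' @param means A `conditioned_means` tibble from [condition_means()] (only
#'   symptom rows contribute), or a plain numeric vector of symptom means.
#' @param which For `conditioned_means` input: sum the `"conditioned"`
#'   (default) or `"baseline"` column.
#' @return ESA as a single number.
#' @examples
#' conditioned_esa(rep(4, 27)) # 108, the 0-4 scale ceiling for 27 items
#' @export
conditioned_esa <- function(means, which = c("conditioned", "baseline")) {
  which <- match.arg(which)
  if (inherits(means, "conditioned_means")) {
    return(sum(means[[which]][means$role == "symptom"]))
  }
  if (!is.numeric(means)) abort("Expected symptom means.")
  sum(means)
}

#' Change in ESA caused by conditioning on RP factors
#'
#' @inheritParams condition_means
#' @param ... Passed on to [condition_means()].
#' @return The signed difference `conditioned ESA - baseline ESA`.
#' @export
esa_delta <- function(model, scenario = list(), ...) {
  cm <- condition_means(model, scenario, ...)
  conditioned_esa(cm, "conditioned") - conditioned_esa(cm, "baseline")
}

#' Scenario presets: all protective factors present / all risk factors present
#'
#' `scenario_protective_present()` fixes every protective factor at its scale
#' maximum ("presence") and every risk factor at its scale minimum
#' ("absence"); `scenario_risk_present()` is the opposite situation.
#'
#' @param model A `hybrid_nodewise_model`.
#' @return A named numeric vector usable as a `scenario`.
#' @export
scenario_protective_present <- function(model) {
  v <- ifelse(model$rp_type == "protective",
              model$ranges[model$rp_factors, "max"],
              model$ranges[model$rp_factors, "min"])
  stats::setNames(v, model$rp_factors)
}

#' @rdname scenario_protective_present
#' @export
scenario_risk_present <- function(model) {
  v <- ifelse(model$rp_type == "risk",
              model$ranges[model$rp_factors, "max"],
              model$ranges[model$rp_factors, "min"])
  stats::setNames(v, model$rp_factors)
}
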