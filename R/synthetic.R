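#' Independent samples from an enumerable Ising model
#'
#' Draws i.i.d. configurations from the exact joint distribution by
#' inverse-CDF sampling over the enumerated states — the independent-sample
#' counterpart of [sample_chain()] for networks small enough to enumerate.
#'
#' @param net An enumerable `ising_network` on the `{0,1}` domain.
#' @param n_samples Number of draws.
#' @param seed Optional integer seed; the same seed reproduces the dataset.
#' @return A tibble of 0/1 indicators, `n_samples` rows, columns named by
#'   node label.
#' @examples
#' dat <- sample_ising_exact(uniform_network(4, -1, 0.5), 100, seed = 1)
#' @export
sample_ising_exact <- function(net, n_samples, seed = NULL) {
  assert_network(net)
  if (net$domain != "01") {
    abort("Exact sampling requires the {0,1} domain; see convert_domain().")
  }
  if (n_samples < 1) abort("`n_samples` must be at least 1.")
  dist <- joint_distribution(net)
  n <- n_nodes(net)
  idx <- with_seed_if(seed, {
    sample.int(length(dist$probs), n_samples, replace = TRUE,
               prob = dist$probs)
  })
  states <- ising_states(n)
  out <- as_tibble(as.data.frame(states[idx, , drop = FALSE]))
  names(out) <- net$labels
  out
}

#' Generate correlated 5-level ordinal symptom-checklist items
#'
#' Emulates checklist-style symptom data: each person has a standard-normal
#' common factor, each item a latent score
#' `sqrt(latent_cor) * factor + sqrt(1 - latent_cor) * noise`, cut at four
#' thresholds into levels 0..4. Item thresholds are placed so that the
#' moderate-or-higher categories (levels 3-4, the ones [binarize()] maps
#' to 1) have marginal prevalences drawn uniformly from `prevalence_band`.
#'
#' @param n_persons Number of rows.
#' @param n_items Number of items (default 27).
#' @param latent_cor Common-factor share of latent variance, in `[0, 1)`
#'   (default 0.3).
#' @param prevalence_band Length-2 vector: range of binarized item
#'   prevalences (default `c(0.05, 0.40)`).
#' @param seed Optional integer seed.
#' @return A tibble of integer levels 0..4 with columns `SCL1..SCLk`; the
#'   per-item binarized target prevalences are attached as attribute
#'   `prevalence`.
#' @export
generate_ordinal_scl <- function(n_persons, n_items = 27, latent_cor = 0.3,
                                 prevalence_band = c(0.05, 0.40),
                                 seed = NULL) {
  if (n_persons < 1 || n_items < 1) abort("Counts must be at least 1.")
  if (latent_cor < 0 || latent_cor >= 1) abort("`latent_cor` must be in [0, 1).")
  with_seed_if(seed, {
    prev <- runif(n_items, prevalence_band[1], prevalence_band[2])
    f <- rnorm(n_persons)
    lat <- sqrt(latent_cor) * f +
      sqrt(1 - latent_cor) * matrix(rnorm(n_persons * n_items), n_persons)
    # c3 fixes the binarized prevalence exactly (latent margins are N(0,1));
    # the lower/upper cuts shape the remaining categories.
    c3 <- qnorm(1 - prev)
    lv <- vapply(seq_len(n_items), function(j) {
      cuts <- c(c3[j] - 1.5, c3[j] - 0.7, c3[j], c3[j] + 0.8)
      findInterval(lat[, j], cuts)
    }, integer(n_persons))
    if (!is.matrix(lv)) lv <- matrix(lv, ncol = n_items)
    out <- as_tibble(as.data.frame(lv))
    names(out) <- paste0("SCL", seq_len(n_items))
    attr(out, "prevalence") <- prev
    out
  })
}

#' Generate a hybrid symptom + RP-factor dataset with known truth
#'
#' Simulates a mixed dataset of continuous-scored symptoms and discrete
#' risk/protective factors together with the generating
#' [hybrid_model()], so conditioning and recovery analyses can be checked
#' against known truth. RP factors are drawn from their marginals; symptoms
#' follow the nodewise-linear structural system
#' `s = intercepts + A_ss s + A_sr r + noise`, solved exactly per person, so
#' the planted coefficient matrix is the true nodewise model. Protective
#' factors are planted with negative symptom coefficients and risk factors
#' with positive ones. Symptom-symptom coupling is a weak nearest-neighbor
#' chain.
#'
#' @param n_persons Number of rows.
#' @param n_symptoms Number of symptom nodes (default 9, scored 0-4).
#' @param rp_factors Tibble describing the factors: columns `label`,
#'   `type` (`"risk"`/`"protective"`), `max_level` (integer scale top).
#'   Defaults to one 0-3 substance-use risk factor and four protective
#'   factors (activity, religious practice, sexual satisfaction, volunteer
#'   work).
#' @param effect_size Absolute size of each planted symptom-RP coefficient
#'   (default 0.2).
#' @param n_targets How many symptoms each RP factor affects (default 3).
#' @param symptom_coupling Nearest-neighbor symptom-symptom coefficient
#'   (default 0.15; keep below 0.5 so the structural system is stable).
#' @param noise_sd Residual standard deviation of symptoms (default 0.6).
#' @param seed Optional integer seed.
#' @return A list with `data` (tibble, symptoms then RP factors) and `model`
#'   (the true `hybrid_nodewise_model`, with baseline means taken from the
#'   generated data).
#' @export
generate_hybrid_dataset <- function(n_persons, n_symptoms = 9,
                                    rp_factors = default_rp_factors(),
                                    effect_size = 0.2, n_targets = 3,
                                    symptom_coupling = 0.15, noise_sd = 0.6,
                                    seed = NULL) {
  if (n_persons < 1) abort("`n_persons` must be at least 1.")
  if (abs(symptom_coupling) >= 0.5) {
    abort("`symptom_coupling` must stay below 0.5 for a stable system.")
  }
  sym <- paste0("SCL", seq_len(n_symptoms))
  rp <- rp_factors$label
  n_rp <- length(rp)
  labels <- c(sym, rp)
  with_seed_if(seed, {
    # RP marginals: binomial counts over the scale, presence prob 0.3
    r <- vapply(seq_len(n_rp), function(k) {
      stats::rbinom(n_persons, rp_factors$max_level[k], 0.3)
    }, numeric(n_persons))
    if (!is.matrix(r)) r <- matrix(r, ncol = n_rp)
    colnames(r) <- rp

    A_sr <- matrix(0, n_symptoms, n_rp, dimnames = list(sym, rp))
    for (k in seq_len(n_rp)) {
      tgt <- sample.int(n_symptoms, min(n_targets, n_symptoms))
      sgn <- if (rp_factors$type[k] == "risk") 1 else -1
      A_sr[tgt, k] <- sgn * effect_size
    }
    A_ss <- matrix(0, n_symptoms, n_symptoms, dimnames = list(sym, sym))
    if (n_symptoms > 1) {
      for (i in seq_len(n_symptoms - 1)) {
        A_ss[i, i + 1] <- symptom_coupling
        A_ss[i + 1, i] <- symptom_coupling
      }
    }
    # intercepts put the implied symptom means mid-scale (1.5) at E[r]
    target_mean <- rep(1.5, n_symptoms)
    er <- rp_factors$max_level * 0.3
    b <- as.numeric((diag(n_symptoms) - A_ss) %*% target_mean) -
      as.numeric(A_sr %*% er)

    inv <- solve(diag(n_symptoms) - A_ss)
    eps <- matrix(rnorm(n_persons * n_symptoms, sd = noise_sd), n_persons)
    s <- t(inv %*% (b + A_sr %*% t(r) + t(eps)))
    s <- pmin(pmax(s, 0), 4)
    colnames(s) <- sym

    data <- as_tibble(as.data.frame(cbind(s, r)))
    coefficients <- matrix(
      0, length(labels), length(labels), dimnames = list(labels, labels)
    )
    coefficients[sym, sym] <- A_ss
    coefficients[sym, rp] <- A_sr
    ranges <- data.frame(
      min = rep(0, length(labels)),
      max = c(rep(4, n_symptoms), rp_factors$max_level),
      row.names = labels
    )
    baseline_means <- colMeans(data)
    model <- hybrid_model(
      intercepts = stats::setNames(c(b, rep(0, n_rp)), labels),
      coefficients = coefficients,
      symptoms = sym, rp_factors = rp,
      rp_type = stats::setNames(rp_factors$type, rp),
      ranges = ranges,
      baseline_means = baseline_means
    )
    list(data = data, model = model)
  })
}

#' Default risk/protective factor definitions for synthetic hybrid data
#'
#' One 0-3 substance-use risk factor (the usual sum of three binary
#' substance items) plus four protective factors on their native scales.
#'
#' @return A tibble with columns `label`, `type`, `max_level`.
#' @export
default_rp_factors <- function() {
  tibble(
    label = c("substance_use", "physical_activity", "religious_practice",
              "sexual_satisfaction", "volunteer_work"),
    type = c("risk", "protective", "protective", "protective", "protective"),
    max_level = c(3, 1, 4, 5, 4)
  )
}
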