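#' Plan for density-guided cluster equalization
#'
#' @param target_size Target size per cluster; defaults to the size of the
#'   largest cluster, so the largest cluster receives no generated cases.
#' @param sigma Standard deviation of the Gaussian perturbation around a
#'   seed case, per dimension, on the 0-100 component scale. Defaults to
#'   half the [pareto_radius()] of the data being augmented.
#' @param max_attempts_per_case Proposal budget per requested case before
#'   augmentation is declared failed.
#' @param seed Integer seed.
#' @return Object of class `augmentation_plan`.
#' @export
augmentation_plan <- function(target_size = NULL, sigma = NULL,
                              max_attempts_per_case = 1000, seed = 42L) {
  if (!is.null(sigma) && sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  structure(list(target_size = target_size, sigma = sigma,
                 max_attempts_per_case = max_attempts_per_case,
                 seed = as.integer(seed)),
            class = "augmentation_plan")
}

#' Cases to add per cluster to reach a common size
#'
#' @param sizes Named or unnamed vector of cluster sizes.
#' @param target_size Common target; defaults to `max(sizes)`.
#' @return Integer vector of additions (`target_size - size`, floored at 0),
#'   same order and names as `sizes`.
#' @export
#' @examples
#' plan_additions(c(17, 2, 1, 7, 53)) # 36 51 52 46 0
plan_additions <- function(sizes, target_size = NULL) {
  if (is.null(target_size)) target_size <- max(sizes)
  setNames(pmax(as.integer(target_size) - as.integer(sizes), 0L), names(sizes))
}

#' Generate valid synthetic cases inside one cluster
#'
#' Generative model for enlarging small clusters: a candidate is a seed case
#' (drawn uniformly from the cluster's members) plus an isotropic Gaussian
#' perturbation, clipped to the observed per-variable ranges. The candidate
#' is accepted with probability `p(BMU(candidate)) / max(P)` — the Bayesian
#' "probability that such a data point exists", read off the P-matrix — and
#' only if its best-matching unit lies in the seed cluster's basin, so every
#' generated case respects both the density and the cluster structure of the
#' observed data.
#'
#' @param model Trained [train_esom()] model.
#' @param p P-matrix counts from [p_matrix()].
#' @param assignment [extract_clusters()] result.
#' @param data The (scaled) data matrix the model was trained on.
#' @param cluster_id Cluster (or outlier-group) label to augment.
#' @param n_new Number of cases to generate.
#' @param plan An [augmentation_plan()].
#' @param require_basin If `FALSE`, the basin-membership check is skipped and
#'   only density acceptance applies.
#' @return Data frame with the generated component vectors plus provenance
#'   columns `seed_row` (row index of the seed case in `data`),
#'   `accepting_neuron` (1-based index) and `acceptance_prob`.
#' @export
generate_cases <- function(model, p, assignment, data, cluster_id, n_new,
                           plan = augmentation_plan(), require_basin = TRUE) {
  data <- as.matrix(data)
  members <- which(assignment$cluster == cluster_id)
  if (length(members) == 0) stop("cluster ", cluster_id, " is empty", call. = FALSE)
  if (n_new == 0) {
    out <- as.data.frame(data[0, , drop = FALSE])
    out$seed_row <- integer(0); out$accepting_neuron <- integer(0)
    out$acceptance_prob <- numeric(0)
    return(out)
  }
  sigma <- plan$sigma
  if (is.null(sigma)) sigma <- pareto_radius(data) * 0.5
  rng <- t(apply(data, 2, range))
  pmax_all <- max(p)

  set.seed(plan$seed + cluster_id)
  kept <- matrix(NA_real_, n_new, ncol(data), dimnames = list(NULL, colnames(data)))
  seed_row <- integer(n_new); neuron <- integer(n_new); prob <- numeric(n_new)
  accepted <- 0L
  attempts <- 0L
  budget <- plan$max_attempts_per_case * n_new
  while (accepted < n_new) {
    if (attempts >= budget) {
      stop(sprintf(
        "augmentation failed for cluster %s: %d of %d cases after %d proposals (acceptance rate %.3f)",
        cluster_id, accepted, n_new, attempts, accepted / attempts), call. = FALSE)
    }
    attempts <- attempts + 1L
    s <- members[sample.int(length(members), 1L)]
    cand <- data[s, ] + stats::rnorm(ncol(data), 0, sigma)
    cand <- pmin(pmax(cand, rng[, 1]), rng[, 2])
    bmu <- assign_bmus(model, matrix(cand, nrow = 1))
    if (require_basin) {
      b <- assignment$neuron_basin[bmu]
      if (is.na(b) || b != cluster_id) next
    }
    # Laplace-smoothed existence probability: the seed case itself is
    # evidence that a data point can exist here, so the count is floored at
    # 1 — otherwise outlier basins, whose prototypes can lie farther than r
    # from their few patients, could never be augmented at all
    p_accept <- max(p[bmu], 1) / pmax_all
    if (stats::runif(1) <= p_accept) {
      accepted <- accepted + 1L
      kept[accepted, ] <- cand
      seed_row[accepted] <- s
      neuron[accepted] <- bmu
      prob[accepted] <- p_accept
    }
  }
  out <- as.data.frame(kept)
  out$seed_row <- seed_row
  out$accepting_neuron <- neuron
  out$acceptance_prob <- prob
  out
}

#' Equalize all cluster sizes by generative augmentation
#'
#' Brings every cluster (and outlier group) up to the target size — by
#' default the size of the largest cluster — by generating
#' `target_size - size` valid cases per cluster with [generate_cases()].
#' Original rows are untouched and flagged `is_synthetic = FALSE`.
#'
#' @inheritParams generate_cases
#' @return List with `data` (augmented matrix of component vectors),
#'   `cluster` (label per row), `is_synthetic` (flag per row),
#'   `provenance` (the generated cases with their seed and neuron), and
#'   `additions` (named count of generated cases per cluster label).
#' @export
equalize_clusters <- function(model, p, assignment, data,
                              plan = augmentation_plan(),
                              require_basin = TRUE) {
  data <- as.matrix(data)
  sizes <- table(assignment$cluster)
  labels <- as.integer(names(sizes))
  additions <- plan_additions(as.integer(sizes), plan$target_size)
  names(additions) <- names(sizes)

  gen_all <- list()
  new_cluster <- integer(0)
  for (k in seq_along(labels)) {
    if (additions[k] == 0) next
    g <- generate_cases(model, p, assignment, data, labels[k], additions[k],
                        plan, require_basin)
    gen_all[[length(gen_all) + 1L]] <- g
    new_cluster <- c(new_cluster, rep(labels[k], additions[k]))
  }
  provenance <- if (length(gen_all)) do.call(rbind, gen_all) else NULL
  gen_mat <- if (length(gen_all)) {
    m <- as.matrix(provenance[, seq_len(ncol(data)), drop = FALSE])
    colnames(m) <- colnames(data)
    m
  } else {
    data[0, , drop = FALSE]
  }
  list(
    data = rbind(data, gen_mat),
    cluster = c(assignment$cluster, new_cluster),
    is_synthetic = c(rep(FALSE, nrow(data)), rep(TRUE, nrow(gen_mat))),
    provenance = provenance,
    additions = additions
  )
}
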