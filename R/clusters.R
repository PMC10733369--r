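#' Extract clusters and outliers from the U*-landscape
#'
#' Automated surrogate for the visual delineation of U-matrix valleys:
#' neurons whose U*-height lies at or below a percentile of the occupied
#' neurons' heights are "valley floor"; their connected components under
#' Moore 8-connectivity (toroidal if the map is) form basins. Every patient
#' inherits the basin of its best-matching unit; occupied neurons above the
#' threshold are attached to the basin of the nearest below-threshold neuron
#' by grid distance (ties broken by lowest row-major index) — unless the
#' neuron sits in a "volcanic crater" of the height landscape, i.e. farther
#' than `attach_radius` grid units from any valley neuron and at a height
#' reaching the `outlier_height_quantile` of the occupied neurons, in which
#' case it forms a basin of its own. This is how isolated outlier patients
#' surface: an outlier's best-matching unit is never valley floor, because
#' its neighboring prototypes interpolate towards the distant bulk of the
#' data.
#' Off-valley neurons not occupied by patients join the nearest basin, so
#' basins tile the grid like watershed catchments. Basins holding fewer than
#' `min_cluster_size` patients are reported as outlier groups rather than
#' clusters.
#'
#' Cluster ids are 1-based in decreasing size order; outlier groups continue
#' the numbering after the clusters.
#'
#' @param u_star U*-heights from [u_star_matrix()] (or U-heights, for a
#'   purely distance-based segmentation).
#' @param bmus 1-based neuron index per patient, from [assign_bmus()].
#' @param model The trained [train_esom()] model (for grid geometry).
#' @param min_cluster_size Basins with fewer patients become outlier groups.
#' @param height_quantile Percentile of occupied-neuron heights used as the
#'   valley threshold.
#' @param attach_radius Maximal grid distance over which an above-threshold
#'   occupied neuron is absorbed into an existing valley basin. The default
#'   (`NULL`) adapts to the map's occupancy: twice the median grid distance
#'   between an occupied neuron and its nearest occupied neighbor, floored
#'   at 2 — on sparsely occupied maps ordinary patients sit further from
#'   the valley floor, and a fixed radius would mislabel them as outliers.
#' @param outlier_height_quantile A stray neuron only qualifies as a crater
#'   if its U*-height also reaches this percentile of the occupied-neuron
#'   heights.
#' @return Object of class `cluster_assignment`: `cluster` (integer label
#'   per patient), `is_outlier` (logical per patient), `sizes` (named,
#'   decreasing within each kind), `neuron_basin` (catchment label per
#'   neuron, `NA` for basins holding no patients), `threshold`,
#'   `min_cluster_size`.
#' @export
extract_clusters <- function(u_star, bmus, model, min_cluster_size = 3,
                             height_quantile = 0.7, attach_radius = NULL,
                             outlier_height_quantile = 0.9) {
  rows <- model$config$rows
  cols <- model$config$cols
  m <- rows * cols
  if (length(u_star) != m) stop("u_star does not match the grid", call. = FALSE)
  occupied <- sort(unique(bmus))
  if (length(occupied) == 0) stop("no occupied neurons", call. = FALSE)

  threshold <- unname(stats::quantile(u_star[occupied], height_quantile, type = 7))
  below <- which(u_star <= threshold)

  if (is.null(attach_radius)) {
    nn <- vapply(occupied, function(idx) {
      d2 <- .grid_dist2(idx, rows, cols, model$config$toroidal)[occupied]
      sqrt(min(d2[d2 > 0], Inf))
    }, numeric(1))
    nn <- nn[is.finite(nn)]
    attach_radius <- max(2, 2 * stats::median(nn, na.rm = TRUE))
    if (!is.finite(attach_radius)) attach_radius <- 2
  }

  edges <- integer(0)
  in_below <- logical(m)
  in_below[below] <- TRUE
  for (idx in below) {
    nb <- .moore_neighbors(idx, rows, cols, model$config$toroidal)
    nb <- nb[in_below[nb] & nb > idx]
    if (length(nb) > 0) edges <- c(edges, rbind(idx, nb))
  }
  g <- igraph::make_graph(edges = as.character(edges),
                          isolates = as.character(setdiff(below, unique(edges))),
                          directed = FALSE)
  comp <- igraph::components(g)
  basin <- rep(NA_integer_, m)
  basin[as.integer(igraph::V(g)$name)] <- comp$membership
  n_basins <- comp$no

  # occupied neurons above the threshold: absorbed into the nearest valley
  # basin, unless they sit in a "volcanic crater" — far from any valley AND
  # on an extreme height — in which case they form basins of their own
  # (connected crater neurons share one basin)
  crater_height <- stats::quantile(u_star[occupied], outlier_height_quantile,
                                   type = 7)
  stray <- setdiff(occupied, below)
  far_stray <- integer(0)
  for (idx in stray) {
    d2 <- .grid_dist2(idx, rows, cols, model$config$toroidal)[below]
    if (min(d2) > attach_radius^2 && u_star[idx] >= crater_height) {
      far_stray <- c(far_stray, idx)
    } else {
      basin[idx] <- basin[below[which.min(d2)]]
    }
  }
  if (length(far_stray) > 0) {
    in_far <- logical(m)
    in_far[far_stray] <- TRUE
    for (idx in far_stray) {
      if (!is.na(basin[idx])) next
      n_basins <- n_basins + 1L
      queue <- idx
      while (length(queue) > 0) {
        cur <- queue[1]
        queue <- queue[-1]
        if (!is.na(basin[cur])) next
        basin[cur] <- n_basins
        nb <- .moore_neighbors(cur, rows, cols, model$config$toroidal)
        queue <- c(queue, nb[in_far[nb] & is.na(basin[nb])])
      }
    }
  }

  # remaining (patient-free) neurons join the catchment of the nearest
  # labeled neuron, so basins tile the whole grid
  bmu_basin <- basin
  labeled <- which(!is.na(basin))
  for (idx in which(is.na(basin))) {
    d2 <- .grid_dist2(idx, rows, cols, model$config$toroidal)[labeled]
    bmu_basin[idx] <- basin[labeled[which.min(d2)]]
  }

  patient_basin <- bmu_basin[bmus]
  counts <- table(patient_basin)
  basin_ids <- as.integer(names(counts))
  n_pat <- as.integer(counts)
  is_cluster <- n_pat >= min_cluster_size
  # clusters first (decreasing size), then outlier groups (decreasing size)
  ord <- order(!is_cluster, -n_pat, basin_ids)
  relabel <- integer(max(basin_ids))
  relabel[basin_ids[ord]] <- seq_along(ord)
  outlier_label <- !is_cluster[ord]

  cluster <- relabel[patient_basin]
  sizes <- n_pat[ord]
  names(sizes) <- ifelse(outlier_label, paste0("outlier_group_", seq_along(ord)),
                         paste0("cluster_", seq_along(ord)))
  neuron_basin <- relabel[bmu_basin]      # full-map catchment labels
  neuron_basin[!is.na(neuron_basin) & neuron_basin == 0] <- NA  # patient-free basins

  structure(list(
    cluster = cluster,
    is_outlier = outlier_label[cluster],
    sizes = sizes,
    neuron_basin = neuron_basin,
    threshold = threshold,
    height_quantile = height_quantile,
    min_cluster_size = min_cluster_size
  ), class = "cluster_assignment")
}

#' Association between map clusters and activity stages
#'
#' Pearson chi-square test of the cluster x stage contingency table,
#' restricted to clusters with at least 5 members (small outlier groups are
#' excluded, as their expected counts are meaningless).
#'
#' @param assignment A [extract_clusters()] result.
#' @param stages Activity stage per patient (factor or character).
#' @param min_members Clusters smaller than this are excluded from the table.
#' @return List with `statistic`, `df`, `p.value`, `residuals` (Pearson
#'   residuals), and the tested `table`.
#' @export
cluster_stage_association <- function(assignment, stages, min_members = 5) {
  keep_labels <- which(assignment$sizes >= min_members)
  keep <- assignment$cluster %in% keep_labels
  tab <- table(cluster = assignment$cluster[keep],
               stage = droplevels(factor(stages[keep])))
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    stop("degenerate contingency table: need >= 2 clusters of >= ",
         min_members, " members and >= 2 stages", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p.value = ct$p.value, residuals = ct$residuals, table = tab)
}
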