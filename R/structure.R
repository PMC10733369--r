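#' U-matrix: local distance structure of a trained map
#'
#' The height of neuron i is the mean Euclidean distance between its
#' prototype and the prototypes of its (up to 8) Moore neighbors on the
#' grid, with toroidal wrap-around if configured. On degenerate grids where
#' wrapped neighbor offsets coincide, neighbors are deduplicated by grid
#' position (and the neuron itself excluded). Valleys of the resulting
#' landscape indicate clusters, ridges indicate cluster boundaries.
#'
#' @param model A trained [train_esom()] model.
#' @return Numeric vector of rows*cols nonnegative heights, row-major.
#' @export
u_matrix <- function(model) {
  rows <- model$config$rows
  cols <- model$config$cols
  m <- rows * cols
  heights <- numeric(m)
  for (idx in seq_len(m)) {
    nb <- .moore_neighbors(idx, rows, cols, model$config$toroidal)
    diffs <- sweep(model$weights[nb, , drop = FALSE], 2, model$weights[idx, ], "-")
    heights[idx] <- mean(sqrt(rowSums(diffs^2)))
  }
  heights
}

# deduplicated Moore neighborhood (1-based row-major indices, self excluded)
.moore_neighbors <- function(idx, rows, cols, toroidal) {
  r0 <- (idx - 1L) %/% cols
  c0 <- (idx - 1L) %% cols
  off <- expand.grid(dr = -1:1, dc = -1:1)
  off <- off[!(off$dr == 0 & off$dc == 0), ]
  r <- r0 + off$dr
  ccol <- c0 + off$dc
  if (toroidal) {
    r <- r %% rows
    ccol <- ccol %% cols
  } else {
    keep <- r >= 0 & r < rows & ccol >= 0 & ccol < cols
    r <- r[keep]
    ccol <- ccol[keep]
  }
  nb <- unique(r * cols + ccol + 1L)
  setdiff(nb, idx)
}

#' Pareto radius: distance-percentile bandwidth for density estimation
#'
#' The radius used by the P-matrix density estimate, taken as a percentile
#' (default: 20th) of the nonzero pairwise Euclidean distances of the data.
#'
#' @param data Numeric matrix (n x d), n >= 2.
#' @param percentile Percentile of the nonzero pairwise distances, in (0,1].
#' @return Positive scalar radius.
#' @export
pareto_radius <- function(data, percentile = 0.2) {
  data <- as.matrix(data)
  if (nrow(data) < 2) stop("need at least 2 data points", call. = FALSE)
  d <- as.numeric(stats::dist(data))
  d <- d[d > 0]
  if (length(d) == 0) {
    stop("all points are identical: no nonzero pairwise distance", call. = FALSE)
  }
  unname(stats::quantile(d, percentile, type = 7))
}

#' P-matrix: data density around each prototype
#'
#' Counts, for each neuron, the data points inside the closed hypersphere of
#' radius `r` around its prototype: p(i) = |{x : d(w_i, x) <= r}|.
#'
#' @param model A trained [train_esom()] model.
#' @param data Numeric matrix of data points (n x d).
#' @param r Positive radius, typically the [pareto_radius()] of the data.
#' @return Integer vector of rows*cols counts, row-major.
#' @export
p_matrix <- function(model, data, r) {
  if (r <= 0) stop("radius r must be > 0", call. = FALSE)
  data <- as.matrix(data)
  if (nrow(data) == 0) return(integer(nrow(model$weights)))
  w2 <- rowSums(model$weights^2)
  x2 <- rowSums(data^2)
  d2 <- outer(w2, x2, "+") - 2 * model$weights %*% t(data)
  as.integer(rowSums(d2 <= r^2 + 1e-12))
}

#' U*-matrix: distance structure rescaled by local density
#'
#' Combines the U-matrix and the P-matrix so that ridges inside dense regions
#' are suppressed and sparse regions amplified:
#' `ustar(i) = u(i) * f(i)` with
#' `f(i) = (p(i) - max(P)) / (mean(P) - max(P))`, clipped below at 0. The
#' factor is 1 at mean density, 0 at maximum density, and above 1 in regions
#' sparser than the mean.
#'
#' @param u U-matrix heights from [u_matrix()].
#' @param p P-matrix counts from [p_matrix()].
#' @return Numeric vector of nonnegative heights, congruent with `u`. If the
#'   density is uniform (mean(P) = max(P)) the U-matrix is returned
#'   unchanged with a warning.
#' @export
u_star_matrix <- function(u, p) {
  if (length(u) != length(p)) stop("u and p must be congruent", call. = FALSE)
  mx <- max(p)
  mn <- mean(p)
  if (mx == mn) {
    warning("uniform density: mean(P) = max(P); returning u unchanged")
    return(u)
  }
  f <- pmax((p - mx) / (mn - mx), 0)
  u * f
}
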