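#' Principal component analysis of z-standardized data
#'
#' Classical PCA via eigendecomposition of the correlation matrix, as applied
#' to the four z-standardized DAS28-CRP components. The percent contribution
#' of variable j to component k is 100 * loading_jk^2 / sum_j loading_jk^2,
#' which for unit-norm eigenvectors reduces to 100 * v_jk^2.
#'
#' @param x Numeric matrix (n x d), n >= 2. Columns must be non-constant.
#' @return List of class `pca_result` with elements `eigenvalues`
#'   (nonincreasing, summing to d), `scores` (n x d matrix of projections of
#'   the z-standardized data), `loadings` (d x d), `contributions` (d x d,
#'   percent, columns sum to 100) and `variance_explained` (percent per PC).
#' @export
pca_project <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 rows", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column(s) cannot be z-standardized: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  z <- scale(x)
  eg <- eigen(stats::cor(x), symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  contributions <- 100 * eg$vectors^2
  contributions <- sweep(contributions, 2, colSums(contributions), "/") * 100
  dimnames(eg$vectors) <- list(colnames(x), paste0("PC", seq_len(ncol(x))))
  dimnames(contributions) <- dimnames(eg$vectors)
  structure(list(
    eigenvalues = ev,
    scores = z %*% eg$vectors,
    loadings = sweep(eg$vectors, 2, sqrt(ev), "*"),
    contributions = contributions,
    variance_explained = 100 * ev / sum(ev)
  ), class = "pca_result")
}

#' Rescale variables to the range 0-100
#'
#' Per-variable linear map sending the observed minimum to 0 and the maximum
#' to 100 — the input scaling used before self-organizing-map training. A
#' constant variable maps to 0 throughout.
#'
#' @param x Numeric matrix (n x d).
#' @return List with `scaled` (n x d matrix in 0-100) and `ranges` (d x 2
#'   matrix of the per-variable `min` and `max` used), which
#'   [unscale_0_100()] uses to invert the map.
#' @export
scale_0_100 <- function(x) {
  x <- as.matrix(x)
  rng <- t(apply(x, 2, range))
  colnames(rng) <- c("min", "max")
  span <- rng[, "max"] - rng[, "min"]
  scaled <- sweep(x, 2, rng[, "min"], "-")
  scaled <- sweep(scaled, 2, ifelse(span > 0, span / 100, 1), "/")
  scaled[, span == 0] <- 0
  list(scaled = scaled, ranges = rng)
}

#' @rdname scale_0_100
#' @param scaled Matrix on the 0-100 scale.
#' @param ranges The `ranges` element returned by [scale_0_100()].
#' @export
unscale_0_100 <- function(scaled, ranges) {
  span <- ranges[, "max"] - ranges[, "min"]
  out <- sweep(as.matrix(scaled), 2, span / 100, "*")
  sweep(out, 2, ranges[, "min"], "+")
}
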