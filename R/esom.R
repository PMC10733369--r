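#' Configuration of an emergent self-organizing map
#'
#' Defaults follow common ESOM practice for emergent structure detection: a
#' large toroidal lattice of 50 x 80 = 4,000 neurons (far more neurons than
#' expected clusters), trained online for 20 epochs with the learning rate
#' annealed linearly from 0.3 to 0.05 and a Gaussian neighborhood whose
#' radius shrinks linearly from `max(rows, cols) / 2` to 1.
#'
#' @param rows,cols Grid dimensions.
#' @param toroidal Use a toroidal (border-free) grid topology.
#' @param epochs Number of passes over the data.
#' @param lr_start,lr_end Learning-rate schedule endpoints, `0 < lr_end <=
#'   lr_start`.
#' @param radius_start,radius_end Gaussian neighborhood radius endpoints, in
#'   grid units.
#' @param seed Integer seed for weight initialization and sample order.
#' @return Object of class `esom_config`.
#' @export
esom_config <- function(rows = 50, cols = 80, toroidal = TRUE, epochs = 20,
                        lr_start = 0.3, lr_end = 0.05,
                        radius_start = max(rows, cols) / 2, radius_end = 1,
                        seed = 42L) {
  if (rows < 1 || cols < 1) stop("grid must have at least one neuron", call. = FALSE)
  if (lr_end <= 0 || lr_end > lr_start) {
    stop("learning rates must satisfy 0 < lr_end <= lr_start", call. = FALSE)
  }
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 toroidal = isTRUE(toroidal), epochs = as.integer(epochs),
                 lr_start = lr_start, lr_end = lr_end,
                 radius_start = radius_start, radius_end = radius_end,
                 seed = as.integer(seed)),
            class = "esom_config")
}

# squared toroidal (or planar) grid distance from one neuron to all neurons.
# Neurons are indexed row-major; positions are 0-based.
.grid_dist2 <- function(idx, rows, cols, toroidal) {
  r0 <- (idx - 1L) %/% cols
  c0 <- (idx - 1L) %% cols
  r <- rep(0:(rows - 1L), each = cols)
  ccol <- rep(0:(cols - 1L), times = rows)
  dr <- abs(r - r0)
  dc <- abs(ccol - c0)
  if (toroidal) {
    dr <- pmin(dr, rows - dr)
    dc <- pmin(dc, cols - dc)
  }
  dr^2 + dc^2
}

#' Train an emergent self-organizing map
#'
#' Online (per-sample) SOM learning on the rectangular grid defined by
#' `config`. At global step t (of n * epochs steps) the learning rate and the
#' Gaussian neighborhood radius are interpolated linearly between their start
#' and end values; each presented sample pulls every prototype towards it
#' with weight `lr * exp(-d_grid^2 / (2 sigma^2))`, where `d_grid` is the
#' (toroidal) grid distance to the sample's best-matching unit. Prototypes
#' are initialized uniformly within the per-variable data ranges. The whole
#' procedure is deterministic given `config$seed`.
#'
#' @param data Numeric matrix (n x d) of training data, typically the
#'   0-100-scaled component matrix from [scale_0_100()].
#' @param config An [esom_config()].
#' @param input_scaling Optional `ranges` matrix from [scale_0_100()],
#'   stored with the model for provenance.
#' @param init_ranges Optional d x 2 matrix of per-variable initialization
#'   ranges; defaults to the per-variable data range.
#' @return Object of class `esom` with elements `weights` (rows*cols x d,
#'   row-major neuron order), `config`, `input_scaling`.
#' @export
train_esom <- function(data, config = esom_config(), input_scaling = NULL,
                       init_ranges = NULL) {
  data <- as.matrix(data)
  if (nrow(data) < 1) stop("training data is empty", call. = FALSE)
  n <- nrow(data)
  d <- ncol(data)
  m <- config$rows * config$cols

  set.seed(config$seed)
  rng <- if (is.null(init_ranges)) t(apply(data, 2, range)) else init_ranges
  weights <- sapply(seq_len(d), function(j) stats::runif(m, rng[j, 1], rng[j, 2]))
  weights <- matrix(weights, nrow = m, ncol = d)

  total_steps <- n * config$epochs
  step <- 0L
  for (epoch in seq_len(config$epochs)) {
    order_idx <- sample.int(n)
    for (i in order_idx) {
      frac <- if (total_steps > 1) step / (total_steps - 1) else 0
      lr <- config$lr_start + frac * (config$lr_end - config$lr_start)
      sigma <- config$radius_start + frac * (config$radius_end - config$radius_start)
      x <- data[i, ]
      diffs <- sweep(weights, 2, x, "-")
      bmu <- which.min(rowSums(diffs^2))
      h <- exp(-.grid_dist2(bmu, config$rows, config$cols, config$toroidal) /
                 (2 * sigma^2))
      weights <- weights - (lr * h) * diffs
      step <- step + 1L
    }
  }
  colnames(weights) <- colnames(data)
  structure(list(weights = weights, config = config,
                 input_scaling = input_scaling),
            class = "esom")
}

#' Best-matching unit of an input vector
#'
#' Returns the grid position of the neuron whose prototype has minimal
#' Euclidean distance to `x`; exact ties are broken by the lowest row-major
#' index.
#'
#' @param model A trained [train_esom()] model.
#' @param x Input vector of the model's input dimension.
#' @return Integer vector `c(row, col)`, 0-based.
#' @export
assign_bmu <- function(model, x) {
  if (length(x) != ncol(model$weights)) {
    stop("input has dimension ", length(x), ", model expects ",
         ncol(model$weights), call. = FALSE)
  }
  idx <- which.min(rowSums(sweep(model$weights, 2, x, "-")^2))
  c(row = (idx - 1L) %/% model$config$cols,
    col = (idx - 1L) %% model$config$cols)
}

#' @rdname assign_bmu
#' @param data Matrix of input vectors (one per row).
#' @return `assign_bmus` returns a 1-based row-major neuron index per row of
#'   `data`.
#' @export
assign_bmus <- function(model, data) {
  data <- as.matrix(data)
  if (ncol(data) != ncol(model$weights)) {
    stop("input has dimension ", ncol(data), ", model expects ",
         ncol(model$weights), call. = FALSE)
  }
  w2 <- rowSums(model$weights^2)
  # argmin_i ||w_i - x||^2 = argmin_i (||w_i||^2 - 2 w_i . x)
  cross <- model$weights %*% t(data)
  apply(w2 - 2 * cross, 2, which.min)
}
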