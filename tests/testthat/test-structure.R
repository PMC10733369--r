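# brute-force oracles, written as plain enumerations independent of the
# package internals
oracle_u_matrix <- function(weights, rows, cols, toroidal = TRUE) {
  out <- numeric(rows * cols)
  for (r0 in 0:(rows - 1)) for (c0 in 0:(cols - 1)) {
    nbs <- list()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r <- r0 + dr; cc <- c0 + dc
      if (toroidal) { r <- r %% rows; cc <- cc %% cols }
      if (r < 0 || r >= rows || cc < 0 || cc >= cols) next
      if (r == r0 && cc == c0) next
      nbs[[paste(r, cc)]] <- r * cols + cc + 1
    }
    idx <- r0 * cols + c0 + 1
    ds <- sapply(unique(unlist(nbs)), function(j) {
      sqrt(sum((weights[idx, ] - weights[j, ])^2))
    })
    out[idx] <- mean(ds)
  }
  out
}

fake_model <- function(weights, rows, cols, toroidal = TRUE) {
  structure(list(weights = weights,
                 config = esom_config(rows = rows, cols = cols,
                                      toroidal = toroidal, seed = 1)),
            class = "esom")
}

test_that("U-matrix equals the neighbor-average oracle on random grids", {
  set.seed(11)
  for (i in 1:5) {
    w <- matrix(rnorm(20 * 3), ncol = 3)
    m <- fake_model(w, 4, 5)
    expect_equal(u_matrix(m), oracle_u_matrix(w, 4, 5), tolerance = 1e-12)
    m_plane <- fake_model(w, 4, 5, toroidal = FALSE)
    expect_equal(u_matrix(m_plane), oracle_u_matrix(w, 4, 5, FALSE),
                 tolerance = 1e-12)
  }
})

test_that("U-matrix heights are zero for identical prototypes and nonnegative", {
  m <- fake_model(matrix(2, 12, 3), 3, 4)
  expect_equal(u_matrix(m), rep(0, 12))
  set.seed(12)
  m2 <- fake_model(matrix(rnorm(12 * 2), ncol = 2), 3, 4)
  expect_true(all(u_matrix(m2) >= 0))
})

test_that("degenerate 1x2 grid deduplicates wrapped neighbors", {
  m <- fake_model(matrix(c(0, 3), ncol = 1), 1, 2)
  expect_equal(u_matrix(m), c(3, 3))
})

test_that("Pareto radius is the percentile of nonzero pairwise distances", {
  two <- rbind(c(0, 0), c(3, 4))
  expect_equal(pareto_radius(two), 5)

  set.seed(13)
  x <- matrix(rnorm(20), ncol = 2)
  d <- c()
  for (i in 1:9) for (j in (i + 1):10) {
    d <- c(d, sqrt(sum((x[i, ] - x[j, ])^2)))
  }
  expect_equal(length(d), 45)
  expect_equal(pareto_radius(x, 0.2), unname(quantile(d, 0.2, type = 7)))
  expect_gt(pareto_radius(x), 0)
  expect_error(pareto_radius(matrix(1, 5, 2)), "identical")
})

test_that("P-matrix counts points in the closed hypersphere exactly", {
  m <- fake_model(matrix(1.0, 1, 1), 1, 1)
  expect_equal(p_matrix(m, matrix(c(0, 1, 2), ncol = 1), r = 1), 3L)
  expect_equal(p_matrix(m, matrix(numeric(0), ncol = 1), r = 1), 0L)

  set.seed(14)
  w <- matrix(rnorm(12 * 2), ncol = 2)
  model <- fake_model(w, 3, 4)
  x <- matrix(rnorm(30), ncol = 2)
  r <- 1.3
  oracle <- sapply(seq_len(12), function(i) {
    sum(sqrt(colSums((t(x) - w[i, ])^2)) <= r)
  })
  expect_equal(p_matrix(model, x, r), as.integer(oracle))
  big_r <- 1e6
  expect_equal(p_matrix(model, x, big_r), rep(15L, 12))
})

test_that("U*-matrix applies the declared density rescaling", {
  p <- c(1, 3, 5)
  u <- c(2, 2, 2)
  got <- u_star_matrix(u, p)
  # mean(P) = 3, max(P) = 5: f = (p - 5)/(3 - 5)
  expect_equal(got, 2 * c((1 - 5) / (3 - 5), (3 - 5) / (3 - 5), 0))
  expect_equal(got[1], 4)  # sparse neuron amplified
  expect_equal(got[2], 2)  # mean density leaves u unchanged
  expect_equal(got[3], 0)  # max density suppressed
  expect_warning(res <- u_star_matrix(u, c(2, 2, 2)), "uniform")
  expect_equal(res, u)
})
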