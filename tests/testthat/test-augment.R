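# one trained two-blob structure (unequal blob sizes) shared by the
# augmentation tests
.blobs <- two_blob_data(n_per = c(60, 25), seed = 21)
.s <- blob_structure(.blobs, seed = 22)
.assign <- extract_clusters(.s$ustar, .s$bmus, .s$model)

test_that("addition arithmetic reaches the largest cluster exactly", {
  expect_equal(unname(plan_additions(c(17, 2, 1, 7, 53))),
               c(36L, 51L, 52L, 46L, 0L))
  expect_equal(unname(plan_additions(c(17, 2, 1, 7, 53), target_size = 53)),
               c(36L, 51L, 52L, 46L, 0L))
  expect_equal(sum(plan_additions(c(17, 2, 1, 7, 53)) + c(17, 2, 1, 7, 53)),
               5 * 53)
  expect_equal(unname(plan_additions(c(5, 5))), c(0L, 0L))
})

test_that("requesting zero cases returns an empty result", {
  out <- generate_cases(.s$model, .s$p, .assign, .blobs$data,
                        cluster_id = 1, n_new = 0)
  expect_equal(nrow(out), 0)
  expect_true(all(c("seed_row", "accepting_neuron", "acceptance_prob") %in%
                    names(out)))
})

test_that("accepted cases stay inside the seed cluster's basin and ranges", {
  proper <- which(!grepl("outlier", names(.assign$sizes)))
  expect_gte(length(proper), 2)
  lab <- proper[which.min(.assign$sizes[proper])]  # smallest real cluster
  out <- generate_cases(.s$model, .s$p, .assign, .blobs$data,
                        cluster_id = lab, n_new = 30,
                        plan = augmentation_plan(seed = 5))
  expect_equal(nrow(out), 30)
  basins <- .assign$neuron_basin[out$accepting_neuron]
  expect_true(all(basins == lab))
  rng <- apply(.blobs$data, 2, range)
  for (j in 1:4) {
    expect_true(all(out[[j]] >= rng[1, j] & out[[j]] <= rng[2, j]))
  }
  # generated cases resemble their cluster: nearest original neighbor
  # belongs to the seed cluster for >= 95%
  gen <- as.matrix(out[, 1:4])
  nn_cluster <- apply(gen, 1, function(g) {
    .assign$cluster[which.min(colSums((t(.blobs$data) - g)^2))]
  })
  expect_gte(mean(nn_cluster == lab), 0.95)
})

test_that("generation density follows the P-matrix over occupied neurons", {
  # size-proportional generation from each cluster; the generated cases'
  # hypersphere density (the same estimator as the P-matrix) must track the
  # observed data density
  proper <- which(!grepl("outlier", names(.assign$sizes)))
  gen <- NULL
  for (lab in proper) {
    out <- generate_cases(.s$model, .s$p, .assign, .blobs$data,
                          cluster_id = lab, n_new = 6 * .assign$sizes[[lab]],
                          plan = augmentation_plan(seed = 6))
    gen <- rbind(gen, as.matrix(out[, 1:4]))
  }
  occupied <- sort(unique(.s$bmus))
  p_gen <- p_matrix(.s$model, gen, .s$radius)
  rho <- cor(p_gen[occupied], .s$p[occupied], method = "spearman")
  expect_gte(rho, 0.5)
})

test_that("vanishing bandwidth reduces generation to seed resampling", {
  lab <- as.integer(names(which.max(table(.assign$cluster))))
  out <- generate_cases(.s$model, .s$p, .assign, .blobs$data,
                        cluster_id = lab, n_new = 20,
                        plan = augmentation_plan(sigma = 1e-9, seed = 7))
  dev <- sapply(seq_len(nrow(out)), function(i) {
    max(abs(as.numeric(out[i, 1:4]) - .blobs$data[out$seed_row[i], ]))
  })
  expect_lt(max(dev), 1e-6)
})

test_that("equalization grows every cluster to the target and flags provenance", {
  eq <- equalize_clusters(.s$model, .s$p, .assign, .blobs$data,
                          augmentation_plan(seed = 8))
  target <- max(table(.assign$cluster))
  expect_true(all(table(eq$cluster) == target))
  expect_equal(sum(!eq$is_synthetic), nrow(.blobs$data))
  expect_equal(eq$data[!eq$is_synthetic, ], .blobs$data, ignore_attr = TRUE)
  expect_equal(unname(eq$additions[which.max(table(.assign$cluster))]), 0L)
})

test_that("impossible acceptance reports the failure rate", {
  # a basin-less target: demand cases for a cluster whose basin the
  # perturbation cannot reach by using an enormous bandwidth and a tiny budget
  lab <- as.integer(names(which.min(table(.assign$cluster))))
  expect_error(
    generate_cases(.s$model, .s$p, .assign, .blobs$data, cluster_id = lab,
                   n_new = 5,
                   plan = augmentation_plan(sigma = 500,
                                            max_attempts_per_case = 2,
                                            seed = 9)),
    "acceptance rate")
})
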