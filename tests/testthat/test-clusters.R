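test_that("identical patients collapse into a single cluster without outliers", {
  x <- matrix(rep(c(10, 20, 30, 40), each = 25), ncol = 4)
  model <- train_esom(x, esom_config(rows = 8, cols = 12, epochs = 3, seed = 3),
                      init_ranges = cbind(rep(0, 4), rep(100, 4)))
  bmus <- assign_bmus(model, x)
  u <- u_matrix(model)
  a <- extract_clusters(u, bmus, model)
  expect_equal(length(unique(a$cluster)), 1)
  expect_false(any(a$is_outlier))
  expect_equal(unname(a$sizes), 25)
  expect_equal(sum(a$sizes), nrow(x))
})

test_that("two separated blobs are recovered with high agreement", {
  skip_if_not_installed("mclust")
  for (seed in 1:5) {
    blobs <- two_blob_data(n_per = 60, seed = seed)
    s <- blob_structure(blobs, seed = seed + 50)
    a <- extract_clusters(s$ustar, s$bmus, s$model)
    ari <- mclust::adjustedRandIndex(a$cluster, blobs$labels)
    expect_gte(ari, 0.9)
  }
})

test_that("a planted far-away pair is flagged as an outlier group", {
  blobs <- two_blob_data(n_per = 40, seed = 9)
  far <- rbind(c(95, 0, 95, 0), c(96, 1, 96, 1))
  x <- rbind(blobs$data, far)
  model <- train_esom(x, esom_config(rows = 20, cols = 30, epochs = 10, seed = 60))
  bmus <- assign_bmus(model, x)
  r <- pareto_radius(x)
  ustar <- u_star_matrix(u_matrix(model), p_matrix(model, x, r))
  a <- extract_clusters(ustar, bmus, model)
  pair <- a$cluster[81:82]
  expect_equal(pair[1], pair[2])
  expect_true(all(a$is_outlier[81:82]))
  expect_equal(sum(a$cluster == pair[1]), 2)
})

test_that("cluster-stage association reproduces hand-computed chi-square", {
  # 10 + 10 patients in two pure clusters: table [[10,0],[0,10]]
  assignment <- structure(list(
    cluster = rep(1:2, each = 10),
    is_outlier = rep(FALSE, 20),
    sizes = c(cluster_1 = 10L, cluster_2 = 10L)
  ), class = "cluster_assignment")
  stages <- rep(c("remission", "low"), each = 10)
  res <- cluster_stage_association(assignment, stages)
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1)

  # proportionally identical rows are independent: chi-square 0
  stages_prop <- rep(c("remission", "low"), times = 10)
  res0 <- cluster_stage_association(assignment, stages_prop)
  expect_equal(res0$statistic, 0, tolerance = 1e-12)

  # 3 x 3 table: df = 4
  a3 <- structure(list(
    cluster = rep(1:3, each = 9),
    is_outlier = rep(FALSE, 27),
    sizes = c(cluster_1 = 9L, cluster_2 = 9L, cluster_3 = 9L)
  ), class = "cluster_assignment")
  st3 <- c(rep(c("remission", "low", "moderate"), 3),
           rep(c("low", "moderate", "remission"), 3),
           rep(c("moderate", "remission", "low"), 3))
  expect_equal(cluster_stage_association(a3, st3)$df, 4)
})

test_that("clusters below the membership floor are excluded from the test", {
  assignment <- structure(list(
    cluster = c(rep(1, 10), rep(2, 10), rep(3, 2)),
    is_outlier = c(rep(FALSE, 20), TRUE, TRUE),
    sizes = c(cluster_1 = 10L, cluster_2 = 10L, outlier_group_3 = 2L)
  ), class = "cluster_assignment")
  stages <- c(rep("remission", 10), rep("low", 10), "moderate", "moderate")
  res <- cluster_stage_association(assignment, stages)
  expect_equal(dim(res$table), c(2L, 2L))  # outlier pair and its stage dropped
  expect_equal(res$statistic, 20)

  single <- structure(list(cluster = rep(1, 10), is_outlier = rep(FALSE, 10),
                           sizes = c(cluster_1 = 10L)),
                      class = "cluster_assignment")
  expect_error(cluster_stage_association(single, rep(c("a", "b"), 5)),
               "degenerate")
})
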