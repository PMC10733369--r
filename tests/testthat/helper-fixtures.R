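# Shared fixtures, all generated in code under fixed seeds.

# Two well-separated 4-D Gaussian blobs; returns data, true labels.
# n_per may be one shared size or one size per blob.
two_blob_data <- function(n_per = 60, sep = 60, sd = 4, seed = 1) {
  set.seed(seed)
  n_per <- rep_len(n_per, 2)
  centers <- rbind(c(20, 20, 20, 20), c(20 + sep, 20 + sep, 20, 20))
  x <- rbind(
    matrix(stats::rnorm(n_per[1] * 4, 0, sd), ncol = 4) +
      matrix(centers[1, ], n_per[1], 4, byrow = TRUE),
    matrix(stats::rnorm(n_per[2] * 4, 0, sd), ncol = 4) +
      matrix(centers[2, ], n_per[2], 4, byrow = TRUE)
  )
  list(data = x, labels = rep(1:2, times = n_per))
}

# Train a small map + structure matrices on the blob data.
blob_structure <- function(blobs, rows = 20, cols = 30, epochs = 10, seed = 2) {
  model <- train_esom(blobs$data,
                      esom_config(rows = rows, cols = cols, epochs = epochs,
                                  seed = seed))
  bmus <- assign_bmus(model, blobs$data)
  r <- pareto_radius(blobs$data)
  u <- u_matrix(model)
  p <- p_matrix(model, blobs$data, r)
  ustar <- u_star_matrix(u, p)
  list(model = model, bmus = bmus, radius = r, u = u, p = p, ustar = ustar)
}

# A tiny one-row cohort with explicit flags, for scoring checks.
one_record_cohort <- function(tender_joints = character(0),
                              swollen_joints = character(0),
                              crp = 0, gh = 0) {
  flags <- setNames(as.list(rep(0L, 56)), c(tender_columns(), swollen_columns()))
  flags[paste0("tender_", tender_joints)] <- 1L
  flags[paste0("swollen_", swollen_joints)] <- 1L
  cbind(data.frame(patient_id = "X1", stringsAsFactors = FALSE),
        as.data.frame(flags),
        data.frame(crp_mg_l = crp, gh_mm = gh))
}
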