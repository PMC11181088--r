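test_that("pose generator is seed-stable and respects its construction", {
  g1 <- generate_poses(6, jitter_sd = 0.1, seed = 171)
  g2 <- generate_poses(6, jitter_sd = 0.1, seed = 171)
  expect_identical(g1, g2)
  # zero jitter: all canonical poses identical, view-independent RDM zero
  g0 <- generate_poses(5, jitter_sd = 0, seed = 172)
  vi <- build_model_rdm(g0$poses, "view_indep_3d")
  expect_lt(max(vi$values), 1e-9)
  # alignment recovers the canonical poses
  for (i in seq_along(g1$poses)) {
    expect_lt(max(abs(align_view_independent(g1$poses[[i]]) -
                        g1$canonical[[i]])), 1e-9)
  }
})

test_that("keypoint generator plants an exact qualifying count", {
  recs <- generate_keypoint_records(10, fraction_valid = 0.3, seed = 181)
  ids <- filter_single_full_person(recs)
  expect_length(ids, 3)
  expect_identical(sort(ids), attr(recs, "valid_ids"))
  all_good <- generate_keypoint_records(7, fraction_valid = 1, seed = 182)
  expect_length(filter_single_full_person(all_good), 7)
  none <- generate_keypoint_records(7, fraction_valid = 0, seed = 183)
  expect_length(filter_single_full_person(none), 0)
})

test_that("response generator reproduces the target geometry and seed", {
  r1 <- random_rdm(20, seed = 191)
  r2 <- random_rdm(20, seed = 192)
  out <- generate_responses(list(r1, r2), c(0.7, 0.3),
                            synthetic_config(n_voxels = 120, n_repeats = 3,
                                             noise_sd = 0.2, seed = 193))
  expect_gte(out$geometry$realized_correlation, 0.95)
  expect_equal(dim(out$dataset$betas), c(60, 120))
  out2 <- generate_responses(list(r1, r2), c(0.7, 0.3),
                             synthetic_config(n_voxels = 120, n_repeats = 3,
                                              noise_sd = 0.2, seed = 193))
  expect_identical(out$dataset$betas, out2$dataset$betas)
  expect_error(generate_responses(list(r1), 0, synthetic_config()),
               "zero")
})

test_that("zero-weight models read out near zero on planted data", {
  set.seed(201)
  n <- 60
  ids <- sprintf("img%04d", 1:n)
  m <- n * (n - 1) / 2
  basis <- qr.Q(qr(cbind(1, matrix(stats::rnorm(m * 2), m))))[, -1]
  mk <- function(v) {
    t_ <- v - min(v) + 0.05
    mat <- matrix(0, n, n); mat[lower.tri(mat)] <- t_
    rdm(mat + t(mat), ids)
  }
  ra <- mk(basis[, 1]); rb <- mk(basis[, 2])
  out <- generate_responses(list(ra, rb), c(1, 0),
                            synthetic_config(n_voxels = 300, n_repeats = 2,
                                             noise_sd = 0, seed = 202))
  nr <- neural_rdm(prepare_patterns(out$dataset))
  expect_gte(rsa_correlation(nr, normalize_rdm(ra)), 0.99)
  expect_lt(abs(rsa_correlation(nr, normalize_rdm(rb))), 0.1)
})

test_that("subject map generator places the blob and is exchangeable", {
  st <- generate_subject_maps(6, c(10, 10, 10),
                              blob = list(center = c(5, 5, 5), radius = 2,
                                          amplitude = 3),
                              noise_sd = 0.5, seed = 211)
  expect_equal(nrow(st$data), 6)
  means <- colMeans(st$data)
  blobvox <- means[array(seq_len(1000), c(10, 10, 10))[5, 5, 5]]
  expect_gt(blobvox, 2)
  # null maps have near-zero mean t over many voxels
  st0 <- generate_subject_maps(8, c(22, 22, 22), blob = NULL, noise_sd = 1,
                               seed = 212)
  tm <- group_t_map(st0)
  expect_lt(abs(mean(tm$volume, na.rm = TRUE)), 0.05)
})

test_that("pose RDM entanglement mirrors natural view dependence", {
  g <- generate_poses(40, seed = 221)
  r2d <- build_model_rdm(g$poses, "view_dep_2d")
  r3d <- build_model_rdm(g$poses, "view_dep_3d")
  rvi <- build_model_rdm(g$poses, "view_indep_3d")
  rvp <- build_model_rdm(g$poses, "viewpoint")
  c_2d_3d <- cor(rdm_triangle(r2d), rdm_triangle(r3d))
  c_vi_vp <- cor(rdm_triangle(rvi), rdm_triangle(rvp))
  expect_gt(c_2d_3d, c_vi_vp)
})
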