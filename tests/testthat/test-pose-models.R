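test_that("rotation matrix <-> quaternion conversion is exact and canonical", {
  expect_equal(as.numeric(rotation_matrix_to_quaternion(diag(3))),
               c(1, 0, 0, 0))
  # half-angle closed form: 90 deg about z -> (cos 45, 0, 0, sin 45)
  q <- rotation_matrix_to_quaternion(rot_z(pi / 2))
  expect_equal(as.numeric(q), c(sqrt(2) / 2, 0, 0, sqrt(2) / 2),
               tolerance = 1e-12)
  # round trip over random rotations, including near-pi angles where the
  # trace-based branch is ill-conditioned
  set.seed(1)
  for (i in 1:50) {
    R <- quaternion_to_rotation_matrix(random_rotations(1)[[1]])
    q <- rotation_matrix_to_quaternion(R)
    expect_lt(max(abs(quaternion_to_rotation_matrix(q) - R)), 1e-8)
    expect_gte(q[1], 0)
  }
  R_pi <- rot_x(pi)
  q <- rotation_matrix_to_quaternion(R_pi)
  expect_lt(max(abs(quaternion_to_rotation_matrix(q) - R_pi)), 1e-8)
  expect_error(rotation_matrix_to_quaternion(matrix(1:9 / 10, 3)),
               "orthonormal")
  expect_error(rotation_matrix_to_quaternion(diag(c(1, 1, -1))),
               "determinant")
})

test_that("2D projection drops depth and nothing else", {
  j <- template_skeleton()
  p <- make_pose(joints = j)
  expect_identical(project_to_2d(p), j[, 1:2])
  j2 <- j; j2[, 3] <- j2[, 3] + stats::runif(19)
  expect_identical(project_to_2d(make_pose(joints = j2)), j[, 1:2])
})

test_that("view-independent alignment inverts the global rotation", {
  P <- template_skeleton()
  expect_equal(align_view_independent(make_pose(joints = P)), P)
  set.seed(7)
  for (i in 1:10) {
    R <- quaternion_to_rotation_matrix(random_rotations(1)[[1]])
    rec <- make_pose(joints = P %*% t(R), R = R)
    expect_lt(max(abs(align_view_independent(rec) - P)), 1e-9)
  }
})

test_that("MPJPE matches hand computations and rejects shape mismatch", {
  a <- template_skeleton()
  expect_identical(mean_per_joint_distance(a, a), 0)
  expect_equal(mean_per_joint_distance(a, a + rep(c(3, 4, 0), each = 19)), 5)
  x <- matrix(0, 2, 3)
  y <- rbind(c(1, 0, 0), c(0, 2, 0))
  expect_equal(mean_per_joint_distance(x, y), 1.5)
  expect_error(mean_per_joint_distance(a, a[, 1:2]), "dimensions")
})

test_that("viewpoint distance is the double-cover-safe quaternion angle", {
  qi <- quaternion(1, 0, 0, 0)
  expect_equal(viewpoint_distance(qi, qi), 0)
  expect_equal(viewpoint_distance(qi, quaternion(-1, 0, 0, 0)), 0)
  expect_equal(viewpoint_distance(qi, quaternion(0, 0, 0, 1)), pi / 2)
  expect_error(viewpoint_distance(c(1, 0, 0, 0.5), qi), "unit")
})

test_that("joint rotation distance averages per-joint angles, sign-invariantly", {
  qi <- quaternion(1, 0, 0, 0)
  qz <- quaternion(0, 0, 0, 1)
  expect_equal(joint_rotation_distance(list(qi, qi), list(qi, qi)), 0)
  expect_equal(joint_rotation_distance(list(qi, qi), list(qi, qz)), pi / 4)
  set.seed(3)
  Qa <- random_rotations(5); Qb <- random_rotations(5)
  flipped <- Qb
  flipped[[2]] <- structure(-unclass(flipped[[2]]), class = "quaternion")
  expect_equal(joint_rotation_distance(Qa, Qb),
               joint_rotation_distance(Qa, flipped))
  expect_error(joint_rotation_distance(Qa, Qb[1:3]), "length")
})

test_that("distance metrics satisfy the metric axioms on random triples", {
  set.seed(42)
  n_tri <- 1000
  for (i in seq_len(n_tri)) {
    a <- matrix(stats::rnorm(9), 3); b <- matrix(stats::rnorm(9), 3)
    c_ <- matrix(stats::rnorm(9), 3)
    dab <- mean_per_joint_distance(a, b)
    dbc <- mean_per_joint_distance(b, c_)
    dac <- mean_per_joint_distance(a, c_)
    expect_true(dab >= 0 && abs(dab - mean_per_joint_distance(b, a)) < 1e-12)
    expect_lte(dac, dab + dbc + 1e-12)
  }
  qs <- random_rotations(3 * n_tri)
  for (i in seq_len(n_tri)) {
    qa <- qs[[3 * i - 2]]; qb <- qs[[3 * i - 1]]; qc <- qs[[3 * i]]
    dab <- viewpoint_distance(qa, qb)
    dbc <- viewpoint_distance(qb, qc)
    dac <- viewpoint_distance(qa, qc)
    expect_true(dab >= 0 && dab <= pi / 2 + 1e-12)
    expect_equal(dab, viewpoint_distance(qb, qa))
    expect_lte(dac, dab + dbc + 1e-9)
  }
})

test_that("model RDMs have the required structure and view-independence", {
  g <- generate_poses(8, jitter_sd = 0.1, seed = 11)
  for (m in c("view_dep_3d", "view_dep_2d", "view_indep_3d", "viewpoint",
              "joint_rotation")) {
    r <- build_model_rdm(g$poses, m)
    expect_s3_class(r, "rdm")
    expect_equal(r$values, t(r$values))
    expect_true(all(diag(r$values) == 0))
    expect_true(all(r$values >= 0))
  }
  # same canonical poses, different rotations: view-independent RDM zero,
  # view-dependent strictly positive off-diagonal
  P <- g$canonical[[1]]
  set.seed(5)
  same <- lapply(1:4, function(i) {
    R <- quaternion_to_rotation_matrix(random_rotations(1)[[1]])
    pose_record(paste0("p", i), P %*% t(R), R)
  })
  vi <- build_model_rdm(same, "view_indep_3d")
  vd <- build_model_rdm(same, "view_dep_3d")
  expect_lt(max(vi$values), 1e-9)
  expect_true(all(vd$values[lower.tri(vd$values)] > 0))
  # identical poses give all-zero RDMs
  two <- list(make_pose("x", P), make_pose("y", P))
  expect_equal(build_model_rdm(two, "view_dep_3d")$values, matrix(0, 2, 2),
               ignore_attr = TRUE)
  expect_error(build_model_rdm(list(make_pose("x", P), make_pose("x", P)),
                               "view_dep_3d"), "duplicate")
  nojr <- list(make_pose("x", P), make_pose("y", P))
  expect_error(build_model_rdm(nojr, "joint_rotation"), "joint rotation")
})

test_that("projection consistency: 2D model RDM equals MPJPE on xy slices", {
  g <- generate_poses(6, seed = 13)
  r2d <- build_model_rdm(g$poses, "view_dep_2d")
  direct <- outer(seq_along(g$poses), seq_along(g$poses),
                  Vectorize(function(i, j)
                    mean_per_joint_distance(g$poses[[i]]$joints3d[, 1:2],
                                            g$poses[[j]]$joints3d[, 1:2])))
  expect_equal(unname(r2d$values), direct)
})

test_that("RDM normalization maps off-diagonal to [0,1] and preserves ranks", {
  v <- matrix(0, 3, 3)
  v[lower.tri(v)] <- c(0, 2, 4); v <- v + t(v)
  r <- normalize_rdm(rdm(v, c("a", "b", "c")))
  expect_equal(sort(r$values[lower.tri(r$values)]), c(0, 0.5, 1))
  expect_true(r$normalized)
  r2 <- normalize_rdm(r)
  expect_equal(r2$values, r$values)
  rr <- random_rdm(12, seed = 9)
  rn <- normalize_rdm(rr)
  expect_equal(rank(rdm_triangle(rr)), rank(rdm_triangle(rn)))
  flat <- matrix(1, 4, 4); diag(flat) <- 0
  expect_error(normalize_rdm(rdm(flat, letters[1:4])), "degenerate")
})

test_that("re-rotating poses changes view-dependent RDMs only", {
  g <- generate_poses(10, seed = 21)
  set.seed(99)
  rerotated <- Map(function(P, i) {
    R <- quaternion_to_rotation_matrix(random_rotations(1)[[1]])
    pose_record(sprintf("img%04d", i), P %*% t(R), R)
  }, g$canonical, seq_along(g$canonical))
  vi_a <- build_model_rdm(g$poses, "view_indep_3d")
  vi_b <- build_model_rdm(rerotated, "view_indep_3d")
  expect_lt(max(abs(vi_a$values - vi_b$values)), 1e-9)
  for (m in c("view_dep_3d", "view_dep_2d", "viewpoint")) {
    a <- build_model_rdm(g$poses, m)
    b <- build_model_rdm(rerotated, m)
    expect_gt(max(abs(a$values - b$values)), 1e-6)
  }
})
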