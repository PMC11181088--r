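make_kp_record <- function(id, n_persons = 1, missing_limbs = character(0),
                           bbox = c(100, 100, 200, 300), area = 3e4,
                           width = 640, height = 480) {
  person <- function() {
    kp <- cbind(stats::runif(17, 0, width), stats::runif(17, 0, height),
                rep(2, 17))
    rownames(kp) <- poseRSA:::coco_keypoint_labels()
    kp[missing_limbs, 3] <- 0
    list(keypoints = kp, bbox = bbox, segmentation_area = area)
  }
  keypoint_record(id, replicate(n_persons, person(), simplify = FALSE),
                  width, height)
}

test_that("single-full-person filter applies the 12-limb rule", {
  set.seed(2)
  recs <- list(
    make_kp_record("a"),                                   # qualifies
    make_kp_record("b", missing_limbs = "left_ankle"),     # 11 of 12
    make_kp_record("c", n_persons = 2),                    # two persons
    make_kp_record("d"),                                   # qualifies
    make_kp_record("e", missing_limbs = c("left_hip", "right_wrist")))
  expect_identical(filter_single_full_person(recs), c("a", "d"))
  # face keypoints are ignored
  r <- make_kp_record("f")
  r$persons[[1]]$keypoints[c("nose", "left_eye", "right_ear"), 3] <- 0
  expect_identical(filter_single_full_person(list(r)), "f")
  # occluded-but-annotated (flag 1) counts as annotated
  r2 <- make_kp_record("g")
  r2$persons[[1]]$keypoints[poseRSA:::coco_limb_labels(), 3] <- 1
  expect_identical(filter_single_full_person(list(r2)), "g")
  # idempotent and order-insensitive
  expect_identical(filter_single_full_person(rev(recs)), c("d", "a"))
  expect_identical(filter_single_full_person(recs[c(1, 4)]), c("a", "d"))
})

test_that("body geometry uses polar coordinates about the image center", {
  set.seed(3)
  r <- make_kp_record("a", bbox = c(320 - 50, 240 - 80, 100, 160), area = 640 * 480 / 2)
  g <- body_geometry(r)
  expect_equal(g$polar_distance, 0)
  expect_equal(g$polar_angle, 0)
  expect_equal(g$relative_size, 0.5)
  r2 <- make_kp_record("b", bbox = c(320 + 10 - 50, 240 - 80, 100, 160))
  g2 <- body_geometry(r2)
  expect_equal(g2$polar_distance, 10)
  expect_equal(g2$polar_angle, 0)
  expect_error(body_geometry(make_kp_record("c", n_persons = 2)),
               "exactly one")
  bad <- make_kp_record("d")
  expect_error(body_geometry(bad, width = 0), "area")
})

test_that("geometry control RDMs wrap angles and difference scalars", {
  set.seed(4)
  geoms <- list(
    list(image_id = "a", polar_angle = 170 * pi / 180, polar_distance = 5,
         relative_size = 0.2),
    list(image_id = "b", polar_angle = -170 * pi / 180, polar_distance = 8,
         relative_size = 0.5))
  ang <- build_control_rdm(geoms, "polar_angle")
  expect_equal(ang$values[1, 2], 20 * pi / 180, tolerance = 1e-12)
  expect_equal(build_control_rdm(geoms, "polar_distance")$values[1, 2], 3)
  expect_equal(build_control_rdm(geoms, "body_size")$values[1, 2], 0.3)
  # invariant to adding 2*pi, bounded by pi
  geoms2 <- geoms
  geoms2[[1]]$polar_angle <- geoms2[[1]]$polar_angle + 2 * pi
  expect_equal(build_control_rdm(geoms2, "polar_angle")$values,
               ang$values)
  set.seed(8)
  many <- lapply(1:20, function(i)
    list(image_id = paste0("i", i),
         polar_angle = stats::runif(1, -pi, pi),
         polar_distance = stats::runif(1, 0, 100),
         relative_size = stats::runif(1)))
  m <- build_control_rdm(many, "polar_angle")
  expect_lte(max(m$values), pi)
})

test_that("embedding control RDMs follow their distance definitions", {
  set.seed(5)
  X <- matrix(stats::rnorm(40), 4)
  emb <- list(item_ids = letters[1:4], vectors = X)
  r1 <- build_control_rdm(emb, "embedding_one_minus_corr")
  expect_equal(unname(r1$values), unname(1 - stats::cor(t(X))))
  expect_true(all(r1$values >= 0 & r1$values <= 2))
  # identical embeddings -> 0; positive scaling leaves 1-corr unchanged
  emb2 <- emb; emb2$vectors[2, ] <- 3.7 * emb2$vectors[1, ]
  r2 <- build_control_rdm(emb2, "embedding_one_minus_corr")
  expect_equal(r2$values[1, 2], 0, tolerance = 1e-12)
  scaled <- emb; scaled$vectors <- emb$vectors * 5
  expect_equal(build_control_rdm(scaled, "embedding_one_minus_corr")$values,
               r1$values)
  # euclidean kind works on unit-normalized vectors
  r3 <- build_control_rdm(emb, "embedding_euclidean")
  u <- X / sqrt(rowSums(X^2))
  expect_equal(unname(r3$values), unname(as.matrix(stats::dist(u))))
  const <- emb; const$vectors[3, ] <- 2
  expect_error(build_control_rdm(const, "embedding_one_minus_corr"), "c")
})

test_that("COCO round trip preserves records and the filter result", {
  recs <- generate_keypoint_records(12, fraction_valid = 0.5, seed = 6)
  path <- tempfile(fileext = ".json")
  write_coco_json(recs, path)
  back <- read_coco_json(path)
  expect_equal(length(back), length(recs))
  expect_identical(filter_single_full_person(back),
                   filter_single_full_person(recs))
  expect_equal(back[[1]]$persons[[1]]$keypoints,
               recs[[1]]$persons[[1]]$keypoints, ignore_attr = TRUE)
})
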