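# Synthetic inputs for every pipeline stage: articulated poses under random
# viewpoints, COCO-style keypoint records, voxel responses with planted
# representational geometry, and subject map stacks for group inference.

#' Canonical template skeleton
#'
#' A standing figure (units roughly meters, y up, z toward the viewer);
#' proportions are fixed in code — only relative geometry matters to every
#' dissimilarity metric.
#'
#' @return 19 x 3 matrix with canonical joint labels.
#' @export
template_skeleton <- function() {
  m <- rbind(
    left_ankle     = c(-0.15, 0.08, 0.00),
    right_ankle    = c( 0.15, 0.08, 0.00),
    left_knee      = c(-0.16, 0.50, 0.02),
    right_knee     = c( 0.16, 0.50, 0.02),
    left_hip       = c(-0.17, 0.95, 0.00),
    right_hip      = c( 0.17, 0.95, 0.00),
    left_wrist     = c(-0.55, 1.00, 0.10),
    right_wrist    = c( 0.55, 1.00, 0.10),
    left_elbow     = c(-0.40, 1.22, 0.05),
    right_elbow    = c( 0.40, 1.22, 0.05),
    left_shoulder  = c(-0.20, 1.45, 0.00),
    right_shoulder = c( 0.20, 1.45, 0.00),
    neck           = c( 0.00, 1.50, 0.00),
    head           = c( 0.00, 1.68, 0.00),
    nose           = c( 0.00, 1.62, 0.10),
    left_eye       = c(-0.03, 1.65, 0.09),
    right_eye      = c( 0.03, 1.65, 0.09),
    left_ear       = c(-0.07, 1.63, 0.02),
    right_ear      = c( 0.07, 1.63, 0.02))
  m[pose_joint_labels(), ]
}

#' Generate synthetic poses under random viewpoints
#'
#' Perturbs the template skeleton per image with Gaussian joint jitter to
#' form canonical poses `P`, draws a uniform random global rotation `R`
#' (normalized 4D Gaussian quaternion, exactly uniform on the rotation
#' group), and stores `joints3d = R P` with `global_rotation = R`.
#' Per-joint rotations are sampled near the identity.
#'
#' @param n Number of poses (>= 2).
#' @param jitter_sd Joint jitter SD in skeleton units (default 0.1, about
#'   10 cm of natural articulation per coordinate).
#' @param seed Integer seed.
#' @return List with `poses` (list of [pose_record()]s) and `canonical`
#'   (list of the unrotated 19 x 3 pose matrices).
#' @export
generate_poses <- function(n, jitter_sd = 0.1, seed = 1L) {
  stopifnot(n >= 2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  tmpl <- template_skeleton()
  labels <- pose_joint_labels()
  canonical <- vector("list", n)
  poses <- vector("list", n)
  for (i in seq_len(n)) {
    P <- tmpl + matrix(stats::rnorm(length(tmpl), sd = jitter_sd),
                       nrow(tmpl), ncol(tmpl))
    q <- stats::rnorm(4)
    q <- quaternion(q[1], q[2], q[3], q[4])
    R <- quaternion_to_rotation_matrix(q)
    jr <- stats::setNames(lapply(labels, function(l) {
      e <- stats::rnorm(3, sd = 0.1)
      quaternion(1, e[1], e[2], e[3])
    }), labels)
    canonical[[i]] <- P
    poses[[i]] <- pose_record(sprintf("img%04d", i), P %*% t(R), R, jr)
  }
  list(poses = poses, canonical = canonical)
}

#' Generate COCO-style keypoint records with a known qualifying subset
#'
#' Exactly `round(n * fraction_valid)` records qualify under
#' [filter_single_full_person()]; the remainder violate it by a randomized
#' mechanism (a second annotated person, a missing limb flag, or boundary
#' truncation dropping several limb annotations).
#'
#' @param n Number of images.
#' @param fraction_valid Fraction qualifying, in `[0, 1]`.
#' @param seed Integer seed.
#' @param width,height Image size in pixels.
#' @return List of [keypoint_record()]s with attribute `valid_ids` naming
#'   the qualifying images.
#' @export
generate_keypoint_records <- function(n, fraction_valid = 0.5, seed = 1L,
                                      width = 640, height = 480) {
  stopifnot(fraction_valid >= 0, fraction_valid <= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_valid <- round(n * fraction_valid)
  valid_slots <- sample(n, n_valid)
  labels <- coco_keypoint_labels()
  limb <- coco_limb_labels()

  random_person <- function(full = TRUE) {
    bw <- stats::runif(1, 80, 300); bh <- stats::runif(1, 120, 400)
    bx <- stats::runif(1, 0, width - bw); by <- stats::runif(1, 0, height - bh)
    kp <- cbind(stats::runif(17, bx, bx + bw),
                stats::runif(17, by, by + bh),
                sample(1:2, 17, replace = TRUE))
    rownames(kp) <- labels
    kp[c("nose", "left_eye", "right_eye"), 3] <-
      sample(0:2, 3, replace = TRUE) # face flags free to be absent
    if (!full) kp[sample(limb, 1), 3] <- 0
    list(keypoints = kp, bbox = c(bx, by, bw, bh),
         segmentation_area = 0.55 * bw * bh)
  }

  records <- vector("list", n)
  for (i in seq_len(n)) {
    id <- sprintf("img%04d", i)
    if (i %in% valid_slots) {
      persons <- list(random_person(full = TRUE))
    } else {
      mech <- sample(c("extra_person", "missing_flag", "truncated"), 1)
      persons <- switch(mech,
        extra_person = list(random_person(TRUE), random_person(TRUE)),
        missing_flag = list(random_person(FALSE)),
        truncated = {
          p <- random_person(TRUE)
          out <- sample(limb, 3)
          p$keypoints[out, 3] <- 0
          p$bbox[1] <- 0 # pushed against the image boundary
          list(p)
        })
    }
    records[[i]] <- keypoint_record(id, persons, width, height)
  }
  attr(records, "valid_ids") <- sprintf("img%04d", sort(valid_slots))
  records
}

#' Synthetic response configuration
#'
#' @param n_voxels Number of voxels (ignored when `mask` is given).
#' @param n_repeats Trials per image.
#' @param noise_sd Isotropic trial noise SD, in units of the (unit)
#'   per-voxel signal SD.
#' @param seed Integer seed.
#' @param mask Optional logical 3D array for the volumetric variant.
#' @param signal_region Optional logical 3D array (subset of `mask`)
#'   holding the signal voxels; elsewhere pure noise.
#' @param voxel_size_mm Voxel size for the volumetric variant.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_voxels = 300L, n_repeats = 2L, noise_sd = 0.5,
                             seed = 1L, mask = NULL, signal_region = NULL,
                             voxel_size_mm = 1.8) {
  stopifnot(noise_sd >= 0, n_repeats >= 1)
  if (!is.null(signal_region) && is.null(mask)) {
    stop("signal_region requires a mask", call. = FALSE)
  }
  if (!is.null(signal_region) && any(signal_region & !mask)) {
    stop("signal_region must lie inside the mask", call. = FALSE)
  }
  structure(list(n_voxels = n_voxels, n_repeats = n_repeats,
                 noise_sd = noise_sd, seed = seed, mask = mask,
                 signal_region = signal_region,
                 voxel_size_mm = voxel_size_mm),
            class = "synthetic_config")
}

# Equalize column sums of squares by Givens rotations; rotations act on the
# right, so the row Gram (the planted item geometry) is untouched.
equalize_column_variance <- function(X, tol = 1e-11) {
  p <- ncol(X)
  v <- colSums(X^2); tgt <- mean(v)
  for (step in seq_len(3L * p)) {
    j <- which.max(v); k <- which.min(v)
    if (v[j] - v[k] < tol * tgt) break
    xj <- X[, j]; xk <- X[, k]
    A <- (v[j] - v[k]) / 2; B <- sum(xj * xk)
    rhs <- min(max((tgt - (v[j] + v[k]) / 2) / sqrt(A^2 + B^2), -1), 1)
    th <- (acos(rhs) + atan2(B, A)) / 2
    ct <- cos(th); st <- sin(th)
    nj <- ct * xj + st * xk; nk <- -st * xj + ct * xk
    X[, j] <- nj; X[, k] <- nk
    v[j] <- sum(nj^2); v[k] <- sum(nk^2)
  }
  X
}

# Item patterns whose pipeline readout (average, per-voxel z-score,
# 1-correlation) reproduces the target dissimilarity affinely.  The readout
# centers patterns across items, so the realizable item Gram G is centered;
# writing G = diag(s) C diag(s) with C the realized correlations forces C
# to carry a positive null vector s (the item pattern norms).  We therefore
# demean the target off-diagonals (Pearson is affine invariant), solve
# (1 - a) s + a n 1 = b D~ s for the norms s and mixing constant a, take b
# as large as positive semidefiniteness of C = (1-a) I + a J - b D~
# allows, and embed G in a voxel frame orthogonal to the constant vector.
# Givens rotations then equalize voxel variances (so z-scoring is a no-op)
# in alternation with row-centering and re-projection onto the exact Gram.
plant_patterns <- function(D, n_voxels, max_iters = 120L) {
  n <- nrow(D)
  if (n_voxels < n + 1L) {
    stop("need n_voxels > n_items to embed the planted geometry",
         call. = FALSE)
  }
  off <- D[lower.tri(D)]
  Dt <- D - mean(off); diag(Dt) <- 0
  s <- rep(1, n); a <- -1 / (n - 1); b <- 1; emin <- NA_real_
  for (bs in 1:60) {
    for (it in 1:400) {
      a <- (b * mean(Dt %*% s) - 1) / (n - 1)
      s_new <- as.vector((b * (Dt %*% s) - a * n) / (1 - a))
      s_new <- s_new / mean(s_new)
      if (max(abs(s_new - s)) < 1e-13) { s <- s_new; break }
      s <- s_new
    }
    C <- (1 - a) * diag(n) + a - b * Dt
    emin <- min(eigen(C, symmetric = TRUE, only.values = TRUE)$values)
    if (emin >= -1e-10 && all(s > 0)) break
    b <- b * 0.85
  }
  G <- diag(s) %*% C %*% diag(s)
  eg <- eigen(G, symmetric = TRUE)
  neg_mass <- sum(abs(pmin(eg$values, 0)))
  if (neg_mass > 0.1 * sum(abs(eg$values))) {
    warning(sprintf("target geometry is poorly embeddable (negative eigenvalue mass %.1f%%); clipped",
                    100 * neg_mass / sum(abs(eg$values))))
  }
  keep <- eg$values > eg$values[1] * 1e-12
  r <- sum(keep)
  U <- eg$vectors[, keep, drop = FALSE]
  Y <- U %*% diag(sqrt(eg$values[keep]), r)
  Ghalf <- U %*% diag(sqrt(eg$values[keep]), r) %*% t(U)
  Q <- qr.Q(qr(cbind(1, matrix(stats::rnorm(n_voxels * r), n_voxels))))
  X <- Y %*% t(Q[, 1 + seq_len(r), drop = FALSE])
  tri <- function(m) m[lower.tri(m)]
  for (it in seq_len(max_iters)) {
    X <- equalize_column_variance(X)
    X <- X - rowMeans(X)
    sv <- svd(Ghalf %*% X)
    X <- Ghalf %*% sv$u %*% t(sv$v)
    if (it %% 20L == 0L) {
      Z <- equalize_column_variance(X)
      real <- stats::cor(tri(1 - stats::cor(t(scale(Z)))), tri(D))
      if (real >= 0.998) break
    }
  }
  X <- equalize_column_variance(X)
  # unit per-voxel signal SD so noise_sd is on the signal scale
  X * sqrt(n_voxels * (n - 1) / sum(X^2))
}

#' Generate voxel responses with planted representational geometry
#'
#' The target dissimilarity is `sum(w_i * normalize(RDM_i))`; items are
#' embedded as voxel patterns whose correlation-distance geometry
#' reproduces it (affinely, hence with Pearson RSA r = 1 in the noiseless
#' limit), and each trial adds isotropic Gaussian noise.  With a mask and
#' signal region in the config, signal patterns occupy the region's voxels
#' and the rest of the mask carries pure noise.
#'
#' @param rdms List of [rdm()]s sharing item ids.
#' @param weights Nonnegative weights, one per RDM, not all zero.
#' @param config A [synthetic_config()].
#' @return List with `dataset` (a [neural_dataset()]) and `geometry` (a
#'   `planted_geometry`: target RDM, weights, item patterns, realized
#'   noiseless readout correlation, seed).
#' @export
generate_responses <- function(rdms, weights, config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"),
            length(rdms) == length(weights), all(weights >= 0))
  if (all(weights == 0)) stop("weights must not all be zero", call. = FALSE)
  ids <- rdms[[1]]$item_ids
  for (r_ in rdms) {
    if (!identical(r_$item_ids, ids)) {
      stop("all RDMs must share item_ids in the same order", call. = FALSE)
    }
  }
  n <- length(ids)
  D <- Reduce(`+`, Map(function(r_, w) w * normalize_rdm(r_)$values,
                       rdms, weights))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  volumetric <- !is.null(config$mask)
  if (volumetric) {
    vox <- which(config$mask, arr.ind = TRUE)
    o <- order(vox[, 1], vox[, 2], vox[, 3], method = "radix")
    vox <- vox[o, , drop = FALSE]
    n_vox <- nrow(vox)
    region <- if (is.null(config$signal_region)) config$mask
              else config$signal_region
    in_region <- region[vox]
    n_signal <- sum(in_region)
  } else {
    n_vox <- config$n_voxels
    n_signal <- n_vox
    in_region <- rep(TRUE, n_vox)
  }

  Xs <- plant_patterns(D, n_signal)
  X <- matrix(0, n, n_vox)
  X[, in_region] <- Xs

  tri <- function(m) m[lower.tri(m)]
  zs <- scale(Xs)
  realized <- stats::cor(tri(1 - stats::cor(t(zs))), tri(D))
  if (realized < 0.95) {
    warning(sprintf("planted geometry realized correlation %.3f < 0.95",
                    realized))
  }

  n_trials <- n * config$n_repeats
  trial_ids <- rep(ids, each = config$n_repeats)
  betas <- X[rep(seq_len(n), each = config$n_repeats), , drop = FALSE] +
    matrix(stats::rnorm(n_trials * n_vox, sd = config$noise_sd),
           n_trials, n_vox)

  dataset <- neural_dataset(betas, trial_ids,
                            voxel_index = if (volumetric) vox else NULL,
                            voxel_size_mm = config$voxel_size_mm,
                            mask = if (volumetric) config$mask else NULL)
  geometry <- structure(list(target = rdm(D, ids, model = "planted"),
                             weights = weights, patterns = X,
                             realized_correlation = realized,
                             seed = config$seed),
                        class = "planted_geometry")
  list(dataset = dataset, geometry = geometry)
}

#' Generate a stack of synthetic subject maps
#'
#' Per-subject map = shared spherical blob (if any) + independent Gaussian
#' noise; with `blob = NULL` the maps are exchangeable and symmetric about
#' zero (the sign-flip null).
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param grid Integer grid shape, length 3.
#' @param blob `NULL`, or list with `center` (grid coords), `radius`
#'   (voxels) and `amplitude`.
#' @param noise_sd Noise SD.
#' @param seed Integer seed.
#' @param voxel_size_mm Voxel size label for the maps.
#' @return A [map_stack()].
#' @export
generate_subject_maps <- function(n_subjects, grid, blob = NULL,
                                  noise_sd = 1, seed = 1L,
                                  voxel_size_mm = 1.8) {
  stopifnot(n_subjects >= 2, length(grid) == 3)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  signal <- array(0, grid)
  if (!is.null(blob)) {
    idx <- which(array(TRUE, grid), arr.ind = TRUE)
    d2 <- (idx[, 1] - blob$center[1])^2 + (idx[, 2] - blob$center[2])^2 +
      (idx[, 3] - blob$center[3])^2
    signal[idx[d2 <= blob$radius^2, , drop = FALSE]] <- blob$amplitude
  }
  maps <- lapply(seq_len(n_subjects), function(s) {
    brain_map(signal + array(stats::rnorm(prod(grid), sd = noise_sd), grid),
              voxel_size_mm = voxel_size_mm, space = "shared")
  })
  map_stack(maps)
}
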