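# Fixed-count spherical searchlights over a masked voxel grid.  Each
# neighborhood is the `count` nearest in-mask voxels by center-to-center
# distance (mm); at mask edges the sphere reaches farther to keep the voxel
# count fixed, following the common MVPA-toolbox convention.

#' Build fixed-count spherical voxel neighborhoods
#'
#' For every in-mask voxel, finds the `count` nearest in-mask voxels by
#' Euclidean center-to-center distance in mm, center included, ordered by
#' nondecreasing distance with ties broken lexicographically by (i, j, k)
#' grid index — deterministic across platforms.
#'
#' @param mask Logical 3D array.
#' @param voxel_size_mm Isotropic voxel edge length in mm.
#' @param count Neighborhood size in voxels (the classic choice is 100,
#'   about a 5.2 mm equivalent radius at 1.8 mm voxels; see
#'   [equivalent_radius()]).
#' @return A `neighborhood_set`: list with `voxels` (in-mask voxel (i,j,k)
#'   rows in lexicographic order), `members` (list of integer index vectors
#'   into `voxels`, one per center), `voxel_size_mm`, `count`, `dim`.
#' @export
build_neighborhoods <- function(mask, voxel_size_mm, count) {
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("mask is empty", call. = FALSE)
  if (count > nrow(idx)) {
    stop(sprintf("count (%d) exceeds in-mask voxels (%d)", count, nrow(idx)),
         call. = FALSE)
  }
  # lexicographic (i, j, k) order; radix order is stable, so equal-distance
  # ties later resolve to this order automatically
  o <- order(idx[, 1], idx[, 2], idx[, 3], method = "radix")
  idx <- idx[o, , drop = FALSE]
  n <- nrow(idx)
  members <- vector("list", n)
  chunk <- max(1L, floor(2e7 / n))
  for (start in seq(1L, n, by = chunk)) {
    rows <- start:min(start + chunk - 1L, n)
    # squared distances in exact integer grid units (isotropic voxels, so
    # the mm scaling does not affect the ordering); exact arithmetic keeps
    # equal-distance ties genuinely tied for the lexicographic tie-break
    d2 <- outer(idx[rows, 1], idx[, 1], "-")^2 +
      outer(idx[rows, 2], idx[, 2], "-")^2 +
      outer(idx[rows, 3], idx[, 3], "-")^2
    for (r in seq_along(rows)) {
      members[[rows[r]]] <- order(d2[r, ], method = "radix")[seq_len(count)]
    }
  }
  structure(list(voxels = idx, members = members,
                 voxel_size_mm = voxel_size_mm, count = count,
                 dim = dim(mask)),
            class = "neighborhood_set")
}

#' Equivalent spherical radius of a fixed-count neighborhood
#'
#' The radius of the sphere whose volume equals `count` voxels:
#' `(4/3) pi r^3 = count * voxel_size^3`.
#'
#' @param count Number of voxels.
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @return Radius in mm.
#' @export
equivalent_radius <- function(count, voxel_size_mm) {
  stopifnot(count >= 1, voxel_size_mm > 0)
  (3 * count * voxel_size_mm^3 / (4 * pi))^(1 / 3)
}

#' Searchlight RSA map
#'
#' Runs RSA within every voxel neighborhood: the neural RDM is computed
#' from the neighborhood's prepared patterns and correlated with the target
#' RDM — partial correlation when controls are given — and the value is
#' written at the neighborhood's center voxel.  Centers whose neighborhood
#' degenerates (an item pattern with zero variance, or fewer than two
#' usable voxels) get NaN.
#'
#' @param data A [neural_dataset()] with `voxel_index` on the same grid as
#'   the neighborhoods.
#' @param target Target model [rdm()] covering the dataset's image ids.
#' @param controls List of control [rdm()]s (empty for standard RSA).
#' @param neighborhoods A `neighborhood_set` from [build_neighborhoods()].
#' @return A `brain_map`: list with `volume` (3D array, NaN outside mask
#'   and at degenerate centers), `dim`, `voxel_size_mm`, `space`, and
#'   `n_degenerate`.
#' @export
searchlight_map <- function(data, target, controls = list(), neighborhoods) {
  stopifnot(inherits(data, "neural_dataset"),
            inherits(neighborhoods, "neighborhood_set"))
  if (is.null(data$voxel_index)) {
    stop("dataset has no voxel grid coordinates", call. = FALSE)
  }
  nb <- neighborhoods
  # map dataset voxels onto the neighborhood voxel list
  key <- function(m) paste(m[, 1], m[, 2], m[, 3])
  pos <- match(key(nb$voxels), key(data$voxel_index))
  if (anyNA(pos)) {
    stop("neighborhood grid does not match the dataset voxel grid",
         call. = FALSE)
  }
  # average + z-score once on the full matrix is NOT equivalent to per-
  # searchlight preparation only through voxel exclusion; averaging is
  # global, standardization is per voxel, so prepare once and slice.
  prep <- prepare_patterns(data)
  zfull <- matrix(NA_real_, length(prep$item_ids), ncol(data$betas))
  zfull[, prep$voxel_subset] <- prep$patterns
  vol <- array(NaN, dim = nb$dim)
  n_degen <- 0L
  for (c_i in seq_along(nb$members)) {
    cols <- pos[nb$members[[c_i]]]
    z <- zfull[, cols, drop = FALSE]
    z <- z[, !is.na(z[1, ]), drop = FALSE] # zero-variance voxels excluded
    v <- NaN
    if (ncol(z) >= 2L) {
      sds <- apply(z, 1, stats::sd)
      if (all(sds > 0)) {
        nrdm <- rdm(unname(pmin(pmax(1 - stats::cor(t(z)), 0), 2)),
                    prep$item_ids, model = "neural")
        v <- if (length(controls)) partial_rsa(nrdm, target, controls)
             else rsa_correlation(nrdm, target)
      }
    }
    if (is.nan(v)) n_degen <- n_degen + 1L
    vol[nb$voxels[c_i, 1], nb$voxels[c_i, 2], nb$voxels[c_i, 3]] <- v
  }
  brain_map(vol, voxel_size_mm = nb$voxel_size_mm, space = "subject",
            n_degenerate = n_degen)
}

#' Construct a brain map
#'
#' @param volume 3D numeric array; NaN marks out-of-mask or degenerate
#'   voxels.
#' @param voxel_size_mm Voxel size in mm.
#' @param space `"subject"` or `"shared"` grid label.
#' @param n_degenerate Count of in-mask centers that produced NaN.
#' @return A `brain_map` object.
#' @export
brain_map <- function(volume, voxel_size_mm = 1, space = "subject",
                      n_degenerate = 0L) {
  stopifnot(is.array(volume), length(dim(volume)) == 3L)
  structure(list(volume = volume, dim = dim(volume),
                 voxel_size_mm = voxel_size_mm, space = space,
                 n_degenerate = n_degenerate),
            class = "brain_map")
}
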