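# Core RSA: pattern preparation, 1-correlation neural RDMs, and standard /
# partial Pearson correlation between RDM triangles.

#' Construct a neural dataset
#'
#' Trial-level response amplitudes (GLM betas) with their image labels and
#' voxel geometry.
#'
#' @param betas Trial x voxel numeric matrix.
#' @param trial_image_ids Image id per trial (repeats allowed).
#' @param voxel_index Optional voxel x 3 integer matrix of (i, j, k) grid
#'   coordinates (required for searchlight use).
#' @param voxel_size_mm Isotropic voxel size in mm.
#' @param mask Optional logical 3D array; all voxel_index rows must fall
#'   inside it.
#' @return A `neural_dataset`.
#' @export
neural_dataset <- function(betas, trial_image_ids, voxel_index = NULL,
                           voxel_size_mm = 1, mask = NULL) {
  if (!is.matrix(betas)) stop("betas must be a trial x voxel matrix",
                              call. = FALSE)
  if (length(trial_image_ids) != nrow(betas)) {
    stop("one image id per trial row is required", call. = FALSE)
  }
  if (length(unique(trial_image_ids)) < 2L) {
    stop("need at least 2 distinct image ids", call. = FALSE)
  }
  all_nan <- apply(betas, 2, function(v) all(is.na(v)))
  if (any(all_nan)) {
    stop(sprintf("%d voxel(s) are all-NA", sum(all_nan)), call. = FALSE)
  }
  if (!is.null(voxel_index)) {
    voxel_index <- as.matrix(voxel_index)
    if (nrow(voxel_index) != ncol(betas) || ncol(voxel_index) != 3L) {
      stop("voxel_index must be one (i,j,k) row per voxel", call. = FALSE)
    }
    if (!is.null(mask)) {
      inside <- mask[voxel_index]
      if (!all(inside)) {
        stop(sprintf("%d voxel(s) fall outside the mask", sum(!inside)),
             call. = FALSE)
      }
    }
  }
  structure(list(betas = betas,
                 trial_image_ids = as.character(trial_image_ids),
                 voxel_index = voxel_index,
                 voxel_size_mm = voxel_size_mm,
                 mask = mask),
            class = "neural_dataset")
}

#' Average repeats and z-score voxels (pattern preparation)
#'
#' Betas of trials showing the same image are averaged, then every voxel is
#' standardized across images to zero mean and unit variance so each
#' contributes equally to the correlation distance.  Voxels constant across
#' images cannot be standardized; they are recorded and excluded.
#'
#' @param data A [neural_dataset()].
#' @param voxel_subset Optional integer indices restricting to a voxel
#'   subset (e.g. one searchlight) before preparation.
#' @return A `pattern_matrix`: list with `item_ids`, `patterns` (item x
#'   surviving voxel, z-scored columns), `voxel_subset` (column indices into
#'   the original dataset) and `excluded` (zero-variance columns dropped).
#' @export
prepare_patterns <- function(data, voxel_subset = NULL) {
  stopifnot(inherits(data, "neural_dataset"))
  b <- data$betas
  if (!is.null(voxel_subset)) b <- b[, voxel_subset, drop = FALSE]
  ids <- unique(data$trial_image_ids)
  if (length(ids) < 3L) {
    stop(sprintf("insufficient data: %d distinct images, need >= 3",
                 length(ids)), call. = FALSE)
  }
  g <- factor(data$trial_image_ids, levels = ids)
  m <- rowsum(b, g) / as.vector(table(g))
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  keep <- sdv > 0
  z <- sweep(sweep(m[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  cols <- if (is.null(voxel_subset)) seq_len(ncol(data$betas)) else voxel_subset
  structure(list(item_ids = ids, patterns = z,
                 voxel_subset = cols[keep], excluded = cols[!keep]),
            class = "pattern_matrix")
}

#' Correlation-distance neural RDM
#'
#' Entry (i, j) is 1 minus the Pearson correlation of item i's and item j's
#' voxel patterns, in `[0, 2]`.
#'
#' @param patterns A `pattern_matrix` from [prepare_patterns()].
#' @return An [rdm()] named `"neural"`.
#' @export
neural_rdm <- function(patterns) {
  stopifnot(inherits(patterns, "pattern_matrix"))
  z <- patterns$patterns
  if (ncol(z) < 2L) stop("need at least 2 surviving voxels", call. = FALSE)
  sds <- apply(z, 1, stats::sd)
  if (any(sds == 0)) {
    stop(sprintf("degenerate (zero-variance) pattern for item(s): %s",
                 paste(patterns$item_ids[sds == 0], collapse = ", ")),
         call. = FALSE)
  }
  d <- 1 - stats::cor(t(z))
  d <- pmin(pmax(d, 0), 2) # clip correlation rounding outside [0, 2]
  rdm(unname(d), patterns$item_ids, model = "neural")
}

align_rdm_items <- function(neural, model) {
  missing <- setdiff(neural$item_ids, model$item_ids)
  extra <- setdiff(model$item_ids, neural$item_ids)
  if (length(missing) || length(extra)) {
    stop(sprintf("RDM item sets differ (missing from model: %s; absent from neural: %s)",
                 paste(missing, collapse = ", "),
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
  rdm_subset(model, neural$item_ids)
}

#' Correlate a neural RDM with a model RDM
#'
#' Pearson correlation between the strictly-lower-triangle vectors of the
#' two RDMs, after reordering the model to the neural item order.
#'
#' @param neural,model [rdm()]s over the same item set (any order).
#' @return Correlation in `[-1, 1]`.
#' @export
rsa_correlation <- function(neural, model) {
  stopifnot(inherits(neural, "rdm"), inherits(model, "rdm"))
  if (length(neural$item_ids) < 3L) stop("need >= 3 items", call. = FALSE)
  model <- align_rdm_items(neural, model)
  x <- rdm_triangle(neural); y <- rdm_triangle(model)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant RDM triangle; correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Partial correlation between neural and target RDMs given controls
#'
#' Residualizes both triangle vectors on the control triangles by least
#' squares (with intercept) and correlates the residuals; with no controls
#' this reduces to [rsa_correlation()].
#'
#' @param neural,target [rdm()]s over the same items.
#' @param controls List of control [rdm()]s (possibly empty).
#' @return Partial Pearson correlation.
#' @export
partial_rsa <- function(neural, target, controls = list()) {
  stopifnot(inherits(neural, "rdm"), inherits(target, "rdm"))
  if (length(controls) == 0L) return(rsa_correlation(neural, target))
  target <- align_rdm_items(neural, target)
  ctrl <- vapply(controls, function(cc)
    rdm_triangle(align_rdm_items(neural, cc)),
    numeric(length(rdm_triangle(neural))))
  x <- rdm_triangle(neural); y <- rdm_triangle(target)
  n <- length(x)
  if (length(controls) >= n - 2L) {
    stop("too many controls for the number of RDM entries", call. = FALSE)
  }
  X <- cbind(1, ctrl)
  qx <- qr(X)
  rx <- qr.resid(qx, x)
  ry <- qr.resid(qx, y)
  vy <- sum(ry^2) / (n - 1)
  if (vy < 1e-12) {
    stop("target RDM is linearly dependent on the controls (collinearity)",
         call. = FALSE)
  }
  if (sum(rx^2) / (n - 1) < 1e-12) {
    stop("neural RDM is linearly dependent on the controls (collinearity)",
         call. = FALSE)
  }
  stats::cor(as.vector(rx), as.vector(ry))
}

#' Fisher z transform
#'
#' `atanh(r)` with `|r|` clipped to `1 - 1e-12` first, so degenerate
#' searchlights cannot inject infinities into group maps.
#'
#' @param r Correlation(s) with `|r| <= 1`.
#' @return Transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop("fisher_z requires |r| <= 1", call. = FALSE)
  }
  atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
}
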