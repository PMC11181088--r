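# Representational dissimilarity matrices: symmetric, nonnegative, zero
# diagonal, keyed by image IDs.

#' Construct an RDM
#'
#' @param values Square symmetric numeric matrix of nonnegative
#'   dissimilarities with zero diagonal.
#' @param item_ids Character vector of image IDs, one per row/column.
#' @param model Name of the generating model (metadata).
#' @param normalized Logical flag: entries min-max scaled to `[0, 1]`.
#' @return An `rdm` object.
#' @export
rdm <- function(values, item_ids, model = "unnamed", normalized = FALSE) {
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop("RDM values must be a square matrix", call. = FALSE)
  }
  if (length(item_ids) != nrow(values)) {
    stop("item_ids length must match matrix dimension", call. = FALSE)
  }
  if (anyDuplicated(item_ids)) {
    stop(sprintf("duplicate image ids: %s",
                 paste(unique(item_ids[duplicated(item_ids)]), collapse = ", ")),
         call. = FALSE)
  }
  if (anyNA(values)) stop("RDM contains NA entries", call. = FALSE)
  if (max(abs(values - t(values))) > 1e-9) {
    stop("RDM is not symmetric within 1e-9", call. = FALSE)
  }
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (min(values) < -1e-12) {
    stop("RDM has negative dissimilarities", call. = FALSE)
  }
  dimnames(values) <- list(item_ids, item_ids)
  structure(list(item_ids = as.character(item_ids), values = values,
                 model = model, normalized = isTRUE(normalized)),
            class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat(sprintf("<rdm> %s: %d items%s\n", x$model, length(x$item_ids),
              if (x$normalized) ", normalized [0,1]" else ""))
  invisible(x)
}

#' Strictly-lower-triangle vector of an RDM
#'
#' The canonical vectorization used for every RDM-to-RDM correlation.
#'
#' @param x An [rdm()] or square matrix.
#' @return Numeric vector of the strictly lower triangle, column-major.
#' @export
rdm_triangle <- function(x) {
  m <- if (inherits(x, "rdm")) x$values else x
  m[lower.tri(m)]
}

#' Build a pose or viewpoint model RDM
#'
#' Computes all pairwise dissimilarities between poses under one of the five
#' model parameterizations:
#' \describe{
#'   \item{view_dep_3d}{MPJPE on raw 3D joint coordinates (viewer frame).}
#'   \item{view_dep_2d}{MPJPE on orthographically projected 2D joints.}
#'   \item{view_indep_3d}{MPJPE after undoing each pose's global rotation.}
#'   \item{viewpoint}{angular distance between global-rotation quaternions.}
#'   \item{joint_rotation}{mean per-joint quaternion angular distance.}
#' }
#' The result is unnormalized; pass through [normalize_rdm()] before RSA.
#'
#' @param poses List of [pose_record()]s (at least 2, distinct image ids).
#' @param model One of the five model names above.
#' @return An unnormalized [rdm()].
#' @export
build_model_rdm <- function(poses,
                            model = c("view_dep_3d", "view_dep_2d",
                                      "view_indep_3d", "viewpoint",
                                      "joint_rotation")) {
  model <- match.arg(model)
  if (length(poses) < 2L) stop("need at least 2 poses", call. = FALSE)
  stopifnot(all(vapply(poses, inherits, logical(1), "pose_record")))
  ids <- vapply(poses, `[[`, character(1), "image_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate image ids: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  }
  n <- length(poses)

  # pairwise distances vectorized per joint / per quaternion set; these are
  # algebraically identical to looping mean_per_joint_distance /
  # viewpoint_distance / joint_rotation_distance over all pairs
  quat_angle_matrix <- function(Q) {
    # rows of Q are unit quaternions
    g <- abs(tcrossprod(Q))
    d <- acos(pmin(g, 1))
    diag(d) <- 0
    d
  }
  mpjpe_matrix <- function(feats) {
    K <- nrow(feats[[1]])
    d <- matrix(0, n, n)
    for (k in seq_len(K)) {
      jk <- t(vapply(feats, function(f) f[k, ], numeric(ncol(feats[[1]]))))
      d <- d + as.matrix(stats::dist(jk))
    }
    d / K
  }

  d <- switch(model,
    view_dep_3d = mpjpe_matrix(lapply(poses, `[[`, "joints3d")),
    view_dep_2d = mpjpe_matrix(lapply(poses, project_to_2d)),
    view_indep_3d = mpjpe_matrix(lapply(poses, align_view_independent)),
    viewpoint = quat_angle_matrix(t(vapply(poses, function(p)
      as.numeric(rotation_matrix_to_quaternion(p$global_rotation)),
      numeric(4)))),
    joint_rotation = {
      missing <- vapply(poses, function(p) is.null(p$joint_rotations),
                        logical(1))
      if (any(missing)) {
        stop(sprintf("joint_rotation model requires joint rotations on all records (missing: %s)",
                     paste(ids[missing], collapse = ", ")), call. = FALSE)
      }
      K <- length(pose_joint_labels())
      acc <- matrix(0, n, n)
      for (k in seq_len(K)) {
        Qk <- t(vapply(poses, function(p)
          as.numeric(p$joint_rotations[[k]]), numeric(4)))
        acc <- acc + quat_angle_matrix(Qk)
      }
      acc / K
    })
  rdm(unname(d), ids, model = model)
}

#' Min-max normalize an RDM to the unit interval
#'
#' Applies `x' = (x - min) / (max - min)` over the off-diagonal entries; the
#' diagonal stays 0.  A constant off-diagonal is an error rather than a
#' silent all-zero matrix, because a flat RDM poisons downstream
#' correlations with NaNs.
#'
#' @param x An [rdm()].
#' @return The normalized [rdm()] (flag set).
#' @export
normalize_rdm <- function(x) {
  stopifnot(inherits(x, "rdm"))
  off <- x$values[lower.tri(x$values)]
  lo <- min(off); hi <- max(off)
  if (hi - lo < 1e-12) {
    stop(sprintf("degenerate RDM '%s': all off-diagonal dissimilarities equal (%.3g)",
                 x$model, lo), call. = FALSE)
  }
  v <- (x$values - lo) / (hi - lo)
  diag(v) <- 0
  rdm(v, x$item_ids, model = x$model, normalized = TRUE)
}

#' Subset an RDM to a set of items
#'
#' Used when a subject saw only part of the stimulus set; the result is
#' unnormalized (renormalize per subject before RSA).
#'
#' @param x An [rdm()].
#' @param ids Item ids to keep, in the requested order.
#' @return The subset [rdm()], `normalized` flag cleared.
#' @export
rdm_subset <- function(x, ids) {
  stopifnot(inherits(x, "rdm"))
  missing <- setdiff(ids, x$item_ids)
  if (length(missing)) {
    stop(sprintf("items not in RDM: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  rdm(x$values[ids, ids, drop = FALSE], ids, model = x$model)
}

#' Write / read an RDM as TSV with a JSON sidecar
#'
#' The TSV holds a header row of item ids and the square numeric body; the
#' sidecar (`<path>.json`) records the model name and normalization flag.
#'
#' @param x An [rdm()].
#' @param path TSV file path.
#' @return `write_rdm_tsv` returns `path` invisibly; `read_rdm_tsv` the
#'   reconstructed [rdm()].
#' @export
write_rdm_tsv <- function(x, path) {
  stopifnot(inherits(x, "rdm"))
  utils::write.table(x$values, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(list(model = x$model, normalized = x$normalized,
                            item_ids = x$item_ids),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rdm_tsv
#' @export
read_rdm_tsv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- as.matrix(utils::read.table(path, sep = "\t", header = TRUE,
                                   check.names = FALSE))
  rdm(unname(m), meta$item_ids, model = meta$model,
      normalized = isTRUE(meta$normalized))
}
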