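# Stimulus selection and control models: the single-full-person keypoint
# filter, body geometry (polar angle/distance, relative size) and control
# RDMs on geometry or precomputed feature embeddings.

coco_keypoint_labels <- function() {
  c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
    "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
    "left_wrist", "right_wrist", "left_hip", "right_hip",
    "left_knee", "right_knee", "left_ankle", "right_ankle")
}

coco_limb_labels <- function() {
  setdiff(coco_keypoint_labels(),
          c("nose", "left_eye", "right_eye", "left_ear", "right_ear"))
}

#' Construct a keypoint annotation record
#'
#' One image's person annotations in the COCO 17-keypoint dialect: per
#' person a 17 x 3 matrix `(x, y, v)` with visibility flag
#' `v` in 0 (not annotated), 1 (annotated, invisible), 2 (annotated,
#' visible); pixel coordinates, x rightward, y downward.
#'
#' @param image_id Image identifier.
#' @param persons List of person annotations; each a list with `keypoints`
#'   (17 x 3 matrix, rows in COCO order), `bbox` `(x, y, w, h)` in pixels,
#'   and `segmentation_area` in pixels^2.
#' @param width,height Image dimensions in pixels.
#' @return A `keypoint_record`.
#' @export
keypoint_record <- function(image_id, persons, width, height) {
  labels <- coco_keypoint_labels()
  persons <- lapply(persons, function(p) {
    k <- p$keypoints
    if (!is.matrix(k) || !all(dim(k) == c(17L, 3L))) {
      stop(sprintf("record %s: keypoints must be a 17 x 3 (x, y, v) matrix",
                   image_id), call. = FALSE)
    }
    if (is.null(rownames(k))) rownames(k) <- labels
    if (!identical(rownames(k), labels)) {
      if (!setequal(rownames(k), labels)) {
        stop(sprintf("record %s: keypoint labels are not the COCO-17 set",
                     image_id), call. = FALSE)
      }
      k <- k[labels, , drop = FALSE]
    }
    if (!all(k[, 3] %in% 0:2)) {
      stop(sprintf("record %s: visibility flags must be 0, 1 or 2", image_id),
           call. = FALSE)
    }
    list(keypoints = k, bbox = as.numeric(p$bbox),
         segmentation_area = as.numeric(p$segmentation_area))
  })
  structure(list(image_id = image_id, persons = persons,
                 width = width, height = height),
            class = "keypoint_record")
}

#' Select single full-person images
#'
#' Keeps images annotated with exactly one person whose 12 limb keypoints
#' (shoulders, elbows, wrists, hips, knees, ankles) are all annotated —
#' visibility flag 1 or 2; occluded counts, missing does not.  Face
#' keypoints are ignored because they are often absent for small figures.
#' Input order is preserved.
#'
#' @param records List of [keypoint_record()]s.
#' @return Character vector of qualifying image ids.
#' @export
filter_single_full_person <- function(records) {
  stopifnot(all(vapply(records, inherits, logical(1), "keypoint_record")))
  limb <- coco_limb_labels()
  keep <- vapply(records, function(r) {
    if (length(r$persons) != 1L) return(FALSE)
    k <- r$persons[[1]]$keypoints
    all(k[limb, 3] > 0)
  }, logical(1))
  vapply(records[keep], `[[`, character(1), "image_id")
}

#' Body geometry of a single-person image
#'
#' Places the person bounding-box center in a polar coordinate system with
#' origin at the image center: `polar_distance` is the Euclidean distance in
#' pixels, `polar_angle` the `atan2` angle in `(-pi, pi]` (0 by convention
#' when the center coincides with the origin).  `relative_size` is the
#' person segmentation area as a fraction of the image area.
#'
#' @param record A [keypoint_record()] that passed the single-person filter.
#' @param width,height Optional pixel dimensions overriding the record's.
#' @return A list `(image_id, polar_angle, polar_distance, relative_size,
#'   center_convention)`.
#' @export
body_geometry <- function(record, width = record$width,
                          height = record$height) {
  stopifnot(inherits(record, "keypoint_record"))
  if (length(record$persons) != 1L) {
    stop(sprintf("record %s has %d persons; body geometry requires exactly one",
                 record$image_id, length(record$persons)), call. = FALSE)
  }
  if (!is.numeric(width) || !is.numeric(height) || width <= 0 || height <= 0) {
    stop("image has zero or invalid area", call. = FALSE)
  }
  p <- record$persons[[1]]
  cx <- p$bbox[1] + p$bbox[3] / 2 - width / 2
  cy <- p$bbox[2] + p$bbox[4] / 2 - height / 2
  d <- sqrt(cx^2 + cy^2)
  ang <- if (d == 0) 0 else atan2(cy, cx)
  list(image_id = record$image_id,
       polar_angle = ang,
       polar_distance = d,
       relative_size = p$segmentation_area / (width * height),
       center_convention = d == 0)
}

circular_angle_diff <- function(a, b) {
  d <- abs(a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}

#' Build a control RDM from body geometry or feature embeddings
#'
#' Dissimilarity kinds:
#' \describe{
#'   \item{polar_angle}{absolute circular difference, wrapped to `[0, pi]`.}
#'   \item{polar_distance, body_size}{absolute scalar difference.}
#'   \item{embedding_euclidean}{Euclidean distance between unit-L2-scaled
#'     vectors (the "normalized embedding" distance).}
#'   \item{embedding_one_minus_corr}{1 - Pearson correlation between raw
#'     vectors, in `[0, 2]`.}
#' }
#'
#' @param source For the geometry kinds, a list of [body_geometry()]
#'   results; for the embedding kinds, a list with `item_ids` and `vectors`
#'   (items x dim numeric matrix).
#' @param kind One of the five kinds above.
#' @return An unnormalized [rdm()].
#' @export
build_control_rdm <- function(source,
                              kind = c("polar_angle", "polar_distance",
                                       "body_size", "embedding_euclidean",
                                       "embedding_one_minus_corr")) {
  kind <- match.arg(kind)
  if (kind %in% c("embedding_euclidean", "embedding_one_minus_corr")) {
    ids <- as.character(source$item_ids)
    X <- source$vectors
    if (!is.matrix(X) || nrow(X) != length(ids) || anyNA(X)) {
      stop("embedding source needs item_ids and a matching items x dim matrix without NAs",
           call. = FALSE)
    }
    if (kind == "embedding_euclidean") {
      n2 <- sqrt(rowSums(X^2))
      if (any(n2 == 0)) {
        stop(sprintf("zero embedding vector for item(s): %s",
                     paste(ids[n2 == 0], collapse = ", ")), call. = FALSE)
      }
      d <- as.matrix(stats::dist(X / n2))
    } else {
      sds <- apply(X, 1, stats::sd)
      if (any(sds == 0)) {
        stop(sprintf("constant embedding vector (zero variance) for item(s): %s",
                     paste(ids[sds == 0], collapse = ", ")), call. = FALSE)
      }
      d <- 1 - stats::cor(t(X))
    }
    return(rdm(unname(d), ids, model = kind))
  }

  ids <- vapply(source, `[[`, character(1), "image_id")
  v <- switch(kind,
    polar_angle = vapply(source, `[[`, numeric(1), "polar_angle"),
    polar_distance = vapply(source, `[[`, numeric(1), "polar_distance"),
    body_size = vapply(source, `[[`, numeric(1), "relative_size"))
  d <- if (kind == "polar_angle") {
    outer(v, v, circular_angle_diff)
  } else {
    abs(outer(v, v, `-`))
  }
  rdm(unname(d), ids, model = kind)
}
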