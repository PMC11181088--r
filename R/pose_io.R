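# Serialization of pose records: a JSON dialect (one object per image) and
# an equivalent long-format CSV. Joints may appear in any order on disk and
# are re-sorted by label on load.

#' Write pose records to JSON
#'
#' One object per image: `image_id`, `joints3d` as label -> [x, y, z],
#' `global_rotation` as 9 row-major reals, and optionally `joint_rotations`
#' as label -> [w, x, y, z].
#'
#' @param poses List of [pose_record()]s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_poses_json <- function(poses, path) {
  objs <- lapply(poses, function(p) {
    o <- list(
      image_id = p$image_id,
      joints3d = stats::setNames(
        lapply(seq_len(nrow(p$joints3d)), function(k) unname(p$joints3d[k, ])),
        rownames(p$joints3d)),
      global_rotation = as.vector(t(p$global_rotation)))
    if (!is.null(p$joint_rotations)) {
      o$joint_rotations <- lapply(p$joint_rotations, function(q)
        unname(as.numeric(q)))
    }
    o
  })
  jsonlite::write_json(objs, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read pose records from JSON
#'
#' @param path File written by [write_poses_json()] (or hand-authored in the
#'   same dialect; joint order on disk is irrelevant).
#' @return List of [pose_record()]s.
#' @export
read_poses_json <- function(path) {
  objs <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(objs, function(o) {
    j <- do.call(rbind, lapply(o$joints3d, function(v) as.numeric(unlist(v))))
    rownames(j) <- names(o$joints3d)
    R <- matrix(as.numeric(unlist(o$global_rotation)), 3, 3, byrow = TRUE)
    jr <- NULL
    if (!is.null(o$joint_rotations)) {
      jr <- lapply(o$joint_rotations, function(v) {
        v <- as.numeric(unlist(v))
        quaternion(v[1], v[2], v[3], v[4])
      })
    }
    pose_record(o$image_id, j, R, jr)
  })
}

#' Write / read pose records as long-format CSV
#'
#' Rows of `image_id, field, label, c1..c4`: one row per joint
#' (`field = "joint"`, xyz in c1..c3), three rows for the rotation matrix
#' (`field = "rotation_row<i>"`), and optionally one row per joint rotation
#' (`field = "joint_rotation"`, wxyz in c1..c4).
#'
#' @param poses List of [pose_record()]s.
#' @param path CSV file path.
#' @return `write_poses_csv`: `path` invisibly; `read_poses_csv`: list of
#'   [pose_record()]s.
#' @export
write_poses_csv <- function(poses, path) {
  rows <- lapply(poses, function(p) {
    jr <- p$joint_rotations
    rbind(
      data.frame(image_id = p$image_id, field = "joint",
                 label = rownames(p$joints3d),
                 c1 = p$joints3d[, 1], c2 = p$joints3d[, 2],
                 c3 = p$joints3d[, 3], c4 = NA_real_),
      data.frame(image_id = p$image_id,
                 field = paste0("rotation_row", 1:3),
                 label = "", c1 = p$global_rotation[, 1],
                 c2 = p$global_rotation[, 2], c3 = p$global_rotation[, 3],
                 c4 = NA_real_),
      if (!is.null(jr)) {
        q <- do.call(rbind, lapply(jr, as.numeric))
        data.frame(image_id = p$image_id, field = "joint_rotation",
                   label = names(jr), c1 = q[, 1], c2 = q[, 2],
                   c3 = q[, 3], c4 = q[, 4])
      })
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_poses_csv
#' @export
read_poses_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(d, factor(d$image_id, levels = unique(d$image_id))),
         function(g) {
    jrows <- g[g$field == "joint", ]
    j <- as.matrix(jrows[, c("c1", "c2", "c3")])
    dimnames(j) <- list(jrows$label, NULL)
    rrow <- g[grepl("^rotation_row", g$field), ]
    rrow <- rrow[order(rrow$field), ]
    R <- as.matrix(rrow[, c("c1", "c2", "c3")]) # rows are matrix rows
    dimnames(R) <- NULL
    qrows <- g[g$field == "joint_rotation", ]
    jr <- NULL
    if (nrow(qrows)) {
      jr <- stats::setNames(lapply(seq_len(nrow(qrows)), function(i)
        quaternion(qrows$c1[i], qrows$c2[i], qrows$c3[i], qrows$c4[i])),
        qrows$label)
    }
    pose_record(g$image_id[1], j, R, jr)
  }) |> unname()
}
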