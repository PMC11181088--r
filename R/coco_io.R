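# COCO-dialect keypoint annotation JSON: top-level `images` and
# `annotations` arrays; keypoints stored flat as [x, y, v] x 17 in the
# standard COCO keypoint order.

#' Write keypoint records as COCO-dialect JSON
#'
#' @param records List of [keypoint_record()]s.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_coco_json <- function(records, path) {
  images <- lapply(records, function(r)
    list(id = r$image_id, width = r$width, height = r$height))
  anns <- list(); aid <- 0L
  for (r in records) {
    for (p in r$persons) {
      aid <- aid + 1L
      anns[[aid]] <- list(
        id = aid, image_id = r$image_id, category_id = 1L,
        keypoints = as.vector(t(p$keypoints)),
        num_keypoints = sum(p$keypoints[, 3] > 0),
        bbox = p$bbox, area = p$segmentation_area)
    }
  }
  jsonlite::write_json(list(images = images, annotations = anns), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read COCO-dialect keypoint annotations
#'
#' Accepts the standard person-keypoints layout: `images` with
#' `id`/`width`/`height`, `annotations` with flat 51-element `keypoints`,
#' `bbox` and `area`.  Images without person annotations yield records with
#' an empty person list.
#'
#' @param path COCO JSON file.
#' @return List of [keypoint_record()]s in `images` order.
#' @export
read_coco_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  by_img <- split(doc$annotations,
                  vapply(doc$annotations, function(a)
                    as.character(a$image_id), character(1)))
  lapply(doc$images, function(im) {
    id <- as.character(im$id)
    persons <- lapply(by_img[[id]] %||% list(), function(a) {
      kp <- matrix(as.numeric(unlist(a$keypoints)), ncol = 3, byrow = TRUE)
      if (nrow(kp) != 17L) {
        stop(sprintf("annotation for image %s has %d keypoints, expected 17",
                     id, nrow(kp)), call. = FALSE)
      }
      list(keypoints = kp, bbox = as.numeric(unlist(a$bbox)),
           segmentation_area = as.numeric(a$area))
    })
    keypoint_record(id, persons, as.numeric(im$width), as.numeric(im$height))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
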