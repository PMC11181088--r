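# ROI-level RSA: localizer-based voxel selection, per-ROI standard/partial
# RSA, and the two-repeat Monte Carlo noise-ceiling estimator.

#' Construct an ROI dataset
#'
#' @param roi ROI name.
#' @param betas Trial x voxel matrix restricted to the ROI.
#' @param trial_image_ids Image id per trial.
#' @param localizer_t Optional per-voxel localizer t values (e.g. the
#'   body-vs-object contrast used to select EBA voxels).
#' @return A `roi_dataset`.
#' @export
roi_dataset <- function(roi, betas, trial_image_ids, localizer_t = NULL) {
  stopifnot(is.matrix(betas))
  if (ncol(betas) < 2L) stop("ROI needs >= 2 voxels", call. = FALSE)
  if (length(trial_image_ids) != nrow(betas)) {
    stop("one image id per trial row is required", call. = FALSE)
  }
  if (!is.null(localizer_t) && length(localizer_t) != ncol(betas)) {
    stop("one localizer t per voxel is required", call. = FALSE)
  }
  structure(list(roi = roi, betas = betas,
                 trial_image_ids = as.character(trial_image_ids),
                 localizer_t = localizer_t),
            class = "roi_dataset")
}

#' Select ROI voxels by localizer t threshold
#'
#' Keeps voxels with localizer t strictly greater than `threshold` (the
#' classic EBA choice is 8.0).
#'
#' @param dataset A [roi_dataset()] with localizer t values.
#' @param threshold Strict lower bound on t.
#' @return The thresholded [roi_dataset()].
#' @export
select_voxels_by_t <- function(dataset, threshold) {
  stopifnot(inherits(dataset, "roi_dataset"))
  if (is.null(dataset$localizer_t)) {
    stop("dataset has no localizer t values", call. = FALSE)
  }
  keep <- dataset$localizer_t > threshold
  if (!any(keep)) {
    stop(sprintf("no voxels with t > %g in ROI %s (max t = %g)", threshold,
                 dataset$roi, max(dataset$localizer_t)), call. = FALSE)
  }
  roi_dataset(dataset$roi, dataset$betas[, keep, drop = FALSE],
              dataset$trial_image_ids, dataset$localizer_t[keep])
}

#' ROI-level RSA
#'
#' Prepares patterns over all ROI voxels, builds the 1-correlation neural
#' RDM, and correlates it with the target (partially, given controls).
#'
#' @param dataset A [roi_dataset()].
#' @param target Target model [rdm()].
#' @param controls List of control [rdm()]s.
#' @return Subject-level correlation scalar.
#' @export
roi_rsa <- function(dataset, target, controls = list()) {
  stopifnot(inherits(dataset, "roi_dataset"))
  nd <- neural_dataset(dataset$betas, dataset$trial_image_ids)
  nrdm <- neural_rdm(prepare_patterns(nd))
  partial_rsa(nrdm, target, controls)
}

#' Write / read an ROI dataset as TSV
#'
#' Plain-text trial x voxel table: first column `image_id`, then one column
#' per voxel (`v1`, `v2`, ...).  Localizer t values, when present, are
#' stored as an extra pseudo-row with `image_id` = `".localizer_t"`.
#'
#' @param dataset A [roi_dataset()].
#' @param path TSV path.
#' @param roi ROI name for `read_roi_tsv`.
#' @return `write_roi_tsv`: `path` invisibly; `read_roi_tsv`: the dataset.
#' @export
write_roi_tsv <- function(dataset, path) {
  stopifnot(inherits(dataset, "roi_dataset"))
  d <- data.frame(image_id = dataset$trial_image_ids, dataset$betas)
  names(d) <- c("image_id", paste0("v", seq_len(ncol(dataset$betas))))
  if (!is.null(dataset$localizer_t)) {
    d <- rbind(d, c(".localizer_t", as.list(dataset$localizer_t)))
  }
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_roi_tsv
#' @export
read_roi_tsv <- function(path, roi = "roi") {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  loc <- NULL
  isloc <- d$image_id == ".localizer_t"
  if (any(isloc)) {
    loc <- as.numeric(d[isloc, -1])
    d <- d[!isloc, , drop = FALSE]
  }
  roi_dataset(roi, as.matrix(sapply(d[, -1, drop = FALSE], as.numeric)),
              d$image_id, loc)
}
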