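# Volumetric external interface: 4D beta series + mask as NIfTI, trial
# image ids as a TSV sidecar, scalar brain maps as 3D NIfTI.

#' Write a volumetric neural dataset as NIfTI + TSV sidecar
#'
#' Produces `<prefix>_betas.nii.gz` (4D, one volume per trial, zeros
#' outside the mask), `<prefix>_mask.nii.gz`, and `<prefix>_trials.tsv`
#' (columns `trial`, `image_id`).
#'
#' @param data A [neural_dataset()] with voxel grid coordinates and mask.
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_neural_nifti <- function(data, prefix) {
  stopifnot(inherits(data, "neural_dataset"))
  if (is.null(data$voxel_index) || is.null(data$mask)) {
    stop("dataset needs voxel_index and mask for volumetric output",
         call. = FALSE)
  }
  dm <- dim(data$mask)
  vol4 <- array(0, c(dm, nrow(data$betas)))
  lin <- data$voxel_index[, 1] +
    (data$voxel_index[, 2] - 1L) * dm[1] +
    (data$voxel_index[, 3] - 1L) * dm[1] * dm[2]
  for (t in seq_len(nrow(data$betas))) {
    v <- array(0, dm)
    v[lin] <- data$betas[t, ]
    vol4[, , , t] <- v
  }
  vs <- data$voxel_size_mm
  img4 <- RNifti::asNifti(vol4)
  RNifti::pixdim(img4) <- c(vs, vs, vs, 1)
  RNifti::writeNifti(img4, paste0(prefix, "_betas.nii.gz"))
  imgm <- RNifti::asNifti(array(as.numeric(data$mask), dm))
  RNifti::pixdim(imgm) <- rep(vs, 3)
  RNifti::writeNifti(imgm, paste0(prefix, "_mask.nii.gz"))
  utils::write.table(data.frame(trial = seq_len(nrow(data$betas)),
                                image_id = data$trial_image_ids),
                     paste0(prefix, "_trials.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Read a volumetric neural dataset written by [write_neural_nifti()]
#'
#' @param prefix Path prefix used when writing.
#' @return A [neural_dataset()].
#' @export
read_neural_nifti <- function(prefix) {
  betas4 <- RNifti::readNifti(paste0(prefix, "_betas.nii.gz"))
  maskvol <- RNifti::readNifti(paste0(prefix, "_mask.nii.gz"))
  trials <- utils::read.table(paste0(prefix, "_trials.tsv"), sep = "\t",
                              header = TRUE, stringsAsFactors = FALSE)
  mask <- array(maskvol > 0.5, dim(maskvol))
  vox <- which(mask, arr.ind = TRUE)
  o <- order(vox[, 1], vox[, 2], vox[, 3], method = "radix")
  vox <- vox[o, , drop = FALSE]
  dm <- dim(mask)
  lin <- vox[, 1] + (vox[, 2] - 1L) * dm[1] + (vox[, 3] - 1L) * dm[1] * dm[2]
  arr <- unclass(betas4)
  betas <- t(apply(arr, 4, function(v) v[lin]))
  if (dim(arr)[4] == 1L) betas <- matrix(betas, nrow = 1L)
  vs <- RNifti::pixdim(betas4)[1]
  neural_dataset(betas, trials$image_id, voxel_index = vox,
                 voxel_size_mm = vs, mask = mask)
}

#' Write / read a scalar brain map as NIfTI
#'
#' @param map A [brain_map()].
#' @param path Output `.nii`/`.nii.gz` path.
#' @param space Space label to attach on read.
#' @return `write_brain_map`: `path` invisibly; `read_brain_map`: the
#'   [brain_map()] (NaN outside mask preserved).
#' @export
write_brain_map <- function(map, path) {
  stopifnot(inherits(map, "brain_map"))
  vs <- map$voxel_size_mm
  img <- RNifti::asNifti(map$volume)
  RNifti::pixdim(img) <- rep(vs, 3)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_brain_map
#' @export
read_brain_map <- function(path, space = "shared") {
  img <- RNifti::readNifti(path)
  brain_map(array(as.numeric(img), dim(img)),
            voxel_size_mm = RNifti::pixdim(img)[1], space = space)
}
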