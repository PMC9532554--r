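stop_format <- function(path, ...) {
  stop(errorCondition(paste0(..., " [", path, "]"),
                      class = c("progreg_format_error", "error")))
}

#' Read and write volumes as NIfTI-1
#'
#' Volumes and label maps are exchanged as 3D NIfTI (`.nii` / `.nii.gz`).
#' Any affine is accepted, but registration operates in voxel space; voxel
#' spacing is carried from/to `pixdim`. Intensity volumes are written as
#' float32 (lossless round-trip for float32 data) and label maps as int16.
#'
#' @param path file to read or write.
#' @param v a `volume` to write.
#' @return `read_volume` returns a `volume`; writers return `path`
#'   invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_format(path, "file not found")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_format(path, "unreadable NIfTI: ",
                                                  conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop_format(path, "expected a 3-d volume, got ", length(d), " dims")
  as_volume(array(as.numeric(img), d), spacing = RNifti::pixdim(img)[1:3])
}

#' @rdname read_volume
#' @export
write_volume <- function(v, path) {
  v <- as_volume(v)
  img <- RNifti::asNifti(unclass(v))
  RNifti::pixdim(img) <- attr(v, "spacing")
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname read_volume
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop_format(path, "file not found")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_format(path, "unreadable NIfTI: ",
                                                  conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 3L)
    stop_format(path, "expected a 3-d label map, got ", length(d), " dims")
  as_label_map(array(as.integer(img), d))
}

#' @rdname read_volume
#' @param l a `label_map` to write.
#' @export
write_labels <- function(l, path) {
  l <- as_label_map(l)
  img <- RNifti::asNifti(unclass(l))
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

.flow_descrip <- "progreg flow: (D,H,W)-axis displacements, voxel units"

#' Read and write displacement fields as 4D NIfTI
#'
#' Flows are serialized as 4D NIfTI with the 4th dimension of size 3; the
#' components are displacements along the D, H, W axes in voxel units (the
#' convention is recorded in the header description field). Round-trip is
#' exact for float32 data.
#'
#' @param path file to read or write.
#' @param u a `flow` to write.
#' @return `read_flow` returns a `flow`; `write_flow` returns `path`
#'   invisibly.
#' @export
read_flow <- function(path) {
  if (!file.exists(path)) stop_format(path, "file not found")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_format(path, "unreadable NIfTI: ",
                                                  conditionMessage(e)))
  d <- dim(img)
  if (length(d) != 4L || d[4] != 3L)
    stop_format(path, "expected a 4-d flow with last dimension 3, got ",
                paste(d, collapse = "x"))
  as_flow(aperm(array(as.numeric(img), d), c(4L, 1L, 2L, 3L)))
}

#' @rdname read_flow
#' @export
write_flow <- function(u, path) {
  u <- as_flow(u)
  arr <- aperm(unclass(u), c(2L, 3L, 4L, 1L))
  img <- RNifti::asNifti(arr)
  img$descrip <- .flow_descrip
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}
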