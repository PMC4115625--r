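#' Read a NIfTI-1 volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return List with `data` (plain numeric array), `voxel_size_mm` (first
#'   three pixdim entries) and `xform` (the 4 x 4 spatial transform).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_("file not found: %s", path)
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  list(data = array(as.numeric(img), dim = dim(img)),
       voxel_size_mm = as.numeric(pd[seq_len(min(3L, length(pd)))]),
       xform = RNifti::xform(img))
}

#' Write a NIfTI-1 volume
#'
#' @param data 3D or 4D numeric (or logical) array.
#' @param voxel_size_mm 3 positive spacings in mm.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_volume <- function(data, voxel_size_mm, path) {
  if (is.logical(data)) data <- array(as.numeric(data), dim(data))
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- if (length(dim(data)) == 3L) voxel_size_mm
                         else c(voxel_size_mm, 1)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a design matrix as delimited text
#'
#' Tab-separated, one header row of regressor labels.
#' @param X A [build_design_matrix()] result.
#' @param path Output path.
#' @export
write_design_matrix <- function(X, path) {
  stopifnot(inherits(X, "design_matrix"))
  utils::write.table(X$values, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write a cluster table as delimited text
#' @param table A [clusterize()] data.frame.
#' @param path Output path.
#' @export
write_cluster_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# cohort manifest: subject id, group, seed, file path
write_manifest <- function(ids, groups, seeds, paths, file) {
  utils::write.table(data.frame(subject = ids, group = groups, seed = seeds,
                                path = paths),
                     file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(file)
}
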