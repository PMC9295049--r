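## ---- file formats: delimited matrices, result TSVs, optional NIfTI

#' Read two-group data from delimited matrix files
#'
#' Each file holds one group's matrix, vertices in rows (row-major lattice
#' order, x fastest) and samples in columns, whitespace- or tab-delimited,
#' no header.
#'
#' @param path_x,path_y file paths for the two groups.
#' @param dims optional lattice dimensions.
#' @return a [two_group_data()].
#' @export
read_two_group_data <- function(path_x, path_y, dims = NULL) {
  x <- as.matrix(utils::read.table(path_x, header = FALSE))
  y <- as.matrix(utils::read.table(path_y, header = FALSE))
  dimnames(x) <- dimnames(y) <- NULL
  if (nrow(x) != nrow(y))
    stop("group matrices disagree on the number of vertices (",
         nrow(x), " vs ", nrow(y), ")")
  two_group_data(x, y, dims = dims)
}

#' Write two-group data to delimited matrix files
#'
#' @param data a [two_group_data()].
#' @param path_x,path_y output paths.
#' @export
write_two_group_data <- function(data, path_x, path_y) {
  utils::write.table(data$x, path_x, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data$y, path_y, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(path_x, path_y))
}

#' Write per-vertex local FDR results to TSV
#'
#' Columns: `vertex` (1-based, row-major with x fastest), lattice
#' coordinates, `lfdr`, and a 0/1 `discovered` flag at the fit's threshold.
#'
#' @param fit a [graphmm()] fit.
#' @param path output file.
#' @export
write_lfdr_tsv <- function(fit, path) {
  d <- as.data.frame(fit)
  d$discovered <- as.integer(d$discovered)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a group of NIfTI volumes into a two-group data matrix
#'
#' Each file becomes one sample column; voxel order is row-major (x
#' fastest), matching [lattice_graph()].  Requires the RNifti package.
#'
#' @param files_x,files_y character vectors of NIfTI paths per group.
#' @return a [two_group_data()] with `dims` from the volume geometry.
#' @export
read_nifti_groups <- function(files_x, files_y) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("reading NIfTI volumes requires the RNifti package")
  rd <- function(fs) {
    vols <- lapply(fs, RNifti::readNifti)
    dims <- dim(vols[[1L]])
    for (v in vols)
      if (!identical(dim(v), dims)) stop("NIfTI volumes differ in geometry")
    list(m = vapply(vols, as.vector, numeric(prod(dims))), dims = dims)
  }
  gx <- rd(files_x)
  gy <- rd(files_y)
  if (!identical(gx$dims, gy$dims)) stop("groups differ in volume geometry")
  two_group_data(gx$m, gy$m, dims = gx$dims)
}

#' Write the fitted local FDRs as a NIfTI volume
#'
#' @param fit a [graphmm()] fit.
#' @param path output `.nii` / `.nii.gz` path.
#' @param reference optional NIfTI image supplying header geometry.
#' @export
write_lfdr_nifti <- function(fit, path, reference = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("writing NIfTI volumes requires the RNifti package")
  vol <- array(fit$lfdr, dim = fit$dims)
  img <- if (is.null(reference)) RNifti::asNifti(vol)
         else RNifti::asNifti(vol, reference = reference)
  RNifti::writeNifti(img, path)
  invisible(path)
}
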