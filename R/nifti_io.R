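# NIfTI plumbing shared by masks, statistical maps and 4-D PDF images.
# Grids are written as an RAS+ diagonal sform/qform (spacing on the
# diagonal, origin in the translation column).

nifti_from_array <- function(arr, grid) {
  img <- RNifti::asNifti(arr)
  nd <- length(dim(arr))
  RNifti::pixdim(img) <- c(rep(grid$spacing, 3L), rep(1, nd - 3L))
  m <- diag(c(rep(grid$spacing, 3L), 1))
  m[1:3, 4] <- grid$origin
  img <- RNifti::`sform<-`(img, structure(m, code = 2L))
  img <- RNifti::`qform<-`(img, structure(m, code = 2L))
  img
}

grid_from_nifti <- function(img) {
  d <- dim(img)
  pd <- RNifti::pixdim(img)[1:3]
  if (max(pd) - min(pd) > 1e-6)
    stopf("anisotropic NIfTI voxels (%s) are not supported",
          paste(signif(pd, 4), collapse = " x "))
  xf <- RNifti::xform(img)
  offdiag <- xf[1:3, 1:3]
  diag(offdiag) <- 0
  if (any(abs(offdiag) > 1e-4) || any(diag(xf)[1:3] < 0))
    stopf("rotated or non-RAS NIfTI orientation is not supported; reorient first")
  origin <- RNifti::voxelToWorld(c(1, 1, 1), img)
  sp <- pd[1]
  structure(list(spacing = sp, origin = as.numeric(origin),
                 shape = as.integer(d[1:3])),
            class = "grid_spec")
}

#' Write / read a binary ROI mask as NIfTI
#'
#' Masks are stored as uint8 gzip-compressed NIfTI-1 with an RAS+
#' diagonal affine carrying the grid spacing and origin.
#'
#' @param mask an \code{roi_mask}.
#' @param path output \code{.nii} or \code{.nii.gz} path.
#' @return invisibly, the path.
#' @export
write_mask_nifti <- function(mask, path) {
  img <- nifti_from_array(array(as.integer(mask$vox), dim = mask$grid$shape),
                          mask$grid)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' @rdname write_mask_nifti
#' @param threshold values > threshold are treated as set when reading.
#' @return \code{read_mask_nifti}: an \code{roi_mask}.
#' @export
read_mask_nifti <- function(path, threshold = 0.5) {
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img)
  roi_mask(grid, array(as.vector(img) > threshold, dim = grid$shape),
           provenance = paste0("file: ", basename(path)))
}

#' Read a statistical map or integer label image
#'
#' @param path NIfTI file.
#' @return list with \code{data} (numeric array) and \code{grid}
#'   (\code{grid_spec}).
#' @export
read_statmap_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  grid <- grid_from_nifti(img)
  list(data = array(as.vector(img), dim = grid$shape), grid = grid)
}

#' Write a statistical map
#' @param data numeric array on \code{grid}.
#' @param grid a \code{grid_spec}.
#' @param path output NIfTI path.
#' @return invisibly, the path.
#' @export
write_statmap_nifti <- function(data, grid, path) {
  img <- nifti_from_array(array(as.numeric(data), dim = grid$shape), grid)
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}
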