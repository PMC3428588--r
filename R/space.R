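#' Affine transforms between stereotaxic spaces
#'
#' Wraps a 4x4 homogeneous matrix mapping mm coordinates to mm
#' coordinates. Internal analysis uses Talairach coordinates; data fitted
#' to the MNI template are adjusted with a built-in MNI-to-Talairach
#' affine before analysis.
#'
#' @param matrix 4x4 numeric matrix; last row must be (0,0,0,1) and the
#'   matrix must be invertible.
#' @return An object of class \code{affine_transform}.
#' @export
affine_transform <- function(matrix) {
  matrix <- unname(as.matrix(matrix))
  stopifnot(identical(dim(matrix), c(4L, 4L)))
  if (!isTRUE(all.equal(matrix[4, ], c(0, 0, 0, 1))))
    stopf("affine last row must be (0, 0, 0, 1)")
  d <- det(matrix)
  if (!is.finite(d) || abs(d) < 1e-12)
    stopf("affine matrix is singular")
  structure(list(matrix = matrix), class = "affine_transform")
}

#' Built-in MNI-to-Talairach pooled affines
#'
#' The two published icbm2tal pooled-coefficient matrices, for data
#' spatially normalized with the FSL or SPM template lineage. The FSL
#' variant is the package default; either can be selected, or a custom
#' matrix supplied via \code{read_affine()}.
#'
#' @param variant \code{"fsl"} (default) or \code{"spm"}.
#' @return an \code{affine_transform}.
#' @references Bias between MNI and Talairach coordinates analyzed
#'   using the ICBM-152 brain template. Hum Brain Mapp 28:1194-1205
#'   (2007).
#' @export
mni_to_tal <- function(variant = c("fsl", "spm")) {
  variant <- match.arg(variant)
  m <- switch(variant,
    fsl = matrix(c(0.9464,  0.0034, -0.0026, -1.0680,
                   -0.0083, 0.9479, -0.0580, -2.5820,
                   0.0053,  0.0617,  0.9010,  0.0093,
                   0, 0, 0, 1), 4L, 4L, byrow = TRUE),
    spm = matrix(c(0.9254,  0.0024, -0.0118, -1.0207,
                   -0.0048, 0.9316, -0.0871, -1.7667,
                   0.0152,  0.0883,  0.8924,  4.0926,
                   0, 0, 0, 1), 4L, 4L, byrow = TRUE))
  affine_transform(m)
}

#' Read a 4x4 affine from whitespace-delimited text
#' @param path text file holding 4 rows of 4 numbers.
#' @return an \code{affine_transform}.
#' @export
read_affine <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  affine_transform(m)
}

#' Invert an affine transform
#' @param t an \code{affine_transform}.
#' @return the inverse \code{affine_transform}.
#' @export
affine_inverse <- function(t) affine_transform(solve(t$matrix))

#' Apply an affine transform to mm coordinates
#'
#' @param t an \code{affine_transform}.
#' @param coords numeric matrix (n x 3) or length-3 vector.
#' @return transformed coordinates, same shape as input.
#' @export
apply_to_coords <- function(t, coords) {
  vec <- is.null(dim(coords))
  if (vec) coords <- matrix(coords, ncol = 3L)
  stopifnot(all(is.finite(coords)))
  out <- tcrossprod(cbind(coords, 1), t$matrix)
  out <- out[, 1:3, drop = FALSE]
  if (vec) drop(out) else out
}

#' Apply an affine to the foci of a table
#'
#' Transforms every coordinate and re-tags the space. Used to adjust
#' MNI-fitted foci to Talairach space before PDF construction.
#'
#' @param t an \code{affine_transform}.
#' @param table a \code{foci_table}.
#' @param new_space space tag of the result (default \code{"TAL"}).
#' @return a \code{foci_table}.
#' @export
apply_to_foci <- function(t, table, new_space = "TAL") {
  r <- table$records
  if (nrow(r)) {
    xyz <- apply_to_coords(t, as.matrix(r[, c("x", "y", "z")]))
    r[, c("x", "y", "z")] <- xyz
  }
  foci_table(r, space = new_space)
}

#' Resample a binary mask through an affine transform
#'
#' Pull (inverse-mapping) nearest-neighbor resampling: each output voxel
#' is set iff its center, mapped through the inverse transform, falls in a
#' set input voxel. Binary data stay binary and no holes are introduced.
#'
#' @param t an \code{affine_transform} mapping input-space mm to
#'   output-space mm.
#' @param mask an \code{roi_mask} on the input grid.
#' @param out_grid a \code{grid_spec} for the output.
#' @return an \code{roi_mask} on \code{out_grid}.
#' @export
apply_to_mask <- function(t, mask, out_grid) {
  tinv <- affine_inverse(t)
  s <- out_grid$shape
  centers <- cbind(
    rep(grid_axis(out_grid, 1L), times = s[2] * s[3]),
    rep(rep(grid_axis(out_grid, 2L), each = s[1]), times = s[3]),
    rep(grid_axis(out_grid, 3L), each = s[1] * s[2]))
  src <- apply_to_coords(tinv, centers)
  idx <- coord_to_voxel(mask$grid, src)
  ok <- !is.na(idx[, 1])
  vox <- array(FALSE, dim = s)
  if (any(ok))
    vox[which(ok)] <- mask$vox[voxel_linear(mask$grid, idx[ok, , drop = FALSE])]
  roi_mask(out_grid, vox,
           provenance = paste0("affine-resampled: ", mask$provenance))
}
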