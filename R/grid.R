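#' Define a voxel grid over a stereotaxic bounding box
#'
#' Grids are node-centered: \code{origin} is the mm coordinate of the
#' center of voxel (1,1,1), and voxel (i,j,k) has center
#' \code{origin + (c(i,j,k) - 1) * spacing}. Axes follow the Talairach
#' convention: x left(-)/right(+), y posterior(-)/anterior(+),
#' z inferior(-)/superior(+). The default bounding box,
#' x in [-90, 90], y in [-126, 90], z in [-72, 108] mm, is a generous
#' superset of the atlas brain extent; enlarging the box only adds empty
#' voxels and leaves all probabilities unchanged.
#'
#' @param spacing isotropic voxel size in mm (1 or 2 for PDF work; any
#'   positive value is accepted for ROI utilities).
#' @param box 2x3 matrix of axis limits in mm (rows: lo, hi), or NULL for
#'   the default Talairach box.
#' @return An object of class \code{grid_spec} with fields \code{spacing},
#'   \code{origin} (length-3), \code{shape} (length-3 integer).
#' @examples
#' g <- grid_spec(2)
#' g$shape     # 91 109 91
#' @export
grid_spec <- function(spacing = 2, box = NULL) {
  stopifnot(is.numeric(spacing), length(spacing) == 1L, spacing > 0)
  if (is.null(box))
    box <- rbind(lo = c(-90, -126, -72), hi = c(90, 90, 108))
  stopifnot(all(box[2, ] > box[1, ]))
  origin <- box[1, ]
  shape <- as.integer(floor((box[2, ] - box[1, ]) / spacing + 1e-9)) + 1L
  structure(list(spacing = spacing, origin = unname(origin),
                 shape = unname(shape)),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %g mm, %d x %d x %d voxels, origin (%g, %g, %g)\n",
              x$spacing, x$shape[1], x$shape[2], x$shape[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(a$spacing, b$spacing)) &&
    isTRUE(all.equal(a$origin, b$origin)) &&
    identical(as.integer(a$shape), as.integer(b$shape))
}

grid_nvox <- function(grid) prod(grid$shape)

#' Map mm coordinates to voxel indices
#'
#' Assigns each coordinate to the nearest voxel center; a coordinate
#' exactly halfway between two centers rounds away from zero per axis
#' (so half-spacing ties resolve outward symmetrically in both
#' hemispheres). Coordinates outside the bounding box map to NA rows.
#'
#' @param grid a \code{grid_spec}.
#' @param coords numeric matrix (n x 3) or length-3 vector of mm
#'   coordinates.
#' @return integer matrix (n x 3) of 1-based voxel indices; out-of-grid
#'   coordinates give NA in all three columns.
#' @export
coord_to_voxel <- function(grid, coords) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3L)
  if (nrow(coords) == 0L)
    return(matrix(integer(), 0L, 3L, dimnames = list(NULL, c("i", "j", "k"))))
  shift <- grid$origin / grid$spacing
  if (all(abs(shift - round(shift)) < 1e-9)) {
    # voxel centers sit on multiples of the spacing: round the scaled
    # coordinate itself, so ties break away from the stereotaxic origin
    idx <- sweep(round_half_away(coords / grid$spacing), 2L,
                 round(shift)) + 1
  } else {
    idx <- round_half_away(sweep(coords, 2L, grid$origin) /
                             grid$spacing) + 1
  }
  bad <- idx < 1 | idx > matrix(grid$shape, nrow(idx), 3L, byrow = TRUE)
  out <- rowSums(bad) > 0
  idx[out, ] <- NA_integer_
  storage.mode(idx) <- "integer"
  colnames(idx) <- c("i", "j", "k")
  idx
}

#' Voxel centers in mm
#' @param grid a \code{grid_spec}.
#' @param idx integer matrix (n x 3) of 1-based voxel indices.
#' @return numeric matrix (n x 3) of mm coordinates.
#' @export
voxel_to_coord <- function(grid, idx) {
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = 3L)
  sweep((idx - 1) * grid$spacing, 2L, grid$origin, `+`)
}

# linear (column-major) voxel index from an (n x 3) index matrix
voxel_linear <- function(grid, idx) {
  s <- grid$shape
  as.integer(idx[, 1] + (idx[, 2] - 1L) * s[1] +
               (idx[, 3] - 1L) * s[1] * s[2])
}

# mm coordinates of every voxel center along each axis
grid_axis <- function(grid, axis) {
  grid$origin[axis] + (seq_len(grid$shape[axis]) - 1) * grid$spacing
}
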