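#' Construct a binary ROI mask on a voxel grid
#'
#' @param grid a \code{grid_spec}.
#' @param vox logical array matching \code{grid$shape} (default all FALSE).
#' @param provenance free-text description of how the ROI was made.
#' @return An object of class \code{roi_mask}.
#' @export
roi_mask <- function(grid, vox = NULL, provenance = "") {
  stopifnot(inherits(grid, "grid_spec"))
  if (is.null(vox)) vox <- array(FALSE, dim = grid$shape)
  vox <- array(as.logical(vox), dim = dim(vox))
  stopifnot(identical(as.integer(dim(vox)), as.integer(grid$shape)))
  vox[is.na(vox)] <- FALSE
  structure(list(grid = grid, vox = vox, provenance = provenance),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> %d voxels set (%g mm^3) on %g-mm grid%s\n",
              sum(x$vox), mask_volume(x), x$grid$spacing,
              if (nzchar(x$provenance)) paste0(" [", x$provenance, "]") else ""))
  invisible(x)
}

#' ROI volume in cubic millimetres
#'
#' Volume is the set-voxel count times the voxel volume
#' (\code{spacing^3}); it is the quantity entering the expected
#' probability as the ROI-to-brain volume ratio.
#'
#' @param mask an \code{roi_mask}.
#' @return numeric volume in mm^3.
#' @export
mask_volume <- function(mask) sum(mask$vox) * mask$grid$spacing^3

#' Threshold a statistical map into an ROI
#'
#' Voxels with value >= threshold are set (closed threshold, so a map
#' thresholded "at z = 2.5" includes voxels exactly at 2.5). Non-finite
#' map values are treated as below threshold.
#'
#' @param map numeric array on \code{grid}, or an object returned by
#'   \code{read_statmap_nifti()}.
#' @param threshold numeric cutoff.
#' @param grid a \code{grid_spec} (ignored when \code{map} carries one).
#' @return an \code{roi_mask}.
#' @export
roi_from_statmap <- function(map, threshold, grid = NULL) {
  if (is.list(map) && !is.null(map$grid)) {
    grid <- map$grid
    map <- map$data
  }
  stopifnot(inherits(grid, "grid_spec"))
  nf <- !is.finite(map)
  if (any(nf)) {
    warnf("%d non-finite map value(s) treated as below threshold", sum(nf))
    map[nf] <- -Inf
  }
  roi_mask(grid, map >= threshold,
           provenance = sprintf("statmap >= %g", threshold))
}

#' Select atlas labels into an ROI
#'
#' @param atlas integer-valued array on \code{grid}, or an object from
#'   \code{read_statmap_nifti()}.
#' @param values integer labels to include.
#' @param grid a \code{grid_spec} (ignored when \code{atlas} carries one).
#' @return an \code{roi_mask} (empty selection warns).
#' @export
roi_from_labels <- function(atlas, values, grid = NULL) {
  if (is.list(atlas) && !is.null(atlas$grid)) {
    grid <- atlas$grid
    atlas <- atlas$data
  }
  stopifnot(inherits(grid, "grid_spec"))
  vox <- array(atlas %in% values, dim = grid$shape)
  if (!any(vox)) warnf("label selection {%s} is empty",
                       paste(values, collapse = ", "))
  roi_mask(grid, vox,
           provenance = sprintf("atlas labels {%s}",
                                paste(values, collapse = ",")))
}

#' Spherical ROI
#'
#' Sets every voxel whose center lies within \code{radius} mm of
#' \code{center}.
#'
#' @param center length-3 mm coordinate.
#' @param radius mm, > 0.
#' @param grid a \code{grid_spec}.
#' @return an \code{roi_mask}.
#' @export
roi_sphere <- function(center, radius, grid) {
  stopifnot(radius > 0, length(center) == 3L)
  dx <- grid_axis(grid, 1L) - center[1]
  dy <- grid_axis(grid, 2L) - center[2]
  dz <- grid_axis(grid, 3L) - center[3]
  r2 <- radius^2
  vox <- outer(outer(dx^2, dy^2, `+`), dz^2, `+`) <= r2
  roi_mask(grid, vox,
           provenance = sprintf("sphere r=%g at (%g,%g,%g)", radius,
                                center[1], center[2], center[3]))
}

#' Morphological dilation with a full 3x3x3 kernel
#'
#' @param mask an \code{roi_mask}.
#' @param iterations number of dilation passes (0 returns the mask
#'   unchanged).
#' @return an \code{roi_mask}.
#' @export
dilate <- function(mask, iterations = 1L) {
  stopifnot(iterations >= 0L)
  vox <- mask$vox
  for (it in seq_len(iterations)) {
    acc <- vox
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0L && dj == 0L && dk == 0L) next
      acc <- acc | shift3(shift3(shift3(vox, 1L, di), 2L, dj), 3L, dk)
    }
    vox <- acc
  }
  roi_mask(mask$grid, vox,
           provenance = sprintf("%s + dilate x%d", mask$provenance,
                                iterations))
}

#' Half-space clip of a mask
#'
#' Keeps voxels on one side of an axis-aligned mm cutoff, e.g. the
#' posterior part of a region (\code{axis = 2, side = "below",
#' cutoff = -27} keeps y <= -27 mm).
#'
#' @param mask an \code{roi_mask}.
#' @param axis 1 (x), 2 (y) or 3 (z).
#' @param side \code{"below"} (keep centers <= cutoff) or \code{"above"}
#'   (keep centers >= cutoff).
#' @param cutoff mm coordinate of the clipping plane.
#' @return an \code{roi_mask}.
#' @export
clip_halfspace <- function(mask, axis, side = c("below", "above"), cutoff) {
  side <- match.arg(side)
  ax <- grid_axis(mask$grid, axis)
  keep <- if (side == "below") ax <= cutoff else ax >= cutoff
  vox <- mask$vox
  d <- dim(vox)
  keep_arr <- array(switch(axis,
                           rep(keep, times = d[2] * d[3]),
                           rep(rep(keep, each = d[1]), times = d[3]),
                           rep(keep, each = d[1] * d[2])), dim = d)
  roi_mask(mask$grid, vox & keep_arr,
           provenance = sprintf("%s, clip axis %d %s %g", mask$provenance,
                                axis, side, cutoff))
}

#' Convert a mask between 1-mm and 2-mm precision
#'
#' Both grids share the bounding box and origin; the coarse voxel at
#' 1-based index i along an axis owns the fine voxels 2i-1 and 2i, so
#' each coarse voxel has exactly 8 children (clipped only on the
#' most-positive box faces, which brain masks never reach).
#' Up-conversion (2 mm to 1 mm) sets every child of a set parent, so
#' volume is preserved exactly. Down-conversion (1 mm to 2 mm) sets a
#' coarse voxel iff at least half of its in-grid children are set
#' (majority rule, ties set); \code{rule = "any"} instead sets the
#' parent when any child is set.
#'
#' @param mask an \code{roi_mask} with spacing 1 or 2.
#' @param target_spacing 1 or 2.
#' @param rule down-conversion rule, \code{"majority"} (default) or
#'   \code{"any"}.
#' @return an \code{roi_mask} on the target grid (same bounding box).
#' @export
resample_mask <- function(mask, target_spacing,
                          rule = c("majority", "any")) {
  rule <- match.arg(rule)
  sp_in <- mask$grid$spacing
  if (!sp_in %in% c(1, 2) || !target_spacing %in% c(1, 2))
    stopf("resample_mask supports only 1-mm and 2-mm spacings (got %g -> %g)",
          sp_in, target_spacing)
  if (sp_in == target_spacing) return(mask)
  box <- rbind(mask$grid$origin,
               mask$grid$origin + (mask$grid$shape - 1L) * sp_in)
  out_grid <- grid_spec(target_spacing, box = box)
  s <- out_grid$shape
  if (target_spacing < sp_in) {
    # up-conversion: fine voxel m belongs to coarse parent ceiling(m/2)
    pmap <- lapply(1:3, function(a)
      pmin(as.integer(ceiling(seq_len(s[a]) / 2)), mask$grid$shape[a]))
    vox <- mask$vox[pmap[[1]], pmap[[2]], pmap[[3]], drop = FALSE]
  } else {
    # down-conversion: tally in-grid children per coarse voxel along each axis
    pmap <- lapply(1:3, function(a)
      pmin(as.integer(ceiling(seq_len(mask$grid$shape[a]) / 2)), s[a]))
    n_set <- array(as.numeric(mask$vox), dim = mask$grid$shape)
    n_kid <- array(1, dim = mask$grid$shape)
    for (a in 1:3) {
      g <- pmap[[a]]
      collapse <- function(arr) {
        d <- dim(arr)
        perm <- c(a, setdiff(1:3, a))
        m <- matrix(aperm(arr, perm), nrow = d[a])
        agg <- rowsum(m, g, reorder = TRUE)
        full <- matrix(0, s[a], ncol(m))
        full[as.integer(rownames(agg)), ] <- agg
        dn <- d
        dn[a] <- s[a]
        aperm(array(full, dim = dn[perm]), order(perm))
      }
      n_set <- collapse(n_set)
      n_kid <- collapse(n_kid)
    }
    vox <- if (rule == "majority") n_kid > 0 & n_set >= n_kid / 2
           else n_set > 0
  }
  roi_mask(out_grid, vox,
           provenance = sprintf("%s, resampled to %g mm", mask$provenance,
                                target_spacing))
}

#' Intersection of two masks on the same grid
#' @param a,b \code{roi_mask} objects on identical grids.
#' @return an \code{roi_mask}.
#' @export
mask_intersect <- function(a, b) {
  if (!grid_equal(a$grid, b$grid))
    stopf("masks are on different grids; resample first")
  roi_mask(a$grid, a$vox & b$vox,
           provenance = paste(a$provenance, "&", b$provenance))
}
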