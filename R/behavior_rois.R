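#' Separable 3-D Gaussian smoothing
#'
#' Convolves a volume with an isotropic Gaussian specified by its full
#' width at half maximum: sigma = FWHM / (2 sqrt(2 ln 2)) per axis, in mm
#' converted to voxels by the grid spacing. The discrete kernel is
#' sampled at voxel offsets out to 4 sigma and renormalized to unit sum,
#' so total mass is conserved exactly away from the volume boundary;
#' boundaries use zero padding (densities vanish off-grid).
#'
#' @param vol numeric 3-D array.
#' @param fwhm_mm full width at half maximum in mm (> 0).
#' @param spacing voxel size in mm.
#' @return smoothed array, same dimensions.
#' @export
gaussian_smooth <- function(vol, fwhm_mm, spacing = 1) {
  stopifnot(fwhm_mm > 0, spacing > 0)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / spacing
  r <- max(1L, as.integer(ceiling(4 * sigma_vox)))
  k <- exp(-((-r):r)^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  out <- vol
  for (axis in 1:3) {
    acc <- k[r + 1L] * out
    for (o in seq_len(r)) {
      acc <- acc + k[r + 1L + o] * (shift3(out, axis, o) +
                                      shift3(out, axis, -o))
    }
    out <- acc
  }
  out
}

#' Behavior-specific ROI from a smoothed PDF channel
#'
#' Smooths one sub-domain's probability-density channel (Gaussian,
#' default FWHM 10 mm) to approximate a continuous density, then keeps
#' voxels at or above a fraction of the smoothed maximum (default 25%).
#'
#' @param pdf a \code{behavior_pdf4d}.
#' @param b sub-domain id.
#' @param fwhm_mm smoothing kernel FWHM in mm.
#' @param rel_threshold fraction of the smoothed maximum (0--1).
#' @return an \code{roi_mask} (empty, with a warning, for a zero
#'   channel).
#' @export
behavior_specific_roi <- function(pdf, b, fwhm_mm = 10,
                                  rel_threshold = 0.25) {
  ch <- pdf$channels[[b]]
  if (!length(ch$idx)) {
    warnf("sub-domain %d has an all-zero channel; ROI is empty", b)
    return(roi_mask(pdf$grid,
                    provenance = sprintf("behavior-ROI b=%d (empty)", b)))
  }
  sm <- gaussian_smooth(pdf_channel_dense(pdf, b), fwhm_mm,
                        spacing = pdf$grid$spacing)
  mx <- max(sm)
  vox <- if (rel_threshold <= 0) sm > 0 else sm >= rel_threshold * mx
  roi_mask(pdf$grid, vox,
           provenance = sprintf("behavior-ROI b=%d fwhm=%g thr=%g", b,
                                fwhm_mm, rel_threshold))
}

#' Self-consistency rank matrix across behavior-specific ROIs
#'
#' For every populated sub-domain i, builds its behavior-specific ROI and
#' runs the full behavior analysis on it, recording the rank (1 =
#' largest z) of every sub-domain in the resulting profile. A
#' well-separated PDF should rank each sub-domain first on its own ROI
#' with a large z. Ties in z are broken by sub-domain id (deterministic).
#'
#' @param pdf a \code{behavior_pdf4d}.
#' @param brain_mask whole-brain \code{roi_mask} on the PDF grid.
#' @param fwhm_mm,rel_threshold passed to \code{behavior_specific_roi}.
#' @param subdomains integer ids to process (default: all populated).
#' @return An object of class \code{rank_matrix}: list with \code{ranks}
#'   (n x 51 integer matrix, rows = ROI source sub-domain), \code{z}
#'   (n x 51 z matrix), \code{diag_rank} (named integer: own-sub-domain
#'   rank per row), \code{diag_z}, \code{tally} (table of diagonal
#'   ranks).
#' @export
self_consistency <- function(pdf, brain_mask, fwhm_mm = 10,
                             rel_threshold = 0.25, subdomains = NULL) {
  pop <- which(pdf$n_foci > 0)
  if (length(pop) < 2L)
    stopf("self-consistency needs at least 2 populated channels")
  subdomains <- subdomains %||% pop
  nb <- nrow(pdf$taxonomy)
  ranks <- matrix(NA_integer_, length(subdomains), nb,
                  dimnames = list(subdomains, pdf$taxonomy$id))
  zmat <- matrix(NA_real_, length(subdomains), nb,
                 dimnames = list(subdomains, pdf$taxonomy$id))
  for (r in seq_along(subdomains)) {
    i <- subdomains[r]
    roi <- behavior_specific_roi(pdf, i, fwhm_mm, rel_threshold)
    prof <- suppressWarnings(analyze_roi(pdf, roi, brain_mask))
    z <- prof$z[order(prof$subdomain_id)]
    zmat[r, ] <- z
    # rank 1 = largest z; NA z ranks last; ties broken by id
    ord <- order(-z, seq_len(nb), na.last = TRUE)
    rk <- integer(nb)
    rk[ord] <- seq_len(nb)
    ranks[r, ] <- rk
  }
  diag_rank <- ranks[cbind(seq_along(subdomains), subdomains)]
  diag_z <- zmat[cbind(seq_along(subdomains), subdomains)]
  names(diag_rank) <- names(diag_z) <- subdomains
  structure(list(ranks = ranks, z = zmat, diag_rank = diag_rank,
                 diag_z = diag_z,
                 tally = table(factor(diag_rank, levels = seq_len(nb)))),
            class = "rank_matrix")
}

#' @export
print.rank_matrix <- function(x, ...) {
  tally <- x$tally[x$tally > 0]
  cat(sprintf("<rank_matrix> %d behavior-specific ROIs; own-sub-domain ranks: %s\n",
              nrow(x$ranks),
              paste(sprintf("%sx rank %s", tally, names(tally)),
                    collapse = ", ")))
  invisible(x)
}

#' Write the rank matrix as CSV
#' @param rm a \code{rank_matrix}.
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_rank_matrix <- function(rm, path) {
  df <- data.frame(roi_subdomain = rownames(rm$ranks), rm$ranks,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
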