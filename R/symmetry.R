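#' Left/right/midline tallies of activation foci
#'
#' In Talairach convention x < 0 is left of midline. Foci exactly on the
#' midline (x = 0) are counted separately and excluded from both
#' hemisphere tallies by default; the \code{midline} rule can assign them
#' to either side instead.
#'
#' @param coords numeric matrix (n x 3) of mm coordinates, or length-3
#'   vector.
#' @param region optional \code{roi_mask}; when given, only foci whose
#'   nearest voxel lies in the region are tallied.
#' @param midline \code{"drop"} (default), \code{"left"} or
#'   \code{"right"}.
#' @return named integer vector \code{c(n_left, n_right, n_midline)}
#'   (n_midline is 0 unless \code{midline = "drop"}).
#' @export
lr_counts <- function(coords, region = NULL,
                      midline = c("drop", "left", "right")) {
  midline <- match.arg(midline)
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3L)
  if (!is.null(region)) {
    idx <- coord_to_voxel(region$grid, coords)
    ok <- !is.na(idx[, 1])
    keep <- logical(nrow(coords))
    keep[ok] <- region$vox[voxel_linear(region$grid,
                                        idx[ok, , drop = FALSE])]
    coords <- coords[keep, , drop = FALSE]
  }
  x <- coords[, 1]
  nl <- sum(x < 0)
  nr <- sum(x > 0)
  nm <- sum(x == 0)
  if (midline == "left") { nl <- nl + nm; nm <- 0L }
  if (midline == "right") { nr <- nr + nm; nm <- 0L }
  c(n_left = as.integer(nl), n_right = as.integer(nr),
    n_midline = as.integer(nm))
}

#' One-sample lateralization z-score
#'
#' Tests whether the fraction of foci left of midline differs from 0.5:
#' with f = n_left / N and N = n_left + n_right,
#' \deqn{z = (f - 0.5) / \sqrt{f(1-f)/N}.}
#' Leftward excess is positive. All-one-side tallies (f at 0 or 1) give
#' +/-Inf with a warning; N < 2 gives NA.
#'
#' @param n_left,n_right hemisphere focus tallies.
#' @return z-score.
#' @export
symmetry_z <- function(n_left, n_right) {
  n <- n_left + n_right
  if (n < 2) {
    warnf("fewer than 2 lateralized foci; z undefined")
    return(NA_real_)
  }
  f <- n_left / n
  if (f == 0 || f == 1) {
    warnf("all foci on one side; z is infinite")
    return(sign(f - 0.5) * Inf)
  }
  (f - 0.5) / sqrt(f * (1 - f) / n)
}

#' Lateralization table by sub-domain or region
#'
#' Tallies left/right foci and computes the lateralization z-score for
#' each behavioral sub-domain of a foci table (default), or for each
#' region mask supplied. Significance is flagged at |z| >= threshold
#' (3.0 by default; 2.0 is the laxer convention sometimes used for
#' region-level tables).
#'
#' @param table a \code{foci_table} in Talairach convention.
#' @param regions optional named list of \code{roi_mask} objects; when
#'   given, rows are per region (all sub-domains pooled) instead of per
#'   sub-domain.
#' @param z_threshold significance threshold on |z| (default 3.0).
#' @param midline midline rule passed to \code{lr_counts}.
#' @param taxonomy a \code{behavior_taxonomy}.
#' @return data.frame of class \code{symmetry_table} with columns
#'   \code{label}, \code{n_left}, \code{n_right}, \code{n_total},
#'   \code{left_fraction}, \code{z}, \code{significant}.
#' @export
symmetry_table <- function(table, regions = NULL, z_threshold = 3.0,
                           midline = "drop",
                           taxonomy = behavior_taxonomy()) {
  rows <- list()
  if (is.null(regions)) {
    index <- foci_index(table, taxonomy)
    for (b in seq_len(nrow(taxonomy))) {
      cnt <- lr_counts(index[[b]], midline = midline)
      rows[[b]] <- data.frame(
        label = paste(taxonomy$domain[b], taxonomy$name[b], sep = ":"),
        n_left = cnt[["n_left"]], n_right = cnt[["n_right"]],
        stringsAsFactors = FALSE)
    }
  } else {
    coords <- as.matrix(table$records[, c("x", "y", "z")])
    nm <- names(regions) %||% paste0("region", seq_along(regions))
    for (i in seq_along(regions)) {
      cnt <- lr_counts(coords, region = regions[[i]], midline = midline)
      rows[[i]] <- data.frame(label = nm[i], n_left = cnt[["n_left"]],
                              n_right = cnt[["n_right"]],
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$n_total <- out$n_left + out$n_right
  out$left_fraction <- ifelse(out$n_total > 0,
                              out$n_left / out$n_total, NA_real_)
  out$z <- vapply(seq_len(nrow(out)), function(i) {
    if (out$n_total[i] < 2) return(NA_real_)
    suppressWarnings(symmetry_z(out$n_left[i], out$n_right[i]))
  }, numeric(1))
  out$significant <- !is.na(out$z) & abs(out$z) >= z_threshold
  rownames(out) <- NULL
  structure(out, z_threshold = z_threshold,
            class = c("symmetry_table", "data.frame"))
}
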