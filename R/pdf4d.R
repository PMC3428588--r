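#' Bin foci into a per-sub-domain 3-D count image
#'
#' Each focus adds one to the voxel whose center is nearest its
#' coordinate (half-spacing ties round away from zero per axis). Foci
#' outside the grid bounding box are dropped with a warning and reported
#' in the \code{dropped} field, so counts plus dropped always equal the
#' number of input foci.
#'
#' Count images are stored sparsely (linear voxel index + count), since
#' foci occupy a small fraction of the grid.
#'
#' @param coords numeric matrix (n x 3) of mm coordinates.
#' @param grid a \code{grid_spec}.
#' @param subdomain_id optional sub-domain id carried along.
#' @return An object of class \code{foci_count_image}: list with
#'   \code{grid}, \code{idx} (sorted linear voxel indices), \code{counts}
#'   (per-index tallies), \code{n} (in-grid foci), \code{dropped},
#'   \code{subdomain_id}.
#' @export
build_count_image <- function(coords, grid, subdomain_id = NA_integer_) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3L)
  vi <- coord_to_voxel(grid, coords)
  ok <- !is.na(vi[, 1])
  dropped <- sum(!ok)
  if (dropped > 0L)
    warnf("dropped %d focus/foci outside the grid bounding box%s", dropped,
          if (!is.na(subdomain_id))
            sprintf(" (sub-domain %d)", subdomain_id) else "")
  lin <- voxel_linear(grid, vi[ok, , drop = FALSE])
  tab <- sort(lin)
  r <- rle(tab)
  structure(list(grid = grid, idx = r$values, counts = r$lengths,
                 n = sum(ok), dropped = dropped,
                 subdomain_id = subdomain_id),
            class = "foci_count_image")
}

#' Normalize a count image to a probability-density channel
#'
#' Divides voxel counts by the sub-domain's total in-grid focus count
#' N_b, so the channel sums to one and its sum over any ROI is the
#' probability that a focus of that behavior falls inside the ROI.
#'
#' @param img a \code{foci_count_image}.
#' @return list with \code{idx}, \code{val} (densities), \code{n_foci};
#'   a zero-focus image yields an all-zero channel with \code{n_foci = 0}
#'   and a warning.
#' @export
normalize_to_pdf <- function(img) {
  if (img$n == 0L) {
    warnf("sub-domain %s has no in-grid foci; channel is all zero",
          ifelse(is.na(img$subdomain_id), "?", img$subdomain_id))
    return(list(idx = integer(), val = numeric(), n_foci = 0L))
  }
  list(idx = img$idx, val = img$counts / img$n, n_foci = img$n)
}

#' Assemble the 51-channel 4-D behavioral probability-density image
#'
#' Runs the count-and-normalize pipeline for every taxonomy sub-domain of
#' a foci table and stacks the 51 channels (taxonomy order) into a 4-D
#' PDF object. Sub-domains absent from the table yield all-zero channels
#' with \code{n_foci = 0}.
#'
#' @param table a \code{foci_table} in Talairach space (apply
#'   \code{mni_to_tal()} first for MNI-tagged tables).
#' @param grid a \code{grid_spec} (2-mm default).
#' @param taxonomy a \code{behavior_taxonomy}.
#' @return An object of class \code{behavior_pdf4d}: list with
#'   \code{grid}, \code{channels} (list of 51 sparse channels),
#'   \code{n_foci} (length-51 integer), \code{dropped} (length-51),
#'   \code{taxonomy}.
#' @export
assemble_pdf4d <- function(table, grid = grid_spec(2),
                           taxonomy = behavior_taxonomy()) {
  if (identical(table$space, "MNI"))
    warnf("foci table is MNI-tagged; internal analysis assumes Talairach")
  index <- foci_index(table, taxonomy)
  channels <- vector("list", nrow(taxonomy))
  nf <- integer(nrow(taxonomy))
  dropped <- integer(nrow(taxonomy))
  for (b in seq_len(nrow(taxonomy))) {
    coords <- index[[b]]
    if (nrow(coords) == 0L) {
      channels[[b]] <- list(idx = integer(), val = numeric(), n_foci = 0L)
      next
    }
    img <- build_count_image(coords, grid, subdomain_id = taxonomy$id[b])
    dropped[b] <- img$dropped
    ch <- suppressWarnings(normalize_to_pdf(img))
    channels[[b]] <- ch
    nf[b] <- ch$n_foci
  }
  structure(list(grid = grid, channels = channels, n_foci = nf,
                 dropped = dropped, taxonomy = taxonomy),
            class = "behavior_pdf4d")
}

#' @export
print.behavior_pdf4d <- function(x, ...) {
  cat(sprintf("<behavior_pdf4d> %d channels (%d populated), %g-mm grid, %d foci\n",
              length(x$channels), sum(x$n_foci > 0), x$grid$spacing,
              sum(x$n_foci)))
  invisible(x)
}

#' Densify one PDF channel
#' @param pdf a \code{behavior_pdf4d}.
#' @param b sub-domain id (1--51).
#' @return numeric 3-D array on the PDF grid.
#' @export
pdf_channel_dense <- function(pdf, b) {
  arr <- array(0, dim = pdf$grid$shape)
  ch <- pdf$channels[[b]]
  arr[ch$idx] <- ch$val
  arr
}

#' Write / read a 4-D PDF image as compressed NIfTI plus JSON sidecar
#'
#' The 4-D volume (dim 4 = 51 sub-domain channels, taxonomy order) is
#' written as gzip-compressed NIfTI-1; the per-channel focus totals N_b,
#' the channel order and the space tag go to a JSON sidecar (same path
#' with \code{.json} appended), without which the image cannot be
#' re-analyzed and reading fails.
#'
#' @param pdf a \code{behavior_pdf4d}.
#' @param path output \code{.nii.gz} path.
#' @return invisibly, the path.
#' @export
write_pdf4d <- function(pdf, path) {
  nb <- length(pdf$channels)
  nvox <- grid_nvox(pdf$grid)
  arr <- array(0, dim = c(pdf$grid$shape, nb))
  for (b in seq_len(nb)) {
    ch <- pdf$channels[[b]]
    if (length(ch$idx)) arr[(b - 1L) * nvox + ch$idx] <- ch$val
  }
  img <- nifti_from_array(arr, pdf$grid)
  RNifti::writeNifti(img, path, datatype = "double")
  sidecar <- list(subdomain_id = pdf$taxonomy$id,
                  subdomain = paste(pdf$taxonomy$domain, pdf$taxonomy$name,
                                    sep = ":"),
                  n_foci = pdf$n_foci, dropped = pdf$dropped,
                  space = "TAL")
  jsonlite::write_json(sidecar, sidecar_path(path), auto_unbox = FALSE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".json")

#' @rdname write_pdf4d
#' @param taxonomy a \code{behavior_taxonomy}.
#' @return \code{read_pdf4d}: a \code{behavior_pdf4d}.
#' @export
read_pdf4d <- function(path, taxonomy = behavior_taxonomy()) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stopf("missing sidecar %s: per-channel focus totals (N_b) are required",
          sc)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    stopf("%s is not a 4-D NIfTI image", path)
  grid <- grid_from_nifti(img)
  nb <- d[4]
  if (nb != length(meta$n_foci))
    stopf("sidecar lists %d channels but image has %d",
          length(meta$n_foci), nb)
  nvox <- prod(d[1:3])
  channels <- vector("list", nb)
  flat <- as.vector(img)
  for (b in seq_len(nb)) {
    v <- flat[((b - 1L) * nvox + 1L):(b * nvox)]
    idx <- which(v != 0)
    channels[[b]] <- list(idx = idx, val = v[idx],
                          n_foci = as.integer(meta$n_foci[b]))
  }
  structure(list(grid = grid, channels = channels,
                 n_foci = as.integer(meta$n_foci),
                 dropped = as.integer(meta$dropped %||%
                                        rep(0L, nb)),
                 taxonomy = taxonomy),
            class = "behavior_pdf4d")
}
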