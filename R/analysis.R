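#' Observed probability of a behavior inside an ROI
#'
#' Sums one sub-domain's probability-density channel over the ROI
#' voxels: the fraction of that behavior's reported foci falling inside
#' the ROI. Reaches 1 for a whole-brain ROI and 0 for an empty one.
#'
#' @param pdf a \code{behavior_pdf4d}.
#' @param roi an \code{roi_mask} on the same grid (resample first
#'   otherwise).
#' @param b sub-domain id (1--51).
#' @return probability in [0, 1].
#' @export
observed_probability <- function(pdf, roi, b) {
  if (!grid_equal(pdf$grid, roi$grid))
    stopf("ROI grid does not match PDF grid; use resample_mask() first")
  ch <- pdf$channels[[b]]
  if (!length(ch$idx)) return(0)
  p <- sum(ch$val[roi$vox[ch$idx]])
  min(max(p, 0), 1)
}

#' Expected probability under spatially uniform foci
#'
#' The ROI-to-brain volume ratio: the probability a focus would fall in
#' the ROI were foci uniformly distributed throughout the brain. ROI
#' voxels outside the brain mask are excluded (with a warning), keeping
#' the numerator consistent with the in-brain analysis volume.
#'
#' @param roi an \code{roi_mask}.
#' @param brain_mask whole-brain \code{roi_mask} on the same grid.
#' @return probability in [0, 1].
#' @export
expected_probability <- function(roi, brain_mask) {
  if (!grid_equal(roi$grid, brain_mask$grid))
    stopf("ROI and brain mask are on different grids; resample first")
  vb <- mask_volume(brain_mask)
  if (vb <= 0) stopf("brain mask has zero volume")
  inter <- roi$vox & brain_mask$vox
  outside <- sum(roi$vox) - sum(inter)
  if (outside > 0L)
    warnf("%d ROI voxel(s) outside the brain mask excluded from p_e",
          outside)
  sum(inter) * roi$grid$spacing^3 / vb
}

#' Binomial effect-size z-score for one sub-domain
#'
#' Tests the null that the observed probability equals the expected
#' (size-matched) probability, with binomial variance for both:
#' \deqn{z = (p_o - p_e) / \sqrt{(p_o(1-p_o) + p_e(1-p_e))/N_b}}
#' where N_b is the sub-domain's whole-brain focus tally.
#'
#' Degenerate cases: when both variance terms vanish (probabilities at 0
#' or 1) and the effect is zero, z = 0; zero variance with a nonzero
#' effect gives +/-Inf; N_b = 0 gives NA.
#'
#' @param p_o observed probability.
#' @param p_e expected probability.
#' @param n_b whole-brain focus count for the sub-domain.
#' @return z-score (possibly Inf or NA).
#' @export
effect_z <- function(p_o, p_e, n_b) {
  stopifnot(p_o >= 0, p_o <= 1, p_e >= 0, p_e <= 1)
  if (is.na(n_b) || n_b < 1) return(NA_real_)
  v <- (p_o * (1 - p_o) + p_e * (1 - p_e)) / n_b
  eff <- p_o - p_e
  if (v == 0) {
    if (eff == 0) return(0)
    return(sign(eff) * Inf)
  }
  eff / sqrt(v)
}

#' Behavior profile of an ROI
#'
#' The full regional behavioral analysis: for each of the 51 behavioral
#' sub-domains, computes the observed probability (PDF sum over the ROI),
#' the expected probability (ROI-to-brain volume ratio), the effect size
#' (p_o - p_e), the relative probability ((p_o - p_e)/p_e), the binomial
#' effect-size z, and a significance flag for positive effects with
#' z >= \code{z_threshold} (default 3.0, Bonferroni-style guard for 51
#' simultaneous tests at overall ~0.05). Rows are ranked by descending z.
#'
#' ROI voxels outside the brain mask are excluded from both the observed
#' sum and the expected volume, keeping the two consistent.
#'
#' @param pdf a \code{behavior_pdf4d}.
#' @param roi an \code{roi_mask} on the PDF grid.
#' @param brain_mask whole-brain \code{roi_mask} on the PDF grid.
#' @param z_threshold significance threshold on z (default 3.0).
#' @return An object of class \code{behavior_profile}: a data.frame with
#'   columns \code{subdomain_id}, \code{domain}, \code{name},
#'   \code{n_foci}, \code{foci_in_roi} (round(p_o * N_b)), \code{p_obs},
#'   \code{p_exp}, \code{effect}, \code{rel_prob}, \code{z},
#'   \code{significant}, ranked by descending z; attributes carry the
#'   threshold, ROI provenance and brain volume.
#' @export
analyze_roi <- function(pdf, roi, brain_mask, z_threshold = 3.0) {
  if (!grid_equal(pdf$grid, roi$grid))
    stopf("ROI grid does not match PDF grid; use resample_mask() first")
  if (!grid_equal(pdf$grid, brain_mask$grid))
    stopf("brain mask grid does not match PDF grid; resample first")
  roi_in <- suppressWarnings(mask_intersect(roi, brain_mask))
  outside <- sum(roi$vox) - sum(roi_in$vox)
  if (outside > 0L)
    warnf("%d ROI voxel(s) outside the brain mask excluded from analysis",
          outside)
  p_e <- expected_probability(roi_in, brain_mask)
  tax <- pdf$taxonomy
  nb <- pdf$n_foci
  p_o <- vapply(seq_len(nrow(tax)), function(b)
    observed_probability(pdf, roi_in, b), numeric(1))
  z <- vapply(seq_len(nrow(tax)), function(b)
    effect_z(p_o[b], p_e, nb[b]), numeric(1))
  effect <- p_o - p_e
  prof <- data.frame(
    subdomain_id = tax$id,
    domain = as.character(tax$domain),
    name = tax$name,
    n_foci = nb,
    foci_in_roi = as.integer(round(p_o * nb)),
    p_obs = p_o,
    p_exp = rep(p_e, nrow(tax)),
    effect = effect,
    rel_prob = ifelse(p_e > 0, effect / p_e, NA_real_),
    z = z,
    significant = !is.na(z) & z >= z_threshold & effect > 0,
    stringsAsFactors = FALSE
  )
  ord <- order(-prof$z, prof$subdomain_id, na.last = TRUE)
  prof <- prof[ord, ]
  rownames(prof) <- NULL
  structure(prof,
            z_threshold = z_threshold,
            roi_provenance = roi$provenance,
            brain_volume_mm3 = mask_volume(brain_mask),
            class = c("behavior_profile", "data.frame"))
}

#' @export
print.behavior_profile <- function(x, n = 10L, ...) {
  cat(sprintf("<behavior_profile> z >= %g: %d significant sub-domain(s)\n",
              attr(x, "z_threshold"), sum(x$significant)))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat(sprintf("... %d more rows\n", nrow(x) - n))
  invisible(x)
}

#' Export a behavior profile
#'
#' @param profile a \code{behavior_profile}.
#' @param path output file.
#' @param format \code{"csv"} or \code{"json"}.
#' @return invisibly, the path.
#' @export
export_profile <- function(profile, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(as.data.frame(profile), path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(z_threshold = attr(profile, "z_threshold"),
           roi_provenance = attr(profile, "roi_provenance"),
           brain_volume_mm3 = attr(profile, "brain_volume_mm3"),
           rows = as.data.frame(profile)),
      path, auto_unbox = TRUE, digits = NA, na = "null")
  }
  invisible(path)
}

#' Re-import an exported JSON profile
#' @param path JSON file written by \code{export_profile}.
#' @return a \code{behavior_profile}.
#' @export
read_profile_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  prof <- as.data.frame(obj$rows)
  structure(prof,
            z_threshold = obj$z_threshold,
            roi_provenance = obj$roi_provenance,
            brain_volume_mm3 = obj$brain_volume_mm3,
            class = c("behavior_profile", "data.frame"))
}
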