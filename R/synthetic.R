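#' Synthetic ellipsoid whole-brain mask
#'
#' An ellipsoid centered at the origin with the given semi-axes,
#' voxelized on the grid (voxel set iff its center lies inside). The
#' default semi-axes (70, 85, 65 mm) give roughly adult-brain volume
#' (~1.6 L). This synthetic mask stands in for a real atlas-derived
#' brain mask in tests and examples; real analyses should supply one.
#'
#' @param grid a \code{grid_spec}.
#' @param semi_axes length-3 positive mm semi-axes (x, y, z).
#' @return an \code{roi_mask}, symmetric under x -> -x by construction.
#' @export
generate_brain_mask <- function(grid = grid_spec(2),
                                semi_axes = c(70, 85, 65)) {
  stopifnot(all(semi_axes > 0))
  u <- (grid_axis(grid, 1L) / semi_axes[1])^2
  v <- (grid_axis(grid, 2L) / semi_axes[2])^2
  w <- (grid_axis(grid, 3L) / semi_axes[3])^2
  vox <- outer(outer(u, v, `+`), w, `+`) <= 1
  roi_mask(grid, vox,
           provenance = sprintf("synthetic ellipsoid brain (%g,%g,%g)",
                                semi_axes[1], semi_axes[2], semi_axes[3]))
}

#' Simulation spec for one behavioral sub-domain
#'
#' Describes how to draw a sub-domain's foci: a mixture of isotropic
#' Gaussian clusters (truncated to the brain by rejection) and a uniform
#' in-brain component, with an optional hemispheric bias.
#'
#' @param subdomain_id taxonomy id (1--51).
#' @param n_foci number of foci to draw.
#' @param clusters list of \code{list(center = c(x,y,z), sd = mm,
#'   weight = w)}; weights plus \code{uniform_fraction} must sum to 1.
#' @param uniform_fraction share of foci drawn uniformly in-brain.
#' @param left_bias probability a focus is reflected to x < 0 (NA for no
#'   reflection).
#' @return an object of class \code{subdomain_sim_spec}.
#' @export
subdomain_sim_spec <- function(subdomain_id, n_foci, clusters = list(),
                               uniform_fraction = 1, left_bias = NA_real_) {
  subdomain_id <- normalize_subdomain_id(subdomain_id)
  w <- vapply(clusters, function(cl) cl$weight %||% 0, numeric(1))
  stopifnot(n_foci >= 0,
            abs(sum(w) + uniform_fraction - 1) < 1e-9,
            all(vapply(clusters, function(cl) (cl$sd %||% 0) > 0,
                       logical(1))) || length(clusters) == 0L,
            is.na(left_bias) || (left_bias >= 0 && left_bias <= 1))
  structure(list(subdomain_id = subdomain_id, n_foci = as.integer(n_foci),
                 clusters = clusters, uniform_fraction = uniform_fraction,
                 left_bias = left_bias),
            class = "subdomain_sim_spec")
}

# rejection sampler shared by the uniform and Gaussian components:
# `draw(m)` proposes m candidate coordinates; candidates outside the mask
# are rejected until n fall inside
sample_into_mask <- function(n, mask, draw, what = "component") {
  out <- matrix(NA_real_, n, 3L)
  filled <- 0L
  tries <- 0L
  while (filled < n) {
    tries <- tries + 1L
    if (tries > 1000L)
      stopf("%s cannot be sampled inside the mask", what)
    m <- max(2L * (n - filled), 100L)
    cand <- draw(m)
    idx <- coord_to_voxel(mask$grid, cand)
    ok <- !is.na(idx[, 1])
    ok[ok] <- mask$vox[voxel_linear(mask$grid, idx[ok, , drop = FALSE])]
    take <- utils::head(which(ok), n - filled)
    if (length(take)) {
      out[(filled + 1L):(filled + length(take)), ] <-
        cand[take, , drop = FALSE]
      filled <- filled + length(take)
    }
  }
  out
}

runif_in_mask <- function(n, mask) {
  if (!any(mask$vox)) stopf("cannot sample from an empty mask")
  grid <- mask$grid
  set <- which(mask$vox)
  s <- grid$shape
  ijk <- cbind((set - 1L) %% s[1] + 1L,
               ((set - 1L) %/% s[1]) %% s[2] + 1L,
               (set - 1L) %/% (s[1] * s[2]) + 1L)
  cc <- voxel_to_coord(grid, ijk)
  lo <- apply(cc, 2, min) - grid$spacing / 2
  hi <- apply(cc, 2, max) + grid$spacing / 2
  sample_into_mask(n, mask, function(m)
    cbind(stats::runif(m, lo[1], hi[1]),
          stats::runif(m, lo[2], hi[2]),
          stats::runif(m, lo[3], hi[3])),
    what = "uniform component")
}

rnorm_in_mask <- function(n, center, sd, mask) {
  sample_into_mask(n, mask, function(m)
    cbind(stats::rnorm(m, center[1], sd),
          stats::rnorm(m, center[2], sd),
          stats::rnorm(m, center[3], sd)),
    what = sprintf("cluster at (%g,%g,%g) sd %g", center[1], center[2],
                   center[3], sd))
}

#' Generate a synthetic foci table with known ground truth
#'
#' Draws foci for each sub-domain spec: each focus is assigned to a
#' Gaussian cluster or the uniform in-brain component according to the
#' mixture weights, drawn with rejection into the brain mask, and
#' optionally reflected to a hemisphere (x < 0 with probability
#' \code{left_bias}, else x > 0). Reproducible for a fixed seed.
#'
#' @param specs list of \code{subdomain_sim_spec} (or a single one).
#' @param brain_mask an \code{roi_mask} to sample within.
#' @param seed integer RNG seed.
#' @return a \code{foci_table} (space "TAL") with a
#'   \code{"ground_truth"} attribute: data.frame of per-focus component
#'   labels ("uniform" or "cluster<k>").
#' @export
generate_foci <- function(specs, brain_mask, seed = 1L) {
  if (inherits(specs, "subdomain_sim_spec")) specs <- list(specs)
  if (!any(brain_mask$vox)) stopf("cannot sample from an empty brain mask")
  set.seed(as.integer(seed))
  recs <- list()
  truth <- list()
  for (sp in specs) {
    n <- sp$n_foci
    if (n == 0L) next
    w <- c(vapply(sp$clusters, function(cl) cl$weight, numeric(1)),
           sp$uniform_fraction)
    comp <- sample.int(length(w), n, replace = TRUE, prob = w)
    xyz <- matrix(NA_real_, n, 3L)
    for (ci in seq_along(sp$clusters)) {
      rows <- which(comp == ci)
      if (length(rows))
        xyz[rows, ] <- rnorm_in_mask(length(rows),
                                     sp$clusters[[ci]]$center,
                                     sp$clusters[[ci]]$sd, brain_mask)
    }
    rows <- which(comp == length(w))
    if (length(rows) && sp$uniform_fraction > 0)
      xyz[rows, ] <- runif_in_mask(length(rows), brain_mask)
    if (!is.na(sp$left_bias)) {
      left <- stats::runif(n) < sp$left_bias
      xyz[, 1] <- ifelse(left, -abs(xyz[, 1]), abs(xyz[, 1]))
    }
    lab <- ifelse(comp == length(w), "uniform", paste0("cluster", comp))
    recs[[length(recs) + 1L]] <- data.frame(
      experiment = sprintf("sim-%02d", sp$subdomain_id),
      subdomain_id = sp$subdomain_id,
      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
      stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      subdomain_id = sp$subdomain_id, component = lab,
      stringsAsFactors = FALSE)
  }
  tab <- foci_table(if (length(recs)) do.call(rbind, recs)
                    else data.frame(experiment = character(),
                                    subdomain_id = integer(),
                                    x = numeric(), y = numeric(),
                                    z = numeric()),
                    space = "TAL")
  attr(tab, "ground_truth") <- if (length(truth)) do.call(rbind, truth)
                               else NULL
  tab
}

# 51 cluster centers, pairwise >= 26 mm apart, inside the default
# ellipsoid: a fixed lattice intersected with a shrunken ellipsoid
disjoint_cluster_centers <- function(semi_axes = c(70, 85, 65)) {
  pts <- as.matrix(expand.grid(x = seq(-52, 52, by = 26),
                               y = seq(-78, 78, by = 26),
                               z = seq(-39, 39, by = 26)))
  r2 <- (pts[, 1] / (0.85 * semi_axes[1]))^2 +
    (pts[, 2] / (0.85 * semi_axes[2]))^2 +
    (pts[, 3] / (0.85 * semi_axes[3]))^2
  pts <- pts[r2 <= 1, , drop = FALSE]
  pts <- pts[order(abs(pts[, 1]) + abs(pts[, 2]) + abs(pts[, 3]),
                   pts[, 1], pts[, 2], pts[, 3]), , drop = FALSE]
  if (nrow(pts) < 51L) stopf("lattice produced only %d centers", nrow(pts))
  unname(pts[1:51, , drop = FALSE])
}

#' Canonical synthetic fixtures with known expected outcomes
#'
#' Builds three reproducible test beds on the default 2-mm grid and
#' ellipsoid brain:
#' \describe{
#'   \item{a (recovery)}{sub-domain 14 draws 2000 foci from a tight
#'     cluster (sd 6 mm) at (-44, 20, 8); the other 50 sub-domains draw
#'     1000 uniform in-brain foci each. A 12-mm sphere over the cluster
#'     should flag exactly sub-domain 14.}
#'   \item{b (lateralization)}{sub-domain 15 draws 2000 uniform foci
#'     reflected left with probability 0.6: expected left fraction 0.6,
#'     z near 9 for n = 2000.}
#'   \item{c (self-consistency)}{every sub-domain draws 400 foci from
#'     its own cluster (sd 4 mm) at one of 51 lattice sites >= 26 mm
#'     apart; each behavior-specific ROI should rank its own sub-domain
#'     first with z > 10.}
#' }
#'
#' @param seed integer seed; sub-fixtures use fixed offsets of it.
#' @param grid a \code{grid_spec}.
#' @return list with elements \code{brain} (\code{roi_mask}), \code{a},
#'   \code{b}, \code{c}; each fixture is a list of its foci table plus
#'   fixture-specific objects (\code{roi}, \code{cluster_center},
#'   \code{centers}).
#' @export
known_answer_suite <- function(seed = 42L, grid = grid_spec(2)) {
  brain <- generate_brain_mask(grid)
  cluster_center <- c(-44, 20, 8)
  specs_a <- c(
    list(subdomain_sim_spec(14L, 2000L,
                            clusters = list(list(center = cluster_center,
                                                 sd = 6, weight = 1)),
                            uniform_fraction = 0)),
    lapply(setdiff(1:51, 14L), function(b)
      subdomain_sim_spec(b, 1000L, uniform_fraction = 1)))
  foci_a <- generate_foci(specs_a, brain, seed = seed)
  roi_a <- roi_sphere(cluster_center, 12, grid)
  foci_b <- generate_foci(
    list(subdomain_sim_spec(15L, 2000L, uniform_fraction = 1,
                            left_bias = 0.6)),
    brain, seed = seed + 1L)
  centers <- disjoint_cluster_centers()
  specs_c <- lapply(1:51, function(b)
    subdomain_sim_spec(b, 400L,
                       clusters = list(list(center = centers[b, ],
                                            sd = 4, weight = 1)),
                       uniform_fraction = 0))
  foci_c <- generate_foci(specs_c, brain, seed = seed + 2L)
  list(brain = brain,
       a = list(foci = foci_a, roi = roi_a,
                cluster_center = cluster_center, clustered_subdomain = 14L),
       b = list(foci = foci_b, biased_subdomain = 15L, left_bias = 0.6),
       c = list(foci = foci_c, centers = centers))
}
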