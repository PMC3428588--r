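# Shared fixture builders for the suite. Everything is generated in code;
# no binary fixtures are stored.

# small node-centered grid: shape n^3, given spacing, origin at a multiple
# of the spacing so half-spacing ties behave as on the default grid
tiny_grid <- function(n = 6L, spacing = 1) {
  grid_spec(spacing,
            box = rbind(c(-spacing, -spacing, -spacing),
                        c((n - 2) * spacing, (n - 2) * spacing,
                          (n - 2) * spacing)))
}

# foci table from a bare coordinate matrix, all in one sub-domain
coords_table <- function(coords, subdomain_id = 1L, space = "TAL") {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3L)
  foci_table(data.frame(experiment = "e1",
                        subdomain_id = subdomain_id,
                        x = coords[, 1], y = coords[, 2], z = coords[, 3],
                        stringsAsFactors = FALSE),
             space = space)
}

# cube-shaped mask, voxel index ranges given as lists of 1-based indices
cube_mask <- function(grid, i, j, k) {
  vox <- array(FALSE, dim = grid$shape)
  vox[i, j, k] <- TRUE
  roi_mask(grid, vox, provenance = "test cube")
}

# full-grid mask
full_mask <- function(grid) {
  roi_mask(grid, array(TRUE, dim = grid$shape), provenance = "full grid")
}

# the canonical synthetic fixtures are expensive enough to share per run
shared_suite <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- known_answer_suite(seed = 42L)
    cache
  }
})

# published left/right foci tallies by sub-domain (2012 database), shipped
# with the package
lr_counts_fixture <- function() {
  utils::read.delim(system.file("extdata", "brainmap2012_lr_counts.tsv",
                                package = "regionbehavior"))
}
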