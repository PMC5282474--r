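#' Default phantom grid
#'
#' 0.4 mm isotropic voxels over a field of view comfortably containing a
#' 12 x 18 x 10 mm mouse-brain bounding box. Finer than a typical small-animal
#' PET reconstruction grid (about 0.8 mm) so voxel-wise statistics have
#' nontrivial spatial support.
#'
#' @return a [grid_spec()].
#' @export
default_grid <- function() grid_spec(c(36L, 51L, 31L), c(0.4, 0.4, 0.4))

# Parametric region layout, mm coordinates centred on the grid centre.
# y is the anterior-posterior (long) axis. Regions with a target_mm3 are
# trimmed/grown to that volume exactly (in whole voxels); NA regions keep
# their nominal parametric extent. Order matters: earlier regions claim
# voxels first, so constrained regions are placed before unconstrained ones.
atlas_region_table <- function() {
  data.frame(
    name = c("ref_wm_tspo", "ref_wm_amyloid",
             "frontal_cortex", "parietal_cortex", "thalamus", "hippocampus",
             "piriform_entorhinal_cortex", "cerebellum", "brainstem"),
    type = c("box", "box",
             "ellipsoid", "ellipsoid", "ellipsoid", "ellipsoid",
             "ellipsoid", "ellipsoid", "ellipsoid"),
    cx = c(0, 0, 0, 0, 0, 0, 0, 0, 0),
    cy = c(-5.9, -3.2, 5.8, 2.6, 0.0, -2.2, 2.0, -6.6, -5.4),
    cz = c(-0.3, -2.6, 1.0, 1.6, -0.6, 0.0, -3.3, 1.4, -1.6),
    sx = c(1.6, 2.3, 2.8, 2.9, 2.6, 2.7, 3.3, 2.9, 1.7),
    sy = c(1.5, 2.0, 1.6, 1.4, 1.1, 1.0, 1.9, 1.5, 2.2),
    sz = c(1.5, 1.3, 2.4, 2.65, 3.0, 2.65, 0.75, 1.65, 1.5),
    target_mm3 = c(29, 67, 45, 45, 36, 30, NA, NA, NA),
    stringsAsFactors = FALSE
  )
}

#' Build the parametric mouse-brain region atlas
#'
#' Constructs an integer-labelled brain volume from parametric ellipsoids and
#' boxes laid out along the anterior-posterior axis: frontal, parietal and
#' piriform/entorhinal cortices, hippocampus, thalamus, cerebellum, brainstem,
#' plus two white-matter reference regions. Reference and forebrain regions
#' are grown or trimmed in whole voxels to hit their configured physical
#' volumes: 29 mm^3 for the TSPO white-matter reference (cerebellum/brainstem
#' white matter), 67 mm^3 for the amyloid reference (pons/midbrain/hindbrain
#' white matter), and 156 mm^3 for the composite forebrain target
#' (frontal + parietal cortex + hippocampus + thalamus).
#'
#' Named VOIs exposed in `voi_defs` include each region, `target_forebrain`,
#' `ref_wm_tspo`, `ref_wm_amyloid`, and `brain` (all labelled voxels).
#' Reference VOIs are disjoint from each other and from all target regions
#' by construction (voxels are claimed in priority order).
#'
#' @param grid a [grid_spec()]; the default is [default_grid()].
#' @param tol_frac tolerance on achieved versus configured VOI volumes
#'   (fraction; default 0.10). Violations raise a sizing error naming the
#'   offending VOI.
#' @return an object of class `region_atlas` with fields `labels` (integer
#'   array, 0 outside the brain), `region_names` (label -> name),
#'   `voi_defs` (name -> integer label set) and `grid`.
#' @examples
#' atlas <- build_atlas()
#' voi_volume_mm3(atlas, "ref_wm_tspo")    # ~29
#' voi_volume_mm3(atlas, "target_forebrain")  # ~156
#' @export
build_atlas <- function(grid = default_grid(), tol_frac = 0.10) {
  assert_that(inherits(grid, "grid_spec"), "grid must be a grid_spec")
  vv <- voxel_volume(grid)
  co <- grid_coords(grid)
  brain_semi <- c(5.9, 8.9, 4.9)
  brain <- (co$x / brain_semi[1])^2 + (co$y / brain_semi[2])^2 +
    (co$z / brain_semi[3])^2 <= 1
  assert_that(any(brain), "grid too small: brain mask is empty")

  regions <- atlas_region_table()
  labels <- array(0L, dim = grid$shape)
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    # normalized "radius" of each voxel w.r.t. the region shape
    if (r$type == "ellipsoid") {
      rad <- sqrt(((co$x - r$cx) / r$sx)^2 + ((co$y - r$cy) / r$sy)^2 +
                    ((co$z - r$cz) / r$sz)^2)
    } else {
      rad <- pmax(abs(co$x - r$cx) / r$sx, abs(co$y - r$cy) / r$sy,
                  abs(co$z - r$cz) / r$sz)
    }
    if (is.na(r$target_mm3)) {
      sel <- which(rad <= 1 & brain & labels == 0L)
    } else {
      n_target <- round(r$target_mm3 / vv)
      # allow modest growth past the nominal surface to hit the voxel count
      elig <- which(rad <= 1.3 & brain & labels == 0L)
      assert_that(length(elig) >= n_target,
                  "grid too small for VOI '%s': %d eligible voxels < %d required",
                  r$name, length(elig), n_target)
      sel <- elig[order(rad[elig])[seq_len(n_target)]]
    }
    labels[sel] <- i
  }
  other <- which(brain & labels == 0L)
  labels[other] <- nrow(regions) + 1L

  region_names <- c(regions$name, "other_brain")
  names(region_names) <- as.character(seq_along(region_names))
  lab_of <- function(nm) match(nm, region_names)
  voi_defs <- c(
    lapply(region_names, function(nm) lab_of(nm)),
    list(target_forebrain = vapply(c("frontal_cortex", "parietal_cortex",
                                     "hippocampus", "thalamus"),
                                   lab_of, integer(1)),
         brain = seq_along(region_names))
  )
  names(voi_defs)[seq_along(region_names)] <- region_names

  atlas <- structure(list(labels = labels, region_names = region_names,
                          voi_defs = voi_defs, grid = grid),
                     class = "region_atlas")

  for (chk in list(c("ref_wm_tspo", 29), c("ref_wm_amyloid", 67),
                   c("target_forebrain", 156))) {
    got <- voi_volume_mm3(atlas, chk[1])
    want <- as.numeric(chk[2])
    assert_that(abs(got - want) <= tol_frac * want,
                "grid too small for VOI '%s': achieved %.1f mm^3 vs target %.0f mm^3",
                chk[1], got, want)
  }
  atlas
}

#' Atlas mask and volume helpers
#'
#' `voi_mask()` returns the logical voxel mask of a named VOI,
#' `brain_mask()` the mask of all labelled voxels, and `voi_volume_mm3()`
#' the physical VOI volume (voxel count times voxel volume).
#'
#' @param atlas a `region_atlas`.
#' @param voi VOI name present in `atlas$voi_defs`.
#' @return logical array / numeric scalar.
#' @export
voi_mask <- function(atlas, voi) {
  assert_that(inherits(atlas, "region_atlas"), "atlas must be a region_atlas")
  assert_that(voi %in% names(atlas$voi_defs), "unknown VOI '%s'", voi)
  array(atlas$labels %in% atlas$voi_defs[[voi]], dim = dim(atlas$labels))
}

#' @rdname voi_mask
#' @export
brain_mask <- function(atlas) {
  array(atlas$labels > 0L, dim = dim(atlas$labels))
}

#' @rdname voi_mask
#' @export
voi_volume_mm3 <- function(atlas, voi) {
  sum(voi_mask(atlas, voi)) * voxel_volume(atlas$grid)
}

# reference VOI appropriate for a tracer
ref_voi_for_tracer <- function(tracer) {
  switch(check_tracer(tracer), tspo = "ref_wm_tspo", amyloid = "ref_wm_amyloid")
}

#' @export
print.region_atlas <- function(x, ...) {
  cat(sprintf("<region_atlas> %s voxels, %d regions, brain %.0f mm^3\n",
              paste(dim(x$labels), collapse = "x"),
              length(x$region_names),
              sum(x$labels > 0) * voxel_volume(x$grid)))
  for (nm in c("ref_wm_tspo", "ref_wm_amyloid", "target_forebrain")) {
    cat(sprintf("  %-18s %6.1f mm^3\n", nm, voi_volume_mm3(x, nm)))
  }
  invisible(x)
}
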