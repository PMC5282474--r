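#' Read and write image volumes as NIfTI-1
#'
#' Thin wrappers around [RNifti::readNifti()] / [RNifti::writeNifti()] that
#' carry the voxel dimensions of a [grid_spec()] in the NIfTI pixdim field.
#'
#' @param image an [image_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_image()` returns `path` invisibly; `read_image()` returns
#'   an [image_volume()].
#' @export
write_image <- function(image, path) {
  assert_that(inherits(image, "image_volume"), "image must be an image_volume")
  nii <- RNifti::asNifti(image$data)
  RNifti::pixdim(nii) <- image$grid$voxel_size
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(path) {
  nii <- RNifti::readNifti(path)
  assert_that(length(dim(nii)) == 3, "expected a 3D NIfTI volume: %s", path)
  data <- array(as.vector(as.array(nii)), dim = dim(nii))  # drop nifti attrs
  image_volume(data, grid_spec(dim(data), RNifti::pixdim(nii)[1:3]))
}

#' Read and write the region atlas
#'
#' The label volume goes to NIfTI-1 and the region-name/VOI tables to a JSON
#' sidecar, so the atlas round-trips through standard formats.
#'
#' @param atlas a `region_atlas`.
#' @param nii_path path for the label volume (`.nii`/`.nii.gz`).
#' @param json_path path for the region-name map; defaults to `nii_path`
#'   with extensions replaced by `_regions.json`.
#' @return `write_atlas()` returns `nii_path` invisibly; `read_atlas()`
#'   returns a `region_atlas`.
#' @export
write_atlas <- function(atlas, nii_path, json_path = NULL) {
  assert_that(inherits(atlas, "region_atlas"), "atlas must be a region_atlas")
  json_path <- json_path %||% atlas_json_path(nii_path)
  nii <- RNifti::asNifti(atlas$labels + 0)
  RNifti::pixdim(nii) <- atlas$grid$voxel_size
  RNifti::writeNifti(nii, nii_path, datatype = "int16")
  jsonlite::write_json(list(region_names = as.list(atlas$region_names),
                            voi_defs = atlas$voi_defs),
                       json_path, auto_unbox = TRUE, digits = NA)
  invisible(nii_path)
}

#' @rdname write_atlas
#' @export
read_atlas <- function(nii_path, json_path = NULL) {
  json_path <- json_path %||% atlas_json_path(nii_path)
  nii <- RNifti::readNifti(nii_path)
  labels <- array(as.integer(as.array(nii)), dim = dim(nii))
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  voi_defs <- lapply(meta$voi_defs, as.integer)
  region_names <- unlist(meta$region_names)
  structure(list(labels = labels, region_names = region_names,
                 voi_defs = voi_defs,
                 grid = grid_spec(dim(labels), RNifti::pixdim(nii)[1:3])),
            class = "region_atlas")
}

atlas_json_path <- function(nii_path) {
  paste0(sub("\\.nii(\\.gz)?$", "", nii_path), "_regions.json")
}

#' Persist a simulated cohort to disk
#'
#' Writes one NIfTI volume per subject-tracer under `dir/images/`, the atlas
#' (NIfTI + JSON region map), `manifest.csv` with image paths filled in, and
#' `biomarkers.csv`.
#'
#' @param cohort a `phantom_cohort` from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the manifest data frame (with paths), invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  assert_that(inherits(cohort, "phantom_cohort"),
              "cohort must be a phantom_cohort")
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  write_atlas(cohort$atlas, file.path(dir, "atlas.nii.gz"))
  m <- cohort$manifest
  for (i in seq_len(nrow(m))) {
    key <- paste(m$subject_id[i], m$tracer[i], sep = ".")
    rel <- file.path("images", paste0(key, ".nii.gz"))
    write_image(cohort$images[[key]], file.path(dir, rel))
    m$path[i] <- rel
  }
  write.csv(m, file.path(dir, "manifest.csv"), row.names = FALSE)
  write.csv(cohort$biomarkers, file.path(dir, "biomarkers.csv"),
            row.names = FALSE)
  invisible(m)
}

#' Load cohort images listed in a manifest
#'
#' @param manifest data frame with columns `subject_id`, `tracer`, `path`.
#' @param dir directory that manifest paths are relative to.
#' @return named list of [image_volume()] keyed `"<subject_id>.<tracer>"`.
#' @export
read_cohort_images <- function(manifest, dir = ".") {
  imgs <- lapply(seq_len(nrow(manifest)), function(i)
    read_image(file.path(dir, manifest$path[i])))
  names(imgs) <- paste(manifest$subject_id, manifest$tracer, sep = ".")
  imgs
}
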