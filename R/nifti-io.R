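#' NIfTI input/output for volume pairs and ECV maps
#'
#' Volumes are written as NIfTI-1 (`.nii.gz`); masks as `uint8`, attenuation
#' volumes as `float`. ECV maps are written `float32` with `NaN` outside the
#' myocardium mask, plus a JSON sidecar recording `hct_used`, `dhu_blood`,
#' `erosion_iterations`, `mean_lv_ecv`, `source` and `n_flagged_voxels`.
#'
#' @param pair A [volume_pair()].
#' @param dir Directory to write `baseline.nii.gz`, `lie.nii.gz`,
#'   `lv_mask.nii.gz`, `bp_mask.nii.gz` into.
#' @return `write_volume_pair()` returns the four paths invisibly;
#'   `read_volume_pair()` returns a [volume_pair()].
#' @export
write_volume_pair <- function(pair, dir) {
  validate_volume_pair(pair)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- pair$voxel_spacing
  paths <- c(baseline = file.path(dir, "baseline.nii.gz"),
             lie = file.path(dir, "lie.nii.gz"),
             lv_mask = file.path(dir, "lv_mask.nii.gz"),
             bp_mask = file.path(dir, "bp_mask.nii.gz"))
  RNifti::writeNifti(as_nifti(pair$baseline_hu, sp), paths["baseline"],
                     datatype = "float")
  RNifti::writeNifti(as_nifti(pair$lie_hu, sp), paths["lie"],
                     datatype = "float")
  RNifti::writeNifti(as_nifti(pair$lv_mask * 1L, sp), paths["lv_mask"],
                     datatype = "uint8")
  RNifti::writeNifti(as_nifti(pair$bp_mask * 1L, sp), paths["bp_mask"],
                     datatype = "uint8")
  invisible(paths)
}

#' @rdname write_volume_pair
#' @param baseline,lie,lv_mask,bp_mask Paths to the four NIfTI files.
#' @export
read_volume_pair <- function(baseline, lie, lv_mask, bp_mask) {
  vols <- purrr::map(list(baseline, lie, lv_mask, bp_mask), read_volume)
  sp <- attr(vols[[1]], "spacing")
  volume_pair(vols[[1]], vols[[2]], vols[[3]], vols[[4]], voxel_spacing = sp)
}

read_volume <- function(path) {
  if (!file.exists(path)) stop("NIfTI file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img))
  attr(arr, "spacing") <- RNifti::pixdim(img)[seq_len(3)]
  arr
}

as_nifti <- function(arr, spacing) {
  img <- RNifti::asNifti(array(arr, dim(arr)))
  RNifti::pixdim(img) <- spacing
  img
}

#' @rdname write_volume_pair
#' @param map An `ecv_map`, as from [compute_ecv_map()].
#' @param path Output `.nii.gz` path for the ECV map; the JSON sidecar is
#'   written next to it with extension `.json`.
#' @param voxel_spacing Voxel spacing (mm) recorded in the NIfTI header.
#' @export
write_ecv_map <- function(map, path, voxel_spacing = c(2, 2, 2)) {
  stopifnot(inherits(map, "ecv_map"))
  ecv <- map$ecv
  ecv[is.na(ecv)] <- NaN
  RNifti::writeNifti(as_nifti(ecv, voxel_spacing), path, datatype = "float")
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(hct_used = map$hct_used, dhu_blood = map$dhu_blood,
         erosion_iterations = map$erosion_iterations,
         mean_lv_ecv = map$mean_lv_ecv, source = map$source,
         n_flagged_voxels = map$n_flagged),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(c(map = path, sidecar = sidecar))
}
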