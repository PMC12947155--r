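#' Registered baseline / late-enhancement volume pair
#'
#' Container for a pair of co-registered attenuation volumes plus the
#' left-ventricular myocardium and blood-pool masks, all sharing one voxel
#' grid. Registration and segmentation are assumed done upstream; no
#' resampling is performed here.
#'
#' @param baseline_hu,lie_hu 3-D numeric arrays (HU): pre-contrast baseline
#'   and late iodine-enhanced acquisitions.
#' @param lv_mask,bp_mask 3-D binary arrays: LV myocardium and blood pool.
#'   The masks must be disjoint and the blood pool non-empty.
#' @param voxel_spacing Voxel spacing in mm (length-3).
#' @return An object of class `volume_pair`.
#' @export
volume_pair <- function(baseline_hu, lie_hu, lv_mask, bp_mask,
                        voxel_spacing = c(2, 2, 2)) {
  pair <- structure(
    list(baseline_hu = baseline_hu, lie_hu = lie_hu,
         lv_mask = lv_mask > 0, bp_mask = bp_mask > 0,
         voxel_spacing = as.numeric(voxel_spacing)),
    class = "volume_pair"
  )
  validate_volume_pair(pair)
}

validate_volume_pair <- function(pair) {
  stopifnot(inherits(pair, "volume_pair"))
  d <- dim(pair$baseline_hu)
  if (length(d) != 3L) stop("Volumes must be 3-D arrays.", call. = FALSE)
  for (f in c("lie_hu", "lv_mask", "bp_mask")) {
    if (!identical(dim(pair[[f]]), d)) {
      stop("`", f, "` does not share the baseline grid shape.", call. = FALSE)
    }
  }
  if (any(pair$lv_mask & pair$bp_mask)) {
    stop("`lv_mask` and `bp_mask` must be disjoint.", call. = FALSE)
  }
  if (!any(pair$bp_mask)) stop("`bp_mask` is empty.", call. = FALSE)
  if (length(pair$voxel_spacing) != 3L || any(pair$voxel_spacing <= 0)) {
    stop("`voxel_spacing` must be three positive lengths (mm).", call. = FALSE)
  }
  pair
}

#' @export
print.volume_pair <- function(x, ...) {
  d <- dim(x$baseline_hu)
  cat(sprintf("<volume_pair> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$voxel_spacing[1], x$voxel_spacing[2],
              x$voxel_spacing[3]))
  cat(sprintf("  LV myocardium %d voxels, blood pool %d voxels\n",
              sum(x$lv_mask), sum(x$bp_mask)))
  invisible(x)
}

#' Ellipsoidal left-ventricle phantom geometry
#'
#' Builds a simple LV phantom on an isotropic grid: the blood pool is an
#' inner ellipsoid and the myocardium the shell between it and a concentric
#' outer ellipsoid. The geometry stands in for the segmentation masks a real
#' study derives from CT angiography.
#'
#' @param dim Grid side length in voxels (cubic grid).
#' @param voxel_spacing Isotropic voxel size in mm.
#' @param outer_frac Outer ellipsoid semi-axes as fractions of `dim/2`.
#' @param inner_frac Inner (blood pool) semi-axes as fractions of the outer
#'   semi-axes.
#' @return List with logical arrays `lv_mask` (shell) and `bp_mask` (core)
#'   plus `voxel_spacing`.
#' @export
phantom_geometry <- function(dim = 64L, voxel_spacing = 2,
                             outer_frac = c(0.80, 0.68, 0.88),
                             inner_frac = 0.62) {
  dim <- as.integer(dim)
  stopifnot(dim >= 16L)
  half <- (dim + 1) / 2
  ax <- outer_frac * dim / 2
  co <- expand_radii(dim, half, ax)
  outer <- co <= 1
  inner <- co <= inner_frac^2
  list(lv_mask = outer & !inner, bp_mask = inner,
       voxel_spacing = rep(voxel_spacing, 3))
}

# squared normalized ellipsoid radius at every voxel
expand_radii <- function(dim, centre, ax) {
  g <- seq_len(dim) - centre
  x2 <- (g / ax[1])^2
  y2 <- (g / ax[2])^2
  z2 <- (g / ax[3])^2
  outer_sum <- outer(x2, y2, `+`)
  r <- array(0, c(dim, dim, dim))
  for (k in seq_len(dim)) r[, , k] <- outer_sum + z2[k]
  r
}

#' Generate a phantom volume pair from a known ECV field
#'
#' Inverts the ECV relation to build a baseline / late-enhancement pair
#' whose pipeline output is known: each myocardial voxel's attenuation
#' change is set to `ecv * dhu_blood / (1 - hct)` and each blood-pool
#' voxel's to `dhu_blood`, then independent Gaussian noise of SD `noise_sd`
#' is added to both volumes. With `noise_sd = 0` the generator is the exact
#' right-inverse of [compute_ecv_map()]: the pipeline recovers `ecv_field`
#' voxel for voxel.
#'
#' @param ecv_field Either a single fraction (uniform field) or a 3-D array
#'   of fractions on the phantom grid; only values inside the myocardial
#'   shell are used.
#' @param hct Serum haematocrit fraction in (0, 1).
#' @param dhu_blood True mean blood-pool attenuation change (HU), positive.
#' @param noise_sd Gaussian noise SD (HU) added independently to each voxel
#'   of each volume.
#' @param seed Integer seed for the noise draws.
#' @param geometry Phantom masks, as from [phantom_geometry()].
#' @return A [volume_pair()].
#' @examples
#' pair <- generate_volume_pair(0.32, hct = 0.40, dhu_blood = 60)
#' compute_ecv_map(pair, hct = 0.40)$mean_lv_ecv # 0.32
#' @export
generate_volume_pair <- function(ecv_field, hct, dhu_blood, noise_sd = 0,
                                 seed = 1L, geometry = phantom_geometry()) {
  if (!is.numeric(hct) || length(hct) != 1L || hct <= 0 || hct >= 1) {
    stop("`hct` must be a fraction strictly inside (0, 1).", call. = FALSE)
  }
  if (!is.numeric(dhu_blood) || length(dhu_blood) != 1L || dhu_blood <= 0) {
    stop("`dhu_blood` must be a positive HU change.", call. = FALSE)
  }
  stopifnot(noise_sd >= 0)
  lv <- geometry$lv_mask
  bp <- geometry$bp_mask
  d <- dim(lv)
  if (length(ecv_field) == 1L) {
    ecv_field <- array(ecv_field, d)
  }
  stopifnot(identical(dim(ecv_field), d))
  if (any(ecv_field[lv] <= 0 | ecv_field[lv] >= 1)) {
    stop("`ecv_field` must lie in (0, 1) inside the myocardial shell.",
         call. = FALSE)
  }
  # tissue-like baseline attenuations: blood ~40 HU, myocardium ~50 HU
  baseline <- array(0, d)
  baseline[bp] <- 40
  baseline[lv] <- 50
  delta <- array(0, d)
  delta[bp] <- dhu_blood
  delta[lv] <- ecv_field[lv] * dhu_blood / (1 - hct)
  lie <- baseline + delta
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      baseline <- baseline + array(stats::rnorm(prod(d), 0, noise_sd), d)
      lie <- lie + array(stats::rnorm(prod(d), 0, noise_sd), d)
    })
  }
  volume_pair(baseline, lie, lv, bp, geometry$voxel_spacing)
}

#' Smooth transmural ECV gradient field for phantom tests
#'
#' Returns an ECV field varying linearly with normalized ellipsoid radius,
#' from `inner` at the endocardial border to `outer` at the epicardial
#' border of the default phantom shell.
#'
#' @param geometry Phantom geometry, as from [phantom_geometry()].
#' @param inner,outer ECV at the inner and outer shell borders.
#' @param dim Grid side length (must match `geometry`).
#' @return 3-D array of ECV fractions.
#' @export
phantom_gradient_field <- function(geometry = phantom_geometry(),
                                   inner = 0.25, outer = 0.45,
                                   dim = base::dim(geometry$lv_mask)[1]) {
  half <- (dim + 1) / 2
  # reconstruct the normalized radius used to build the geometry
  ax <- c(0.80, 0.68, 0.88) * dim / 2
  r2 <- expand_radii(dim, half, ax)
  r <- sqrt(pmin(pmax(r2, 0), 1))
  inner + (outer - inner) * r
}
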