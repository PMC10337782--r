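#' Digital PET phantom specification
#'
#' Describes an abdominal uptake phantom: two kidneys modelled as
#' ellipsoid shells of tracer-avid parenchyma around a hot
#' pelvicocaliceal urine core, a descending-aorta cylinder at blood-pool
#' SUV, optional spherical tumors, a uniform background, a Gaussian
#' point-spread blur and additive Gaussian noise.
#'
#' Each kidney is a list with `center` (mm, world coordinates),
#' `outer_semi_axes` (mm), `parenchyma_suv`, and optionally
#' `core_semi_axes` and `core_suv` (omit or set `core_semi_axes = NULL`
#' for no urine core). Each tumor is a list with `center`, `radius` (mm)
#' and `suv`. The aorta is a z-axis-aligned cylinder given by `center_xy`
#' (mm), `radius` (mm), `z_range` (mm) and `blood_suv`.
#'
#' @param shape Integer length-3 grid dimensions (voxels).
#' @param spacing Voxel size per axis, mm.
#' @param kidneys Named list with elements `left` and/or `right`, each a
#'   kidney description as above.
#' @param background_suv Background SUV (default 1).
#' @param aorta Aorta description or `NULL`.
#' @param tumors List of tumor descriptions (possibly empty).
#' @param psf_fwhm Full width at half maximum of the isotropic Gaussian
#'   point-spread function, mm (default 4; 0 disables blurring).
#' @param noise_sd Standard deviation of additive Gaussian noise, SUV
#'   units (0 disables).
#' @param seed Integer seed for the noise field.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing, kidneys, background_suv = 1,
                         aorta = NULL, tumors = list(),
                         psf_fwhm = 4, noise_sd = 0, seed = 1L) {
  stopifnot(length(shape) == 3L, all(shape >= 1), length(spacing) == 3L,
            all(spacing > 0))
  if (psf_fwhm < 0) stop("`psf_fwhm` must be >= 0", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  for (k in kidneys) {
    if (!is.null(k$core_semi_axes) &&
        any(k$core_semi_axes >= k$outer_semi_axes))
      stop("pelvicocaliceal core must lie strictly inside the kidney ellipsoid",
           call. = FALSE)
  }
  structure(
    list(shape = as.integer(shape), spacing = as.numeric(spacing),
         kidneys = kidneys, background_suv = background_suv, aorta = aorta,
         tumors = tumors, psf_fwhm = psf_fwhm, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Default two-kidney phantom
#'
#' A convenience spec: symmetric kidneys (outer semi-axes 50 x 30 x 30 mm,
#' core 25 x 15 x 15 mm) at parenchymal SUV 8, urine cores at SUV 20,
#' background SUV 1, and a 12-mm-radius aorta at blood SUV 2.5, on a
#' 2-mm isotropic grid.
#'
#' @inheritParams phantom_spec
#' @param left_suv,right_suv Parenchymal SUV per kidney.
#' @param left_scale,right_scale Linear scale factor on each kidney's
#'   semi-axes (volume scales with the cube); 0 removes the kidney.
#' @export
default_phantom_spec <- function(psf_fwhm = 4, noise_sd = 0, seed = 1L,
                                 left_suv = 8, right_suv = 8,
                                 left_scale = 1, right_scale = 1,
                                 tumors = list(), spacing = c(2, 2, 2)) {
  shape <- round(c(240, 200, 320) / spacing)
  mk_kidney <- function(cx, suv, scale) {
    if (scale <= 0) return(NULL)
    list(center = c(cx, 100, 160),
         outer_semi_axes = c(30, 30, 50) * scale,
         core_semi_axes = c(15, 15, 25) * scale,
         parenchyma_suv = suv, core_suv = 20)
  }
  kid <- list()
  kl <- mk_kidney(170, left_suv, left_scale)   # patient left = +x
  kr <- mk_kidney(70, right_suv, right_scale)
  if (!is.null(kl)) kid$left <- kl
  if (!is.null(kr)) kid$right <- kr
  phantom_spec(shape = shape, spacing = spacing, kidneys = kid,
               background_suv = 1,
               aorta = list(center_xy = c(120, 60), radius = 12,
                            z_range = c(60, 260), blood_suv = 2.5),
               tumors = tumors, psf_fwhm = psf_fwhm, noise_sd = noise_sd,
               seed = seed)
}

# Voxel-center world coordinates along one axis.
axis_coords <- function(n, spacing, origin) origin + (seq_len(n) - 0.5) * spacing

# Logical mask of voxels whose centers fall inside an axis-aligned ellipsoid.
ellipsoid_mask <- function(shape, spacing, origin, center, semi_axes) {
  cx <- axis_coords(shape[1], spacing[1], origin[1])
  cy <- axis_coords(shape[2], spacing[2], origin[2])
  cz <- axis_coords(shape[3], spacing[3], origin[3])
  dx2 <- ((cx - center[1]) / semi_axes[1])^2
  dy2 <- ((cy - center[2]) / semi_axes[2])^2
  dz2 <- ((cz - center[3]) / semi_axes[3])^2
  q <- outer(outer(dx2, dy2, `+`), dz2, `+`)
  q <= 1
}

cylinder_mask_z <- function(shape, spacing, origin, center_xy, radius, z_range) {
  cx <- axis_coords(shape[1], spacing[1], origin[1])
  cy <- axis_coords(shape[2], spacing[2], origin[2])
  cz <- axis_coords(shape[3], spacing[3], origin[3])
  r2 <- outer((cx - center_xy[1])^2, (cy - center_xy[2])^2, `+`) <= radius^2
  inz <- cz >= z_range[1] & cz <= z_range[2]
  outer(r2, inz, `&`)
}

# Separable truncated-Gaussian convolution (banded matrix product per
# axis); kernel rows renormalized so a constant field is preserved at
# the grid edges.
gaussian_blur3d <- function(values, spacing, fwhm) {
  if (fwhm <= 0) return(values)
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  blur_axis <- function(arr, axis) {
    n <- dim(arr)[axis]
    s <- sigma / spacing[axis]
    if (s < 1e-6) return(arr)
    x <- seq_len(n)
    K <- exp(-outer(x, x, `-`)^2 / (2 * s^2))
    K[abs(outer(x, x, `-`)) > ceiling(4 * s)] <- 0
    K <- K / rowSums(K)
    d <- dim(arr)
    perm <- c(axis, setdiff(1:3, axis))
    m <- matrix(aperm(arr, perm), nrow = n)
    out <- array(K %*% m, dim = d[perm])
    aperm(out, order(perm))
  }
  for (ax in 1:3) values <- blur_axis(values, ax)
  values
}

#' Build a digital PET phantom
#'
#' Paints the compartments in priority order (urine core over parenchyma
#' over aorta/tumor over background), applies the Gaussian PSF, then adds
#' seeded Gaussian noise. Ground truth (analytic volumes, compartment
#' masks, and the renal indices implied by the painted values) is
#' computed before blur and noise.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (a `pet_volume`, SUV), `vois`
#'   (named list of `voi_mask`: generous per-kidney VOIs including the
#'   core, the aorta, and per-tumor masks), and `truth` (a
#'   `phantom_truth`: per-kidney analytic parenchymal volume in ml, true
#'   SUVmean, voxelized compartment masks, blood SUV, and the true
#'   ACI/TKA/split computed from those values).
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$shape; spacing <- spec$spacing; origin <- c(0, 0, 0)
  extent <- shape * spacing

  values <- array(spec$background_suv, dim = shape)
  vois <- list()
  truth_masks <- list()
  truth <- list()

  if (!is.null(spec$aorta)) {
    a <- spec$aorta
    am <- cylinder_mask_z(shape, spacing, origin, a$center_xy, a$radius,
                          a$z_range)
    values[am] <- a$blood_suv
    vois$aorta <- voi_mask(am, "AORTA")
    truth_masks$aorta <- am
    truth$blood_suv <- a$blood_suv
  } else truth$blood_suv <- NA_real_

  for (ti in seq_along(spec$tumors)) {
    tu <- spec$tumors[[ti]]
    sm <- ellipsoid_mask(shape, spacing, origin, tu$center, rep(tu$radius, 3))
    values[sm] <- tu$suv
    # generous tumor VOI: bounding sphere 1.5x the lesion radius
    vm <- ellipsoid_mask(shape, spacing, origin, tu$center,
                         rep(tu$radius * 1.5, 3))
    vois[[paste0("tumor", ti)]] <- voi_mask(vm, "TUMOR")
    truth_masks[[paste0("tumor", ti)]] <- sm
    truth[[paste0("tumor", ti, "_volume_ml")]] <-
      4 * pi / 3 * tu$radius^3 / 1000
    truth[[paste0("tumor", ti, "_suv")]] <- tu$suv
  }

  kidney_truth <- list()
  for (side in names(spec$kidneys)) {
    k <- spec$kidneys[[side]]
    check_inside <- k$center - k$outer_semi_axes
    if (any(check_inside < 0) || any(k$center + k$outer_semi_axes > extent))
      stop("geometry error: kidney '", side, "' extends outside the grid",
           call. = FALSE)
    outer_m <- ellipsoid_mask(shape, spacing, origin, k$center,
                              k$outer_semi_axes)
    if (!is.null(k$core_semi_axes)) {
      core_m <- ellipsoid_mask(shape, spacing, origin, k$center,
                               k$core_semi_axes)
      core_vol <- prod(k$core_semi_axes)
      core_suv <- k$core_suv
    } else {
      core_m <- array(FALSE, dim = shape)
      core_vol <- 0
      core_suv <- NA_real_
    }
    shell_m <- outer_m & !core_m
    values[shell_m] <- k$parenchyma_suv
    if (any(core_m)) values[core_m] <- core_suv
    # freehand-style VOI: padded bounding ellipsoid around the whole kidney
    voi_m <- ellipsoid_mask(shape, spacing, origin, k$center,
                            k$outer_semi_axes + 3 * spacing)
    label <- if (side == "left") "LEFT_KIDNEY" else "RIGHT_KIDNEY"
    vois[[side]] <- voi_mask(voi_m, label)
    truth_masks[[paste0(side, "_parenchyma")]] <- shell_m
    truth_masks[[paste0(side, "_core")]] <- core_m
    vol_ml <- 4 * pi / 3 * (prod(k$outer_semi_axes) - core_vol) / 1000
    kidney_truth[[side]] <- list(
      parenchymal_volume_ml = vol_ml,
      suv_mean = k$parenchyma_suv,
      aci = compute_aci(vol_ml, k$parenchyma_suv),
      tka = compute_tka(k$parenchyma_suv, vol_ml)
    )
  }
  truth$kidneys <- kidney_truth
  if (all(c("left", "right") %in% names(kidney_truth))) {
    truth$split_left_pct <- split_renal_function(
      kidney_truth$left$aci, kidney_truth$right$aci)$split_left_pct
  } else if ("left" %in% names(kidney_truth)) {
    truth$split_left_pct <- 100
  } else if ("right" %in% names(kidney_truth)) {
    truth$split_left_pct <- 0
  } else truth$split_left_pct <- NA_real_
  truth$masks <- truth_masks

  values <- gaussian_blur3d(values, spacing, spec$psf_fwhm)
  if (spec$noise_sd > 0) {
    rng_state <- withr_seed(spec$seed)
    on.exit(restore_seed(rng_state), add = TRUE)
    values <- values + array(stats::rnorm(length(values), 0, spec$noise_sd),
                             dim = shape)
  }

  list(volume = pet_volume(values, spacing, origin, "SUV", frame_time = 32),
       vois = vois,
       truth = structure(truth, class = "phantom_truth"))
}

# Seed scoping: set the RNG locally, restore the caller's state on exit.
withr_seed <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
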