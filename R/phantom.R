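#' Dynamic image container
#'
#' A 4D activity volume (x, y, z, frame) with its voxel size and acquisition
#' schedule. Activities are decay-corrected concentrations in kBq/mL, the
#' convention of clinical reconstructions.
#'
#' @param data 4D numeric array.
#' @param voxel_mm Isotropic voxel size in mm.
#' @param schedule A [frame_schedule()] whose length matches `dim(data)[4]`.
#' @return An object of class `dynamic_image`.
#' @export
dynamic_image <- function(data, voxel_mm, schedule) {
  if (length(dim(data)) != 4L) stop("data must be a 4D array")
  if (dim(data)[4] != n_frames(schedule))
    stop("4th dimension must match the number of frames")
  if (voxel_mm <= 0) stop("voxel size must be positive")
  structure(list(data = data, voxel_mm = voxel_mm, schedule = schedule),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_image> %dx%dx%d voxels (%.1f mm), %d frames\n",
              d[1], d[2], d[3], x$voxel_mm, d[4]))
  invisible(x)
}

# --- geometric primitives ---------------------------------------------------

#' Geometric primitives for phantom regions
#'
#' Region shapes are defined in mm in the grid coordinate system (voxel
#' centers at (i - 0.5) * voxel_mm). `cylinder` is axis-aligned.
#'
#' @param center Length-3 center, mm.
#' @param radius,radii Sphere radius / ellipsoid semi-axes, mm.
#' @param half_length Cylinder half-length along `axis`, mm.
#' @param axis Cylinder axis, one of `"x"`, `"y"`, `"z"`.
#' @return A shape description list.
#' @name shapes
NULL

#' @rdname shapes
#' @export
shape_sphere <- function(center, radius) {
  stopifnot(length(center) == 3, radius > 0)
  list(type = "sphere", center = center, radius = radius)
}

#' @rdname shapes
#' @export
shape_ellipsoid <- function(center, radii) {
  stopifnot(length(center) == 3, length(radii) == 3, all(radii > 0))
  list(type = "ellipsoid", center = center, radii = radii)
}

#' @rdname shapes
#' @export
shape_cylinder <- function(center, radius, half_length, axis = "z") {
  stopifnot(length(center) == 3, radius > 0, half_length > 0,
            axis %in% c("x", "y", "z"))
  list(type = "cylinder", center = center, radius = radius,
       half_length = half_length, axis = axis)
}

shape_bbox <- function(shape) {
  c0 <- shape$center
  r <- switch(shape$type,
    sphere = rep(shape$radius, 3),
    ellipsoid = shape$radii,
    cylinder = {
      ax <- match(shape$axis, c("x", "y", "z"))
      r <- rep(shape$radius, 3); r[ax] <- shape$half_length; r
    })
  rbind(lo = c0 - r, hi = c0 + r)
}

# logical mask of voxels whose centers fall inside the shape
rasterize_shape <- function(shape, dim, voxel_mm) {
  cx <- (seq_len(dim[1]) - 0.5) * voxel_mm
  cy <- (seq_len(dim[2]) - 0.5) * voxel_mm
  cz <- (seq_len(dim[3]) - 0.5) * voxel_mm
  c0 <- shape$center
  X <- array(rep(cx, times = dim[2] * dim[3]), dim)
  Y <- array(rep(rep(cy, each = dim[1]), times = dim[3]), dim)
  Z <- array(rep(cz, each = dim[1] * dim[2]), dim)
  switch(shape$type,
    sphere = (X - c0[1])^2 + (Y - c0[2])^2 + (Z - c0[3])^2 <= shape$radius^2,
    ellipsoid = ((X - c0[1]) / shape$radii[1])^2 +
                ((Y - c0[2]) / shape$radii[2])^2 +
                ((Z - c0[3]) / shape$radii[3])^2 <= 1,
    cylinder = {
      co <- list(X - c0[1], Y - c0[2], Z - c0[3])
      ax <- match(shape$axis, c("x", "y", "z"))
      rad <- co[-ax]
      rad[[1]]^2 + rad[[2]]^2 <= shape$radius^2 &
        abs(co[[ax]]) <= shape$half_length
    })
}

# --- phantom specification --------------------------------------------------

#' Phantom specification
#'
#' Describes a digital phantom: grid geometry, a list of organ regions and a
#' list of spherical lesions (each with two-tissue compartment kinetics),
#' injection and acquisition settings, the point-spread-function width, and
#' the TAC noise coefficient. Regions are painted in list order, lesions
#' last, so later regions overwrite earlier ones where they overlap.
#'
#' @param dim Grid dimensions in voxels (length 3).
#' @param voxel_mm Isotropic voxel size, mm.
#' @param organs List of `list(name =, shape =, params =)` entries, `shape`
#'   from [shape_sphere()], [shape_ellipsoid()] or [shape_cylinder()] and
#'   `params` a [kinetic_params()].
#' @param lesions List of `list(name =, center =, diameter_mm =, params =)`.
#' @param injected_dose_mbq Injected activity, MBq.
#' @param body_weight_kg Body weight, kg.
#' @param psf_fwhm_mm Isotropic Gaussian PSF full width at half maximum, mm
#'   (0 disables smoothing).
#' @param noise_alpha TAC noise coefficient (see [default_noise_alpha()]).
#' @param seed Integer seed for the voxel noise.
#' @param schedule A [frame_schedule()].
#' @param input An [input_function()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dim = c(64, 64, 48), voxel_mm = 4,
                         organs = list(), lesions = list(),
                         injected_dose_mbq = 200, body_weight_kg = 70,
                         psf_fwhm_mm = 0, noise_alpha = 0, seed = 1,
                         schedule = default_schedule(),
                         input = make_input_function()) {
  if (length(dim) != 3 || any(dim < 1)) stop("dim must be three positive sizes")
  if (injected_dose_mbq <= 0) stop("injected_dose must be positive")
  if (body_weight_kg <= 0) stop("body weight must be positive")
  if (psf_fwhm_mm < 0 || noise_alpha < 0) stop("psf and noise must be >= 0")
  extent <- dim * voxel_mm
  check_inside <- function(shape, what) {
    bb <- shape_bbox(shape)
    if (any(bb["lo", ] < 0) || any(bb["hi", ] > extent))
      stop(what, " does not fit inside the grid")
  }
  for (o in organs) {
    stopifnot(!is.null(o$name), !is.null(o$shape), !is.null(o$params))
    check_inside(o$shape, paste("organ", o$name))
  }
  for (l in lesions) {
    stopifnot(!is.null(l$name), !is.null(l$center), !is.null(l$params))
    if (is.null(l$diameter_mm) || l$diameter_mm <= 0)
      stop("lesion diameters must be > 0")
    check_inside(shape_sphere(l$center, l$diameter_mm / 2),
                 paste("lesion", l$name))
  }
  structure(list(dim = dim, voxel_mm = voxel_mm, organs = organs,
                 lesions = lesions, injected_dose_mbq = injected_dose_mbq,
                 body_weight_kg = body_weight_kg, psf_fwhm_mm = psf_fwhm_mm,
                 noise_alpha = noise_alpha, seed = seed, schedule = schedule,
                 input = input),
            class = "phantom_spec")
}

#' Calibrate liver K1 to a target percent injected dose
#'
#' Given the liver's exchange-rate shape (k2, k3, k4, vB) and volume, returns
#' the K1 for which the liver holds `target_pct` percent of the injected dose
#' at the frame containing `t_min` (the forward model is linear in K1 apart
#' from the blood-volume term).
#'
#' @param inp An [input_function()].
#' @param schedule A [frame_schedule()].
#' @param k2,k3,k4,vB Liver exchange rates and blood volume fraction.
#' @param target_pct Target percent injected dose.
#' @param t_min Time whose containing frame anchors the calibration, min.
#' @param dose_mbq Injected dose, MBq.
#' @param volume_ml Liver volume, mL.
#' @return Calibrated K1 (mL cm^-3 min^-1).
#' @export
calibrate_liver_k1 <- function(inp, schedule, k2 = 0.25, k3 = 0.12, k4 = 0,
                               vB = 0.15, target_pct = 30, t_min = 30,
                               dose_mbq = 200, volume_ml = 1470) {
  fi <- frame_containing(schedule, t_min)
  if (is.na(fi)) stop("no frame contains t = ", t_min, " min")
  ctx <- kinetic_context(inp, schedule)
  unit <- tissue_frame_avg(ctx, 1, k2, k3, k4)[fi]
  c_target <- target_pct / 100 * dose_mbq * 1000 / volume_ml  # kBq/mL
  k1 <- (c_target - vB * ctx$avg_cwb[fi]) / ((1 - vB) * unit)
  if (k1 <= 0) stop("calibration target unreachable with these rates")
  k1
}

#' Default digital phantom specification
#'
#' A 64 x 64 x 48 grid of 4-mm voxels holding a soft-tissue body ellipsoid,
#' a ~1.47 L liver with irreversible kinetics calibrated to hold 30% of the
#' injected dose at 30 min, a descending-aorta cylinder carrying pure whole
#' blood (the IDIF source), two bone regions, and nine spherical lesions of
#' 8-25 mm diameter: eight with irreversible estrogen-receptor-avid kinetics
#' spanning Ki roughly 0.04-0.08 mL cm^-3 min^-1 and one cold
#' (receptor-negative) lesion expected to fail the SUVmax inclusion screen.
#'
#' @param seed Seed for the voxel noise.
#' @param noise_alpha TAC noise coefficient; default [default_noise_alpha()].
#' @param psf_fwhm_mm PSF width, mm; default 6 (typical clinical whole-body
#'   reconstruction resolution).
#' @param schedule,input Acquisition schedule and blood input; defaults
#'   [default_schedule()] and [make_input_function()].
#' @return A [phantom_spec()].
#' @export
default_phantom_spec <- function(seed = 1, noise_alpha = default_noise_alpha(),
                                 psf_fwhm_mm = 6,
                                 schedule = default_schedule(),
                                 input = make_input_function()) {
  soft <- kinetic_params(0.05, 0.20, 0.012, 0, 0.05)
  bone <- kinetic_params(0.07, 0.25, 0.015, 0, 0.04)
  blood <- kinetic_params(0, 0, 0, 0, 1)
  liver_shape <- shape_ellipsoid(c(118, 90, 70), c(100, 62, 56))
  liver_vol <- 4 / 3 * pi * prod(c(100, 62, 56)) / 1000  # mL
  liver_k1 <- calibrate_liver_k1(input, schedule, k2 = 0.25, k3 = 0.12,
                                 k4 = 0, vB = 0.15, target_pct = 30,
                                 t_min = 30, dose_mbq = 200,
                                 volume_ml = liver_vol)
  organs <- list(
    list(name = "soft_tissue",
         shape = shape_ellipsoid(c(128, 128, 96), c(120, 120, 92)),
         params = soft),
    list(name = "liver", shape = liver_shape,
         params = kinetic_params(liver_k1, 0.25, 0.12, 0, 0.15)),
    list(name = "spine",
         shape = shape_cylinder(c(128, 190, 96), 14, 70, "z"),
         params = bone),
    list(name = "pelvic_bone", shape = shape_sphere(c(48, 128, 56), 12),
         params = bone),
    list(name = "aorta",
         shape = shape_cylinder(c(128, 156, 96), 11, 70, "z"),
         params = blood)
  )
  les <- function(name, center, d, K1, k2, k3, vB = 0.05)
    list(name = name, center = center, diameter_mm = d,
         params = kinetic_params(K1, k2, k3, 0, vB))
  lesions <- list(
    les("lesion_01", c(212, 128, 96), 25, 0.45, 0.35, 0.08),
    les("lesion_02", c(56, 150, 120), 20, 0.35, 0.30, 0.06),
    les("lesion_03", c(72, 60, 140),  18, 0.30, 0.35, 0.10),
    les("lesion_04", c(128, 128, 160), 16, 0.40, 0.40, 0.05),
    les("lesion_05", c(190, 80, 140), 14, 0.25, 0.25, 0.05),
    les("lesion_06", c(160, 200, 60), 12, 0.30, 0.30, 0.07),
    les("lesion_07", c(100, 160, 170), 10, 0.35, 0.30, 0.08),
    les("lesion_08", c(150, 56, 150),  8, 0.40, 0.35, 0.09),
    les("lesion_cold", c(80, 190, 60), 14, 0.05, 0.25, 0.005)
  )
  phantom_spec(dim = c(64, 64, 48), voxel_mm = 4, organs = organs,
               lesions = lesions, injected_dose_mbq = 200,
               body_weight_kg = 70, psf_fwhm_mm = psf_fwhm_mm,
               noise_alpha = noise_alpha, seed = seed, schedule = schedule,
               input = input)
}

# --- smoothing --------------------------------------------------------------

# separable isotropic Gaussian smoothing of a 3D array; kernel truncated at
# +- 3 sigma and row-normalized (mass conserved away from grid edges)
gaussian_smooth_3d <- function(arr, sigma_vox) {
  if (sigma_vox <= 0) return(arr)
  d <- dim(arr)
  kmat <- function(n) {
    K <- stats::dnorm(outer(seq_len(n), seq_len(n), "-"), sd = sigma_vox)
    K[abs(outer(seq_len(n), seq_len(n), "-")) > ceiling(3 * sigma_vox)] <- 0
    K / rowSums(K)
  }
  # axis 1
  arr <- array(kmat(d[1]) %*% matrix(arr, d[1]), d)
  # axis 2
  arr <- aperm(array(kmat(d[2]) %*% matrix(aperm(arr, c(2, 1, 3)), d[2]),
                     d[c(2, 1, 3)]), c(2, 1, 3))
  # axis 3
  arr <- aperm(array(kmat(d[3]) %*% matrix(aperm(arr, c(3, 1, 2)), d[3]),
                     d[c(3, 1, 2)]), c(2, 3, 1))
  arr
}

# --- phantom construction ---------------------------------------------------

#' Build a 4D phantom image from a specification
#'
#' Rasterizes the spec's regions to voxel masks (later regions overwrite
#' earlier ones, lesions last), assigns every voxel the noiseless
#' frame-averaged TAC of its region, optionally applies an isotropic
#' Gaussian PSF per frame, and finally adds voxelwise Gaussian noise with SD
#' `alpha * sqrt(value / duration)`. Also emits, per lesion, a background
#' shell mask (a 3-voxel dilation band around the lesion clipped to the
#' lesion's host organ) for visibility statistics.
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (a [dynamic_image()]), `masks` (named list of
#'   logical arrays, mutually exclusive), `lesion_bg` (named list of
#'   background shells), `region_tacs` (named list of noiseless [tac()]s),
#'   `region_volumes_ml`, and the `spec`.
#' @export
build_phantom <- function(spec) {
  d <- spec$dim
  regions <- c(lapply(spec$organs, function(o)
                 list(name = o$name, shape = o$shape, params = o$params)),
               lapply(spec$lesions, function(l)
                 list(name = l$name,
                      shape = shape_sphere(l$center, l$diameter_mm / 2),
                      params = l$params)))
  n_org <- length(spec$organs)
  id <- array(0L, d)
  host <- integer(length(regions))  # organ id owning each region's center
  for (r in seq_along(regions)) {
    m <- rasterize_shape(regions[[r]]$shape, d, spec$voxel_mm)
    cvox <- pmin(pmax(ceiling(regions[[r]]$shape$center / spec$voxel_mm), 1), d)
    host[r] <- id[cvox[1], cvox[2], cvox[3]]
    id[m] <- r
  }

  ctx <- kinetic_context(spec$input, spec$schedule)
  nf <- n_frames(spec$schedule)
  tacs <- lapply(regions, function(r) signal_frame_avg(ctx, r$params))
  lut <- rbind(0, do.call(rbind, tacs))  # region 0 = air

  vol <- array(0, c(d, nf))
  sigma_vox <- spec$psf_fwhm_mm / (2 * sqrt(2 * log(2))) / spec$voxel_mm
  idx1 <- as.vector(id) + 1L
  for (f in seq_len(nf)) {
    fr <- array(lut[idx1, f], d)
    if (sigma_vox > 0) fr <- gaussian_smooth_3d(fr, sigma_vox)
    vol[, , , f] <- fr
  }
  if (spec$noise_alpha > 0) {
    dur <- rep(spec$schedule$dur, each = prod(d))
    sdv <- spec$noise_alpha * sqrt(pmax(vol, 0) / dur)
    vol <- vol + array(with_seed(spec$seed, rnorm(length(vol), 0, sdv)),
                       dim(vol))
  }

  masks <- lapply(seq_along(regions), function(r) id == r)
  names(masks) <- vapply(regions, `[[`, "", "name")

  # background shells: band of 3 voxel widths around each lesion sphere,
  # restricted to the organ that hosts the lesion center
  lesion_bg <- list()
  for (j in seq_along(spec$lesions)) {
    l <- spec$lesions[[j]]
    r <- n_org + j
    outer_m <- rasterize_shape(
      shape_sphere(l$center, l$diameter_mm / 2 + 3 * spec$voxel_mm),
      d, spec$voxel_mm)
    shell <- outer_m & id == host[r]
    lesion_bg[[l$name]] <- shell
  }

  list(image = dynamic_image(vol, spec$voxel_mm, spec$schedule),
       masks = masks, lesion_bg = lesion_bg,
       region_tacs = stats::setNames(
         lapply(seq_along(regions), function(r)
           tac(spec$schedule$mid, spec$schedule$dur, tacs[[r]],
               label = regions[[r]]$name)),
         names(masks)),
       region_volumes_ml = vapply(masks, sum, 0) * spec$voxel_mm^3 / 1000,
       spec = spec)
}

#' Percent injected dose in a region
#'
#' @param img A [dynamic_image()].
#' @param mask Logical region mask.
#' @param dose_mbq Injected dose, MBq.
#' @param t_min Time (min); the frame containing it is used.
#' @return Percent of the injected dose inside the mask at that frame.
#' @export
percent_injected_dose <- function(img, mask, dose_mbq, t_min) {
  fi <- frame_containing(img$schedule, t_min)
  if (is.na(fi)) stop("no frame contains t = ", t_min, " min")
  vox_ml <- img$voxel_mm^3 / 1000
  frame <- img$data[, , , fi]
  sum(frame[mask]) * vox_ml / (dose_mbq * 1000) * 100
}
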