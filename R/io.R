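# full-precision CSV writer (17 significant digits round-trips doubles)
write_csv_full <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 17, format = "g"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
}

check_columns <- function(df, need, what, path) {
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(what, " file ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
}

#' Read and write time-activity curves as CSV
#'
#' CSV columns: `time_min` (frame mid-time), `duration_min`,
#' `activity_kbq_ml`. Values are written with 17 significant digits so the
#' round trip is exact.
#'
#' @param x A [tac()].
#' @param path File path.
#' @return `read_tac_csv` returns a [tac()]; `write_tac_csv` returns `path`
#'   invisibly.
#' @export
write_tac_csv <- function(x, path) {
  write_csv_full(data.frame(time_min = x$time, duration_min = x$duration,
                            activity_kbq_ml = x$activity), path)
  invisible(path)
}

#' @rdname write_tac_csv
#' @export
read_tac_csv <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("time_min", "duration_min", "activity_kbq_ml"),
                "TAC", path)
  tac(df$time_min, df$duration_min, df$activity_kbq_ml)
}

#' Read and write blood sample tables as CSV
#'
#' CSV columns: `time_min`, `whole_blood`, `plasma`, `parent_fraction`.
#'
#' @param x A `blood_sample_table` data frame (see [sample_blood()]).
#' @param path File path.
#' @return `read_blood_table` returns a `blood_sample_table`;
#'   `write_blood_table` returns `path` invisibly.
#' @export
write_blood_table <- function(x, path) {
  write_csv_full(as.data.frame(x), path)
  invisible(path)
}

#' @rdname write_blood_table
#' @export
read_blood_table <- function(path) {
  df <- read.csv(path)
  check_columns(df, c("time_min", "whole_blood", "plasma", "parent_fraction"),
                "blood table", path)
  class(df) <- c("blood_sample_table", "data.frame")
  df
}

#' Write a corrected input function as CSV
#'
#' Columns: `time_min`, `cwb` (whole blood), `cp_parent`
#' (metabolite-corrected parent plasma), evaluated at the knot grid.
#'
#' @param inp An [input_function()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_input_csv <- function(inp, path) {
  write_csv_full(data.frame(time_min = inp$t_knots, cwb = inp$cwb_knots,
                            cp_parent = inp$cp_knots), path)
  invisible(path)
}

#' Read and write dynamic images as NIfTI
#'
#' The 4D volume is written as NIfTI (voxel size in the header, mm) next to
#' a `<stem>_frames.csv` sidecar holding the frame schedule.
#'
#' @param img A [dynamic_image()].
#' @param path Path to the `.nii` or `.nii.gz` file.
#' @return `read_dynamic_image` returns a [dynamic_image()];
#'   `write_dynamic_image` returns `path` invisibly.
#' @export
write_dynamic_image <- function(img, path) {
  nii <- RNifti::asNifti(img$data)
  RNifti::pixdim(nii) <- c(rep(img$voxel_mm, 3), 1)
  RNifti::writeNifti(nii, path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  write_csv_full(data.frame(start_min = img$schedule$start,
                            end_min = img$schedule$end),
                 paste0(stem, "_frames.csv"))
  invisible(path)
}

#' @rdname write_dynamic_image
#' @export
read_dynamic_image <- function(path) {
  nii <- RNifti::readNifti(path)
  stem <- sub("\\.nii(\\.gz)?$", "", path)
  fr <- read.csv(paste0(stem, "_frames.csv"))
  check_columns(fr, c("start_min", "end_min"), "frame schedule", path)
  dynamic_image(array(as.numeric(nii), dim(nii)),
                voxel_mm = RNifti::pixdim(nii)[1],
                schedule = frame_schedule(fr$start_min, fr$end_min))
}

#' Read and write 3D volumes as NIfTI
#'
#' Used for masks and parametric/SUV volumes.
#'
#' @param vol 3D numeric or logical array.
#' @param voxel_mm Isotropic voxel size, mm.
#' @param path Path to the `.nii` or `.nii.gz` file.
#' @return `read_volume` returns a list with `data` and `voxel_mm`;
#'   `write_volume` returns `path` invisibly.
#' @export
write_volume <- function(vol, voxel_mm, path) {
  nii <- RNifti::asNifti(vol * 1)
  RNifti::pixdim(nii) <- rep(voxel_mm, 3)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  nii <- RNifti::readNifti(path)
  list(data = array(as.numeric(nii), dim(nii)),
       voxel_mm = RNifti::pixdim(nii)[1])
}

#' Write a kinetic fit as JSON
#'
#' @param fit A `fit_2tcm` object.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  out <- list(mode = fit$mode, params = unclass(fit$params), ki = fit$ki,
              rss = fit$rss, aic = fit$aic, n_frames = fit$n_frames,
              n_free_params = fit$n_free_params, se = as.list(fit$se),
              converged = fit$converged)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Read and write phantom specifications as YAML
#'
#' Serializes the full [phantom_spec()] (grid, organs, lesions, acquisition
#' schedule, input-function knots and parent-fraction parameters) to YAML.
#'
#' @param spec A [phantom_spec()].
#' @param path File path.
#' @return `read_phantom_spec` returns a [phantom_spec()];
#'   `write_phantom_spec` returns `path` invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  ser <- list(
    dim = spec$dim, voxel_mm = spec$voxel_mm,
    organs = lapply(spec$organs, function(o)
      list(name = o$name, shape = o$shape, params = unclass(o$params))),
    lesions = lapply(spec$lesions, function(l)
      list(name = l$name, center = l$center, diameter_mm = l$diameter_mm,
           params = unclass(l$params))),
    injected_dose_mbq = spec$injected_dose_mbq,
    body_weight_kg = spec$body_weight_kg,
    psf_fwhm_mm = spec$psf_fwhm_mm, noise_alpha = spec$noise_alpha,
    seed = spec$seed,
    schedule = list(start = spec$schedule$start, end = spec$schedule$end,
                    labels = spec$schedule$labels),
    input = list(t_knots = spec$input$t_knots,
                 cwb_knots = spec$input$cwb_knots,
                 p2wb_ratio = spec$input$p2wb_ratio,
                 pf_model = if (!is.null(spec$input$pf_model))
                   unclass(spec$input$pf_model)))
  yaml::write_yaml(ser, path, precision = 17)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  s <- yaml::read_yaml(path)
  mk_shape <- function(sh) {
    switch(sh$type,
      sphere = shape_sphere(unlist(sh$center), sh$radius),
      ellipsoid = shape_ellipsoid(unlist(sh$center), unlist(sh$radii)),
      cylinder = shape_cylinder(unlist(sh$center), sh$radius,
                                sh$half_length, sh$axis),
      stop("unknown shape type: ", sh$type))
  }
  mk_params <- function(p)
    kinetic_params(p$K1, p$k2, p$k3, p$k4, p$vB)
  pf <- if (!is.null(s$input$pf_model))
    parent_fraction_model(s$input$pf_model$t50, s$input$pf_model$hill_n,
                          s$input$pf_model$floor_b)
  phantom_spec(
    dim = unlist(s$dim), voxel_mm = s$voxel_mm,
    organs = lapply(s$organs, function(o)
      list(name = o$name, shape = mk_shape(o$shape),
           params = mk_params(o$params))),
    lesions = lapply(s$lesions, function(l)
      list(name = l$name, center = unlist(l$center),
           diameter_mm = l$diameter_mm, params = mk_params(l$params))),
    injected_dose_mbq = s$injected_dose_mbq,
    body_weight_kg = s$body_weight_kg, psf_fwhm_mm = s$psf_fwhm_mm,
    noise_alpha = s$noise_alpha, seed = s$seed,
    schedule = frame_schedule(unlist(s$schedule$start),
                              unlist(s$schedule$end),
                              unlist(s$schedule$labels)),
    input = input_function(unlist(s$input$t_knots),
                           unlist(s$input$cwb_knots),
                           s$input$p2wb_ratio, pf))
}
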