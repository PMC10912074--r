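#' Extract an image-derived input function (IDIF)
#'
#' Per-frame mean activity over a vascular volume of interest (here intended
#' to be the descending aorta), returned as a whole-blood TAC.
#'
#' @param img A [dynamic_image()].
#' @param mask Logical 3D mask matching the spatial dimensions of `img`.
#' @return A [tac()] labelled `"IDIF"`.
#' @export
extract_idif <- function(img, mask) {
  d <- dim(img$data)
  if (!identical(dim(mask), d[1:3])) stop("mask does not match image grid")
  if (!any(mask)) stop("mask is empty")
  mat <- matrix(img$data, prod(d[1:3]), d[4])
  tac(img$schedule$mid, img$schedule$dur, colMeans(mat[as.vector(mask), ,
      drop = FALSE]), label = "IDIF")
}

#' Fit the metabolite correction from blood samples
#'
#' Least-squares fit of the three-parameter parent-fraction model to the
#' measured parent fractions, plus the plasma-to-whole-blood ratio as the
#' mean of the per-sample plasma/whole-blood ratios.
#'
#' @param samples A `blood_sample_table` (see [sample_blood()]) or data frame
#'   with columns `time_min`, `whole_blood`, `plasma`, `parent_fraction`.
#' @return An object of class `metabolite_correction` with `pf_model`,
#'   `p2wb_ratio`, `pf_residuals`, `pf_rms`, `ratio_samples`.
#' @export
fit_metabolite_correction <- function(samples) {
  need <- c("time_min", "whole_blood", "plasma", "parent_fraction")
  miss <- setdiff(need, names(samples))
  if (length(miss)) stop("blood table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(samples) < 3) stop("need at least 3 blood samples")
  tt <- samples$time_min
  pf <- samples$parent_fraction
  if (any(pf < 0 | pf > 1)) stop("parent fractions must be in [0, 1]")
  ratios <- samples$plasma / samples$whole_blood
  if (any(!is.finite(ratios) | ratios <= 0))
    stop("plasma/whole-blood ratios must be positive")

  lower <- c(t50 = 1e-3, n = 0.05, b = 0)
  upper <- c(t50 = 1e4, n = 10, b = 0.9999)
  # heuristic start: midpoint crossing time, unit Hill slope, shrunken floor
  mid <- (1 + min(pf)) / 2
  t0 <- tt[which.min(abs(pf - mid))]
  start <- c(t50 = max(t0, 0.1), n = 1, b = 0.8 * min(pf))
  resid_fn <- function(p) {
    pf - parent_fraction(parent_fraction_model(p[1], p[2], min(p[3], 0.9999)),
                         tt)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error") || !(fit$info %in% 1:4))
    stop("non-convergence fitting the parent-fraction model; residuals at ",
         "start: ", paste(signif(resid_fn(start), 3), collapse = ", "))
  p <- fit$par
  model <- parent_fraction_model(p[1], p[2], min(p[3], 0.9999))
  res <- resid_fn(p)
  structure(list(pf_model = model, p2wb_ratio = mean(ratios),
                 pf_residuals = res, pf_rms = sqrt(mean(res^2)),
                 ratio_samples = ratios),
            class = "metabolite_correction")
}

#' @export
print.metabolite_correction <- function(x, ...) {
  cat(sprintf("<metabolite_correction> p2wb = %.4g, pf RMS = %.3g\n",
              x$p2wb_ratio, x$pf_rms))
  print(x$pf_model)
  invisible(x)
}

#' Metabolite-corrected plasma input from an IDIF
#'
#' Builds the continuous input-function set Cp(t) = Cwb(t) * R * pf(t) from
#' a whole-blood IDIF and a fitted metabolite correction. The IDIF is
#' interpolated piecewise-linearly with (0, 0) prepended and extrapolated as
#' a constant beyond the last frame mid-time.
#'
#' @param idif A whole-blood [tac()] (e.g. from [extract_idif()]).
#' @param corr A [fit_metabolite_correction()] result, or a list with
#'   `p2wb_ratio` and `pf_model`.
#' @param delay Optional fixed time shift of the IDIF, min (default 0).
#' @return An [input_function()].
#' @export
correct_input <- function(idif, corr, delay = 0) {
  t <- idif$time + delay
  if (any(t <= 0)) stop("delayed mid-times must stay positive")
  input_function(c(0, t), c(0, idif$activity),
                 p2wb_ratio = corr$p2wb_ratio, pf_model = corr$pf_model,
                 label = "metabolite-corrected IDIF")
}
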