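#' Standardized uptake value image
#'
#' Duration-weighted mean of the frames spanning the acquisition window,
#' scaled to SUV units: SUV = concentration x body weight / injected dose.
#' With concentration in kBq/mL, dose in MBq and weight in kg the unit
#' conversions cancel exactly (dose x 1000 to kBq against weight x 1000 to
#' g), so the scale factor is simply `weight_kg / dose_mbq` and the result
#' is in g/mL; [suv_scale_factor()] centralizes this.
#'
#' @param img A [dynamic_image()].
#' @param window Length-2 window in minutes; default `c(60, 70)`. Must be
#'   tiled exactly by frame boundaries.
#' @param dose_mbq Injected dose, MBq.
#' @param weight_kg Body weight, kg.
#' @return An object of class `suv_image` with the 3D `data` array (g/mL),
#'   `window`, `dose_mbq`, `weight_kg`, `voxel_mm`.
#' @export
suv_image <- function(img, window = c(60, 70), dose_mbq, weight_kg) {
  if (dose_mbq <= 0 || weight_kg <= 0) stop("dose and weight must be positive")
  sched <- img$schedule
  idx <- frames_in_window(sched, window)
  if (length(idx) == 0 ||
      abs(min(sched$start[idx]) - window[1]) > 1e-9 ||
      abs(max(sched$end[idx]) - window[2]) > 1e-9 ||
      abs(sum(sched$dur[idx]) - diff(window)) > 1e-9) {
    inside <- which(sched$end > window[1] & sched$start < window[2])
    stop("window [", window[1], ", ", window[2], "] min is not aligned to ",
         "frame boundaries; overlapping frames: ",
         paste(sprintf("[%g, %g]", sched$start[inside], sched$end[inside]),
               collapse = ", "))
  }
  w <- sched$dur[idx] / sum(sched$dur[idx])
  d <- dim(img$data)
  mean_img <- array(0, d[1:3])
  for (j in seq_along(idx)) mean_img <- mean_img + w[j] * img$data[, , , idx[j]]
  structure(list(data = mean_img * suv_scale_factor(dose_mbq, weight_kg),
                 window = window, dose_mbq = dose_mbq, weight_kg = weight_kg,
                 voxel_mm = img$voxel_mm),
            class = "suv_image")
}

#' SUV scale factor
#'
#' Converts an activity concentration in kBq/mL to SUV in g/mL for a given
#' injected dose (MBq) and body weight (kg): the kBq-per-MBq and g-per-kg
#' factors of 1000 cancel, leaving `weight_kg / dose_mbq`.
#'
#' @param dose_mbq Injected dose, MBq.
#' @param weight_kg Body weight, kg.
#' @return Multiplicative factor (g/mL per kBq/mL).
#' @export
suv_scale_factor <- function(dose_mbq, weight_kg) weight_kg / dose_mbq

#' 50% isocontour volume of interest
#'
#' Finds the hottest voxel within the seed mask, thresholds at
#' `frac x max`, and returns the 26-connected component containing the
#' maximum voxel, searched within the seed's bounding box padded by
#' `pad_vox` voxels (so a blurred lesion's half-maximum contour may extend
#' slightly beyond the drawn seed). Ties for the maximum are broken by the
#' lowest linear index.
#'
#' @param vol 3D numeric array.
#' @param seed_mask Logical 3D array, non-empty.
#' @param frac Threshold fraction of the maximum (default 0.5).
#' @param pad_vox Bounding-box padding in voxels (default 3).
#' @return Logical 3D VOI mask.
#' @export
isocontour_voi <- function(vol, seed_mask, frac = 0.5, pad_vox = 3) {
  d <- dim(vol)
  if (!identical(dim(seed_mask), d)) stop("seed mask does not match volume")
  if (!any(seed_mask)) stop("seed mask is empty")
  idx_seed <- which(seed_mask)
  vmax_idx <- idx_seed[which.max(vol[idx_seed])]  # which.max: first = lowest index
  vmax <- vol[vmax_idx]
  co <- arrayInd(idx_seed, d)
  lo <- pmax(apply(co, 2, min) - pad_vox, 1)
  hi <- pmin(apply(co, 2, max) + pad_vox, d)
  inbox <- array(FALSE, d)
  inbox[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  cand <- inbox & vol >= frac * vmax
  # BFS flood fill with 26-connectivity from the max voxel
  voi <- array(FALSE, d)
  start <- arrayInd(vmax_idx, d)
  queue <- matrix(start, ncol = 3)
  voi[vmax_idx] <- TRUE
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    nxt <- sweep(nb, 2, as.numeric(cur), "+")
    ok <- nxt[, 1] >= 1 & nxt[, 1] <= d[1] & nxt[, 2] >= 1 & nxt[, 2] <= d[2] &
      nxt[, 3] >= 1 & nxt[, 3] <= d[3]
    nxt <- nxt[ok, , drop = FALSE]
    lin <- nxt[, 1] + d[1] * (nxt[, 2] - 1) + d[1] * d[2] * (nxt[, 3] - 1)
    new <- cand[lin] & !voi[lin]
    if (any(new)) {
      voi[lin[new]] <- TRUE
      queue <- rbind(queue, nxt[new, , drop = FALSE])
    }
  }
  voi
}

#' Target-to-background and contrast-to-noise ratios
#'
#' TBR = mean(target) / mean(background);
#' CNR = (mean(target) - mean(background)) / SD(background), with the
#' population (not sample) SD over background voxels.
#'
#' @param vol 3D numeric array (SUV or Ki image).
#' @param voi_mask Logical target mask.
#' @param bg_mask Logical background mask, disjoint from the target.
#' @return Named numeric vector `c(tbr =, cnr =)`.
#' @export
lesion_stats <- function(vol, voi_mask, bg_mask) {
  if (!any(voi_mask) || !any(bg_mask)) stop("masks must be non-empty")
  if (any(voi_mask & bg_mask)) stop("target and background masks overlap")
  tv <- vol[voi_mask]; bv <- vol[bg_mask]
  mb <- mean(bv)
  if (mb == 0) stop("TBR undefined: background mean is zero")
  sdb <- sqrt(mean((bv - mb)^2))
  if (sdb == 0) stop("CNR undefined: background SD is zero")
  c(tbr = mean(tv) / mb, cnr = (mean(tv) - mb) / sdb)
}

#' Screen lesions by SUVmax
#'
#' Computes SUVmax and SUVmean per candidate lesion and flags those with
#' SUVmax >= `threshold` (default 1.5) as included.
#'
#' @param suv A [suv_image()].
#' @param lesion_masks Named list of logical VOI masks.
#' @param threshold Inclusion threshold on SUVmax (default 1.5; the
#'   comparison is `>=`).
#' @return A data frame with columns `lesion`, `suv_max`, `suv_mean`,
#'   `included`.
#' @export
screen_lesions <- function(suv, lesion_masks, threshold = 1.5) {
  if (length(lesion_masks) == 0)
    return(data.frame(lesion = character(), suv_max = numeric(),
                      suv_mean = numeric(), included = logical()))
  mx <- vapply(lesion_masks, function(m) max(suv$data[m]), 0)
  mn <- vapply(lesion_masks, function(m) mean(suv$data[m]), 0)
  data.frame(lesion = names(lesion_masks), suv_max = mx, suv_mean = mn,
             included = mx >= threshold, row.names = NULL)
}

#' Paired log-ratio comparison of two image types
#'
#' Compares a per-lesion metric (TBR or CNR) between two image types by
#' log-transformation and a paired t-test, as is standard for ratio-scaled
#' imaging metrics: d = log(b) - log(a) per lesion, ratio = exp(mean d)
#' (the geometric-mean ratio, reported clinically as the "median ratio"),
#' with 95% CI exp(mean d +- t(0.975, n-1) SE).
#'
#' @param a Values in the reference image (e.g. SUV), all > 0.
#' @param b Values in the comparison image (e.g. Ki), all > 0.
#' @param names Optional lesion names used in error messages.
#' @return An object of class `ratio_comparison` with `n`, `ratio`,
#'   `ci` (length 2), `p_value`, `n_higher` (pairs with b > a).
#' @export
compare_image_types <- function(a, b, names = NULL) {
  if (length(a) != length(b) || length(a) < 2)
    stop("need >= 2 paired values")
  bad <- !(a > 0 & b > 0)
  if (any(bad)) {
    who <- if (is.null(names)) which(bad) else names[bad]
    stop("non-positive values for lesion(s): ", paste(who, collapse = ", "))
  }
  d <- log(b) - log(a)
  n <- length(d)
  m <- mean(d)
  se <- sd(d) / sqrt(n)
  tstat <- if (se > 0) m / se else if (m == 0) 0 else Inf * sign(m)
  p <- 2 * pt(-abs(tstat), df = n - 1)
  half <- qt(0.975, n - 1) * se
  structure(list(n = n, ratio = exp(m), ci = exp(c(m - half, m + half)),
                 p_value = p, n_higher = sum(b > a)),
            class = "ratio_comparison")
}

#' @export
print.ratio_comparison <- function(x, ...) {
  cat(sprintf(
    "<ratio_comparison> ratio %.3f (95%% CI %.3f-%.3f), p = %.3g, b > a in %d/%d\n",
    x$ratio, x$ci[1], x$ci[2], x$p_value, x$n_higher, x$n))
  invisible(x)
}
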