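make_flat_dyn <- function(values, windows = list(c(60, 65), c(65, 70)),
                          dim = c(6, 6, 4)) {
  # one uniform value per frame
  sch <- frame_schedule(vapply(windows, `[`, 0, 1),
                        vapply(windows, `[`, 0, 2))
  arr <- array(rep(values, each = prod(dim)), c(dim, length(values)))
  dynamic_image(arr, 4, sch)
}

test_that("SUV normalization is the identity at C = dose / weight", {
  img <- make_flat_dyn(c(200 / 70, 200 / 70))
  suv <- suv_image(img, c(60, 70), dose_mbq = 200, weight_kg = 70)
  expect_equal(suv$data, array(1, dim(suv$data)))
})

test_that("the SUV window mean is duration-weighted", {
  img <- make_flat_dyn(c(4, 6))
  suv <- suv_image(img, c(60, 70), dose_mbq = 200, weight_kg = 70)
  expect_equal(suv$data[1, 1, 1], 5 * 70 / 200)
  img2 <- make_flat_dyn(c(4, 6), windows = list(c(60, 62), c(62, 70)))
  suv2 <- suv_image(img2, c(60, 70), 200, 70)
  expect_equal(suv2$data[1, 1, 1], (4 * 2 + 6 * 8) / 10 * 70 / 200)
})

test_that("misaligned SUV windows raise a named error", {
  img <- make_flat_dyn(c(4, 6))
  expect_error(suv_image(img, c(61, 70), 200, 70), "not aligned")
  expect_error(suv_image(img, c(60, 75), 200, 70), "not aligned")
  expect_error(suv_image(img, c(60, 70), -1, 70), "positive")
})

test_that("isocontour VOI covers a uniform sphere on a cold background", {
  d <- c(20, 20, 20)
  vol <- array(0, d)
  sph <- dwbpet:::rasterize_shape(shape_sphere(c(40, 40, 40), 14), d, 4)
  vol[sph] <- 5
  expect_equal(isocontour_voi(vol, sph), sph)
})

test_that("isocontour VOI keeps only the blob holding the maximum", {
  d <- c(20, 10, 6)
  vol <- array(0, d)
  vol[3:5, 4:6, 3:4] <- 2       # cooler blob
  vol[14:16, 4:6, 3:4] <- 3     # hotter blob
  seed <- array(TRUE, d)
  voi <- isocontour_voi(vol, seed)
  expect_true(all(which(voi) %in% which(vol == 3)))
  expect_equal(sum(voi), sum(vol == 3))
})

test_that("blurred-sphere VOI matches a brute-force component closure", {
  d <- c(24, 24, 24)
  vol <- array(0, d)
  sph <- dwbpet:::rasterize_shape(shape_sphere(c(48, 48, 48), 16), d, 4)
  vol[sph] <- 10
  vol <- dwbpet:::gaussian_smooth_3d(vol, 1.2)
  voi <- isocontour_voi(vol, sph)
  # closure property: voi is exactly the 26-connected threshold component
  # containing the max (no thresholded neighbor of a voi voxel is excluded)
  idx_seed <- which(sph)
  vmax <- max(vol[idx_seed])
  co <- which(sph, arr.ind = TRUE)
  lo <- pmax(apply(co, 2, min) - 3, 1); hi <- pmin(apply(co, 2, max) + 3, d)
  box <- array(FALSE, d); box[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  cand <- box & vol >= 0.5 * vmax
  expect_true(all(vol[voi] >= 0.5 * vmax))
  expect_true(all(box[voi]))
  grow <- which(voi, arr.ind = TRUE)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  for (k in seq_len(nrow(nb))) {
    sh <- sweep(grow, 2, nb[k, ], "+")
    ok <- sh[, 1] >= 1 & sh[, 1] <= d[1] & sh[, 2] >= 1 & sh[, 2] <= d[2] &
      sh[, 3] >= 1 & sh[, 3] <= d[3]
    lin <- sh[ok, 1] + d[1] * (sh[ok, 2] - 1) + d[1] * d[2] * (sh[ok, 3] - 1)
    expect_true(all(voi[lin] | !cand[lin]))
  }
  expect_error(isocontour_voi(vol, sph & FALSE), "empty")
})

test_that("lesion statistics match hand-computed values and brute force", {
  d <- c(4, 4, 2)
  vol <- array(0, d)
  voi <- bg <- array(FALSE, d)
  vol[1:2, 1, 1] <- 4; voi[1:2, 1, 1] <- TRUE
  vol[1:4, 2, 1] <- c(1, 1, 3, 3); bg[1:4, 2, 1] <- TRUE
  s <- lesion_stats(vol, voi, bg)
  expect_equal(unname(s["tbr"]), 2)
  expect_equal(unname(s["cnr"]), 2)           # (4 - 2) / 1, population SD
  # brute force over random small images
  set.seed(9)
  for (i in 1:5) {
    v <- array(runif(prod(d), 0.1, 5), d)
    sb <- lesion_stats(v, voi, bg)
    tv <- NULL; bv <- NULL
    for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
      if (voi[x, y, z]) tv <- c(tv, v[x, y, z])
      if (bg[x, y, z]) bv <- c(bv, v[x, y, z])
    }
    expect_equal(unname(sb["tbr"]), mean(tv) / mean(bv))
    expect_equal(unname(sb["cnr"]),
                 (mean(tv) - mean(bv)) /
                   sqrt(sum((bv - mean(bv))^2) / length(bv)))
    # scale invariance
    expect_equal(lesion_stats(3 * v, voi, bg), sb)
  }
  expect_error(lesion_stats(vol, voi, voi), "overlap")
  expect_error(lesion_stats(vol * 0, voi, bg), "background mean")
  flat <- vol; flat[bg] <- 1
  expect_error(lesion_stats(flat, voi, bg), "background SD")
})

test_that("equal target and background means give TBR 1 and CNR 0", {
  d <- c(4, 4, 1)
  vol <- array(c(2, 2, 2, 2, 1, 3, 1, 3, rep(0, 8)), d)
  voi <- array(c(rep(TRUE, 4), rep(FALSE, 12)), d)
  bg <- array(c(rep(FALSE, 4), rep(TRUE, 4), rep(FALSE, 8)), d)
  s <- lesion_stats(vol, voi, bg)
  expect_equal(unname(s["tbr"]), 1)
  expect_equal(unname(s["cnr"]), 0)
})

test_that("lesion screening applies the SUVmax >= 1.5 rule inclusively", {
  suv <- structure(list(data = array(0.2, c(6, 6, 2))), class = "suv_image")
  m1 <- m2 <- m3 <- array(FALSE, c(6, 6, 2))
  m1[1:2, 1, 1] <- TRUE; suv$data[1, 1, 1] <- 1.49
  m2[3:4, 1, 1] <- TRUE; suv$data[3, 1, 1] <- 1.5
  m3[5:6, 1, 1] <- TRUE; suv$data[5, 1, 1] <- 4
  scr <- screen_lesions(suv, list(a = m1, b = m2, c = m3))
  expect_equal(scr$included, c(FALSE, TRUE, TRUE))
  expect_equal(scr$suv_max, c(1.49, 1.5, 4))
  empty <- screen_lesions(suv, list())
  expect_equal(nrow(empty), 0)
})

test_that("paired log-ratio comparison matches a hand oracle exactly", {
  # hand computation at n = 3: d = log(b) - log(a)
  a <- c(2, 3, 5); b <- c(3, 7, 6)
  d <- log(b) - log(a)
  m <- mean(d); se <- sd(d) / sqrt(3)
  cmp <- compare_image_types(a, b)
  expect_identical(cmp$ratio, exp(m))
  expect_identical(cmp$ci, exp(c(m - qt(0.975, 2) * se, m + qt(0.975, 2) * se)))
  expect_equal(cmp$p_value, t.test(log(b), log(a), paired = TRUE)$p.value)
  expect_equal(cmp$n_higher, 3)
})

test_that("degenerate and exact-ratio pairs behave as defined", {
  eq <- compare_image_types(c(2, 3, 4), c(2, 3, 4))
  expect_equal(eq$ratio, 1)
  expect_equal(eq$ci, c(1, 1))
  expect_equal(eq$n_higher, 0)
  doubled <- compare_image_types(c(1, 2, 4), c(2, 4, 8))
  expect_equal(doubled$ratio, 2)
  expect_error(compare_image_types(c(1, -1, 2), c(1, 1, 1),
                                   names = c("p", "q", "r")), "q")
  expect_error(compare_image_types(1, 2), ">= 2")
})

test_that("log-ratio CI agrees with a bootstrap on many lognormal pairs", {
  set.seed(31)
  n <- 164
  a <- exp(rnorm(n, 1, 0.5))
  b <- a * exp(rnorm(n, log(2.45), 0.4))   # true ratio 2.45
  cmp <- compare_image_types(a, b)
  d <- log(b) - log(a)
  boots <- vapply(1:4000, function(i) mean(d[sample.int(n, replace = TRUE)]),
                  0)
  bci <- exp(quantile(boots, c(0.025, 0.975)))
  expect_lt(abs(cmp$ratio - exp(mean(d))), 1e-12)
  expect_lt(abs(cmp$ci[1] - bci[[1]]) / bci[[1]], 0.02)
  expect_lt(abs(cmp$ci[2] - bci[[2]]) / bci[[2]], 0.02)
  expect_true(cmp$ci[1] < cmp$ratio && cmp$ratio < cmp$ci[2])
})
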