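test_that("rasterization follows the pixel-centre rule exactly", {
  # 10x10 rectangle with edges half a pixel beyond the covered centres
  m <- rasterize_roi(rect_roi(0, 9, 0, 9), c(12, 12))
  expect_equal(sum(m), 100)
  expect_true(all(m[1:10, 1:10]))
  expect_false(any(m[11:12, ]) || any(m[, 11:12]))
})

test_that("scanline rasterization agrees with a brute-force ray cast", {
  tri <- roi_polygon(c(0.2, 9.4, 4.1), c(0.4, 2.3, 9.4))
  expect_identical(rasterize_roi(tri, c(10, 10)), brute_rasterize(tri, c(10, 10)))

  set.seed(7)
  for (r in 1:5) {
    # star-shaped random polygon around a centre: simple by construction
    n <- sample(5:9, 1)
    ang <- sort(runif(n, 0, 2 * pi))
    rad <- runif(n, 1, 6)
    poly <- roi_polygon(6 + rad * cos(ang), 6 + rad * sin(ang))
    expect_identical(rasterize_roi(poly, c(13, 13)),
                     brute_rasterize(poly, c(13, 13)))
  }
})

test_that("degenerate and out-of-bounds polygons are handled explicitly", {
  expect_error(roi_polygon(c(0, 1), c(0, 1)), ">= 3")
  expect_error(roi_polygon(c(0, 1, 2), c(0, 0, 0)), "area")
  # bow-tie self-intersection (non-zero net area so the crossing check fires)
  expect_error(roi_polygon(c(0, 4, 4, 0), c(0, 4, 0, 3)), "self-intersecting")
  # fully outside the image: empty mask plus warnings
  far <- rect_roi(20, 25, 20, 25)
  expect_warning(expect_warning(m <- rasterize_roi(far, c(10, 10)),
                                "beyond the image"), "empty mask")
  expect_false(any(m))
})

test_that("mean mucosal height is the arithmetic mean with strict inputs", {
  expect_equal(mean_mucosal_height(mucosa_heights(rep(300, 10))), 300)
  expect_equal(mean_mucosal_height(mucosa_heights(seq(100, 1000, by = 100))),
               550)
  expect_warning(h <- mucosa_heights(c(300)), "expected 10")
  expect_equal(h$mean_um, 300)
  expect_error(mucosa_heights(numeric(0)), "missing measurement")
  expect_error(mucosa_heights(c(100, -5, 300, 1, 1, 1, 1, 1, 1, 1)), "> 0")
})

test_that("mucosal length honours the area / mean-height definition", {
  expect_equal(mucosa_length(10000, 1, 100), 100)
  expect_equal(mucosa_length(10000, 0.5, 50), 50)   # 10000 * 0.25 / 50
  # inverse proportionality in height, quadratic scaling in pixel size
  expect_equal(mucosa_length(10000, 1, 200), 50)
  expect_equal(mucosa_length(10000, 2, 100), 400)
  expect_error(mucosa_length(10000, 1, 0), "invalid normalizer")
})

test_that("expression per um is the guarded quotient", {
  expect_equal(expression_per_um(0, 123), 0)
  expect_equal(expression_per_um(5000, 100), 50)
  expect_error(expression_per_um(5000, 0), "invalid normalizer")
  expect_error(expression_per_um(-1, 10), ">= 0")
})

test_that("percent DAB area is the mask ratio with an ROI guard", {
  roi <- matrix(FALSE, 20, 20); roi[1:10, 1:20] <- TRUE           # 200 px
  dab <- matrix(FALSE, 20, 20); dab[1:5, 1:5] <- TRUE             # 25 inside
  expect_equal(percent_dab_area(dab, roi), 12.5)
  expect_equal(percent_dab_area(roi, roi), 100)                   # superset
  expect_equal(percent_dab_area(!roi, roi), 0)                    # disjoint
  expect_error(percent_dab_area(dab, matrix(FALSE, 20, 20)), "invalid ROI")
})

test_that("a blank white image quantifies to zero expression", {
  img <- flat_image(c(255, 255, 255), h = 20, w = 20)
  q <- quantify_sample(img, rect_roi(2, 17, 2, 17), rep(10, 10))
  expect_equal(q$expr_per_um, 0)
  expect_equal(q$pct_area, 0)
  expect_equal(q$total_intensity, 0)
})

test_that("measured percent area tracks the ground-truth area fraction", {
  for (s in c(5, 6)) {
    sl <- generate_slide(synthetic_slide_spec(noise_sd = 0, seed = s))
    q <- quantify_sample(sl$image, sl$roi, sl$heights)
    expect_lt(abs(q$pct_area - sl$truth$area_fraction_pct), 2)
  }
})

test_that("tiling a ROI conserves intensity, area and the per-um statistic", {
  sl <- generate_slide(synthetic_slide_spec(noise_sd = 0, seed = 9))
  cfg <- run_config()
  q <- quantify_sample(sl$image, sl$roi, sl$heights, cfg)
  hpx <- dim(sl$image$px)[1]; wpx <- dim(sl$image$px)[2]

  # recompute totals on the two column halves of the same band
  band <- sl$truth$roi_mask
  conc <- deconvolve(rgb_to_od(sl$image), cfg$stains)
  map <- apply_threshold_window(
    to_inverted_8bit(conc$dab, detect_dab(conc$dab, cfg$od_threshold),
                     cfg$scale_od, sl$image$pixel_size_um), cfg$window)
  mid <- wpx %/% 2
  left <- band; left[, (mid + 1):wpx] <- FALSE
  right <- band; right[, 1:mid] <- FALSE
  t1 <- sum(map$map[left & map$mask]); t2 <- sum(map$map[right & map$mask])
  a1 <- sum(left); a2 <- sum(right)
  expect_identical(t1 + t2, q$total_intensity)
  expect_identical(a1 + a2, q$roi_area_px)

  mh <- sl$heights$mean_um
  l1 <- mucosa_length(a1, 1, mh); l2 <- mucosa_length(a2, 1, mh)
  expect_equal((t1 + t2) / (l1 + l2), q$expr_per_um, tolerance = 1e-12)
  # the union statistic is the length-weighted mean of the parts
  e1 <- expression_per_um(t1, l1); e2 <- expression_per_um(t2, l2)
  expect_equal((e1 * l1 + e2 * l2) / (l1 + l2), q$expr_per_um,
               tolerance = 1e-12)
})

test_that("doubling the mean mucosal height doubles expression per um", {
  sl <- generate_slide(synthetic_slide_spec(noise_sd = 0, seed = 10))
  q1 <- quantify_sample(sl$image, sl$roi, sl$heights)
  q2 <- quantify_sample(sl$image, sl$roi,
                        mucosa_heights(sl$heights$heights * 2))
  expect_equal(q2$expr_per_um / q1$expr_per_um, 2, tolerance = 1e-12)
  expect_equal(q2$length_um * 2, q1$length_um, tolerance = 1e-9)
  # the bookkeeping invariant holds in both cases
  expect_equal(q1$length_um * q1$mean_height_um, q1$roi_area_um2,
               tolerance = 1e-6)
  expect_equal(q2$length_um * q2$mean_height_um, q2$roi_area_um2,
               tolerance = 1e-6)
})

test_that("adding DAB-positive pixels never decreases either statistic", {
  # two images composed from nested concentration fields: the second adds a
  # DAB patch inside the ROI and leaves every other pixel untouched
  a <- t(unclass(default_hdab_stain_matrix()))
  compose <- function(conc_d) {
    px <- array(0, dim = c(20, 20, 3))
    for (c3 in 1:3) px[, , c3] <- round(255 * 10^(-a[c3, 2] * conc_d))
    rgb_image(px, 1)
  }
  base <- matrix(0, 20, 20); base[14:16, 3:5] <- 0.4
  more <- base; more[14:16, 12:14] <- 0.35
  roi <- rect_roi(1, 18, 10, 18)
  hts <- rep(9, 10)
  q1 <- quantify_sample(compose(base), roi, hts)
  q2 <- quantify_sample(compose(more), roi, hts)
  expect_gt(q2$total_intensity, q1$total_intensity)
  expect_gt(q2$pct_area, q1$pct_area)
  expect_gt(q2$expr_per_um, q1$expr_per_um)
})

test_that("pixel-size mismatch between image and ROI is refused", {
  img <- flat_image(c(255, 255, 255), 10, 10, pixel_size_um = 1)
  roi <- rect_roi(1, 8, 1, 8, pixel_size_um = 2)
  expect_error(quantify_sample(img, roi, rep(5, 10)), "pixel sizes")
})
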