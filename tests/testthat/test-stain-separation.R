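test_that("default H-DAB stain matrix satisfies its geometric contract", {
  m <- default_hdab_stain_matrix()
  expect_equal(unname(sqrt(rowSums(unclass(m)^2))), rep(1, 3), tolerance = 1e-9)
  expect_true(all(m >= 0))
  expect_lt(kappa(unclass(m), exact = TRUE), 1e6)
  expect_identical(m, default_hdab_stain_matrix())  # deterministic

  # a pure-DAB pixel built by forward Beer-Lambert deconvolves to zero
  # hematoxylin and the exact DAB concentration
  a <- t(unclass(m))
  cdab <- 0.37
  od <- as.numeric(a %*% c(0, cdab, 0))
  odim <- structure(list(od = array(od, dim = c(1, 1, 3)),
                         background = c(255, 255, 255)), class = "od_image")
  conc <- deconvolve(odim, m)
  expect_equal(conc$hematoxylin[1, 1], 0, tolerance = 1e-6)
  expect_equal(conc$dab[1, 1], cdab, tolerance = 1e-9)
  expect_equal(conc$residual[1, 1], 0, tolerance = 1e-6)
})

test_that("stain matrix construction rejects bad bases", {
  expect_error(stain_matrix(c(1, 0, 0), c(-1, 0, 0)), "non-negative")
  expect_error(stain_matrix(c(0, 0, 0), c(0, 1, 0)), "non-zero")
  expect_error(stain_matrix(c(1, 0, 0), c(1, 0, 0), c(1, 0, 0)),
               "ill-conditioned")
})

test_that("rgb_to_od implements the guarded Beer-Lambert transform", {
  # background pixel maps to zero OD
  od <- rgb_to_od(flat_image(c(255, 255, 255)))
  expect_true(all(od$od == 0))

  # grey pixel: -log10(25/255) per channel
  od <- rgb_to_od(flat_image(c(25, 25, 25)))
  expect_equal(od$od[1, 1, ], rep(-log10(25 / 255), 3), tolerance = 1e-9)
  expect_equal(od$od[1, 1, 1], 1.0086002, tolerance = 1e-6)

  # saturated black: epsilon guard yields finite -log10(1/255)
  od <- rgb_to_od(flat_image(c(0, 0, 0)))
  expect_true(all(is.finite(od$od)))
  expect_equal(od$od[1, 1, ], rep(-log10(1 / 255), 3), tolerance = 1e-9)

  # pixels brighter than the reference clamp at zero, never negative
  od <- rgb_to_od(flat_image(c(250, 250, 250)), background = c(200, 200, 200))
  expect_true(all(od$od == 0))

  expect_error(rgb_to_od(flat_image(c(9, 9, 9)), background = c(0, 255, 255)),
               "invalid background")
})

test_that("whole-image deconvolution matches per-pixel linear solves", {
  m <- default_hdab_stain_matrix()
  a <- t(unclass(m))
  set.seed(42)
  for (r in 1:5) {
    d <- sample(2:8, 2)
    od_arr <- array(runif(prod(d) * 3, 0, 1.5), dim = c(d, 3))
    odim <- structure(list(od = od_arr, background = c(255, 255, 255)),
                      class = "od_image")
    conc <- deconvolve(odim, m)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      ref <- pmax(solve(a, od_arr[i, j, ]), 0)
      expect_equal(c(conc$hematoxylin[i, j], conc$dab[i, j],
                     conc$residual[i, j]), unname(ref), tolerance = 1e-9)
    }
  }
})

test_that("deconvolving an all-zero OD image gives all-zero concentrations", {
  odim <- structure(list(od = array(0, dim = c(4, 4, 3)),
                         background = c(255, 255, 255)), class = "od_image")
  conc <- deconvolve(odim, default_hdab_stain_matrix())
  expect_true(all(conc$hematoxylin == 0) && all(conc$dab == 0) &&
              all(conc$residual == 0))
})

test_that("detect_dab thresholds the concentration field", {
  f <- matrix(c(0, 0.1, 0.2, 0.5), 2, 2)
  expect_equal(detect_dab(f, 0), f > 0)           # support at threshold 0
  expect_equal(sum(detect_dab(f, 0.15)), 2)
  expect_false(any(detect_dab(f, 1)))             # above the field maximum
  expect_error(detect_dab(f, -1), ">= 0")
})

test_that("inverted 8-bit conversion saturates, zeroes and reverses order", {
  f <- matrix(c(0, 0.25, 1, 2), 2, 2)
  mask <- matrix(TRUE, 2, 2)
  map <- to_inverted_8bit(f, mask, scale_od = 1)
  expect_equal(map$map[1, 1], 0)      # zero concentration inside the mask
  expect_equal(map$map[2, 1], 64)
  expect_equal(map$map[1, 2], 255)    # saturation point
  expect_equal(map$map[2, 2], 255)    # above saturation clamps

  # straight inversion exactly reverses the pixel ordering (tie-free map)
  g <- to_inverted_8bit(matrix(c(0, 0.25, 0.5, 0.75), 2, 2), mask, 1)$map
  inv <- 255 - g
  expect_equal(order(as.vector(g)), rev(order(as.vector(inv))))

  # outside the mask the map is zero
  mask2 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  map2 <- to_inverted_8bit(f, mask2, scale_od = 1)
  expect_true(all(map2$map[!mask2] == 0))
})

test_that("threshold window filters values and stays idempotent", {
  expect_error(threshold_window(10, 10), "low < high")
  expect_error(threshold_window(-1, 10), "low < high")

  f <- matrix(seq(0, 1, length.out = 64), 8, 8)
  mask <- matrix(TRUE, 8, 8)
  map <- to_inverted_8bit(f, mask, scale_od = 1)

  # full-range window changes nothing
  full <- apply_threshold_window(map, threshold_window(0.0001, 255))
  expect_equal(full$map, map$map)

  # a map holding only value 5 inside the mask is emptied by window (10, 250)
  lo <- to_inverted_8bit(matrix(5 / 255, 4, 4), matrix(TRUE, 4, 4), 1)
  gone <- apply_threshold_window(lo, threshold_window(10, 250))
  expect_false(any(gone$mask))
  expect_true(all(gone$map == 0))

  # surviving pixel count equals independent histogram mass in [low, high]
  w <- threshold_window(10, 250)
  filt <- apply_threshold_window(map, w)
  expect_equal(sum(filt$mask), sum(map$map >= 10 & map$map <= 250 & map$mask))

  # idempotence and mask-zero consistency
  again <- apply_threshold_window(filt, w)
  expect_identical(again$map, filt$map)
  expect_identical(again$mask, filt$mask)
  expect_true(all(filt$map[!filt$mask] == 0))
})
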