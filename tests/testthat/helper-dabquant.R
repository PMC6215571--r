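# small, fast slide specs used across tests
tiny_spec <- function(...) {
  validation_slide_spec(noise_sd = 0, ...)
}

# independent brute-force point-in-polygon oracle (classic crossing-number
# ray cast, one pixel centre at a time)
pnpoly <- function(px, py, tx, ty) {
  n <- length(px)
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    if (((py[i] > ty) != (py[j] > ty)) &&
        (tx < (px[j] - px[i]) * (ty - py[i]) / (py[j] - py[i]) + px[i])) {
      inside <- !inside
    }
    j <- i
  }
  inside
}

brute_rasterize <- function(poly, shape) {
  h <- shape[1]; w <- shape[2]
  m <- matrix(FALSE, h, w)
  for (i in 0:(h - 1)) for (j in 0:(w - 1)) {
    m[i + 1, j + 1] <- pnpoly(poly$x, poly$y, j, i)
  }
  m
}

# rectangle polygon covering pixel centres cols x0..x1, rows y0..y1 (0-based)
rect_roi <- function(x0, x1, y0, y1, pixel_size_um = 1) {
  roi_polygon(c(x0 - 0.5, x1 + 0.5, x1 + 0.5, x0 - 0.5),
              c(y0 - 0.5, y0 - 0.5, y1 + 0.5, y1 + 0.5),
              pixel_size_um = pixel_size_um)
}

# uniform image of one colour
flat_image <- function(rgb, h = 8, w = 8, pixel_size_um = 1) {
  px <- array(0, dim = c(h, w, 3))
  for (c3 in 1:3) px[, , c3] <- rgb[c3]
  rgb_image(px, pixel_size_um)
}
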