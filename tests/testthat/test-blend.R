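brute_distance <- function(m) {
  # O(n^2) nearest-background search, the independent oracle for distmap
  out <- matrix(0, nrow(m), ncol(m))
  bg <- which(m == 0, arr.ind = TRUE)
  fg <- which(m != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(fg))) {
    d <- sqrt((bg[, 1] - fg[k, 1])^2 + (bg[, 2] - fg[k, 2])^2)
    out[fg[k, 1], fg[k, 2]] <- min(d)
  }
  out
}

test_that("feathering weights equal the distance to the nearest background pixel", {
  expect_equal(distance_weights(matrix(0, 3, 4)), matrix(0, 3, 4))
  expect_equal(distance_weights(matrix(c(0, 1, 1, 1, 0), 1)),
               matrix(c(0, 1, 2, 1, 0), 1))
  single <- matrix(0, 5, 5); single[3, 3] <- 1
  w <- distance_weights(single)
  expect_equal(w[3, 3], 1)
  expect_equal(sum(w > 0), 1)
  set.seed(8)
  rnd <- matrix(runif(15 * 12) > 0.6, 15, 12)
  expect_equal(distance_weights(rnd), brute_distance(rnd), tolerance = 1e-9)
})

test_that("weights vanish outside the mask and grow toward the interior", {
  m <- tiny_sweep()$true_masks[[1]]
  w <- distance_weights(m)
  expect_true(all(w[!m] == 0))
  expect_true(all(w[m] > 0))
  # border pixels weigh strictly less than an interior pixel
  border <- m & !(slitmosaic:::local_min3(m * 1) > 0)
  interior_max <- max(w)
  expect_true(all(w[border] < interior_max))
  expect_lte(max(w[border]), sqrt(2) + 1e-9)   # background is adjacent
})

test_that("shrinking a mask never increases the feathering weight anywhere", {
  set.seed(5)
  for (rep in 1:5) {
    m <- matrix(runif(20 * 20) > 0.4, 20, 20)
    shrink <- m & (matrix(runif(20 * 20) > 0.2, 20, 20))
    expect_true(all(distance_weights(shrink) <= distance_weights(m) + 1e-12))
  }
})

test_that("a single frame composites to itself restricted to its mask", {
  sq <- tiny_clean()
  fr <- sq$frames[[1]]; m <- sq$true_masks[[1]]
  cv <- composite(list(fr), list(m), matrix(c(0, 0), 1, 2))
  inside <- which(m, arr.ind = TRUE)
  for (ch in 1:3)
    expect_equal(cv$mosaic[, , ch][inside], fr[, , ch][inside],
                 tolerance = 1e-12)
  expect_equal(cv$alpha > 0, m)
})

test_that("the worked two-pixel example blends to the weighted mean", {
  # weights 1 and 3, intensities 0.10 and 0.50 -> (1*0.10 + 3*0.50)/4 = 0.40
  f1 <- array(0.10, c(1, 1, 3)); f2 <- array(0.50, c(1, 1, 3))
  m <- matrix(1, 1, 1)
  cv <- composite(list(f1, f2), list(m, m), matrix(0, 2, 2),
                  weights = list(matrix(1, 1, 1), matrix(3, 1, 1)))
  expect_equal(as.vector(cv$mosaic[1, 1, ]), rep(0.40, 3),
               tolerance = 1e-12)
})

test_that("equal-valued overlaps blend to that value and weights normalize to one", {
  sq <- tiny_clean()
  fr <- sq$frames[[1]]; m <- sq$true_masks[[1]]
  # identical frames at identical positions: weighted mean of equal values
  cv <- composite(list(fr, fr, fr), list(m, m, m), matrix(0, 3, 2))
  inside <- which(m, arr.ind = TRUE)
  expect_equal(cv$mosaic[, , 2][inside], fr[, , 2][inside],
               tolerance = 1e-12)
  # constant-one frames expose the normalization: mosaic must be exactly 1
  ones <- array(1, dim(fr))
  masks <- sq$true_masks[1:3]
  pos <- cbind(c(0, 10, 20), c(0, 0, 0))
  cv1 <- composite(list(ones, ones, ones), masks, pos)
  expect_lt(max(abs(cv1$mosaic[, , 1][cv1$alpha > 0] - 1)), 1e-9)
})

test_that("fractional positions are placed by bilinear interpolation", {
  fr <- array(0.6, c(4, 4, 3))
  m <- matrix(1, 4, 4)
  cv <- composite(list(fr), list(m), matrix(c(0.5, 0), 1, 2))
  # constant image shifted by half a pixel stays constant in the interior
  expect_equal(cv$mosaic[2, 3, 1], 0.6, tolerance = 1e-12)
  expect_equal(dim(cv$alpha), c(4, 5))
})

test_that("frames without positions are skipped with a warning", {
  fr <- array(0.5, c(4, 4, 3)); m <- matrix(1, 4, 4)
  expect_warning(
    cv <- composite(list(fr, fr), list(m, m),
                    matrix(c(0, NA, 0, NA), 2, 2)),
    "without a solved position")
  expect_equal(dim(cv$alpha), c(4, 4))
})

test_that("identical inputs make all compositors agree", {
  sq <- tiny_clean()
  fr <- sq$frames[[1]]; m <- sq$true_masks[[1]]
  cc <- compare_compositors(list(fr, fr), list(m, m), matrix(0, 2, 2))
  for (nm in c("overwrite", "mean", "median"))
    expect_equal(cc$mosaics[[nm]][cc$seam], cc$mosaics$feather[cc$seam],
                 tolerance = 1e-9)
})

test_that("feathering demotes a wrongly segmented glare speck", {
  # two frames; frame 2 has an isolated 1-px mask patch holding a bright
  # outlier. Feathering gives it weight 1 against the deep interior of
  # frame 1, overwrite lets it win outright.
  f1 <- array(0.4, c(9, 9, 3))
  f2 <- array(0.4, c(9, 9, 3)); f2[5, 5, ] <- 1
  m1 <- matrix(TRUE, 9, 9)
  m2 <- matrix(FALSE, 9, 9); m2[5, 5] <- TRUE
  cv <- composite(list(f1, f2), list(m1, m2), matrix(0, 2, 2))
  feather_val <- cv$mosaic[5, 5, 1]
  cc <- compare_compositors(list(f1, f2), list(m1, m2), matrix(0, 2, 2))
  over_val <- cc$mosaics$overwrite[5, 5, 1]
  consensus <- 0.4
  expect_lt(abs(feather_val - consensus), abs(over_val - consensus))
})

test_that("mosaics write as RGBA PNG with coverage in the alpha channel", {
  sq <- tiny_clean()
  cv <- composite(sq$frames[1:2], sq$true_masks[1:2],
                  cbind(c(0, 14), c(0, 0)))
  path <- withr::local_tempfile(fileext = ".png")
  write_mosaic(cv, path)
  img <- png::readPNG(path)
  expect_equal(dim(img)[3], 4)
  expect_equal(img[, , 4] > 0, cv$alpha > 0)
})
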