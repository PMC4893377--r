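test_that("fundus generation is deterministic and artifact-free without noise", {
  spec <- tiny_spec(seed = 3)
  f1 <- make_fundus(spec)
  f2 <- make_fundus(spec)
  expect_identical(f1, f2)
  # no saturated pixels in the latent retina itself
  expect_lt(max(f1), 1)
  expect_gte(min(f1), 0)
})

test_that("vessels are darker than the locally smoothed background", {
  f <- make_fundus(tiny_spec(seed = 7))
  vmap <- attr(f, "vessel_map")
  lum <- 0.299 * f[, , 1] + 0.587 * f[, , 2] + 0.114 * f[, , 3]
  bg <- as.matrix(EBImage::medianFilter(lum, size = 5))
  core <- which(vmap > 0.6)   # vessel centrelines after anti-alias smoothing
  expect_gt(length(core), 50)
  frac_darker <- mean(lum[core] < bg[core])
  expect_gt(frac_darker, 0.9)
})

test_that("rendering returns frames, masks and trajectory together", {
  sq <- tiny_sweep()
  expect_length(sq$frames, 8)
  expect_length(sq$true_masks, 8)
  expect_equal(nrow(sq$trajectory), 8)
  one <- render_sequence(tiny_spec(), matrix(c(60, 100), 1, 2))
  expect_length(one$frames, 1)
  expect_length(one$true_masks, 1)
})

test_that("slit profile peaks at the centre and decays at the borders", {
  sq <- tiny_clean()
  p <- sq$profile
  mid <- p[nrow(p) %/% 2, ]
  expect_equal(max(p), 1)
  expect_lt(mid[1], 0.01)                  # near zero at frame border
  expect_lt(mid[length(mid)], 0.01)
  expect_gt(mid[length(mid) %/% 2], 0.9)   # maximal near slit centre
})

test_that("without noise and glare, pixels outside the true mask sit below the visibility floor", {
  sq <- tiny_clean()
  fr <- sq$frames[[1]]; m <- sq$true_masks[[1]]
  outside_max <- max(fr[array(rep(!m, 3), dim(fr))])
  expect_lt(outside_max, 0.2)
})

test_that("identical offsets render identical frames when noise and glare are off", {
  sp <- tiny_spec(seed = 5); sp$noise_sigma <- 0; sp$glare_count <- 0L
  sq <- render_sequence(sp, matrix(c(60, 60, 100, 100), 2, 2))
  expect_identical(sq$frames[[1]], sq$frames[[2]])
  expect_identical(sq$true_masks[[1]], sq$true_masks[[2]])
})

test_that("out-of-bounds trajectory offsets name the offending frame", {
  expect_error(render_sequence(tiny_spec(), matrix(c(0, 9999, 0, 0), 2, 2)),
               "frame 2")
})

test_that("invalid scene specifications are rejected", {
  expect_error(scene_spec(noise_sigma = -1), "noise_sigma")
  expect_error(scene_spec(slit_width = 10000), "slit")
  expect_error(scene_spec(frame_size = c(5000, 5000)), "fundus")
})

test_that("the slit is narrow: foreground covers less than half the frame", {
  for (sq in list(tiny_sweep(), default_loop()))
    for (m in sq$true_masks) expect_lt(mean(m), 0.5)
})

test_that("consecutive frames keep at least 25% mask overlap in global coordinates", {
  sq <- tiny_sweep()
  tr <- sq$trajectory
  for (i in seq_len(length(sq$frames) - 1)) {
    dx <- round(tr[i + 1, 1] - tr[i, 1]); dy <- round(tr[i + 1, 2] - tr[i, 2])
    m1 <- sq$true_masks[[i]]; m2 <- sq$true_masks[[i + 1]]
    H <- nrow(m1); W <- ncol(m1)
    # overlap window of frame i with frame i+1 shifted by (dx, dy)
    xs1 <- max(1, 1 + dx):min(W, W + dx)
    ys1 <- max(1, 1 + dy):min(H, H + dy)
    ov <- sum(m1[ys1, xs1] & m2[ys1 - dy, xs1 - dx])
    expect_gte(ov / sum(m1), 0.25)
  }
})

test_that("sequences round-trip through the on-disk format", {
  sq <- tiny_clean()
  dir <- withr::local_tempdir()
  write_sequence(sq, dir)
  expect_true(file.exists(file.path(dir, "frame_0001.png")))
  frames <- read_frames(dir)
  expect_length(frames, 4)
  expect_lt(max(abs(frames[[1]] - sq$frames[[1]])), 1 / 254)
  tr <- read.csv(file.path(dir, "trajectory.csv"))
  expect_equal(names(tr), c("frame", "x", "y"))
  expect_equal(as.numeric(tr$x), as.numeric(sq$trajectory[, 1]))
})

test_that("trajectory presets cover sweep, loop and static scenarios", {
  sw <- make_trajectory("sweep", 5, 10, origin = c(0, 0))
  expect_equal(sw[, 1], c(0, 10, 20, 30, 40), ignore_attr = TRUE)
  lp <- make_trajectory("loop", 40, 20)
  expect_equal(lp[1, ], lp[40, ], ignore_attr = TRUE)   # returns to start
  steps <- sqrt(rowSums(diff(unclass(lp))^2))
  expect_true(all(steps <= 80))                          # < slit width
  st <- make_trajectory("static", 3)
  expect_true(all(diff(unclass(st)) == 0))
})
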