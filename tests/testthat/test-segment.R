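test_that("the thresholding baseline implements r - 0.7g > 0 strictly", {
  px <- function(r, g, b = 0.5) array(c(r, g, b), c(1, 1, 3))
  expect_true(richa_baseline_mask(px(1, 0))$binary[1, 1])
  expect_false(richa_baseline_mask(px(0, 1))$binary[1, 1])
  # boundary case 0.70 - 0.7 * 1.00 = 0 fails the strict inequality
  expect_false(richa_baseline_mask(px(0.70, 1.00))$binary[1, 1])
})

test_that("feature scenarios produce exactly 9, 11 and 21 aligned planes", {
  fr <- tiny_sweep()$frames[[1]]
  fa <- extract_features(fr, "A")
  fb <- extract_features(fr, "B")
  fc <- extract_features(fr, "C")
  expect_equal(dim(fa$planes)[3], 9)
  expect_equal(dim(fb$planes)[3], 11)
  expect_equal(dim(fc$planes)[3], 21)
  expect_equal(dim(fa$planes)[1:2], dim(fr)[1:2] %/% 4)
  expect_error(extract_features(fr, "D"), "scenario")
})

test_that("the Gabor bank holds 12 zero-mean kernels (3 scales x 4 directions)", {
  bank <- gabor_bank()
  expect_length(bank, 12)
  for (k in bank) {
    expect_lt(abs(mean(k)), 1e-12)
    expect_equal(sum(abs(k)), 1)
  }
})

test_that("coordinate planes are normalized to [0,1] across the frame", {
  fr <- tiny_sweep()$frames[[1]]
  fb <- extract_features(fr, "B")
  xp <- fb$planes[, , match("x", fb$names)]
  yp <- fb$planes[, , match("y", fb$names)]
  expect_equal(unique(xp[, 1]), 0)
  expect_equal(unique(xp[, ncol(xp)]), 1)
  expect_true(all(apply(xp, 2, function(col) length(unique(col)) == 1)))
  expect_equal(unique(yp[1, ]), 0)
  expect_equal(unique(yp[nrow(yp), ]), 1)
})

test_that("all feature planes lie in [0,1]", {
  fr <- tiny_sweep()$frames[[2]]
  for (sc in c("A", "B", "C")) {
    p <- extract_features(fr, sc)$planes
    expect_gte(min(p), 0)
    expect_lte(max(p), 1)
  }
})

make_separable_frames <- function(n = 2, seed = 4) {
  set.seed(seed)
  frames <- list(); masks <- list()
  for (k in seq_len(n)) {
    r <- matrix(0.1 + 0.02 * runif(32 * 32), 32, 32)
    m <- matrix(FALSE, 32, 32)
    m[, 9:24] <- TRUE
    r[m] <- 0.9 + 0.02 * runif(sum(m))
    fr <- array(0.3, c(32, 32, 3)); fr[, , 1] <- r
    frames[[k]] <- fr; masks[[k]] <- m
  }
  list(frames = frames, masks = masks)
}

test_that("training on red-separable data reaches perfect training AUC", {
  d <- make_separable_frames()
  clf <- train_classifier(d$frames, d$masks, "A",
                          boost_config(rounds = 30, seed = 9))
  v <- predict_votes(clf, d$frames[[1]])
  lab <- downscale_mean(d$masks[[1]] * 1, 4) > 0.5
  expect_equal(roc_auc(as.vector(v), as.vector(lab))$auc, 1.0)
  expect_gte(min(v), 0)
  expect_lte(max(v), 1)
})

test_that("single-class annotations are rejected", {
  d <- make_separable_frames()
  empty <- lapply(d$masks, function(m) m & FALSE)
  expect_error(train_classifier(d$frames, empty, "A"), "class")
})

test_that("training and prediction are deterministic under a fixed seed", {
  d <- make_separable_frames()
  cfg <- boost_config(rounds = 20, seed = 31)
  v1 <- predict_votes(train_classifier(d$frames, d$masks, "B", cfg),
                      d$frames[[2]])
  v2 <- predict_votes(train_classifier(d$frames, d$masks, "B", cfg),
                      d$frames[[2]])
  expect_identical(v1, v2)
})

test_that("the vote-to-mask chain thresholds, smooths and upscales as documented", {
  # constant vote planes pass through regardless of threshold
  all1 <- votes_to_binary(matrix(1, 8, 8), threshold = 0.9,
                          smoothing_scale = 2, downscale = 4)
  expect_true(all(all1$binary))
  expect_equal(dim(all1$binary), c(32, 32))
  all0 <- votes_to_binary(matrix(0, 8, 8), threshold = 0.1)
  expect_false(any(all0$binary))
  # a single-pixel vote spike amid zeros is suppressed by the smoothing:
  # its smoothed peak 1/(2*pi*sigma^2) < 0.5 for sigma >= 1
  spike <- matrix(0, 15, 15); spike[8, 8] <- 1
  sm <- votes_to_binary(spike, threshold = 0.5, smoothing_scale = 1)
  expect_false(any(sm$binary))
  # without smoothing the same spike survives (idempotent re-threshold)
  raw <- votes_to_binary(spike, threshold = 0.5, smoothing_scale = 0)
  expect_equal(sum(raw$binary), 16)        # one low-res pixel x 4x4
  again <- votes_to_binary(raw$votes, threshold = 0.5, smoothing_scale = 0)
  expect_identical(raw$binary, again$binary)
  expect_error(votes_to_binary(spike, threshold = 1.5), "threshold")
})

test_that("a classifier survives serialization to disk", {
  d <- make_separable_frames()
  clf <- train_classifier(d$frames, d$masks, "A",
                          boost_config(rounds = 15, seed = 2))
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(clf, path)
  clf2 <- load_classifier(path)
  expect_identical(predict_votes(clf, d$frames[[1]]),
                   predict_votes(clf2, d$frames[[1]]))
})

test_that("the learned segmenter matches the simulator ground truth closely", {
  sq <- tiny_sweep()
  clf <- train_classifier(sq$frames, sq$true_masks, "B",
                          boost_config(seed = 7))
  agree <- mean(predict_mask(clf, sq$frames[[1]])$binary ==
                  sq$true_masks[[1]])
  expect_gt(agree, 0.95)
})
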