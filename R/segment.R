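#' Gradient-boosting configuration for pixel classification
#'
#' Hyperparameters of the boosted-trees pixel classifier: 200 boosting
#' rounds, shrinkage (learning rate) 0.1, row subsampling 0.5, maximal tree
#' depth 3, squared loss, and a downscale factor of 4 applied to all images
#' before feature extraction (noise suppression and a 16x reduction in
#' pixel count).
#'
#' @param rounds boosting iterations.
#' @param shrinkage learning rate.
#' @param subsample row subsampling fraction per round.
#' @param max_depth maximal tree depth.
#' @param downscale_factor integer image downscaling factor.
#' @param seed RNG seed for the subsampling.
#' @return object of class `boost_config`.
#' @export
boost_config <- function(rounds = 200L, shrinkage = 0.1, subsample = 0.5,
                         max_depth = 3L, downscale_factor = 4L, seed = 1L) {
  cfg <- list(rounds = as.integer(rounds), shrinkage = shrinkage,
              subsample = subsample, max_depth = as.integer(max_depth),
              loss = "squared", downscale_factor = as.integer(downscale_factor),
              seed = as.integer(seed))
  stopifnot(cfg$rounds > 0, cfg$shrinkage > 0, cfg$subsample > 0,
            cfg$max_depth > 0, cfg$downscale_factor > 0)
  class(cfg) <- "boost_config"
  cfg
}

#' Foreground-by-thresholding baseline mask
#'
#' The colour-threshold slit segmentation used by earlier slit-lamp
#' mosaicking work: a pixel is foreground iff `r - 0.7 * g > 0`, evaluated
#' per pixel at full resolution on the red and green channels. Votes equal
#' the binary decision.
#'
#' @param frame RGB array `[H, W, 3]` in [0, 1].
#' @return object of class `foreground_mask` with elements `votes`
#'   (numeric matrix), `binary` (logical matrix, full resolution) and
#'   `downscale` (1).
#' @export
#' @examples
#' f <- array(c(1, 0, 0, 1, 0, 0), c(1, 2, 3))
#' richa_baseline_mask(f)$binary
richa_baseline_mask <- function(frame) {
  assert_rgb(frame, "frame")
  d <- dim(frame)
  r <- matrix(frame[, , 1], d[1], d[2])
  g <- matrix(frame[, , 2], d[1], d[2])
  bin <- (r - 0.7 * g) > 0
  foreground_mask(votes = bin * 1, binary = bin, downscale = 1L)
}

foreground_mask <- function(votes, binary, downscale) {
  structure(list(votes = votes, binary = binary,
                 downscale = as.integer(downscale)),
            class = "foreground_mask")
}

# One real-valued Gabor kernel; zero-mean and L1-normalised so responses on
# [0,1] images stay within roughly [-1, 1].
gabor_kernel <- function(wavelength, theta_deg, sigma = 0.56 * wavelength,
                         gamma = 0.5, psi = 0) {
  n <- 2L * as.integer(ceiling(2.5 * sigma)) + 1L
  half <- (n - 1L) / 2
  xs <- matrix(-half:half, n, n, byrow = TRUE)
  ys <- matrix(-half:half, n, n)
  th <- theta_deg * pi / 180
  xp <- xs * cos(th) + ys * sin(th)
  yp <- -xs * sin(th) + ys * cos(th)
  k <- exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) *
    cos(2 * pi * xp / wavelength + psi)
  k <- k - mean(k)
  k / sum(abs(k))
}

#' Gabor filter bank
#'
#' Twelve real Gabor kernels: 3 scales (octave-spaced wavelengths, default
#' 4, 8, 16 px on the downscaled grid) times 4 orientations (0, 45, 90,
#' 135 degrees).
#'
#' @param wavelengths numeric vector of 3 wavelengths, pixels.
#' @param orientations numeric vector of 4 orientations, degrees.
#' @return named list of kernels, length `length(wavelengths) *
#'   length(orientations)`.
#' @export
gabor_bank <- function(wavelengths = c(4, 8, 16),
                       orientations = c(0, 45, 90, 135)) {
  bank <- list()
  for (wl in wavelengths)
    for (th in orientations)
      bank[[sprintf("gabor_w%g_t%g", wl, th)]] <- gabor_kernel(wl, th)
  bank
}

#' Per-pixel feature stack for slit segmentation
#'
#' Downscales the frame by the configured factor, then computes aligned
#' per-pixel feature planes, all rescaled to [0, 1]:
#' \describe{
#'   \item{Scenario A}{RGB, Lab, HSV — 9 planes.}
#'   \item{Scenario B}{A plus normalized x and y coordinates — 11 planes.
#'     The slit sits near the frame centre, so position is informative.}
#'   \item{Scenario C}{A plus 12 Gabor responses (3 scales x 4
#'     orientations) on the value plane — 21 planes.}
#' }
#' Colour conversions use the standard sRGB to HSV and sRGB to CIELAB (D65)
#' definitions; L is divided by 100 and a, b mapped from [-128, 127].
#'
#' @param frame RGB array `[H, W, 3]` in [0, 1].
#' @param scenario one of "A", "B", "C".
#' @param downscale integer downscale factor (default 4).
#' @return object of class `feature_stack`: list with `planes` (array
#'   `[h, w, k]`), `names`, `scenario`, `downscale`, `orig_dim`.
#' @export
extract_features <- function(frame, scenario = c("B", "A", "C"),
                             downscale = 4L) {
  assert_rgb(frame, "frame")
  scenario <- as.character(scenario[1])
  if (!scenario %in% c("A", "B", "C"))
    stop("unknown feature scenario '", scenario, "' (use A, B or C)",
         call. = FALSE)
  r <- downscale_mean(frame[, , 1], downscale)
  g <- downscale_mean(frame[, , 2], downscale)
  b <- downscale_mean(frame[, , 3], downscale)
  h <- nrow(r); w <- ncol(r)
  rgbm <- rbind(as.vector(r), as.vector(g), as.vector(b))
  hsv <- rgb2hsv(rgbm, maxColorValue = 1)
  lab <- convertColor(t(rgbm), from = "sRGB", to = "Lab")
  planes <- list(R = r, G = g, B = b,
                 L = matrix(clamp(lab[, 1] / 100), h, w),
                 a = matrix(clamp((lab[, 2] + 128) / 255), h, w),
                 b_op = matrix(clamp((lab[, 3] + 128) / 255), h, w),
                 H = matrix(hsv[1, ], h, w),
                 S = matrix(hsv[2, ], h, w),
                 V = matrix(hsv[3, ], h, w))
  if (scenario == "B") {
    planes$x <- matrix(if (w > 1) (seq_len(w) - 1) / (w - 1) else 0,
                       h, w, byrow = TRUE)
    planes$y <- matrix(if (h > 1) (seq_len(h) - 1) / (h - 1) else 0, h, w)
  }
  if (scenario == "C") {
    v <- planes$V
    for (nm in names(bank <- gabor_bank())) {
      resp <- conv_replicate(v, bank[[nm]])
      planes[[nm]] <- clamp((resp + 1) / 2)
    }
  }
  structure(list(planes = array(unlist(planes), c(h, w, length(planes))),
                 names = names(planes), scenario = scenario,
                 downscale = as.integer(downscale),
                 orig_dim = dim(frame)[1:2]),
            class = "feature_stack")
}

# Flatten a feature stack to a pixels x planes design matrix.
feature_matrix <- function(fs) {
  k <- dim(fs$planes)[3]
  m <- matrix(fs$planes, ncol = k)
  colnames(m) <- fs$names
  m
}

#' Train the boosted-trees pixel classifier
#'
#' Fits a gradient-boosted regression (squared loss) on the per-pixel
#' feature vectors of all annotated frames; the target is the binary
#' foreground label of the downscaled annotation mask. All downscaled
#' pixels of every annotated frame are used (boosting's own 0.5 row
#' subsample is the only subsampling). Deterministic under
#' `config$seed`.
#'
#' @param frames list of RGB arrays.
#' @param masks list of full-resolution binary annotation masks (logical or
#'   0/1), one per frame.
#' @param scenario feature scenario "A", "B" or "C".
#' @param config a [boost_config()].
#' @return object of class `slit_classifier`.
#' @export
train_classifier <- function(frames, masks, scenario = "B",
                             config = boost_config()) {
  if (length(frames) < 2 || length(frames) != length(masks))
    stop("need >= 2 annotated frames with one mask per frame",
         call. = FALSE)
  Xs <- vector("list", length(frames))
  ys <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fs <- extract_features(frames[[i]], scenario, config$downscale_factor)
    Xs[[i]] <- feature_matrix(fs)
    ys[[i]] <- as.numeric(downscale_mean(masks[[i]] * 1,
                                         config$downscale_factor) > 0.5)
  }
  X <- do.call(rbind, Xs)
  y <- unlist(ys)
  if (length(unique(y)) < 2)
    stop("training data contains a single class; both foreground and ",
         "background pixels are required", call. = FALSE)
  dm <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  booster <- with_seed(config$seed, xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = config$shrinkage,
                  subsample = config$subsample, max_depth = config$max_depth,
                  nthread = 1, seed = config$seed),
    data = dm, nrounds = config$rounds, verbose = 0))
  structure(list(booster = booster, scenario = scenario, config = config,
                 feature_names = colnames(X)),
            class = "slit_classifier")
}

#' Per-pixel foreground votes for one frame
#'
#' @param classifier a [train_classifier()] result.
#' @param frame RGB array.
#' @return numeric matrix of votes in [0, 1] at the downscaled resolution.
#' @export
predict_votes <- function(classifier, frame) {
  if (!inherits(classifier, "slit_classifier"))
    stop("classifier must be a trained slit_classifier", call. = FALSE)
  fs <- extract_features(frame, classifier$scenario,
                         classifier$config$downscale_factor)
  v <- predict(classifier$booster, feature_matrix(fs))
  matrix(clamp(v), dim(fs$planes)[1], dim(fs$planes)[2])
}

#' Predict the foreground mask of a frame
#'
#' Votes are computed at the downscaled resolution, smoothed with a
#' Gaussian kernel, thresholded, and the binary result upscaled back to
#' full resolution with nearest-neighbour interpolation (smoothing happens
#' before upscaling, so narrow glare borders survive thresholding).
#'
#' @param classifier a [train_classifier()] result.
#' @param frame RGB array.
#' @param threshold vote threshold in (0, 1); default 0.5.
#' @param smoothing_scale Gaussian sigma in downscaled pixels; default 2.
#' @return a `foreground_mask` (votes at 1/downscale resolution, binary at
#'   full resolution).
#' @export
predict_mask <- function(classifier, frame, threshold = 0.5,
                         smoothing_scale = 2) {
  votes <- predict_votes(classifier, frame)
  votes_to_binary(votes, threshold, smoothing_scale,
                  classifier$config$downscale_factor, dim(frame)[1:2])
}

#' Turn a vote plane into a full-resolution binary mask
#'
#' The documented chain: Gaussian-smooth the (downscaled) votes, threshold,
#' and upscale the binary result to full resolution with nearest-neighbour
#' interpolation. Isolated single-pixel vote spikes are suppressed by the
#' smoothing; re-applying the chain to an already binary result is
#' idempotent when `smoothing_scale = 0`.
#'
#' @param votes numeric matrix in [0, 1] at downscaled resolution.
#' @param threshold vote threshold in (0, 1).
#' @param smoothing_scale Gaussian sigma in downscaled pixels (0 disables).
#' @param downscale integer upscale factor.
#' @param out_dim c(H, W) of the full-resolution mask.
#' @return a `foreground_mask`.
#' @export
votes_to_binary <- function(votes, threshold = 0.5, smoothing_scale = 2,
                            downscale = 4L, out_dim = dim(votes) * downscale) {
  if (!(threshold > 0 && threshold < 1))
    stop("threshold must lie in (0, 1)", call. = FALSE)
  smoothed <- gblur0(votes, smoothing_scale)
  bin <- upscale_nn(smoothed >= threshold, downscale, out_dim)
  foreground_mask(votes = votes, binary = bin, downscale = downscale)
}

#' Serialize / restore a trained classifier
#'
#' The booster is stored in xgboost's UBJSON format together with the
#' scenario and configuration, in one RDS file.
#'
#' @param classifier a `slit_classifier`.
#' @param path file path.
#' @return `save_classifier`: invisibly, `path`; `load_classifier`: the
#'   restored classifier.
#' @export
save_classifier <- function(classifier, path) {
  raw <- xgboost::xgb.save.raw(classifier$booster)
  obj <- classifier
  obj$booster <- raw
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(path) {
  obj <- readRDS(path)
  obj$booster <- xgboost::xgb.load.raw(obj$booster)
  obj
}
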