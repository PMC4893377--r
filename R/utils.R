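#' @keywords internal
#' @importFrom stats rnorm runif pnorm median quantile approx
#' @importFrom utils read.csv write.csv
#' @importFrom grDevices rgb2hsv convertColor
"_PACKAGE"

# Clamp values into [lo, hi].
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so library calls never disturb
#' user-level random streams.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a top-level seed; keeps results < 2^31.
stage_seed <- function(seed, stage) {
  offsets <- c(simulate = 11L, train = 23L, ransac = 37L, folds = 53L,
               fundus = 71L, noise = 89L)
  s <- (as.double(seed) * 1009 + offsets[[stage]]) %% 2147483647
  as.integer(s)
}

# Check an image array: [H, W, 3] numeric in [0, 1].
assert_rgb <- function(img, what = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(what, " must be an RGB array with dim [height, width, 3]",
         call. = FALSE)
  if (any(dim(img)[1:2] < 1L)) stop(what, " has empty dimensions",
                                    call. = FALSE)
  invisible(img)
}

# Luminance plane (Rec. 601 weights) of an RGB array.
luminance <- function(img) {
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

# Bilinear upsampling of a matrix to H x W (used for low-frequency fields).
upsample_bilinear <- function(m, H, W) {
  ys <- seq(1, nrow(m), length.out = H)
  xs <- seq(1, ncol(m), length.out = W)
  y0 <- pmin(floor(ys), nrow(m) - 1L); y0[nrow(m) == 1] <- 1L
  x0 <- pmin(floor(xs), ncol(m) - 1L); x0[ncol(m) == 1] <- 1L
  ty <- ys - y0; tx <- xs - x0
  y1 <- pmin(y0 + 1L, nrow(m)); x1 <- pmin(x0 + 1L, ncol(m))
  outer(1 - ty, 1 - tx) * m[y0, x0, drop = FALSE] +
    outer(1 - ty, tx) * m[y0, x1, drop = FALSE] +
    outer(ty, 1 - tx) * m[y1, x0, drop = FALSE] +
    outer(ty, tx) * m[y1, x1, drop = FALSE]
}

# Block-mean downscaling of a matrix by an integer factor (crops the
# trailing remainder rows/columns first).
downscale_mean <- function(m, f) {
  f <- as.integer(f)
  if (f == 1L) return(m)
  H2 <- nrow(m) %/% f
  W2 <- ncol(m) %/% f
  if (H2 < 1L || W2 < 1L)
    stop("image too small for downscale factor ", f, call. = FALSE)
  a <- m[seq_len(H2 * f), seq_len(W2 * f), drop = FALSE]
  # column-major fold: (f, H2, f, W2) -> mean over dims 1 and 3
  dim(a) <- c(f, H2, f * W2)
  a <- colMeans(a)                      # (H2, f*W2)
  dim(a) <- c(H2, f, W2)
  a <- aperm(a, c(2, 1, 3))
  dim(a) <- c(f, H2 * W2)
  matrix(colMeans(a), H2, W2)
}

# Nearest-neighbour upscaling of a matrix by an integer factor, then
# replicate-padding to the requested full-resolution size.
upscale_nn <- function(m, f, out_dim) {
  up <- m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f),
          drop = FALSE]
  ri <- pmin(seq_len(out_dim[1]), nrow(up))
  ci <- pmin(seq_len(out_dim[2]), ncol(up))
  up[ri, ci, drop = FALSE]
}

# 2-D convolution with replicate-padded borders; tolerates kernels larger
# than the image (EBImage::filter2 alone does not).
conv_replicate <- function(m, kernel) {
  ky <- (nrow(kernel) - 1L) %/% 2L
  kx <- (ncol(kernel) - 1L) %/% 2L
  ri <- clamp(seq(1 - ky, nrow(m) + ky), 1, nrow(m))
  ci <- clamp(seq(1 - kx, ncol(m) + kx), 1, ncol(m))
  padded <- m[ri, ci, drop = FALSE]
  out <- EBImage::filter2(padded, kernel, boundary = "replicate")
  out[ky + seq_len(nrow(m)), kx + seq_len(ncol(m)), drop = FALSE]
}

# Gaussian blur that tolerates sigma = 0 and small images.
gblur0 <- function(m, sigma) {
  if (sigma <= 0) return(m)
  size <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  conv_replicate(m, EBImage::makeBrush(size, "Gaussian", sigma = sigma))
}
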