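# Foreground-aware feathering: each frame's pixels are weighted by their
# Euclidean distance to the nearest background pixel of that frame's
# foreground mask, so poorly lit slit borders and small mis-segmented
# patches contribute little, and the mosaic is the per-pixel weighted mean
# of all covering frames.

#' Feathering weights from a foreground mask
#'
#' Euclidean distance transform of the binary mask: the weight of a pixel
#' is its distance to the nearest background pixel, zero outside the mask
#' and increasing toward the mask interior. An all-foreground mask (no
#' background anywhere) is capped at the image diagonal.
#'
#' @param mask `foreground_mask` or binary matrix (full resolution).
#' @return numeric matrix of weights, same size as the mask.
#' @export
#' @examples
#' distance_weights(matrix(c(0, 1, 1, 1, 0), 1))
distance_weights <- function(mask) {
  m <- if (inherits(mask, "foreground_mask")) mask$binary else mask
  m <- (m > 0) * 1
  if (!any(m > 0)) return(matrix(0, nrow(m), ncol(m)))
  d <- as.matrix(EBImage::distmap(m, metric = "euclidean"))
  cap <- sqrt(nrow(m)^2 + ncol(m)^2)
  d[!is.finite(d)] <- cap
  d
}

# Shift an image (matrix or [H,W,C] array) by a fractional offset in
# (0,1)^2 with bilinear interpolation onto an (H+1)x(W+1) canvas whose
# origin is the original origin. Integer shifts bypass this entirely.
shift_bilinear <- function(img, fy, fx) {
  is_mat <- is.matrix(img)
  if (is_mat) dim(img) <- c(dim(img), 1L)
  H <- dim(img)[1]; W <- dim(img)[2]; C <- dim(img)[3]
  out <- array(0, c(H + 1L, W + 1L, C))
  w00 <- (1 - fy) * (1 - fx); w01 <- (1 - fy) * fx
  w10 <- fy * (1 - fx);       w11 <- fy * fx
  out[1:H, 1:W, ] <- out[1:H, 1:W, , drop = FALSE] + w00 * img
  out[1:H, 2:(W + 1), ] <- out[1:H, 2:(W + 1), , drop = FALSE] + w01 * img
  out[2:(H + 1), 1:W, ] <- out[2:(H + 1), 1:W, , drop = FALSE] + w10 * img
  out[2:(H + 1), 2:(W + 1), ] <-
    out[2:(H + 1), 2:(W + 1), , drop = FALSE] + w11 * img
  if (is_mat) out[, , 1] else out
}

#' Composite positioned frames into a mosaic
#'
#' Translates every frame by its solved global position onto a common
#' canvas (the bounding box of all placed frames) and accumulates
#' `weight x intensity` and `weight` planes. The final mosaic is the
#' normalized weighted mean, `accumulator / weight` wherever the total
#' weight is positive; never-covered pixels are flagged by a zero alpha
#' plane rather than painted black. Integer positions are placed exactly;
#' fractional positions use bilinear interpolation.
#'
#' @param frames list of RGB arrays.
#' @param masks list of `foreground_mask` objects or binary matrices.
#' @param positions `[n, 2]` matrix of (x, y) global positions (NA rows are
#'   skipped with a warning).
#' @param weights optional list of precomputed feathering weight matrices;
#'   defaults to [distance_weights()] of each mask.
#' @return object of class `mosaic_canvas`: list with `mosaic` (RGB array),
#'   `alpha` (0/1 matrix), `weight` (summed weights), `accumulator`,
#'   `origin` (c(x0, y0): canvas offset in global coordinates).
#' @export
composite <- function(frames, masks, positions, weights = NULL) {
  n <- length(frames)
  stopifnot(length(masks) == n, nrow(positions) == n)
  usable <- which(apply(is.finite(positions), 1, all))
  if (length(usable) < n)
    warning("skipping ", n - length(usable),
            " frame(s) without a solved position")
  if (!length(usable)) stop("no frame has a solved position", call. = FALSE)
  if (is.null(weights)) weights <- lapply(masks, distance_weights)
  fh <- nrow(frames[[1]]); fw <- ncol(frames[[1]])
  x0 <- floor(min(positions[usable, 1]))
  y0 <- floor(min(positions[usable, 2]))
  x1 <- ceiling(max(positions[usable, 1])) + fw
  y1 <- ceiling(max(positions[usable, 2])) + fh
  Hc <- as.integer(y1 - y0); Wc <- as.integer(x1 - x0)
  acc <- array(0, c(Hc, Wc, 3))
  wsum <- matrix(0, Hc, Wc)
  for (f in usable) {
    px <- positions[f, 1] - x0; py <- positions[f, 2] - y0
    ix <- floor(px); iy <- floor(py)
    fx <- px - ix; fy <- py - iy
    w <- weights[[f]]
    img <- frames[[f]] * as.vector(w)
    if (fx > 1e-9 || fy > 1e-9) {
      img <- shift_bilinear(img, fy, fx)
      w <- shift_bilinear(w, fy, fx)
      # the shifted canvas only extends along genuinely fractional axes
      keep_r <- seq_len(nrow(w) - (fy <= 1e-9))
      keep_c <- seq_len(ncol(w) - (fx <= 1e-9))
      img <- img[keep_r, keep_c, , drop = FALSE]
      w <- w[keep_r, keep_c, drop = FALSE]
    }
    hh <- nrow(w); ww <- ncol(w)
    ys <- iy + seq_len(hh); xs <- ix + seq_len(ww)
    acc[ys, xs, ] <- acc[ys, xs, , drop = FALSE] + img
    wsum[ys, xs] <- wsum[ys, xs] + w
  }
  mosaic <- array(0, c(Hc, Wc, 3))
  covered <- wsum > 0
  for (ch in 1:3) {
    plane <- acc[, , ch]
    plane[covered] <- plane[covered] / wsum[covered]
    mosaic[, , ch] <- plane
  }
  structure(list(mosaic = clamp(mosaic), alpha = covered * 1,
                 weight = wsum, accumulator = acc,
                 origin = c(x = x0, y = y0)),
            class = "mosaic_canvas")
}

# Place binary masks on the canvas grid (integer-rounded positions); used
# by the straw-man compositors and the seam metric.
placed_masks <- function(masks, positions, usable, origin, dims) {
  lapply(usable, function(f) {
    m <- if (inherits(masks[[f]], "foreground_mask")) masks[[f]]$binary
         else masks[[f]] > 0
    ix <- round(positions[f, 1] - origin[1])
    iy <- round(positions[f, 2] - origin[2])
    list(f = f, ys = iy + seq_len(nrow(m)), xs = ix + seq_len(ncol(m)),
         mask = m)
  })
}

#' Compare compositing strategies
#'
#' Builds the mosaic with four compositors — `overwrite` (later frames
#' replace earlier content inside their mask), `mean` (unweighted mean of
#' covering frames), `median` (per-pixel median, robust to intensity
#' outliers), and `feather` — and reports a seam metric for each: the mean
#' luminance gradient magnitude over frame-boundary pixels (mask borders
#' of the placed frames). Illumination falloff at slit borders makes
#' overwrite and mean seams visible; feathering suppresses them.
#'
#' @inheritParams composite
#' @return list with `metrics` (named numeric vector of seam scores) and
#'   `mosaics` (named list of RGB arrays).
#' @export
compare_compositors <- function(frames, masks, positions) {
  n <- length(frames)
  usable <- which(apply(is.finite(positions), 1, all))
  feather <- composite(frames, masks, positions)
  dims <- dim(feather$alpha)
  pl <- placed_masks(masks, positions, usable, feather$origin, dims)
  Hc <- dims[1]; Wc <- dims[2]

  over <- array(0, c(Hc, Wc, 3)); over_cov <- matrix(FALSE, Hc, Wc)
  sum_acc <- array(0, c(Hc, Wc, 3)); cnt <- matrix(0, Hc, Wc)
  stacks <- vector("list", length(pl))
  for (k in seq_along(pl)) {
    p <- pl[[k]]
    fr <- frames[[p$f]]
    msel <- p$mask
    for (ch in 1:3) {
      sub <- over[p$ys, p$xs, ch]
      sub[msel] <- fr[, , ch][msel]
      over[p$ys, p$xs, ch] <- sub
      sum_acc[p$ys, p$xs, ch] <- sum_acc[p$ys, p$xs, ch] +
        fr[, , ch] * msel
    }
    over_cov[p$ys, p$xs] <- over_cov[p$ys, p$xs] | msel
    cnt[p$ys, p$xs] <- cnt[p$ys, p$xs] + msel
  }
  mean_m <- array(0, c(Hc, Wc, 3))
  for (ch in 1:3) {
    plane <- sum_acc[, , ch]
    plane[cnt > 0] <- plane[cnt > 0] / cnt[cnt > 0]
    mean_m[, , ch] <- plane
  }
  # median: per-pixel median over covering frames, channel by channel
  med <- array(0, c(Hc, Wc, 3))
  for (ch in 1:3) {
    vals <- matrix(NA_real_, Hc * Wc, length(pl))
    for (k in seq_along(pl)) {
      p <- pl[[k]]
      plane <- matrix(NA_real_, Hc, Wc)
      sub <- frames[[p$f]][, , ch]
      sub[!p$mask] <- NA_real_
      plane[p$ys, p$xs] <- sub
      vals[, k] <- as.vector(plane)
    }
    has <- rowSums(!is.na(vals)) > 0
    medv <- rep(0, Hc * Wc)
    medv[has] <- apply(vals[has, , drop = FALSE], 1, median, na.rm = TRUE)
    med[, , ch] <- matrix(medv, Hc, Wc)
  }
  mosaics <- list(overwrite = over, mean = mean_m, median = med,
                  feather = feather$mosaic)

  # seam pixels: mask borders of placed frames, restricted to covered area
  seam <- matrix(FALSE, Hc, Wc)
  for (p in pl) {
    er <- p$mask & !(local_min3(p$mask * 1) > 0)   # border = mask minus erosion
    seam[p$ys, p$xs] <- seam[p$ys, p$xs] | er
  }
  seam <- seam & (feather$alpha > 0)
  metrics <- vapply(mosaics, function(mz) {
    lum <- luminance(mz)
    gx <- matrix(0, Hc, Wc); gy <- matrix(0, Hc, Wc)
    gx[, 2:(Wc - 1)] <- (lum[, 3:Wc] - lum[, 1:(Wc - 2)]) / 2
    gy[2:(Hc - 1), ] <- (lum[3:Hc, ] - lum[1:(Hc - 2), ]) / 2
    mean(sqrt(gx^2 + gy^2)[seam])
  }, numeric(1))
  list(metrics = metrics, mosaics = mosaics, seam = seam)
}

# 3x3 neighbourhood minimum (replicate edges); erosion for binary masks.
local_min3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- m[c(1, seq_len(H), H), c(1, seq_len(W), W)]
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- pmin(out, pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)])
  }
  out
}

#' Write the mosaic as an RGBA PNG
#'
#' The alpha channel encodes coverage (0 = never covered), so empty canvas
#' is transparent rather than black. The weight plane can be written
#' alongside as a float TIFF when the tiff package is available.
#'
#' @param canvas a [composite()] result.
#' @param path PNG output path.
#' @param weight_path optional TIFF path for the weight plane.
#' @return invisibly, `path`.
#' @export
write_mosaic <- function(canvas, path, weight_path = NULL) {
  rgba <- array(0, c(dim(canvas$alpha), 4))
  rgba[, , 1:3] <- canvas$mosaic
  rgba[, , 4] <- canvas$alpha
  png::writePNG(rgba, path)
  if (!is.null(weight_path)) {
    if (requireNamespace("tiff", quietly = TRUE)) {
      w <- canvas$weight
      tiff::writeTIFF(w / max(w, 1), weight_path, bits.per.sample = 32L)
    } else {
      warning("tiff package unavailable; weight plane not written")
    }
  }
  invisible(path)
}
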