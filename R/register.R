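# Pairwise translation registration: upright multi-scale blob features
# restricted to the segmented foreground, nearest-neighbour descriptor
# matching with a ratio test, and translation-only RANSAC.

# 3x3 neighbourhood maximum of a matrix via shifted pmax (replicate edges).
local_max3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- m[c(1, seq_len(H), H), c(1, seq_len(W), W)]
  out <- m
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    out <- pmax(out, pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)])
  }
  out
}

#' Detect upright blob keypoints inside the foreground
#'
#' Difference-of-Gaussians blob detection on the luminance plane, with
#' quadratic sub-pixel refinement and no orientation assignment (upright
#' features: inter-frame rotation is assumed negligible). The response
#' threshold defaults low so that a large number of interest points are
#' retained; only points whose (full-resolution) mask value is foreground
#' are kept.
#'
#' The luminance is first divided by its local mean (a wide Gaussian
#' blur), which flattens the slit's static illumination profile: without
#' this, blob responses anchored to the illumination pattern — which does
#' not move with the retina — contaminate matching with phantom
#' zero-displacement correspondences.
#'
#' @param frame RGB array `[H, W, 3]`.
#' @param mask `foreground_mask` or logical matrix at full resolution; NULL
#'   keeps all keypoints.
#' @param n_scales number of DoG levels (default 4).
#' @param sigma0 base Gaussian scale (default 1.6 px).
#' @param threshold minimal absolute DoG response (default 0.004, low).
#' @param max_points keep at most this many strongest points (default 400).
#' @param edge_ratio principal-curvature ratio above which a response is
#'   discarded as an edge rather than a blob (default 10); the slit's
#'   illumination borders otherwise flood the detector with poorly
#'   localized edge responses.
#' @param erode_px keypoints closer than this to the mask border are
#'   dropped (default 4 px), keeping features inside well-lit content.
#' @param illum_sigma scale (pixels) of the local-mean divisor used for
#'   illumination flattening; 0 disables it. The divisor must be tight
#'   enough to track the slit's border falloff (a few pixels), otherwise
#'   residual static illumination structure seeds phantom matches;
#'   retinal texture at finer scales survives the division.
#' @return data.frame with columns `x`, `y` (sub-pixel, full-resolution,
#'   1-based), `sigma`, `level`, `response`; the per-level blurred images
#'   are attached as attribute `pyramid` for descriptor extraction.
#' @export
detect_keypoints <- function(frame, mask = NULL, n_scales = 4L,
                             sigma0 = 1.6, threshold = 0.004,
                             max_points = 400L, edge_ratio = 10,
                             erode_px = 4, illum_sigma = 4) {
  assert_rgb(frame, "frame")
  gray <- luminance(frame)
  if (illum_sigma > 0)
    gray <- gray / (gblur0(gray, illum_sigma) + 0.02)
  binmask <- mask_binary(mask, dim(gray))
  if (!is.null(binmask) && erode_px > 0 && any(binmask))
    binmask <- distance_weights(binmask) > erode_px
  sigmas <- sigma0 * 2^((0:n_scales) / 2)
  blurred <- lapply(sigmas, function(s) gblur0(gray, s))
  kps <- list()
  for (k in seq_len(n_scales)) {
    D <- blurred[[k + 1]] - blurred[[k]]
    for (sgn in c(1, -1)) {
      S <- sgn * D
      is_max <- S >= local_max3(S) & S > threshold
      # keep away from the image border so descriptors fit
      is_max[c(1:8, nrow(S) - 0:7), ] <- FALSE
      is_max[, c(1:8, ncol(S) - 0:7)] <- FALSE
      if (!is.null(binmask)) is_max <- is_max & binmask
      idx <- which(is_max)
      if (!length(idx)) next
      yy <- (idx - 1) %% nrow(S) + 1
      xx <- (idx - 1) %/% nrow(S) + 1
      ii <- cbind(yy, xx)
      # edge suppression: reject responses whose principal-curvature
      # ratio marks them as edges (poor localization along the edge)
      dxx <- S[cbind(yy, xx + 1)] - 2 * S[ii] + S[cbind(yy, xx - 1)]
      dyy <- S[cbind(yy + 1, xx)] - 2 * S[ii] + S[cbind(yy - 1, xx)]
      dxy <- (S[cbind(yy + 1, xx + 1)] - S[cbind(yy + 1, xx - 1)] -
                S[cbind(yy - 1, xx + 1)] + S[cbind(yy - 1, xx - 1)]) / 4
      det_h <- dxx * dyy - dxy^2
      tr_h <- dxx + dyy
      blobby <- det_h > 0 &
        tr_h^2 / det_h < (edge_ratio + 1)^2 / edge_ratio
      if (!any(blobby)) next
      yy <- yy[blobby]; xx <- xx[blobby]
      ii <- cbind(yy, xx)
      # quadratic sub-pixel refinement along each axis
      dxp <- S[cbind(yy, xx + 1)]; dxm <- S[cbind(yy, xx - 1)]
      dyp <- S[cbind(yy + 1, xx)]; dym <- S[cbind(yy - 1, xx)]
      den_x <- dxp - 2 * S[ii] + dxm
      den_y <- dyp - 2 * S[ii] + dym
      off_x <- ifelse(abs(den_x) > 1e-12,
                      clamp(-0.5 * (dxp - dxm) / den_x, -0.5, 0.5), 0)
      off_y <- ifelse(abs(den_y) > 1e-12,
                      clamp(-0.5 * (dyp - dym) / den_y, -0.5, 0.5), 0)
      kps[[length(kps) + 1]] <- data.frame(
        x = xx + off_x, y = yy + off_y, sigma = sigmas[k], level = k,
        response = sgn * S[ii])
    }
  }
  if (!length(kps)) {
    out <- data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
                      level = integer(0), response = numeric(0))
  } else {
    out <- do.call(rbind, kps)
    out <- out[order(-abs(out$response)), , drop = FALSE]
    if (nrow(out) > max_points) out <- out[seq_len(max_points), ,
                                           drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "pyramid") <- blurred
  out
}

mask_binary <- function(mask, dims) {
  if (is.null(mask)) return(NULL)
  m <- if (inherits(mask, "foreground_mask")) mask$binary else mask
  if (!all(dim(m) == dims))
    stop("mask dimensions do not match the frame", call. = FALSE)
  m > 0
}

#' Upright gradient descriptors for detected keypoints
#'
#' For each keypoint, gradients of the Gaussian-blurred image at the
#' keypoint's scale are sampled on a 9 x 9 grid with spacing proportional
#' to the scale, Gaussian-weighted, and pooled into 3 x 3 cells of
#' (sum dx, sum |dx|, sum dy, sum |dy|) — a 36-dimensional upright
#' descriptor, L2-normalised. No orientation normalisation is applied.
#' The support is kept compact (about 17 px at the base scale) so that
#' descriptors of keypoints inside the slit do not reach into the static
#' illumination falloff outside it.
#'
#' @param keypoints result of [detect_keypoints()] (with its pyramid
#'   attribute).
#' @return numeric matrix `[n_keypoints, 36]`.
#' @export
describe_keypoints <- function(keypoints) {
  pyr <- attr(keypoints, "pyramid")
  if (is.null(pyr)) stop("keypoints carry no scale-space pyramid",
                         call. = FALSE)
  n <- nrow(keypoints)
  desc <- matrix(0, n, 36)
  if (n == 0) return(desc)
  grid <- -4:4
  cell_of <- (grid + 4) %/% 3 + 1        # 1..3 per axis
  for (lev in unique(keypoints$level)) {
    G <- pyr[[lev]]
    H <- nrow(G); W <- ncol(G)
    dx <- matrix(0, H, W); dy <- matrix(0, H, W)
    dx[, 2:(W - 1)] <- (G[, 3:W] - G[, 1:(W - 2)]) / 2
    dy[2:(H - 1), ] <- (G[3:H, ] - G[1:(H - 2), ]) / 2
    sel <- which(keypoints$level == lev)
    step <- max(1, round(keypoints$sigma[sel][1]))
    cx <- round(keypoints$x[sel]); cy <- round(keypoints$y[sel])
    for (gy in seq_along(grid)) for (gx in seq_along(grid)) {
      oy <- grid[gy] * step; ox <- grid[gx] * step
      w <- exp(-(ox^2 + oy^2) / (2 * (4 * step)^2))
      yy <- clamp(cy + oy, 1, H); xx <- clamp(cx + ox, 1, W)
      ii <- cbind(yy, xx)
      cell <- (cell_of[gy] - 1) * 3 + cell_of[gx]   # 1..9
      base <- (cell - 1) * 4
      gdx <- dx[ii]; gdy <- dy[ii]
      desc[sel, base + 1] <- desc[sel, base + 1] + w * gdx
      desc[sel, base + 2] <- desc[sel, base + 2] + w * abs(gdx)
      desc[sel, base + 3] <- desc[sel, base + 3] + w * gdy
      desc[sel, base + 4] <- desc[sel, base + 4] + w * abs(gdy)
    }
  }
  nrm <- sqrt(rowSums(desc^2))
  desc / pmax(nrm, 1e-12)
}

#' Match descriptors between two frames
#'
#' Nearest-neighbour matching on Euclidean descriptor distance with a
#' Lowe-style ratio test (best distance < ratio x second-best), applied in
#' both directions; the union of forward and reverse matches is returned
#' (duplicates removed). Matching is restricted to keypoints of the same
#' scale level: a pure translation preserves blob scale, so cross-scale
#' matches are necessarily spurious.
#'
#' @param kp1,kp2 keypoint data.frames from [detect_keypoints()].
#' @param d1,d2 descriptor matrices from [describe_keypoints()].
#' @param ratio ratio-test threshold (default 0.8).
#' @param mutual if TRUE keep only matches that are nearest neighbours in
#'   both directions (intersection instead of union).
#' @return data.frame `i1, i2, x1, y1, x2, y2, dist` (class `match_set`).
#' @export
match_descriptors <- function(kp1, d1, kp2, d2, ratio = 0.8,
                              mutual = FALSE) {
  empty <- data.frame(i1 = integer(0), i2 = integer(0), x1 = numeric(0),
                      y1 = numeric(0), x2 = numeric(0), y2 = numeric(0),
                      dist = numeric(0))
  class(empty) <- c("match_set", "data.frame")
  if (nrow(kp1) < 2 || nrow(kp2) < 2) return(empty)
  # unit descriptors: dist^2 = 2 - 2 * similarity; cross-scale pairs are
  # pushed out of range so they can never win the ratio test
  sim <- d1 %*% t(d2)
  sim <- sim - 10 * outer(kp1$level, kp2$level, "!=")
  fwd <- ratio_matches(sim, ratio)
  rev <- ratio_matches(t(sim), ratio)
  pairs <- if (mutual) {
    key_f <- paste(fwd[, 1], fwd[, 2]); key_r <- paste(rev[, 2], rev[, 1])
    fwd[key_f %in% key_r, , drop = FALSE]
  } else {
    p <- rbind(fwd, rev[, c(2, 1, 3), drop = FALSE])
    p[!duplicated(p[, 1:2, drop = FALSE]), , drop = FALSE]
  }
  if (!nrow(pairs)) return(empty)
  out <- data.frame(i1 = pairs[, 1], i2 = pairs[, 2],
                    x1 = kp1$x[pairs[, 1]], y1 = kp1$y[pairs[, 1]],
                    x2 = kp2$x[pairs[, 2]], y2 = kp2$y[pairs[, 2]],
                    dist = pairs[, 3])
  class(out) <- c("match_set", "data.frame")
  out
}

# Row-wise nearest neighbour with ratio test on a similarity matrix of
# unit descriptors; returns cbind(row, col, dist).
ratio_matches <- function(sim, ratio) {
  best <- max.col(sim, ties.method = "first")
  s1 <- sim[cbind(seq_len(nrow(sim)), best)]
  sim[cbind(seq_len(nrow(sim)), best)] <- -Inf
  s2 <- sim[cbind(seq_len(nrow(sim)), max.col(sim, ties.method = "first"))]
  dist1 <- sqrt(pmax(2 - 2 * s1, 0))
  dist2 <- sqrt(pmax(2 - 2 * s2, 0))
  keep <- which(dist1 < ratio * dist2)
  cbind(keep, best[keep], dist1[keep])
}

#' Estimate a pure translation from matches with RANSAC
#'
#' Each RANSAC hypothesis is the displacement of a single randomly drawn
#' match; inliers are matches whose displacement lies within `margin_px`
#' (Euclidean) of the hypothesis. The best hypothesis (most inliers; ties
#' broken toward the smaller refined residual) is refined as the mean
#' displacement over its inliers. The pair is accepted iff the inlier
#' count reaches `min_inliers` (default 6 correspondences).
#'
#' The returned delta is `(dx, dy)` such that `x_i - x_j = dx` for the
#' global frame positions, i.e. the displacement of content from frame i
#' to frame j equals the camera translation from j to i.
#'
#' @param matches a `match_set` (frame i keypoints in `x1, y1`, frame j in
#'   `x2, y2`).
#' @param i,j frame indices recorded on the edge.
#' @param iterations RANSAC iterations (default 100).
#' @param margin_px inlier error margin (default 3 px, Euclidean).
#' @param min_inliers acceptance floor (default 6).
#' @param seed RNG seed for hypothesis sampling.
#' @return object of class `pairwise_translation`: list `i, j, delta,
#'   inliers, accepted, residual`.
#' @export
estimate_translation <- function(matches, i = 1L, j = 2L,
                                 iterations = 100L, margin_px = 3,
                                 min_inliers = 6L, seed = 1L) {
  res <- list(i = i, j = j, delta = c(NA_real_, NA_real_), inliers = 0L,
              accepted = FALSE, residual = NA_real_)
  class(res) <- "pairwise_translation"
  n <- nrow(matches)
  if (n == 0) return(res)
  vx <- matches$x2 - matches$x1
  vy <- matches$y2 - matches$y1
  hyp <- with_seed(seed, sample.int(n, iterations, replace = TRUE))
  best <- NULL
  for (h in unique(hyp)) {
    d2 <- (vx - vx[h])^2 + (vy - vy[h])^2
    inl <- which(d2 <= margin_px^2)
    cand <- list(count = length(inl), inl = inl)
    if (is.null(best) || cand$count > best$count) {
      best <- cand
    } else if (cand$count == best$count) {
      # tie-break: smaller residual about the refined mean
      if (refined_rms(vx, vy, cand$inl) < refined_rms(vx, vy, best$inl))
        best <- cand
    }
  }
  dx <- mean(vx[best$inl]); dy <- mean(vy[best$inl])
  res$delta <- c(dx, dy)
  res$inliers <- best$count
  res$accepted <- best$count >= min_inliers
  res$residual <- refined_rms(vx, vy, best$inl)
  res
}

refined_rms <- function(vx, vy, inl) {
  sqrt(mean((vx[inl] - mean(vx[inl]))^2 + (vy[inl] - mean(vy[inl]))^2))
}

#' Enumerate frame pairs to attempt
#'
#' All unordered pairs (i, j), i < j, with `j - i <= window`. An infinite
#' window reproduces the all-pairs strategy, which allows both minute and
#' large motions (including loop closures) to enter the bundle adjustment.
#'
#' @param n_frames number of frames (>= 2).
#' @param window maximal index separation; `Inf` for all pairs.
#' @return integer matrix `[n_pairs, 2]`, columns `i`, `j` (1-based).
#' @export
propose_pairs <- function(n_frames, window = Inf) {
  if (n_frames < 2) stop("need at least 2 frames", call. = FALSE)
  if (!is.numeric(window) || window < 1)
    stop("window must be >= 1", call. = FALSE)
  p <- t(utils::combn(n_frames, 2L))
  p <- p[p[, 2] - p[, 1] <= window, , drop = FALSE]
  colnames(p) <- c("i", "j")
  p
}

#' Register all proposed frame pairs
#'
#' Detects and describes keypoints once per frame (restricted to each
#' frame's foreground mask), then runs matching and translation RANSAC for
#' every proposed pair. Accepted estimates are finally vetted
#' photometrically: the two frames' texture planes (illumination-flattened
#' luminance, band-passed to the 1-3 px texture scale so that every trace
#' of the static slit structure is gone), overlaid at the estimated
#' translation, must correlate over the shared foreground (normalized
#' cross-correlation at least `ncc_min` over at least `min_overlap_px`
#' pixels). This rejects coincidental RANSAC consensus between frames
#' that do not actually overlap, which becomes possible when the per-pair
#' match count is small.
#'
#' @param frames list of RGB arrays.
#' @param masks list of `foreground_mask` objects or logical matrices
#'   (NULL for unmasked detection).
#' @param pairs matrix from [propose_pairs()].
#' @param ratio ratio-test threshold.
#' @param iterations,margin_px,min_inliers RANSAC parameters.
#' @param ncc_min minimal normalized cross-correlation for an accepted
#'   edge to survive photometric vetting (0 disables vetting).
#' @param min_overlap_px minimal shared-foreground overlap for vetting.
#' @param illum_sigma illumination-flattening scale, shared with
#'   [detect_keypoints()].
#' @param seed RNG seed; each pair uses a seed derived from it.
#' @param ... passed to [detect_keypoints()].
#' @return data.frame of accepted, verified edges `i, j, dx, dy, inliers`;
#'   all attempted pairs (with `accepted` and `verified` flags) are
#'   attached as attribute `attempts`.
#' @export
register_pairs <- function(frames, masks = NULL, pairs = NULL, ratio = 0.8,
                           mutual = FALSE, iterations = 100L, margin_px = 3,
                           min_inliers = 6L, ncc_min = 0.5,
                           min_overlap_px = 100L, illum_sigma = 4,
                           seed = 1L, ...) {
  n <- length(frames)
  if (is.null(pairs)) pairs <- propose_pairs(n)
  kps <- vector("list", n)
  descs <- vector("list", n)
  binmasks <- vector("list", n)
  flats <- vector("list", n)
  for (f in seq_len(n)) {
    m <- if (is.null(masks)) NULL else masks[[f]]
    kps[[f]] <- detect_keypoints(frames[[f]], m, illum_sigma = illum_sigma,
                                 ...)
    descs[[f]] <- describe_keypoints(kps[[f]])
    binmasks[[f]] <- if (is.null(m))
      matrix(TRUE, nrow(frames[[f]]), ncol(frames[[f]]))
    else mask_binary(m, dim(frames[[f]])[1:2])
    lum <- luminance(frames[[f]])
    if (illum_sigma > 0) lum <- lum / (gblur0(lum, illum_sigma) + 0.02)
    # texture band: 1-3 px, free of static illumination structure
    flats[[f]] <- gblur0(lum, 1) - gblur0(lum, 3)
  }
  rows <- vector("list", nrow(pairs))
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    mt <- match_descriptors(kps[[i]], descs[[i]], kps[[j]], descs[[j]],
                            ratio = ratio, mutual = mutual)
    est <- estimate_translation(mt, i = i, j = j, iterations = iterations,
                                margin_px = margin_px,
                                min_inliers = min_inliers,
                                seed = stage_seed(seed, "ransac") + p)
    verified <- est$accepted
    if (est$accepted && ncc_min > 0) {
      cc <- overlap_ncc(flats[[i]], binmasks[[i]], flats[[j]],
                        binmasks[[j]], est$delta, min_overlap_px)
      verified <- is.finite(cc) && cc >= ncc_min
    }
    rows[[p]] <- data.frame(i = i, j = j,
                            dx = est$delta[1], dy = est$delta[2],
                            inliers = est$inliers,
                            accepted = est$accepted,
                            verified = verified)
  }
  attempts <- do.call(rbind, rows)
  edges <- attempts[attempts$verified & is.finite(attempts$dx),
                    c("i", "j", "dx", "dy", "inliers")]
  rownames(edges) <- NULL
  attr(edges, "attempts") <- attempts
  edges
}

# Spatially robust normalized cross-correlation of two texture planes
# overlaid at translation delta (x_i - x_j), over their shared foreground;
# NA when the overlap is below min_px. Content at p in frame i sits at
# p + delta in frame j. The overlap is split into tiles and the median
# per-tile correlation returned, so that one coincidentally similar patch
# (a vessel segment aligning with another vessel) cannot carry the score:
# genuine overlap correlates everywhere, coincidence does not.
overlap_ncc <- function(flat_i, mask_i, flat_j, mask_j, delta,
                        min_px = 100L) {
  dxi <- round(delta[1]); dyi <- round(delta[2])
  H <- nrow(flat_i); W <- ncol(flat_i)
  if (!is.finite(dxi) || !is.finite(dyi) ||
      abs(dxi) >= W || abs(dyi) >= H) return(NA_real_)
  xs <- max(1, 1 - dxi):min(W, W - dxi)
  ys <- max(1, 1 - dyi):min(H, H - dyi)
  ov <- mask_i[ys, xs] & mask_j[ys + dyi, xs + dxi]
  n_ov <- sum(ov)
  if (n_ov < min_px) return(NA_real_)
  a <- flat_i[ys, xs][ov]
  b <- flat_j[ys + dyi, xs + dxi][ov]
  idx <- which(ov, arr.ind = TRUE)
  # ~square tiles of >= 150 px each, at most 4 cuts per axis
  n_tiles <- max(1, min(16, n_ov %/% 150))
  per_axis <- max(1, floor(sqrt(n_tiles)))
  tile_of <- function(v, k) {
    if (k == 1) return(rep(1L, length(v)))
    as.integer(cut(rank(v, ties.method = "first"), k))
  }
  tiles <- paste(tile_of(idx[, 1], per_axis), tile_of(idx[, 2], per_axis))
  cors <- vapply(split(seq_along(a), tiles), function(s) {
    if (length(s) < 50 || stats::sd(a[s]) == 0 || stats::sd(b[s]) == 0)
      return(NA_real_)
    stats::cor(a[s], b[s])
  }, numeric(1))
  cors <- cors[is.finite(cors)]
  if (!length(cors)) return(NA_real_)
  stats::median(cors)
}

#' Read / write registration edges as CSV
#'
#' Columns `i, j, dx, dy, inliers` with 1-based frame indices.
#'
#' @param edges edge data.frame.
#' @param path CSV path.
#' @return `write_edges`: invisibly, `path`; `read_edges`: the data.frame.
#' @export
write_edges <- function(edges, path) {
  write.csv(edges[, c("i", "j", "dx", "dy", "inliers")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges
#' @export
read_edges <- function(path) read.csv(path)
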