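#' Synthetic slit-lamp scene specification
#'
#' Describes the virtual retina and the slit-lamp imaging conditions used by
#' the simulator: a large latent fundus image, a narrow bright vertical slit
#' whose illumination falls off smoothly toward its borders, additive glare
#' blobs that occlude content, and Gaussian sensor noise. Defaults emulate a
#' clinical slit-lamp video sensor at quarter scale (frames of 256 x 340
#' pixels standing in for 1024 x 1360), so a full pipeline run stays
#' desk-sized while keeping the slit geometry: the slit covers roughly a
#' quarter of the frame width and most of its height.
#'
#' @param fundus_size integer c(H, W) of the latent retina image.
#' @param frame_size integer c(H, W) of each rendered video frame.
#' @param slit_width nominal width of the illuminated slit, pixels.
#' @param slit_height nominal height of the illuminated slit, pixels.
#' @param illumination_falloff scale (pixels) of the smooth intensity decay
#'   at the slit borders; the horizontal profile is a boxcar of
#'   `slit_width` convolved with a Gaussian of this scale.
#' @param glare_count number of glare blobs added per frame.
#' @param glare_radius_range c(min, max) glare blob radius, pixels.
#' @param noise_sigma standard deviation of per-pixel Gaussian sensor noise
#'   on the [0, 1] intensity scale.
#' @param seed integer RNG seed; the same spec renders bit-identical output.
#' @return object of class `scene_spec`.
#' @export
#' @examples
#' spec <- scene_spec(seed = 7)
#' spec$slit_width
scene_spec <- function(fundus_size = c(768L, 768L),
                       frame_size = c(256L, 340L),
                       slit_width = 80,
                       slit_height = 232,
                       illumination_falloff = 10,
                       glare_count = 2L,
                       glare_radius_range = c(5, 12),
                       noise_sigma = 0.02,
                       seed = 1L) {
  spec <- list(fundus_size = as.integer(fundus_size),
               frame_size = as.integer(frame_size),
               slit_width = slit_width,
               slit_height = slit_height,
               illumination_falloff = illumination_falloff,
               glare_count = as.integer(glare_count),
               glare_radius_range = glare_radius_range,
               noise_sigma = noise_sigma,
               seed = as.integer(seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  if (any(spec$fundus_size < 8) || any(spec$frame_size < 8))
    stop("scene_spec: image sizes must be at least 8 px", call. = FALSE)
  if (any(spec$frame_size > spec$fundus_size))
    stop("scene_spec: frame must fit inside the fundus", call. = FALSE)
  if (spec$slit_width <= 0 || spec$slit_width > spec$frame_size[2] ||
      spec$slit_height <= 0 || spec$slit_height > spec$frame_size[1])
    stop("scene_spec: slit must fit inside the frame", call. = FALSE)
  if (spec$noise_sigma < 0)
    stop("scene_spec: noise_sigma must be >= 0", call. = FALSE)
  if (spec$illumination_falloff <= 0)
    stop("scene_spec: illumination_falloff must be > 0", call. = FALSE)
  if (length(spec$glare_radius_range) != 2 ||
      any(spec$glare_radius_range <= 0) ||
      diff(spec$glare_radius_range) < 0)
    stop("scene_spec: glare_radius_range must be increasing and positive",
         call. = FALSE)
  invisible(spec)
}

#' Generate the latent fundus image
#'
#' Renders the virtual retina the simulator films through the slit: a
#' low-frequency orange/red background, darker branching vessel-like
#' curves radiating from a bright optic-disc analogue, and fine speckle
#' texture (so that blob features exist everywhere, as they do on a real
#' fundus). Deterministic under `spec$seed`.
#'
#' @param spec a [scene_spec()].
#' @return RGB array `[H, W, 3]` in [0, 1); the rasterized vessel tree is
#'   attached as attribute `vessel_map` (useful as a drawing oracle).
#' @export
make_fundus <- function(spec) {
  validate_scene_spec(spec)
  H <- spec$fundus_size[1]; W <- spec$fundus_size[2]
  with_seed(stage_seed(spec$seed, "fundus"), {
    base <- c(0.72, 0.38, 0.16)          # orange/red fundus hue
    amp <- c(0.10, 0.07, 0.04)
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      coarse <- matrix(rnorm(24 * 24, base[ch], amp[ch]), 24, 24)
      img[, , ch] <- upsample_bilinear(coarse, H, W)
    }
    # fine speckle texture shared across channels (choroidal mottling)
    speckle <- gblur0(matrix(rnorm(H * W, 0, 1), H, W), 1.2)
    speckle <- 0.05 * speckle / max(stats::sd(speckle), 1e-8)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + speckle * c(1, 0.8, 0.5)[ch]

    # optic-disc analogue: bright disc, vessels radiate from it
    disc <- c(runif(1, 0.35, 0.65) * H, runif(1, 0.35, 0.65) * W)
    disc_r <- min(H, W) / 14
    yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W,
                                                 byrow = TRUE)
    d <- sqrt((yy - disc[1])^2 + (xx - disc[2])^2)
    halo <- clamp(1 - (d - disc_r) / (0.5 * disc_r), 0, 1)
    for (ch in 1:3) img[, , ch] <- img[, , ch] + halo * c(0.22, 0.20, 0.08)[ch]

    # vessels: smooth random walks stamped as dark tubes
    vmap <- matrix(0, H, W)
    n_vessels <- 9L
    for (v in seq_len(n_vessels)) {
      theta <- runif(1, 0, 2 * pi)
      pos <- disc + disc_r * 0.6 * c(sin(theta), cos(theta))
      width <- runif(1, 1.5, 3.5)
      n_steps <- as.integer(0.45 * max(H, W))
      for (s in seq_len(n_steps)) {
        theta <- theta + rnorm(1, 0, 0.09)
        pos <- pos + 2 * c(sin(theta), cos(theta))
        if (any(pos < 1) || pos[1] > H || pos[2] > W) break
        w <- max(1, width * (1 - 0.5 * s / n_steps))
        r <- ceiling(w)
        ys <- clamp(round(pos[1]) + (-r:r), 1, H)
        xs <- clamp(round(pos[2]) + (-r:r), 1, W)
        dd <- sqrt(outer((ys - pos[1])^2, (xs - pos[2])^2, "+"))
        vmap[ys, xs] <- pmax(vmap[ys, xs], clamp(1 - dd / w, 0, 1))
      }
    }
    vmap <- clamp(gblur0(vmap, 0.8), 0, 1)
    for (ch in 1:3)
      img[, , ch] <- img[, , ch] * (1 - c(0.55, 0.6, 0.45)[ch] * vmap)
    # keep a small headroom so an artifact-free fundus never saturates
    structure(clamp(img, 0, 0.98), vessel_map = vmap)
  })
}

# Separable slit illumination profile on the frame grid, normalized to a
# maximum of 1. Horizontal: boxcar(slit_width) * Gaussian(falloff), which
# has the closed form pnorm difference; vertical: same construction with a
# 4x softer falloff, so the slit spans most of the frame height with a
# gentle decay.
slit_profile <- function(spec) {
  H <- spec$frame_size[1]; W <- spec$frame_size[2]
  f <- spec$illumination_falloff
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  x <- seq_len(W); y <- seq_len(H)
  hx <- pnorm((x - cx + spec$slit_width / 2) / f) -
    pnorm((x - cx - spec$slit_width / 2) / f)
  vy <- pnorm((y - cy + spec$slit_height / 2) / (4 * f)) -
    pnorm((y - cy - spec$slit_height / 2) / (4 * f))
  p <- outer(vy, hx)
  p / max(p)
}

#' Ground-truth camera trajectories
#'
#' Returns a planted 2-D translation trajectory (global top-left offsets of
#' each frame on the fundus, 0-based pixels) for one of three presets:
#' `"sweep"`, a monotone horizontal scan; `"loop"`, a rectangular path that
#' returns to its starting position (the standard fixture for drift tests,
#' because sequential chaining accumulates error around the loop while
#' bundle adjustment does not); `"static"`, a non-moving sequence whose
#' mosaic should reduce to a noise-averaged single frame.
#'
#' @param preset one of "sweep", "loop", "static".
#' @param n_frames number of frames.
#' @param step integer step size in pixels between consecutive frames.
#' @param origin c(x, y) offset of the first frame on the fundus; defaults
#'   to a placement that keeps the whole path inside the default fundus.
#' @return object of class `trajectory`: a matrix `[n_frames, 2]` of (x, y)
#'   offsets with the preset stored as an attribute.
#' @export
make_trajectory <- function(preset = c("sweep", "loop", "static"),
                            n_frames = 40L, step = 20L,
                            origin = c(120, 200)) {
  preset <- match.arg(preset)
  n <- as.integer(n_frames)
  if (n < 1) stop("n_frames must be >= 1", call. = FALSE)
  step <- as.integer(step)
  pos <- switch(preset,
    static = matrix(0, n, 2),
    sweep = cbind(step * (seq_len(n) - 1), 0),
    loop = {
      # rectangle: right, down, left, up; returns to start
      per_side <- max(1L, n %/% 4L)
      dirs <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
      side <- pmin(((seq_len(n - 1) - 1) %/% per_side) + 1L, 4L)
      moves <- dirs[side, , drop = FALSE] * step
      # force closure: last moves cancel any residual
      p <- rbind(c(0, 0), apply(moves, 2, cumsum))
      resid <- p[n, ]
      if (any(resid != 0) && n > 2) {
        p[n, ] <- c(0, 0)
      }
      p
    })
  pos <- sweep(pos, 2, as.numeric(origin), "+")
  colnames(pos) <- c("x", "y")
  structure(pos, class = c("trajectory", class(pos)), preset = preset)
}

#' Render a synthetic slit-lamp sequence
#'
#' Crops the latent fundus at each trajectory offset, multiplies by the
#' static slit illumination profile, adds near-saturated glare blobs inside
#' the illuminated region and Gaussian sensor noise, and records the
#' ground-truth foreground mask of each frame: pixels whose illumination is
#' at least 20 % of the slit-centre illumination and that are not
#' glare-saturated.
#'
#' @param spec a [scene_spec()].
#' @param trajectory a [make_trajectory()] result, or an `[n, 2]` matrix of
#'   (x, y) global offsets in pixels (0-based).
#' @return object of class `synthetic_sequence`: list with `frames` (list of
#'   RGB arrays), `true_masks` (list of logical matrices), `trajectory`,
#'   `fundus`, `profile` and `spec`.
#' @export
#' @examples
#' seq <- render_sequence(scene_spec(seed = 3),
#'                        make_trajectory("sweep", n_frames = 3))
#' length(seq$frames)
render_sequence <- function(spec, trajectory) {
  validate_scene_spec(spec)
  traj <- unclass(trajectory)
  if (is.null(dim(traj)) || ncol(traj) != 2)
    stop("trajectory must be an [n, 2] matrix of (x, y) offsets",
         call. = FALSE)
  H <- spec$frame_size[1]; W <- spec$frame_size[2]
  FH <- spec$fundus_size[1]; FW <- spec$fundus_size[2]
  for (i in seq_len(nrow(traj))) {
    ox <- traj[i, 1]; oy <- traj[i, 2]
    if (ox < 0 || oy < 0 || ox + W > FW || oy + H > FH)
      stop("trajectory offset for frame ", i,
           " places the frame outside the fundus", call. = FALSE)
  }
  fundus <- make_fundus(spec)
  profile <- slit_profile(spec)
  floor_lvl <- 0.2 * max(profile)
  illuminated <- which(profile > floor_lvl)
  n <- nrow(traj)
  frames <- vector("list", n)
  masks <- vector("list", n)
  with_seed(stage_seed(spec$seed, "noise"), {
    for (i in seq_len(n)) {
      ox <- round(traj[i, 1]); oy <- round(traj[i, 2])
      crop <- fundus[oy + seq_len(H), ox + seq_len(W), , drop = FALSE]
      fr <- crop * as.vector(profile)   # recycles profile over channels
      glare <- matrix(0, H, W)
      if (spec$glare_count > 0 && length(illuminated) > 0) {
        centers <- sample(illuminated, spec$glare_count, replace = TRUE)
        radii <- runif(spec$glare_count, spec$glare_radius_range[1],
                       spec$glare_radius_range[2])
        for (g in seq_len(spec$glare_count)) {
          cy <- (centers[g] - 1) %% H + 1
          cx <- (centers[g] - 1) %/% H + 1
          r <- radii[g]
          ys <- max(1, floor(cy - 3 * r)):min(H, ceiling(cy + 3 * r))
          xs <- max(1, floor(cx - 3 * r)):min(W, ceiling(cx + 3 * r))
          dd <- outer((ys - cy)^2, (xs - cx)^2, "+")
          glare[ys, xs] <- glare[ys, xs] + 0.95 * exp(-dd / (2 * (r / 2)^2))
        }
        fr <- fr + array(rep(glare, 3), c(H, W, 3))
      }
      if (spec$noise_sigma > 0)
        fr <- fr + array(rnorm(H * W * 3, 0, spec$noise_sigma), c(H, W, 3))
      frames[[i]] <- clamp(fr, 0, 1)
      masks[[i]] <- (profile >= floor_lvl) & (glare <= 0.5)
    }
  })
  structure(list(frames = frames, true_masks = masks,
                 trajectory = traj, fundus = fundus,
                 profile = profile, spec = spec),
            class = "synthetic_sequence")
}

#' Write a synthetic sequence to disk
#'
#' Frames as 8-bit RGB PNG (`frame_0001.png`, ...), ground-truth masks as
#' 8-bit binary PNG (0 background, 255 foreground), the trajectory as CSV
#' with header `frame,x,y` (frame index 1-based), and the scene spec as
#' YAML.
#'
#' @param seq a [render_sequence()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
write_sequence <- function(seq, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mdir <- file.path(dir, "masks")
  dir.create(mdir, showWarnings = FALSE)
  for (i in seq_along(seq$frames)) {
    png::writePNG(seq$frames[[i]],
                  file.path(dir, sprintf("frame_%04d.png", i)))
    png::writePNG(seq$true_masks[[i]] * 1,
                  file.path(mdir, sprintf("mask_%04d.png", i)))
  }
  tr <- data.frame(frame = seq_len(nrow(seq$trajectory)),
                   x = seq$trajectory[, 1], y = seq$trajectory[, 2])
  write.csv(tr, file.path(dir, "trajectory.csv"), row.names = FALSE)
  sp <- seq$spec; class(sp) <- NULL
  yaml::write_yaml(sp, file.path(dir, "scene_spec.yaml"))
  invisible(dir)
}
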