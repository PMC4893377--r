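# Shared fixtures, built in code and memoised for the duration of one test
# run. Sizes are desk-scale: unit tests use a small scene, the acceptance
# checks use the simulator defaults.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small scene: 128 x 170 frames, slit ~ 1/4 of the width.
tiny_spec <- function(seed = 11, ...) {
  scene_spec(fundus_size = c(384L, 384L), frame_size = c(128L, 170L),
             slit_width = 44, slit_height = 112, illumination_falloff = 6,
             glare_count = 2L, glare_radius_range = c(4, 8),
             noise_sigma = 0.02, seed = seed, ...)
}

tiny_sweep <- function() memo("tiny_sweep", function()
  render_sequence(tiny_spec(), make_trajectory("sweep", n_frames = 8,
                                               step = 14,
                                               origin = c(60, 100))))

tiny_clean <- function() memo("tiny_clean", function() {
  sp <- tiny_spec(); sp$noise_sigma <- 0; sp$glare_count <- 0L
  render_sequence(sp, make_trajectory("sweep", n_frames = 4, step = 14,
                                      origin = c(60, 100)))
})

# Default-scale sequences for the cross-validation and pipeline checks:
# 40-frame loop plus a 20-frame sweep gives 60 annotated frames.
default_loop <- function(seed = 29) memo("default_loop", function()
  render_sequence(scene_spec(seed = seed), make_trajectory("loop")))

default_sweep <- function(seed = 31) memo("default_sweep", function()
  render_sequence(scene_spec(seed = seed),
                  make_trajectory("sweep", n_frames = 20,
                                  origin = c(20, 256))))

# Tenfold cross-validation over the 60 default-scale frames, learned model
# (scenario B) and thresholding baseline, on identical folds.
cv_results <- function() memo("cv_results", function() {
  frames <- c(default_loop()$frames, default_sweep()$frames)
  masks <- c(default_loop()$true_masks, default_sweep()$true_masks)
  list(
    b = crossval(frames, masks, scenario = "B", k = 10, seed = 101,
                 config = boost_config(seed = 101)),
    baseline = crossval_baseline(frames, masks, k = 10, seed = 101)
  )
})

# Full pipeline on the default loop preset (noise and glare on).
loop_pipeline <- function() memo("loop_pipeline", function() {
  cfg <- pipeline_config(source = default_loop(), seed = 53)
  run_pipeline(cfg)
})

# Synthetic matches with a planted shift: n_in consistent correspondences
# plus n_out uniform outliers.
planted_matches <- function(shift, n_in, n_out = 0, jitter = 0,
                            seed = 1, span = 200) {
  set.seed(seed)
  x1 <- runif(n_in + n_out, 20, span)
  y1 <- runif(n_in + n_out, 20, span)
  x2 <- x1 + shift[1] + rnorm(n_in + n_out, 0, jitter)
  y2 <- y1 + shift[2] + rnorm(n_in + n_out, 0, jitter)
  if (n_out > 0) {
    o <- n_in + seq_len(n_out)
    x2[o] <- runif(n_out, 20, span)
    y2[o] <- runif(n_out, 20, span)
  }
  out <- data.frame(i1 = seq_along(x1), i2 = seq_along(x1),
                    x1 = x1, y1 = y1, x2 = x2, y2 = y2, dist = 0)
  class(out) <- c("match_set", "data.frame")
  out
}

# Dense pseudoinverse oracle for the pose-graph solver: minimum-norm
# least-squares solution of the unanchored system, shifted so the anchor
# sits at zero.
pinv_positions <- function(edges, n_nodes, anchor = 1) {
  A <- matrix(0, nrow(edges), n_nodes)
  for (r in seq_len(nrow(edges))) {
    A[r, edges$i[r]] <- 1
    A[r, edges$j[r]] <- -1
  }
  Ap <- MASS::ginv(A)
  xs <- Ap %*% edges$dx
  ys <- Ap %*% edges$dy
  cbind(xs - xs[anchor], ys - ys[anchor])
}

# Random connected pose graph: spanning tree plus extra edges, noisy
# deltas from a random ground-truth layout.
random_graph <- function(n_nodes, n_extra, seed) {
  set.seed(seed)
  truth <- cbind(runif(n_nodes, -50, 50), runif(n_nodes, -50, 50))
  i <- integer(0); j <- integer(0)
  for (v in seq_len(n_nodes)[-1]) {
    u <- sample(v - 1, 1)
    i <- c(i, v); j <- c(j, u)
  }
  for (k in seq_len(n_extra)) {
    p <- sample(n_nodes, 2)
    i <- c(i, p[1]); j <- c(j, p[2])
  }
  edges <- data.frame(i = i, j = j)
  edges$dx <- truth[i, 1] - truth[j, 1] + rnorm(length(i), 0, 1)
  edges$dy <- truth[i, 2] - truth[j, 2] + rnorm(length(i), 0, 1)
  list(edges = edges, truth = truth, n_nodes = n_nodes)
}
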