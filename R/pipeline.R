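# End-to-end orchestration: simulate (or read) frames, train and apply the
# slit segmenter, register frame pairs, bundle adjust, blend, evaluate.
# One top-level seed drives every random stage through fixed per-stage
# derivations.

#' Pipeline configuration
#'
#' All registration and boosting defaults equal the method's stated
#' operating values: RANSAC 100 iterations with a 3 px margin and a
#' 6-correspondence acceptance floor; boosting 200 rounds, shrinkage 0.1,
#' subsample 0.5, depth 3, squared loss; images downscaled by 4 for
#' segmentation.
#'
#' @param source input: a `synthetic_sequence`, a directory of numbered
#'   PNG frames, or a [scene_spec()] (rendered with `trajectory`).
#' @param trajectory trajectory preset name or matrix (simulator sources).
#' @param scenario feature scenario (default "B").
#' @param boost a [boost_config()].
#' @param window pair-proposal window (default Inf = all pairs).
#' @param ransac_iters,ransac_margin_px,min_inliers RANSAC parameters.
#' @param threshold,smoothing_scale mask prediction parameters.
#' @param compositor one of "feather", "overwrite", "mean", "median".
#' @param min_coverage skip frames whose predicted mask covers less than
#'   this fraction of the image (default 0.01).
#' @param stride temporal subsampling stride for frame reading.
#' @param seed top-level seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(source = NULL, trajectory = "loop",
                            scenario = "B", boost = NULL, window = Inf,
                            ransac_iters = 100L, ransac_margin_px = 3,
                            min_inliers = 6L, threshold = 0.5,
                            smoothing_scale = 2, compositor = "feather",
                            min_coverage = 0.01, stride = 1L, seed = 1L) {
  if (is.null(boost)) boost <- boost_config(seed = stage_seed(seed, "train"))
  cfg <- list(source = source, trajectory = trajectory,
              scenario = scenario, boost = boost, window = window,
              ransac_iters = as.integer(ransac_iters),
              ransac_margin_px = ransac_margin_px,
              min_inliers = as.integer(min_inliers),
              threshold = threshold, smoothing_scale = smoothing_scale,
              compositor = compositor, min_coverage = min_coverage,
              stride = as.integer(stride), seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read an ordered frame sequence
#'
#' A directory of PNG/TIFF frames is read in filename order and normalized
#' to [0, 1] RGB. Grayscale input is rejected (three channels are required
#' by the colour features and the `r - 0.7g` baseline). Container video
#' files are not decoded; extract frames to PNG first.
#'
#' @param source directory path.
#' @param stride keep every `stride`-th frame (default 1).
#' @return list of RGB arrays.
#' @export
read_frames <- function(source, stride = 1L) {
  if (!dir.exists(source)) {
    if (file.exists(source))
      stop("unsupported container file '", source,
           "': decode to a directory of PNG frames first", call. = FALSE)
    stop("input '", source, "' does not exist", call. = FALSE)
  }
  files <- sort(list.files(source, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (!length(files)) stop("no frames found in '", source, "'",
                           call. = FALSE)
  files <- files[seq(1, length(files), by = as.integer(stride))]
  lapply(files, function(f) {
    img <- if (grepl("png$", f, ignore.case = TRUE)) png::readPNG(f)
           else as.array(EBImage::readImage(f))
    if (length(dim(img)) == 2 || dim(img)[3] < 3)
      stop("frame '", basename(f), "' is grayscale; RGB input is required",
           call. = FALSE)
    img[, , 1:3, drop = FALSE]
  })
}

#' Run the full mosaicking pipeline
#'
#' Stages: (1) obtain frames (simulator or disk); (2) train the pixel
#' classifier (on the simulator's ground-truth masks, or on the provided
#' annotations) and predict a foreground mask per frame; (3) skip frames
#' with near-empty masks, propose pairs and estimate pairwise translations
#' with RANSAC; (4) bundle adjust the accepted edges into global
#' positions; (5) composite the mosaic with feathering; (6) when ground
#' truth exists, report trajectory recovery and drift. All artefacts are
#' written under `outdir` when given: per-frame masks (PNG), edges CSV,
#' positions CSV, mosaic PNG, evaluation JSON and a run log with every
#' parameter and seed.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @param annotations optional list of binary training masks (defaults to
#'   the simulator's ground truth when the source is synthetic).
#' @return list with `frames`, `masks`, `edges`, `positions`, `canvas`,
#'   `report` (list of evaluation numbers), `config`.
#' @export
run_pipeline <- function(config, outdir = NULL, annotations = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- c(sprintf("slitmosaic run, seed=%d", config$seed),
                 utils::capture.output(utils::str(
                   config[setdiff(names(config), "source")])))
  # --- frames
  src <- config$source
  truth <- NULL
  if (inherits(src, "scene_spec")) {
    traj <- if (is.character(config$trajectory))
      make_trajectory(config$trajectory) else config$trajectory
    src <- render_sequence(src, traj)
  }
  if (inherits(src, "synthetic_sequence")) {
    frames <- src$frames
    truth <- src$trajectory
    if (is.null(annotations)) annotations <- src$true_masks
  } else if (is.character(src)) {
    frames <- read_frames(src, config$stride)
  } else stop("config$source must be a scene_spec, synthetic_sequence or ",
              "frame directory", call. = FALSE)
  n <- length(frames)

  # --- segmentation
  if (is.null(annotations))
    stop("no annotations available to train the segmenter", call. = FALSE)
  clf <- train_classifier(frames, annotations, config$scenario,
                          config$boost)
  masks <- lapply(frames, function(fr)
    predict_mask(clf, fr, config$threshold, config$smoothing_scale))

  # --- registration
  coverage <- vapply(masks, function(m) mean(m$binary), numeric(1))
  active <- which(coverage >= config$min_coverage)
  if (length(active) < 2) stop("graph empty: fewer than 2 usable frames",
                               call. = FALSE)
  pairs_all <- propose_pairs(n, config$window)
  pairs <- pairs_all[pairs_all[, 1] %in% active &
                       pairs_all[, 2] %in% active, , drop = FALSE]
  edges <- register_pairs(frames, masks, pairs,
                          iterations = config$ransac_iters,
                          margin_px = config$ransac_margin_px,
                          min_inliers = config$min_inliers,
                          seed = config$seed)
  if (nrow(edges) == 0) stop("graph empty: no accepted pairwise edges",
                             call. = FALSE)

  # --- bundle adjustment
  positions <- solve_positions(edges, n_nodes = n, anchor = active[1])
  placed <- which(apply(is.finite(positions), 1, all))
  if (length(placed) == 1)
    warning("anchor component has a single frame; mosaic degenerates to ",
            "one frame")

  # --- blending
  canvas <- composite(frames[placed], masks[placed],
                      positions[placed, , drop = FALSE])

  # --- evaluation
  report <- list(n_frames = n, n_active = length(active),
                 n_edges = nrow(edges), n_placed = length(placed),
                 mean_mask_coverage = mean(coverage))
  dr <- drift_report(positions[placed, , drop = FALSE],
                     remap_edges(edges, placed),
                     truth = if (!is.null(truth))
                       truth[placed, , drop = FALSE])
  report$max_edge_residual <- dr$max_residual
  report$rms_edge_residual <- dr$rms_residual
  if (!is.null(truth)) {
    te <- trajectory_error(positions[placed, , drop = FALSE],
                           truth[placed, , drop = FALSE])
    report$trajectory_rmse <- te$rmse
    report$endpoint_drift_global <- dr$endpoint_drift_global
    report$endpoint_drift_chained <- dr$endpoint_drift_chained
  }

  # --- outputs
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    mdir <- file.path(outdir, "masks")
    dir.create(mdir, showWarnings = FALSE)
    for (i in seq_len(n))
      png::writePNG(masks[[i]]$binary * 1,
                    file.path(mdir, sprintf("mask_%04d.png", i)))
    write_edges(edges, file.path(outdir, "edges.csv"))
    write_positions(positions, file.path(outdir, "positions.csv"))
    write_mosaic(canvas, file.path(outdir, "mosaic.png"))
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(outdir, "run.log"))
  }
  list(frames = frames, masks = masks, classifier = clf, edges = edges,
       positions = positions, canvas = canvas, report = report,
       truth = truth, config = config)
}

# Re-index edges after subsetting frames to `placed` (1..length(placed)).
remap_edges <- function(edges, placed) {
  map <- match(seq_len(max(placed)), placed)
  out <- edges[edges$i %in% placed & edges$j %in% placed, , drop = FALSE]
  out$i <- map[out$i]
  out$j <- map[out$j]
  out
}

#' Run the pipeline from a YAML config file
#'
#' Thin wrapper used by the command-line entry point: reads a YAML file
#' whose keys mirror [pipeline_config()] (plus `preset`, `n_frames`,
#' `step` and scene-spec fields for simulator sources, and `outdir`).
#'
#' @param path YAML config path.
#' @return the [run_pipeline()] result, invisibly.
#' @export
run_pipeline_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  seed <- as.integer(y$seed %||% 1L)
  source <- if (!is.null(y$frames_dir)) y$frames_dir else {
    sp_args <- y$scene_spec %||% list()
    sp_args$seed <- sp_args$seed %||% seed
    do.call(scene_spec, sp_args)
  }
  traj <- if (!is.null(y$preset))
    make_trajectory(y$preset, n_frames = y$n_frames %||% 40L,
                    step = y$step %||% 20L,
                    origin = y$origin %||% c(120, 200)) else "loop"
  keep <- intersect(names(y), names(formals(pipeline_config)))
  keep <- setdiff(keep, c("source", "trajectory", "boost"))
  cfg <- do.call(pipeline_config,
                 c(list(source = source, trajectory = traj), y[keep]))
  invisible(run_pipeline(cfg, outdir = y$outdir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
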