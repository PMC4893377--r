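# Global bundle adjustment: every accepted pairwise translation (i, j,
# delta) contributes one linear constraint per axis, x_i - x_j = delta,
# assembled into an over-determined sparse system Ax = b and solved by
# least squares after gauge fixing (anchoring one frame at the origin).

#' Build the bundle-adjustment linear system
#'
#' One row per accepted edge per axis: `+1` in column i, `-1` in column j,
#' right-hand side the measured delta, encoding `x_i - x_j = delta`.
#' Duplicate edges stay as separate rows — over-determination is the point
#' of bundle adjustment. The same sparse A serves both axes, with separate
#' right-hand sides `bx` and `by`.
#'
#' @param edges data.frame with columns `i, j, dx, dy` (1-based frame
#'   indices).
#' @param n_nodes total number of frames (columns of A); defaults to
#'   `max(i, j)`.
#' @return list `A` (sparse `[n_edges, n_nodes]`), `bx`, `by`, `n_nodes`.
#' @export
build_system <- function(edges, n_nodes = NULL) {
  if (is.null(edges) || nrow(edges) == 0)
    stop("cannot build a system from zero edges", call. = FALSE)
  if (is.null(n_nodes)) n_nodes <- max(edges$i, edges$j)
  if (any(edges$i < 1 | edges$j < 1 | edges$i > n_nodes |
          edges$j > n_nodes))
    stop("edge references a node outside 1..", n_nodes, call. = FALSE)
  if (any(edges$i == edges$j))
    stop("self-edges (i == j) are not allowed", call. = FALSE)
  m <- nrow(edges)
  A <- Matrix::sparseMatrix(i = c(seq_len(m), seq_len(m)),
                            j = c(edges$i, edges$j),
                            x = c(rep(1, m), rep(-1, m)),
                            dims = c(m, n_nodes))
  list(A = A, bx = edges$dx, by = edges$dy, n_nodes = n_nodes)
}

# Connected components of the constraint graph (simple BFS).
edge_components <- function(edges, n_nodes) {
  comp <- integer(n_nodes)
  adj <- vector("list", n_nodes)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  cur <- 0L
  for (s in seq_len(n_nodes)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      new <- nb[comp[nb] == 0L]
      comp[new] <- cur
      queue <- c(queue, new)
    }
  }
  comp
}

#' Solve for globally consistent frame positions
#'
#' Least-squares solution of the anchored system: the anchor frame is
#' pinned at (0, 0) (gauge fixing — without it A is rank-deficient by
#' exactly the global-translation degree of freedom per axis), its column
#' dropped, and the sparse normal equations solved per axis. Only the
#' connected component containing the anchor is placed; frames outside it
#' get NA positions and are reported via the `dropped` attribute.
#'
#' @param edges accepted edge data.frame (`i, j, dx, dy`, optionally
#'   `inliers`).
#' @param n_nodes total number of frames; defaults to `max(i, j)`.
#' @param anchor frame pinned at the origin (default 1).
#' @param weight_by_inliers if TRUE, each constraint row is weighted by the
#'   square root of its inlier count (off by default: all constraints equal).
#' @return matrix `[n_nodes, 2]` of (x, y) positions, NA outside the
#'   anchor's component; attributes `component` (membership vector) and
#'   `dropped` (excluded frame indices).
#' @export
solve_positions <- function(edges, n_nodes = NULL, anchor = 1L,
                            weight_by_inliers = FALSE) {
  if ((is.null(edges) || nrow(edges) == 0)) {
    if (is.null(n_nodes) || n_nodes == 1L) {
      out <- matrix(0, 1, 2, dimnames = list(NULL, c("x", "y")))
      attr(out, "component") <- 1L
      attr(out, "dropped") <- integer(0)
      return(out)
    }
    stop("cannot solve a graph with zero edges", call. = FALSE)
  }
  if (is.null(n_nodes)) n_nodes <- max(edges$i, edges$j)
  comp <- edge_components(edges, n_nodes)
  keep_nodes <- which(comp == comp[anchor])
  keep_edges <- edges[edges$i %in% keep_nodes & edges$j %in% keep_nodes, ,
                      drop = FALSE]
  sys <- build_system(keep_edges, n_nodes)
  A <- sys$A[, keep_nodes, drop = FALSE]
  bx <- sys$bx; by <- sys$by
  if (weight_by_inliers && !is.null(keep_edges$inliers)) {
    w <- sqrt(keep_edges$inliers)
    A <- A * w
    bx <- bx * w; by <- by * w
  }
  a_col <- match(anchor, keep_nodes)
  Ar <- A[, -a_col, drop = FALSE]
  pos <- matrix(NA_real_, n_nodes, 2, dimnames = list(NULL, c("x", "y")))
  pos[anchor, ] <- 0
  if (ncol(Ar) > 0) {
    M <- Matrix::crossprod(Ar)
    xs <- Matrix::solve(M, Matrix::crossprod(Ar, bx))
    ys <- Matrix::solve(M, Matrix::crossprod(Ar, by))
    pos[keep_nodes[-a_col], 1] <- as.numeric(xs)
    pos[keep_nodes[-a_col], 2] <- as.numeric(ys)
  }
  attr(pos, "component") <- comp
  attr(pos, "dropped") <- which(comp != comp[anchor])
  pos
}

#' Integrate consecutive deltas only (sequential chaining)
#'
#' The drift-prone alternative to bundle adjustment: positions are obtained
#' by summing the deltas of consecutive-frame edges `(i, i+1)` alone,
#' ignoring all other constraints. Frames with no incoming consecutive
#' edge inherit the previous position (logged via NA handling upstream).
#'
#' @param edges edge data.frame.
#' @param n_nodes number of frames.
#' @return matrix `[n_nodes, 2]` of chained positions (anchor = frame 1 at
#'   the origin).
#' @export
chain_positions <- function(edges, n_nodes) {
  pos <- matrix(0, n_nodes, 2, dimnames = list(NULL, c("x", "y")))
  if (n_nodes < 2) return(pos)
  for (f in 2:n_nodes) {
    e <- edges[edges$i == f - 1 & edges$j == f, , drop = FALSE]
    if (nrow(e) == 0) {
      e <- edges[edges$i == f & edges$j == f - 1, , drop = FALSE]
      if (nrow(e) == 0) { pos[f, ] <- pos[f - 1, ]; next }
      # x_{f} - x_{f-1} = dx  =>  step = +delta
      pos[f, ] <- pos[f - 1, ] + c(e$dx[1], e$dy[1])
    } else {
      # x_{f-1} - x_f = dx  =>  step = -delta
      pos[f, ] <- pos[f - 1, ] - c(e$dx[1], e$dy[1])
    }
  }
  pos
}

#' Residuals of a solved pose graph, and drift against chaining
#'
#' Per-edge residuals `r_e = (x_i - x_j) - delta` per axis, their maximum
#' and RMS, and — when a ground-truth trajectory is supplied — the
#' endpoint drift (Euclidean error of the final frame after anchoring) of
#' the globally adjusted positions compared with sequential chaining.
#'
#' @param positions solved positions `[n, 2]`.
#' @param edges edge data.frame.
#' @param truth optional ground-truth trajectory `[n, 2]`.
#' @return list with `residuals` (data.frame `i, j, rx, ry`), `max_residual`,
#'   `rms_residual`, and (with truth) `endpoint_drift_global`,
#'   `endpoint_drift_chained`, `chained` positions.
#' @export
drift_report <- function(positions, edges, truth = NULL) {
  rx <- (positions[edges$i, 1] - positions[edges$j, 1]) - edges$dx
  ry <- (positions[edges$i, 2] - positions[edges$j, 2]) - edges$dy
  res <- data.frame(i = edges$i, j = edges$j, rx = rx, ry = ry)
  out <- list(residuals = res,
              max_residual = max(abs(c(rx, ry))),
              rms_residual = sqrt(mean(c(rx^2 + ry^2))))
  if (!is.null(truth)) {
    n <- nrow(positions)
    chained <- chain_positions(edges, n)
    anchor2 <- function(p) sweep(p, 2, p[1, ])
    tt <- anchor2(unclass(truth))
    eg <- anchor2(positions)[n, ] - tt[n, ]
    ec <- anchor2(chained)[n, ] - tt[n, ]
    out$endpoint_drift_global <- sqrt(sum(eg^2))
    out$endpoint_drift_chained <- sqrt(sum(ec^2))
    out$chained <- chained
  }
  out
}

#' Read / write solved positions as CSV
#'
#' Columns `frame, x, y` with 1-based frame indices.
#'
#' @param positions `[n, 2]` matrix.
#' @param path CSV path.
#' @return `write_positions`: invisibly, `path`; `read_positions`: the
#'   matrix.
#' @export
write_positions <- function(positions, path) {
  df <- data.frame(frame = seq_len(nrow(positions)),
                   x = positions[, 1], y = positions[, 2])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_positions
#' @export
read_positions <- function(path) {
  df <- read.csv(path)
  as.matrix(df[, c("x", "y")])
}
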