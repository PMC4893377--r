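test_that("constraint rows carry +1 at i, -1 at j and the delta on the rhs", {
  edges <- data.frame(i = 2, j = 1, dx = 5, dy = -1)
  sys <- build_system(edges)
  A <- as.matrix(sys$A)
  expect_equal(A, matrix(c(-1, 1), 1, 2), ignore_attr = TRUE)
  expect_equal(sys$bx, 5)
  expect_equal(sys$by, -1)
})

test_that("degenerate systems are rejected with clear errors", {
  expect_error(build_system(data.frame()[0, ]), "zero edges")
  expect_error(build_system(data.frame(i = 1, j = 5, dx = 0, dy = 0),
                            n_nodes = 3), "node")
  expect_error(build_system(data.frame(i = 2, j = 2, dx = 0, dy = 0)),
               "self-edges")
})

test_that("duplicate edges are kept as separate rows", {
  edges <- data.frame(i = c(2, 2), j = c(1, 1), dx = c(5, 7), dy = 0)
  sys <- build_system(edges)
  expect_equal(nrow(sys$A), 2)
  # least squares averages the contradicting duplicates
  pos <- solve_positions(edges)
  expect_equal(as.numeric(pos[2, 1]), 6)
})

test_that("a consistent chain solves exactly by forward substitution", {
  edges <- data.frame(i = c(2, 3), j = c(1, 2), dx = c(5, 7), dy = c(1, 2))
  pos <- solve_positions(edges)
  expect_equal(pos[, 1], c(0, 5, 12), ignore_attr = TRUE)
  expect_equal(pos[, 2], c(0, 1, 3), ignore_attr = TRUE)
  rep <- drift_report(pos, edges)
  expect_equal(rep$max_residual, 0)
})

test_that("the over-determined triangle solves to the least-squares optimum", {
  edges <- data.frame(i = c(2, 3, 3), j = c(1, 2, 1), dx = c(1, 1, 1),
                      dy = 0)
  pos <- solve_positions(edges)
  expect_equal(pos[, 1], c(0, 2 / 3, 4 / 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  rep <- drift_report(pos, edges)
  expect_equal(rep$residuals$rx, c(-1 / 3, -1 / 3, 1 / 3),
               tolerance = 1e-12)
})

test_that("a single anchored node sits at the origin", {
  pos <- solve_positions(NULL, n_nodes = 1)
  expect_equal(pos, matrix(0, 1, 2), ignore_attr = TRUE)
})

test_that("residuals are gauge invariant; anchoring removes one dof per axis", {
  g <- random_graph(8, 10, seed = 21)
  pos <- solve_positions(g$edges)
  shifted <- pos + matrix(rep(c(13, -4), each = 8), 8, 2)
  r1 <- drift_report(pos, g$edges)
  r2 <- drift_report(shifted, g$edges)
  expect_equal(r1$residuals, r2$residuals, tolerance = 1e-12)
  expect_equal(pos[1, ], c(x = 0, y = 0))
})

test_that("sparse solver agrees with the dense pseudoinverse oracle", {
  skip_if_not_installed("MASS")
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(2:10, 1)
    g <- random_graph(n, sample(0:15, 1), seed = seed * 7)
    pos <- solve_positions(g$edges, n_nodes = n)
    oracle <- pinv_positions(g$edges, n)
    expect_lt(max(abs(pos - oracle)), 1e-9)
  }
})

test_that("noiseless constraints recover the ground-truth layout exactly", {
  g <- random_graph(9, 12, seed = 5)
  g$edges$dx <- g$truth[g$edges$i, 1] - g$truth[g$edges$j, 1]
  g$edges$dy <- g$truth[g$edges$i, 2] - g$truth[g$edges$j, 2]
  pos <- solve_positions(g$edges, n_nodes = 9)
  anchored_truth <- sweep(g$truth, 2, g$truth[1, ])
  expect_equal(unclass(pos), anchored_truth, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("global adjustment beats sequential chaining on noisy loops", {
  wins <- 0
  drift_g <- drift_c <- numeric(0)
  for (seed in 1:20) {
    set.seed(seed)
    n <- 12
    truth <- cbind(c(0, cumsum(rep(c(10, 0, -10, 0), each = 3))[1:(n - 1)]),
                   c(0, cumsum(rep(c(0, 10, 0, -10), each = 3))[1:(n - 1)]))
    pairs <- rbind(cbind(1:(n - 1), 2:n), c(1, n))   # chain + loop closure
    edges <- data.frame(i = pairs[, 1], j = pairs[, 2])
    edges$dx <- truth[edges$i, 1] - truth[edges$j, 1] + rnorm(n, 0, 1)
    edges$dy <- truth[edges$i, 2] - truth[edges$j, 2] + rnorm(n, 0, 1)
    rep <- drift_report(solve_positions(edges, n_nodes = n), edges,
                        truth = truth)
    wins <- wins + (rep$endpoint_drift_global <= rep$endpoint_drift_chained)
    drift_g <- c(drift_g, rep$endpoint_drift_global)
    drift_c <- c(drift_c, rep$endpoint_drift_chained)
  }
  # least squares dominates integration on loops, per trial and on average
  expect_gte(wins, 14)
  expect_lt(mean(drift_g), mean(drift_c))
})

test_that("nodes disconnected from the anchor are excluded and reported", {
  edges <- data.frame(i = c(2, 4), j = c(1, 5), dx = c(1, 1), dy = 0)
  pos <- solve_positions(edges, n_nodes = 5)
  expect_equal(attr(pos, "dropped"), c(3L, 4L, 5L))
  expect_true(all(is.na(pos[3:5, ])))
  expect_equal(as.numeric(pos[2, 1]), 1)
})

test_that("positions round-trip through CSV", {
  pos <- matrix(c(0, 1.5, -2, 0, 3, 4), 3, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_positions(pos, path)
  expect_equal(read_positions(path), pos, ignore_attr = TRUE)
})
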