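mods14 <- c(rep("EEG", 8), rep("EMG", 6))

test_that("normalize_blocks rescales each block to [0, 1]", {
  set.seed(109)
  p <- 6
  mods <- c(rep("EEG", 3), rep("EMG", 3))
  W <- matrix(rnorm(p * p), p)
  W <- (W + t(W)) / 2; diag(W) <- 0
  Wn <- normalize_blocks(W, mods)
  expect_true(isSymmetric(Wn))
  expect_equal(diag(Wn), rep(0, p), ignore_attr = TRUE)
  for (blk in list(1:3, 4:6)) {
    off <- Wn[blk, blk][row(Wn[blk, blk]) != col(Wn[blk, blk])]
    expect_equal(range(off), c(0, 1))
  }
  cross <- Wn[1:3, 4:6]
  expect_equal(range(cross), c(0, 1))
  # order preserved within a block by the absolute weight
  ord_in <- order(abs(W[1:3, 4:6]))
  expect_identical(order(cross), ord_in)
})

test_that("degenerate blocks are zeroed with a warning", {
  mods <- c("EEG", "EEG", "EEG", "EMG", "EMG")
  W <- matrix(0, 5, 5)
  W[1, 2] <- W[2, 1] <- 0.5          # EEG block varies (0 and 0.5)
  W[4, 5] <- W[5, 4] <- 0.3          # EMG block constant: degenerate
  W[1, 4] <- W[4, 1] <- 0.2          # cross block varies
  expect_warning(Wn <- normalize_blocks(W, mods), "degenerate")
  expect_equal(Wn[4, 5], 0)
  expect_equal(Wn[1, 2], 1)
  expect_equal(Wn[1, 4], 1)
})

test_that("threshold rule picks the largest t with K >= 2 ln N", {
  expect_equal(select_threshold_from_curve(c(0.50, 0.55, 0.60),
                                           c(6.1, 5.4, 4.9), 14), 0.55)
  expect_equal(select_threshold_from_curve(c(0.2, 0.4), c(9, 8), 10), 0.4)
  expect_warning(
    thr <- select_threshold_from_curve(c(0.2, 0.4), c(2, 1), 14),
    "no threshold")
  expect_equal(thr, 0)
})

test_that("threshold_select averages degrees across matrices", {
  # single matrix: 4 nodes all tied at 0.75
  Wn <- matrix(0.75, 4, 4); diag(Wn) <- 0
  sel <- threshold_select(list(Wn), step = 0.1)
  expect_true(sel$threshold %in% sel$curve$threshold)
  k_at <- sel$curve$k_mean[sel$curve$threshold == sel$threshold]
  expect_gte(k_at, 2 * log(4))
  expect_identical(names(sel$curve), c("threshold", "k_mean", "k_sd"))
  # degree at t=0.7 counts Wn >= t
  at <- function(t) sel$curve$k_mean[which.min(abs(sel$curve$threshold - t))]
  expect_equal(at(0.7), 3)
  expect_equal(at(0.8), 0)
})

test_that("binarize_adjacency thresholds inclusively with zero diagonal", {
  Wn <- matrix(c(0, .5, .2, .5, 0, .8, .2, .8, 0), 3)
  A <- binarize_adjacency(Wn, 0.5)
  expect_equal(A, matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3))
})

test_that("graph metrics on canonical graphs", {
  K4 <- matrix(1, 4, 4); diag(K4) <- 0
  m <- graph_metrics(K4)
  expect_equal(m$L, 1)
  expect_equal(m$C, 1)
  expect_equal(m$K_i, rep(3, 4), ignore_attr = TRUE)
  expect_equal(m$n_disconnected_pairs, 0)

  P4 <- matrix(0, 4, 4)
  P4[1, 2] <- P4[2, 3] <- P4[3, 4] <- 1
  P4 <- P4 + t(P4)
  m <- graph_metrics(P4)
  expect_equal(m$L, 5 / 3)
  expect_equal(m$C, 0)

  star <- matrix(0, 5, 5)
  star[1, 2:5] <- 1; star <- star + t(star)
  m <- graph_metrics(star)
  expect_equal(m$L, (4 * 1 * 2 + 4 * 3 * 2) / 20)
  expect_equal(m$C, 0)
  expect_identical(unname(core_nodes(star)), 1L)

  empty <- matrix(0, 3, 3)
  m <- graph_metrics(empty)
  expect_true(is.na(m$L))
  expect_equal(m$C, 0)
  expect_equal(m$n_disconnected_pairs, 6)
})

test_that("path lengths agree with a BFS oracle on random graphs", {
  set.seed(113)
  for (rep in 1:25) {
    n <- sample(3:10, 1)
    A <- matrix(rbinom(n * n, 1, 0.35), n)
    A[lower.tri(A)] <- t(A)[lower.tri(A)]
    diag(A) <- 0
    m <- graph_metrics(A)
    D <- bfs_distances(A)
    off <- D[row(D) != col(D)]
    if (all(is.infinite(off))) {
      expect_true(is.na(m$L))
    } else {
      expect_equal(m$L, mean(off[is.finite(off)]), tolerance = 1e-12)
    }
    expect_equal(m$n_disconnected_pairs, sum(is.infinite(off)))
  }
})

test_that("clustering matches triangle counting", {
  set.seed(127)
  A <- matrix(rbinom(64, 1, 0.5), 8)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  m <- graph_metrics(A)
  K <- rowSums(A)
  tri <- diag(A %*% A %*% A) / 2
  Ci <- ifelse(K < 2, 0, 2 * tri / (K * (K - 1)))
  expect_equal(m$C_i, Ci, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("core_nodes returns all ties and metrics validate input", {
  A <- matrix(0, 4, 4)
  A[1, 2] <- A[2, 1] <- A[3, 4] <- A[4, 3] <- 1
  expect_identical(unname(core_nodes(A)), 1:4)
  expect_error(graph_metrics(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(graph_metrics(matrix(c(1, 1, 1, 1), 2)), "symmetric")
  expect_error(graph_metrics(matrix(c(0, 2, 2, 0), 2)), "symmetric")
})
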