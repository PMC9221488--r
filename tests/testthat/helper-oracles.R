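# Independent reference implementations used to cross-check the package.

# All-pairs Kendall tau-b: O(n^2) sign counting with tie corrections.
naive_kendall_tau <- function(x, y) {
  n <- length(x)
  num <- 0; tx <- 0; ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
      num <- num + dx * dy
      if (dx == 0) tx <- tx + 1
      if (dy == 0) ty <- ty + 1
    }
  }
  n0 <- n * (n - 1) / 2
  num / sqrt((n0 - tx) * (n0 - ty))
}

# Decode a Pruefer sequence into the edge list of a labeled tree on n nodes.
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, 0, 2)
  for (s in seq) {
    leaf <- min(which(degree == 1L))
    edges <- rbind(edges, c(min(leaf, s), max(leaf, s)))
    degree[leaf] <- degree[leaf] - 1L
    degree[s] <- degree[s] - 1L
  }
  last <- which(degree == 1L)
  rbind(edges, c(min(last), max(last)))
}

# Every labeled spanning tree of the complete graph on n nodes (n <= 6).
all_spanning_trees <- function(n) {
  if (n == 2) return(list(matrix(c(1L, 2L), 1)))
  seqs <- do.call(expand.grid, rep(list(seq_len(n)), n - 2))
  lapply(seq_len(nrow(seqs)), function(i)
    prufer_decode(as.integer(seqs[i, ]), n))
}

tree_weight <- function(edges, W) sum(W[edges])

edge_key <- function(edges)
  sort(apply(edges, 1, function(r) paste(sort(r), collapse = "-")))

# Breadth-first shortest-path distance matrix of a binary adjacency matrix.
bfs_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- integer(0)
      for (v in frontier) {
        nb <- which(A[v, ] == 1 & is.infinite(D[s, ]))
        D[s, nb] <- d
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
  }
  D
}

# Literal loop-based AR(1)+GJR-GARCH(1,1)-t log-likelihood.
naive_garch_loglik <- function(p, x) {
  n <- length(x)
  a <- x[-1] - p[["c0"]] - p[["c1"]] * x[-n]
  m <- length(a)
  s2 <- numeric(m)
  s2[1] <- var(a)
  for (t in 2:m)
    s2[t] <- p[["omega"]] +
      (p[["alpha"]] + p[["gamma"]] * (a[t - 1] < 0)) * a[t - 1]^2 +
      p[["beta"]] * s2[t - 1]
  z <- a / sqrt(s2)
  s <- sqrt(p[["dof"]] / (p[["dof"]] - 2))
  sum(dt(z * s, df = p[["dof"]], log = TRUE) + log(s) - 0.5 * log(s2))
}

# Log density of the trivariate Gaussian copula with correlation matrix R.
mvn3_copula_logdensity <- function(R, U) {
  Z <- qnorm(U)
  Q <- solve(R) - diag(3)
  -0.5 * log(det(R)) - 0.5 * rowSums((Z %*% Q) * Z)
}

# Fixed 5-variable Gaussian vine truth used in structure-recovery tests.
recovery_vine5 <- function() {
  edges <- rbind(c(1, 2), c(2, 3), c(2, 4), c(4, 5))
  taus <- c(0.6, 0.5, 0.4, 0.3)
  cops <- lapply(taus, function(tt)
    pair_copula("gaussian", params_from_tau("gaussian", tt)))
  list(vine = vine_from_tree1(edges, cops, 5), edges = edges, taus = taus)
}

all_test_copulas <- function() list(
  pair_copula("independence"),
  pair_copula("gaussian", c(rho = 0.6)),
  pair_copula("gaussian", c(rho = -0.75)),
  pair_copula("student_t", c(rho = 0.45, nu = 5)),
  pair_copula("clayton", c(theta = 1.7)),
  pair_copula("clayton", c(theta = 1.2), rotation = 90),
  pair_copula("clayton", c(theta = 2.0), rotation = 180),
  pair_copula("clayton", c(theta = 0.8), rotation = 270),
  pair_copula("gumbel", c(theta = 2.5)),
  pair_copula("gumbel", c(theta = 3.0), rotation = 180),
  pair_copula("frank", c(theta = 5)),
  pair_copula("frank", c(theta = -4)))
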