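#' @name network
#' @title Corticomuscular functional networks
#'
#' @description
#' The dependence matrix (absolute Kendall tau from the vine's first
#' tree, or spectral Granger causality) is normalized per block --
#' EEG-EEG, EMG-EMG and EEG-EMG cells are min-max scaled separately,
#' because within-modality dependence dwarfs cross-modality dependence --
#' then binarized at a threshold chosen as the largest value on a 0.05
#' grid whose average node degree K still satisfies \eqn{K \ge 2\ln N}.
#' Binary-graph metrics follow: characteristic path length (mean
#' shortest-path length over connected ordered pairs), clustering
#' coefficient \eqn{C_i = 2E_i/(K_i(K_i-1))}, and core nodes (maximum
#' degree).
NULL

#' Block-wise min-max normalization of a dependence matrix
#'
#' Absolute weights within each of the EEG-EEG, EMG-EMG and EEG-EMG
#' blocks are scaled to \[0, 1\] using that block's off-diagonal min and
#' max. A degenerate block (max equal to min) is zeroed with a warning.
#'
#' @param W symmetric numeric weight matrix.
#' @param modalities `"EEG"`/`"EMG"` label per node.
#' @return normalized symmetric matrix with zero diagonal.
#' @export
normalize_blocks <- function(W, modalities) {
  W <- as.matrix(W)
  n <- nrow(W)
  if (n != ncol(W) || !isTRUE(all.equal(W, t(W), tolerance = 1e-8)))
    stop("W must be a symmetric square matrix")
  if (length(modalities) != n) stop("one modality per node required")
  A <- abs(W)
  out <- matrix(0, n, n, dimnames = dimnames(W))
  eeg <- modalities == "EEG"
  blocks <- list(list(eeg, eeg), list(!eeg, !eeg), list(eeg, !eeg))
  off <- !diag(n)
  for (bl in blocks) {
    mask <- outer(bl[[1]], bl[[2]]) | outer(bl[[2]], bl[[1]])
    mask <- mask & off
    if (!any(mask)) next
    vals <- A[mask]
    lo <- min(vals); hi <- max(vals)
    if (hi - lo < 1e-14) {
      warning("degenerate block (all weights equal); set to 0")
      out[mask] <- 0
    } else {
      out[mask] <- (A[mask] - lo) / (hi - lo)
    }
  }
  diag(out) <- 0
  out
}

#' Apply the average-degree rule to a K(t) curve
#'
#' Returns the largest threshold whose average node degree is at least
#' \eqn{2 \ln N}; if no threshold qualifies, 0 with a warning.
#'
#' @param thresholds numeric vector of candidate thresholds.
#' @param k_mean average node degree at each threshold.
#' @param n_nodes number of network nodes N.
#' @return the selected threshold.
#' @export
select_threshold_from_curve <- function(thresholds, k_mean, n_nodes) {
  if (length(thresholds) != length(k_mean))
    stop("thresholds and k_mean must align")
  ok <- k_mean >= 2 * log(n_nodes)
  if (!any(ok)) {
    warning("no threshold satisfies K >= 2 ln N; returning 0")
    return(0)
  }
  max(thresholds[ok])
}

#' Select a shared network threshold
#'
#' Scans thresholds 0..1 on a fixed grid; at each, every normalized
#' matrix is binarized (edge when weight >= t), its mean node degree
#' computed, and degrees averaged across matrices (one per task
#' condition). The selected threshold is the largest with average degree
#' at least \eqn{2\ln N}.
#'
#' @param Wn_list list of normalized weight matrices sharing a node count.
#' @param step grid step in (0, 0.5\].
#' @return list with `threshold`, and the scan `curve` (threshold, mean K
#'   across matrices, sd across matrices).
#' @export
threshold_select <- function(Wn_list, step = 0.05) {
  if (!is.list(Wn_list)) Wn_list <- list(Wn_list)
  if (step <= 0 || step > 0.5) stop("step must lie in (0, 0.5]")
  n <- nrow(Wn_list[[1]])
  if (any(vapply(Wn_list, nrow, 0L) != n))
    stop("all matrices must share one node count")
  ts <- seq(0, 1, by = step)
  kmat <- vapply(ts, function(t) {
    vapply(Wn_list, function(W) {
      A <- binarize_adjacency(W, t)
      mean(rowSums(A))
    }, 0)
  }, numeric(length(Wn_list)))
  kmat <- matrix(kmat, nrow = length(Wn_list))
  k_mean <- colMeans(kmat)
  k_sd <- if (nrow(kmat) > 1) apply(kmat, 2, stats::sd) else rep(0, ncol(kmat))
  thr <- select_threshold_from_curve(ts, k_mean, n)
  list(threshold = thr,
       curve = data.frame(threshold = ts, k_mean = k_mean, k_sd = k_sd))
}

#' Binarize a normalized weight matrix
#'
#' @param Wn normalized symmetric matrix.
#' @param threshold edge retained when `Wn >= threshold` (off-diagonal).
#' @return binary adjacency matrix with zero diagonal.
#' @export
binarize_adjacency <- function(Wn, threshold) {
  A <- (Wn >= threshold) * 1
  diag(A) <- 0
  A
}

#' Binary-graph metrics
#'
#' Characteristic path length L (mean shortest-path length over connected
#' ordered pairs; disconnected pairs are excluded and counted), clustering
#' coefficients \eqn{C_i = 2E_i/(K_i(K_i-1))} with \eqn{C_i = 0} for
#' degree below 2, their mean C, and node degrees.
#'
#' @param A symmetric binary adjacency matrix with zero diagonal.
#' @return list with `L`, `C`, `C_i`, `K_i`, `n_disconnected_pairs`.
#' @export
graph_metrics <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  if (!isTRUE(all.equal(A, t(A))) || any(!A %in% c(0, 1)) ||
      any(diag(A) != 0))
    stop("A must be symmetric binary with zero diagonal")
  K <- rowSums(A)
  Ci <- vapply(seq_len(n), function(i) {
    if (K[i] < 2) return(0)
    nb <- which(A[i, ] == 1)
    Ei <- sum(A[nb, nb]) / 2
    2 * Ei / (K[i] * (K[i] - 1))
  }, 0)
  if (sum(A) == 0) {
    return(list(L = NA_real_, C = 0, C_i = Ci, K_i = K,
                n_disconnected_pairs = n * (n - 1)))
  }
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  D <- igraph::distances(g)
  off <- D[row(D) != col(D)]
  disc <- sum(is.infinite(off))
  L <- if (all(is.infinite(off))) NA_real_ else mean(off[is.finite(off)])
  list(L = L, C = mean(Ci), C_i = Ci, K_i = K,
       n_disconnected_pairs = disc)
}

#' Core nodes of a binary network
#'
#' All nodes attaining the maximum degree (ties returned together).
#'
#' @param A binary adjacency matrix.
#' @return integer indices of core nodes (named when A has dimnames).
#' @export
core_nodes <- function(A) {
  K <- rowSums(A != 0)
  idx <- which(K == max(K))
  if (!is.null(rownames(A))) names(idx) <- rownames(A)[idx]
  idx
}
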