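#' @name synth
#' @title Synthetic EEG/EMG scenarios with known ground truth
#'
#' @description
#' Generates multichannel data from exactly the model class the pipeline
#' assumes: cross-channel dependence is injected at the innovation level
#' through a known R-vine copula (an EEG chain, an EMG chain and one
#' EEG-EMG bridge in the first tree, Gaussian pairs, independence above),
#' and each channel's innovations drive an AR(1)+GJR-GARCH(1,1)-t
#' recursion. Within-modality dependence is set stronger than
#' cross-modality dependence, the pattern seen in real corticomuscular
#' recordings.
NULL

eeg_channel_names <- c("Cz", "C3", "C4", "Cp1", "Cp2", "FC3", "FC4", "Fz")
emg_channel_names <- c("FDS", "BR", "BB", "ED", "FCU", "ECU")

default_garch_truth <- c(c0 = 0, c1 = 0.2, omega = 0.05, alpha = 0.05,
                         beta = 0.85, gamma = 0.05, dof = 8)

#' Define a ground-truth scenario
#'
#' First-tree structure: EEG channels in a chain, EMG channels in a
#' chain, and a single bridge edge between the chain midpoints. Chain
#' edges carry Gaussian pair copulas at `tau_within`, the bridge at
#' `tau_cross` (independence when 0); all higher trees are independent.
#'
#' @param n_eeg,n_emg channel counts per modality.
#' @param tau_within Kendall tau on within-modality chain edges.
#' @param tau_cross Kendall tau on the EEG-EMG bridge edge
#'   (`0 <= tau_cross < tau_within`).
#' @param n_samples samples per channel.
#' @param fs sampling rate in Hz.
#' @param seed integer seed fixing the simulation.
#' @param garch_params per-channel marginal truth (recycled to a list).
#' @return An object of class `cmc_scenario`.
#' @export
make_scenario <- function(n_eeg = 8, n_emg = 6, tau_within = 0.5,
                          tau_cross = 0.15, n_samples = 3000, fs = 1000,
                          seed = 1, garch_params = default_garch_truth) {
  if (!(tau_cross >= 0 && tau_cross < tau_within && tau_within < 1))
    stop("need 0 <= tau_cross < tau_within < 1")
  if (n_eeg < 2 || n_emg < 2) stop("need at least 2 channels per modality")
  p <- n_eeg + n_emg
  names <- c(head(eeg_channel_names, n_eeg),
             if (n_eeg > length(eeg_channel_names))
               paste0("EEG", seq_len(n_eeg - length(eeg_channel_names))),
             head(emg_channel_names, n_emg),
             if (n_emg > length(emg_channel_names))
               paste0("EMG", seq_len(n_emg - length(emg_channel_names))))
  modalities <- c(rep("EEG", n_eeg), rep("EMG", n_emg))

  chain <- function(idx) cbind(idx[-length(idx)], idx[-1])
  bridge <- c(ceiling(n_eeg / 2), n_eeg + ceiling(n_emg / 2))
  edges <- rbind(chain(seq_len(n_eeg)),
                 chain(n_eeg + seq_len(n_emg)),
                 bridge)
  taus <- c(rep(tau_within, p - 2), tau_cross)
  copulas <- lapply(taus, function(tt) {
    if (abs(tt) < 1e-12) pair_copula("independence")
    else pair_copula("gaussian", params_from_tau("gaussian", tt))
  })
  vine <- vine_from_tree1(edges, copulas, p, names = names)

  if (is.atomic(garch_params)) garch_params <- rep(list(garch_params), p)
  if (length(garch_params) != p) stop("one GARCH truth per channel required")

  structure(list(n_eeg = n_eeg, n_emg = n_emg, names = names,
                 modalities = modalities, vine_truth = vine,
                 tree1_edges = edges, tree1_taus = taus, bridge = bridge,
                 garch_truth = garch_params, fs = fs,
                 n_samples = n_samples, seed = seed),
            class = "cmc_scenario")
}

#' @export
print.cmc_scenario <- function(x, ...) {
  cat(sprintf("<cmc_scenario> %d EEG + %d EMG channels, %d samples @ %g Hz, seed %d\n",
              x$n_eeg, x$n_emg, x$n_samples, x$fs, x$seed))
  invisible(x)
}

#' Analytic Kendall-tau matrix of a scenario
#'
#' With Gaussian pair copulas on a first tree and independence above, the
#' joint copula is Gaussian with a Markov-tree correlation structure:
#' the correlation of two variables is the product of edge correlations
#' along the connecting path, and tau follows from
#' \eqn{\tau = (2/\pi) \arcsin \rho}.
#'
#' @param sc a `cmc_scenario`.
#' @return symmetric tau matrix with unit diagonal.
#' @export
scenario_tau_matrix <- function(sc) {
  p <- sc$n_eeg + sc$n_emg
  rho_edge <- sin(pi * sc$tree1_taus / 2)
  g <- igraph::graph_from_edgelist(sc$tree1_edges, directed = FALSE)
  igraph::E(g)$rho <- rho_edge
  Tau <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      path <- igraph::shortest_paths(g, i, j, output = "epath")$epath[[1]]
      rho <- prod(igraph::E(g)$rho[as.integer(path)])
      Tau[i, j] <- Tau[j, i] <- 2 / pi * asin(rho)
    }
  }
  dimnames(Tau) <- list(sc$names, sc$names)
  Tau
}

#' Simulate a scenario
#'
#' Samples uniforms from the vine truth, maps each column through the
#' scaled Student-t quantile to unit-variance innovations, and runs the
#' per-channel GARCH recursion (with a burn-in segment discarded).
#'
#' @param sc a `cmc_scenario`.
#' @param burn initial vine-coupled samples discarded per channel.
#' @return list with `cm` (a [channel_matrix()]), `innovations_u` (the
#'   post-burn-in vine uniforms), `true_tau` (analytic tau matrix) and
#'   `true_edges` (first-tree edge matrix).
#' @export
simulate_scenario <- function(sc, burn = 200) {
  U <- sample_rvine(sc$vine_truth, sc$n_samples + burn, seed = sc$seed)
  p <- ncol(U)
  X <- matrix(NA_real_, p, sc$n_samples)
  for (ch in seq_len(p)) {
    prm <- sc$garch_truth[[ch]]
    d <- prm[["dof"]]
    xi <- qt(U[, ch], df = d) * sqrt((d - 2) / d)
    x <- simulate_garch(prm, innovations = xi)
    X[ch, ] <- x[(burn + 1):length(x)]
  }
  cm <- channel_matrix(X, sc$names, sc$modalities, sc$fs)
  list(cm = cm,
       innovations_u = U[(burn + 1):nrow(U), , drop = FALSE],
       true_tau = scenario_tau_matrix(sc),
       true_edges = sc$tree1_edges)
}

#' Expected network implied by a scenario
#'
#' Pushes the analytic tau matrix through block normalization and the
#' average-degree threshold rule: the answer a perfect recovery of the
#' scenario should produce.
#'
#' @param sc a `cmc_scenario`.
#' @param step threshold grid step.
#' @param threshold optional fixed threshold overriding the rule.
#' @return list with `Wn`, `threshold`, binary `A`, `metrics` and
#'   `core_nodes`.
#' @export
true_network <- function(sc, step = 0.05, threshold = NULL) {
  Tau <- scenario_tau_matrix(sc)
  W <- Tau; diag(W) <- 0
  Wn <- normalize_blocks(W, sc$modalities)
  if (is.null(threshold))
    threshold <- threshold_select(list(Wn), step = step)$threshold
  A <- binarize_adjacency(Wn, threshold)
  list(Wn = Wn, threshold = threshold, A = A,
       metrics = graph_metrics(A), core_nodes = core_nodes(A))
}
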