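#' @name granger
#' @title Bivariate spectral Granger causality (Geweke)
#'
#' @description
#' A bivariate VAR is fitted by least squares with AIC lag selection; the
#' spectral matrix \eqn{S(f) = H(f)\,\Sigma\,H(f)^*} follows from the
#' transfer function \eqn{H(f) = (I - \sum_k A_k e^{-2\pi i f k/f_s})^{-1}}
#' and the innovation covariance \eqn{\Sigma}. The Geweke measure
#' \deqn{G_{x\to y}(f) = \ln\frac{S_{yy}(f)}
#'   {|H_{yy}(f)|^2\,(\Sigma_{yy} - \Sigma_{xy}^2/\Sigma_{xx})}}
#' decomposes the power of y into an intrinsic part and the part driven
#' by x (after orthogonalizing the innovations), and symmetrically for
#' \eqn{G_{y\to x}}.
NULL

# Least-squares VAR(p) on a T x k matrix; returns coefficient array and
# innovation covariance (ML scaling).
fit_var <- function(Y, p) {
  Tn <- nrow(Y); k <- ncol(Y)
  Z <- stats::embed(Y, p + 1)
  resp <- Z[, 1:k, drop = FALSE]
  X <- cbind(1, Z[, -(1:k), drop = FALSE])
  B <- qr.solve(X, resp)                      # (1 + k p) x k
  E <- resp - X %*% B
  neff <- nrow(resp)
  Sigma <- crossprod(E) / neff
  A <- array(0, dim = c(k, k, p))
  for (l in seq_len(p))
    A[, , l] <- t(B[1 + ((l - 1) * k + 1):(l * k), , drop = FALSE])
  list(A = A, Sigma = Sigma, const = B[1, ], neff = neff,
       aic = log(det(Sigma)) + 2 * p * k^2 / neff)
}

var_stable <- function(A) {
  k <- dim(A)[1]; p <- dim(A)[3]
  comp <- matrix(0, k * p, k * p)
  for (l in seq_len(p))
    comp[1:k, ((l - 1) * k + 1):(l * k)] <- A[, , l]
  if (p > 1)
    comp[(k + 1):(k * p), 1:(k * (p - 1))] <- diag(k * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}

#' Spectral Granger causality between two series
#'
#' @param x,y univariate numeric series of equal length (>= 200).
#' @param fs sampling rate in Hz.
#' @param max_order maximum VAR lag order; the order minimizing AIC is
#'   used.
#' @param band frequency band (Hz) over which the scalar measures average;
#'   defaults to the 8-30 Hz sensorimotor range.
#' @param n_freq number of frequency-grid points on \[0, fs/2\].
#' @return An object of class `granger_result`: `order`, `freqs`,
#'   curves `gc_xy`/`gc_yx`, band means `gc_xy_scalar`/`gc_yx_scalar`,
#'   auto-spectra `Sxx`/`Syy`, `noise_cov`, and transfer magnitudes `H`.
#' @export
spectral_gc <- function(x, y, fs = 1000, max_order = 20, band = c(8, 30),
                        n_freq = 256) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 200) stop("need at least 200 samples")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite input")
  Y <- cbind(x - mean(x), y - mean(y))

  fits <- lapply(seq_len(max_order), function(p) fit_var(Y, p))
  aics <- vapply(fits, `[[`, 0, "aic")
  p <- which.min(aics)
  fit <- fits[[p]]
  if (var_stable(fit$A) >= 1)
    stop("estimated VAR is unstable (root on or inside the unit circle)")

  Sig <- fit$Sigma
  freqs <- seq(0, fs / 2, length.out = n_freq)
  gc_xy <- numeric(n_freq); gc_yx <- numeric(n_freq)
  Sxx <- numeric(n_freq); Syy <- numeric(n_freq)
  Hxx <- numeric(n_freq); Hyy <- numeric(n_freq)
  s2y_part <- Sig[2, 2] - Sig[1, 2]^2 / Sig[1, 1]
  s2x_part <- Sig[1, 1] - Sig[1, 2]^2 / Sig[2, 2]
  for (i in seq_len(n_freq)) {
    Af <- diag(2) + 0i
    for (l in seq_len(p))
      Af <- Af - fit$A[, , l] * exp(-2i * pi * freqs[i] * l / fs)
    H <- solve(Af)
    S <- H %*% Sig %*% Conj(t(H))
    Sxx[i] <- Re(S[1, 1]); Syy[i] <- Re(S[2, 2])
    Hxx[i] <- Mod(H[1, 1]); Hyy[i] <- Mod(H[2, 2])
    gc_xy[i] <- max(0, Re(log(Syy[i] / (Mod(H[2, 2])^2 * s2y_part))))
    gc_yx[i] <- max(0, Re(log(Sxx[i] / (Mod(H[1, 1])^2 * s2x_part))))
  }
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band)) stop("band contains no frequency-grid point")
  structure(list(order = p, freqs = freqs, gc_xy = gc_xy, gc_yx = gc_yx,
                 gc_xy_scalar = mean(gc_xy[in_band]),
                 gc_yx_scalar = mean(gc_yx[in_band]),
                 Sxx = Sxx, Syy = Syy, noise_cov = Sig,
                 H = list(Hxx = Hxx, Hyy = Hyy), band = band, fs = fs),
            class = "granger_result")
}

#' @export
print.granger_result <- function(x, ...) {
  cat(sprintf("<granger_result> VAR(%d): band %g-%g Hz  x->y %.4f  y->x %.4f\n",
              x$order, x$band[1], x$band[2], x$gc_xy_scalar, x$gc_yx_scalar))
  invisible(x)
}

#' Time-domain Granger causality
#'
#' Geweke's time-domain measure \eqn{\ln(\sigma^2_{restricted} /
#' \sigma^2_{full})}: log ratio of the innovation variance of y from a
#' univariate AR(p) against the bivariate VAR(p). By Geweke's identity it
#' equals the average of the spectral measure over the full frequency
#' range.
#'
#' @param x,y series; the measure is for x driving y.
#' @param order AR/VAR order.
#' @return scalar measure (>= 0 up to estimation noise).
#' @export
time_domain_gc <- function(x, y, order) {
  Y <- cbind(x - mean(x), y - mean(y))
  full <- fit_var(Y, order)
  Zr <- stats::embed(Y[, 2], order + 1)
  Xr <- cbind(1, Zr[, -1, drop = FALSE])
  er <- Zr[, 1] - Xr %*% qr.solve(Xr, Zr[, 1])
  s2r <- sum(er^2) / length(er)
  log(s2r / full$Sigma[2, 2])
}

#' Pairwise spectral-GC weight matrix
#'
#' Band-mean Geweke measures for every ordered channel pair; entry (i, j)
#' is the influence of channel i on channel j. Optionally symmetrized by
#' the elementwise maximum for undirected network construction.
#'
#' @param cm a [channel_matrix()] (preprocessed).
#' @param max_order,band,n_freq passed to [spectral_gc()].
#' @param symmetrize return `max(G[i,j], G[j,i])` in both cells.
#' @return a square matrix with zero diagonal.
#' @export
gc_matrix <- function(cm, max_order = 20, band = c(8, 30), n_freq = 256,
                      symmetrize = FALSE) {
  stopifnot(inherits(cm, "channel_matrix"))
  n <- nrow(cm$data)
  G <- matrix(0, n, n, dimnames = list(cm$channel_ids, cm$channel_ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- tryCatch(
        spectral_gc(cm$data[i, ], cm$data[j, ], fs = cm$fs,
                    max_order = max_order, band = band, n_freq = n_freq),
        error = function(e)
          stop("spectral GC failed for pair (", cm$channel_ids[i], ", ",
               cm$channel_ids[j], "): ", conditionMessage(e)))
      G[i, j] <- r$gc_xy_scalar
      G[j, i] <- r$gc_yx_scalar
    }
  }
  if (symmetrize) G <- pmax(G, t(G))
  diag(G) <- 0
  G
}
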