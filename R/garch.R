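#' @name garch
#' @title AR(1) + GJR-GARCH(1,1) margins with Student-t innovations
#'
#' @description
#' Each channel is modelled as
#' \deqn{x_t = c_0 + c_1 x_{t-1} + a_t, \quad a_t = \sigma_t \xi_t,}
#' \deqn{\sigma_t^2 = \omega + \alpha a_{t-1}^2 + \gamma a_{t-1}^2
#'   1\{a_{t-1} < 0\} + \beta \sigma_{t-1}^2,}
#' with \eqn{\xi_t} a unit-variance Student-t innovation with `dof`
#' degrees of freedom (the raw t variate scaled by
#' \eqn{\sqrt{(d-2)/d}}), so that \eqn{\sigma_t^2} is the conditional
#' variance. The leverage indicator multiplies \eqn{\gamma} only after
#' negative residuals, the usual GJR asymmetry. Standardized residuals are
#' mapped to uniform margins by the Student-t probability integral
#' transform.
NULL

garch_par_names <- c("c0", "c1", "omega", "alpha", "beta", "gamma", "dof")

# Admissibility: positivity, covariance stationarity (symmetric
# innovations give E[1{a<0}] = 1/2, hence the gamma/2 term), d > 2.
garch_admissible <- function(p) {
  p["omega"] > 0 && p["alpha"] >= 0 && p["beta"] >= 0 &&
    p["alpha"] + p["gamma"] >= 0 &&
    p["alpha"] + p["beta"] + p["gamma"] / 2 < 1 &&
    p["dof"] > 2 && abs(p["c1"]) < 1
}

# Mean-equation residuals and conditional variance recursion.
# Returns list(a, sigma2) of length n-1 (one observation lost to the lag);
# sigma2[1] is initialized at the sample variance of the residuals.
garch_recursion <- function(p, x) {
  n <- length(x)
  a <- x[-1] - p[["c0"]] - p[["c1"]] * x[-n]
  m <- length(a)
  s2_1 <- stats::var(a)
  if (m < 2) return(list(a = a, sigma2 = rep(s2_1, m)))
  drive <- p[["omega"]] +
    (p[["alpha"]] + p[["gamma"]] * (a[-m] < 0)) * a[-m]^2
  s2 <- c(s2_1, stats::filter(drive, p[["beta"]], method = "recursive",
                              init = s2_1))
  list(a = a, sigma2 = as.numeric(s2))
}

# Log density of the unit-variance Student-t.
dstdt <- function(z, dof, log = TRUE) {
  s <- sqrt(dof / (dof - 2))
  out <- stats::dt(z * s, df = dof, log = TRUE) + log(s)
  if (log) out else exp(out)
}

#' GARCH log-likelihood
#'
#' Log-likelihood of the AR(1)+GJR-GARCH(1,1)-t model for a parameter
#' vector `(c0, c1, omega, alpha, beta, gamma, dof)`. Inadmissible
#' parameters (violating positivity, the stationarity bound
#' \eqn{\alpha+\beta+\gamma/2<1}, or `dof <= 2`) return `-Inf` rather
#' than raising an error, so optimizers can reject them.
#'
#' @param params numeric vector of length 7, optionally named as above.
#' @param x univariate numeric series.
#' @return scalar log-likelihood.
#' @export
garch_loglik <- function(params, x) {
  p <- stats::setNames(as.numeric(params), garch_par_names)
  if (!all(is.finite(p)) || !garch_admissible(p)) return(-Inf)
  .garch_loglik_cpp(unname(p), as.numeric(x))
}

# Unconstrained <-> natural parameter transforms used by the optimizer.
garch_to_natural <- function(psi, scale) {
  c(c0 = psi[1] * scale,
    c1 = tanh(psi[2]),
    omega = exp(psi[3]) * scale^2,
    alpha = exp(psi[4]),
    beta = exp(psi[5]),
    gamma = exp(psi[6]),
    dof = 2.1 + exp(psi[7]))
}
garch_to_psi <- function(p, scale) {
  c(p[["c0"]] / scale, atanh(p[["c1"]]), log(p[["omega"]] / scale^2),
    log(max(p[["alpha"]], 1e-6)), log(max(p[["beta"]], 1e-6)),
    log(max(p[["gamma"]], 1e-6)), log(p[["dof"]] - 2.1))
}

#' Fit the AR(1)+GJR-GARCH(1,1)-t model
#'
#' Maximum likelihood with a Nelder-Mead search on transformed
#' (unconstrained) parameters from three fixed starting points, keeping
#' the best optimum. Stationarity is enforced by a smooth penalty;
#' standard errors come from the numerical Hessian at the optimum in the
#' natural parameter space.
#'
#' @param x univariate numeric series (at least 100 observations
#'   recommended; 500 or more for stable variance-equation estimates).
#' @return An object of class `garch_marginal`: fitted parameters `params`,
#'   standard errors `se`, conditional variances `sigma2`, residuals
#'   `resid`, standardized residuals `std_resid`, the PIT series `pit`,
#'   `loglik`, `aic`, `bic` and a `converged` flag.
#' @export
fit_garch <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 50) stop("series too short to fit a GARCH model")
  if (!all(is.finite(x))) stop("non-finite values in series")
  if (stats::sd(x) < 1e-12) stop("constant series: zero variance")
  scale <- stats::sd(x)

  # moment-based AR(1) start
  c1_0 <- stats::cor(x[-1], x[-length(x)])
  c1_0 <- max(min(c1_0, 0.95), -0.95)
  c0_0 <- mean(x) * (1 - c1_0)
  v <- stats::var(x - mean(x))
  starts <- list(
    c(c0 = c0_0, c1 = c1_0, omega = 0.10 * v, alpha = 0.05, beta = 0.85,
      gamma = 0.02, dof = 8),
    c(c0 = c0_0, c1 = c1_0, omega = 0.45 * v, alpha = 0.10, beta = 0.50,
      gamma = 0.05, dof = 6),
    c(c0 = c0_0, c1 = 0,    omega = 0.90 * v, alpha = 0.02, beta = 0.10,
      gamma = 0.01, dof = 12)
  )

  nll_psi <- function(psi) {
    p <- garch_to_natural(psi, scale)
    persist <- p[["alpha"]] + p[["beta"]] + p[["gamma"]] / 2
    if (!is.finite(persist)) return(1e10)
    if (persist >= 0.9999)
      return(1e8 + 1e8 * (persist - 0.9999))
    ll <- garch_loglik(p, x)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  # short probe from each start, then a long polish from the best
  best <- NULL
  for (s in starts) {
    psi0 <- garch_to_psi(s, scale)
    opt <- tryCatch(
      stats::optim(psi0, nll_psi, method = "Nelder-Mead",
                   control = list(maxit = 400, reltol = 1e-8)),
      error = function(e) NULL)
    if (is.null(opt)) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best)) stop("GARCH optimization failed from every start")
  # polish until Nelder-Mead reports convergence (restarts rebuild the
  # simplex around the current optimum, escaping degenerate simplices)
  for (round in 1:5) {
    best <- stats::optim(best$par, nll_psi, method = "Nelder-Mead",
                         control = list(maxit = 2500, reltol = 1e-10))
    if (best$convergence == 0) break
  }

  p <- garch_to_natural(best$par, scale)
  converged <- best$convergence == 0 && garch_admissible(p) &&
    p[["alpha"]] + p[["beta"]] + p[["gamma"]] / 2 < 0.9999

  # SEs from the observed information in natural parameters
  se <- rep(NA_real_, 7)
  H <- tryCatch(
    stats::optimHess(unname(p), function(q) {
      ll <- garch_loglik(q, x)
      if (is.finite(ll)) -ll else 1e10
    }),
    error = function(e) NULL)
  if (!is.null(H)) {
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      dv <- diag(V)
      se <- sqrt(pmax(dv, 0))
      se[dv <= 0] <- NA_real_
    }
  }
  names(se) <- garch_par_names

  r <- garch_recursion(p, x)
  z <- r$a / sqrt(r$sigma2)
  ll <- garch_loglik(p, x)
  k <- 7
  m <- structure(
    list(params = p, se = se, sigma2 = r$sigma2, resid = r$a,
         std_resid = z, loglik = ll,
         aic = -2 * ll + 2 * k, bic = -2 * ll + k * log(length(z)),
         converged = converged, n = length(x),
         x_last = x[length(x)]),
    class = "garch_marginal")
  m$pit <- pit_transform(m, check_converged = FALSE)
  m
}

#' @export
print.garch_marginal <- function(x, ...) {
  cat("<garch_marginal> AR(1)+GJR-GARCH(1,1)-t, loglik",
      sprintf("%.2f,", x$loglik),
      if (x$converged) "converged" else "NOT converged", "\n")
  print(round(x$params, 4))
  invisible(x)
}

#' One-step-ahead conditional CDF
#'
#' Probability that the next observation is at most `x_next`, given the
#' fitted model's state at the end of the series: the Student-t CDF of
#' the standardized one-step innovation with the variance recursion
#' advanced one step.
#'
#' @param m a fitted `garch_marginal`.
#' @param x_next scalar (or vector of) candidate next values.
#' @return probabilities in (0, 1).
#' @export
conditional_cdf <- function(m, x_next) {
  if (!inherits(m, "garch_marginal")) stop("m must be a fitted garch_marginal")
  p <- m$params
  n <- length(m$resid)
  a_n <- m$resid[n]
  s2_next <- p[["omega"]] +
    (p[["alpha"]] + p[["gamma"]] * (a_n < 0)) * a_n^2 +
    p[["beta"]] * m$sigma2[n]
  z <- (x_next - p[["c0"]] - p[["c1"]] * m$x_last) / sqrt(s2_next)
  stats::pt(z * sqrt(p[["dof"]] / (p[["dof"]] - 2)), df = p[["dof"]])
}

#' Probability integral transform of standardized residuals
#'
#' Maps standardized residuals through the CDF of the fitted
#' unit-variance Student-t innovation, yielding an approximately uniform
#' series on (0,1), clipped away from the boundary.
#'
#' @param m a fitted `garch_marginal`.
#' @param check_converged error when the fit did not converge.
#' @return numeric vector in (0, 1), same length as `m$std_resid`.
#' @export
pit_transform <- function(m, check_converged = TRUE) {
  if (!inherits(m, "garch_marginal")) stop("m must be a fitted garch_marginal")
  if (check_converged && !isTRUE(m$converged))
    stop("model did not converge; refusing to transform")
  d <- m$params[["dof"]]
  clip01(stats::pt(m$std_resid * sqrt(d / (d - 2)), df = d))
}

#' Simulate from the AR(1)+GJR-GARCH(1,1)-t model
#'
#' Runs the variance recursion forward from the unconditional variance.
#' Innovations can be supplied (e.g. vine-coupled uniforms mapped through
#' the t quantile) or drawn i.i.d.
#'
#' @param params parameter vector `(c0, c1, omega, alpha, beta, gamma, dof)`.
#' @param n number of samples (ignored when `innovations` is given).
#' @param innovations optional vector of unit-variance innovations.
#' @param burn extra initial samples discarded (only when innovations are
#'   drawn internally).
#' @return numeric series of length `n` (or `length(innovations)`).
#' @export
simulate_garch <- function(params, n = 3000, innovations = NULL, burn = 200) {
  p <- stats::setNames(as.numeric(params), garch_par_names)
  if (!garch_admissible(p)) stop("inadmissible GARCH parameters")
  if (is.null(innovations)) {
    d <- p[["dof"]]
    innovations <- stats::rt(n + burn, df = d) * sqrt((d - 2) / d)
  } else burn <- 0
  m <- length(innovations)
  s2 <- numeric(m); a <- numeric(m); x <- numeric(m)
  s2[1] <- p[["omega"]] / (1 - p[["alpha"]] - p[["beta"]] - p[["gamma"]] / 2)
  a[1] <- sqrt(s2[1]) * innovations[1]
  x[1] <- p[["c0"]] / (1 - p[["c1"]]) + a[1]
  for (t in 2:m) {
    s2[t] <- p[["omega"]] +
      (p[["alpha"]] + p[["gamma"]] * (a[t - 1] < 0)) * a[t - 1]^2 +
      p[["beta"]] * s2[t - 1]
    a[t] <- sqrt(s2[t]) * innovations[t]
    x[t] <- p[["c0"]] + p[["c1"]] * x[t - 1] + a[t]
  }
  if (burn > 0) x <- x[-seq_len(burn)]
  x
}
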