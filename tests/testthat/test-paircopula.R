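test_that("pair_copula validates construction", {
  pc <- pair_copula("gaussian", c(rho = 0.5))
  expect_s3_class(pc, "pair_copula")
  expect_equal(pc$tau, tau_from_params("gaussian", c(rho = 0.5)))
  expect_output(print(pc), "gaussian")
  expect_error(pair_copula("gaussian", c(rho = 1.5)))
  expect_error(pair_copula("clayton", c(theta = -1)))
  expect_error(pair_copula("gumbel", c(theta = 0.5)))
  expect_error(pair_copula("student_t", c(rho = 0.3, nu = 1.5)))
  expect_error(pair_copula("gaussian", c(rho = 0.5), rotation = 45))
  expect_error(pair_copula("banana", c(theta = 1)))
})

test_that("tau closed forms invert and match large-sample empirical tau", {
  for (fam in c("gaussian", "clayton", "gumbel", "frank")) {
    for (tt in c(0.2, 0.5, 0.7)) {
      prm <- params_from_tau(fam, tt)
      expect_equal(tau_from_params(fam, prm), tt, tolerance = 1e-8,
                   label = fam)
    }
  }
  set.seed(41)
  for (pc in list(pair_copula("clayton", c(theta = 2)),
                  pair_copula("gumbel", c(theta = 2.5)),
                  pair_copula("frank", c(theta = 6)),
                  pair_copula("student_t", c(rho = 0.6, nu = 5)))) {
    UV <- sample_pair_copula(pc, 4000)
    expect_equal(empirical_kendall_tau(UV[, 1], UV[, 2]), pc$tau,
                 tolerance = 0.05, label = pc$family)
  }
})

test_that("empirical Kendall tau matches the naive oracle, with ties", {
  set.seed(43)
  x <- rnorm(60); y <- 0.5 * x + rnorm(60)
  expect_equal(empirical_kendall_tau(x, y), naive_kendall_tau(x, y),
               tolerance = 1e-12)
  xt <- sample(1:5, 80, TRUE); yt <- sample(1:4, 80, TRUE)
  expect_equal(empirical_kendall_tau(xt, yt), naive_kendall_tau(xt, yt),
               tolerance = 1e-12)
  expect_equal(empirical_kendall_tau(x, -y), -empirical_kendall_tau(x, y),
               tolerance = 1e-12)
})

test_that("tau_matrix is symmetric with unit diagonal and flags constants", {
  set.seed(47)
  U <- matrix(runif(300), ncol = 3)
  Tm <- tau_matrix(U)
  expect_true(isSymmetric(Tm))
  expect_equal(diag(Tm), rep(1, 3), ignore_attr = TRUE)
  expect_equal(Tm[1, 2], naive_kendall_tau(U[, 1], U[, 2]), tolerance = 1e-12)
  Uc <- cbind(U, 0.5)
  expect_error(tau_matrix(Uc), "constant")
})

test_that("copula densities integrate to one", {
  gl <- vinecmc:::gauss_legendre01(60)
  for (pc in all_test_copulas()) {
    vals <- outer(gl$nodes, gl$nodes,
                  function(u, v) copula_pdf(pc, u, v))
    integral <- as.numeric(gl$weights %*% vals %*% gl$weights)
    expect_equal(integral, 1, tolerance = 5e-3,
                 label = paste(pc$family, pc$rotation))
  }
})

test_that("copula_cdf has uniform margins and Frechet bounds", {
  u <- seq(0.05, 0.95, by = 0.15)
  for (pc in all_test_copulas()) {
    lbl <- paste(pc$family, pc$rotation)
    expect_equal(copula_cdf(pc, u, rep(1, length(u))), u,
                 tolerance = 1e-6, label = lbl)
    expect_equal(copula_cdf(pc, rep(1, length(u)), u), u,
                 tolerance = 1e-6, label = lbl)
    expect_lt(max(abs(copula_cdf(pc, u, rep(1e-9, length(u))))), 1e-6)
    grid <- expand.grid(u = u, v = u)
    cc <- copula_cdf(pc, grid$u, grid$v)
    expect_true(all(cc <= pmin(grid$u, grid$v) + 1e-8), label = lbl)
    expect_true(all(cc >= pmax(grid$u + grid$v - 1, 0) - 1e-8), label = lbl)
  }
})

test_that("h_inverse inverts h_function on random points", {
  set.seed(53)
  u <- runif(200, 0.01, 0.99); v <- runif(200, 0.01, 0.99)
  for (pc in all_test_copulas()) {
    h <- h_function(pc, u, v)
    expect_true(all(h >= 0 & h <= 1))
    back <- h_inverse(pc, h, v)
    expect_equal(back, u, tolerance = 1e-7,
                 label = paste(pc$family, pc$rotation))
  }
})

test_that("quadrature tau identity matches closed forms", {
  for (pc in list(pair_copula("gaussian", c(rho = 0.5)),
                  pair_copula("clayton", c(theta = 2)),
                  pair_copula("gumbel", c(theta = 3)),
                  pair_copula("frank", c(theta = 5)),
                  pair_copula("clayton", c(theta = 1.5), rotation = 90))) {
    expect_equal(tau_copula_integral(pc), pc$tau, tolerance = 1e-4,
                 label = paste(pc$family, pc$rotation))
  }
})

test_that("rotations act as expected on tau and density mass", {
  pc0 <- pair_copula("clayton", c(theta = 2))
  pc90 <- pair_copula("clayton", c(theta = 2), rotation = 90)
  pc180 <- pair_copula("clayton", c(theta = 2), rotation = 180)
  expect_equal(pc90$tau, -pc0$tau, tolerance = 1e-12)
  expect_equal(pc180$tau, pc0$tau, tolerance = 1e-12)
  # survival copula density is the point reflection of the base density
  expect_equal(copula_pdf(pc180, 0.3, 0.2), copula_pdf(pc0, 0.7, 0.8),
               tolerance = 1e-12)
  expect_equal(copula_pdf(pc90, 0.3, 0.2), copula_pdf(pc0, 0.7, 0.2),
               tolerance = 1e-12)
})

test_that("fit_pair_copula recovers the generating family", {
  set.seed(59)
  cases <- list(pair_copula("clayton", c(theta = 3)),
                pair_copula("gumbel", c(theta = 3)),
                pair_copula("gaussian", c(rho = 0.7)),
                pair_copula("clayton", c(theta = 2.5), rotation = 90))
  for (pc in cases) {
    UV <- sample_pair_copula(pc, 1500)
    fit <- fit_pair_copula(UV[, 1], UV[, 2])
    expect_identical(fit$family, pc$family, label = pc$family)
    expect_identical(fit$rotation, pc$rotation)
    expect_equal(fit$params[[1]], pc$params[[1]], tolerance = 0.25)
  }
})

test_that("independence is selected for independent data under BIC", {
  set.seed(61)
  u <- runif(800); v <- runif(800)
  fit <- fit_pair_copula(u, v, criterion = "bic")
  expect_identical(fit$family, "independence")
})

test_that("fit_pair_copula validates inputs", {
  expect_error(fit_pair_copula(c(0.1, 0.5), c(0.2, 1.5)))
  expect_error(fit_pair_copula(runif(50), runif(49)))
  expect_error(fit_pair_copula(runif(100), runif(100), criterion = "hic"))
})
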