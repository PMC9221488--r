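test_that("max_spanning_tree matches brute force on a fixed matrix", {
  W <- matrix(c(0, .9, .1, .2,
                .9, 0, .8, .3,
                .1, .8, 0, .7,
                .2, .3, .7, 0), 4, 4)
  mst <- max_spanning_tree(W)
  best <- NULL; bw <- -Inf
  for (tr in all_spanning_trees(4)) {
    w <- tree_weight(tr, W)
    if (w > bw) { bw <- w; best <- tr }
  }
  expect_equal(sort(tree_weight(mst, W)), bw, tolerance = 1e-12)
  expect_identical(edge_key(mst), edge_key(best))
})

test_that("max_spanning_tree reports disconnection", {
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 1] <- 1
  W[3, 4] <- W[4, 3] <- 1
  allowed <- W > 0
  expect_error(max_spanning_tree(W, allowed = allowed), "connect")
})

test_that("build_rvine fits a valid model and beats independence", {
  set.seed(67)
  tv <- recovery_vine5()
  U <- sample_rvine(tv$vine, 1200, seed = 7)
  vm <- build_rvine(U, candidates = c("independence", "gaussian"))
  expect_s3_class(vm, "vine_model")
  expect_true(validate_rvine(vm))
  expect_length(vm$trees, 4)
  expect_length(vm$trees[[1]], 4)
  expect_length(vm$trees[[4]], 1)
  expect_gt(vm$loglik, 0)
  expect_equal(vm$aic, -2 * vm$loglik +
                 2 * sum(vapply(unlist(vm$trees, recursive = FALSE),
                                function(e) length(e$copula$params), 0L)))
  expect_output(print(vm), "vine_model")
})

test_that("3-variable gaussian vine density matches the MVN copula", {
  rho12 <- 0.6; rho23 <- 0.5
  # partial correlation zero => conditional pair is independence
  cops <- list(pair_copula("gaussian", c(rho = rho12)),
               pair_copula("gaussian", c(rho = rho23)))
  vm <- vinecmc:::vine_from_tree1(rbind(c(1, 2), c(2, 3)), cops, 3)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- rho12
  R[2, 3] <- R[3, 2] <- rho23
  R[1, 3] <- R[3, 1] <- rho12 * rho23
  set.seed(71)
  U <- matrix(runif(60), ncol = 3)
  expect_equal(vine_log_density(vm, U), mvn3_copula_logdensity(R, U),
               tolerance = 1e-8)
})

test_that("sampling is seed-deterministic and recovers tau", {
  tv <- recovery_vine5()
  U1 <- sample_rvine(tv$vine, 500, seed = 3)
  U2 <- sample_rvine(tv$vine, 500, seed = 3)
  expect_identical(U1, U2)
  U3 <- sample_rvine(tv$vine, 500, seed = 4)
  expect_false(identical(U1, U3))
  U <- sample_rvine(tv$vine, 4000, seed = 9)
  expect_true(all(U > 0 & U < 1))
  emp <- tau_matrix(U)
  for (k in seq_len(nrow(tv$edges)))
    expect_equal(emp[tv$edges[k, 1], tv$edges[k, 2]], tv$taus[k],
                 tolerance = 0.05)
})

test_that("truncation fills higher trees with independence", {
  set.seed(73)
  tv <- recovery_vine5()
  U <- sample_rvine(tv$vine, 800, seed = 11)
  vm <- build_rvine(U, candidates = c("independence", "gaussian"),
                    trunc_level = 1)
  fams <- unlist(lapply(vm$trees[-1], function(tr)
    vapply(tr, function(e) e$copula$family, "")))
  expect_true(all(fams == "independence"))
  expect_true(validate_rvine(vm))
})

test_that("vine_from_tree1 builds a proximity-valid vine", {
  tv <- recovery_vine5()
  expect_true(validate_rvine(tv$vine))
  expect_identical(edge_key(do.call(rbind, lapply(tv$vine$trees[[1]],
                                                  function(e) e$conditioned))),
                   edge_key(tv$edges))
})

test_that("first_tree_summary reports modalities, bridges and cores", {
  tv <- recovery_vine5()
  mods <- c("EEG", "EEG", "EEG", "EMG", "EMG")
  s <- first_tree_summary(tv$vine, mods)
  expect_s3_class(s$edges, "data.frame")
  expect_equal(nrow(s$edges), 4)
  expect_equal(sum(s$edges$bridge), 1)  # single EEG-EMG crossing: 2-4
  expect_setequal(names(which(s$degree == max(s$degree))),
                  unname(s$core_nodes))
})

test_that("build_rvine validates its input", {
  expect_error(build_rvine(matrix(runif(10), ncol = 1)))
  expect_error(build_rvine(matrix(c(runif(99), 1.7), ncol = 2)))
})
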