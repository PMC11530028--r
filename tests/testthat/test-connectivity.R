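test_that("exclusion masks follow Euclidean distance on the geometry", {
  geom <- cbind(c(0, 1, 0, 1, 5), c(0, 0, 1, 1, 5))
  m0 <- build_exclusion_mask(geom, radius = 0)
  expect_equal(unclass(m0), diag(5) == 1, ignore_attr = TRUE)

  mInf <- build_exclusion_mask(geom, radius = Inf)
  expect_true(all(mInf))

  # unit grid, radius 1: rook neighbors excluded, diagonal neighbor kept
  m1 <- build_exclusion_mask(geom, radius = 1)
  expect_true(m1[1, 2] && m1[1, 3])   # distance 1
  expect_false(m1[1, 4])              # distance sqrt(2)
  expect_false(m1[1, 5])
})

test_that("combinedFC removes chain and collider spurious edges", {
  set.seed(21)
  ok_chain <- ok_coll <- 0
  for (k in 1:20) {
    Wc <- matrix(0, 3, 3); Wc[2, 1] <- 1; Wc[3, 2] <- 1   # X -> Y -> Z
    fc <- combinedfc(sem_sim(Wc, 2000))
    if (fc$weights[1, 3] == 0 && fc$weights[3, 1] == 0) ok_chain <- ok_chain + 1
    Wk <- matrix(0, 3, 3); Wk[3, 1] <- 1; Wk[3, 2] <- 1   # X -> Z <- Y
    fc <- combinedfc(sem_sim(Wk, 2000))
    if (fc$weights[1, 2] == 0 && fc$weights[2, 1] == 0) ok_coll <- ok_coll + 1
  }
  expect_gte(ok_chain, 19)
  expect_gte(ok_coll, 19)
})

test_that("combinedFC recovers a known 2-unit weight", {
  set.seed(22)
  W <- matrix(0, 2, 2); W[2, 1] <- 0.5
  fc <- combinedfc(sem_sim(W, 5000))
  expect_lt(abs(fc$weights[2, 1] - 0.5), 0.05)
})

test_that("combinedFC output respects mask, diagonal, and stage nesting", {
  set.seed(23)
  cfg <- tiny_config(seed = 23, n_timepoints_rest = 400)
  m <- generate_ground_truth(cfg)
  rest <- simulate_rest(m, cfg)[[1]]
  mask <- build_exclusion_mask(m$geometry, radius = 1)
  fc <- combinedfc(rest, mask = mask)
  expect_true(all(diag(fc$weights) == 0))
  expect_true(all(fc$weights[unclass(mask)] == 0))
  # stage 2 only ever removes stage-1 edges
  expect_true(all(fc$skeleton <= fc$skeleton_stage1))
  expect_lte(sum(fc$weights != 0), sum(fc$skeleton_stage1))
})

test_that("stage-3 weights converge to the true target rows on SEM data", {
  cfg <- sim_config(seed = 24, n_participants = 1, n_timepoints_rest = 5000,
                    n_runs_rest = 2)
  m <- generate_ground_truth(cfg)
  rest <- simulate_rest(m, cfg)[[1]]
  fc <- combinedfc(rest)
  cxu <- complex_units(m)
  rel <- sqrt(sum((fc$weights[cxu, ] - m$weights[cxu, ])^2) /
                sum(m$weights[cxu, ]^2))
  expect_lt(rel, 0.1)
})

test_that("combinedFC rejects degenerate inputs", {
  expect_error(combinedfc(matrix(rnorm(100), 10, 10)), "more time points")
  x <- matrix(rnorm(60), 3, 20)
  x <- rbind(x, x[1, ])               # duplicated unit -> singular covariance
  expect_error(combinedfc(x), "regularized")
})

test_that("lasso penalty limits reduce to zero and OLS solutions", {
  set.seed(25)
  x <- matrix(rnorm(12 * 300), 12, 300)
  expect_true(all(lasso_row(x, 1, penalty = 1e6) == 0))
  r0 <- lasso_row(x, 1, penalty = 0)
  ols <- lm.fit(cbind(1, t(x[-1, ])), x[1, ])$coefficients[-1]
  expect_equal(r0[-1], unname(ols), tolerance = 1e-5)
  expect_equal(r0[1], 0)
})

test_that("regularized FC recovers sparse support across runs", {
  set.seed(26)
  p <- 201
  beta <- numeric(p); beta[2:6] <- c(0.8, -0.6, 0.7, 0.5, -0.9)
  mkrun <- function(nt) {
    X <- matrix(rnorm(p * nt), p, nt)
    X[1, ] <- crossprod(X[-1, , drop = FALSE], beta[-1]) + rnorm(nt)
    X
  }
  fc <- regularized_fc(list(mkrun(300), mkrun(300)), targets = 1)
  est <- which(fc$weights[1, ] != 0)
  tp <- length(intersect(est, 2:6))
  f1 <- 2 * tp / (length(est) + 5)
  expect_gte(f1, 0.8)
  expect_equal(fc$weights[1, 1], 0)

  expect_error(regularized_fc(list(mkrun(100))), "two resting-state runs")
})

test_that("regularized FC warns on a constant target series", {
  set.seed(27)
  r1 <- matrix(rnorm(5 * 50), 5, 50); r2 <- matrix(rnorm(5 * 50), 5, 50)
  r1[2, ] <- 0; r2[2, ] <- 0
  expect_warning(fc <- regularized_fc(list(r1, r2), targets = 2),
                 "constant")
  expect_true(all(fc$weights[2, ] == 0))
})
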