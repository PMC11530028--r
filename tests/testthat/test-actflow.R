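test_that("activity-flow mapping is the connectivity-weighted sum", {
  # 4 units: target 4 mapped from sources 1-3
  W <- matrix(0, 4, 4)
  W[4, 1:3] <- c(0.5, 1.0, -2.0)
  act <- matrix(c(2, -1, 0.5, 99), 4, 1)   # target's own value must not enter
  mp <- map_activity(act, W, targets = 4)
  expect_equal(as.numeric(mp$mapped), 2 * 0.5 + (-1) * 1.0 + 0.5 * (-2.0))

  # zero sources map to zero
  expect_equal(as.numeric(map_activity(act * 0, W, targets = 4)$mapped), 0)

  # linearity: map(a + b) = map(a) + map(b)
  a <- matrix(rnorm(4), 4, 1); b <- matrix(rnorm(4), 4, 1)
  expect_equal(map_activity(a + b, W, targets = 4)$mapped,
               map_activity(a, W, targets = 4)$mapped +
                 map_activity(b, W, targets = 4)$mapped)
})

test_that("flow products sum exactly to the mapped value", {
  set.seed(31)
  W <- matrix(rnorm(36), 6, 6); diag(W) <- 0
  act <- matrix(rnorm(18), 6, 3)
  mp <- map_activity(act, W, targets = c(2, 5))
  expect_equal(apply(mp$flows, c(1, 3), sum), unname(mp$mapped))
})

test_that("a target never appears in its own explicit source set", {
  W <- matrix(1, 3, 3); diag(W) <- 0
  act <- matrix(1, 3, 2)
  expect_error(map_activity(act, W, targets = 2, sources = c(1, 2)),
               "circularity")
  # default all-other-units filter silently excludes the target
  mp <- map_activity(act, W, targets = 2)
  expect_equal(as.numeric(mp$mapped), c(2, 2))
})

test_that("exact generative recovery holds with ground-truth weights", {
  fx <- get_noiseless(local_fraction = 0)
  cxu <- complex_units(fx$model)
  mp <- map_activity(fx$data$truth_activations[[1]], fx$model$weights,
                     targets = cxu)
  expect_lt(max(abs(mp$mapped - fx$data$truth_activations[[1]][cxu, ])),
            1e-10)
})

test_that("V1-initialized mapping centers the mapped category condition", {
  # single V1 source: mapped = w * (a - mean) = 0 when it is the only vertex
  W <- matrix(0, 3, 3); W[3, 1] <- 2
  act <- matrix(c(5, 0, 0), 3, 1)
  mp <- v1_initialized_map(act, W, v1_units = 1, targets = 3,
                           center_conditions = 1)
  expect_equal(as.numeric(mp), 0)

  # two V1 sources, activations [3, 1] (mean 2)
  W2 <- matrix(0, 4, 4)
  act2 <- matrix(c(3, 1, 0, 0), 4, 1)
  W2[4, 1:2] <- c(1, 1)
  expect_equal(as.numeric(
    v1_initialized_map(act2, W2, 1:2, 4, center_conditions = 1)), 0)
  W2[4, 1:2] <- c(1, -1)
  expect_equal(as.numeric(
    v1_initialized_map(act2, W2, 1:2, 4, center_conditions = 1)), 2)

  # uncentered conditions keep raw activations
  W2[4, 1:2] <- c(1, 1)
  act3 <- cbind(act2, act2)
  mp3 <- v1_initialized_map(act3, W2, 1:2, 4, center_conditions = 1)
  expect_equal(as.numeric(mp3), c(0, 3 + 1))

  expect_error(v1_initialized_map(act2, W2, integer(0), 4), "non-empty")
  expect_error(v1_initialized_map(act2, W2, c(1, 4), 4), "disjoint")
})

test_that("propagation settles to the closed-form linear solution", {
  set.seed(32)
  n <- 20; W <- matrix(rnorm(n * n, sd = 0.3), n, n); diag(W) <- 0
  exo <- 1:4; free <- 5:n
  rho <- max(Mod(eigen(W[free, free])$values))
  W[free, ] <- W[free, ] * 0.5 / rho
  x0 <- matrix(0, n, 2); x0[exo, ] <- rnorm(8)
  pr <- propagate(x0, W, exogenous = exo)
  expect_true(pr$settled)
  closed <- solve(diag(length(free)) - W[free, free],
                  W[free, exo] %*% x0[exo, ])
  expect_lt(max(abs(pr$final[free, ] - closed)) / max(abs(closed)), 1e-3)
  # the fixed point satisfies x = mapped(x) within tolerance
  nxt <- pr$final; nxt[free, ] <- (W %*% pr$final)[free, ]
  expect_lt(max(abs(nxt - pr$final)), pr$tolerance)
})

test_that("zero connectivity settles immediately at zero", {
  x0 <- matrix(rnorm(12), 4, 3)
  pr <- propagate(x0, matrix(0, 4, 4))
  expect_true(pr$settled)
  expect_equal(pr$settle_step, 2)
  expect_true(all(pr$final == 0))
})

test_that("supercritical systems raise a divergence error", {
  set.seed(33)
  W <- matrix(rnorm(25, sd = 1), 5, 5); diag(W) <- 0
  W <- W * 1.5 / max(Mod(eigen(W)$values))
  expect_error(propagate(matrix(1, 5, 2), W), "divergen")
})

test_that("two-step mapping composes V1 and region-level flows", {
  # 4 vertices (1 = V1) in regions c(1, 2, 2, 3); 3 regions
  v2r <- c(1L, 2L, 2L, 3L)
  act <- matrix(c(4, 0, 0, 0), 4, 1)
  Wv <- matrix(0, 4, 4); Wv[2, 1] <- 1; Wv[3, 1] <- 0.5; Wv[4, 1] <- 2
  # step-1 values: v2 = 4, v3 = 2, v4 = 8 -> region 2 = 3, region 3 = 8
  # region 1 (V1-only region) falls back to actual mean = 4

  # identity-excluded second step: fc rows all zero -> zero output
  Wr0 <- matrix(0, 3, 3)
  out0 <- two_step_map(act, Wv, Wr0, v1_units = 1, vertex_to_region = v2r,
                       targets_region = 3)
  expect_equal(as.numeric(out0), 0)

  # region 3 wholly driven by region 2 with weight 1
  Wr <- matrix(0, 3, 3); Wr[3, 2] <- 1
  out <- two_step_map(act, Wv, Wr, v1_units = 1, vertex_to_region = v2r,
                      targets_region = 3)
  expect_equal(as.numeric(out), 3)

  expect_error(two_step_map(act, Wv, Wr, 1, c(1L, NA, 2L, 3L), 3),
               "region assignment")
})

test_that("two-step mapping beats V1-only mapping on distributed truth", {
  fx <- get_noiseless(local_fraction = 0)
  m <- fx$model
  act <- fx$data$truth_activations[[1]]
  cxu <- complex_units(m)
  v1 <- m$v1_units
  v1_only <- v1_initialized_map(act, m$weights, v1, cxu)
  # the vertex subsystem covers V1 + the complexes (the visual system);
  # regions outside it contribute their actual activations in step 2
  sub <- c(v1, cxu)
  two <- two_step_map(act[sub, ], m$weights[sub, sub], m$weights,
                      v1_units = seq_along(v1),
                      vertex_to_region = sub,
                      targets_region = cxu,
                      act_regions = act)
  truth <- act[cxu, ]
  expect_gt(cor(as.numeric(two), as.numeric(truth)),
            cor(as.numeric(v1_only), as.numeric(truth)))
})

test_that("accuracy metrics match their closed forms", {
  set.seed(34)
  a <- matrix(rnorm(40), 8, 5)
  r <- accuracy(a, a)
  expect_equal(r$pearson_r, 1)
  expect_equal(r$mae, 0)
  expect_equal(r$r_squared, 1)

  cshift <- 0.3
  r2 <- accuracy(a, a + cshift)
  expect_equal(r2$pearson_r, 1)
  expect_equal(r2$mae, cshift)
  expect_equal(r2$r_squared,
               1 - length(a) * cshift^2 / sum((a - mean(a))^2))

  expect_equal(accuracy(a, -a)$pearson_r, -1)
  expect_error(accuracy(matrix(1, 2, 2), matrix(1, 2, 2)), "zero variance")

  # participant lists average the per-participant metrics
  lst <- accuracy(list(a, a), list(a + 0.3, a))
  expect_equal(lst$mae, 0.15)
})
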