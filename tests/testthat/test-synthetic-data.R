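test_that("ground-truth generation is deterministic and well formed", {
  cfg <- tiny_config(seed = 1)
  m1 <- generate_ground_truth(cfg)
  m2 <- generate_ground_truth(cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(m1$partition, m2$partition)

  expect_true(all(diag(m1$weights) == 0))
  expect_equal(length(levels(m1$partition)), 12)
  expect_true(all(table(m1$partition) >= 1))
  expect_lt(m1$spectral_radius, 1)

  cxu <- complex_units(m1)
  expect_length(intersect(cxu, m1$v1_units), 0)
  expect_length(cxu, 8)
})

test_that("complex fingerprints are pairwise distinct (cosine < 0.9)", {
  m <- generate_ground_truth(tiny_config(seed = 2))
  fps <- lapply(m$complexes, function(cx) m$weights[cx$units[1], ])
  for (a in seq_along(fps)) for (b in seq_along(fps)) {
    if (a >= b) next
    cos_ab <- sum(fps[[a]] * fps[[b]]) /
      sqrt(sum(fps[[a]]^2) * sum(fps[[b]]^2))
    expect_lt(cos_ab, 0.9)
  }
})

test_that("too-small configurations are rejected", {
  expect_error(sim_config(n_units = 10), "n_units")
  expect_error(sim_config(local_fraction = 1.2), "local_fraction")
  expect_error(sim_config(category_conditions = list(body = c(1, 99))),
               "indices")
})

test_that("rest simulation matches the closed-form SEM covariance", {
  # 2-unit oracle: cov = (I-W)^-1 (I-W)^-T sigma^2
  W <- matrix(0, 2, 2); W[1, 2] <- 0.5
  A <- solve(diag(2) - W)
  sigma <- A %*% t(A)           # noise_sd = 1
  set.seed(99)
  x <- sem_sim(W, 10000)
  expect_lt(norm(cov(t(x)) - sigma, "F") / norm(sigma, "F"), 0.05)

  # through the package path: full model covariance at n = 10,000
  cfg <- sim_config(seed = 5, n_participants = 1, n_timepoints_rest = 5000,
                    n_runs_rest = 2, noise_sd = 1)
  m <- generate_ground_truth(cfg)
  r <- simulate_rest(m, cfg)[[1]]
  A <- solve(diag(cfg$n_units) - m$weights)
  sigma <- A %*% t(A)
  expect_lt(norm(cov(t(r)) - sigma, "F") / norm(sigma, "F"), 0.05)
})

test_that("W = 0 rest samples are independent across units", {
  cfg <- sim_config(seed = 6, n_participants = 1, n_timepoints_rest = 2500,
                    n_runs_rest = 2)
  m <- generate_ground_truth(cfg)
  m$weights[] <- 0
  m$spectral_radius <- 0
  r <- simulate_rest(m, cfg)[[1]]
  cors <- cor(t(r))
  expect_lt(max(abs(cors[upper.tri(cors)])), 0.06)
})

test_that("rest simulation refuses a non-stationary model", {
  m <- generate_ground_truth(tiny_config(seed = 7))
  m$weights <- m$weights * 3
  m$spectral_radius <- m$spectral_radius * 3
  expect_error(simulate_rest(m), "non-stationary")
})

test_that("rest and task are reproducible under a fixed seed", {
  cfg <- tiny_config(seed = 8)
  m <- generate_ground_truth(cfg)
  expect_identical(simulate_rest(m, cfg), simulate_rest(m, cfg))
  expect_identical(simulate_task(m, cfg)$task_bold,
                   simulate_task(m, cfg)$task_bold)
})

test_that("local_fraction endpoints behave as constructed", {
  fx0 <- get_noiseless(local_fraction = 0)
  cxu <- complex_units(fx0$model)
  expect_equal(fx0$data$truth_activations[[1]][cxu, ],
               fx0$data$truth_flow_component[[1]][cxu, ])

  fx1 <- get_noiseless(local_fraction = 1)
  cxu1 <- complex_units(fx1$model)
  # pure local: truth equals the local component, flow term weight is zero
  expect_equal(fx1$data$truth_activations[[1]][cxu1, ],
               fx1$data$truth_local_component[[1]][cxu1, ])
})

test_that("target truths equal the stated flow/local mixture at any mixing", {
  fx <- get_noiseless(local_fraction = 0.4)
  cxu <- complex_units(fx$model)
  mix <- 0.6 * fx$data$truth_flow_component[[1]][cxu, ] +
    0.4 * fx$data$truth_local_component[[1]][cxu, ]
  expect_equal(fx$data$truth_activations[[1]][cxu, ], mix, tolerance = 1e-12)
})

test_that("noiseless GLM betas reproduce truth activations", {
  fx <- get_noiseless(local_fraction = 0.25)
  b <- estimate_betas(fx$data$task_bold[[1]], fx$data$design_matrix)
  expect_equal(b, fx$data$truth_activations[[1]], tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("dataset TSV/JSON round-trips", {
  cfg <- tiny_config(seed = 9, n_participants = 1)
  m <- generate_ground_truth(cfg)
  d <- simulate_task(m, cfg)
  dir <- withr::local_tempdir()
  write_dataset(d, dir = dir)
  back <- read_matrix_tsv(file.path(dir, "task_bold_p01.tsv"))
  expect_equal(unname(back), unname(d$task_bold[[1]]), tolerance = 1e-10)
  side <- jsonlite::read_json(file.path(dir, "dataset.json"))
  expect_equal(side$seed, 9)
  expect_length(side$partition, cfg$n_units)
})
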