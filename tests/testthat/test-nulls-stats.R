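test_that("fingerprint substitution rewrites rows per the null recipe", {
  set.seed(61)
  W <- matrix(rnorm(144), 12, 12); diag(W) <- 0
  tgt <- 1:2; don <- 5:6
  Wn <- substitute_fingerprint(W, tgt, don)
  # donor rows fill the target rows outside both special blocks
  other <- setdiff(1:12, c(tgt, don))
  expect_equal(Wn[tgt, other], W[don, other])
  # target self-block zeroed
  expect_true(all(Wn[tgt, tgt] == 0))
  # donor-column block carries the transposed original estimates
  expect_equal(Wn[tgt, don], t(W[don, tgt]))
  # all other rows untouched
  expect_equal(Wn[other, ], W[other, ])

  # donor = target: input with the self-block zeroed
  Wi <- substitute_fingerprint(W, tgt, tgt)
  Wref <- W; Wref[tgt, tgt] <- 0
  expect_equal(Wi, Wref)

  expect_error(substitute_fingerprint(W, 1:2, 2:3), "disjoint")
})

test_that("true fingerprints yield higher mapped selectivity than nulls", {
  cfg <- sim_config(seed = 62, n_participants = 10, local_fraction = 0.25)
  m <- generate_ground_truth(cfg)
  d <- simulate_task(m, cfg)
  cx <- "body"
  units <- m$complexes[[cx]]$units
  cat_c <- cfg$category_conditions[[cx]]
  non_c <- setdiff(unlist(cfg$category_conditions), cat_c)
  sel_with <- function(W) {
    mean(vapply(seq_len(cfg$n_participants), function(p) {
      b <- estimate_betas(d$task_bold[[p]], d$design_matrix)
      mp <- map_activity(b, W, targets = units)$mapped
      complex_selectivity(b[units, , drop = FALSE], mp, cat_c,
                          non_c)$mapped_selectivity
    }, numeric(1)))
  }
  true_sel <- sel_with(m$weights)
  for (donor in setdiff(names(m$complexes), cx)) {
    Wn <- substitute_fingerprint(m$weights, units,
                                 m$complexes[[donor]]$units)
    expect_gt(true_sel, sel_with(Wn))
  }
})

test_that("architecture permutation preserves weights, degrees, and masks", {
  set.seed(63)
  p <- 40; W <- matrix(0, p, p)
  idx <- which(row(W) != col(W))
  W[sample(idx, 150)] <- runif(150, 0.1, 1)
  ns <- permute_architecture(W, n_perms = 5, seed = 7)
  expect_s3_class(ns, "null_fc_set")
  frac_same <- vapply(ns$nulls, function(Wn) {
    expect_equal(sort(Wn[Wn != 0]), sort(W[W != 0]))
    expect_equal(rowSums(Wn != 0), rowSums(W != 0))
    expect_equal(colSums(Wn != 0), colSums(W != 0))
    expect_true(all(diag(Wn) == 0))
    sum(Wn != 0 & W != 0) / 150
  }, numeric(1))
  expect_lt(max(frac_same), 0.5)

  expect_error(permute_architecture(matrix(0, 4, 4)), "too few edges")
})

test_that("max-T corrected p-values behave at the degenerate extremes", {
  # identical condition values: all corrected p = 1 under label exchange
  md <- maxt_test(matrix(1, 30, 4), mu0 = 1, scheme = "condition_shuffle",
                  n_perm = 200)
  expect_true(all(md$p_corrected == 1))
  expect_true(all(md$p_corrected >= 1 / (md$n_perm + 1)))

  # a strong standardized effect survives correction among 12 comparisons
  set.seed(64)
  X <- cbind(rnorm(50, mean = 2), matrix(rnorm(50 * 11), 50, 11))
  mt <- maxt_test(X, n_perm = 1000, seed = 2)
  expect_lt(mt$p_corrected[1], 0.01)
  # max-T p of the largest observed statistic equals the permutation p of
  # the max statistic itself
  i_max <- which.max(mt$observed)
  expect_equal(mt$p_corrected[i_max],
               (1 + sum(mt$max_t >= max(mt$observed))) / (1 + mt$n_perm))
})

test_that("max-T controls the family-wise error under the null", {
  set.seed(65)
  nrep <- 60
  fwer <- mean(vapply(seq_len(nrep), function(r) {
    X <- matrix(rnorm(30 * 8), 30, 8)
    any(maxt_test(X, n_perm = 400, seed = r)$p_corrected <= 0.05)
  }, logical(1)))
  ci_half <- 1.96 * sqrt(0.05 * 0.95 / nrep)
  expect_lt(fwer, 0.05 + ci_half + 0.02)
})

test_that("max-T results are reproducible under a fixed seed", {
  X <- matrix(rnorm(20 * 3), 20, 3)
  expect_equal(maxt_test(X, seed = 5)$p_corrected,
               maxt_test(X, seed = 5)$p_corrected)
  expect_error(maxt_test(X[1, , drop = FALSE]), "2 participants")
})
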