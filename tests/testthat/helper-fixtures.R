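# Shared fixtures: everything is generated in code at test time.

# Draw n samples from the contemporaneous SEM x = Wx + e (unit x time).
sem_sim <- function(W, n, sd = 1) {
  p <- nrow(W)
  solve(diag(p) - W, matrix(stats::rnorm(p * n, sd = sd), p, n))
}

# Small, fast cohort configuration used across module tests.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_participants = 2, n_timepoints_rest = 300, n_runs_rest = 2),
    list(...))
  do.call(sim_config, args)
}

# One cached small model + noiseless dataset (built once per test run).
fixture_env <- new.env()
get_noiseless <- function(local_fraction = 0) {
  key <- paste0("lf", local_fraction)
  if (is.null(fixture_env[[key]])) {
    cfg <- sim_config(seed = 42, noise_sd = 0, n_participants = 1,
                      local_fraction = local_fraction)
    m <- generate_ground_truth(cfg)
    fixture_env[[key]] <- list(cfg = cfg, model = m,
                               data = simulate_task(m, cfg))
  }
  fixture_env[[key]]
}

# Per-participant distributed-contribution estimates for a simulated cohort,
# mapping complexes with the supplied connectivity (defaults to ground truth).
cohort_contributions <- function(cfg, model, dataset, fc_list = NULL) {
  cxu <- complex_units(model)
  vapply(seq_len(cfg$n_participants), function(p) {
    b <- estimate_betas(dataset$task_bold[[p]], dataset$design_matrix)
    W <- if (is.null(fc_list)) model$weights else fc_list[[p]]
    mp <- map_activity(b, W, targets = cxu)$mapped
    mean(vapply(names(model$complexes), function(cx) {
      u <- model$complexes[[cx]]$units
      rows <- match(u, cxu)
      cat_c <- cfg$category_conditions[[cx]]
      non_c <- setdiff(unlist(cfg$category_conditions), cat_c)
      complex_selectivity(b[u, , drop = FALSE], mp[rows, , drop = FALSE],
                          cat_c, non_c)$contribution_pct
    }, numeric(1)))
  }, numeric(1))
}
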