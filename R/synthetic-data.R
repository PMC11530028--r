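#' Simulation configuration
#'
#' Bundles every parameter of the synthetic study: cohort size, scan lengths,
#' condition structure, and the distributed-vs-local mixture written into the
#' ground truth. The seed fully determines all generated outputs.
#'
#' @param n_units Number of cortical units (regions). Must be large enough to
#'   allocate 12 networks, 4 two-unit functional complexes, and a V1 source
#'   set (>= 24).
#' @param n_timepoints_rest Time points per resting-state run.
#' @param n_runs_rest Resting-state runs per participant.
#' @param n_participants Participants in the simulated cohort.
#' @param n_conditions Task conditions (default 24, of which 8 encode the four
#'   visual categories as 0-back/2-back pairs).
#' @param category_conditions Named list mapping each category to its two
#'   condition indices.
#' @param local_fraction Fraction of each target (complex) unit's activation
#'   generated within-region rather than by distributed activity flow, in
#'   [0, 1].
#' @param noise_sd Standard deviation of the Gaussian noise added to rest
#'   innovations and task BOLD.
#' @param drive_strength Amplitude of condition-specific source drives
#'   (arbitrary BOLD units).
#' @param n_blocks Task blocks per condition.
#' @param block_duration Block length in time points.
#' @param block_gap Inter-block interval in time points.
#' @param spectral_target Spectral radius the source-subgraph weights are
#'   scaled to (< 1 keeps the stationary rest model well defined).
#' @param seed Integer seed determining every random draw.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_units = 60,
                       n_timepoints_rest = 1000,
                       n_runs_rest = 2,
                       n_participants = 20,
                       n_conditions = 24,
                       category_conditions = list(
                         body  = c(1L, 2L),
                         face  = c(3L, 4L),
                         place = c(5L, 6L),
                         tool  = c(7L, 8L)
                       ),
                       local_fraction = 0.25,
                       noise_sd = 0.5,
                       drive_strength = 3,
                       n_blocks = 3,
                       block_duration = 8,
                       block_gap = 4,
                       spectral_target = 0.5,
                       seed = 1L) {
  stopifnot(n_units >= 24, n_conditions >= 9,
            n_timepoints_rest > 10, n_runs_rest >= 1, n_participants >= 1)
  if (local_fraction < 0 || local_fraction > 1)
    stop("local_fraction must be in [0, 1]")
  idx <- unlist(category_conditions)
  if (any(idx < 1L) || any(idx > n_conditions))
    stop("category_conditions indices must lie in 1..n_conditions")
  if (spectral_target <= 0 || spectral_target >= 1)
    stop("spectral_target must be in (0, 1)")
  structure(list(
    n_units = as.integer(n_units),
    n_timepoints_rest = as.integer(n_timepoints_rest),
    n_runs_rest = as.integer(n_runs_rest),
    n_participants = as.integer(n_participants),
    n_conditions = as.integer(n_conditions),
    category_conditions = lapply(category_conditions, as.integer),
    local_fraction = local_fraction,
    noise_sd = noise_sd,
    drive_strength = drive_strength,
    n_blocks = as.integer(n_blocks),
    block_duration = as.integer(block_duration),
    block_gap = as.integer(block_gap),
    spectral_target = spectral_target,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Canonical 12-network labels (CAB-NP style).
NETWORK_LABELS <- c("VIS1", "VIS2", "SMN", "CON", "DAN", "LAN",
                    "FPN", "AUD", "DMN", "PMM", "VMM", "OAN")

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

#' Generate a ground-truth network model
#'
#' Builds the simulation truth: a directed weight matrix organized into 12
#' network blocks, four functional complexes (body, face, place, tool) whose
#' rows carry distinctive connectivity fingerprints preferentially weighting
#' their category's source units, a designated V1 source set, a unit -> network
#' partition, and 2-D grid geometry used to emulate spatial exclusion masks.
#'
#' Complex units are sinks (zero outgoing weights), so that multiple-regression
#' connectivity estimated on the stationary rest model recovers their incoming
#' weight rows — the rows the activity-flow equation consumes. Fingerprint
#' distinctiveness (pairwise cosine similarity < 0.9) is enforced by rejection
#' sampling.
#'
#' @param config A [sim_config()].
#' @return An object of class `ground_truth` with elements `weights`
#'   (target x source), `partition` (factor of network labels), `complexes`
#'   (named list with `units` and `category`), `v1_units`, `geometry`
#'   (n_units x 2 grid coordinates), `spectral_radius`,
#'   `condition_sources` (list: units driven by each condition),
#'   `v1_tuning` (V1 units x conditions drive pattern), `baseline_condition`,
#'   and the echoed `config`.
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_units
  n_net <- length(NETWORK_LABELS)
  n_complex_units <- 8L
  n_v1 <- 4L
  if (n < n_net + n_complex_units + n_v1)
    stop("invalid config: n_units too small to allocate 12 networks, ",
         "4 complexes and V1")
  set.seed(config$seed)

  ## Partition: contiguous blocks, sizes as equal as possible.
  sizes <- rep(n %/% n_net, n_net)
  sizes[seq_len(n %% n_net)] <- sizes[seq_len(n %% n_net)] + 1L
  partition <- factor(rep(NETWORK_LABELS, times = sizes),
                      levels = NETWORK_LABELS)
  net_units <- split(seq_len(n), partition)

  ## V1 lives in VIS1; complexes occupy two units each in visual/attention/
  ## default networks (disjoint from V1).
  v1_units <- net_units$VIS1[seq_len(min(n_v1, length(net_units$VIS1)))]
  pick2 <- function(net) {
    avail <- setdiff(net_units[[net]], v1_units)
    avail[seq_len(2L)]
  }
  complexes <- list(
    body  = list(units = pick2("VIS2"), category = "body"),
    face  = list(units = pick2("DAN"),  category = "face"),
    place = list(units = pick2("DMN"),  category = "place"),
    tool  = list(units = pick2("FPN"),  category = "tool")
  )
  complex_units <- unlist(lapply(complexes, `[[`, "units"), use.names = FALSE)
  source_units <- setdiff(seq_len(n), complex_units)

  ## Geometry: square-ish 2-D grid (row-major), arbitrary length units.
  ncol_grid <- ceiling(sqrt(n))
  geometry <- cbind(x = (seq_len(n) - 1L) %% ncol_grid,
                    y = (seq_len(n) - 1L) %/% ncol_grid)

  ## Condition -> driven source units. Category conditions drive dedicated
  ## non-V1 source groups; the remaining conditions (except a no-drive
  ## baseline) drive the leftover sources round-robin.
  n_cond <- config$n_conditions
  baseline_condition <- n_cond
  cat_conds <- config$category_conditions
  pool <- setdiff(source_units, v1_units)
  condition_sources <- vector("list", n_cond)
  grp_size <- 2L
  taken <- integer(0)
  for (cat in names(cat_conds)) {
    grp <- setdiff(pool, taken)[seq_len(grp_size)]
    taken <- c(taken, grp)
    for (cc in cat_conds[[cat]]) condition_sources[[cc]] <- grp
  }
  rest_conds <- setdiff(seq_len(n_cond),
                        c(unlist(cat_conds), baseline_condition))
  leftover <- setdiff(pool, taken)
  for (k in seq_along(rest_conds)) {
    i0 <- ((k - 1L) * grp_size) %% length(leftover)
    condition_sources[[rest_conds[k]]] <-
      leftover[((i0 + seq_len(grp_size) - 1L) %% length(leftover)) + 1L]
  }
  condition_sources[[baseline_condition]] <- integer(0)

  ## V1 tuning: every driven condition engages V1 with a positive,
  ## condition-specific pattern across V1 units (stimulus entry point).
  v1_tuning <- matrix(0, length(v1_units), n_cond)
  for (cc in setdiff(seq_len(n_cond), baseline_condition))
    v1_tuning[, cc] <- stats::runif(length(v1_units), 0.2, 1)

  ## Weights among non-complex units: block structure, stronger within
  ## network, scaled to the requested spectral radius.
  W <- matrix(0, n, n)
  same_net <- outer(partition, partition, `==`)
  src <- source_units
  for (i in src) for (j in src) {
    if (i == j) next
    if (same_net[i, j]) {
      if (stats::runif(1) < 0.5) W[i, j] <- stats::runif(1, 0.15, 0.35)
    } else if (stats::runif(1) < 0.08) {
      W[i, j] <- stats::runif(1, 0.02, 0.1)
    }
  }
  rho <- max(Mod(eigen(W[src, src], only.values = TRUE)$values))
  if (rho > 0) W[src, src] <- W[src, src] * (config$spectral_target / rho)

  ## Complex fingerprints: high weight on own-category source groups and on
  ## V1 in proportion to the category conditions' V1 pattern; low baseline
  ## weight on all other driven sources. Rejection-sample until all pairwise
  ## cosines < 0.9.
  w_hi <- 0.5
  w_lo <- 0.15
  draw_fingerprint <- function(cat) {
    fp <- numeric(n)
    fp[pool] <- w_lo * stats::runif(length(pool), 0.6, 1.4)
    own <- unique(unlist(condition_sources[cat_conds[[cat]]]))
    fp[own] <- w_hi * stats::runif(length(own), 0.9, 1.1)
    v1_pat <- rowMeans(v1_tuning[, cat_conds[[cat]], drop = FALSE])
    fp[v1_units] <- w_hi * v1_pat / max(v1_pat)
    fp
  }
  for (attempt in seq_len(100L)) {
    fps <- lapply(names(complexes), draw_fingerprint)
    names(fps) <- names(complexes)
    cos_ok <- TRUE
    for (a in seq_along(fps)) for (b in seq_along(fps)) {
      if (a < b && cosine_sim(fps[[a]], fps[[b]]) >= 0.9) cos_ok <- FALSE
    }
    if (cos_ok) break
  }
  if (!cos_ok) stop("could not draw distinct complex fingerprints")
  for (cx in names(complexes)) {
    for (u in complexes[[cx]]$units) {
      jit <- stats::runif(n, 0.95, 1.05)
      W[u, ] <- fps[[cx]] * jit
      W[u, complex_units] <- 0   # complexes never source each other
      W[u, u] <- 0
    }
  }
  ## Complexes are sinks: no outgoing edges.
  W[, complex_units] <- 0
  diag(W) <- 0

  spectral_radius <- max(Mod(eigen(W, only.values = TRUE)$values))

  structure(list(
    weights = W,
    partition = partition,
    complexes = complexes,
    v1_units = v1_units,
    geometry = geometry,
    spectral_radius = spectral_radius,
    condition_sources = condition_sources,
    v1_tuning = v1_tuning,
    baseline_condition = baseline_condition,
    config = config
  ), class = "ground_truth")
}

#' Units belonging to any functional complex
#' @param model A `ground_truth` model.
#' @return Integer vector of complex unit indices.
#' @export
complex_units <- function(model) {
  unlist(lapply(model$complexes, `[[`, "units"), use.names = FALSE)
}

#' Simulate resting-state time series
#'
#' Draws stationary series from the contemporaneous linear structural equation
#' model x = W x + e, solved as x = (I - W)^-1 e with i.i.d. Gaussian
#' innovations, per run and participant. Runs are returned concatenated.
#'
#' @param model A `ground_truth` model (spectral radius must be < 1).
#' @param config A [sim_config()]; `n_timepoints_rest`, `n_runs_rest`,
#'   `n_participants`, `noise_sd` and `seed` are used.
#' @return List with one unit x time matrix per participant; each carries a
#'   `runs` attribute giving run lengths.
#' @export
simulate_rest <- function(model, config = model$config) {
  if (model$spectral_radius >= 1)
    stop("non-stationary: spectral radius ", signif(model$spectral_radius, 4),
         " >= 1")
  n <- nrow(model$weights)
  A <- solve(diag(n) - model$weights)
  set.seed(config$seed + 1L)
  lapply(seq_len(config$n_participants), function(p) {
    runs <- lapply(seq_len(config$n_runs_rest), function(r) {
      e <- matrix(stats::rnorm(n * config$n_timepoints_rest,
                               sd = config$noise_sd),
                  n, config$n_timepoints_rest)
      A %*% e
    })
    x <- do.call(cbind, runs)
    attr(x, "runs") <- rep(config$n_timepoints_rest, config$n_runs_rest)
    x
  })
}

## Noiseless per-condition drives (units x conditions) for one participant.
## Participant-level variability enters as a multiplicative jitter on drives.
participant_drives <- function(model, config, jitter = NULL) {
  n <- nrow(model$weights)
  n_cond <- config$n_conditions
  D <- matrix(0, n, n_cond)
  for (cc in seq_len(n_cond)) {
    grp <- model$condition_sources[[cc]]
    if (length(grp)) D[grp, cc] <- config$drive_strength
    if (cc != model$baseline_condition)
      D[model$v1_units, cc] <- config$drive_strength * model$v1_tuning[, cc]
  }
  if (!is.null(jitter)) D <- D * jitter
  D
}

## Flow, local, and mixed truth activations at target (complex) units.
## local = flow with the other categories' conditions suppressed to baseline;
## this makes mapped/actual selectivity equal (1 - local_fraction) exactly in
## the noiseless case (see methods vignette).
truth_components <- function(model, config, drives) {
  W <- model$weights
  cx_units <- complex_units(model)
  n_cond <- config$n_conditions
  truth <- drives                       # source units: exogenous drive
  flow <- matrix(0, nrow(W), n_cond)
  local <- matrix(0, nrow(W), n_cond)
  cat_of_unit <- rep(NA_character_, nrow(W))
  for (cx in names(model$complexes))
    cat_of_unit[model$complexes[[cx]]$units] <- model$complexes[[cx]]$category
  for (u in cx_units) {
    f <- as.numeric(W[u, ] %*% drives)  # Eq.-1 flow from exogenous sources
    own_conds <- config$category_conditions[[cat_of_unit[u]]]
    other_cat_conds <- setdiff(unlist(config$category_conditions), own_conds)
    g <- f
    g[other_cat_conds] <- 0             # suppress non-preferred categories
    flow[u, ] <- f
    local[u, ] <- g
    truth[u, ] <- (1 - config$local_fraction) * f + config$local_fraction * g
  }
  list(truth = truth, flow = flow, local = local)
}

#' Simulate a block-design task dataset
#'
#' Injects condition-specific drives into condition-preferred source units and
#' V1, generates target (complex) activations as a controllable mixture of
#' distributed activity flow and a within-region (local) component, and
#' renders BOLD as the block design convolved with the canonical HRF times the
#' activation amplitudes, plus Gaussian noise.
#'
#' @param model A `ground_truth` model.
#' @param config A [sim_config()].
#' @return An object of class `synthetic_dataset` with `task_bold` (list per
#'   participant, unit x time), `design` (timing table: condition, onset,
#'   duration), `truth_activations`, `truth_flow_component`,
#'   `truth_local_component` (lists of unit x condition matrices), `model`,
#'   and `config`.
#' @export
simulate_task <- function(model, config = model$config) {
  stopifnot(inherits(model, "ground_truth"))
  n <- nrow(model$weights)
  n_cond <- config$n_conditions
  set.seed(config$seed + 2L)

  ## Interleaved block order: condition sequence repeated n_blocks times.
  slot_len <- config$block_duration + config$block_gap
  order_mat <- replicate(config$n_blocks, sample.int(n_cond))
  onsets <- numeric(0); conds <- integer(0)
  t0 <- 1L
  for (b in seq_len(config$n_blocks)) for (k in seq_len(n_cond)) {
    conds <- c(conds, order_mat[k, b]); onsets <- c(onsets, t0)
    t0 <- t0 + slot_len
  }
  n_time <- t0 + 20L                    # tail for HRF decay
  timing <- data.frame(condition = paste0("cond", conds),
                       onset = onsets,
                       duration = config$block_duration)
  design <- build_design(timing, n_timepoints = n_time, dt = 1,
                         conditions = paste0("cond", seq_len(n_cond)))

  X <- design$matrix[, design$condition_columns, drop = FALSE]
  participants <- lapply(seq_len(config$n_participants), function(p) {
    jitter <- matrix(exp(stats::rnorm(n * n_cond, sd = 0.1)), n, n_cond)
    drives <- participant_drives(model, config, jitter)
    comp <- truth_components(model, config, drives)
    noise <- matrix(stats::rnorm(n * n_time, sd = config$noise_sd), n, n_time)
    bold <- comp$truth %*% t(X) + noise
    list(bold = bold, comp = comp)
  })

  structure(list(
    task_bold = lapply(participants, `[[`, "bold"),
    design = timing,
    design_matrix = design,
    truth_activations = lapply(participants, function(p) p$comp$truth),
    truth_flow_component = lapply(participants, function(p) p$comp$flow),
    truth_local_component = lapply(participants, function(p) p$comp$local),
    model = model,
    config = config
  ), class = "synthetic_dataset")
}

#' Write a synthetic dataset to TSV + JSON sidecar
#'
#' Rest/task series and truth matrices go to TSV (units x columns); the
#' partition, complexes, V1 set, seed and config are echoed into a JSON
#' sidecar.
#'
#' @param dataset A `synthetic_dataset`.
#' @param rest Optional list of rest series (from [simulate_rest()]).
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, rest = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  model <- dataset$model
  for (p in seq_along(dataset$task_bold)) {
    write_matrix_tsv(dataset$task_bold[[p]],
                     file.path(dir, sprintf("task_bold_p%02d.tsv", p)))
    write_matrix_tsv(dataset$truth_activations[[p]],
                     file.path(dir, sprintf("truth_act_p%02d.tsv", p)))
    if (!is.null(rest))
      write_matrix_tsv(rest[[p]],
                       file.path(dir, sprintf("rest_p%02d.tsv", p)))
  }
  utils::write.table(dataset$design, file.path(dir, "design.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sidecar <- list(
    partition = as.character(model$partition),
    complexes = lapply(model$complexes, function(cx)
      list(units = cx$units, category = cx$category)),
    v1_units = model$v1_units,
    baseline_condition = model$baseline_condition,
    seed = dataset$config$seed,
    config = unclass(dataset$config)
  )
  jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
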