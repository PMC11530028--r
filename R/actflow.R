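#' Activity-flow mapping
#'
#' Maps each held-out target unit's task activation as the sum of source
#' activations weighted by the target's connectivity row:
#' mapped_j = sum_i act_i * w_ji over allowed sources i (never including the
#' target itself). The per-source flow products (act_i * w_ji) are retained so
#' downstream network decompositions operate on the same quantities that sum
#' to the mapped value.
#'
#' @param activations Unit x condition activation matrix.
#' @param fc Connectivity (target x source): an `fc_matrix` or plain matrix.
#' @param targets Target unit indices (default: all units).
#' @param sources Allowed source units (default: all units; the target itself
#'   is always removed per target). Supplying a named subset gives e.g. a
#'   V1-only model; supplying `exclude` gives held-out-source controls.
#' @param exclude Units removed from every target's source set.
#' @return Object of class `actflow_map`: `mapped` (targets x conditions),
#'   `flows` (targets x units x conditions; zero at disallowed sources),
#'   `targets`, `sources`.
#' @export
map_activity <- function(activations, fc, targets = NULL, sources = NULL,
                         exclude = NULL) {
  act <- as.matrix(activations)
  W <- fc_weights(fc)
  if (nrow(act) != ncol(W) || nrow(W) != ncol(W))
    stop("activations and fc must index the same units")
  n <- nrow(act); n_cond <- ncol(act)
  if (is.null(targets)) targets <- seq_len(n)
  default_sources <- is.null(sources)
  if (default_sources) sources <- seq_len(n)
  sources <- setdiff(sources, exclude)
  ## Circularity guard: an explicitly named source set must not contain a
  ## target; the default all-other-units filter removes the target itself.
  if (!default_sources && length(intersect(targets, sources)))
    stop("circularity: target unit(s) ",
         paste(intersect(targets, sources), collapse = ", "),
         " appear in their own source set")

  flows <- array(0, dim = c(length(targets), n, n_cond))
  mapped <- matrix(0, length(targets), n_cond)
  for (ti in seq_along(targets)) {
    j <- targets[ti]
    src <- setdiff(sources, j)
    fl <- W[j, src] * act[src, , drop = FALSE]
    flows[ti, src, ] <- fl
    mapped[ti, ] <- colSums(fl)
  }
  dimnames(mapped) <- list(NULL, colnames(act))
  structure(list(mapped = mapped, flows = flows,
                 targets = targets, sources = sources),
            class = "actflow_map")
}

#' V1-initialized activity-flow mapping
#'
#' Maps targets from V1 sources only. For the conditions named in
#' `center_conditions` (the category-specific conditions being mapped), the
#' cross-V1 mean activation of that condition is subtracted from each V1
#' source before the flow summation, guarding against category information fed
#' back into V1; other conditions are mapped without centering.
#'
#' @param activations Unit x condition matrix (vertex level in the full
#'   analysis).
#' @param fc Connectivity matrix or `fc_matrix`.
#' @param v1_units V1 source unit indices (non-empty, disjoint from targets).
#' @param targets Target unit indices.
#' @param center_conditions Condition indices to mean-center across V1.
#' @return Targets x conditions mapped activation matrix.
#' @export
v1_initialized_map <- function(activations, fc, v1_units, targets,
                               center_conditions = NULL) {
  if (!length(v1_units)) stop("v1_units must be non-empty")
  if (length(intersect(v1_units, targets)))
    stop("v1_units must be disjoint from targets")
  act <- as.matrix(activations)
  act_src <- act
  for (cc in center_conditions)
    act_src[v1_units, cc] <- act[v1_units, cc] - mean(act[v1_units, cc])
  map_activity(act_src, fc, targets = targets, sources = v1_units)$mapped
}

#' Multi-step activity-flow propagation
#'
#' Iterates the activity-flow mapping over a restricted system: at each step
#' every non-exogenous unit's activation is replaced by the flow sum of all
#' other units' previous-step activations (each target excludes itself as a
#' source); units listed in `exogenous` are clamped at their initial values
#' and act as the injected input. Iteration stops at the first step where the
#' maximum absolute change falls below `tolerance` ("no longer changing within
#' four decimal point precision"), or at `max_steps` with a non-settled flag.
#'
#' @param initial Unit x condition matrix of step-1 activations.
#' @param fc Connectivity of the restricted system (diagonal forced to zero).
#' @param exogenous Units held fixed (the injected input); may be empty.
#' @param tolerance Settling threshold on the max absolute elementwise change.
#' @param max_steps Step cap.
#' @return Object of class `propagation_trace`: `trace` (list of matrices,
#'   step 1 = initial), `settle_step`, `settled`, `spectral_radius`,
#'   `tolerance`.
#' @export
propagate <- function(initial, fc, exogenous = NULL, tolerance = 0.5e-4,
                      max_steps = 500) {
  if (tolerance <= 0) stop("tolerance must be positive")
  x <- as.matrix(initial)
  W <- fc_weights(fc)
  diag(W) <- 0
  free <- setdiff(seq_len(nrow(W)), exogenous)
  rho <- max(Mod(eigen(W[free, free, drop = FALSE],
                       only.values = TRUE)$values))
  if (rho >= 1)
    stop("divergent propagation: subsystem spectral radius ",
         signif(rho, 4), " >= 1")
  trace <- list(x)
  settled <- FALSE
  step <- 1L
  while (step < max_steps) {
    x_new <- x
    x_new[free, ] <- (W %*% x)[free, , drop = FALSE]
    step <- step + 1L
    trace[[step]] <- x_new
    if (max(abs(x_new)) > 1e12)
      stop("divergent propagation: values overflow (spectral radius ",
           signif(rho, 4), ")")
    if (max(abs(x_new - x)) < tolerance) {
      ## x (step - 1) is already the fixed point: mapping it again changed
      ## nothing beyond tolerance
      settled <- TRUE
      step <- step - 1L
      x <- x_new
      break
    }
    x <- x_new
  }
  structure(list(trace = trace, settle_step = if (settled) step else NA_integer_,
                 settled = settled, spectral_radius = rho,
                 tolerance = tolerance, final = x),
            class = "propagation_trace")
}

#' Two-step stimulus-driven + fully distributed mapping
#'
#' Step 1 maps vertex-level targets from V1 sources ([v1_initialized_map()]);
#' the vertex maps are averaged into regions (unweighted mean of member
#' vertices); step 2 re-maps region-level targets from all other regions
#' ([map_activity()]), with step-1 mapped values standing in as the source
#' activations for the regions the vertex system covers and actual region
#' activations elsewhere.
#'
#' @param activations Vertex x condition matrix.
#' @param fc_v1_block Vertex-level connectivity for step 1.
#' @param fc_full Region-level connectivity for step 2.
#' @param v1_units Vertex indices of V1.
#' @param vertex_to_region Integer vector mapping every vertex to its region
#'   (NA for none triggers an error).
#' @param targets_region Region indices to map in step 2.
#' @param center_conditions Passed to [v1_initialized_map()].
#' @param act_regions Optional region x condition actual activations used for
#'   regions not covered by the vertex system (required if any).
#' @return Region-level mapped matrix (`targets_region` x conditions).
#' @export
two_step_map <- function(activations, fc_v1_block, fc_full, v1_units,
                         vertex_to_region, targets_region,
                         center_conditions = NULL, act_regions = NULL) {
  if (anyNA(vertex_to_region))
    stop("every vertex needs a region assignment")
  n_vert <- nrow(as.matrix(activations))
  if (length(vertex_to_region) != n_vert)
    stop("vertex_to_region length must equal the number of vertices")
  verts <- setdiff(seq_len(n_vert), v1_units)
  step1 <- v1_initialized_map(activations, fc_v1_block, v1_units,
                              targets = verts,
                              center_conditions = center_conditions)

  n_region <- nrow(fc_weights(fc_full))
  n_cond <- ncol(as.matrix(activations))
  region_act <- matrix(NA_real_, n_region, n_cond)
  if (!is.null(act_regions)) region_act <- as.matrix(act_regions)
  for (r in unique(vertex_to_region[verts])) {
    members <- which(vertex_to_region[verts] == r)
    region_act[r, ] <- colMeans(step1[members, , drop = FALSE])
  }
  ## V1-only regions (if any) fall back to the mean of actual activations.
  v1_only <- setdiff(unique(vertex_to_region[v1_units]),
                     unique(vertex_to_region[verts]))
  for (r in v1_only) {
    members <- which(vertex_to_region == r)
    region_act[r, ] <- colMeans(as.matrix(activations)[members, , drop = FALSE])
  }
  if (anyNA(region_act))
    stop("regions without vertex coverage need act_regions")
  map_activity(region_act, fc_full, targets = targets_region)$mapped
}

#' Mapping accuracy: Pearson r, MAE, and R-squared
#'
#' Compares mapped against actual activations over all entries. R-squared is
#' the coefficient of determination 1 - SS_res/SS_tot with SS_tot taken about
#' the mean of the actual values (so it can be negative). When given lists
#' (one matrix per participant), metrics are computed per participant and then
#' averaged.
#'
#' @param actual Actual activations (matrix/vector, or list per participant).
#' @param mapped Mapped activations of the same shape.
#' @return List of class `accuracy_report`: `pearson_r`, `mae`, `r_squared`.
#' @export
accuracy <- function(actual, mapped) {
  if (is.list(actual) && !is.matrix(actual)) {
    reps <- Map(accuracy, actual, mapped)
    out <- list(
      pearson_r = mean(vapply(reps, `[[`, numeric(1), "pearson_r")),
      mae = mean(vapply(reps, `[[`, numeric(1), "mae")),
      r_squared = mean(vapply(reps, `[[`, numeric(1), "r_squared")))
    class(out) <- "accuracy_report"
    return(out)
  }
  a <- as.numeric(as.matrix(actual))
  m <- as.numeric(as.matrix(mapped))
  if (length(a) != length(m)) stop("actual and mapped shapes differ")
  if (length(a) < 2) stop("need at least two entries")
  ss_tot <- sum((a - mean(a))^2)
  if (ss_tot == 0)
    stop("zero variance in actual: r and R-squared undefined")
  structure(list(
    pearson_r = stats::cor(a, m),
    mae = mean(abs(a - m)),
    r_squared = 1 - sum((a - m)^2) / ss_tot
  ), class = "accuracy_report")
}
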