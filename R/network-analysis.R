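#' Network-averaged activity-flow contributions
#'
#' Averages the per-source flow products (act_i * w_ji) of an
#' [map_activity()] result within each network of the partition, per condition
#' (flows averaged over the map's targets first).
#'
#' @param flows An `actflow_map` (its `flows` tensor is used) or a
#'   source x condition matrix of flow products for a single target.
#' @param partition Factor/character vector of network labels per source unit.
#' @return Network x condition matrix of mean flow values.
#' @export
flows_by_network <- function(flows, partition) {
  if (inherits(flows, "actflow_map")) {
    fl <- apply(flows$flows, c(2, 3), mean)   # sources x conditions
    src <- flows$sources
  } else {
    fl <- as.matrix(flows)
    src <- seq_len(nrow(fl))
  }
  if (anyNA(partition[src])) stop("unlabeled source unit")
  partition <- factor(partition)
  out <- t(vapply(levels(partition), function(nw) {
    members <- intersect(which(partition == nw), src)
    if (!length(members)) return(rep(NA_real_, ncol(fl)))
    colMeans(fl[members, , drop = FALSE])
  }, numeric(ncol(fl))))
  rownames(out) <- levels(partition)
  out
}

#' Network-restricted activity-flow maps
#'
#' Re-computes the activity-flow mapping with sources restricted to each
#' network in turn. By linearity the components sum exactly to the fully
#' distributed map.
#'
#' @param activations Unit x condition matrix.
#' @param fc Connectivity matrix or `fc_matrix`.
#' @param partition Network label per unit (must cover all sources, no
#'   overlaps — each unit has exactly one label).
#' @param targets Target unit indices.
#' @return Named list of targets x conditions matrices, one per network.
#' @export
network_restricted_maps <- function(activations, fc, partition, targets) {
  if (anyNA(partition)) stop("partition must cover all sources")
  partition <- factor(partition)
  out <- lapply(levels(partition), function(nw) {
    src <- which(partition == nw)
    src_ok <- setdiff(src, targets)
    if (!length(src_ok))
      return(matrix(0, length(targets), ncol(as.matrix(activations))))
    map_activity(activations, fc, targets = targets,
                 sources = src_ok)$mapped
  })
  names(out) <- levels(partition)
  out
}

## R-squared of y ~ X[, subset] with intercept, from precomputed
## cross-products on centered data.
subset_r2 <- function(Sxx, Sxy, Syy, subset) {
  if (!length(subset)) return(0)
  b <- solve(Sxx[subset, subset, drop = FALSE], Sxy[subset])
  as.numeric(crossprod(Sxy[subset], b)) / Syy
}

#' Dominance analysis of predictor networks
#'
#' Decomposes the full-model R-squared of `actual ~ components` into
#' per-predictor partial R-squared by enumerating every non-empty predictor
#' subset as a candidate model and averaging each predictor's incremental
#' R-squared contribution within each subset size, then across sizes (general
#' dominance). Partial R-squared values sum exactly to the full-model
#' R-squared; relative importance is partial / full * 100.
#'
#' @param components Condition x predictor matrix (e.g., 12 network-restricted
#'   mapped response profiles), or a named list of per-network profiles.
#' @param actual Actual response profile (length = conditions).
#' @return List of class `dominance_result`: `full_r2`, `partial_r2` (named),
#'   `relative_importance_pct` (named), `n_candidate_models`.
#' @export
dominance <- function(components, actual) {
  if (is.list(components) && !is.matrix(components))
    components <- do.call(cbind, lapply(components, as.numeric))
  X <- as.matrix(components)
  y <- as.numeric(actual)
  p <- ncol(X)
  if (length(y) <= p)
    stop("need more conditions than predictors for the full model")
  Xc <- scale(X, scale = FALSE)
  yc <- y - mean(y)
  Sxx <- crossprod(Xc); Sxy <- crossprod(Xc, yc); Syy <- sum(yc^2)
  if (Syy == 0) stop("actual profile has zero variance")
  full_ok <- tryCatch({solve(Sxx); TRUE}, error = function(e) FALSE)
  if (!full_ok) stop("predictors are collinear to singularity")

  n_models <- 2^p - 1
  r2 <- numeric(2^p)                    # index = bitmask + 1; empty model = 0
  masks <- 0:(2^p - 1)
  for (m in masks[-1]) {
    subset <- which(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0)
    r2[m + 1] <- subset_r2(Sxx, Sxy, Syy, subset)
  }

  sizes <- vapply(masks, function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0),
                  numeric(1))
  partial <- numeric(p)
  for (i in seq_len(p)) {
    bit <- bitwShiftL(1L, i - 1)
    without_i <- masks[bitwAnd(masks, bit) == 0]
    inc <- r2[bitwOr(without_i, bit) + 1] - r2[without_i + 1]
    ## average within each subset size, then across sizes
    partial[i] <- mean(tapply(inc, sizes[without_i + 1], mean))
  }
  full_r2 <- r2[2^p]
  names(partial) <- colnames(X) %||% paste0("net", seq_len(p))
  structure(list(
    full_r2 = full_r2,
    partial_r2 = partial,
    relative_importance_pct = 100 * partial / full_r2,
    n_candidate_models = n_models
  ), class = "dominance_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
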