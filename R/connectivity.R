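#' Build a spatial exclusion mask
#'
#' Emulates dilated-mask source exclusion: sources within `radius` (Euclidean
#' distance in geometry units) of a target are excluded from that target's
#' source set, in addition to the target itself.
#'
#' @param geometry Unit x 2 coordinate matrix.
#' @param radius Exclusion radius (same units as geometry). `0` excludes only
#'   the unit itself; on a unit-spaced grid, `1` excludes rook neighbors but
#'   keeps diagonal neighbors.
#' @return Logical target x source matrix of class `exclusion_mask`; `TRUE`
#'   marks an excluded source.
#' @export
build_exclusion_mask <- function(geometry, radius = 1) {
  geometry <- as.matrix(geometry)
  d <- as.matrix(stats::dist(geometry))
  mask <- d <= radius
  diag(mask) <- TRUE
  structure(mask, class = c("exclusion_mask", "matrix", "array"),
            radius = radius)
}

fc_weights <- function(fc) {
  if (is.list(fc) && !is.null(fc$weights)) fc$weights else as.matrix(fc)
}

## Fisher-z two-sided test of a (partial) correlation; `conditioned` = number
## of conditioning variables.
fisher_z_p <- function(r, n, conditioned = 0) {
  df <- n - conditioned - 3
  if (df <= 0) stop("too few time points for Fisher-z test")
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12)) * sqrt(df)
  2 * stats::pnorm(-abs(z))
}

#' Three-stage combinedFC connectivity estimation
#'
#' Stage 1 computes the partial correlation of each pair conditioning on all
#' other units (from the inverse covariance) and keeps edges significant at
#' `alpha_partial` (two-sided Fisher-z). Stage 2 removes kept edges whose
#' bivariate Pearson correlation is statistically indistinguishable from zero
#' at `alpha_zero` (collider pruning). Stage 3 regresses each target on its
#' remaining connected sources; the regression weights fill the target's row.
#'
#' @param rest Unit x time matrix of resting-state series.
#' @param mask Optional [build_exclusion_mask()]; masked pairs never enter any
#'   stage.
#' @param alpha_partial Stage-1 significance level.
#' @param alpha_zero Stage-2 level for the "equal to zero" decision (edges
#'   whose bivariate p exceeds `alpha_zero` are removed).
#' @return List of class `fc_matrix`: `weights` (target x source), `mask`,
#'   `skeleton_stage1`, `skeleton` (post stage 2), `alphas`, `n_timepoints`.
#' @export
combinedfc <- function(rest, mask = NULL, alpha_partial = 0.01,
                       alpha_zero = 0.01) {
  ts <- t(as.matrix(rest))              # time x units
  n_time <- nrow(ts); p <- ncol(ts)
  if (n_time <= p)
    stop("need more time points than units at the region level")
  S <- stats::cov(ts)
  P <- tryCatch(solve(S), error = function(e)
    stop("singular covariance; use the regularized variant ",
         "(regularized_fc) instead"))
  dP <- sqrt(diag(P))
  pcor <- -P / tcrossprod(dP)
  diag(pcor) <- 0

  allowed <- matrix(TRUE, p, p)
  if (!is.null(mask)) allowed <- !unclass(mask)
  diag(allowed) <- FALSE

  ## Stage 1: partial-correlation skeleton.
  p_partial <- fisher_z_p(pcor, n_time, conditioned = p - 2)
  skel1 <- allowed & (p_partial < alpha_partial)
  skel1 <- skel1 | t(skel1)             # symmetric skeleton
  skel1 <- skel1 & allowed

  ## Stage 2: collider pruning on the bivariate correlation.
  r_biv <- stats::cor(ts)
  p_biv <- fisher_z_p(r_biv, n_time, conditioned = 0)
  skel <- skel1 & (p_biv < alpha_zero)

  ## Stage 3: per-target multiple regression on connected sources.
  W <- matrix(0, p, p)
  for (j in seq_len(p)) {
    src <- which(skel[j, ])
    if (!length(src)) next
    fit <- stats::lm.fit(cbind(1, ts[, src, drop = FALSE]), ts[, j])
    W[j, src] <- fit$coefficients[-1]
  }
  dimnames(W) <- dimnames(S)
  structure(list(weights = W, mask = mask,
                 skeleton_stage1 = skel1, skeleton = skel,
                 alphas = c(partial = alpha_partial, zero = alpha_zero),
                 n_timepoints = n_time),
            class = "fc_matrix")
}

#' L1-regularized connectivity estimation (vertex level)
#'
#' Per-target lasso regression of the target series on all allowed sources,
#' with the penalty chosen by cross-validation across resting-state runs over
#' a grid of 100 log-spaced penalties (from the smallest penalty that zeroes
#' all coefficients down four orders of magnitude).
#'
#' @param rest_runs List of unit x time matrices, one per run (>= 2 runs).
#' @param mask Optional exclusion mask; masked sources never enter.
#' @param n_penalties Penalty-grid size.
#' @param targets Target units to estimate (default all).
#' @param penalties Optional explicit penalty grid overriding the default.
#' @param rule Penalty selection on the CV curve: `"1se"` picks the sparsest
#'   penalty whose CV error is within one standard error of the minimum (the
#'   usual parsimony convention when the support defines a graph); `"min"`
#'   picks the error minimizer.
#' @return `fc_matrix` list: `weights`, `mask`, `penalty` (chosen per target),
#'   `n_penalties`.
#' @export
regularized_fc <- function(rest_runs, mask = NULL, n_penalties = 100,
                           targets = NULL, penalties = NULL,
                           rule = c("1se", "min")) {
  rule <- match.arg(rule)
  if (!is.list(rest_runs) || length(rest_runs) < 2)
    stop("cross-validation requires at least two resting-state runs")
  p <- nrow(rest_runs[[1]])
  ts <- t(do.call(cbind, rest_runs))    # time x units
  foldid <- rep(seq_along(rest_runs),
                vapply(rest_runs, ncol, integer(1)))
  if (is.null(targets)) targets <- seq_len(p)
  allowed <- matrix(TRUE, p, p)
  if (!is.null(mask)) allowed <- !unclass(mask)
  diag(allowed) <- FALSE

  W <- matrix(0, p, p)
  chosen <- rep(NA_real_, p)
  for (j in targets) {
    src <- which(allowed[j, ])
    y <- ts[, j]
    if (stats::sd(y) == 0) {
      warning("target ", j, " has an all-zero (constant) series; zero row")
      next
    }
    X <- ts[, src, drop = FALSE]
    lam <- penalties
    if (is.null(lam)) {
      lam_max <- max(abs(crossprod(scale(X, scale = FALSE),
                                   y - mean(y)))) / length(y)
      lam <- exp(seq(log(lam_max), log(lam_max * 1e-4),
                     length.out = n_penalties))
    }
    ## Leave-one-run-out CV on mean squared prediction error
    ## (cross-validation across resting-state runs).
    mse <- matrix(NA_real_, length(rest_runs), length(lam))
    for (k in seq_along(rest_runs)) {
      tr <- foldid != k
      fit <- glmnet::glmnet(X[tr, , drop = FALSE], y[tr], lambda = lam,
                            standardize = FALSE, thresh = 1e-10)
      pred <- stats::predict(fit, X[!tr, , drop = FALSE], s = lam)
      mse[k, ] <- colMeans((y[!tr] - pred)^2)
    }
    cv <- colMeans(mse)
    imin <- which.min(cv)
    if (rule == "1se") {
      se_min <- stats::sd(mse[, imin]) / sqrt(nrow(mse))
      imin <- min(which(cv <= cv[imin] + se_min))
    }
    best <- lam[imin]
    fit <- glmnet::glmnet(X, y, lambda = lam, standardize = FALSE,
                          thresh = 1e-10)
    co <- as.numeric(stats::coef(fit, s = best, exact = FALSE))[-1]
    W[j, src] <- co
    chosen[j] <- best
  }
  structure(list(weights = W, mask = mask, penalty = chosen,
                 n_penalties = if (is.null(penalties)) n_penalties
                               else length(penalties)),
            class = "fc_matrix")
}

#' Single-target lasso row at a fixed penalty
#'
#' Convenience for inspecting penalty limits: the lasso solution for one
#' target at a given penalty (`penalty = 0` reduces to OLS when the problem is
#' overdetermined).
#'
#' @param rest Unit x time matrix.
#' @param target Target unit index.
#' @param penalty Non-negative lasso penalty.
#' @param mask Optional exclusion mask.
#' @return Length-`n_units` coefficient row (zero at the target and masked
#'   entries).
#' @export
lasso_row <- function(rest, target, penalty, mask = NULL) {
  p <- nrow(rest)
  ts <- t(as.matrix(rest))
  allowed <- rep(TRUE, p)
  if (!is.null(mask)) allowed <- !unclass(mask)[target, ]
  allowed[target] <- FALSE
  src <- which(allowed)
  X <- ts[, src, drop = FALSE]
  y <- ts[, target]
  fit <- glmnet::glmnet(X, y,
                        lambda = unique(c(max(penalty * 4, penalty + 0.1),
                                          penalty)),
                        standardize = FALSE, thresh = 1e-12)
  co <- as.numeric(stats::coef(fit, s = penalty, exact = FALSE))[-1]
  row <- numeric(p)
  row[src] <- co
  row
}
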