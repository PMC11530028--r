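#' Canonical double-gamma hemodynamic response function
#'
#' SPM-style canonical HRF: a gamma density peaking near 6 s minus a scaled
#' gamma density modelling the undershoot near 16 s, sampled at `dt` and
#' normalized to unit peak.
#'
#' @param dt Sampling interval in seconds (> 0).
#' @param peak_delay,peak_dispersion Gamma delay/dispersion of the positive
#'   lobe (seconds); shape = delay/dispersion, rate = 1/dispersion.
#' @param undershoot_delay,undershoot_dispersion Same for the undershoot lobe.
#' @param ratio Undershoot-to-peak amplitude ratio of the two gamma densities.
#' @param duration Kernel length in seconds.
#' @return Numeric kernel vector of length `duration/dt + 1`, max value 1.
#' @export
canonical_hrf <- function(dt, peak_delay = 6, peak_dispersion = 1,
                          undershoot_delay = 16, undershoot_dispersion = 1,
                          ratio = 1 / 6, duration = 32) {
  if (dt <= 0) stop("dt must be positive")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay / peak_dispersion,
                     rate = 1 / peak_dispersion) -
    ratio * stats::dgamma(t, shape = undershoot_delay / undershoot_dispersion,
                          rate = 1 / undershoot_dispersion)
  h / max(h)
}

#' Build a task design matrix
#'
#' One regressor per condition: a boxcar over the condition's blocks convolved
#' with the HRF kernel, plus an optional intercept column.
#'
#' @param timing Data frame with columns `condition`, `onset`, `duration`
#'   (onsets/durations in time-point units, onsets 1-based).
#' @param n_timepoints Number of scan time points (rows of the design).
#' @param dt Sampling interval in seconds, passed to [canonical_hrf()].
#' @param hrf HRF kernel; defaults to `canonical_hrf(dt)`. Pass `1` for an
#'   identity (no-convolution) kernel.
#' @param conditions Optional condition ordering; defaults to order of first
#'   appearance.
#' @param intercept Include an intercept column.
#' @return List of class `design_matrix`: `matrix` (time x regressor),
#'   `labels`, `condition_columns` (indices of condition regressors).
#' @export
build_design <- function(timing, n_timepoints, dt = 1,
                         hrf = canonical_hrf(dt), conditions = NULL,
                         intercept = TRUE) {
  stopifnot(all(c("condition", "onset", "duration") %in% names(timing)))
  if (nrow(timing) > 0 &&
      (any(timing$onset < 1) ||
       any(timing$onset + timing$duration - 1 > n_timepoints)))
    stop("block onsets/durations fall outside the run")
  if (is.null(conditions)) conditions <- unique(as.character(timing$condition))
  X <- matrix(0, n_timepoints, length(conditions))
  for (k in seq_along(conditions)) {
    box <- numeric(n_timepoints)
    rows <- which(as.character(timing$condition) == conditions[k])
    for (r in rows) {
      idx <- timing$onset[r] + seq_len(timing$duration[r]) - 1L
      box[idx] <- box[idx] + 1  # overlapping same-condition blocks add
    }
    conv <- stats::convolve(box, rev(hrf), type = "open")[seq_len(n_timepoints)]
    X[, k] <- conv
  }
  labels <- conditions
  cond_cols <- seq_along(conditions)
  if (intercept) {
    X <- cbind(X, 1)
    labels <- c(labels, "intercept")
  }
  colnames(X) <- labels
  structure(list(matrix = X, labels = labels,
                 condition_columns = cond_cols),
            class = "design_matrix")
}

#' Estimate condition activation amplitudes by ordinary least squares
#'
#' Fits the GLM per unit and returns the condition betas only (nuisance and
#' intercept columns are estimated but dropped).
#'
#' @param bold Unit x time matrix.
#' @param design A `design_matrix` from [build_design()] (or a plain matrix,
#'   in which case all columns are treated as conditions).
#' @return Unit x condition matrix of beta amplitudes, class
#'   `activation_matrix` attribute `unit_level = "region"`.
#' @export
estimate_betas <- function(bold, design) {
  if (inherits(design, "design_matrix")) {
    X <- design$matrix
    cond_cols <- design$condition_columns
    labels <- design$labels
  } else {
    X <- as.matrix(design)
    cond_cols <- seq_len(ncol(X))
    labels <- colnames(X)
  }
  if (ncol(bold) != nrow(X))
    stop("bold has ", ncol(bold), " time points but design has ", nrow(X))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- labels[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  betas <- t(qr.coef(qx, t(bold)))
  out <- betas[, cond_cols, drop = FALSE]
  colnames(out) <- labels[cond_cols]
  attr(out, "unit_level") <- "region"
  out
}

first_difference <- function(x) {
  d <- apply(as.matrix(x), 2, function(col) c(0, diff(col)))
  d
}

#' Construct the nuisance-regressor design
#'
#' Standard fMRI nuisance expansion: the 6 motion parameters plus their first
#' differences plus the squares of those 12 (24 columns), and 5 aCompCor
#' principal components per tissue compartment (white matter, ventricles) plus
#' derivatives plus squares of those 20 (40 columns) — 64 columns altogether.
#'
#' @param motion Time x 6 matrix of motion parameters.
#' @param tissue_pcs Time x 10 matrix (5 PCs x 2 compartments), or a list of
#'   two time x 5 matrices.
#' @return List of class `design_matrix`: `matrix` (time x 64), `labels`.
#' @export
build_nuisance_set <- function(motion, tissue_pcs) {
  motion <- as.matrix(motion)
  if (is.list(tissue_pcs) && !is.matrix(tissue_pcs))
    tissue_pcs <- do.call(cbind, tissue_pcs)
  tissue_pcs <- as.matrix(tissue_pcs)
  if (ncol(motion) != 6) stop("expected 6 motion series, got ", ncol(motion))
  if (ncol(tissue_pcs) != 10)
    stop("expected 10 tissue PCs (5 per compartment), got ", ncol(tissue_pcs))
  if (nrow(motion) != nrow(tissue_pcs))
    stop("motion and tissue series lengths differ")

  expand <- function(base, prefix) {
    d <- first_difference(base)
    ext <- cbind(base, d)
    quad <- ext^2
    out <- cbind(ext, quad)
    colnames(out) <- c(paste0(prefix, seq_len(ncol(base))),
                       paste0(prefix, "_deriv", seq_len(ncol(base))),
                       paste0(prefix, "_sq", seq_len(ncol(base))),
                       paste0(prefix, "_deriv_sq", seq_len(ncol(base))))
    out
  }
  X <- cbind(expand(motion, "motion"), expand(tissue_pcs, "compcor"))
  structure(list(matrix = X, labels = colnames(X),
                 condition_columns = integer(0)),
            class = "design_matrix")
}
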