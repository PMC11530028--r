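#' Min-max normalization (feature scaling)
#'
#' Rescales x to [a, b] via xn = a + (x - min_ref)(b - a)/(max_ref - min_ref).
#' The reference minimum and maximum are taken from `ref` — in the selectivity
#' pipeline, always the *actual* activations across all conditions — and
#' applied to both actual and mapped values, so mapped values may fall outside
#' [a, b].
#'
#' @param x Numeric vector (activations across conditions).
#' @param ref Reference vector supplying min/max (default `x` itself).
#' @param a,b Lower and upper bounds of the rescaled data.
#' @return Normalized vector. A flat reference (max_ref == min_ref) returns
#'   constant `a` with a warning and attribute `flat = TRUE`.
#' @export
minmax_normalize <- function(x, ref = x, a = 0, b = 1) {
  if (b <= a) stop("b must exceed a")
  mn <- min(ref); mx <- max(ref)
  if (mx == mn) {
    warning("flat reference: returning constant a")
    return(structure(rep(a, length(x)), flat = TRUE))
  }
  a + (x - mn) * (b - a) / (mx - mn)
}

#' Category selectivity ratio
#'
#' Ratio of the mean normalized response to a category's conditions over the
#' mean normalized response to the other categories' conditions (the
#' non-category set holds only the other categories' n-back conditions). A
#' value of 1.0 is the hypothesized null (no selectivity).
#'
#' @param normalized Normalized activation vector across conditions, or a
#'   unit x condition matrix (rows are averaged after per-row selectivity when
#'   `aggregate = "per-unit"`, or before when `aggregate = "average-first"`).
#' @param category_conditions Indices of the category's conditions.
#' @param noncategory_conditions Indices of the other categories' conditions.
#' @param aggregate Aggregation across units for matrix input.
#' @return Selectivity ratio (scalar).
#' @export
category_selectivity <- function(normalized, category_conditions,
                                 noncategory_conditions,
                                 aggregate = c("per-unit", "average-first")) {
  aggregate <- match.arg(aggregate)
  sel1 <- function(v) {
    num <- mean(v[category_conditions])
    den <- mean(v[noncategory_conditions])
    if (den <= 0)
      stop("undefined selectivity: non-positive non-category mean")
    num / den
  }
  if (is.matrix(normalized)) {
    if (aggregate == "per-unit")
      return(mean(apply(normalized, 1, sel1)))
    return(sel1(colMeans(normalized)))
  }
  sel1(normalized)
}

#' Percent contribution of distributed processes
#'
#' 100 * mapped selectivity / actual selectivity, per participant. Values
#' statistically above 50% indicate selectivity generated primarily by
#' distributed activity flows.
#'
#' @param mapped_sel,actual_sel Selectivity values (vectors over
#'   participants).
#' @return Percentages, same length.
#' @export
distributed_contribution <- function(mapped_sel, actual_sel) {
  if (any(actual_sel <= 0)) stop("actual selectivity must be positive")
  100 * mapped_sel / actual_sel
}

#' Median-absolute-deviation outlier removal
#'
#' Flags participants whose score deviates from the group median by more than
#' `n_mad` scaled median absolute deviations (MAD scaled by 1.4826).
#'
#' @param scores Numeric vector (>= 3 values).
#' @param n_mad Deviation threshold (default 5, a conservative cut).
#' @return List: `scores` (non-outliers), `flags` (logical, TRUE = outlier),
#'   `median`, `mad`.
#' @export
remove_outliers <- function(scores, n_mad = 5) {
  if (length(scores) < 3) stop("need at least 3 participants")
  med <- stats::median(scores)
  md <- stats::mad(scores)             # 1.4826 scaling is mad()'s default
  if (md == 0) {
    warning("MAD is zero: no outliers removed")
    flags <- rep(FALSE, length(scores))
  } else {
    flags <- abs(scores - med) / md > n_mad
  }
  list(scores = scores[!flags], flags = flags, median = med, mad = md)
}

#' Category vs non-category benchmark contrast
#'
#' One-tailed paired t test that category responses exceed the average of the
#' three remaining categories' responses, with Cohen's d for paired samples
#' (mean difference over SD of differences).
#'
#' @param category,noncategory Per-participant response vectors (paired).
#' @return List: `t`, `df`, `p` (one-tailed parametric), `cohens_d`,
#'   `mean_diff`.
#' @export
benchmark_contrast <- function(category, noncategory) {
  if (length(category) != length(noncategory))
    stop("category and noncategory must be paired")
  if (length(category) < 2) stop("need at least 2 participants")
  d <- category - noncategory
  sd_d <- stats::sd(d)
  if (sd_d == 0) stop("zero variance in paired differences: t undefined")
  n <- length(d)
  tstat <- mean(d) / (sd_d / sqrt(n))
  list(t = tstat, df = n - 1,
       p = stats::pt(tstat, n - 1, lower.tail = FALSE),
       cohens_d = mean(d) / sd_d, mean_diff = mean(d))
}

#' Per-participant complex selectivity and distributed contribution
#'
#' Pipeline helper tying the pieces together for one participant and one
#' functional complex: min-max normalizes actual and mapped activations using
#' the actual reference (per unit), computes actual and mapped category
#' selectivity, and the percent distributed contribution.
#'
#' @param actual Unit x condition actual activations of the complex's units.
#' @param mapped Unit x condition mapped activations (same units).
#' @param category_conditions,noncategory_conditions Condition index sets.
#' @param aggregate Passed to [category_selectivity()].
#' @param separate_reference If TRUE, mapped values are normalized with their
#'   own min/max instead of the actual reference (reported by the study as a
#'   near-equivalent variant).
#' @return List: `actual_selectivity`, `mapped_selectivity`,
#'   `contribution_pct`.
#' @export
complex_selectivity <- function(actual, mapped, category_conditions,
                                noncategory_conditions,
                                aggregate = "per-unit",
                                separate_reference = FALSE) {
  actual <- rbind(as.matrix(actual))
  mapped <- rbind(as.matrix(mapped))
  na <- t(apply(actual, 1, function(r) minmax_normalize(r, ref = r)))
  nm <- matrix(NA_real_, nrow(mapped), ncol(mapped))
  for (i in seq_len(nrow(mapped)))
    nm[i, ] <- minmax_normalize(mapped[i, ],
                                ref = if (separate_reference) mapped[i, ]
                                      else actual[i, ])
  s_act <- category_selectivity(na, category_conditions,
                                noncategory_conditions, aggregate)
  s_map <- category_selectivity(nm, category_conditions,
                                noncategory_conditions, aggregate)
  list(actual_selectivity = s_act, mapped_selectivity = s_map,
       contribution_pct = distributed_contribution(s_map, s_act))
}
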