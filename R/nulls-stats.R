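#' Substitute a complex's connectivity fingerprint
#'
#' Null connectivity model: the target complex's rows (its connectivity
#' fingerprint) are replaced by the donor complex's rows; the target
#' complex's self-connection block is set to zero; and the entries from the
#' target complex to the donor complex's columns — zero in the donor's own
#' rows — are filled with the transposed original estimates
#' fc[donor rows, target columns].
#'
#' @param fc Connectivity matrix or `fc_matrix`.
#' @param target_complex Unit indices of the complex whose fingerprint is
#'   replaced.
#' @param donor_complex Unit indices of the donor complex (same size; disjoint
#'   from the target complex unless identical).
#' @return Weight matrix of the same shape with the substituted fingerprint.
#' @export
substitute_fingerprint <- function(fc, target_complex, donor_complex) {
  W <- fc_weights(fc)
  if (length(target_complex) != length(donor_complex))
    stop("complexes must have equal size for fingerprint substitution")
  same <- identical(sort(target_complex), sort(donor_complex))
  if (!same && length(intersect(target_complex, donor_complex)))
    stop("complexes must be disjoint")
  out <- W
  out[target_complex, ] <- W[donor_complex, ]
  out[target_complex, target_complex] <- 0
  if (!same)
    out[target_complex, donor_complex] <-
      t(W[donor_complex, target_complex, drop = FALSE])
  out
}

## One attempt at a directed double-edge swap: (a->b, c->d) => (a->d, c->b).
## Preserves every unit's in- and out-degree.
try_swap <- function(edges, n, present, forbidden) {
  k <- nrow(edges)
  pick <- sample.int(k, 2)
  e1 <- edges[pick[1], ]; e2 <- edges[pick[2], ]
  a <- e1[1]; b <- e1[2]; c <- e2[1]; d <- e2[2]
  if (a == d || c == b) return(NULL)                       # self-loops
  if (present[a, d] || present[c, b]) return(NULL)          # duplicates
  if (forbidden[a, d] || forbidden[c, b]) return(NULL)      # masked
  list(pick = pick, new1 = c(a, d), new2 = c(c, b))
}

#' Degree- and strength-preserving permuted connectivity
#'
#' Null architectures built by double-edge-swap rewiring (preserving every
#' unit's binary in/out-degree) followed by a random permutation of the
#' original nonzero edge-weight multiset over the rewired edges. Zero diagonal
#' and exclusion masks are respected.
#'
#' @param fc Connectivity matrix or `fc_matrix`.
#' @param n_perms Number of null matrices.
#' @param seed RNG seed recorded in the output.
#' @param n_swaps Swap attempts per null (default 10x the edge count).
#' @param mask Optional exclusion mask forbidding rewired edges.
#' @return List of class `null_fc_set`: `nulls` (list of matrices),
#'   `null_kind = "permuted-architecture"`, `seed`.
#' @export
permute_architecture <- function(fc, n_perms = 100, seed = 1L,
                                 n_swaps = NULL, mask = NULL) {
  W <- fc_weights(fc)
  n <- nrow(W)
  edges <- which(W != 0, arr.ind = TRUE)
  if (nrow(edges) < 2) stop("graph has too few edges to rewire")
  forbidden <- matrix(FALSE, n, n)
  if (!is.null(mask)) forbidden <- unclass(mask)
  diag(forbidden) <- TRUE
  if (is.null(n_swaps)) n_swaps <- 10L * nrow(edges)
  set.seed(seed)
  nulls <- lapply(seq_len(n_perms), function(k) {
    e <- edges
    present <- W != 0
    done <- 0L; attempts <- 0L
    while (done < n_swaps && attempts < 100L * n_swaps) {
      attempts <- attempts + 1L
      sw <- try_swap(e, n, present, forbidden)
      if (is.null(sw)) next
      old1 <- e[sw$pick[1], ]; old2 <- e[sw$pick[2], ]
      present[old1[1], old1[2]] <- FALSE
      present[old2[1], old2[2]] <- FALSE
      present[sw$new1[1], sw$new1[2]] <- TRUE
      present[sw$new2[1], sw$new2[2]] <- TRUE
      e[sw$pick[1], ] <- sw$new1
      e[sw$pick[2], ] <- sw$new2
      done <- done + 1L
    }
    if (done == 0L)
      stop("graph too dense or degenerate to rewire")
    Wn <- matrix(0, n, n)
    Wn[e] <- sample(W[edges])           # permute the weight multiset
    Wn
  })
  structure(list(nulls = nulls, null_kind = "permuted-architecture",
                 seed = seed),
            class = "null_fc_set")
}

#' Max-T family-wise error corrected permutation test
#'
#' Runs the max-T procedure across a family of comparisons sharing the
#' participant axis. Per permutation the scheme is applied — condition-label
#' exchange for paired contrasts (equivalent to sign-flipping the paired
#' differences) or sign-flipping of participant deviations from the null mean
#' for one-sample tests against a non-zero null — all t statistics are
#' recomputed, and the maximum is recorded. Corrected p-values are
#' (1 + #\{max-T >= observed\}) / (1 + n_perm); the corrected threshold is the
#' (1 - alpha) quantile of the max-T distribution.
#'
#' @param data Participant x comparison matrix. For `condition_shuffle`,
#'   supply the paired differences (category minus non-category) per
#'   comparison.
#' @param mu0 Null mean subtracted before testing (e.g., 1.0 for selectivity
#'   ratios, 50 for contribution percentages).
#' @param n_perm Number of permutations.
#' @param alpha Family-wise error level for the threshold.
#' @param scheme `"sign_flip"` or `"condition_shuffle"` (both realized as
#'   sign-flips of the appropriate deviations; the label records the design).
#' @param alternative `"greater"` (default, one-tailed), `"less"`, or
#'   `"two.sided"`.
#' @param seed RNG seed recorded in the result.
#' @return List of class `maxt_result`: `observed` (t per comparison),
#'   `max_t` (null distribution), `threshold`, `p_corrected`, `n_perm`,
#'   `seed`, `scheme`.
#' @export
maxt_test <- function(data, mu0 = 0, n_perm = 1000, alpha = 0.05,
                      scheme = c("sign_flip", "condition_shuffle"),
                      alternative = c("greater", "less", "two.sided"),
                      seed = 1L) {
  scheme <- match.arg(scheme)
  alternative <- match.arg(alternative)
  X <- as.matrix(data) - mu0
  n <- nrow(X); k <- ncol(X)
  if (n < 2) stop("need at least 2 participants")
  tstat <- function(M) {
    mu <- colMeans(M)
    se <- apply(M, 2, stats::sd) / sqrt(n)
    ## exchangeability-degenerate comparisons (zero spread, zero mean) get
    ## t = 0 so their corrected p is 1
    t <- ifelse(se == 0, ifelse(mu == 0, 0, sign(mu) * Inf), mu / se)
    switch(alternative, greater = t, less = -t, two.sided = abs(t))
  }
  observed <- tstat(X)
  set.seed(seed)
  max_t <- vapply(seq_len(n_perm), function(i) {
    signs <- sample(c(-1, 1), n, replace = TRUE)
    max(tstat(X * signs))
  }, numeric(1))
  p_corr <- vapply(observed, function(t0)
    (1 + sum(max_t >= t0)) / (1 + n_perm), numeric(1))
  structure(list(observed = observed,
                 max_t = max_t,
                 threshold = stats::quantile(max_t, 1 - alpha, names = FALSE),
                 p_corrected = p_corr,
                 n_perm = n_perm, seed = seed, scheme = scheme,
                 alternative = alternative),
            class = "maxt_result")
}
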