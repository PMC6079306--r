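#' Victor-Purpura spike-train distance
#'
#' Minimum cost of transforming one spike train into another using the edit
#' operations: add or delete a spike (cost 1) and shift a spike by `dt`
#' (cost `q * |dt|`). Computed by dynamic programming; a proper metric on
#' spike trains.
#'
#' @param a,b sorted spike-time vectors (s).
#' @param q shift cost rate (1/s); 10/s in the learning analyses.
#' @return non-negative distance.
#' @export
victor_purpura <- function(a, b, q = 10) {
  if (q < 0) stop("q must be >= 0")
  if (is.unsorted(a) || is.unsorted(b)) stop("spike trains must be sorted")
  cpp_vp_distance(as.numeric(a), as.numeric(b), q)
}

#' Correlation index of a group of PA channels
#'
#' Mean pairwise Victor-Purpura distance among a group of channels,
#' averaged across stimuli. Convention: this is a distance, so a LOWER index
#' means MORE correlated spiking. The learning analyses compare the ten
#' high-end-weight "winner" channels against ten high-seed-weight "loser"
#' channels; the winners-are-more-correlated effect appears as
#' `index(losers) - index(winners) > 0`.
#'
#' @param trains_by_stimulus list over stimuli; each element a list of spike
#'   trains, one per group member.
#' @param q Victor-Purpura shift cost rate (1/s).
#' @return list with `index` (scalar mean pairwise VPd), `per_synapse`
#'   (each member's mean distance to the rest of the group, averaged over
#'   stimuli) and `per_stimulus`.
#' @export
correlation_index <- function(trains_by_stimulus, q = 10) {
  if (length(trains_by_stimulus) == 0) stop("empty group")
  m <- length(trains_by_stimulus[[1]])
  per_stim <- numeric(length(trains_by_stimulus))
  per_syn <- matrix(0, length(trains_by_stimulus), m)
  for (s in seq_along(trains_by_stimulus)) {
    tr <- trains_by_stimulus[[s]]
    if (length(tr) != m) stop("group size must be constant across stimuli")
    d <- matrix(0, m, m)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d[i, j] <- d[j, i] <- victor_purpura(tr[[i]], tr[[j]], q)
    }
    per_stim[s] <- mean(d[upper.tri(d)])
    per_syn[s, ] <- rowSums(d) / (m - 1)
  }
  list(index = mean(per_stim), per_synapse = colMeans(per_syn),
       per_stimulus = per_stim)
}

#' Reconstructed synaptic response
#'
#' Convolves each PA spike train with the EPSP exponential-decay kernel
#' (time constant 6.4 ms), weights each convolved signal by its synaptic
#' weight and sums: the simulated intracellular synaptic signal of the CN.
#'
#' @param trains list of spike trains (s).
#' @param w_exc weight vector, same length as `trains`.
#' @param tau EPSP decay constant (s).
#' @param duration window (s).
#' @param dt response grid step (s); 1 ms default.
#' @return numeric series on `seq(0, duration, by = dt)`.
#' @export
reconstruct_response <- function(trains, w_exc, tau = 6.4e-3,
                                 duration, dt = 1e-3) {
  if (length(trains) != length(w_exc))
    stop("weights and spike trains must have equal length")
  t_grid <- seq(0, duration, by = dt)
  out <- numeric(length(t_grid))
  decay <- exp(-dt / tau)
  for (i in seq_along(trains)) {
    if (w_exc[i] == 0 || length(trains[[i]]) == 0) next
    counts <- tabulate(pmin(floor(trains[[i]] / dt) + 1L, length(t_grid)),
                       nbins = length(t_grid))
    s <- as.numeric(stats::filter(counts, decay, method = "recursive"))
    out <- out + w_exc[i] * s
  }
  out
}

#' Normalized zero-lag cross-correlation
#'
#' `sum(x y) / sqrt(sum(x^2) sum(y^2))`, the zero-lag value of the
#' normalized cross-correlation sequence (no mean subtraction), in
#' `[-1, 1]`. Zero-variance input yields 0 with a warning.
#'
#' @param x,y equal-length numeric series.
#' @return correlation coefficient.
#' @export
zero_lag_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("series must have equal length")
  nx <- sum(x^2); ny <- sum(y^2)
  if (nx == 0 || ny == 0) {
    warning("zero-energy input; correlation defined as 0")
    return(0)
  }
  sum(x * y) / sqrt(nx * ny)
}

#' Sparseness of a weight vector
#'
#' Ratio of the l2 and l1 norms: 1 for a one-hot vector, `1/sqrt(n)` for a
#' uniform vector of length n. Scale invariant. Used to track the dispersion
#' of the synaptic weight distribution during learning.
#'
#' @param w non-negative weight vector, not all zero.
#' @return value in `(0, 1]`.
#' @export
sparseness <- function(w) {
  if (any(w < 0)) stop("weights must be non-negative")
  l1 <- sum(w)
  if (l1 == 0) stop("all-zero weight vector")
  sqrt(sum(w^2)) / l1
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Double-centered Gram eigendecomposition (classical MDS) of a symmetric
#' distance matrix, typically Euclidean distances between 80-dimensional
#' synaptic weight landscapes. If fewer than `dims` positive eigenvalues
#' exist the remaining coordinates are zero-padded with a warning.
#'
#' @param d symmetric non-negative matrix with zero diagonal, or a `dist`.
#' @param dims embedding dimension (default 2).
#' @return list with `points` (n x dims coordinates) and `eig`
#'   (eigenvalues).
#' @export
classical_mds <- function(d, dims = 2) {
  dm <- as.matrix(d)
  if (nrow(dm) != ncol(dm) || any(abs(dm - t(dm)) > 1e-8) ||
      any(abs(diag(dm)) > 1e-12))
    stop("d must be a symmetric distance matrix with zero diagonal")
  fit <- stats::cmdscale(dm, k = min(dims, nrow(dm) - 1), eig = TRUE)
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1)
  if (ncol(pts) < dims) {
    warning("fewer than ", dims, " positive eigenvalues; zero-padding")
    pts <- cbind(pts, matrix(0, nrow(pts), dims - ncol(pts)))
  }
  rownames(pts) <- rownames(dm)
  list(points = pts[, seq_len(dims), drop = FALSE], eig = fit$eig)
}

#' Paired comparison of before/after values
#'
#' Paired two-sided t-test or Wilcoxon signed-rank test, as used to report
#' learning effects (winner/loser correlation indices, response
#' decorrelation). Degenerate input (all differences zero) returns p = 1
#' with a note instead of an error.
#'
#' @param before,after equal-length numeric vectors (n >= 5).
#' @param test `"t"` or `"wilcoxon"`.
#' @return list with `statistic`, `p_value`, `test` and optional `note`.
#' @export
paired_stats <- function(before, after, test = c("t", "wilcoxon")) {
  test <- match.arg(test)
  if (length(before) != length(after)) stop("paired vectors must match")
  if (length(before) < 5) stop("need at least 5 pairs")
  if (all(before == after)) {
    return(list(statistic = 0, p_value = 1, test = test,
                note = "all paired differences are zero"))
  }
  d <- after - before
  if (stats::sd(d) == 0) {
    # constant non-zero shift: the paired t statistic is unbounded
    return(list(statistic = sign(mean(before) - mean(after)) * Inf,
                p_value = 0, test = test,
                note = "all paired differences are identical"))
  }
  res <- if (test == "t") stats::t.test(before, after, paired = TRUE)
  else stats::wilcox.test(before, after, paired = TRUE, exact = FALSE)
  list(statistic = unname(res$statistic), p_value = res$p.value, test = test)
}
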