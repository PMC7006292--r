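#' Maximal grid size B(n)
#'
#' Total-cell budget for the MIC grid search, \code{B(n) = n^alpha}. Grids
#' with \code{n_bins_x * n_bins_y >= B(n)} are not searched. With a binary
#' phenotype the y-axis always contributes 2 bins, so the admissible x-bin
#' counts are \code{2 <= k} with \code{2 * k < B(n)} (relaxed to always admit
#' k = 2, see \code{\link{mic_binary}}).
#'
#' @param n Sample count, at least 8.
#' @param alpha Grid-size exponent in (0, 1); default 0.6.
#' @return The real-valued bound \code{n^alpha}.
#' @examples
#' max_grid_size(100)      # 15.848...
#' max_grid_size(12, 0.6)  # 4.44..., so only a single cut is admissible
#' @export
max_grid_size <- function(n, alpha = 0.6) {
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n < 8)
    stop("`n` must be a single finite number >= 8 (minimum sample count is 8)")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single number strictly between 0 and 1")
  n^alpha
}

#' Mutual information of a binned binary-label table
#'
#' Mutual information (bits) between the bin assignment and the binary label,
#' from a table of label counts per bin: \code{I = H(Y) - H(Y | bin)} with the
#' convention \code{0 * log(0) = 0}.
#'
#' @param counts Numeric matrix of non-negative counts with bins as rows and
#'   the two label values as columns (k x 2), or the transpose (2 x k) when k
#'   is not 2; total count must be at least 1 and there must be at least 2 bins.
#' @return Mutual information in bits, in \code{[0, min(H(Y), log2(k))]}.
#' @examples
#' binned_mi(rbind(c(4, 0), c(0, 4)))  # perfect separation: 1 bit
#' binned_mi(rbind(c(2, 2), c(2, 2)))  # independence: 0
#' @export
binned_mi <- function(counts) {
  if (is.null(counts) || length(counts) == 0L)
    stop("`counts` must be a non-empty matrix of label counts per bin")
  counts <- as.matrix(counts)
  if (ncol(counts) != 2L && nrow(counts) == 2L) counts <- t(counts)
  if (ncol(counts) != 2L)
    stop("`counts` must have two label columns (bins as rows)")
  if (nrow(counts) < 2L) stop("`counts` must have at least 2 bins")
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("`counts` must be non-negative and finite")
  n <- sum(counts)
  if (n < 1) stop("`counts` must sum to at least 1")
  hy <- .entropy_bits(colSums(counts))
  w <- rowSums(counts)
  hcond <- sum(vapply(seq_len(nrow(counts)), function(i) {
    if (w[i] == 0) 0 else (w[i] / n) * .entropy_bits(counts[i, ])
  }, numeric(1)))
  max(hy - hcond, 0)
}

# Shannon entropy in bits of a count vector (0 log 0 = 0).
.entropy_bits <- function(cnt) {
  tot <- sum(cnt)
  if (tot == 0) return(0)
  p <- cnt[cnt > 0] / tot
  -sum(p * log2(p))
}

# Validate an (x, y) expression/label pair; returns y recoded to 0/1 integer.
.validate_series <- function(x, y) {
  if (length(x) != length(y))
    stop("`x` and `y` must have equal length")
  n <- length(x)
  if (n < 8) stop("at least 8 samples are required (got ", n, ")")
  if (any(is.na(x)) || any(!is.finite(x)))
    stop("`x` contains missing or non-finite values")
  uy <- sort(unique(y))
  if (length(uy) != 2L)
    stop("`y` must contain exactly two distinct label values, each at least once")
  as.integer(y == uy[2L])
}

# Admissible number of x-axis bins: 2 <= k with 2k < n^alpha, relaxed so that
# k = 2 (the single-cut family) is always available for n >= 8.
.kmax_bins <- function(n, alpha) {
  max(2L, as.integer(ceiling(n^alpha / 2) - 1))
}

#' MIC between a continuous vector and a binary label
#'
#' Estimates the maximal information coefficient for a continuous expression
#' vector against a binary phenotype. Because the phenotype axis has exactly
#' two categories, every grid normalises by \code{log2(2) = 1} and the
#' characteristic-matrix maximisation reduces to maximising the mutual
#' information over partitions of the x axis. The default exhaustive mode
#' finds the exact optimum by dynamic programming over cut positions; cuts are
#' placed only between strictly different consecutive sorted values, so tied
#' samples are never split and the score depends on x only through its
#' ordering (invariant under strictly increasing transforms).
#'
#' A constant \code{x} admits no cut and returns \code{mic = 0} with
#' \code{n_bins_x = 1} rather than an error, so whole-matrix scans never abort.
#'
#' The \code{"chi_square"} termination is a greedy approximation in the spirit
#' of chi-square-pruned MIC estimators: cuts are added one at a time, each
#' time choosing the split that most increases the mutual information, and
#' refinement stops when the 2x2 table of the two newly created sub-bins shows
#' no association at \code{chi_level} (plain Pearson chi-square, df = 1). It
#' trades exactness for resistance to finite-sample inflation and is never
#' used where an exact optimum is asserted.
#'
#' @param x Numeric expression vector (length >= 8, finite).
#' @param y Binary label vector, same length, both labels present.
#' @param alpha Grid-size exponent for \code{\link{max_grid_size}}.
#' @param termination \code{"exhaustive"} (exact DP, default) or
#'   \code{"chi_square"} (greedy early stop).
#' @param chi_level Significance level for the chi-square early stop.
#' @return A list of class \code{"mic_result"}: \code{mic} (in [0, 1]),
#'   \code{n_bins_x}, and \code{cuts} — the optimizing cut positions as
#'   indices into the x-sorted sample order (a cut at t separates sorted
#'   samples 1..t from t+1..n).
#' @examples
#' mic_binary(c(1, 2, 3, 4, 10, 11, 12, 13), c(0, 0, 0, 0, 1, 1, 1, 1))$mic  # 1
#' mic_binary(1:12, c(0, 0, 0, 0, 1, 1, 1, 1, 0, 0, 0, 0))$mic  # 0.2516...
#' @export
mic_binary <- function(x, y, alpha = 0.6,
                       termination = c("exhaustive", "chi_square"),
                       chi_level = 0.05) {
  termination <- match.arg(termination)
  if (!is.numeric(chi_level) || length(chi_level) != 1L ||
      chi_level <= 0 || chi_level >= 1)
    stop("`chi_level` must be strictly between 0 and 1")
  y01 <- .validate_series(x, y)
  n <- length(x)
  max_grid_size(n, alpha)  # validates n and alpha

  ord <- order(x)
  ys <- y01[ord]
  xs <- x[ord]
  cand <- which(diff(xs) > 0)      # cut after position t splits xs[t] < xs[t+1]
  if (length(cand) == 0L)
    return(structure(list(mic = 0, n_bins_x = 1L, cuts = integer(0)),
                     class = "mic_result"))
  kmax <- min(.kmax_bins(n, alpha), length(cand) + 1L)
  prefix1 <- c(0L, cumsum(ys))     # class-1 count among first t sorted samples

  if (termination == "chi_square")
    return(.mic_greedy_chisq(prefix1, cand, n, kmax, chi_level))
  .mic_dp(prefix1, cand, n, kmax)
}

# Weighted-entropy cost (in bits, scaled by segment size) of sorted segments
# (u, v]; u, v vectors of boundary positions with prefix1 the 0-based prefix
# class-1 counts. Minimising the summed cost maximises I = H(Y) - cost/n.
.segment_cost <- function(prefix1, u, v) {
  tot <- v - u
  n1 <- prefix1[v + 1L] - prefix1[u + 1L]
  n0 <- tot - n1
  plog <- function(k, t) ifelse(k > 0, k * log2(k / t), 0)
  -(plog(n1, tot) + plog(n0, tot))
}

# Exact DP over cut positions. pos = attainable boundaries (0, candidates, n);
# D_k[j] = minimal summed segment cost of splitting (0, pos_j] into k bins.
# Mutual information never decreases under refinement, so the optimum over
# "at most kmax" bins is scanned by taking the best over k = 2..kmax; the
# smallest k attaining the maximum (within 1e-12) is reported.
.mic_dp <- function(prefix1, cand, n, kmax) {
  pos <- c(0L, cand, n)
  m <- length(pos)
  hy <- .entropy_bits(c(prefix1[n + 1L], n - prefix1[n + 1L]))

  # cost matrix C[i, j] for segment (pos_i, pos_j], i < j
  C <- matrix(Inf, m, m)
  iu <- which(upper.tri(C), arr.ind = TRUE)
  C[iu] <- .segment_cost(prefix1, pos[iu[, 1L]], pos[iu[, 2L]])

  D <- C[1L, ]                               # k = 1: one bin (0, pos_j]
  back <- vector("list", kmax)               # back[[k]][j]: argmin boundary
  mic_by_k <- rep(NA_real_, kmax)
  for (k in 2:kmax) {
    M <- D + C                               # M[i, j] = D[i] + C[i, j]
    D <- apply(M, 2L, min)
    back[[k]] <- apply(M, 2L, which.min)
    if (is.finite(D[m])) mic_by_k[k] <- max(hy - D[m] / n, 0)
  }
  if (all(is.na(mic_by_k)))
    return(structure(list(mic = 0, n_bins_x = 1L, cuts = integer(0)),
                     class = "mic_result"))
  best_mic <- max(mic_by_k, na.rm = TRUE)
  best_k <- which(!is.na(mic_by_k) & mic_by_k >= best_mic - 1e-12)[1L]
  cuts <- integer(0)
  j <- m
  for (k in best_k:2L) {
    j <- back[[k]][j]
    cuts <- c(pos[j], cuts)
  }
  structure(list(mic = best_mic, n_bins_x = best_k, cuts = cuts),
            class = "mic_result")
}

# Greedy refinement with a chi-square local stop: repeatedly add the cut that
# maximises I; accept it only while the 2x2 table of the two sub-bins it
# creates is significant (Pearson chi-square, df = 1, no continuity
# correction) at chi_level.
.mic_greedy_chisq <- function(prefix1, cand, n, kmax, chi_level) {
  hy <- .entropy_bits(c(prefix1[n + 1L], n - prefix1[n + 1L]))
  bounds <- c(0L, n)
  cuts <- integer(0)
  repeat {
    if (length(bounds) - 1L >= kmax) break
    avail <- setdiff(cand, cuts)
    if (length(avail) == 0L) break
    # cost change from inserting each available cut into its segment
    delta <- vapply(avail, function(t) {
      lo <- max(bounds[bounds < t])
      hi <- min(bounds[bounds > t])
      sum(.segment_cost(prefix1, c(lo, t), c(t, hi))) -
        .segment_cost(prefix1, lo, hi)
    }, numeric(1))
    t_new <- avail[which.min(delta)]
    lo <- max(bounds[bounds < t_new])
    hi <- min(bounds[bounds > t_new])
    tab <- rbind(
      c(t_new - lo - (prefix1[t_new + 1L] - prefix1[lo + 1L]),
        prefix1[t_new + 1L] - prefix1[lo + 1L]),
      c(hi - t_new - (prefix1[hi + 1L] - prefix1[t_new + 1L]),
        prefix1[hi + 1L] - prefix1[t_new + 1L]))
    p <- tryCatch(
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value),
      error = function(e) 1)
    if (!is.finite(p) || p >= chi_level) break
    cuts <- sort(c(cuts, t_new))
    bounds <- sort(c(bounds, t_new))
  }
  cost <- sum(.segment_cost(prefix1, bounds[-length(bounds)], bounds[-1L]))
  k <- length(bounds) - 1L
  mic <- if (k >= 2L) max(hy - cost / n, 0) else 0
  structure(list(mic = mic, n_bins_x = max(k, 1L), cuts = cuts),
            class = "mic_result")
}

#' Brute-force MIC oracle
#'
#' Exhaustively enumerates every admissible cut-point subset and returns the
#' maximising grid. Intended as an independent verification oracle for
#' \code{\link{mic_binary}} on small inputs; refuses \code{n > 30}.
#'
#' @inheritParams mic_binary
#' @return A list like \code{\link{mic_binary}}'s.
#' @export
brute_force_mic <- function(x, y, alpha = 0.6) {
  if (length(x) > 30)
    stop("brute_force_mic is limited to n <= 30 (got ", length(x), ")")
  y01 <- .validate_series(x, y)
  n <- length(x)
  max_grid_size(n, alpha)
  ord <- order(x)
  ys <- y01[ord]
  xs <- x[ord]
  cand <- which(diff(xs) > 0)
  if (length(cand) == 0L)
    return(structure(list(mic = 0, n_bins_x = 1L, cuts = integer(0)),
                     class = "mic_result"))
  kmax <- min(.kmax_bins(n, alpha), length(cand) + 1L)
  prefix1 <- c(0L, cumsum(ys))
  hy <- .entropy_bits(c(prefix1[n + 1L], n - prefix1[n + 1L]))
  best <- NULL
  for (k in 2:kmax) {
    if (length(cand) < k - 1L) break
    # combn(scalar, m) would enumerate 1:scalar; guard the single-cut case
    combs <- if (length(cand) == 1L) list(cand) else
      utils::combn(cand, k - 1L, simplify = FALSE)
    for (cc in combs) {
      b <- c(0L, cc, n)
      cost <- sum(.segment_cost(prefix1, b[-length(b)], b[-1L]))
      mic <- max(hy - cost / n, 0)
      if (is.null(best) || mic > best$mic + 1e-12)
        best <- list(mic = mic, n_bins_x = k, cuts = cc)
    }
  }
  structure(best, class = "mic_result")
}
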