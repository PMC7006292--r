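#' Permutation null distribution and MIC significance threshold
#'
#' Builds the finite-sample MIC null by repeatedly (i) drawing one gene
#' uniformly at random from the expression matrix (with replacement),
#' (ii) shuffling its sample order, and (iii) computing the MIC of the
#' shuffled expression against the unshuffled labels. The permuted scores are
#' sorted ascending and the threshold is the nearest-rank fractile at
#' \code{level}: the value at 1-based index \code{ceiling(level * n_perm)}.
#' This threshold (the 95\% fractile by default) is the significance floor
#' subtracted inside the NDC numerator.
#'
#' @param mat Numeric genes-by-samples expression matrix with row and column
#'   names (see \code{\link{read_expression}}).
#' @param labels Binary label vector aligned to the matrix columns.
#' @param n_perm Number of permutations, at least 100; default 1000.
#' @param level Fractile level in (0, 1); default 0.95.
#' @param seed Integer RNG seed; the run is fully reproducible given it.
#' @param alpha Grid-size exponent passed to \code{\link{mic_binary}}.
#' @return A list of class \code{"ndc_null"}: \code{values} (sorted permuted
#'   MIC scores), \code{n_perm}, \code{level}, \code{threshold}, \code{seed}.
#' @export
perm_threshold <- function(mat, labels, n_perm = 1000, level = 0.95,
                           seed = 42L, alpha = 0.6) {
  mat <- .as_expr_matrix(mat)
  if (n_perm < 100)
    stop("`n_perm` must be at least 100: the fractile is too unstable below that")
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("`level` must be strictly between 0 and 1")
  if (ncol(mat) != length(labels))
    stop("`labels` length must equal the number of matrix columns")
  if (all(apply(mat, 1L, function(v) stats::var(v) == 0)))
    stop("all genes in the matrix are constant; no permutation null can be built")
  vals <- .with_seed(seed, {
    gi <- sample(nrow(mat), n_perm, replace = TRUE)
    vapply(gi, function(g) {
      mic_binary(sample(mat[g, ]), labels, alpha = alpha)$mic
    }, numeric(1))
  })
  vals <- sort(vals)
  idx <- ceiling(level * n_perm)
  structure(list(values = vals, n_perm = as.integer(n_perm), level = level,
                 threshold = vals[idx], seed = as.integer(seed)),
            class = "ndc_null")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' The NDC score
#'
#' The normalized differential correlation for one gene:
#' \deqn{NDC = (MIC - R^2 - Thre_{MIC}) / |R|}
#' The numerator is the nonlinear association in excess of both the linear
#' association (\eqn{R^2}) and the finite-sample MIC significance floor
#' (\eqn{Thre_{MIC}}); dividing by \eqn{|R|} amplifies genes whose linear
#' correlation with the phenotype is weak. A large positive score therefore
#' flags a strong nonlinear but weak linear association. The denominator is
#' floored at \code{eps} so that genes with essentially zero linear
#' correlation give large finite scores of the numerator's sign rather than
#' non-finite values.
#'
#' @param mic MIC score in [0, 1].
#' @param r Point-biserial correlation in [-1, 1].
#' @param threshold The permutation MIC threshold in [0, 1].
#' @param eps Denominator floor; default 1e-8.
#' @return The NDC score (may be negative). Vectorised over its arguments.
#' @examples
#' ndc_score(0.8, 0.1, 0.3)   # 4.9
#' ndc_score(0.5, -0.5, 0.25) # 0
#' @export
ndc_score <- function(mic, r, threshold, eps = 1e-8) {
  (mic - r^2 - threshold) / pmax(abs(r), eps)
}

#' Score every gene of an expression matrix
#'
#' Computes, for each gene (row), the MIC against the labels, the
#' point-biserial correlation and determination coefficient, the Welch-t
#' comparator, and the NDC score using the supplied permutation null.
#' Constant genes have an undefined correlation; they receive
#' \code{ndc = -Inf} (a rank-last sentinel) with a warning, so the output
#' always has one row per input gene in input order.
#'
#' @inheritParams perm_threshold
#' @param null A permutation null from \code{\link{perm_threshold}}, or a
#'   single numeric threshold.
#' @param eps Denominator floor for \code{\link{ndc_score}}.
#' @return A data frame with one row per gene: \code{gene_id}, \code{mic},
#'   \code{r}, \code{r2}, \code{ndc}, \code{t_stat}, \code{t_p}.
#' @export
score_all <- function(mat, labels, null, eps = 1e-8, alpha = 0.6) {
  mat <- .as_expr_matrix(mat)
  if (ncol(mat) != length(labels))
    stop("`labels` length must equal the number of matrix columns")
  threshold <- if (inherits(null, "ndc_null")) null$threshold else as.numeric(null)
  if (!is.finite(threshold) || threshold < 0 || threshold > 1)
    stop("`null` must be an ndc_null object or a threshold in [0, 1]")
  ids <- rownames(mat)
  n_genes <- nrow(mat)
  mic <- r <- r2 <- tstat <- tp <- numeric(n_genes)
  for (g in seq_len(n_genes)) {
    xg <- mat[g, ]
    mic[g] <- mic_binary(xg, labels, alpha = alpha)$mic
    pb <- point_biserial(xg, labels)
    r[g] <- pb$r
    r2[g] <- pb$r2
    if (is.na(pb$r)) {
      tstat[g] <- NA_real_
      tp[g] <- NA_real_
    } else {
      # genes constant within each class have no defined t; keep the row
      wt <- tryCatch(welch_t(xg, labels),
                     error = function(e) list(t = NA_real_, p = NA_real_))
      tstat[g] <- wt$t
      tp[g] <- wt$p
    }
  }
  ndc <- ifelse(is.na(r), -Inf, ndc_score(mic, r, threshold, eps))
  n_const <- sum(is.na(r))
  if (n_const > 0)
    warning(n_const, " constant gene(s) received the rank-last NDC sentinel")
  data.frame(gene_id = ids, mic = mic, r = r, r2 = r2, ndc = ndc,
             t_stat = tstat, t_p = tp, stringsAsFactors = FALSE)
}

#' Two-stage final gene ranking
#'
#' Stage 1 sorts all genes by NDC score descending (ties: MIC descending,
#' then gene id). Stage 2 re-sorts the first \code{min(top_pool, n_genes)}
#' genes of that ordering by MIC descending (ties: NDC descending, then gene
#' id), so that among the strongly nonlinear candidates the most informative
#' rise to the top; genes outside the pool keep their stage-1 order after the
#' pool.
#'
#' @param scores A data frame from \code{\link{score_all}} (needs columns
#'   \code{gene_id}, \code{ndc}, \code{mic}).
#' @param top_pool Size of the stage-2 re-sort pool; default 1000.
#' @return Character vector of gene ids in final rank order.
#' @export
final_ranking <- function(scores, top_pool = 1000) {
  if (!is.data.frame(scores) || nrow(scores) == 0L)
    stop("`scores` must be a non-empty data frame")
  if (top_pool < 1) stop("`top_pool` must be at least 1")
  stage1 <- scores[order(-scores$ndc, -scores$mic, scores$gene_id), ]
  pool <- min(top_pool, nrow(stage1))
  head_df <- stage1[seq_len(pool), ]
  head_df <- head_df[order(-head_df$mic, -head_df$ndc, head_df$gene_id), ]
  c(head_df$gene_id, stage1$gene_id[-seq_len(pool)])
}

#' Rank genes by normalized differential correlation
#'
#' The full pipeline: build (or accept) the permutation MIC threshold, score
#' every gene, and attach both ranking positions — \code{rank_ndc}, the
#' position in the plain NDC-descending ordering, and \code{rank_final}, the
#' position after the two-stage re-sort (\code{NA} outside the top pool).
#'
#' @inheritParams perm_threshold
#' @inheritParams score_all
#' @param top_pool Stage-2 pool size for \code{\link{final_ranking}}.
#' @param log2p1 Apply \code{log2(x + 1)} to the matrix before scoring (for
#'   raw-scale inputs; Xena level-3 matrices arrive already log-transformed).
#'   MIC is invariant to this monotone transform but r and r2 are not.
#' @param null Optional precomputed \code{\link{perm_threshold}} result; when
#'   supplied, \code{n_perm}/\code{level}/\code{seed} are ignored.
#' @return A list of class \code{"ndc_ranking"}: \code{scores} (the
#'   \code{\link{score_all}} frame plus \code{rank_ndc}, \code{rank_final},
#'   rows in input gene order), \code{null}, and \code{config} (the effective
#'   settings).
#' @export
ndc_rank <- function(mat, labels, n_perm = 1000, level = 0.95, seed = 42L,
                     alpha = 0.6, eps = 1e-8, top_pool = 1000,
                     log2p1 = FALSE, null = NULL) {
  mat <- .as_expr_matrix(mat)
  if (log2p1) {
    if (any(mat < 0))
      stop("log2(x + 1) transform requested but the matrix has negative values")
    mat <- log2(mat + 1)
  }
  if (is.null(null))
    null <- perm_threshold(mat, labels, n_perm = n_perm, level = level,
                           seed = seed, alpha = alpha)
  scores <- score_all(mat, labels, null, eps = eps, alpha = alpha)
  ord_ndc <- order(-scores$ndc, -scores$mic, scores$gene_id)
  scores$rank_ndc <- NA_integer_
  scores$rank_ndc[ord_ndc] <- seq_len(nrow(scores))
  fin <- final_ranking(scores, top_pool = top_pool)
  pool <- min(top_pool, nrow(scores))
  scores$rank_final <- NA_integer_
  scores$rank_final[match(fin[seq_len(pool)], scores$gene_id)] <- seq_len(pool)
  config <- list(n_perm = null$n_perm, level = null$level, seed = null$seed,
                 alpha = alpha, eps = eps, top_pool = top_pool,
                 log2p1 = log2p1, termination = "exhaustive")
  structure(list(scores = scores, null = null, config = config),
            class = "ndc_ranking")
}

# Coerce to a named numeric genes-by-samples matrix, inventing names if absent.
.as_expr_matrix <- function(mat) {
  if (is.data.frame(mat)) mat <- as.matrix(mat)
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("the expression matrix must be numeric with genes as rows")
  if (nrow(mat) < 1L) stop("the expression matrix has no genes")
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("gene%0*d", nchar(nrow(mat)), seq_len(nrow(mat)))
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("sample%0*d", nchar(ncol(mat)), seq_len(ncol(mat)))
  if (anyDuplicated(rownames(mat)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  mat
}
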