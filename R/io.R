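#' Read a genes-by-samples expression matrix
#'
#' Reads a tab-separated expression matrix in the Xena genomicMatrix dialect:
#' a header row whose first cell is arbitrary (Xena writes "sample") followed
#' by sample IDs, then one row per gene starting with the gene identifier.
#' Plain or gzip-compressed files are accepted. Values are expected to be
#' already normalised (e.g. log2(x+1) RSEM for TCGA level-3 data).
#'
#' Genes as rows is the only accepted orientation; if most first-column
#' tokens parse as numbers the file looks transposed and loading fails with
#' a hint. Non-numeric cells follow the NA policy: by default the whole gene
#' row is dropped with a warning; \code{strict = TRUE} escalates to an error.
#'
#' @param path Path to the TSV (optionally \code{.gz}).
#' @param strict Fail instead of dropping genes with missing values.
#' @return A named numeric matrix, genes as rows.
#' @export
read_expression <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (length(lines) < 2L) stop("expression file needs a header and at least one gene row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  n_col <- length(header)
  if (n_col < 2L) stop("header declares no sample columns")
  sample_ids <- header[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  body <- fields[-1L]
  ragged <- which(lengths(body) != n_col)
  if (length(ragged) > 0L)
    stop("ragged row: line ", ragged[1L] + 1L, " has ", lengths(body)[ragged[1L]],
         " fields, expected ", n_col)
  gene_ids <- vapply(body, `[[`, character(1), 1L)
  if (anyDuplicated(gene_ids))
    stop("duplicate gene ids: ",
         paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  looks_numeric <- suppressWarnings(!is.na(as.numeric(gene_ids)))
  if (mean(looks_numeric) > 0.5)
    stop("more than half of the first-column entries are numeric: ",
         "the matrix looks transposed (samples as rows); ",
         "genes must be rows, samples columns")
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(lapply(body, `[`, -1L))),
           nrow = length(body), ncol = n_col - 1L, byrow = TRUE,
           dimnames = list(gene_ids, sample_ids)))
  bad <- which(apply(vals, 1L, function(v) any(!is.finite(v))))
  if (length(bad) > 0L) {
    if (strict)
      stop("non-numeric or missing values in gene(s): ",
           paste(utils::head(gene_ids[bad], 5L), collapse = ", "))
    warning("dropping ", length(bad), " gene(s) with non-numeric or missing values: ",
            paste(utils::head(gene_ids[bad], 5L), collapse = ", "))
    vals <- vals[-bad, , drop = FALSE]
  }
  if (nrow(vals) == 0L) stop("no genes left after applying the NA policy")
  vals
}

#' Write an expression matrix in the same TSV dialect
#'
#' @param mat Named numeric matrix, genes as rows.
#' @param path Output path (plain text; use a \code{.gz} suffix to compress).
#' @export
write_expression <- function(mat, path) {
  mat <- .as_expr_matrix(mat)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste(c("sample", colnames(mat)), collapse = "\t"), con)
  body <- apply(mat, 1L, function(v)
    paste(format(v, trim = TRUE, scientific = FALSE), collapse = "\t"))
  writeLines(paste(rownames(mat), body, sep = "\t"), con)
  invisible(path)
}

#' Read and align binary sample labels
#'
#' Reads a two-column tab-separated file (\code{sample_id}, \code{label};
#' no header) and aligns it to the columns of an expression matrix. Exactly
#' two distinct label values must occur among the matched samples; they are
#' encoded 0/1 by lexicographic order (e.g. \code{normal -> 0, tumor -> 1})
#' and the mapping is reported via a message, since the sign of the
#' correlation depends on it while MIC, |r|, r2 and NDC do not.
#'
#' @param path Path to the labels TSV.
#' @param mat The expression matrix to align to.
#' @return Integer 0/1 vector in matrix column order, with the original
#'   label values in \code{attr(, "levels")} and sample IDs as names.
#' @export
read_labels <- function(path, mat) {
  if (!file.exists(path)) stop("file not found: ", path)
  mat <- .as_expr_matrix(mat)
  df <- utils::read.delim(path, header = FALSE, colClasses = "character",
                          col.names = c("sample_id", "label"))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in labels file: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  missing_in_labels <- setdiff(colnames(mat), df$sample_id)
  if (length(missing_in_labels) > 0L)
    stop("matrix samples missing from the labels file: ",
         paste(utils::head(missing_in_labels, 10L), collapse = ", "))
  extra <- setdiff(df$sample_id, colnames(mat))
  if (length(extra) > 0L)
    message("ignoring ", length(extra), " labelled sample(s) absent from the matrix")
  df <- df[match(colnames(mat), df$sample_id), ]
  lev <- sort(unique(df$label))
  if (length(lev) != 2L)
    stop("exactly two distinct labels are required among matched samples, got ",
         length(lev), ": ", paste(lev, collapse = ", "))
  if (ncol(mat) < 8L)
    stop("fewer than 8 matched samples; at least 8 are required")
  y <- as.integer(df$label == lev[2L])
  if (min(sum(y == 0L), sum(y == 1L)) < 1L)
    stop("both label values must occur among matched samples")
  message("label encoding: ", lev[1L], " -> 0, ", lev[2L], " -> 1")
  names(y) <- df$sample_id
  attr(y, "levels") <- lev
  y
}

#' Write a ranked gene table
#'
#' Writes the scored genes as a commented-header TSV: \code{#}-prefixed
#' header lines echo the effective configuration, the permutation threshold
#' and the seed, followed by the columns \code{gene, mic, r, r2, ndc,
#' rank_ndc, rank_final, t_stat, t_p}. Rows appear in final-rank order first,
#' then the remaining genes by NDC rank. Numeric cells use fixed 6-decimal
#' formatting so re-runs under the same configuration are byte-identical.
#'
#' @param ranking An \code{"ndc_ranking"} object from \code{\link{ndc_rank}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ranked <- function(ranking, path) {
  if (!inherits(ranking, "ndc_ranking"))
    stop("`ranking` must come from ndc_rank()")
  sc <- ranking$scores
  cfg <- ranking$config
  ord <- order(is.na(sc$rank_final), sc$rank_final, sc$rank_ndc)
  sc <- sc[ord, ]
  fmt <- function(v) ifelse(is.finite(v), sprintf("%.6f", v),
                            ifelse(is.na(v), "NA", as.character(v)))
  hdr <- c(
    paste0("# ndcrank ranked gene table"),
    sprintf("# n_perm=%d level=%g seed=%d alpha=%g eps=%g top_pool=%d log2p1=%s termination=%s",
            cfg$n_perm, cfg$level, cfg$seed, cfg$alpha, cfg$eps, cfg$top_pool,
            tolower(as.character(cfg$log2p1)), cfg$termination),
    sprintf("# threshold=%.6f", ranking$null$threshold))
  body <- paste(sc$gene_id, fmt(sc$mic), fmt(sc$r), fmt(sc$r2), fmt(sc$ndc),
                ifelse(is.na(sc$rank_ndc), "NA", sc$rank_ndc),
                ifelse(is.na(sc$rank_final), "NA", sc$rank_final),
                fmt(sc$t_stat), fmt(sc$t_p), sep = "\t")
  con <- file(path, "wt")
  on.exit(close(con))
  tryCatch({
    writeLines(hdr, con)
    writeLines(paste(c("gene", "mic", "r", "r2", "ndc", "rank_ndc",
                       "rank_final", "t_stat", "t_p"), collapse = "\t"), con)
    writeLines(body, con)
  }, error = function(e) stop("cannot write ranked table to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Write a two-column labels file
#'
#' @param labels 0/1 integer vector with sample-ID names (or a
#'   \code{\link{paired_layout}} frame).
#' @param path Output path.
#' @param level_names Character vector of length 2 mapping codes 0 and 1 to
#'   written label strings; default \code{c("normal", "tumor")}.
#' @export
write_labels <- function(labels, path, level_names = c("normal", "tumor")) {
  if (is.data.frame(labels)) {
    ids <- labels$sample_id
    y <- labels$label
  } else {
    ids <- names(labels)
    y <- as.integer(labels)
  }
  if (is.null(ids)) stop("`labels` must carry sample ids (names or a layout frame)")
  writeLines(paste(ids, level_names[y + 1L], sep = "\t"), path)
  invisible(path)
}
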