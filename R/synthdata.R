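#' Describe a planted expression pattern
#'
#' A specification for a block of genes sharing one generative pattern, used
#' by \code{\link{simulate_expression}}. All values are on the log2 expression
#' scale typical of normalised RNA-seq matrices.
#'
#' Pattern kinds:
#' \describe{
#'   \item{null}{no association: both classes \code{Normal(base_mean, base_sd)}.}
#'   \item{linear_de}{a mean shift: class 1 shifted up by \code{shift}.}
#'   \item{bimodal}{class 1 unimodal at \code{base_mean}; class 0 a
#'     two-component mixture at \code{base_mean -/+ gap/2} flanking it — the
#'     archetypal nonlinear pattern where one class splits into low and high
#'     expressers, giving near-zero linear correlation but high MIC.}
#'   \item{stratified}{four distinct expression levels: class 0 a mixture at
#'     \code{base_mean -/+ gap/2}, class 1 a mixture at
#'     \code{base_mean -/+ 3*gap/2}, emulating genes whose expression is
#'     stratified into four strata across tumor/normal pairs.}
#' }
#'
#' @param kind One of \code{"null"}, \code{"linear_de"}, \code{"bimodal"},
#'   \code{"stratified"}.
#' @param count Number of genes with this pattern.
#' @param base_mean Expression location (log2 units); default 8.
#' @param base_sd Within-component spread; default 0.5.
#' @param shift Mean difference for \code{linear_de}; default 1.5.
#' @param gap Component separation for \code{bimodal}/\code{stratified};
#'   default 4.
#' @param mix_weight Probability a sample falls in the upper mixture
#'   component; default 0.5.
#' @return A list of class \code{"pattern_spec"}.
#' @export
pattern_spec <- function(kind, count, base_mean = 8, base_sd = 0.5,
                         shift = 1.5, gap = 4, mix_weight = 0.5) {
  kind <- match.arg(kind, c("null", "linear_de", "bimodal", "stratified"))
  if (!is.numeric(count) || length(count) != 1L || count < 0 || count != round(count))
    stop("invalid pattern spec: `count` must be a non-negative integer")
  if (!is.numeric(base_sd) || base_sd <= 0)
    stop("invalid pattern spec: `base_sd` must be positive")
  if (!is.numeric(gap) || gap <= 0)
    stop("invalid pattern spec: `gap` must be positive")
  if (!is.numeric(mix_weight) || mix_weight <= 0 || mix_weight >= 1)
    stop("invalid pattern spec: `mix_weight` must be strictly between 0 and 1")
  structure(list(kind = kind, count = as.integer(count), base_mean = base_mean,
                 base_sd = base_sd, shift = shift, gap = gap,
                 mix_weight = mix_weight),
            class = "pattern_spec")
}

#' Generate a synthetic expression matrix with planted patterns
#'
#' Draws a genes-by-samples matrix whose rows follow the requested pattern
#' specs, together with binary class labels and a per-gene ground-truth
#' record for recovery testing. Class 0 plays the role of the normal /
#' paracarcinoma tissue and class 1 the tumor. All values are clipped at 0
#' (log2-scale expression is non-negative). Fully reproducible given
#' \code{seed}; different seeds change the values but not the dimensions or
#' the truth labels.
#'
#' @param n_per_class Samples per class, at least 10.
#' @param specs A single \code{\link{pattern_spec}} or a list of them; total
#'   gene count must be at least 1.
#' @param seed Integer RNG seed.
#' @return A list: \code{mat} (genes x samples, named), \code{labels}
#'   (0/1 integer vector, class 0 first), and \code{truth} (data frame
#'   \code{gene_id}, \code{kind}).
#' @export
simulate_expression <- function(n_per_class, specs, seed = 42L) {
  if (!is.numeric(n_per_class) || length(n_per_class) != 1L || n_per_class < 10)
    stop("`n_per_class` must be at least 10")
  if (inherits(specs, "pattern_spec")) specs <- list(specs)
  if (!all(vapply(specs, inherits, logical(1), "pattern_spec")))
    stop("`specs` must be pattern_spec objects (see pattern_spec())")
  n_genes <- sum(vapply(specs, function(s) s$count, integer(1)))
  if (n_genes < 1L) stop("the specs request zero genes in total")
  n_per_class <- as.integer(n_per_class)
  n <- 2L * n_per_class
  labels <- rep(0:1, each = n_per_class)

  .with_seed(seed, {
    rows <- vector("list", length(specs))
    kinds <- character(0)
    for (si in seq_along(specs)) {
      s <- specs[[si]]
      if (s$count == 0L) next
      block <- t(vapply(seq_len(s$count), function(i) .draw_gene(s, labels),
                        numeric(n)))
      rows[[si]] <- block
      kinds <- c(kinds, rep(s$kind, s$count))
    }
    mat <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    mat[mat < 0] <- 0
    rownames(mat) <- sprintf("g%0*d", nchar(n_genes), seq_len(n_genes))
    colnames(mat) <- sprintf("s%0*d_%s", nchar(n),
                             seq_len(n), c("N", "T")[labels + 1L])
    list(mat = mat,
         labels = labels,
         truth = data.frame(gene_id = rownames(mat), kind = kinds,
                            stringsAsFactors = FALSE))
  })
}

# One gene's expression vector for a given pattern spec and label vector.
.draw_gene <- function(s, labels) {
  n <- length(labels)
  cls1 <- labels == 1L
  mixture <- function(m, lo, hi) {
    up <- stats::runif(m) < s$mix_weight
    stats::rnorm(m, ifelse(up, hi, lo), s$base_sd)
  }
  switch(s$kind,
    null = stats::rnorm(n, s$base_mean, s$base_sd),
    linear_de = stats::rnorm(n, s$base_mean + s$shift * cls1, s$base_sd),
    bimodal = {
      x <- numeric(n)
      x[cls1] <- stats::rnorm(sum(cls1), s$base_mean, s$base_sd)
      x[!cls1] <- mixture(sum(!cls1), s$base_mean - s$gap / 2,
                          s$base_mean + s$gap / 2)
      x
    },
    stratified = {
      x <- numeric(n)
      x[!cls1] <- mixture(sum(!cls1), s$base_mean - s$gap / 2,
                          s$base_mean + s$gap / 2)
      x[cls1] <- mixture(sum(cls1), s$base_mean - 3 * s$gap / 2,
                         s$base_mean + 3 * s$gap / 2)
      x
    })
}

#' Standard recovery simulation specs
#'
#' The canonical planted-gene design used throughout the package's recovery
#' tests: 20 bimodal-nonlinear genes, 40 linearly shifted genes, and nulls up
#' to \code{n_genes} total, at the default effect sizes (gap 4, sd 0.5,
#' shift 1.5).
#'
#' @param n_genes Total number of genes; default 2000.
#' @param n_bimodal,n_linear Planted pattern counts; defaults 20 and 40.
#' @return A list of \code{\link{pattern_spec}} objects.
#' @export
recovery_specs <- function(n_genes = 2000, n_bimodal = 20, n_linear = 40) {
  if (n_genes < n_bimodal + n_linear)
    stop("`n_genes` must cover the planted genes")
  list(pattern_spec("bimodal", n_bimodal),
       pattern_spec("linear_de", n_linear),
       pattern_spec("null", n_genes - n_bimodal - n_linear))
}

#' Paired tumor/normal sample layout
#'
#' Emits sample identifiers and labels mimicking a paired tumor /
#' paracarcinoma design: each patient contributes one tumor and one adjacent
#' normal sample, with the patient and tissue decodable from every ID
#' (\code{P<number>-T} / \code{P<number>-N}). NDC itself uses only the
#' labels; this exists so fixtures mirror the layout of real paired cohorts.
#'
#' @param n_patients Number of patients, at least 10.
#' @return A data frame with \code{sample_id}, \code{patient},
#'   \code{tissue} (\code{"tumor"}/\code{"normal"}), and \code{label}
#'   (normal = 0, tumor = 1), two rows per patient.
#' @examples
#' nrow(paired_layout(51))  # 102 samples, 51 per class
#' @export
paired_layout <- function(n_patients) {
  if (!is.numeric(n_patients) || length(n_patients) != 1L || n_patients < 10)
    stop("`n_patients` must be at least 10")
  n_patients <- as.integer(n_patients)
  pat <- sprintf("P%0*d", max(4L, nchar(n_patients)), rep(seq_len(n_patients), each = 2L))
  tissue <- rep(c("tumor", "normal"), times = n_patients)
  data.frame(sample_id = paste0(pat, "-", ifelse(tissue == "tumor", "T", "N")),
             patient = pat,
             tissue = tissue,
             label = as.integer(tissue == "tumor"),
             stringsAsFactors = FALSE)
}
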