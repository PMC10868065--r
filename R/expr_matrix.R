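#' Construct an expression matrix with replicate and average layers
#'
#' The central expression container: a genes (or orthogroups) x samples
#' replicate layer plus a genes x organisms average-TPM layer. "Average TPM"
#' is the arithmetic mean over an organism's replicates, computed on the raw
#' TPM scale before any transformation. A gene missing from an organism's
#' annotation is `NA` there, never 0.
#'
#' @param replicates Numeric matrix, rows = genes/OGs, columns = samples.
#' @param samples Data frame with columns `sample`, `organism`, `replicate`
#'   describing the replicate columns.
#' @param pseudocount Pseudocount used by the log2 layer (default 0.01).
#' @param average Optional precomputed average layer (rows x organisms); when
#'   supplied, `replicates`/`samples` may be `NULL` (average-only matrix).
#' @return Object of class `expression_matrix` with elements `replicates`,
#'   `samples`, `average`, `log2` (filled by [filter_low_and_log()]) and
#'   `pseudocount`.
#' @export
expression_matrix <- function(replicates = NULL, samples = NULL,
                              pseudocount = 0.01, average = NULL) {
  if (is.null(average)) {
    stopifnot(is.matrix(replicates), !is.null(samples))
    if (any(replicates < 0, na.rm = TRUE)) stop("negative TPM values")
    samples <- as.data.frame(samples)
    orgs <- unique(samples$organism)
    average <- vapply(orgs, function(o) {
      cols <- samples$sample[samples$organism == o]
      rowMeans(replicates[, cols, drop = FALSE])
    }, numeric(nrow(replicates)))
    dimnames(average) <- list(rownames(replicates), orgs)
  } else {
    stopifnot(is.matrix(average))
    if (any(average < 0, na.rm = TRUE)) stop("negative TPM values")
  }
  structure(list(replicates = replicates, samples = samples,
                 average = average, log2 = NULL,
                 pseudocount = pseudocount),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("Expression matrix:", nrow(x$average), "rows x",
      ncol(x$average), "organisms")
  if (!is.null(x$replicates)) cat(" (", ncol(x$replicates), "samples )")
  cat("\n  layers: average", if (!is.null(x$replicates)) "replicates",
      if (!is.null(x$log2)) sprintf("log2(avg + %g)", x$pseudocount), "\n")
  invisible(x)
}

#' Call expressed genes by an average-TPM cutoff
#'
#' A gene is called expressed in an organism when its average TPM is greater
#' than or equal to the threshold (inclusive). Genes missing from an
#' organism's annotation are not expressed there.
#'
#' @param em An `expression_matrix`.
#' @param threshold Average-TPM cutoff; default 1, with 0.1 the usual
#'   sensitivity alternative.
#' @return Logical matrix rows x organisms, with per-organism expressed
#'   counts in attribute `"counts"`.
#' @export
call_expressed <- function(em, threshold = 1) {
  stopifnot(inherits(em, "expression_matrix"), threshold > 0)
  calls <- em$average >= threshold
  calls[is.na(calls)] <- FALSE
  attr(calls, "counts") <- colSums(calls)
  calls
}

#' Aggregate gene expressed-calls to orthogroup level
#'
#' An orthogroup is expressed in an organism when at least one of its member
#' genes there is expressed. Orthogroups with no annotated gene in an
#' organism are not expressed in it.
#'
#' @param orthogroups An `orthogroup_table`.
#' @param gene_calls Logical genes x organisms matrix from [call_expressed()].
#' @return Logical OG x organism matrix with attributes `"n_expressing"`
#'   (organisms per OG), `"species_specific"` (OG ids expressed in exactly
#'   one organism) and `"universal"` (expressed in all organisms).
#' @export
og_expression_calls <- function(orthogroups, gene_calls) {
  orgs <- attr(orthogroups, "organisms")
  out <- matrix(FALSE, length(orthogroups), length(orgs),
                dimnames = list(names(orthogroups), orgs))
  for (og in names(orthogroups)) {
    for (o in orgs) {
      genes <- intersect(orthogroups[[og]][[o]], rownames(gene_calls))
      if (length(genes)) out[og, o] <- any(gene_calls[genes, o])
    }
  }
  n <- rowSums(out)
  attr(out, "n_expressing") <- n
  attr(out, "species_specific") <- names(n)[n == 1L]
  attr(out, "universal") <- names(n)[n == length(orgs)]
  out
}

#' Pairwise similarity of binary expression-content profiles
#'
#' Encodes orthogroup expression as a 0/1 matrix (columns = organisms) and
#' computes pairwise Pearson correlations between organisms, together with
#' directional shared-expression fractions: `shared[i, j]` is the fraction
#' of organism i's expressed orthogroups that are also expressed in j.
#'
#' @param og_calls Logical OG x organism matrix from [og_expression_calls()].
#' @return List with `correlation` (organisms x organisms, `NA` with a
#'   warning where a column is constant) and `shared_fraction`.
#' @export
binary_content_correlation <- function(og_calls) {
  stopifnot(ncol(og_calls) >= 2)
  b <- og_calls * 1
  if (any(colSums(b) == 0))
    stop("every organism must express at least one orthogroup")
  const <- apply(b, 2, function(col) length(unique(col)) == 1L)
  if (any(const))
    warning("constant 0/1 column(s), correlation undefined for: ",
            paste(colnames(b)[const], collapse = ", "))
  r <- suppressWarnings(stats::cor(b))
  r[const, ] <- NA_real_
  r[, const] <- NA_real_
  diag(r) <- ifelse(const, NA_real_, 1)

  m <- ncol(b)
  shared <- matrix(NA_real_, m, m, dimnames = dimnames(r))
  for (i in seq_len(m)) for (j in seq_len(m))
    shared[i, j] <- sum(b[, i] & b[, j]) / sum(b[, i])
  list(correlation = r, shared_fraction = shared)
}

#' Drop universally low rows and attach the log2 layer
#'
#' Removes rows whose average TPM is below the threshold in every organism
#' (background-noise filter), then computes `log2(average + pseudocount)`
#' for the kept rows.
#'
#' @param em An `expression_matrix` (typically on 1:1 orthogroup rows).
#' @param threshold Low-expression cutoff (default 1 average TPM).
#' @param pseudocount Pseudocount added before log2 (default 0.01).
#' @return A filtered `expression_matrix` with the `log2` layer set; the
#'   ids of dropped rows are in attribute `"dropped"`.
#' @export
filter_low_and_log <- function(em, threshold = 1, pseudocount = em$pseudocount) {
  stopifnot(inherits(em, "expression_matrix"))
  keep <- apply(em$average, 1, function(v) any(v >= threshold, na.rm = TRUE))
  dropped <- rownames(em$average)[!keep]
  em$average <- em$average[keep, , drop = FALSE]
  if (!is.null(em$replicates))
    em$replicates <- em$replicates[keep, , drop = FALSE]
  em$pseudocount <- pseudocount
  em$log2 <- log2(em$average + pseudocount)
  attr(em, "dropped") <- dropped
  em
}

#' Expression-level similarity: correlation, clustering, PCA
#'
#' `expression_correlation` computes pairwise Pearson correlations between
#' organisms on the log2 layer. `expression_dendrogram` clusters organisms
#' by average linkage (UPGMA) on the distance 1 - r. `expression_pca` runs a
#' principal component analysis with organisms as observations on the
#' row-centered log2 layer.
#'
#' @param em An `expression_matrix` with the log2 layer attached
#'   (see [filter_low_and_log()]).
#' @return `expression_correlation`: organisms x organisms matrix.
#'   `expression_dendrogram`: an `hclust` object. `expression_pca`: a list
#'   with `scores`, `loadings` and `variance_explained` (sums to 1).
#' @export
expression_correlation <- function(em) {
  lg <- .log_layer(em)
  if (ncol(lg) < 2) stop("need at least 2 organisms")
  stats::cor(lg)
}

#' @rdname expression_correlation
#' @export
expression_dendrogram <- function(em) {
  r <- expression_correlation(em)
  stats::hclust(stats::as.dist(1 - r), method = "average")
}

#' @rdname expression_correlation
#' @param log Use the log2 layer (default) or the raw average layer.
#' @export
expression_pca <- function(em, log = TRUE) {
  x <- if (log) .log_layer(em) else em$average
  if (ncol(x) < 2) stop("need at least 2 organisms")
  if (nrow(x) < 3) stop("need at least 3 rows")
  p <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  ve <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, loadings = p$rotation, variance_explained = ve)
}

.log_layer <- function(em) {
  stopifnot(inherits(em, "expression_matrix"))
  if (is.null(em$log2))
    stop("log2 layer not computed; run filter_low_and_log() first")
  if (anyNA(em$log2))
    stop("log2 layer contains missing values; restrict to complete rows")
  em$log2
}

#' Build an orthogroup-level expression matrix from a 1:1 ortholog set
#'
#' Maps each organism's assigned gene in each 1:1 orthogroup to its
#' average-TPM value, yielding an OG x organism matrix on which all
#' downstream tree / dominance / conservation analyses operate.
#'
#' @param one2one A `one2one_set` from [trim_all()].
#' @param em A gene-level `expression_matrix`.
#' @param pseudocount Pseudocount carried into the OG-level matrix.
#' @return An average-layer `expression_matrix` with OG rows.
#' @export
og_expression_matrix <- function(one2one, em, pseudocount = em$pseudocount) {
  stopifnot(inherits(one2one, "one2one_set"),
            inherits(em, "expression_matrix"))
  asn <- one2one$assignments
  ogs <- unique(asn$orthogroup)
  orgs <- unique(asn$organism)
  avg <- matrix(NA_real_, length(ogs), length(orgs),
                dimnames = list(ogs, orgs))
  ridx <- match(asn$gene, rownames(em$average))
  ok <- !is.na(ridx)
  avg[cbind(match(asn$orthogroup, ogs), match(asn$organism, orgs))[ok, ,
      drop = FALSE]] <-
    em$average[cbind(ridx, match(asn$organism, colnames(em$average)))[ok, ,
      drop = FALSE]]
  expression_matrix(average = avg, pseudocount = pseudocount)
}
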