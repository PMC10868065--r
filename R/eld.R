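#' Thresholds for expression-level dominance categories
#'
#' Bins of the mid-parent dominance/additivity ratio `|d/a|`: additive
#' (<= 0.2), partial dominance (0.2 < ratio <= 0.8), dominance
#' (0.8 < ratio <= 1.2), over-dominance (> 1.2). `epsilon` guards the
#' degenerate case of (near-)equal parents, where `a` is (near) zero.
#'
#' @param additive Upper bound of the additive bin (default 0.2).
#' @param partial Upper bound of the partial-dominance bin (default 0.8).
#' @param dominance Upper bound of the dominance bin (default 1.2).
#' @param epsilon Tolerance below which `|a|` (and `|d|`) count as zero on
#'   the TPM scale (default 1e-9).
#' @return A list of class `eld_thresholds`.
#' @export
eld_thresholds <- function(additive = 0.2, partial = 0.8, dominance = 1.2,
                           epsilon = 1e-9) {
  stopifnot(0 < additive, additive < partial, partial < dominance)
  structure(list(additive = additive, partial = partial,
                 dominance = dominance, epsilon = epsilon),
            class = "eld_thresholds")
}

.eld_levels <- c("additive", "partial-dominance", "dominance",
                 "over-dominance")

#' Classify expression-level dominance from polyploid and parent expression
#'
#' Given the polyploid total expression P and the two parental expression
#' levels A and D (all average TPM), computes the dominant deviation
#' `d = P - (A + D)/2` (deviation from the mid-parent value), the additive
#' half-difference `a = (A - D)/2`, and bins `|d/a|` into the four
#' dominance categories. When the parents are (numerically) equal the ratio
#' is undefined: the call is additive if the polyploid also sits at the
#' mid-parent value, otherwise over-dominance (ratio infinite).
#'
#' @param P,A,D Non-negative numeric vectors (recycled to common length) of
#'   polyploid total, A-parent and D-parent average TPM.
#' @param thresholds An `eld_thresholds`.
#' @return Data frame with columns `P`, `A`, `D`, `d`, `a`, `ratio`,
#'   `category` (factor with the four levels).
#' @export
classify_eld <- function(P, A, D, thresholds = eld_thresholds()) {
  n <- max(length(P), length(A), length(D))
  P <- rep_len(P, n); A <- rep_len(A, n); D <- rep_len(D, n)
  if (any(P < 0 | A < 0 | D < 0)) stop("P, A, D must be non-negative")
  d <- P - (A + D) / 2
  a <- (A - D) / 2
  ratio <- abs(d) / abs(a)
  eps <- thresholds$epsilon
  deg <- abs(a) < eps
  ratio[deg] <- ifelse(abs(d[deg]) < eps, 0, Inf)
  category <- cut(ratio,
                  breaks = c(-Inf, thresholds$additive, thresholds$partial,
                             thresholds$dominance, Inf),
                  labels = .eld_levels)
  data.frame(P = P, A = A, D = D, d = d, a = a, ratio = ratio,
             category = category)
}

#' Total homoeolog expression of a tetraploid
#'
#' The expression level of a tetraploid ortholog is represented by the sum
#' of the average TPM of its two subgenome homoeologs, on the raw (unlogged)
#' scale.
#'
#' @param em An `expression_matrix` whose columns include both subgenome
#'   organisms of the tetraploid (rows = 1:1 orthogroups).
#' @param organisms An `organism_set`.
#' @param tetraploid Tetraploid id (e.g. `"AD1"`).
#' @return Named numeric vector of per-row totals; rows where either
#'   homoeolog is missing are `NA` and listed in attribute `"excluded"`.
#' @export
polyploid_total <- function(em, organisms, tetraploid) {
  subs <- subgenome_ids(organisms, tetraploid)
  avg <- if (inherits(em, "expression_matrix")) em$average else em
  miss <- setdiff(subs, colnames(avg))
  if (length(miss))
    stop("subgenome organism(s) absent from matrix: ",
         paste(miss, collapse = ", "))
  P <- avg[, subs[1]] + avg[, subs[2]]
  excl <- rownames(avg)[is.na(P)]
  attr(P, "excluded") <- excl
  P
}

#' Expression-level dominance table for one parent configuration
#'
#' Classifies every 1:1 orthogroup for a tetraploid against a chosen
#' A-genome parent (an extant diploid column, or an inferred ancestral
#' transcriptome supplied as `ancestral`) and a D-genome parent. Rows where
#' polyploid and both parents all fall below the expressed threshold are
#' excluded from classification (reported separately) to avoid inflating
#' the additive bin with 0/0 comparisons.
#'
#' @param em OG-level `expression_matrix` (average TPM).
#' @param organisms An `organism_set`.
#' @param tetraploid Tetraploid id.
#' @param a_parent A-genome parent organism id, or the name to report when
#'   `ancestral` is supplied (e.g. `"A0"`).
#' @param d_parent D-genome parent organism id (e.g. `"D5"`).
#' @param ancestral Optional named numeric vector of inferred ancestral
#'   average TPM (names = orthogroup ids); required when `a_parent` is not a
#'   column of the matrix.
#' @param thresholds An `eld_thresholds`.
#' @param expressed_threshold Average-TPM cutoff for the all-silent
#'   exclusion rule (default 1).
#' @return List of class `eld_table` with `calls` (per-OG data frame
#'   including `orthogroup` and `category`), `counts` (named integer vector
#'   over the four categories), `excluded` (orthogroup ids), and the
#'   configuration tag.
#' @export
eld_table <- function(em, organisms, tetraploid, a_parent, d_parent,
                      ancestral = NULL, thresholds = eld_thresholds(),
                      expressed_threshold = 1) {
  avg <- if (inherits(em, "expression_matrix")) em$average else em
  P <- polyploid_total(em, organisms, tetraploid)
  if (a_parent %in% colnames(avg)) {
    A <- avg[, a_parent]
  } else {
    if (is.null(ancestral))
      stop("a_parent '", a_parent, "' is not an organism column and no ",
           "ancestral expression table was supplied")
    A <- ancestral[rownames(avg)]
  }
  if (!d_parent %in% colnames(avg))
    stop("d_parent '", d_parent, "' not in matrix")
  D <- avg[, d_parent]

  ok <- !is.na(P) & !is.na(A) & !is.na(D)
  silent <- ok & P < expressed_threshold & A < expressed_threshold &
    D < expressed_threshold
  use <- ok & !silent
  calls <- classify_eld(P[use], A[use], D[use], thresholds)
  calls <- cbind(orthogroup = rownames(avg)[use], calls,
                 stringsAsFactors = FALSE)
  counts <- table(factor(calls$category, levels = .eld_levels))
  structure(list(calls = calls,
                 counts = stats::setNames(as.integer(counts),
                                          names(counts)),
                 excluded = rownames(avg)[silent | !ok],
                 config = list(tetraploid = tetraploid, a_parent = a_parent,
                               d_parent = d_parent)),
            class = "eld_table")
}

#' @export
print.eld_table <- function(x, ...) {
  cat("Expression-level dominance:", x$config$tetraploid, "vs (",
      x$config$a_parent, "x", x$config$d_parent, ")\n")
  print(x$counts)
  cat(" ", length(x$excluded), "orthogroups excluded (missing or all-silent)\n")
  invisible(x)
}

#' Chi-square comparison of a category count between parent configurations
#'
#' Tests whether the number of orthogroups falling in a dominance category
#' differs between two parent configurations evaluated on the same
#' orthogroup universe of size N, by a Pearson chi-square test (df = 1, no
#' continuity correction) on the 2x2 table of in-category vs out-of-category
#' counts.
#'
#' @param n1,n2 In-category counts under the two configurations.
#' @param N Size of the shared orthogroup universe.
#' @return List with `statistic` and `p.value`.
#' @export
compare_parent_configs <- function(n1, n2, N) {
  if (N < max(n1, n2)) stop("universe size N smaller than a category count")
  tab <- rbind(c(n1, N - n1), c(n2, N - n2))
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ht$statistic), p.value = unname(ht$p.value))
}
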