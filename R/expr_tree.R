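#' Stationary Ornstein-Uhlenbeck expression distance
#'
#' Under a stationary OU model of expression evolution the correlation of
#' log-expression profiles between two organisms decays exponentially with
#' their divergence, so the divergence is recovered as minus the log of the
#' Pearson correlation: `d = -ln(rho)`. Correlations at or below
#' `rho_floor` are clamped so distances stay finite; correlations above 1
#' (numerical noise) clamp to 0 distance.
#'
#' @param x,y Numeric log-expression vectors of two organisms over the same
#'   rows (length >= 3).
#' @param rho_floor Lower clamp for the correlation (default 1e-9).
#' @return Non-negative distance.
#' @export
sou_distance <- function(x, y, rho_floor = 1e-9) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate expression profile: constant vector")
  rho <- stats::cor(x, y)
  -log(min(max(rho, rho_floor), 1))
}

#' Pairwise sOU distance matrix between organisms
#'
#' @param em An `expression_matrix` with a log2 layer, or a numeric matrix
#'   (rows = genes/OGs, columns = organisms) already on the log scale.
#' @param rho_floor Lower clamp for correlations (default 1e-9).
#' @return Symmetric organism x organism distance matrix (class `matrix`)
#'   with attribute `"n_rows"` recording the number of rows used.
#' @export
sou_distance_matrix <- function(em, rho_floor = 1e-9) {
  lg <- if (inherits(em, "expression_matrix")) .log_layer(em) else em
  if (nrow(lg) < 3) stop("need at least 3 rows")
  if (any(apply(lg, 2, stats::sd) == 0))
    stop("degenerate expression profile: constant organism column")
  d <- -log(pmin(pmax(stats::cor(lg), rho_floor), 1))
  diag(d) <- 0
  attr(d, "n_rows") <- nrow(lg)
  attr(d, "method") <- "sOU"
  d
}

# Set negative NJ branch lengths to zero, transferring the deficit to the
# adjacent branches below so path lengths through the node are preserved.
.fix_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1]
    deficit <- -tree$edge.length[e]
    tree$edge.length[e] <- 0
    child <- tree$edge[e, 2]
    below <- which(tree$edge[, 1] == child)
    if (length(below)) tree$edge.length[below] <-
        tree$edge.length[below] + deficit
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Neighbor-joining expression tree rooted on an outgroup
#'
#' Standard Saitou-Nei neighbor joining on an sOU distance matrix. Negative
#' branch lengths (an NJ artifact) are set to zero with the deficit pushed
#' to the adjacent descendant branches; the tree is then rooted on the
#' outgroup edge.
#'
#' @param d Symmetric organism distance matrix (e.g. from
#'   [sou_distance_matrix()]).
#' @param outgroup Organism id to root on; must be a row of `d`.
#' @return A rooted `phylo` tree.
#' @export
nj_tree <- function(d, outgroup) {
  d <- as.matrix(d)
  if (!outgroup %in% rownames(d))
    stop("outgroup '", outgroup, "' not present in the distance matrix")
  tree <- ape::nj(stats::as.dist(d))
  tree <- .fix_negative_branches(tree)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Gene-resampling bootstrap supports for the expression tree
#'
#' Resamples matrix rows (genes / orthogroups) with replacement, rebuilds
#' the sOU distance matrix and NJ tree for each replicate, and reports for
#' every internal edge of the full-data tree the percentage of replicates
#' containing the same bipartition.
#'
#' @param em Log-scale matrix or `expression_matrix` with log2 layer
#'   (>= 10 rows).
#' @param outgroup Organism id used to root every tree.
#' @param B Number of bootstrap replicates (default 500).
#' @param seed Random seed (required for reproducibility).
#' @param rho_floor Correlation clamp passed through.
#' @return The rooted full-data tree (`phylo`) with `node.label` holding the
#'   supports (0-100) and attribute `"supports"` a named numeric vector.
#' @export
bootstrap_supports <- function(em, outgroup, B = 500, seed,
                               rho_floor = 1e-9) {
  if (B < 1) stop("B must be >= 1")
  lg <- if (inherits(em, "expression_matrix")) .log_layer(em) else em
  if (nrow(lg) < 10) stop("need at least 10 rows for bootstrapping")
  main <- nj_tree(sou_distance_matrix(lg, rho_floor), outgroup)
  set.seed(seed)
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(lg), nrow(lg), replace = TRUE)
    boots[[b]] <- nj_tree(sou_distance_matrix(lg[idx, , drop = FALSE],
                                              rho_floor), outgroup)
  }
  counts <- ape::prop.clades(main, boots, rooted = TRUE)
  counts[is.na(counts)] <- 0
  supp <- counts / B * 100
  main$node.label <- as.character(round(supp, 1))
  attr(main, "supports") <- supp
  main
}

#' Ancestral expression estimation by Brownian-motion pruning
#'
#' Estimates, per gene, the maximum-likelihood (generalized least squares)
#' ancestral value under Brownian motion at a chosen internal node of the
#' expression tree, by recursive pruning: a node joining two subtrees with
#' estimates x1, x2 at branch distances b1, b2 contributes
#' `(x1/b1 + x2/b2) / (1/b1 + 1/b2)` with the merged node carrying the
#' branch correction `b1*b2/(b1+b2)`. Information from all tips flows to the
#' target node. Zero-length branches are replaced by a small epsilon.
#'
#' @param tree A rooted `phylo` whose tip labels are organism ids.
#' @param em Log-scale matrix (rows x organisms) or `expression_matrix` with
#'   log2 layer.
#' @param node_tips Character vector of tip labels whose most recent common
#'   ancestor is the target node (e.g. `c("A1", "A2")` for the ancestor of
#'   the two A-genome diploids).
#' @param organisms_used Optional subset of tip labels to restrict the tree
#'   and matrix to before estimation (e.g. the diploids only); default all
#'   tips present in the matrix.
#' @param eps Replacement for zero branch lengths (default 1e-6).
#' @return Numeric vector of per-gene ancestral values on the log scale
#'   (names = row ids).
#' @export
ancestral_expression <- function(tree, em, node_tips, organisms_used = NULL,
                                 eps = 1e-6) {
  lg <- if (inherits(em, "expression_matrix")) .log_layer(em) else em
  keep <- intersect(tree$tip.label, colnames(lg))
  if (!is.null(organisms_used)) keep <- intersect(keep, organisms_used)
  if (length(keep) < 2) stop("fewer than 2 usable tips")
  tr <- ape::keep.tip(tree, keep)
  missing_tips <- setdiff(node_tips, tr$tip.label)
  if (length(missing_tips))
    stop("node tip(s) not present after restriction: ",
         paste(missing_tips, collapse = ", "))
  target <- if (length(node_tips) == 1L) match(node_tips, tr$tip.label)
            else ape::getMRCA(tr, node_tips)
  if (is.na(target) || target <= length(tr$tip.label))
    stop("target node not an internal node of the restricted tree")

  len <- pmax(tr$edge.length, eps)
  nb <- lapply(seq_len(max(tr$edge)), function(i) integer(0))
  for (e in seq_len(nrow(tr$edge))) {
    a <- tr$edge[e, 1]; b <- tr$edge[e, 2]
    nb[[a]] <- c(nb[[a]], e)
    nb[[b]] <- c(nb[[b]], e)
  }
  ntip <- length(tr$tip.label)
  x <- lg[, tr$tip.label, drop = FALSE]

  # returns list(value = per-gene estimate, b = branch-length correction)
  # for the subtree reached through edge `via` from node `from`
  prune <- function(node, via) {
    if (node <= ntip)
      return(list(value = x[, node], b = 0))
    parts <- list()
    for (e in nb[[node]]) {
      if (e == via) next
      other <- if (tr$edge[e, 1] == node) tr$edge[e, 2] else tr$edge[e, 1]
      sub <- prune(other, e)
      parts[[length(parts) + 1L]] <- list(value = sub$value,
                                          b = len[e] + sub$b)
    }
    w <- vapply(parts, function(p) 1 / p$b, numeric(1))
    val <- Reduce(`+`, Map(function(p, wi) p$value * wi, parts, w)) / sum(w)
    list(value = val, b = 1 / sum(w))
  }

  parts <- list()
  for (e in nb[[target]]) {
    other <- if (tr$edge[e, 1] == target) tr$edge[e, 2] else tr$edge[e, 1]
    sub <- prune(other, e)
    parts[[length(parts) + 1L]] <- list(value = sub$value, b = len[e] + sub$b)
  }
  w <- vapply(parts, function(p) 1 / p$b, numeric(1))
  est <- Reduce(`+`, Map(function(p, wi) p$value * wi, parts, w)) / sum(w)
  names(est) <- rownames(lg)
  est
}

#' Back-transform log2 ancestral values to the TPM scale
#'
#' Inverts the `log2(TPM + pseudocount)` transform and floors at zero, so
#' inferred ancestral expression can enter mid-parent dominance analysis on
#' the same scale as observed average TPM.
#'
#' @param v Numeric vector on the log2 scale.
#' @param pseudocount Pseudocount used in the forward transform
#'   (default 0.01).
#' @return Non-negative TPM-scale values.
#' @export
ancestral_tpm <- function(v, pseudocount = 0.01) {
  pmax(2^v - pseudocount, 0)
}
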