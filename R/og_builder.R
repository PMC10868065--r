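#' Configuration for 1:1 orthogroup trimming
#'
#' Thresholds for the homology filter and the cap on exhaustive assignment
#' enumeration. A hit qualifies when percent identity is strictly greater
#' than `min_identity`, E-value is at most `max_evalue` and alignment
#' coverage (alignment length / min(query length, subject length)) is at
#' least `min_coverage`.
#'
#' @param min_identity Percent identity threshold, strict `>` (default 50).
#' @param max_evalue E-value ceiling, inclusive (default 1e-3).
#' @param min_coverage Coverage floor as a fraction, inclusive (default 0.5).
#' @param enumeration_cap Maximum number of candidate assignments enumerated
#'   exhaustively before falling back to the iterated conditional
#'   maximization heuristic (default 10000).
#' @return A list of class `og_trim_config`.
#' @export
og_trim_config <- function(min_identity = 50, max_evalue = 1e-3,
                           min_coverage = 0.5, enumeration_cap = 10000) {
  stopifnot(min_coverage >= 0, min_coverage <= 1, enumeration_cap >= 1)
  structure(list(min_identity = min_identity, max_evalue = max_evalue,
                 min_coverage = min_coverage,
                 enumeration_cap = enumeration_cap),
            class = "og_trim_config")
}

#' Classify orthogroup occupancy
#'
#' Counts, per orthogroup, how many organisms contribute at least one gene,
#' and flags species-complete orthogroups (every organism occupied) and
#' single-copy orthogroups (exactly one gene everywhere).
#'
#' @param orthogroups An `orthogroup_table`.
#' @param organisms An `organism_set`.
#' @return Data frame with columns `orthogroup`, `n_occupied`,
#'   `species_complete`, `single_copy`.
#' @export
classify_occupancy <- function(orthogroups, organisms) {
  stopifnot(length(orthogroups) > 0)
  orgs <- organisms$id
  counts <- t(vapply(orthogroups, function(og)
    vapply(orgs, function(o) length(og[[o]]), integer(1)),
    integer(length(orgs))))
  data.frame(
    orthogroup = names(orthogroups),
    n_occupied = rowSums(counts > 0),
    species_complete = rowSums(counts > 0) == length(orgs),
    single_copy = apply(counts == 1L, 1, all),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Logical vector: which hits pass the identity/evalue/coverage thresholds.
# Coverage uses the shorter of the two sequences as denominator.
.hit_qualifies <- function(hits, config) {
  coverage <- hits$length / pmin(hits$qlen, hits$slen)
  hits$pident > config$min_identity &
    hits$evalue <= config$max_evalue &
    coverage >= config$min_coverage
}

# gene -> organism lookup for the genes of one orthogroup
.gene2org <- function(og_genes) {
  g <- unlist(og_genes, use.names = FALSE)
  stats::setNames(rep(names(og_genes), lengths(og_genes)), g)
}

#' Homology-filter the genes of one orthogroup
#'
#' A gene copy is retained when it has at least one qualifying hit (in
#' either search direction) to a gene of a *different* organism in the same
#' orthogroup. Within-organism (paralog) hits never qualify.
#'
#' @param og_genes Named list organism -> character vector of gene ids.
#' @param hits A `blast_hits` data frame (restricted or not; only hits among
#'   the orthogroup's genes are considered).
#' @param config An `og_trim_config`.
#' @return List with `retained` (named list organism -> genes) and `reason`
#'   (`NULL`, or a string when some organism lost all copies, in which case
#'   the orthogroup must be rejected).
#' @export
filter_homology <- function(og_genes, hits, config = og_trim_config()) {
  g2o <- .gene2org(og_genes)
  genes <- names(g2o)
  h <- hits[hits$query %in% genes & hits$subject %in% genes, , drop = FALSE]
  h <- h[.hit_qualifies(h, config), , drop = FALSE]
  cross <- g2o[h$query] != g2o[h$subject]
  h <- h[cross, , drop = FALSE]
  supported <- unique(c(h$query, h$subject))
  retained <- lapply(og_genes, function(g) intersect(g, supported))
  empty <- names(retained)[lengths(retained) == 0L]
  reason <- if (length(empty))
    paste0("no qualifying copy for organism(s): ",
           paste(empty, collapse = ", ")) else NULL
  list(retained = retained, reason = reason)
}

# Symmetric pair-score lookup among a gene set: max qualifying bit score
# over the two hit directions; 0 where no qualifying cross-organism hit.
.pair_scores <- function(genes, g2o, hits, config) {
  n <- length(genes)
  s <- matrix(0, n, n, dimnames = list(genes, genes))
  h <- hits[hits$query %in% genes & hits$subject %in% genes, , drop = FALSE]
  h <- h[.hit_qualifies(h, config), , drop = FALSE]
  h <- h[g2o[h$query] != g2o[h$subject], , drop = FALSE]
  for (k in seq_len(nrow(h))) {
    i <- h$query[k]; j <- h$subject[k]
    if (h$bitscore[k] > s[i, j]) {
      s[i, j] <- h$bitscore[k]
      s[j, i] <- h$bitscore[k]
    }
  }
  s
}

# Total score of one assignment (one gene per organism): sum of pair scores
# over unordered organism pairs.
.assignment_score <- function(genes, scores) {
  tot <- 0
  n <- length(genes)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      tot <- tot + scores[genes[i], genes[j]]
  tot
}

#' Select the best 1:1 assignment for one orthogroup
#'
#' Chooses one gene per organism maximizing the total bit score, summed over
#' unordered organism pairs with the pair score defined as the larger of the
#' two directional qualifying bit scores (0 when no qualifying hit links the
#' pair). All candidate assignments are enumerated exhaustively when their
#' number (product of per-organism copy counts) does not exceed
#' `enumeration_cap`; beyond that an iterated conditional maximization
#' heuristic is used (started from the per-organism highest-scoring copies
#' and restarted from every single-organism swap) and the result is flagged
#' `exact = FALSE`. Ties are broken deterministically by the
#' lexicographically smallest gene-id tuple in sorted organism order.
#'
#' @param og_genes Named list organism -> retained gene ids (all non-empty;
#'   run [filter_homology()] first).
#' @param hits A `blast_hits` data frame.
#' @param config An `og_trim_config`.
#' @return List with `assignment` (named character, organism -> gene),
#'   `score` and `exact`.
#' @export
best_one2one <- function(og_genes, hits, config = og_trim_config()) {
  stopifnot(all(lengths(og_genes) >= 1L))
  orgs <- sort(names(og_genes))
  og_genes <- lapply(og_genes[orgs], sort)
  g2o <- .gene2org(og_genes)
  scores <- .pair_scores(names(g2o), g2o, hits, config)

  n_cand <- prod(lengths(og_genes))
  if (n_cand <= config$enumeration_cap) {
    grid <- expand.grid(og_genes, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    total <- numeric(nrow(grid))
    k <- length(orgs)
    for (i in seq_len(k - 1))
      for (j in (i + 1):k)
        total <- total + scores[cbind(grid[[i]], grid[[j]])]
    best_score <- max(total)
    cand <- grid[total == best_score, , drop = FALSE]
    # deterministic tie-break: lexicographically smallest gene tuple in
    # sorted organism order
    ord <- do.call(order, cand)
    best <- as.character(cand[ord[1], ])
    names(best) <- orgs
    return(list(assignment = best, score = best_score, exact = TRUE))
  }

  # heuristic: coordinate ascent with single-swap restarts
  start <- vapply(orgs, function(o) {
    g <- og_genes[[o]]
    g[which.max(vapply(g, function(x) sum(scores[x, ]), numeric(1)))]
  }, character(1))
  climb <- function(cur) {
    repeat {
      improved <- FALSE
      for (o in orgs) {
        for (g in og_genes[[o]]) {
          cand <- cur; cand[o] <- g
          if (.assignment_score(cand, scores) >
              .assignment_score(cur, scores)) {
            cur <- cand; improved <- TRUE
          }
        }
      }
      if (!improved) return(cur)
    }
  }
  best <- climb(start)
  best_score <- .assignment_score(best, scores)
  for (o in orgs) for (g in og_genes[[o]]) {
    alt <- best; alt[o] <- g
    alt <- climb(alt)
    sc <- .assignment_score(alt, scores)
    if (sc > best_score ||
        (sc == best_score && .lex_less(alt, best))) {
      best <- alt; best_score <- sc
    }
  }
  list(assignment = best, score = best_score, exact = FALSE)
}

.lex_less <- function(a, b) {
  if (is.null(b)) return(TRUE)
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Trim all species-complete orthogroups to 1:1 sets
#'
#' Applies [filter_homology()] and [best_one2one()] to every
#' species-complete orthogroup. Orthogroups where some organism loses all
#' copies are rejected with a reason; rejections never abort the batch.
#'
#' @param orthogroups An `orthogroup_table`.
#' @param hits A `blast_hits` data frame.
#' @param organisms An `organism_set`.
#' @param config An `og_trim_config`.
#' @return Object of class `one2one_set`: list with `assignments` (data
#'   frame `orthogroup`, `organism`, `gene`, `score`, `exact`) and `rejects`
#'   (data frame `orthogroup`, `reason`).
#' @export
trim_all <- function(orthogroups, hits, organisms,
                     config = og_trim_config()) {
  occ <- classify_occupancy(orthogroups, organisms)
  todo <- occ$orthogroup[occ$species_complete]
  # pre-split hits by the orthogroup of their query gene (genes belong to
  # at most one orthogroup) so each orthogroup only sees its own hits
  gene_og <- stats::setNames(
    rep(names(orthogroups), vapply(orthogroups, function(g)
      length(unlist(g, use.names = FALSE)), integer(1))),
    unlist(orthogroups, use.names = FALSE))
  hit_og <- unname(gene_og[hits$query])
  hit_idx <- split(seq_len(nrow(hits)), hit_og)
  rows <- list(); rej <- list()
  for (og in todo) {
    og_hits <- hits[hit_idx[[og]], , drop = FALSE]
    genes <- orthogroups[[og]][organisms$id]
    if (all(lengths(genes) == 1L)) {
      # already 1:1: no trimming decision to make, keep as-is (score = total
      # qualifying bit score of the unique assignment, 0 with no hit graph)
      g2o <- .gene2org(genes)
      sc <- .pair_scores(names(g2o), g2o, og_hits, config)
      asn <- list(assignment = vapply(genes, `[`, character(1), 1),
                  score = sum(sc[upper.tri(sc)]), exact = TRUE)
    } else {
      flt <- filter_homology(genes, og_hits, config)
      if (!is.null(flt$reason)) {
        rej[[og]] <- data.frame(orthogroup = og, reason = flt$reason,
                                stringsAsFactors = FALSE)
        next
      }
      asn <- best_one2one(flt$retained, og_hits, config)
    }
    rows[[og]] <- data.frame(
      orthogroup = og, organism = names(asn$assignment),
      gene = unname(asn$assignment), score = asn$score, exact = asn$exact,
      stringsAsFactors = FALSE)
  }
  structure(list(
    assignments = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
                  else data.frame(orthogroup = character(), organism = character(),
                                  gene = character(), score = numeric(),
                                  exact = logical()),
    rejects = if (length(rej)) do.call(rbind, c(rej, make.row.names = FALSE))
              else data.frame(orthogroup = character(), reason = character())),
    class = "one2one_set")
}

#' @export
print.one2one_set <- function(x, ...) {
  cat("1:1 ortholog set:", length(unique(x$assignments$orthogroup)),
      "orthogroups kept,", nrow(x$rejects), "rejected\n")
  if (nrow(x$assignments) && any(!x$assignments$exact))
    cat("  (", length(unique(x$assignments$orthogroup[!x$assignments$exact])),
        "orthogroups assigned heuristically )\n")
  invisible(x)
}

#' Write a 1:1 ortholog set and its rejects as TSV
#'
#' @param x A `one2one_set`.
#' @param dir Output directory; writes `one2one.tsv` and `og_rejects.tsv`.
#' @export
write_one2one <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(x$assignments, file.path(dir, "one2one.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$rejects, file.path(dir, "og_rejects.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
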