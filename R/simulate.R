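#' Default cotton-like organism set for simulations
#'
#' Eleven organisms mirroring the study design: six diploids (A1, A2, D1,
#' D5, E1, G2), the subgenomes of two allotetraploids (At1/Dt1 of AD1,
#' At2/Dt2 of AD2) treated as independent organisms, and one outgroup
#' (Tcacao).
#'
#' @return An `organism_set`.
#' @export
default_organisms <- function() {
  organism_set(
    ids = c("A1", "A2", "D1", "D5", "E1", "G2",
            "At1", "Dt1", "At2", "Dt2", "Tcacao"),
    roles = c(rep("diploid", 6), rep("subgenome", 4), "outgroup"),
    subgenome_parent = c(At1 = "AD1", Dt1 = "AD1",
                         At2 = "AD2", Dt2 = "AD2"))
}

# Newick of the default 11-organism topology; branch lengths are in sOU
# divergence units (patristic distance d gives expected correlation e^-d).
# The A1/A2 ancestor is labelled A0.
.default_tree_text <- paste0(
  "((((A1:0.15,A2:0.15)A0:0.35,(At1:0.2,Dt1:0.3):0.3):0.15,",
  "((D1:0.25,D5:0.25):0.3,(At2:0.25,Dt2:0.3):0.25):0.2):0.25,",
  "(E1:0.7,G2:0.75):0.2,Tcacao:1.6);")

#' Simulation configuration
#'
#' The stated world of the generator: log2 expression deviations evolve on
#' a fixed organism tree under a stationary Ornstein-Uhlenbeck process with
#' gene-specific conservation `W ~ Gamma(w_alpha, rate = w_beta)` scaling
#' the stationary variance as `1/(2W)`; a gene-level baseline log2
#' expression ~ Normal(`baseline_mean`, `baseline_sd`) shared across
#' organisms; 3 noisy replicates per organism with multiplicative lognormal
#' noise; an allotetraploid whose per-gene total homoeolog expression
#' follows a fixed additive / partial-dominant / dominant / over-dominant
#' mixture against two designated parents; orthogroups carrying paralogous
#' decoy copies with below-threshold homology.
#'
#' @param tree_text Newick string of the organism tree (default: the
#'   11-organism cotton-like topology).
#' @param n_genes Number of genes / orthogroups (default 6000).
#' @param w_alpha,w_beta Gamma hyper-parameters of the conservation prior
#'   (default shape 2, rate 4).
#' @param n_reps Replicates per organism (default 3).
#' @param rep_noise_sd Lognormal (natural-log) sd of replicate noise on TPM
#'   (default 0.2).
#' @param baseline_mean,baseline_sd Normal parameters of the gene baseline
#'   on the log2-TPM scale (default mean 3, sd 2).
#' @param eld_mixture Probabilities of the four dominance categories
#'   (default additive 0.40, partial 0.25, dominance 0.20, over 0.15).
#' @param split_shape Beta shape parameters of the homoeolog split fraction
#'   (default c(2, 2)).
#' @param paralog_rate Probability an organism carries a decoy paralog copy
#'   in an orthogroup (default 0.15).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(tree_text = .default_tree_text, n_genes = 6000,
                       w_alpha = 2, w_beta = 4, n_reps = 3,
                       rep_noise_sd = 0.2, baseline_mean = 3,
                       baseline_sd = 2,
                       eld_mixture = c(additive = 0.40, partial = 0.25,
                                       dominance = 0.20, over = 0.15),
                       split_shape = c(2, 2), paralog_rate = 0.15) {
  if (abs(sum(eld_mixture) - 1) > 1e-8)
    stop("eld_mixture must sum to 1")
  stopifnot(paralog_rate >= 0, paralog_rate <= 1, n_genes >= 1)
  structure(list(tree_text = tree_text, n_genes = n_genes,
                 w_alpha = w_alpha, w_beta = w_beta, n_reps = n_reps,
                 rep_noise_sd = rep_noise_sd,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 eld_mixture = eld_mixture, split_shape = split_shape,
                 paralog_rate = paralog_rate),
            class = "sim_config")
}

# Simulate a stationary OU process along each edge of a tree, vectorized
# over genes. sigma is the per-gene stationary sd; correlation between two
# tips equals exp(-patristic distance). Returns values at every node.
.simulate_ou_on_tree <- function(tree, sigma) {
  n <- length(sigma)
  nnode <- length(tree$tip.label) + tree$Nnode
  vals <- matrix(NA_real_, n, nnode)
  root <- length(tree$tip.label) + 1L
  vals[, root] <- stats::rnorm(n) * sigma
  edges <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(edges$edge))) {
    par <- edges$edge[e, 1]; child <- edges$edge[e, 2]
    t <- edges$edge.length[e]
    vals[, child] <- vals[, par] * exp(-t) +
      stats::rnorm(n) * sigma * sqrt(1 - exp(-2 * t))
  }
  vals
}

#' Simulate tree-structured expression with known ground truth
#'
#' Draws per-gene conservation `W`, evolves log2-expression deviations
#' along the organism tree under the stationary OU model (stationary
#' variance `1/(2W)`, tip correlation `exp(-patristic distance)`), adds the
#' gene baseline, exponentiates to TPM, and emits noisy replicates. Truth
#' tables record `W`, the realized deviations at tips *and* internal nodes,
#' and the tree correlation matrix.
#'
#' @param config A `sim_config`.
#' @param seed Random seed (mandatory).
#' @return List of class `expression_sim` with elements `config`, `seed`,
#'   `tree` (`phylo`), `organisms`, `genes` (orthogroup-style row ids),
#'   `W`, `baseline`, `dev` (genes x tips log2 deviations), `node_dev`
#'   (genes x internal nodes, columns named by node label where present),
#'   `tpm` (noiseless genes x organisms), `replicates` (named list organism
#'   -> genes x n_reps TPM matrix), `R_tree`.
#' @export
simulate_expression <- function(config = sim_config(), seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  set.seed(seed)
  tree <- ape::read.tree(text = config$tree_text)
  dmat <- ape::cophenetic.phylo(tree)
  if (any(dmat[upper.tri(dmat)] <= 0))
    stop("tree must have positive path lengths between all tips")
  R_tree <- exp(-dmat)

  n <- config$n_genes
  genes <- sprintf("OG%06d", seq_len(n))
  W <- stats::rgamma(n, shape = config$w_alpha, rate = config$w_beta)
  sigma <- 1 / sqrt(2 * W)
  vals <- .simulate_ou_on_tree(tree, sigma)
  ntip <- length(tree$tip.label)
  dev <- vals[, seq_len(ntip), drop = FALSE]
  colnames(dev) <- tree$tip.label
  node_dev <- vals[, ntip + seq_len(tree$Nnode), drop = FALSE]
  nlab <- tree$node.label
  colnames(node_dev) <- if (!is.null(nlab))
    ifelse(nzchar(nlab), nlab, paste0("node", ntip + seq_len(tree$Nnode)))
  else paste0("node", ntip + seq_len(tree$Nnode))
  rownames(dev) <- rownames(node_dev) <- genes

  baseline <- stats::rnorm(n, config$baseline_mean, config$baseline_sd)
  names(baseline) <- genes
  tpm <- 2^(dev + baseline)

  replicates <- lapply(tree$tip.label, function(o) {
    m <- matrix(tpm[, o], n, config$n_reps) *
      exp(matrix(stats::rnorm(n * config$n_reps, 0, config$rep_noise_sd),
                 n, config$n_reps))
    dimnames(m) <- list(genes, paste0(o, "_r", seq_len(config$n_reps)))
    m
  })
  names(replicates) <- tree$tip.label

  structure(list(config = config, seed = seed, tree = tree,
                 organisms = default_organisms(), genes = genes, W = W,
                 baseline = baseline, dev = dev, node_dev = node_dev,
                 tpm = tpm, replicates = replicates, R_tree = R_tree),
            class = "expression_sim")
}

#' @export
print.expression_sim <- function(x, ...) {
  cat("Expression simulation:", length(x$genes), "genes x",
      length(x$tree$tip.label), "organisms,", x$config$n_reps,
      "replicates (seed", x$seed, ")\n")
  invisible(x)
}

#' Graft a tetraploid with a known dominance mixture onto a simulation
#'
#' Assigns each gene a true dominance category from the mixture and sets
#' the tetraploid total expression P accordingly from the two parents'
#' noiseless TPM values A and D: additive at the mid-parent value
#' (`|d/a| = 0`), partial dominance halfway to the A parent (`|d/a| = 0.5`),
#' dominance at one parent's level (coin flip, `|d/a| = 1`), over-dominance
#' outside the parental range at `|d/a| = 2` (direction flipped upward when
#' the downward target would be negative). P is split into two homoeolog
#' levels by a Beta-distributed fraction and replicate noise is added.
#'
#' @param sim An `expression_sim`.
#' @param a_parent,d_parent Parent organism ids among the simulated tips.
#' @param mixture Category probabilities (defaults from `sim$config`).
#' @param name Tetraploid name used in homoeolog organism ids (default
#'   `"ADx"`, giving organisms `"Atx"` and `"Dtx"`).
#' @param seed Random seed.
#' @return List of class `polyploid_sim` with `truth` (data frame: gene,
#'   category, P, A, D, split), `tpm` (noiseless genes x 2 homoeolog
#'   matrix), `replicates` (list of 2 homoeolog replicate matrices),
#'   `at_organism`, `dt_organism`.
#' @export
graft_polyploid <- function(sim, a_parent, d_parent,
                            mixture = sim$config$eld_mixture,
                            name = "ADx", seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  if (abs(sum(mixture) - 1) > 1e-8) stop("mixture must sum to 1")
  stopifnot(all(c(a_parent, d_parent) %in% colnames(sim$tpm)))
  set.seed(seed)
  n <- length(sim$genes)
  A <- sim$tpm[, a_parent]
  D <- sim$tpm[, d_parent]
  mpv <- (A + D) / 2
  a <- (A - D) / 2
  category <- sample(names(mixture), n, replace = TRUE, prob = mixture)
  P <- mpv
  i <- category == "partial"
  P[i] <- mpv[i] + 0.5 * a[i]           # halfway toward the A parent
  i <- category == "dominance"
  toA <- stats::runif(sum(i)) < 0.5
  P[i] <- ifelse(toA, A[i], D[i])       # |d/a| = 1
  i <- category == "over"
  up <- stats::runif(sum(i)) < 0.5
  lowtarget <- mpv[i] - 2 * abs(a[i])
  up[lowtarget < 0] <- TRUE             # keep TPM non-negative
  P[i] <- mpv[i] + ifelse(up, 2, -2) * abs(a[i])

  split <- stats::rbeta(n, sim$config$split_shape[1],
                        sim$config$split_shape[2])
  at_org <- paste0("At_", name); dt_org <- paste0("Dt_", name)
  tpm <- cbind(P * split, P * (1 - split))
  dimnames(tpm) <- list(sim$genes, c(at_org, dt_org))
  replicates <- lapply(c(at_org, dt_org), function(o) {
    m <- matrix(tpm[, o], n, sim$config$n_reps) *
      exp(matrix(stats::rnorm(n * sim$config$n_reps, 0,
                              sim$config$rep_noise_sd),
                 n, sim$config$n_reps))
    dimnames(m) <- list(sim$genes, paste0(o, "_r", seq_len(sim$config$n_reps)))
    m
  })
  names(replicates) <- c(at_org, dt_org)
  structure(list(
    truth = data.frame(gene = sim$genes,
                       category = factor(
                         c(additive = "additive",
                           partial = "partial-dominance",
                           dominance = "dominance",
                           over = "over-dominance")[category],
                         levels = .eld_levels),
                       P = unname(P), A = unname(A), D = unname(D),
                       split = split, stringsAsFactors = FALSE),
    tpm = tpm, replicates = replicates,
    at_organism = at_org, dt_organism = dt_org),
    class = "polyploid_sim")
}

#' Simulate orthogroups, paralog decoys and homology hits with known truth
#'
#' Every simulated gene becomes an orthogroup with one true copy per
#' organism (gene ids `<organism>_<OG>`); with probability `paralog_rate`
#' an organism additionally carries a decoy paralog copy. True copies are
#' linked by qualifying cross-organism hits whose bit scores make the true
#' assignment the unique total-bit-score maximum; decoy copies only receive
#' hits failing the homology filter (identity at or below 50 percent, or
#' alignment coverage below 0.5).
#'
#' @param sim An `expression_sim`.
#' @param seed Random seed.
#' @return List of class `orthogroup_sim` with `orthogroups`
#'   (`orthogroup_table`), `hits` (`blast_hits`), and `truth` (data frame
#'   `orthogroup`, `organism`, `gene` of the optimal assignment).
#' @export
simulate_orthogroups <- function(sim, seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  set.seed(seed)
  orgs <- sim$tree$tip.label
  genes <- sim$genes
  n <- length(genes)
  norg <- length(orgs)
  prate <- sim$config$paralog_rate
  plen <- 300  # protein length used for all synthetic hits

  decoy <- matrix(stats::runif(n * norg) < prate, n, norg,
                  dimnames = list(genes, orgs))
  og_list <- lapply(seq_len(n), function(gi) {
    members <- lapply(orgs, function(o) {
      g <- paste0(o, "_", genes[gi])
      if (decoy[gi, o]) c(g, paste0(g, "_p")) else g
    })
    names(members) <- orgs
    members
  })
  names(og_list) <- genes

  # true-copy hits: every cross-organism pair within every orthogroup
  pairs <- utils::combn(orgs, 2)
  np <- ncol(pairs)
  q_org <- rep(pairs[1, ], times = n)
  s_org <- rep(pairs[2, ], times = n)
  g_rep <- rep(genes, each = np)
  nth <- n * np
  th <- data.frame(
    query = paste0(q_org, "_", g_rep), subject = paste0(s_org, "_", g_rep),
    pident = stats::runif(nth, 60, 95),
    length = round(plen * stats::runif(nth, 0.8, 1)),
    mismatch = 0, gapopen = 0, qstart = 1, qend = plen,
    sstart = 1, send = plen, evalue = 1e-50,
    bitscore = round(stats::runif(nth, 100, 500), 1),
    qlen = plen, slen = plen, stringsAsFactors = FALSE)

  # decoy hits fail the filter: half by identity <= 50, half by coverage
  dg <- which(decoy, arr.ind = TRUE)
  dh <- NULL
  if (nrow(dg)) {
    nd <- nrow(dg)
    tgt_org <- orgs[(dg[, 2] - 1L + sample.int(norg - 1L, nd,
                                               replace = TRUE)) %% norg + 1L]
    low_ident <- stats::runif(nd) < 0.5
    dh <- data.frame(
      query = paste0(orgs[dg[, 2]], "_", genes[dg[, 1]], "_p"),
      subject = paste0(tgt_org, "_", genes[dg[, 1]]),
      pident = ifelse(low_ident, stats::runif(nd, 20, 50),
                      stats::runif(nd, 60, 95)),
      length = ifelse(low_ident, round(plen * 0.9),
                      round(plen * stats::runif(nd, 0.1, 0.45))),
      mismatch = 0, gapopen = 0, qstart = 1, qend = plen,
      sstart = 1, send = plen, evalue = 1e-20,
      bitscore = round(stats::runif(nd, 600, 900), 1),
      qlen = plen, slen = plen, stringsAsFactors = FALSE)
  }
  hits <- rbind(th, dh)
  rownames(hits) <- NULL
  hits$self <- hits$query == hits$subject
  class(hits) <- c("blast_hits", "data.frame")
  truth <- do.call(rbind, lapply(genes, function(og)
    data.frame(orthogroup = og, organism = orgs,
               gene = paste0(orgs, "_", og), stringsAsFactors = FALSE)))
  structure(list(
    orthogroups = structure(og_list, class = "orthogroup_table",
                            organisms = orgs),
    hits = hits, truth = truth),
    class = "orthogroup_sim")
}

#' Generate one random orthogroup with a fully scored hit graph
#'
#' Produces a small orthogroup where several organisms carry multiple
#' copies, every copy passes the homology filter, and cross-organism pairs
#' are linked by hits with random bit scores -- the setting where the
#' total-bit-score 1:1 assignment is non-trivial. Used to validate the
#' assignment optimizer against brute-force enumeration.
#'
#' @param n_org Number of organisms (default 4).
#' @param max_copies Maximum copies per organism (default 3).
#' @param hit_prob Probability that a cross-organism gene pair has a hit
#'   (default 0.7).
#' @param seed Random seed.
#' @return List with `og_genes` (named list organism -> gene ids) and
#'   `hits` (`blast_hits`).
#' @export
simulate_random_og <- function(n_org = 4, max_copies = 3, hit_prob = 0.7,
                               seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  set.seed(seed)
  orgs <- paste0("S", seq_len(n_org))
  og_genes <- lapply(orgs, function(o)
    paste0(o, "_c", seq_len(sample.int(max_copies, 1))))
  names(og_genes) <- orgs
  g2o <- .gene2org(og_genes)
  genes <- names(g2o)
  pairs <- utils::combn(genes, 2)
  cross <- g2o[pairs[1, ]] != g2o[pairs[2, ]]
  pairs <- pairs[, cross, drop = FALSE]
  keep <- stats::runif(ncol(pairs)) < hit_prob
  pairs <- pairs[, keep, drop = FALSE]
  np <- ncol(pairs)
  plen <- 300
  hits <- data.frame(
    query = pairs[1, ], subject = pairs[2, ],
    pident = stats::runif(np, 55, 95),
    length = round(plen * stats::runif(np, 0.6, 1)),
    mismatch = 0, gapopen = 0, qstart = 1, qend = plen,
    sstart = 1, send = plen, evalue = 1e-30,
    bitscore = round(stats::runif(np, 50, 500), 1),
    qlen = plen, slen = plen, self = FALSE, stringsAsFactors = FALSE)
  class(hits) <- c("blast_hits", "data.frame")
  list(og_genes = og_genes, hits = hits)
}

#' Simulate Brownian motion on a tree with recorded node states
#'
#' Plain Brownian motion (no pull to the mean): each child value is the
#' parent value plus Normal(0, sigma^2 * branch length) noise. Internal
#' node states are recorded, giving exact ground truth for ancestral-state
#' estimation.
#'
#' @param tree A `phylo` with branch lengths.
#' @param n_genes Number of independent traits.
#' @param sigma Brownian rate (sd per unit branch length, default 1).
#' @param root_mean Root state (default 0).
#' @param seed Random seed.
#' @return List with `tips` (genes x tips) and `nodes` (genes x internal
#'   nodes, column `nodeK` = node number K).
#' @export
simulate_brownian <- function(tree, n_genes, sigma = 1, root_mean = 0,
                              seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  vals <- matrix(NA_real_, n_genes, nnode)
  vals[, ntip + 1L] <- root_mean
  edges <- ape::reorder.phylo(tree, "cladewise")
  for (e in seq_len(nrow(edges$edge))) {
    par <- edges$edge[e, 1]; child <- edges$edge[e, 2]
    vals[, child] <- vals[, par] +
      stats::rnorm(n_genes, 0, sigma * sqrt(edges$edge.length[e]))
  }
  tips <- vals[, seq_len(ntip), drop = FALSE]
  colnames(tips) <- tree$tip.label
  nodes <- vals[, ntip + seq_len(tree$Nnode), drop = FALSE]
  colnames(nodes) <- paste0("node", ntip + seq_len(tree$Nnode))
  list(tips = tips, nodes = nodes)
}

#' Write a simulation to disk in the pipeline's input formats
#'
#' Emits per-organism TPM TSV tables, a sample sheet TSV, an
#' Orthogroups.tsv, a 14-column homology hit table, and truth TSVs, so the
#' whole pipeline can be exercised through its file readers.
#'
#' @param sim An `expression_sim`.
#' @param dir Output directory (created).
#' @param ogsim Optional `orthogroup_sim`; when supplied, the TPM tables
#'   use the organism-specific gene ids of the orthogroup world and the
#'   orthogroup/hit tables are written.
#' @param polysim Optional `polyploid_sim` whose homoeolog tables are
#'   appended as two extra organisms.
#' @return Invisibly, the path of the written sample sheet.
#' @export
write_simulation <- function(sim, dir, ogsim = NULL, polysim = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reps <- sim$replicates
  if (!is.null(polysim)) reps <- c(reps, polysim$replicates)
  rows <- list()
  for (o in names(reps)) {
    m <- reps[[o]]
    ids <- if (!is.null(ogsim) && o %in% sim$tree$tip.label)
      paste0(o, "_", rownames(m)) else rownames(m)
    df <- data.frame(gene = ids, m, check.names = FALSE,
                     stringsAsFactors = FALSE)
    path <- file.path(dir, paste0("tpm_", o, ".tsv"))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    rows[[o]] <- data.frame(sample = colnames(m), organism = o,
                            replicate = seq_len(ncol(m)),
                            path = basename(path),
                            stringsAsFactors = FALSE)
  }
  sheet <- do.call(rbind, rows)
  sheet_path <- file.path(dir, "samples.tsv")
  utils::write.table(sheet, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(ogsim)) {
    write_orthogroups(ogsim$orthogroups, file.path(dir, "Orthogroups.tsv"))
    write_blast_tabular(ogsim$hits, file.path(dir, "blast.tsv"))
  }
  utils::write.table(
    data.frame(gene = sim$genes, W = sim$W, baseline = sim$baseline),
    file.path(dir, "truth_genes.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  invisible(sheet_path)
}
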