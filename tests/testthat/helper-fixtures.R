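# Shared fixture builders and independent oracles for the test suite.

# One homology hit row in the 14-column dialect.
make_hit <- function(query, subject, pident = 80, length = 240,
                     evalue = 1e-30, bitscore = 200, qlen = 300,
                     slen = 300) {
  data.frame(query = query, subject = subject, pident = pident,
             length = length, mismatch = 0, gapopen = 0, qstart = 1,
             qend = length, sstart = 1, send = length, evalue = evalue,
             bitscore = bitscore, qlen = qlen, slen = slen,
             self = query == subject, stringsAsFactors = FALSE)
}

make_hits <- function(...) {
  h <- do.call(rbind, list(...))
  class(h) <- c("blast_hits", "data.frame")
  h
}

# A minimal 3-organism set (two diploids + outgroup) for format tests.
tiny_organisms <- function() {
  organism_set(c("orgA", "orgB", "orgC"),
               c("diploid", "diploid", "outgroup"))
}

# Independent brute-force 1:1 assignment oracle. Recomputes qualifying
# pair scores straight from the hit rows (no shared code with the
# implementation) and enumerates every assignment.
brute_force_one2one <- function(og_genes, hits, min_identity = 50,
                                max_evalue = 1e-3, min_coverage = 0.5) {
  g2o <- character(0)
  for (o in names(og_genes))
    g2o[og_genes[[o]]] <- o
  qual <- hits$pident > min_identity & hits$evalue <= max_evalue &
    (hits$length / pmin(hits$qlen, hits$slen)) >= min_coverage &
    hits$query %in% names(g2o) & hits$subject %in% names(g2o)
  h <- hits[qual, , drop = FALSE]
  h <- h[g2o[h$query] != g2o[h$subject], , drop = FALSE]
  pair_score <- function(g1, g2) {
    sel <- (h$query == g1 & h$subject == g2) |
      (h$query == g2 & h$subject == g1)
    if (any(sel)) max(h$bitscore[sel]) else 0
  }
  orgs <- sort(names(og_genes))
  grid <- expand.grid(lapply(og_genes[orgs], sort),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  best_score <- -Inf
  for (r in seq_len(nrow(grid))) {
    cand <- as.character(grid[r, ])
    sc <- 0
    for (i in seq_len(length(cand) - 1))
      for (j in (i + 1):length(cand))
        sc <- sc + pair_score(cand[i], cand[j])
    if (sc > best_score) {
      best <- cand
      best_score <- sc
    }
  }
  names(best) <- orgs
  list(assignment = best, score = best_score)
}

# Vectors of unit variance with an exactly prescribed Pearson correlation:
# y = rho * x + sqrt(1 - rho^2) * z with x, z standardized and orthogonal.
correlated_pair <- function(rho, n = 12) {
  x <- scale(seq_len(n))[, 1]
  z <- scale((seq_len(n) %% 2) * 2 - 1)[, 1]
  z <- z - x * sum(x * z) / sum(x * x)
  z <- z / stats::sd(z)
  x <- x / stats::sd(x)
  list(x = x, y = rho * x + sqrt(1 - rho^2) * z)
}
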