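test_that("occupancy classification flags species-complete and single-copy", {
  os <- tiny_organisms()
  ogs <- structure(list(
    OG1 = list(orgA = "a1", orgB = "b1", orgC = "c1"),
    OG2 = list(orgA = c("a2", "a2b"), orgB = "b2", orgC = "c2"),
    OG3 = list(orgA = "a3", orgB = character(0), orgC = character(0))),
    class = "orthogroup_table", organisms = c("orgA", "orgB", "orgC"))
  occ <- classify_occupancy(ogs, os)
  expect_equal(occ$n_occupied, c(3, 3, 1))
  expect_equal(occ$species_complete, c(TRUE, TRUE, FALSE))
  expect_equal(occ$single_copy, c(TRUE, FALSE, FALSE))
})

test_that("homology filter applies identity/evalue/coverage rules", {
  og <- list(orgA = c("a1", "a2"), orgB = "b1", orgC = "c1")
  # a1: qualifying cross-organism hit (identity 62.5, coverage 0.8)
  # a2: only a paralog (within-organism) hit -> dropped
  # boundary: identity exactly 50 does not pass the strict > rule
  hits <- make_hits(
    make_hit("a1", "b1", pident = 62.5, length = 80, evalue = 1e-30,
             bitscore = 150, qlen = 100, slen = 100),
    make_hit("a2", "a1", pident = 90, length = 90, qlen = 100, slen = 100),
    make_hit("b1", "c1", pident = 50.0, length = 90, qlen = 100,
             slen = 100),
    make_hit("c1", "a1", pident = 70, length = 60, qlen = 100, slen = 100))
  flt <- filter_homology(og, hits)
  expect_equal(flt$retained$orgA, "a1")
  expect_null(flt$reason)
  expect_true("b1" %in% flt$retained$orgB)  # supported by the a1 hit alone
  expect_true("c1" %in% flt$retained$orgC)

  # coverage below 0.5 disqualifies
  h2 <- make_hits(make_hit("a1", "b1", pident = 80, length = 40,
                           qlen = 100, slen = 100))
  flt2 <- filter_homology(list(orgA = "a1", orgB = "b1"), h2)
  expect_match(flt2$reason, "no qualifying copy")

  # e-value boundary is inclusive
  h3 <- make_hits(make_hit("a1", "b1", pident = 80, length = 80,
                           evalue = 1e-3, qlen = 100, slen = 100))
  expect_null(filter_homology(list(orgA = "a1", orgB = "b1"), h3)$reason)
})

test_that("raising the identity threshold never retains more genes", {
  set.seed(31)
  for (k in 1:20) {
    ro <- simulate_random_og(n_org = 3, max_copies = 3, seed = 100 + k)
    prev <- Inf
    for (thr in c(40, 55, 70, 85)) {
      flt <- filter_homology(ro$og_genes, ro$hits,
                             og_trim_config(min_identity = thr))
      n <- sum(lengths(flt$retained))
      expect_lte(n, prev)
      prev <- n
    }
  }
})

test_that("best 1:1 assignment maximizes total bit score", {
  # single copy everywhere: the unique assignment, exact
  og1 <- list(orgA = "a1", orgB = "b1")
  h <- make_hits(make_hit("a1", "b1", bitscore = 120))
  r1 <- best_one2one(og1, h)
  expect_equal(r1$assignment, c(orgA = "a1", orgB = "b1"))
  expect_true(r1$exact)
  expect_equal(r1$score, 120)

  # one organism with two copies: totals 300 vs 250
  og2 <- list(orgA = c("a1", "a2"), orgB = "b1", orgC = "c1")
  h2 <- make_hits(
    make_hit("a1", "b1", bitscore = 150), make_hit("a1", "c1", bitscore = 150),
    make_hit("a2", "b1", bitscore = 125), make_hit("a2", "c1", bitscore = 125),
    make_hit("b1", "c1", bitscore = 10))
  r2 <- best_one2one(og2, h2)
  expect_equal(unname(r2$assignment["orgA"]), "a1")
  expect_equal(r2$score, 310)  # 150 + 150 + 10

  # pair score is the max over the two hit directions
  h3 <- make_hits(make_hit("a1", "b1", bitscore = 90),
                  make_hit("b1", "a1", bitscore = 110))
  expect_equal(best_one2one(og1, h3)$score, 110)

  # 3 organisms x 2 copies: a non-greedy optimum, checked by brute force
  og4 <- list(orgA = c("a1", "a2"), orgB = c("b1", "b2"),
              orgC = c("c1", "c2"))
  h4 <- make_hits(
    make_hit("a1", "b1", bitscore = 100), make_hit("a1", "c1", bitscore = 10),
    make_hit("b1", "c1", bitscore = 10), make_hit("a2", "b2", bitscore = 60),
    make_hit("a2", "c2", bitscore = 60), make_hit("b2", "c2", bitscore = 60))
  r4 <- best_one2one(og4, h4)
  oracle <- brute_force_one2one(og4, h4)
  expect_equal(r4$score, oracle$score)
  expect_equal(r4$assignment, oracle$assignment)
  expect_equal(unname(r4$assignment["orgA"]), "a2")  # non-greedy optimum
})

test_that("assignment equals the brute-force oracle on random orthogroups", {
  for (k in 1:60) {
    ro <- simulate_random_og(n_org = sample(3:5, 1), max_copies = 3,
                             seed = 500 + k)
    got <- best_one2one(ro$og_genes, ro$hits)
    want <- brute_force_one2one(ro$og_genes, ro$hits)
    expect_equal(got$score, want$score, tolerance = 1e-9,
                 label = paste("score, og seed", 500 + k))
    expect_true(got$exact)
  }
})

test_that("assignment score is invariant to hit ordering", {
  ro <- simulate_random_og(n_org = 4, max_copies = 3, seed = 77)
  r1 <- best_one2one(ro$og_genes, ro$hits)
  set.seed(1)
  shuffled <- ro$hits[sample.int(nrow(ro$hits)), , drop = FALSE]
  r2 <- best_one2one(ro$og_genes, shuffled)
  expect_equal(r1$assignment, r2$assignment)
  expect_equal(r1$score, r2$score)
})

test_that("the capped heuristic path still finds good assignments", {
  ro <- simulate_random_og(n_org = 4, max_copies = 3, seed = 91)
  exact <- best_one2one(ro$og_genes, ro$hits)
  heur <- best_one2one(ro$og_genes, ro$hits,
                       og_trim_config(enumeration_cap = 1))
  expect_false(heur$exact)
  expect_lte(heur$score, exact$score)
  # with single-swap restarts the heuristic matches the optimum here
  expect_equal(heur$score, exact$score)
})

test_that("batch trimming keeps, rejects and reports deterministically", {
  os <- tiny_organisms()
  sim <- simulate_expression(sim_config(n_genes = 40, paralog_rate = 0.3),
                             seed = 21)
  ogsim <- simulate_orthogroups(sim, seed = 22)
  o2o <- trim_all(ogsim$orthogroups, ogsim$hits, default_organisms())
  # decoy copies never displace true copies
  asn <- merge(o2o$assignments, ogsim$truth,
               by = c("orthogroup", "organism"))
  expect_equal(asn$gene.x, asn$gene.y)
  expect_equal(length(unique(o2o$assignments$orthogroup)), 40L)

  # empty hit list: multi-copy orthogroups rejected, single-copy kept at 0
  occ <- classify_occupancy(ogsim$orthogroups, default_organisms())
  no_hits <- ogsim$hits[0, , drop = FALSE]
  o2o0 <- trim_all(ogsim$orthogroups, no_hits, default_organisms())
  kept0 <- unique(o2o0$assignments$orthogroup)
  expect_setequal(kept0, occ$orthogroup[occ$single_copy])
  expect_true(all(o2o0$assignments$score == 0))
  expect_setequal(o2o0$rejects$orthogroup,
                  occ$orthogroup[occ$species_complete & !occ$single_copy])

  # rerun is byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_one2one(o2o, d1)
  write_one2one(trim_all(ogsim$orthogroups, ogsim$hits,
                         default_organisms()), d2)
  expect_identical(readLines(file.path(d1, "one2one.tsv")),
                   readLines(file.path(d2, "one2one.tsv")))
})
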