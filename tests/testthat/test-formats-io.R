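test_that("organism set enforces its structural invariants", {
  os <- default_organisms()
  expect_s3_class(os, "organism_set")
  expect_equal(outgroup_id(os), "Tcacao")
  expect_equal(sort(subgenome_ids(os, "AD1")), c("At1", "Dt1"))
  expect_setequal(diploid_ids(os), c("A1", "A2", "D1", "D5", "E1", "G2"))

  expect_error(organism_set(c("A", "A"), c("diploid", "diploid")), "unique")
  expect_error(organism_set(c("A", "B"), c("outgroup", "outgroup")),
               "one outgroup")
  expect_error(organism_set(c("At", "X"), c("subgenome", "diploid"),
                            subgenome_parent = c(At = "AD")),
               "exactly 2 subgenomes")
  expect_error(organism_set("At", "subgenome"), "subgenome_parent")
})

test_that("sample sheets require unique replicates within organism", {
  expect_error(
    sample_sheet(c("s1", "s2"), c("A", "A"), c(1, 1), c("p", "p")),
    "unique within organism")
  sh <- sample_sheet(c("s1", "s2"), c("A", "A"), c(1, 2), c("p", "p"))
  expect_s3_class(sh, "sample_sheet")
  expect_error(
    sample_sheet("s1", "Zorg", 1, "p", organisms = tiny_organisms()),
    "unknown organism")
})

test_that("orthogroup tables parse the tab-separated dialect", {
  os <- tiny_organisms()
  f <- withr::local_tempfile(lines = c(
    "Orthogroup\torgA\torgB\torgC",
    "OG0000001\tgA1, gA2\tgB1\tgC1",
    "OG0000002\t\tgB2\tgC2"))
  tab <- read_orthogroups(f, os)
  expect_length(tab, 2)
  expect_equal(tab[["OG0000001"]][["orgA"]], c("gA1", "gA2"))
  expect_equal(tab[["OG0000001"]][["orgB"]], "gB1")
  expect_equal(tab[["OG0000002"]][["orgA"]], character(0))

  # header omitting a declared organism is a hard error naming it
  f2 <- withr::local_tempfile(lines = c(
    "Orthogroup\torgA\torgB", "OG1\tgA1\tgB1"))
  expect_error(read_orthogroups(f2, os), "orgC missing")

  # unknown column
  f3 <- withr::local_tempfile(lines = c(
    "Orthogroup\torgA\torgB\torgC\torgZ", "OG1\tg1\tg2\tg3\tg4"))
  expect_error(read_orthogroups(f3, os), "orgZ")

  # a gene in two orthogroups is a hard error naming the gene
  f4 <- withr::local_tempfile(lines = c(
    "Orthogroup\torgA\torgB\torgC",
    "OG1\tgA1\tgB1\tgC1",
    "OG2\tgA1\tgB2\tgC2"))
  expect_error(read_orthogroups(f4, os), "gA1")
})

test_that("orthogroup tables round-trip through write/read", {
  os <- tiny_organisms()
  sim <- simulate_expression(sim_config(n_genes = 20), seed = 11)
  ogsim <- simulate_orthogroups(sim, seed = 12)
  f <- withr::local_tempfile()
  write_orthogroups(ogsim$orthogroups, f)
  back <- read_orthogroups(f, default_organisms())
  expect_equal(unclass(back)[], unclass(ogsim$orthogroups)[],
               ignore_attr = TRUE)
})

test_that("tabular homology hits parse with lengths and fail loudly", {
  f <- withr::local_tempfile(lines = paste(
    "q1", "s1", "62.5", "80", "30", "0", "1", "80", "1", "80",
    "1e-30", "150", "100", "100", sep = "\t"))
  h <- read_blast_tabular(f)
  expect_equal(h$pident, 62.5)
  expect_equal(h$bitscore, 150)
  expect_equal(h$qlen, 100)
  expect_false(h$self)

  # scientific notation e-values parse numerically
  f2 <- withr::local_tempfile(lines = paste(
    "q1", "q1", "99", "100", "0", "0", "1", "100", "1", "100",
    "1e-3", "180", "100", "100", sep = "\t"))
  h2 <- read_blast_tabular(f2)
  expect_equal(h2$evalue, 0.001)
  expect_true(h2$self)  # self-hit retained but flagged

  # 12-column input must ask for lengths
  f3 <- withr::local_tempfile(lines = paste(
    "q1", "s1", "62.5", "80", "30", "0", "1", "80", "1", "80",
    "1e-30", "150", sep = "\t"))
  expect_error(read_blast_tabular(f3), "qlen/slen")

  # malformed numerics carry the line number
  f4 <- withr::local_tempfile(lines = c(
    paste("q1", "s1", "62.5", "80", "30", "0", "1", "80", "1", "80",
          "1e-30", "150", "100", "100", sep = "\t"),
    paste("q2", "s2", "oops", "80", "30", "0", "1", "80", "1", "80",
          "1e-30", "150", "100", "100", sep = "\t")))
  expect_error(read_blast_tabular(f4), "line 2")
})

test_that("TPM tables distinguish missing genes from zero expression", {
  d <- withr::local_tempdir()
  writeLines(c("gene\ta_r1\ta_r2\ta_r3",
               "g1\t1\t2\t3", "g2\t0\t0\t0"),
             file.path(d, "a.tsv"))
  writeLines(c("gene\tb_r1\tb_r2\tb_r3",
               "g1\t5\t5\t5"), file.path(d, "b.tsv"))
  sh <- sample_sheet(c(paste0("a_r", 1:3), paste0("b_r", 1:3)),
                     rep(c("orgA", "orgB"), each = 3), rep(1:3, 2),
                     rep(file.path(d, c("a.tsv", "b.tsv")), each = 3))
  em <- read_tpm_tables(sh)
  expect_equal(dim(em$replicates), c(2L, 6L))
  expect_equal(em$average["g1", "orgA"], 2)
  expect_equal(em$average["g2", "orgA"], 0)     # observed zero
  expect_true(is.na(em$average["g2", "orgB"]))  # missing, not zero

  writeLines(c("gene\tc_r1", "g1\t-1"), file.path(d, "c.tsv"))
  shc <- sample_sheet("c_r1", "orgC", 1, file.path(d, "c.tsv"))
  expect_error(read_tpm_tables(shc), "negative TPM")

  writeLines(c("gene\td_r1", "g1\t1", "g1\t2"), file.path(d, "d.tsv"))
  shd <- sample_sheet("d_r1", "orgD", 1, file.path(d, "d.tsv"))
  expect_error(read_tpm_tables(shd), "duplicated gene")
})

test_that("Newick trees round-trip with supports and labels", {
  f <- withr::local_tempfile(lines = "((A:1,B:1)90:2,C:3);")
  tr <- read_newick(f)
  f2 <- withr::local_tempfile()
  write_newick(tr, f2)
  tr2 <- read_newick(f2)
  expect_equal(tr2$tip.label, tr$tip.label)
  expect_equal(tr2$edge.length, tr$edge.length, tolerance = 1e-6)
  expect_equal(tr2$node.label, tr$node.label)

  f3 <- withr::local_tempfile(lines = "((A:1,B:0.0)A0:2,C:3);")
  tr3 <- read_newick(f3)
  expect_true("A0" %in% tr3$node.label)
  expect_true(any(tr3$edge.length == 0))

  f4 <- withr::local_tempfile(lines = "((A:1,B:1,C:3);")
  expect_error(read_newick(f4))
})
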