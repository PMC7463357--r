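expr_fixture <- function(dir = withr::local_tempdir(
                           .local_envir = parent.frame())) {
  expr <- data.frame(
    gene_id = c("L1", "G1"), gene_class = c("lncRNA", "PCG"),
    P1_N = c(2, 4), P1_T = c(8, 4), P2_N = c(1, 2), P2_T = c(2, 1),
    P3_N = c(3, 3), P3_T = c(6, 9), check.names = FALSE)
  pairing <- data.frame(
    sample = c("P1_N", "P1_T", "P2_N", "P2_T", "P3_N", "P3_T"),
    patient = rep(c("P1", "P2", "P3"), each = 2),
    tissue = rep(c("N", "T"), 3))
  ep <- file.path(dir, "expr.tsv"); pp <- file.path(dir, "pairing.tsv")
  write.table(expr, ep, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pairing, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  list(expr = expr, expr_path = ep, pairing_path = pp, dir = dir)
}

test_that("matched expression parses values as written and validates pairing", {
  fx <- expr_fixture()
  m <- read_matched_expression(fx$expr_path, fx$pairing_path)
  expect_equal(length(m$gene_ids), 2L)
  expect_equal(length(m$patient_ids), 3L)
  expect_equal(m$normal["L1", "P2"], 1)
  expect_equal(m$tumor["G1", "P3"], 9)
  expect_equal(unname(m$gene_class["L1"]), "lncRNA")

  # dropping P2's tumor column is a pairing error naming the patient
  broken <- fx$expr[, setdiff(names(fx$expr), "P2_T")]
  bp <- file.path(fx$dir, "broken.tsv")
  write.table(broken, bp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_matched_expression(bp, fx$pairing_path), "P2")

  # duplicate gene id is a format error naming the gene
  dup <- rbind(fx$expr, fx$expr[1, ])
  dp <- file.path(fx$dir, "dup.tsv")
  write.table(dup, dp, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_matched_expression(dp, fx$pairing_path), "L1")

  # negative values are rejected
  neg <- fx$expr; neg$P1_N[1] <- -1
  np <- file.path(fx$dir, "neg.tsv")
  write.table(neg, np, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_matched_expression(np, fx$pairing_path), "negative")
})

test_that("matched expression is invariant to input column permutation", {
  fx <- expr_fixture()
  m1 <- read_matched_expression(fx$expr_path, fx$pairing_path)
  perm <- fx$expr[, c("gene_id", "gene_class",
                      "P3_T", "P2_N", "P1_T", "P1_N", "P3_N", "P2_T")]
  pp <- file.path(fx$dir, "perm.tsv")
  write.table(perm, pp, sep = "\t", quote = FALSE, row.names = FALSE)
  m2 <- read_matched_expression(pp, fx$pairing_path)
  expect_identical(m1, m2)
})

test_that("matched expression round-trips through its writer", {
  fx <- expr_fixture()
  m1 <- read_matched_expression(fx$expr_path, fx$pairing_path)
  ep <- file.path(fx$dir, "out.tsv"); pp <- file.path(fx$dir, "outp.tsv")
  write_matched_expression(m1, ep, pp)
  m2 <- read_matched_expression(ep, pp)
  expect_equal(m1$normal, m2$normal, tolerance = 1e-12)
  expect_equal(m1$tumor, m2$tumor, tolerance = 1e-12)
  expect_identical(m1$gene_class, m2$gene_class)
})

test_that("interaction reader deduplicates and enforces one class per target", {
  dir <- withr::local_tempdir()
  df <- data.frame(mirna_id = c("m1", "m1", "m1", "m2"),
                   target_id = c("L1", "L1", "G1", "G2"),
                   target_class = c("lncRNA", "lncRNA", "PCG", "PCG"))
  p <- file.path(dir, "int.tsv")
  write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  it <- read_interactions(p)
  expect_equal(nrow(it), 3L)
  expect_equal(unname(attr(it, "counts")["mirnas"]), 2L)

  bad <- df; bad$target_class[3] <- "lncRNA"; bad$target_id[3] <- "G2"
  write.table(bad, p, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_interactions(p), "more than one class")

  writeLines("mirna_id\ttarget_id\ttarget_class", p)
  expect_warning(it0 <- read_interactions(p), "empty")
  expect_equal(nrow(it0), 0L)
})

test_that("GMT reader collapses duplicate members and rejects empty sets", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "sets.gmt")
  writeLines(c("S1\tfirst\ta\tb\tc",
               "S2\tsecond\td\te\tf\tg\th"), p)
  gs <- read_gene_sets(p)
  expect_equal(unname(lengths(gs$sets)), c(3L, 5L))
  expect_equal(unname(gs$labels["S2"]), "second")

  writeLines(c("S1\tfirst\ta\ta\tb"), p)
  expect_equal(unname(lengths(read_gene_sets(p)$sets)), 2L)

  writeLines(c("S1\tfirst"), p)
  expect_error(read_gene_sets(p), "no members")
})

test_that("clinical, region and coordinate validation rejects bad rows", {
  expect_silent(clinical_table(data.frame(patient_id = "P1", time = 730,
                                          event = 1)))
  expect_error(clinical_table(data.frame(patient_id = "P1", time = 0,
                                         event = 1)), "positive")
  expect_error(enhancer_regions(data.frame(
    chrom = "chr1", start = 100, end = 100, enhancer_class = "SE",
    cell_line = "a")), "coordinate")
  expect_error(gene_coords(data.frame(
    gene_id = "L1", chrom = "chr1", start = 1, end = 10, strand = ".")),
    "strand")
  gc <- gene_coords(data.frame(gene_id = c("A", "B"), chrom = "chr1",
                               start = c(0, 100), end = c(50, 200),
                               strand = c("+", "-")))
  expect_equal(gc$tss, c(0, 200))  # strand-aware TSS
})

test_that("result tables round-trip to 1e-12 and keep strings exactly", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "res.tsv")
  df <- data.frame(lncrna_id = c("L1", "L2"), pcg_id = c("G1", "G2"),
                   cor = c(1 / 3, -sqrt(2) / 7), p_value = c(0.05, 1e-12),
                   functional = c(TRUE, FALSE), stringsAsFactors = FALSE)
  write_results(df, p)
  back <- read_results(p)
  expect_identical(back$lncrna_id, df$lncrna_id)
  expect_equal(back$cor, df$cor, tolerance = 1e-12)
  expect_equal(back$p_value, df$p_value, tolerance = 1e-12)
  expect_identical(back$functional, df$functional)

  write_results(df[0, ], p)
  expect_equal(nrow(read_results(p)), 0L)
  expect_error(write_results(df, file.path(dir, "nope", "res.tsv")),
               "cannot write")
})
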