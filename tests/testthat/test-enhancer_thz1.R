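toy_coords <- function() {
  gene_coords(data.frame(
    gene_id = c("L1", "L2", "L3"),
    chrom = "chr1",
    start = c(100, 30000, 90000),
    end = c(200, 31000, 95000),
    strand = c("+", "+", "+")))
}

test_that("enhancer assignment applies overlap, proximal and closest rules", {
  coords <- toy_coords()
  # region inside L1's body: overlap at distance 0 (and closest)
  reg <- enhancer_regions(data.frame(
    chrom = "chr1", start = 150, end = 160, enhancer_class = "SE",
    cell_line = "cellA"))
  asg <- assign_enhancers(reg, coords)
  l1 <- asg[asg$gene_id == "L1", ]
  expect_equal(l1$rule, "overlap")
  expect_equal(l1$distance, 0)

  # centre at 30000 from a TSS at 1000: proximal within the 50 kb window
  reg2 <- enhancer_regions(data.frame(
    chrom = "chr1", start = 29995, end = 30005, enhancer_class = "TE",
    cell_line = "cellA"))
  coords2 <- gene_coords(data.frame(
    gene_id = "LX", chrom = "chr1", start = 1000, end = 2000,
    strand = "+"))
  asg2 <- assign_enhancers(reg2, coords2)
  expect_equal(asg2$rule, "proximal")  # strongest rule wins over closest
  expect_equal(asg2$distance, 29000)

  # nearer gene gets proximal (and closest); farther gene outside the
  # window gets nothing
  reg3 <- enhancer_regions(data.frame(
    chrom = "chr1", start = 19995, end = 20005, enhancer_class = "SE",
    cell_line = "cellA"))
  coords3 <- gene_coords(data.frame(
    gene_id = c("NEAR", "FAR"), chrom = "chr1",
    start = c(10000, 110000), end = c(11000, 111000),
    strand = c("+", "+")))
  asg3 <- assign_enhancers(reg3, coords3)
  expect_setequal(asg3$gene_id, "NEAR")
  expect_equal(asg3$rule, "proximal")
  expect_equal(asg3$distance, 10000)

  # regions on chromosomes without genes are skipped with a warning
  reg4 <- enhancer_regions(data.frame(
    chrom = "chrX", start = 0, end = 10, enhancer_class = "SE",
    cell_line = "cellA"))
  expect_warning(out4 <- assign_enhancers(reg4, coords), "skipping")
  expect_equal(nrow(out4), 0L)
})

test_that("assignment invariants: window bound, one closest, monotone coverage", {
  set.seed(8)
  coords <- gene_coords(data.frame(
    gene_id = sprintf("GENE%02d", 1:20),
    chrom = rep(c("chr1", "chr2"), 10),
    start = rep(seq(0, 90000, by = 10000), each = 2),
    end = rep(seq(0, 90000, by = 10000), each = 2) + 4000,
    strand = sample(c("+", "-"), 20, TRUE)))
  regions <- enhancer_regions(local({
    st <- sample(0:80000, 6)
    data.frame(chrom = sample(c("chr1", "chr2"), 6, TRUE),
               start = st, end = st + 2000,
               enhancer_class = sample(c("SE", "TE"), 6, TRUE),
               cell_line = "cellA")
  }))
  narrow <- assign_enhancers(regions, coords, proximal_window = 15000)
  expect_true(all(narrow$distance[narrow$rule == "proximal"] <= 15000))
  # every region emits exactly one closest-or-stronger assignment per
  # (cell line, class); widening the window never removes assignments
  wide <- assign_enhancers(regions, coords, proximal_window = 60000)
  key <- function(a) paste(a$gene_id, a$cell_line, a$enhancer_class)
  expect_true(all(key(narrow) %in% key(wide)))
})

test_that("SE/TE labelling uses the any-cell-line union rule with SE precedence", {
  asg <- data.frame(
    gene_id = c("L1", "L1", "L1", "L1", "L2", "L3x"),
    cell_line = c("c1", "c2", "c3", "c4", "c1", "c1"),
    enhancer_class = c("SE", "TE", "TE", "TE", "TE", "SE"),
    rule = "overlap", distance = 0, stringsAsFactors = FALSE)
  lab <- label_se_te_lncrnas(asg, c("L1", "L2", "L9"))
  expect_equal(lab$label[lab$lncrna_id == "L1"], "SE")  # SE in 1 line wins
  expect_equal(lab$label[lab$lncrna_id == "L2"], "TE")
  expect_equal(lab$label[lab$lncrna_id == "L9"], "none")
})

test_that("THZ1 sensitivity applies the activity filter and fold cutoff", {
  tc <- data.frame(
    gene_id = rep(c("A", "B", "C", "D"), 2),
    treatment = rep(c("DMSO", "THZ1"), each = 4),
    timepoint = 12,
    value = c(10, 10, 0.5, 8, 6, 10, 0.1, NA))
  tc <- tc[!is.na(tc$value), ]
  expect_message(res <- thz1_sensitive(tc), "skipped")
  expect_true(res$sensitive[res$gene_id == "A"])    # 10/6 > 1.5
  expect_false(res$sensitive[res$gene_id == "B"])   # fold 1
  expect_false("C" %in% res$gene_id)                # inactive (DMSO <= 1)
  expect_equal(attr(res, "excluded_inactive"), "C")
  expect_equal(attr(res, "n_skipped"), 1L)          # D lacks THZ1
  expect_equal(res$fold_change[res$gene_id == "A"], 10.01 / 6.01)

  # at fold_cutoff = 1 every strictly decreased active gene is marked
  res1 <- thz1_sensitive(tc, fold_cutoff = 1)
  expect_true(res1$sensitive[res1$gene_id == "A"])
  expect_false(res1$sensitive[res1$gene_id == "B"])
})

test_that("the THZ1 subnetwork seeds on shared or unioned sensitive lncRNAs", {
  net <- cerna_network(data.frame(
    lncrna_id = c("L1", "L2", "L3"), pcg_id = c("G1", "G2", "G3")))
  sens_a <- data.frame(gene_id = c("L1", "L2"), sensitive = c(TRUE, TRUE))
  sens_b <- data.frame(gene_id = c("L1", "L2"),
                       sensitive = c(TRUE, FALSE))
  shared <- thz1_network(list(a = sens_a, b = sens_b), net,
                         require_shared = TRUE)
  expect_setequal(shared$edges$lncrna_id, "L1")
  unioned <- thz1_network(list(a = sens_a, b = sens_b), net,
                          require_shared = FALSE)
  expect_setequal(unioned$edges$lncrna_id, c("L1", "L2"))
  # SE/TE labels restrict the seeds
  lab <- data.frame(lncrna_id = c("L1", "L2"), label = c("none", "SE"))
  lab_net <- thz1_network(list(a = sens_a, b = sens_b), net,
                          labels = lab, require_shared = FALSE)
  expect_setequal(lab_net$edges$lncrna_id, "L2")
  # seeds without edges give an empty subnetwork (non-nodes are warned)
  expect_warning(
    none <- thz1_network(data.frame(gene_id = "L9", sensitive = TRUE),
                         net, require_shared = FALSE),
    "ignoring")
  expect_equal(nrow(none$edges), 0L)
})
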