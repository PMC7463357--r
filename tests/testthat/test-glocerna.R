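# Core scorer: relative expression, per-sample consistency, DEC score,
# global correlation, decision rule, and the vectorized pipeline.

test_that("relative expression is log2 tumor minus log2 normal", {
  m <- matched_expr(matrix(2, 1, 3, dimnames = list("L1", paste0("P", 1:3))),
                    matrix(8, 1, 3, dimnames = list("L1", paste0("P", 1:3))),
                    c(L1 = "lncRNA"))
  rel <- relative_expression(m)
  expect_equal(unname(rel$e["L1", ]), rep(2, 3))

  same <- matched_expr(
    matrix(5, 2, 3, dimnames = list(c("L1", "G1"), paste0("P", 1:3))),
    matrix(5, 2, 3, dimnames = list(c("L1", "G1"), paste0("P", 1:3))),
    c(L1 = "lncRNA", G1 = "PCG"))
  expect_true(all(relative_expression(same)$e == 0))

  zero <- matched_expr(
    matrix(1, 1, 3, dimnames = list("L1", paste0("P", 1:3))),
    matrix(c(0, 1, 1), 1, 3, dimnames = list("L1", paste0("P", 1:3))),
    c(L1 = "lncRNA"))
  expect_error(relative_expression(zero), "pseudocount")
  expect_silent(relative_expression(zero, pseudocount = 0.01))
})

test_that("per-sample consistency score follows the strict ternary rule", {
  expect_identical(dec_sample(3.1, 2.2), 1L)
  expect_identical(dec_sample(-2.0, -3.0), -1L)
  expect_identical(dec_sample(1.0, 2.0), 0L)   # boundary is strict
  expect_identical(dec_sample(2.0, -2.0), 0L)  # discordant directions
  expect_error(dec_sample(NA_real_, 1), "finite")
  # sign symmetry: dec(-a, -b) = -dec(a, b)
  set.seed(42)
  a <- stats::rnorm(200, 0, 2); b <- stats::rnorm(200, 0, 2)
  expect_identical(dec_sample(-a, -b), -dec_sample(a, b))
})

test_that("DEC score counts consistent samples and is symmetric and bounded", {
  # per-sample dec vector (+1, -1, 0, +1, 0) sums |.| to 3
  e <- rbind(L1 = c(2, -3, 0.5, 4, 2),
             G1 = c(3, -2, 2.0, 2, -2))
  colnames(e) <- paste0("P", 1:5)
  rel <- structure(list(e = e, gene_ids = rownames(e),
                        gene_class = c(L1 = "lncRNA", G1 = "PCG"),
                        patient_ids = colnames(e)),
                   class = "relative_expr")
  expect_identical(dec_score(rel, "L1", "G1"), 3L)
  expect_identical(dec_score(rel, "G1", "L1"), 3L)  # symmetric in (l, g)
  expect_error(dec_score(rel, "L1", "G9"), "unknown gene")

  zero <- rel; zero$e[] <- 0
  expect_identical(dec_score(zero, "L1", "G1"), 0L)

  # random pair, n = 8: equals the loop-and-count oracle; permutation
  # invariant; monotone non-increasing in the threshold
  for (seed in 1:5) {
    set.seed(seed)
    e <- matrix(stats::rnorm(16, 0, 2), 2,
                dimnames = list(c("L1", "G1"), paste0("P", 1:8)))
    rel <- structure(list(e = e, gene_ids = rownames(e),
                          gene_class = c(L1 = "lncRNA", G1 = "PCG"),
                          patient_ids = colnames(e)),
                     class = "relative_expr")
    loop <- 0L
    for (i in 1:8) {
      if (e["L1", i] > 1 && e["G1", i] > 1) loop <- loop + 1L
      if (e["L1", i] < -1 && e["G1", i] < -1) loop <- loop + 1L
    }
    expect_identical(dec_score(rel, "L1", "G1"), loop)
    expect_lte(dec_score(rel, "L1", "G1"), 8L)
    perm <- rel; perm$e <- perm$e[, sample(8)]
    expect_identical(dec_score(perm, "L1", "G1"),
                     dec_score(rel, "L1", "G1"))
    scores <- vapply(c(0.5, 1, 2, 4), function(th)
      dec_score(rel, "L1", "G1", fc_threshold = th), integer(1))
    expect_true(all(diff(scores) <= 0L))
  }
})

test_that("global correlation matches exact cases and the manual formula", {
  mk_rel <- function(el, eg) {
    e <- rbind(L1 = el, G1 = eg)
    colnames(e) <- paste0("P", seq_along(el))
    structure(list(e = e, gene_ids = rownames(e),
                   gene_class = c(L1 = "lncRNA", G1 = "PCG"),
                   patient_ids = colnames(e)), class = "relative_expr")
  }
  el <- c(0.3, -1, 2, 0.8, -0.5)
  expect_equal(global_correlation(mk_rel(el, 2 * el + 1),
                                  "L1", "G1")$cor, 1.0)
  expect_equal(global_correlation(mk_rel(1:4, 4:1), "L1", "G1")$cor, -1.0)

  for (seed in 1:5) {
    set.seed(seed)
    el <- stats::rnorm(10); eg <- stats::rnorm(10)
    got <- global_correlation(mk_rel(el, eg), "L1", "G1")
    want <- manual_pearson(el, eg)
    expect_equal(got$cor, want$r, tolerance = 1e-10)
    expect_equal(got$p_value, want$p, tolerance = 1e-10)
    sym <- global_correlation(mk_rel(eg, el), "L1", "G1")
    expect_equal(sym$cor, got$cor, tolerance = 1e-12)
    expect_true(abs(got$cor) <= 1 && got$p_value > 0 && got$p_value <= 1)
  }
  expect_error(global_correlation(mk_rel(rep(1, 5), stats::rnorm(5)),
                                  "L1", "G1"),
               class = "glocerna_zero_variance")
})

test_that("the functional decision applies all three cutoffs strictly", {
  expect_true(classify_pair(6, 0.5, 0.01))
  expect_false(classify_pair(5, 0.9, 0.001))   # DEC > 5 is strict
  expect_false(classify_pair(6, -0.2, 0.001))  # cor must exceed 0
  expect_false(classify_pair(6, 0.5, 0.05))    # p must be below 0.05
  cfg <- glocerna_config(dec_cutoff = 0, cor_cutoff = 0.4, p_cutoff = 0.2)
  expect_true(classify_pair(1, 0.5, 0.1, cfg))
  expect_false(classify_pair(1, 0.4, 0.1, cfg))
})

test_that("run_glocerna separates a planted pair from a null pair", {
  set.seed(11)
  n <- 20
  z <- sample(c(-1, 1), n, TRUE) * 2 + stats::rnorm(n, 0, 0.5)
  fc <- rbind(L1 = z + stats::rnorm(n, 0, 0.5),
              G1 = z + stats::rnorm(n, 0, 0.5),
              L2 = stats::rnorm(n, 0, 0.5),
              G2 = stats::rnorm(n, 0, 0.5))
  colnames(fc) <- sprintf("P%02d", 1:n)
  normal <- matrix(2^stats::rnorm(4 * n, 5, 1), 4, n,
                   dimnames = dimnames(fc))
  m <- matched_expr(normal, normal * 2^fc,
                    c(L1 = "lncRNA", G1 = "PCG", L2 = "lncRNA",
                      G2 = "PCG"))
  pairs <- data.frame(lncrna_id = c("L1", "L2"), pcg_id = c("G1", "G2"),
                      shared_mirna_count = 1L, stringsAsFactors = FALSE)
  res <- run_glocerna(m, pairs)
  expect_true(res$functional[res$lncrna_id == "L1"])
  expect_false(res$functional[res$lncrna_id == "L2"])

  # a DEC cutoff of n is vacuous: no pair can exceed it
  res_n <- run_glocerna(m, pairs, glocerna_config(dec_cutoff = n))
  expect_false(any(res_n$functional))

  # patient permutation leaves the result table unchanged
  perm <- sample(n)
  m2 <- matched_expr(normal[, perm], (normal * 2^fc)[, perm],
                     c(L1 = "lncRNA", G1 = "PCG", L2 = "lncRNA",
                       G2 = "PCG"))
  res2 <- run_glocerna(m2, pairs)
  expect_equal(as.data.frame(res), as.data.frame(res2), tolerance = 1e-12)

  # pairs with absent genes are skipped and counted
  pairs3 <- rbind(pairs, data.frame(lncrna_id = "L9", pcg_id = "G1",
                                    shared_mirna_count = 1L))
  res3 <- run_glocerna(m, pairs3)
  expect_equal(attr(res3, "n_skipped"), 1L)
  expect_equal(nrow(res3), 2L)
  expect_error(run_glocerna(matched_expr(normal[, 1:2], normal[, 1:2],
                                         c(L1 = "lncRNA", G1 = "PCG",
                                           L2 = "lncRNA", G2 = "PCG")),
                            pairs), "n >= 3")
})

test_that("run_glocerna equals the per-pair composition of its parts", {
  set.seed(21)
  n <- 10; m <- 12
  ids <- c(sprintf("L%02d", 1:6), sprintf("G%02d", 1:6))
  cls <- stats::setNames(rep(c("lncRNA", "PCG"), each = 6), ids)
  normal <- matrix(2^stats::rnorm(m * n, 5, 1), m, n,
                   dimnames = list(ids, sprintf("P%02d", 1:n)))
  tumor <- normal * 2^matrix(stats::rnorm(m * n, 0, 1.5), m, n)
  mat <- matched_expr(normal, tumor, cls)
  pairs <- expand.grid(lncrna_id = ids[1:6], pcg_id = ids[7:12],
                       stringsAsFactors = FALSE)[sample(36, 18), ]
  pairs$shared_mirna_count <- 1L
  res <- run_glocerna(mat, pairs)
  rel <- relative_expression(mat)
  cfg <- glocerna_config()
  for (i in seq_len(nrow(res))) {
    l <- res$lncrna_id[i]; g <- res$pcg_id[i]
    d <- dec_score(rel, l, g, cfg$fc_threshold)
    gc <- global_correlation(rel, l, g)
    expect_identical(res$dec_score[i], d)
    expect_equal(res$cor[i], gc$cor, tolerance = 1e-10)
    expect_equal(res$p_value[i], gc$p_value, tolerance = 1e-10)
    expect_identical(res$functional[i],
                     classify_pair(d, gc$cor, gc$p_value, cfg))
  }
})

test_that("zero-variance genes are excluded, not scored as cor = 0", {
  n <- 6
  ids <- c("L1", "G1")
  normal <- matrix(4, 2, n, dimnames = list(ids, paste0("P", 1:n)))
  tumor <- normal
  tumor["G1", ] <- 4 * 2^stats::rnorm(n)
  m <- matched_expr(normal, tumor, c(L1 = "lncRNA", G1 = "PCG"))
  res <- run_glocerna(m, data.frame(lncrna_id = "L1", pcg_id = "G1",
                                    shared_mirna_count = 1L))
  expect_equal(nrow(res), 0L)
  expect_equal(attr(res, "n_excluded_zero_variance"), 1L)
})

test_that("the traditional baseline recovers a strong planted pair", {
  set.seed(31)
  n <- 20
  z <- stats::rnorm(n, 2, 1)  # consistently upregulated pair
  fc <- rbind(L1 = z + stats::rnorm(n, 0, 0.3),
              G1 = z + stats::rnorm(n, 0, 0.3),
              L2 = stats::rnorm(n, 0, 0.5),
              G2 = stats::rnorm(n, 0, 0.5))
  colnames(fc) <- sprintf("P%02d", 1:n)
  normal <- matrix(2^stats::rnorm(4 * n, 5, 1), 4, n,
                   dimnames = dimnames(fc))
  m <- matched_expr(normal, normal * 2^fc,
                    c(L1 = "lncRNA", G1 = "PCG", L2 = "lncRNA",
                      G2 = "PCG"))
  pairs <- data.frame(lncrna_id = c("L1", "L2"), pcg_id = c("G1", "G2"),
                      shared_mirna_count = 1L, stringsAsFactors = FALSE)
  res <- baseline_identify(m, pairs, de_fdr = 0.05)
  expect_true(res$functional[res$lncrna_id == "L1"])
  expect_false(res$functional[res$lncrna_id == "L2"])

  # tumor identical to normal: nothing differentially expressed
  flat <- matched_expr(normal, normal,
                       c(L1 = "lncRNA", G1 = "PCG", L2 = "lncRNA",
                         G2 = "PCG"))
  expect_equal(sum(baseline_identify(flat, pairs)$functional), 0L)

  # when sharing is ubiquitous the hypergeometric criterion (p = 1 for
  # all) passes nothing, so the hyper variant selects a subset
  it <- interaction_set(data.frame(
    mirna_id = rep("m1", 4), target_id = c("L1", "L2", "G1", "G2"),
    target_class = c("lncRNA", "lncRNA", "PCG", "PCG")))
  with_h <- baseline_identify(m, pairs, use_hyper = TRUE,
                              interactions = it)
  expect_true(all(with_h$functional <= res$functional))
})
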