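# The GloceRNA scorer: per-patient relative expression (log2 fold change),
# local direction-consistency (DEC score), global correlation of relative
# expression, and the functional-ceRNA decision.

#' Configuration for the GloceRNA scorer
#'
#' All cutoffs are strict, matching the method's decision rule: a pair is
#' functional iff `DEC score > dec_cutoff`, `cor > cor_cutoff` and
#' `p < p_cutoff`. `DEC > 5` therefore means `DEC >= 6`.
#'
#' @param fc_threshold per-sample log2 fold-change threshold for calling a
#'   gene up/down in one matched sample (log2 units, default 1, strict).
#' @param dec_cutoff minimum-exceeded number of direction-consistent samples
#'   (default 5, strict `>`).
#' @param cor_cutoff correlation cutoff (default 0, strict `>`).
#' @param p_cutoff significance cutoff on the correlation p-value
#'   (default 0.05, strict `<`).
#' @param pseudocount added to expression before log2 (default 0; recommended
#'   0.01 for count-derived data). Non-positive `value + pseudocount` is a
#'   hard error rather than a silent shift.
#' @param p_sided `"two"` (default) or `"one"`: sidedness of the Pearson
#'   p-value. Two-sided combined with `cor > 0` approximates a one-sided
#'   test at half the nominal level.
#' @param fdr if `TRUE`, classify on Benjamini-Hochberg adjusted correlation
#'   p-values across all scored pairs instead of raw p (default `FALSE`;
#'   the decision rule uses raw `P < 0.05`).
#' @return A list of class `glocerna_config`.
#' @export
glocerna_config <- function(fc_threshold = 1, dec_cutoff = 5L,
                            cor_cutoff = 0, p_cutoff = 0.05,
                            pseudocount = 0,
                            p_sided = c("two", "one"), fdr = FALSE) {
  p_sided <- match.arg(p_sided)
  if (fc_threshold <= 0) stop("fc_threshold must be > 0")
  if (p_cutoff <= 0 || p_cutoff >= 1) stop("p_cutoff must be in (0, 1)")
  if (dec_cutoff < 0 || dec_cutoff != as.integer(dec_cutoff))
    stop("dec_cutoff must be a non-negative integer")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  structure(list(fc_threshold = fc_threshold,
                 dec_cutoff = as.integer(dec_cutoff),
                 cor_cutoff = cor_cutoff, p_cutoff = p_cutoff,
                 pseudocount = pseudocount, p_sided = p_sided, fdr = fdr),
            class = "glocerna_config")
}

#' Per-patient relative expression (log2 fold change tumor vs normal)
#'
#' Converts the `m x 2n` matched matrix into the `m x n` relative expression
#' matrix `e[g, i] = log2(tumor[g, i] + pseudocount) -
#' log2(normal[g, i] + pseudocount)`.
#'
#' @param x a [matched_expr] object.
#' @param pseudocount non-negative shift applied before log2 (default 0).
#' @return An object of class `relative_expr`: a list with `e` (the `m x n`
#'   log2FC matrix), `gene_ids`, `gene_class`, `patient_ids`.
#' @export
relative_expression <- function(x, pseudocount = 0) {
  stopifnot(inherits(x, "matched_expr"))
  tn <- x$tumor + pseudocount
  nn <- x$normal + pseudocount
  if (any(tn <= 0) || any(nn <= 0))
    stop("non-positive expression after pseudocount; ",
         "use a positive pseudocount for zero-containing data")
  structure(list(e = log2(tn) - log2(nn),
                 gene_ids = x$gene_ids, gene_class = x$gene_class,
                 patient_ids = x$patient_ids),
            class = "relative_expr")
}

#' Per-sample differential-expression consistency score
#'
#' The ternary single-sample score of a lncRNA-PCG pair: `+1` when both log2
#' fold changes strictly exceed `fc_threshold` (consistently upregulated),
#' `-1` when both are strictly below `-fc_threshold` (consistently
#' downregulated), `0` otherwise. Vectorized over samples.
#'
#' @param e_l,e_g numeric log2 fold changes of the lncRNA and the PCG.
#' @param fc_threshold strict log2FC threshold (default 1).
#' @return Integer vector of scores in `{-1, 0, +1}`.
#' @export
dec_sample <- function(e_l, e_g, fc_threshold = 1) {
  if (any(!is.finite(e_l)) || any(!is.finite(e_g)))
    stop("dec_sample requires finite log2 fold changes")
  up <- e_l > fc_threshold & e_g > fc_threshold
  down <- e_l < -fc_threshold & e_g < -fc_threshold
  as.integer(up) - as.integer(down)
}

#' DEC score: local regulatory direction consistency of a pair
#'
#' Counts the matched samples in which the pair is direction-consistent:
#' `DEC(l, g) = sum_i |dec_i(l, g)|`, an integer in `[0, n]`. Both up- and
#' downregulated consistent samples count, so the score tolerates
#' patient-to-patient heterogeneity in the direction of dysregulation.
#'
#' @param rel a `relative_expr` object (see [relative_expression()]).
#' @param lncrna_id,pcg_id gene ids present in `rel`.
#' @param fc_threshold strict log2FC threshold (default 1).
#' @return Integer DEC score.
#' @export
dec_score <- function(rel, lncrna_id, pcg_id, fc_threshold = 1) {
  stopifnot(inherits(rel, "relative_expr"))
  for (g in c(lncrna_id, pcg_id))
    if (!g %in% rel$gene_ids) stop("unknown gene id: ", g)
  sum(abs(dec_sample(rel$e[lncrna_id, ], rel$e[pcg_id, ], fc_threshold)))
}

#' Global regulatory direction consistency of a pair
#'
#' Pearson correlation of the two genes' relative expression (log2FC) across
#' patients, with the p-value of the correlation test
#' (`t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df).
#'
#' @param rel a `relative_expr` object.
#' @param lncrna_id,pcg_id gene ids present in `rel`.
#' @param p_sided `"two"` (default) or `"one"` (upper tail).
#' @return A list with elements `cor` and `p_value`.
#' @export
global_correlation <- function(rel, lncrna_id, pcg_id,
                               p_sided = c("two", "one")) {
  stopifnot(inherits(rel, "relative_expr"))
  p_sided <- match.arg(p_sided)
  for (g in c(lncrna_id, pcg_id))
    if (!g %in% rel$gene_ids) stop("unknown gene id: ", g)
  el <- rel$e[lncrna_id, ]
  eg <- rel$e[pcg_id, ]
  if (length(el) < 3L) stop("global correlation requires n >= 3 patients")
  if (stats::sd(el) == 0 || stats::sd(eg) == 0)
    stop(structure(
      list(message = paste0(
        "zero variance for pair (", lncrna_id, ", ", pcg_id,
        "); correlation undefined, pair must be excluded"),
        call = sys.call(-1)),
      class = c("glocerna_zero_variance", "error", "condition")))
  ht <- stats::cor.test(el, eg,
                        alternative = if (p_sided == "two") "two.sided"
                                      else "greater")
  list(cor = unname(ht$estimate), p_value = ht$p.value)
}

#' Functional-ceRNA decision for one scored pair
#'
#' A pair is called a functional ceRNA relationship iff all three criteria
#' hold strictly: `dec_score > dec_cutoff`, `cor > cor_cutoff`, and
#' `p < p_cutoff`.
#'
#' @param dec_score integer DEC score.
#' @param cor Pearson correlation of relative expression.
#' @param p p-value of the correlation.
#' @param config a [glocerna_config()].
#' @return Logical.
#' @export
classify_pair <- function(dec_score, cor, p, config = glocerna_config()) {
  dec_score > config$dec_cutoff & cor > config$cor_cutoff & p < config$p_cutoff
}

# Row-wise Pearson correlation and p for aligned matrices (pairs x patients).
.rowwise_pearson <- function(A, B, p_sided = "two") {
  n <- ncol(A)
  Ac <- A - rowMeans(A)
  Bc <- B - rowMeans(B)
  sa <- sqrt(rowSums(Ac^2))
  sb <- sqrt(rowSums(Bc^2))
  r <- rowSums(Ac * Bc) / (sa * sb)
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 0))
  p <- if (p_sided == "two")
    2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  else stats::pt(tt, df = n - 2, lower.tail = FALSE)
  p[r == 1 & p_sided == "two"] <- 0
  p[abs(r) == 1] <- 0
  list(r = r, p = p, zero_var = sa == 0 | sb == 0)
}

#' Run the GloceRNA two-stage scorer over candidate pairs
#'
#' For every candidate lncRNA-PCG pair present in the matrix, computes the
#' DEC score (local criterion) and the Pearson correlation of relative
#' expression with its p-value (global criterion), then applies the
#' functional decision rule. Pairs with a gene absent from the matrix are
#' skipped and counted; pairs in which either gene has zero log2FC variance
#' have an undefined correlation and are excluded and counted (never scored
#' as `cor = 0`).
#'
#' @param x a [matched_expr] object (`n >= 3` patients).
#' @param pairs a `candidate_pairs` data.frame.
#' @param config a [glocerna_config()].
#' @return A data.frame of class `cerna_results` with columns `lncrna_id`,
#'   `pcg_id`, `shared_mirna_count`, `dec_score`, `cor`, `p_value`,
#'   `functional`, ordered by (lncrna_id, pcg_id). Attributes: `n_patients`,
#'   `n_tested`, `n_skipped`, `n_excluded_zero_variance`, `config`.
#' @export
run_glocerna <- function(x, pairs, config = glocerna_config()) {
  stopifnot(inherits(x, "matched_expr"))
  n <- length(x$patient_ids)
  if (n < 3L) stop("cohort-size error: GloceRNA requires n >= 3 matched samples")
  rel <- relative_expression(x, config$pseudocount)

  present <- pairs$lncrna_id %in% x$gene_ids & pairs$pcg_id %in% x$gene_ids
  n_skipped <- sum(!present)
  pr <- pairs[present, , drop = FALSE]

  if (!nrow(pr)) {
    out <- data.frame(lncrna_id = character(), pcg_id = character(),
                      shared_mirna_count = integer(), dec_score = integer(),
                      cor = numeric(), p_value = numeric(),
                      functional = logical(), stringsAsFactors = FALSE)
  } else {
    A <- rel$e[pr$lncrna_id, , drop = FALSE]
    B <- rel$e[pr$pcg_id, , drop = FALSE]
    th <- config$fc_threshold
    dec <- rowSums(A > th & B > th) + rowSums(A < -th & B < -th)
    pc <- .rowwise_pearson(A, B, config$p_sided)
    keep <- !pc$zero_var
    out <- data.frame(
      lncrna_id = pr$lncrna_id, pcg_id = pr$pcg_id,
      shared_mirna_count = if ("shared_mirna_count" %in% names(pr))
        pr$shared_mirna_count else NA_integer_,
      dec_score = as.integer(dec), cor = pc$r, p_value = pc$p,
      stringsAsFactors = FALSE)[keep, , drop = FALSE]
    p_class <- if (config$fdr)
      stats::p.adjust(out$p_value, method = "BH") else out$p_value
    out$functional <- classify_pair(out$dec_score, out$cor, p_class, config)
  }
  n_excluded <- nrow(pr) - nrow(out)
  out <- out[order(out$lncrna_id, out$pcg_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_patients") <- n
  attr(out, "n_tested") <- nrow(out)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_excluded_zero_variance") <- n_excluded
  attr(out, "config") <- config
  class(out) <- c("cerna_results", "data.frame")
  out
}

#' @export
print.cerna_results <- function(x, n = 6L, ...) {
  cat("GloceRNA results:", nrow(x), "pairs scored over",
      attr(x, "n_patients"), "patients;",
      sum(x$functional), "functional;",
      attr(x, "n_skipped"), "skipped;",
      attr(x, "n_excluded_zero_variance"), "excluded (zero variance)\n")
  if (nrow(x)) {
    print.data.frame(utils::head(x, n))
    if (nrow(x) > n) cat("... and", nrow(x) - n, "more rows\n")
  }
  invisible(x)
}

#' Traditional three-criterion ceRNA identification (baseline)
#'
#' Implements the conventional scheme against which the two-stage scorer is
#' compared. A pair passes iff:
#' (i) co-expression: Pearson correlation of relative expression `> 0` with
#' Benjamini-Hochberg FDR `< cor_fdr` across tested pairs;
#' (ii) differential expression: both genes differentially expressed by a
#' paired two-sided t-test on matched (tumor, normal) log2 expression —
#' equivalently a one-sample t-test on per-patient log2 fold changes — with
#' BH FDR `< de_fdr` across genes (a documented stand-in for SAM/Limma);
#' (iii) miRNA sharing: if `use_hyper`, the shared-miRNA hypergeometric test
#' must reach BH FDR `< hyper_fdr`; otherwise sharing at least one miRNA
#' (already implied by candidacy) suffices.
#'
#' @param x a [matched_expr] object.
#' @param pairs a `candidate_pairs` data.frame.
#' @param de_fdr FDR threshold for differential expression (0.01 or 0.05).
#' @param use_hyper logical; apply the shared-miRNA significance criterion.
#' @param interactions the `interaction_set` (required when `use_hyper`).
#' @param universe_size optional universe for the sharing test.
#' @param cor_fdr FDR threshold for the correlation criterion (default 0.05).
#' @param hyper_fdr FDR threshold for the sharing criterion (default 0.05).
#' @param use_absolute correlate absolute tumor expression rather than
#'   relative (log2FC) expression (default `FALSE`).
#' @param pseudocount shift before log2 (default 0).
#' @return A data.frame of class `cerna_results` (columns as
#'   [run_glocerna()] minus `dec_score`, plus the per-criterion q-values).
#' @export
baseline_identify <- function(x, pairs, de_fdr = 0.05, use_hyper = FALSE,
                              interactions = NULL, universe_size = NULL,
                              cor_fdr = 0.05, hyper_fdr = 0.05,
                              use_absolute = FALSE, pseudocount = 0) {
  stopifnot(inherits(x, "matched_expr"))
  if (length(x$patient_ids) < 3L)
    stop("cohort-size error: requires n >= 3 matched samples")
  rel <- relative_expression(x, pseudocount)
  n <- length(x$patient_ids)

  # per-gene paired t-test: one-sample t on the log2FC rows
  fc <- rel$e
  mu <- rowMeans(fc)
  s <- apply(fc, 1L, stats::sd)
  tstat <- ifelse(s > 0, mu / (s / sqrt(n)), 0)
  de_p <- 2 * stats::pt(abs(tstat), df = n - 1, lower.tail = FALSE)
  de_q <- stats::p.adjust(de_p, method = "BH")
  names(de_q) <- rownames(fc)

  present <- pairs$lncrna_id %in% x$gene_ids & pairs$pcg_id %in% x$gene_ids
  n_skipped <- sum(!present)
  pr <- pairs[present, , drop = FALSE]
  if (!nrow(pr)) {
    out <- data.frame(lncrna_id = character(), pcg_id = character(),
                      shared_mirna_count = integer(), cor = numeric(),
                      p_value = numeric(), cor_q = numeric(),
                      de_q_lncrna = numeric(), de_q_pcg = numeric(),
                      hyper_q = numeric(), functional = logical(),
                      stringsAsFactors = FALSE)
    n_excluded <- 0L
  } else {
    E <- if (use_absolute) log2(x$tumor + pseudocount) else rel$e
    A <- E[pr$lncrna_id, , drop = FALSE]
    B <- E[pr$pcg_id, , drop = FALSE]
    pc <- .rowwise_pearson(A, B, "two")
    keep <- !pc$zero_var
    out <- data.frame(
      lncrna_id = pr$lncrna_id, pcg_id = pr$pcg_id,
      shared_mirna_count = pr$shared_mirna_count,
      cor = pc$r, p_value = pc$p, stringsAsFactors = FALSE)[keep, , drop = FALSE]
    out$cor_q <- stats::p.adjust(out$p_value, method = "BH")
    out$de_q_lncrna <- unname(de_q[out$lncrna_id])
    out$de_q_pcg <- unname(de_q[out$pcg_id])
    if (use_hyper) {
      if (is.null(interactions))
        stop("use_hyper requires the interaction set")
      ht <- shared_mirna_test(pr[keep, , drop = FALSE], interactions,
                              universe_size)
      out$hyper_q <- ht$q_value
    } else out$hyper_q <- rep(NA_real_, nrow(out))
    pass <- out$cor > 0 & out$cor_q < cor_fdr &
      out$de_q_lncrna < de_fdr & out$de_q_pcg < de_fdr
    if (use_hyper) pass <- pass & out$hyper_q < hyper_fdr
    out$functional <- pass
    n_excluded <- nrow(pr) - nrow(out)
  }
  out <- out[order(out$lncrna_id, out$pcg_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_patients") <- n
  attr(out, "n_tested") <- nrow(out)
  attr(out, "n_skipped") <- n_skipped
  attr(out, "n_excluded_zero_variance") <- n_excluded
  class(out) <- c("cerna_results", "data.frame")
  out
}
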