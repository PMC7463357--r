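# Synthetic-data generators: a matched N/T cohort with planted ceRNA pairs
# and shared-miRNA structure, expression-linked survival, a toy genome with
# planted SE/TE regions, and a THZ1 treatment time course. Every generator
# is deterministic under the config seed, so the whole pipeline is testable
# offline with known ground truth.

#' Configuration of the synthetic cohort generator
#'
#' Each planted ("true") ceRNA pair receives, per patient `i`, a shared
#' latent log2 fold change `z_i ~ Normal(s_i * effect_mean, effect_sd)`;
#' both genes of the pair observe `z_i` plus independent
#' `Normal(0, noise_sd)` noise, while null genes draw their log2FC from
#' `Normal(0, null_fc_sd)`. With `sign_mode = "patient"` (default) the
#' direction `s_i` is drawn independently per patient — the
#' cancer-heterogeneity regime the per-sample consistency score is designed
#' for, in which a pair is jointly up in some patients and jointly down in
#' others. With `sign_mode = "pair"` the direction is fixed per pair (half
#' up, half down across pairs), i.e. a homogeneous-dysregulation regime.
#' Decoy pairs share miRNAs by construction but have independent (null)
#' expression, isolating the expression criteria from the pairing
#' criterion.
#'
#' @param n_patients matched N/T patients (default 20).
#' @param n_lncrnas,n_pcgs,n_mirnas gene and miRNA pool sizes (defaults
#'   120, 400, 1000).
#' @param n_true_pairs planted ceRNA pairs (default 100), each using
#'   distinct genes.
#' @param n_decoy_pairs miRNA-sharing pairs with null expression (default
#'   900), drawn from genes outside the true pairs.
#' @param effect_mean latent effect magnitude, log2 units (default 2).
#' @param effect_sd patient-to-patient sd of the latent effect (default
#'   0.5).
#' @param noise_sd per-gene noise sd around the latent effect (default
#'   0.5).
#' @param null_fc_sd log2FC sd of null genes (default 0.5).
#' @param baseline_log_mean,baseline_log_sd log2-scale mean and sd of
#'   normal-tissue expression (defaults 5, 1; microarray-like intensities).
#' @param sign_mode `"patient"` or `"pair"` (see above).
#' @param hazard_beta log-hazard per sd of the survival-linked gene's tumor
#'   expression (default 1.5); 0 gives a null survival cohort.
#' @param base_time baseline mean survival time in days (default 1000).
#' @param censor_rate expected fraction of independently censored patients
#'   (default 0.2, in [0, 1)).
#' @param n_sensitive planted THZ1-sensitive lncRNAs (default 5).
#' @param n_se_lncrnas,n_te_lncrnas lncRNAs receiving planted SE / TE
#'   regions (defaults 5, 5).
#' @param seed integer RNG seed.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_patients = 20L, n_lncrnas = 120L,
                             n_pcgs = 400L, n_mirnas = 1000L,
                             n_true_pairs = 100L, n_decoy_pairs = 900L,
                             effect_mean = 2, effect_sd = 0.5,
                             noise_sd = 0.5, null_fc_sd = 0.5,
                             baseline_log_mean = 5, baseline_log_sd = 1,
                             sign_mode = c("patient", "pair"),
                             hazard_beta = 1.5, base_time = 1000,
                             censor_rate = 0.2, n_sensitive = 5L,
                             n_se_lncrnas = 5L, n_te_lncrnas = 5L,
                             seed = 1L) {
  sign_mode <- match.arg(sign_mode)
  cfg <- list(n_patients = as.integer(n_patients),
              n_lncrnas = as.integer(n_lncrnas),
              n_pcgs = as.integer(n_pcgs),
              n_mirnas = as.integer(n_mirnas),
              n_true_pairs = as.integer(n_true_pairs),
              n_decoy_pairs = as.integer(n_decoy_pairs),
              effect_mean = effect_mean, effect_sd = effect_sd,
              noise_sd = noise_sd, null_fc_sd = null_fc_sd,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd, sign_mode = sign_mode,
              hazard_beta = hazard_beta, base_time = base_time,
              censor_rate = censor_rate,
              n_sensitive = as.integer(n_sensitive),
              n_se_lncrnas = as.integer(n_se_lncrnas),
              n_te_lncrnas = as.integer(n_te_lncrnas),
              seed = as.integer(seed))
  with(cfg, {
    if (min(n_patients, n_lncrnas, n_pcgs, n_mirnas, n_true_pairs) < 1L)
      stop("config error: all counts must be >= 1")
    if (min(effect_sd, noise_sd, null_fc_sd, baseline_log_sd) <= 0)
      stop("config error: standard deviations must be > 0")
    if (censor_rate < 0 || censor_rate >= 1)
      stop("config error: censor_rate must be in [0, 1)")
    if (n_true_pairs > min(n_lncrnas, n_pcgs))
      stop("config error: true pairs need distinct genes; ",
           "n_true_pairs exceeds the gene pools")
    if (n_decoy_pairs >
        (n_lncrnas - n_true_pairs) * (n_pcgs - n_true_pairs))
      stop("config error: not enough null genes for the decoy pairs")
    if (n_mirnas < n_true_pairs + n_decoy_pairs)
      stop("config error: need one miRNA per planted pair; ",
           "increase n_mirnas")
  })
  structure(cfg, class = "synthetic_config")
}

.syn_structure <- function(config) {
  lnc <- sprintf("LNC%04d", seq_len(config$n_lncrnas))
  pcg <- sprintf("PCG%04d", seq_len(config$n_pcgs))
  mir <- sprintf("MIR%04d", seq_len(config$n_mirnas))
  true_lnc <- sample(lnc, config$n_true_pairs)
  true_pcg <- sample(pcg, config$n_true_pairs)
  null_lnc <- setdiff(lnc, true_lnc)
  null_pcg <- setdiff(pcg, true_pcg)
  grid <- sample.int(length(null_lnc) * length(null_pcg),
                     config$n_decoy_pairs)
  decoy_lnc <- null_lnc[(grid - 1L) %% length(null_lnc) + 1L]
  decoy_pcg <- null_pcg[(grid - 1L) %/% length(null_lnc) + 1L]
  pair_sign <- rep_len(c(1L, -1L), config$n_true_pairs)

  all_l <- c(true_lnc, decoy_lnc)
  all_p <- c(true_pcg, decoy_pcg)
  pair_mir <- mir[seq_along(all_l)]
  interactions <- interaction_set(data.frame(
    mirna_id = rep(pair_mir, 2L),
    target_id = c(all_l, all_p),
    target_class = rep(c("lncRNA", "PCG"), each = length(all_l)),
    stringsAsFactors = FALSE))

  sensitive <- sample(true_lnc, min(config$n_sensitive, length(true_lnc)))
  se_lnc <- sample(true_lnc, min(config$n_se_lncrnas, length(true_lnc)))
  te_pool <- setdiff(lnc, se_lnc)
  te_lnc <- sample(te_pool, min(config$n_te_lncrnas, length(te_pool)))

  structure(list(
    lncrna_ids = lnc, pcg_ids = pcg, mirna_ids = mir,
    true_pairs = data.frame(lncrna_id = true_lnc, pcg_id = true_pcg,
                            sign = pair_sign, effect = config$effect_mean,
                            stringsAsFactors = FALSE),
    decoy_pairs = data.frame(lncrna_id = decoy_lnc, pcg_id = decoy_pcg,
                             stringsAsFactors = FALSE),
    interactions = interactions,
    survival_gene = true_lnc[1L],
    sensitive_genes = sensitive,
    se_lncrnas = se_lnc, te_lncrnas = te_lnc),
    class = "synthetic_truth")
}

#' Generate a matched N/T cohort with planted ceRNA pairs
#'
#' Draws normal expression from a log-normal baseline, plants the latent
#' shared log2FC signal of the true pairs (see [synthetic_config()]),
#' assigns null log2FC to every other gene, and sets
#' `tumor = normal * 2^log2FC`. Interactions are built so that every true
#' pair and every decoy pair shares exactly one dedicated miRNA, making the
#' candidate-pair set equal to the planted pairs. Fully deterministic under
#' `config$seed`; supplying a previously generated `truth` reuses the pair
#' and interaction structure and redraws only the expression — two cohorts
#' from the same truth emulate independent datasets of the same biology.
#'
#' @param config a [synthetic_config()].
#' @param truth optional `synthetic_truth` from a previous call.
#' @return A list with elements `matrix` (a [matched_expr]),
#'   `interactions` (an `interaction_set`) and `truth` (a
#'   `synthetic_truth`: planted pairs with effect sizes, the
#'   survival-linked gene, THZ1-sensitive and SE/TE-planted gene sets).
#' @export
generate_cohort <- function(config, truth = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  if (is.null(truth)) truth <- .syn_structure(config)

  gene_ids <- c(truth$lncrna_ids, truth$pcg_ids)
  gene_class <- stats::setNames(
    rep(c("lncRNA", "PCG"),
        c(length(truth$lncrna_ids), length(truth$pcg_ids))), gene_ids)
  m <- length(gene_ids)
  n <- config$n_patients
  patients <- sprintf("P%03d", seq_len(n))

  normal <- matrix(2^stats::rnorm(m * n, config$baseline_log_mean,
                                  config$baseline_log_sd),
                   m, n, dimnames = list(gene_ids, patients))
  fc <- matrix(stats::rnorm(m * n, 0, config$null_fc_sd),
               m, n, dimnames = list(gene_ids, patients))
  for (j in seq_len(nrow(truth$true_pairs))) {
    s <- if (config$sign_mode == "patient")
      sample(c(-1L, 1L), n, replace = TRUE)
    else rep(truth$true_pairs$sign[j], n)
    z <- stats::rnorm(n, s * config$effect_mean, config$effect_sd)
    fc[truth$true_pairs$lncrna_id[j], ] <-
      z + stats::rnorm(n, 0, config$noise_sd)
    fc[truth$true_pairs$pcg_id[j], ] <-
      z + stats::rnorm(n, 0, config$noise_sd)
  }
  tumor <- normal * 2^fc
  list(matrix = matched_expr(normal, tumor, gene_class),
       interactions = truth$interactions, truth = truth)
}

#' Generate clinical survival data linked to one gene's tumor expression
#'
#' Event times are exponential with per-patient log-hazard
#' `hazard_beta * z`, where `z` is the standardized log2 tumor expression of
#' the truth's survival-linked gene, scaled so the baseline mean survival is
#' `base_time` days. Censoring is independent: each patient draws a
#' censoring time with rate chosen so the expected censored fraction equals
#' `censor_rate`.
#'
#' @param config a [synthetic_config()].
#' @param x the cohort's [matched_expr] matrix.
#' @param truth the cohort's `synthetic_truth`.
#' @return A `clinical_table` (`patient_id`, `time`, `event`).
#' @export
generate_clinical <- function(config, x, truth) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(x, "matched_expr"))
  set.seed(config$seed + 1L)
  v <- log2(x$tumor[truth$survival_gene, ] + 1)
  z <- if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  rate <- exp(config$hazard_beta * z) / config$base_time
  n <- length(rate)
  t_event <- stats::rexp(n, rate)
  if (config$censor_rate > 0) {
    c_rate <- rate * config$censor_rate / (1 - config$censor_rate)
    t_cens <- stats::rexp(n, c_rate)
    event <- as.integer(t_event <= t_cens)
    time <- pmin(t_event, t_cens)
  } else {
    event <- rep(1L, n)
    time <- t_event
  }
  clinical_table(data.frame(patient_id = x$patient_ids,
                            time = pmax(time, 1e-6), event = event,
                            stringsAsFactors = FALSE))
}

#' Generate gene coordinates on a two-chromosome toy genome
#'
#' Genes are laid out as non-overlapping 5 kb bodies spaced 10 kb apart,
#' alternating between two chromosomes, with random strand (0-based
#' half-open).
#'
#' @param config a [synthetic_config()].
#' @param gene_ids gene ids to place.
#' @return A `gene_coords` table.
#' @export
generate_gene_coords <- function(config, gene_ids) {
  set.seed(config$seed + 2L)
  k <- seq_along(gene_ids)
  chrom <- ifelse(k %% 2L == 1L, "chr1", "chr2")
  pos <- stats::ave(k, chrom, FUN = seq_along)
  start <- pos * 10000L
  gene_coords(data.frame(
    gene_id = gene_ids, chrom = chrom, start = start, end = start + 5000L,
    strand = sample(c("+", "-"), length(k), replace = TRUE),
    stringsAsFactors = FALSE))
}

#' Generate SE/TE regions overlapping planted lncRNA loci
#'
#' Each SE-planted lncRNA receives a super-enhancer region inside its gene
#' body in every cell line; TE-planted lncRNAs receive typical-enhancer
#' regions the same way.
#'
#' @param config a [synthetic_config()].
#' @param coords a `gene_coords` table containing the planted genes.
#' @param truth the cohort's `synthetic_truth`.
#' @param cell_lines cell line names (default `c("cellA", "cellB")`).
#' @return An `enhancer_regions` table.
#' @export
generate_regions <- function(config, coords, truth,
                             cell_lines = c("cellA", "cellB")) {
  set.seed(config$seed + 3L)
  plant <- function(ids, cls) {
    sel <- coords[match(ids, coords$gene_id), , drop = FALSE]
    sel <- sel[!is.na(sel$gene_id), , drop = FALSE]
    do.call(rbind, lapply(cell_lines, function(cl)
      data.frame(chrom = sel$chrom, start = sel$start + 1000L,
                 end = sel$start + 3000L, enhancer_class = cls,
                 cell_line = cl, stringsAsFactors = FALSE)))
  }
  enhancer_regions(rbind(plant(truth$se_lncrnas, "SE"),
                         plant(truth$te_lncrnas, "TE")))
}

#' Generate a THZ1/DMSO treatment time course
#'
#' Every gene receives DMSO and THZ1 values at 2, 4, 6, 8 and 12 h.
#' Planted sensitive genes have their 12 h THZ1 value set to
#' `DMSO / sensitive_fold` (default 2, beyond the 1.5-fold sensitivity
#' cutoff); all other genes keep a fold change of ~1. The first
#' `n_inactive` non-sensitive genes are planted inactive (DMSO below the
#' FPKM activity filter).
#'
#' @param config a [synthetic_config()].
#' @param truth the cohort's `synthetic_truth`.
#' @param gene_ids genes to include (default: the truth's lncRNAs).
#' @param sensitive_fold planted fold change of sensitive genes (default
#'   2).
#' @param n_inactive planted inactive genes (default 2).
#' @return A data.frame (`gene_id`, `treatment`, `timepoint`, `value`)
#'   with attribute `inactive_genes`.
#' @export
generate_timecourse <- function(config, truth, gene_ids = NULL,
                                sensitive_fold = 2, n_inactive = 2L) {
  set.seed(config$seed + 4L)
  if (is.null(gene_ids)) gene_ids <- truth$lncrna_ids
  timepoints <- c(2, 4, 6, 8, 12)
  base <- stats::runif(length(gene_ids), 5, 50)
  names(base) <- gene_ids
  inactive <- head(setdiff(gene_ids, truth$sensitive_genes), n_inactive)
  base[inactive] <- 0.5
  rows <- list()
  for (tp in timepoints) {
    thz1 <- base
    if (tp == 12) {
      sens <- intersect(truth$sensitive_genes, gene_ids)
      thz1[sens] <- base[sens] / sensitive_fold
    } else {
      thz1 <- base * stats::runif(length(base), 0.95, 1.05)
    }
    rows[[as.character(tp)]] <- data.frame(
      gene_id = rep(gene_ids, 2L),
      treatment = rep(c("DMSO", "THZ1"), each = length(gene_ids)),
      timepoint = tp, value = c(unname(base), unname(thz1)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "inactive_genes") <- inactive
  out
}

#' Generate a hallmark-style gene-set collection with one planted set
#'
#' Builds `n_sets` gene sets over the PCG pool; the first set is drawn from
#' the true pairs' PCGs (and is therefore enriched among ceRNA-network
#' PCGs), the rest are random background sets. Also returns a set-to-
#' hallmark map.
#'
#' @param config a [synthetic_config()].
#' @param truth the cohort's `synthetic_truth`.
#' @param n_sets number of sets (default 5).
#' @param set_size members per set (default 40).
#' @return A list with `collection` (a `gene_set_collection`) and `map`
#'   (data.frame `set_id`, `hallmark`).
#' @export
generate_gene_sets <- function(config, truth, n_sets = 5L, set_size = 40L) {
  set.seed(config$seed + 5L)
  hallmarks <- c("Sustaining proliferative signaling",
                 "Evading growth suppressors", "Resisting cell death",
                 "Genome instability", "Activating invasion",
                 "Angiogenesis", "Enabling replicative immortality",
                 "Tumor-promoting inflammation",
                 "Avoiding immune destruction",
                 "Disrupting cellular energetics")
  pool <- truth$pcg_ids
  true_pcgs <- truth$true_pairs$pcg_id
  sets <- list()
  sets[["GO:SYN0001"]] <- sample(true_pcgs, min(set_size, length(true_pcgs)))
  for (i in seq_len(n_sets - 1L) + 1L)
    sets[[sprintf("GO:SYN%04d", i)]] <- sample(pool, min(set_size,
                                                         length(pool)))
  labels <- stats::setNames(
    rep_len(hallmarks, length(sets)), names(sets))
  list(collection = gene_set_collection(sets, labels),
       map = data.frame(set_id = names(sets), hallmark = unname(labels),
                        stringsAsFactors = FALSE))
}
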