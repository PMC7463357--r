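# Assignment of SE/TE regions to genes (overlap / proximal / closest),
# SE/TE labelling of ce-lncRNAs, and THZ1-sensitivity classification with
# its ceRNA subnetwork.

.rule_rank <- c(overlap = 1L, proximal = 2L, closest = 3L)

#' Assign enhancer regions to genes
#'
#' Per region and cell line, three rules are applied against the gene
#' coordinate table:
#' * `overlap`: every gene whose body overlaps the region (distance 0);
#' * `proximal`: every gene whose TSS lies within `proximal_window` bp of
#'   the region centre;
#' * `closest`: the single gene with minimal TSS-to-centre distance (ties
#'   broken by smaller distance, then lexicographic gene id).
#' The union is emitted, deduplicated per (gene, cell line, enhancer class)
#' keeping the strongest rule (`overlap` > `proximal` > `closest`). Regions
#' on chromosomes absent from the coordinate table are skipped with a
#' warning. Coordinates are 0-based half-open; the TSS is strand-aware.
#'
#' @param regions an `enhancer_regions` data.frame (see [read_regions()]).
#' @param coords a `gene_coords` data.frame (see [read_gene_coords()]).
#' @param proximal_window TSS-to-centre window in bp (default 50000).
#' @return A data.frame with columns `gene_id`, `cell_line`,
#'   `enhancer_class`, `rule`, `distance`.
#' @export
assign_enhancers <- function(regions, coords, proximal_window = 50000) {
  stopifnot(inherits(regions, "enhancer_regions"),
            inherits(coords, "gene_coords"))
  bad_chrom <- setdiff(unique(regions$chrom), unique(coords$chrom))
  if (length(bad_chrom)) {
    warning("skipping region(s) on chromosome(s) without genes: ",
            paste(bad_chrom, collapse = ", "))
    regions <- regions[!regions$chrom %in% bad_chrom, , drop = FALSE]
  }
  if (!nrow(regions))
    return(data.frame(gene_id = character(), cell_line = character(),
                      enhancer_class = character(), rule = character(),
                      distance = numeric(), stringsAsFactors = FALSE))

  # 0-based half-open -> 1-based closed for IRanges
  gene_gr <- GenomicRanges::GRanges(
    coords$chrom, IRanges::IRanges(coords$start + 1L, coords$end))
  reg_gr <- GenomicRanges::GRanges(
    regions$chrom, IRanges::IRanges(regions$start + 1L, regions$end))
  hits <- GenomicRanges::findOverlaps(reg_gr, gene_gr)
  centre <- (regions$start + regions$end) / 2

  rows <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    on_chrom <- which(coords$chrom == regions$chrom[i])
    dist <- abs(coords$tss[on_chrom] - centre[i])
    ov <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    prox <- on_chrom[dist <= proximal_window]
    ord <- order(dist, coords$gene_id[on_chrom])
    closest <- on_chrom[ord[1L]]
    dist_of <- function(j) abs(coords$tss[j] - centre[i])
    rows[[i]] <- data.frame(
      gene_id = coords$gene_id[c(ov, prox, closest)],
      cell_line = regions$cell_line[i],
      enhancer_class = regions$enhancer_class[i],
      rule = rep(c("overlap", "proximal", "closest"),
                 c(length(ov), length(prox), 1L)),
      distance = c(rep(0, length(ov)), dist_of(prox), dist_of(closest)),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(.rule_rank[out$rule], out$distance), , drop = FALSE]
  key <- paste(out$gene_id, out$cell_line, out$enhancer_class, sep = "\r")
  out <- out[!duplicated(key), , drop = FALSE]
  out <- out[order(out$gene_id, out$cell_line, out$enhancer_class), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Label ce-lncRNAs as SE-, TE-associated or neither
#'
#' Union rule across cell lines: a lncRNA is `SE` if it is SE-assigned in
#' any cell line; otherwise `TE` if TE-assigned in any cell line; otherwise
#' `none`.
#'
#' @param assignments output of [assign_enhancers()] (one or more cell
#'   lines).
#' @param ce_lncrnas character vector of ce-lncRNA ids to label.
#' @return A data.frame with columns `lncrna_id`, `label`
#'   (`SE`/`TE`/`none`); attribute `detail` holds the per-cell-line
#'   assignments restricted to the labelled lncRNAs.
#' @export
label_se_te_lncrnas <- function(assignments, ce_lncrnas) {
  se <- unique(assignments$gene_id[assignments$enhancer_class == "SE"])
  te <- unique(assignments$gene_id[assignments$enhancer_class == "TE"])
  label <- ifelse(ce_lncrnas %in% se, "SE",
                  ifelse(ce_lncrnas %in% te, "TE", "none"))
  out <- data.frame(lncrna_id = ce_lncrnas, label = label,
                    stringsAsFactors = FALSE)
  attr(out, "detail") <- assignments[
    assignments$gene_id %in% ce_lncrnas, , drop = FALSE]
  out
}

#' Classify THZ1-sensitive genes from a treatment time course
#'
#' Genes whose DMSO-control expression at the evaluation timepoint is at or
#' below `active_min` (FPKM-like units) are excluded as inactive. For the
#' remaining genes the fold change `(DMSO + eps) / (THZ1 + eps)` is
#' computed; a gene is sensitive iff its expression decreased more than
#' `fold_cutoff`-fold under THZ1 (strict). Genes lacking either condition at
#' the timepoint are skipped with a message.
#'
#' @param timecourse data.frame with columns `gene_id`, `treatment`
#'   (`DMSO`/`THZ1`), `timepoint` (hours), `value` (>= 0).
#' @param genes gene ids to classify (default: all genes in the table).
#' @param fold_cutoff sensitivity fold-change cutoff (default 1.5).
#' @param timepoint evaluation timepoint in hours (default 12).
#' @param active_min minimum DMSO expression for a gene to count as active
#'   (default 1).
#' @param eps pseudocount guarding zero THZ1 values (default 0.01).
#' @return A data.frame with columns `gene_id`, `dmso`, `thz1`,
#'   `fold_change`, `sensitive`; attributes `n_skipped` and
#'   `excluded_inactive` (gene ids failing the activity filter).
#' @export
thz1_sensitive <- function(timecourse, genes = NULL, fold_cutoff = 1.5,
                           timepoint = 12, active_min = 1, eps = 0.01) {
  tc <- timecourse[timecourse$timepoint == timepoint, , drop = FALSE]
  if (is.null(genes)) genes <- unique(timecourse$gene_id)
  dmso <- tc[tc$treatment == "DMSO", ]
  thz1 <- tc[tc$treatment == "THZ1", ]
  d <- stats::setNames(dmso$value, dmso$gene_id)[genes]
  t1 <- stats::setNames(thz1$value, thz1$gene_id)[genes]
  have <- !is.na(d) & !is.na(t1)
  n_skipped <- sum(!have)
  if (n_skipped)
    message("thz1_sensitive: ", n_skipped,
            " gene(s) missing a condition at ", timepoint, " h, skipped")
  genes <- genes[have]; d <- d[have]; t1 <- t1[have]
  inactive <- d <= active_min
  excluded <- genes[inactive]
  genes <- genes[!inactive]; d <- d[!inactive]; t1 <- t1[!inactive]
  fc <- (d + eps) / (t1 + eps)
  out <- data.frame(gene_id = genes, dmso = unname(d), thz1 = unname(t1),
                    fold_change = unname(fc),
                    sensitive = unname(fc > fold_cutoff),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  attr(out, "excluded_inactive") <- excluded
  out
}

#' Build the THZ1-sensitive ceRNA subnetwork
#'
#' Seed lncRNAs are the THZ1-sensitive genes of the supplied per-cell-line
#' sensitivity tables — intersected across cell lines when `require_shared`
#' (the shared-sensitivity rule), or their union otherwise — optionally
#' restricted to SE/TE-labelled ce-lncRNAs. The subnetwork is the
#' first-neighbour extraction of those seeds from the ceRNA network.
#'
#' @param sensitivity a data.frame from [thz1_sensitive()] or a (named)
#'   list of such data.frames, one per cell line.
#' @param net a `cerna_network`.
#' @param labels optional output of [label_se_te_lncrnas()]; when supplied,
#'   only seeds labelled `SE` or `TE` are kept.
#' @param require_shared require sensitivity in every cell line
#'   (default `TRUE`).
#' @return A `cerna_network` (see [extract_subnetwork()]).
#' @export
thz1_network <- function(sensitivity, net, labels = NULL,
                         require_shared = TRUE) {
  if (is.data.frame(sensitivity)) sensitivity <- list(sensitivity)
  sets <- lapply(sensitivity, function(s) s$gene_id[s$sensitive])
  seeds <- if (require_shared) Reduce(intersect, sets)
           else unique(unlist(sets))
  if (!is.null(labels))
    seeds <- intersect(seeds,
                       labels$lncrna_id[labels$label %in% c("SE", "TE")])
  extract_subnetwork(net, seeds)
}
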