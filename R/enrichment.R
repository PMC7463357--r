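# Hypergeometric gene-set enrichment of ceRNA-network PCGs against
# cancer-hallmark GO-term proxies, network-wide and per ce-lncRNA.

#' Hypergeometric enrichment of a query gene set against one gene set
#'
#' Query and set are intersected with the universe before testing. With
#' overlap `k`, set size `K`, query size `nq` and universe size `N`, the
#' enrichment p-value is the upper tail `P(X >= k)` under
#' Hypergeometric(N, K, nq).
#'
#' @param query_genes character vector of query gene ids.
#' @param gene_set character vector of set members.
#' @param universe character vector of background gene ids (non-empty).
#' @return A one-row data.frame with columns `k`, `K`, `nq`, `N`, `p_value`.
#' @export
enrich <- function(query_genes, gene_set, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("enrichment universe must be non-empty")
  q <- intersect(unique(query_genes), universe)
  s <- intersect(unique(gene_set), universe)
  k <- length(intersect(q, s))
  data.frame(k = k, K = length(s), nq = length(q), N = length(universe),
             p_value = stats::phyper(k - 1L, length(s),
                                     length(universe) - length(s),
                                     length(q), lower.tail = FALSE))
}

#' Network-wide cancer-hallmark enrichment
#'
#' The query is the union of all PCGs adjacent to any ce-lncRNA in the
#' network (i.e. all PCG nodes). Each set of the collection is tested with
#' [enrich()]; raw `p < p_cutoff` defines significance (Benjamini-Hochberg
#' q-values are also reported). When `hallmark_map` is supplied, a hallmark
#' is called enriched if any of its member GO-term sets is significant.
#'
#' @param network a `cerna_network`.
#' @param collection a `gene_set_collection`.
#' @param universe background gene ids (typically all PCGs appearing in
#'   candidate pairs).
#' @param hallmark_map optional data.frame with columns `set_id`,
#'   `hallmark`.
#' @param p_cutoff significance threshold on raw p (default 0.05).
#' @return A data.frame with one row per set (`set_id`, `label`, `k`, `K`,
#'   `nq`, `N`, `p_value`, `q_value`, `significant`). When `hallmark_map`
#'   is given, attribute `hallmarks` holds a data.frame (`hallmark`,
#'   `n_sets`, `n_significant`, `enriched`).
#' @export
hallmark_enrichment <- function(network, collection, universe,
                                hallmark_map = NULL, p_cutoff = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- network$nodes$node_id[network$nodes$node_type == "PCG"]
  rows <- lapply(names(collection$sets), function(id)
    cbind(data.frame(set_id = id, stringsAsFactors = FALSE),
          enrich(query, collection$sets[[id]], universe)))
  out <- do.call(rbind, rows)
  out$label <- if (is.null(collection$labels)) out$set_id
               else unname(collection$labels[out$set_id])
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$p_value < p_cutoff
  out <- out[, c("set_id", "label", "k", "K", "nq", "N",
                 "p_value", "q_value", "significant")]
  if (!is.null(hallmark_map)) {
    m <- merge(hallmark_map, out[, c("set_id", "significant")],
               by = "set_id")
    agg <- stats::aggregate(significant ~ hallmark, data = m,
                            FUN = function(v) c(n = length(v), s = sum(v)))
    hm <- data.frame(hallmark = agg$hallmark,
                     n_sets = agg$significant[, "n"],
                     n_significant = agg$significant[, "s"],
                     stringsAsFactors = FALSE)
    hm$enriched <- hm$n_significant > 0L
    attr(out, "hallmarks") <- hm[order(hm$hallmark), ]
  }
  out
}

#' Per-lncRNA hallmark enrichment and enriched-term counts
#'
#' For each ce-lncRNA, the query is its own set of PCG neighbours; every set
#' of the collection is tested, enriched (lncRNA, set) pairs are those with
#' raw `p < p_cutoff` (q is BH-adjusted across sets within each lncRNA).
#' lncRNAs with no PCG neighbours contribute no rows. The per-lncRNA count
#' ranking is stable, with ties broken by lncRNA id.
#'
#' @inheritParams hallmark_enrichment
#' @return A list with `table` (data.frame `lncrna_id`, `set_id`, `k`,
#'   `p_value`, `q_value` for enriched pairs only) and `counts`
#'   (data.frame `lncrna_id`, `n_enriched`, ranked by decreasing count then
#'   id).
#' @export
per_lncrna_hallmarks <- function(network, collection, universe,
                                 p_cutoff = 0.05) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lnc <- network$nodes$node_id[network$nodes$node_type == "lncRNA"]
  nb <- split(network$edges$pcg_id,
              factor(network$edges$lncrna_id, levels = lnc))
  set_ids <- names(collection$sets)
  tabs <- list()
  for (l in lnc) {
    q <- nb[[l]]
    if (!length(q)) next
    res <- do.call(rbind, lapply(set_ids, function(id)
      cbind(data.frame(lncrna_id = l, set_id = id,
                       stringsAsFactors = FALSE),
            enrich(q, collection$sets[[id]], universe))))
    res$q_value <- stats::p.adjust(res$p_value, method = "BH")
    tabs[[l]] <- res[res$p_value < p_cutoff,
                     c("lncrna_id", "set_id", "k", "p_value", "q_value"),
                     drop = FALSE]
  }
  tab <- if (length(tabs)) do.call(rbind, tabs) else
    data.frame(lncrna_id = character(), set_id = character(),
               k = integer(), p_value = numeric(), q_value = numeric(),
               stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  counts <- data.frame(lncrna_id = lnc,
                       n_enriched = vapply(lnc, function(l)
                         sum(tab$lncrna_id == l), integer(1)),
                       stringsAsFactors = FALSE)
  counts <- counts[order(-counts$n_enriched, counts$lncrna_id), ,
                   drop = FALSE]
  rownames(counts) <- NULL
  list(table = tab, counts = counts)
}
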