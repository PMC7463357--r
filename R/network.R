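# Bipartite ceRNA network assembly, topology (degree, betweenness),
# pairwise lncRNA similarity, cross-cohort overlap, and subnetworks.

#' Construct a bipartite ceRNA network
#'
#' @param edges data.frame with columns `lncrna_id`, `pcg_id` (one row per
#'   functional pair); duplicates are collapsed.
#' @return An object of class `cerna_network`: a list with `nodes`
#'   (data.frame `node_id`, `node_type`) and `edges` (data.frame
#'   `lncrna_id`, `pcg_id`).
#' @export
cerna_network <- function(edges) {
  edges <- unique(edges[, c("lncrna_id", "pcg_id"), drop = FALSE])
  if (nrow(edges) && any(edges$lncrna_id == edges$pcg_id))
    stop("self-loop: a gene cannot be both sides of a ceRNA pair")
  if (length(intersect(edges$lncrna_id, edges$pcg_id)))
    stop("lncRNA and PCG id spaces must be disjoint")
  edges <- edges[order(edges$lncrna_id, edges$pcg_id), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- data.frame(
    node_id = c(sort(unique(edges$lncrna_id)), sort(unique(edges$pcg_id))),
    node_type = rep(c("lncRNA", "PCG"),
                    c(length(unique(edges$lncrna_id)),
                      length(unique(edges$pcg_id)))),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges), class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("ceRNA network:", sum(x$nodes$node_type == "lncRNA"), "lncRNAs,",
      sum(x$nodes$node_type == "PCG"), "PCGs,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Build the ceRNA network from scored results
#'
#' Keeps only the functional pairs of a `cerna_results` table.
#'
#' @param results a `cerna_results` data.frame (see [run_glocerna()]), or
#'   any data.frame with `lncrna_id`, `pcg_id` and logical `functional`.
#' @return A `cerna_network`.
#' @export
build_network <- function(results) {
  stopifnot(all(c("lncrna_id", "pcg_id", "functional") %in% names(results)))
  cerna_network(results[results$functional %in% TRUE, , drop = FALSE])
}

.as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("lncrna_id", "pcg_id")], directed = FALSE,
    vertices = net$nodes$node_id)
  g
}

#' Node degree of every network node
#'
#' @param net a `cerna_network`.
#' @return Named integer vector (degree per node, isolated nodes 0); the sum
#'   of degrees equals twice the edge count.
#' @export
node_degree <- function(net) {
  if (!nrow(net$nodes)) return(stats::setNames(integer(), character()))
  d <- igraph::degree(.as_igraph(net))
  stats::setNames(as.integer(d), names(d))
}

#' Unnormalized betweenness centrality of every network node
#'
#' Classical betweenness on the undirected, unweighted bipartite graph
#' including both node types: for node `v`, the sum over unordered pairs
#' `(s, t)` (both distinct from `v`) of the fraction of shortest `s`-`t`
#' paths passing through `v`. No normalization is applied.
#'
#' @param net a `cerna_network`.
#' @return Named numeric vector of betweenness values (>= 0).
#' @export
node_betweenness <- function(net) {
  if (!nrow(net$nodes)) return(stats::setNames(numeric(), character()))
  b <- igraph::betweenness(.as_igraph(net), directed = FALSE,
                           normalized = FALSE)
  stats::setNames(as.numeric(b), names(b))
}

#' Pairwise lncRNA similarity by shared PCG partners
#'
#' For every unordered pair of lncRNA nodes, the number of shared PCG
#' neighbours and the Jaccard index of the two neighbour sets (shared /
#' union; 0 when the union is empty).
#'
#' @param net a `cerna_network` with at least two lncRNA nodes.
#' @return A data.frame with columns `lncrna_a`, `lncrna_b`,
#'   `shared_pcg_count`, `jaccard`, sorted by ids (`lncrna_a < lncrna_b`).
#' @export
lncrna_similarity <- function(net) {
  lnc <- sort(net$nodes$node_id[net$nodes$node_type == "lncRNA"])
  if (length(lnc) < 2L)
    stop("lncRNA similarity requires at least two lncRNA nodes")
  nb <- split(net$edges$pcg_id, factor(net$edges$lncrna_id, levels = lnc))
  idx <- utils::combn(length(lnc), 2L)
  shared <- integer(ncol(idx)); jac <- numeric(ncol(idx))
  for (j in seq_len(ncol(idx))) {
    a <- nb[[idx[1, j]]]; b <- nb[[idx[2, j]]]
    s <- length(intersect(a, b)); u <- length(union(a, b))
    shared[j] <- s
    jac[j] <- if (u) s / u else 0
  }
  data.frame(lncrna_a = lnc[idx[1, ]], lncrna_b = lnc[idx[2, ]],
             shared_pcg_count = shared, jaccard = jac,
             stringsAsFactors = FALSE)
}

.overlap_p <- function(n_a, n_b, n_shared, universe) {
  if (universe < max(n_a, n_b))
    stop("consistency error: universe smaller than observed sets")
  stats::phyper(n_shared - 1L, n_b, universe - n_b, n_a, lower.tail = FALSE)
}

#' Overlap of two ceRNA networks with hypergeometric significance
#'
#' Computes the conservative network (edges present in both inputs) and the
#' counts of shared lncRNAs, PCGs and edges, each with an upper-tail
#' hypergeometric p-value: observing the shared count when drawing one
#' network's set from the stated universe with the other network's set as
#' successes. Counts and p-values are symmetric in the two inputs.
#'
#' @param net_a,net_b `cerna_network` objects.
#' @param universes list with integer elements `lncrnas`, `pcgs`, `pairs`:
#'   the candidate counts testable in both cohorts.
#' @return A list with `conservative` (a `cerna_network` of shared edges)
#'   and `overlap` (data.frame `what`, `n_a`, `n_b`, `shared`, `universe`,
#'   `p_value`).
#' @export
intersect_networks <- function(net_a, net_b, universes) {
  stopifnot(all(c("lncrnas", "pcgs", "pairs") %in% names(universes)))
  la <- net_a$nodes$node_id[net_a$nodes$node_type == "lncRNA"]
  lb <- net_b$nodes$node_id[net_b$nodes$node_type == "lncRNA"]
  pa <- net_a$nodes$node_id[net_a$nodes$node_type == "PCG"]
  pb <- net_b$nodes$node_id[net_b$nodes$node_type == "PCG"]
  ea <- paste(net_a$edges$lncrna_id, net_a$edges$pcg_id, sep = "\r")
  eb <- paste(net_b$edges$lncrna_id, net_b$edges$pcg_id, sep = "\r")
  shared_edges <- net_a$edges[ea %in% eb, , drop = FALSE]
  overlap <- data.frame(
    what = c("lncrnas", "pcgs", "pairs"),
    n_a = c(length(la), length(pa), length(ea)),
    n_b = c(length(lb), length(pb), length(eb)),
    shared = c(length(intersect(la, lb)), length(intersect(pa, pb)),
               nrow(shared_edges)),
    universe = c(universes$lncrnas, universes$pcgs, universes$pairs),
    stringsAsFactors = FALSE)
  overlap$p_value <- mapply(.overlap_p, overlap$n_a, overlap$n_b,
                            overlap$shared, overlap$universe)
  list(conservative = cerna_network(shared_edges), overlap = overlap)
}

#' Extract the first-neighbour subnetwork of seed lncRNAs
#'
#' Induced subgraph on the seed lncRNAs and their PCG neighbours, keeping
#' only seed-neighbour edges. Seed ids that are not lncRNA nodes of the
#' network are ignored with a warning.
#'
#' @param net a `cerna_network`.
#' @param seed_lncrnas character vector of lncRNA node ids.
#' @return A `cerna_network`.
#' @export
extract_subnetwork <- function(net, seed_lncrnas) {
  lnc <- net$nodes$node_id[net$nodes$node_type == "lncRNA"]
  unknown <- setdiff(seed_lncrnas, lnc)
  if (length(unknown))
    warning("ignoring seed id(s) that are not lncRNA nodes: ",
            paste(unknown, collapse = ", "))
  seeds <- intersect(seed_lncrnas, lnc)
  cerna_network(net$edges[net$edges$lncrna_id %in% seeds, , drop = FALSE])
}

#' Export a network edge list as TSV
#' @param net a `cerna_network`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  write_results(net$edges, path)
}
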