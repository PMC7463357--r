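# Candidate lncRNA-PCG pair construction from shared miRNAs, and the
# hypergeometric test of sharing significance.

#' Build candidate lncRNA-PCG pairs sharing at least one miRNA
#'
#' Under the ceRNA hypothesis a lncRNA can only compete with a protein-coding
#' gene for miRNAs that target both. Candidates are therefore exactly the
#' lncRNA x PCG pairs whose miRNA regulator sets intersect.
#'
#' @param interactions an `interaction_set` (see [read_interactions()]).
#' @return A data.frame of class `candidate_pairs` with columns `lncrna_id`,
#'   `pcg_id`, `shared_mirna_count` and `shared_mirnas` (comma-joined ids),
#'   sorted by (lncrna_id, pcg_id). Empty output is allowed.
#' @export
build_candidate_pairs <- function(interactions) {
  ln <- interactions[interactions$target_class == "lncRNA",
                     c("mirna_id", "target_id")]
  pg <- interactions[interactions$target_class == "PCG",
                     c("mirna_id", "target_id")]
  empty <- data.frame(lncrna_id = character(), pcg_id = character(),
                      shared_mirna_count = integer(),
                      shared_mirnas = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(ln) || !nrow(pg)) {
    class(empty) <- c("candidate_pairs", "data.frame")
    return(empty)
  }
  names(ln)[2] <- "lncrna_id"
  names(pg)[2] <- "pcg_id"
  joined <- merge(ln, pg, by = "mirna_id")
  if (!nrow(joined)) {
    class(empty) <- c("candidate_pairs", "data.frame")
    return(empty)
  }
  key <- paste(joined$lncrna_id, joined$pcg_id, sep = "\r")
  mir <- split(joined$mirna_id, key)
  mir <- lapply(mir, function(v) sort(unique(v)))
  ids <- do.call(rbind, strsplit(names(mir), "\r", fixed = TRUE))
  out <- data.frame(lncrna_id = ids[, 1], pcg_id = ids[, 2],
                    shared_mirna_count = lengths(mir),
                    shared_mirnas = vapply(mir, paste, character(1),
                                           collapse = ","),
                    stringsAsFactors = FALSE)
  out <- out[order(out$lncrna_id, out$pcg_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_pairs", "data.frame")
  out
}

#' Hypergeometric significance of miRNA sharing for candidate pairs
#'
#' For each pair, tests whether the observed number `k` of shared miRNAs is
#' surprising when `nq` miRNA regulators of the PCG are drawn from a universe
#' of `N` miRNAs of which `K` target the lncRNA:
#' `p = P(X >= k)` under Hypergeometric(N, K, nq) (upper tail). The universe
#' defaults to the number of distinct miRNAs in the interaction set, the
#' natural sampling frame of the sharing test; it can be overridden.
#' q-values are Benjamini-Hochberg across all tested pairs.
#'
#' @param pairs a `candidate_pairs` data.frame (see
#'   [build_candidate_pairs()]).
#' @param interactions the `interaction_set` the pairs were derived from.
#' @param universe_size optional integer universe `N`
#'   (must satisfy `N >= max(K, nq)` over all pairs).
#' @return `pairs` with added columns `k`, `K`, `nq`, `N`, `p_value`,
#'   `q_value`.
#' @export
shared_mirna_test <- function(pairs, interactions, universe_size = NULL) {
  n_per_target <- tapply(interactions$mirna_id, interactions$target_id,
                         function(v) length(unique(v)))
  N <- if (is.null(universe_size))
    length(unique(interactions$mirna_id)) else as.integer(universe_size)
  K <- as.integer(n_per_target[pairs$lncrna_id])
  nq <- as.integer(n_per_target[pairs$pcg_id])
  k <- pairs$shared_mirna_count
  if (nrow(pairs)) {
    if (anyNA(K) || anyNA(nq))
      stop("pair gene absent from interaction set")
    if (any(k > pmin(K, nq)))
      stop("consistency error: shared count exceeds min(K, nq)")
    if (N < max(K, nq))
      stop("universe_size must be >= max(K, nq)")
  }
  p <- stats::phyper(k - 1L, K, N - K, nq, lower.tail = FALSE)
  out <- pairs
  out$k <- k
  out$K <- K
  out$nq <- nq
  out$N <- N
  out$p_value <- p
  out$q_value <- stats::p.adjust(p, method = "BH")
  out
}
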