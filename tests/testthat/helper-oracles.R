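# Independent brute-force oracles used to cross-check the implementation.
# Each is written from the definition, not by calling the code it checks.

# Upper-tail hypergeometric P(X >= k) by exhaustive enumeration of all
# C(N, nq) draws from a universe whose first K items are successes.
enum_hyper_upper <- function(N, K, nq, k) {
  draws <- utils::combn(N, nq)
  hits <- colSums(draws <= K)
  mean(hits >= k)
}

# Pearson correlation and t-test p-value from the textbook formulas.
manual_pearson <- function(x, y, sided = "two") {
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  n <- length(x)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  p <- if (sided == "two") 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
       else stats::pt(tt, n - 2, lower.tail = FALSE)
  list(r = r, p = p)
}

# Two-group log-rank chi-square from the O-E / hypergeometric-variance
# definition, computed time point by time point.
manual_logrank <- function(time, event, group) {
  group <- as.character(group)
  g1 <- unique(group)[1]
  o_minus_e <- 0; v <- 0
  for (tj in sort(unique(time[event == 1]))) {
    at_risk <- time >= tj
    nj <- sum(at_risk)
    n1j <- sum(at_risk & group == g1)
    dj <- sum(time == tj & event == 1)
    d1j <- sum(time == tj & event == 1 & group == g1)
    o_minus_e <- o_minus_e + (d1j - dj * n1j / nj)
    if (nj > 1)
      v <- v + dj * (n1j / nj) * (1 - n1j / nj) * (nj - dj) / (nj - 1)
  }
  chisq <- o_minus_e^2 / v
  list(statistic = chisq,
       p_value = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# All-pairs shortest-path betweenness by explicit BFS path counting
# (naive Brandes-style accumulation over unordered pairs).
brute_betweenness <- function(nodes, edges_a, edges_b) {
  adj <- lapply(stats::setNames(seq_along(nodes), nodes), function(i)
    unique(c(edges_b[edges_a == nodes[i]], edges_a[edges_b == nodes[i]])))
  bw <- stats::setNames(numeric(length(nodes)), nodes)
  count_paths <- function(s) {
    dist <- stats::setNames(rep(Inf, length(nodes)), nodes)
    sigma <- stats::setNames(rep(0, length(nodes)), nodes)
    preds <- stats::setNames(vector("list", length(nodes)), nodes)
    dist[s] <- 0; sigma[s] <- 1
    queue <- s; order_seen <- character()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_seen <- c(order_seen, v)
      for (w in adj[[v]]) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    list(sigma = sigma, preds = preds, order = order_seen)
  }
  for (s in nodes) {
    bfs <- count_paths(s)
    delta <- stats::setNames(numeric(length(nodes)), nodes)
    for (w in rev(bfs$order)) {
      for (v in bfs$preds[[w]])
        delta[v] <- delta[v] + bfs$sigma[v] / bfs$sigma[w] * (1 + delta[w])
      if (w != s) bw[w] <- bw[w] + delta[w]
    }
  }
  bw / 2  # each unordered (s, t) pair counted from both endpoints
}

# Candidate-pair construction by a double loop over all lncRNA x PCG
# combinations.
brute_pairs <- function(interactions) {
  lnc <- unique(interactions$target_id[interactions$target_class == "lncRNA"])
  pcg <- unique(interactions$target_id[interactions$target_class == "PCG"])
  mir_of <- function(g) unique(interactions$mirna_id[
    interactions$target_id == g])
  out <- list()
  for (l in sort(lnc)) for (g in sort(pcg)) {
    shared <- intersect(mir_of(l), mir_of(g))
    if (length(shared))
      out[[paste(l, g)]] <- data.frame(
        lncrna_id = l, pcg_id = g,
        shared_mirna_count = length(shared),
        shared_mirnas = paste(sort(shared), collapse = ","),
        stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(lncrna_id = character(), pcg_id = character(),
               shared_mirna_count = integer(), shared_mirnas = character(),
               stringsAsFactors = FALSE)
}

# Random interaction fixture over small gene/miRNA pools.
random_interactions <- function(n_mirnas, n_lncrnas, n_pcgs, n_edges,
                                seed) {
  set.seed(seed)
  mir <- sprintf("miR%02d", seq_len(n_mirnas))
  lnc <- sprintf("L%02d", seq_len(n_lncrnas))
  pcg <- sprintf("G%02d", seq_len(n_pcgs))
  targets <- c(lnc, pcg)
  cls <- rep(c("lncRNA", "PCG"), c(n_lncrnas, n_pcgs))
  idx <- sample(length(targets), n_edges, replace = TRUE)
  interaction_set(data.frame(
    mirna_id = sample(mir, n_edges, replace = TRUE),
    target_id = targets[idx], target_class = cls[idx],
    stringsAsFactors = FALSE))
}

# Tiny matched cohort built directly from normal/tumor matrices.
tiny_cohort <- function(normal, tumor, gene_class) {
  matched_expr(normal, tumor, gene_class)
}
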