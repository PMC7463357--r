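# Kaplan-Meier / log-rank screening of ce-lncRNAs, PCGs and ceRNA pairs
# with mean-expression dichotomization. Product-limit estimation and the
# two-group log-rank test are delegated to the survival package.

#' Dichotomize patients by mean expression
#'
#' Patients with expression strictly above the mean form the `high` group;
#' the rest (ties at the mean included) form the `low` group.
#'
#' @param values named numeric vector (patient id -> expression), length
#'   >= 2.
#' @return A list of class `survival_grouping` with `groups` (named
#'   character, `"high"`/`"low"`) and `cutoff` (the mean).
#' @export
dichotomize_by_mean <- function(values) {
  if (length(values) < 2L) stop("dichotomization requires >= 2 patients")
  if (is.null(names(values))) stop("values must be named by patient id")
  cutoff <- mean(values)
  groups <- ifelse(values > cutoff, "high", "low")
  if (length(unique(groups)) < 2L)
    stop("degenerate grouping: all expression values equal")
  structure(list(groups = groups, cutoff = cutoff),
            class = "survival_grouping")
}

#' Per-patient pair expression of a ceRNA pair
#'
#' The arithmetic mean of the two genes' expression per patient, used to
#' dichotomize patients jointly on the pair.
#'
#' @param expr numeric genes x patients matrix with dimnames.
#' @param lncrna_id,pcg_id row ids present in `expr`.
#' @return Named numeric vector (patient -> pair expression).
#' @export
pair_expression <- function(expr, lncrna_id, pcg_id) {
  for (g in c(lncrna_id, pcg_id))
    if (!g %in% rownames(expr)) stop("unknown gene id: ", g)
  v <- (expr[lncrna_id, , drop = FALSE] + expr[pcg_id, , drop = FALSE]) / 2
  stats::setNames(as.numeric(v), colnames(expr))
}

#' Kaplan-Meier curves and two-group log-rank test
#'
#' Product-limit survival estimate per group and the standard two-group
#' log-rank chi-square statistic (1 df, upper-tail p). Patients present in
#' both the clinical table and the grouping are used.
#'
#' @param clinical a `clinical_table` (see [read_clinical()]).
#' @param grouping a `survival_grouping` (see [dichotomize_by_mean()]).
#' @return A list of class `logrank_result`: `curves` (per group, a
#'   data.frame `time`, `surv`, `n_risk`, `n_event`), `statistic`,
#'   `p_value`, `group_sizes`, `events_per_group`.
#' @export
km_logrank <- function(clinical, grouping) {
  stopifnot(inherits(grouping, "survival_grouping"))
  ids <- intersect(clinical$patient_id, names(grouping$groups))
  cl <- clinical[match(ids, clinical$patient_id), , drop = FALSE]
  grp <- factor(grouping$groups[ids], levels = c("low", "high"))
  if (any(table(grp) == 0L))
    stop("grouping error: both groups must be non-empty")
  if (sum(cl$event) == 0L)
    stop("undefined test: no events observed")
  surv <- survival::Surv(cl$time, cl$event)
  sd0 <- survival::survdiff(surv ~ grp)
  statistic <- unname(sd0$chisq)
  p_value <- stats::pchisq(statistic, df = 1L, lower.tail = FALSE)
  fit <- survival::survfit(surv ~ grp)
  sm <- summary(fit, censored = FALSE)
  strata <- if (is.null(sm$strata)) rep(levels(grp)[1], length(sm$time))
            else sub("^grp=", "", as.character(sm$strata))
  curves <- lapply(levels(grp), function(g) {
    sel <- strata == g
    data.frame(time = sm$time[sel], surv = sm$surv[sel],
               n_risk = sm$n.risk[sel], n_event = sm$n.event[sel])
  })
  names(curves) <- levels(grp)
  structure(list(curves = curves, statistic = statistic, p_value = p_value,
                 group_sizes = table(grp),
                 events_per_group = tapply(cl$event, grp, sum)),
            class = "logrank_result")
}

#' Survival screen of genes and ceRNA pairs
#'
#' For each target gene the patients are split at the mean of its tumor
#' expression (or relative expression with `use_relative`) and screened by
#' Kaplan-Meier / log-rank; `significant` flags `p < p_cutoff`. For each
#' ceRNA pair the per-patient pair expression (mean of the two genes) is
#' screened the same way; `pair_better` flags pairs whose joint signature is
#' significant while neither single gene is (`pair p < p_cutoff` with both
#' single-gene p-values available and `>= p_cutoff`). Targets whose
#' grouping or test is undefined are skipped and counted.
#'
#' @param x a [matched_expr] object.
#' @param clinical a `clinical_table`.
#' @param genes character vector of gene ids to screen (may be empty).
#' @param pairs optional data.frame with columns `lncrna_id`, `pcg_id`.
#' @param use_relative use per-patient log2 fold changes instead of absolute
#'   tumor expression (default `FALSE`).
#' @param pseudocount shift before log2 when `use_relative` (default 0).
#' @param p_cutoff significance threshold (default 0.05).
#' @return A data.frame with columns `target`, `type` (`gene` or `pair`),
#'   `statistic`, `p_value`, `significant`, `pair_better`; attribute
#'   `n_skipped` counts skipped targets.
#' @export
survival_screen <- function(x, clinical, genes = character(), pairs = NULL,
                            use_relative = FALSE, pseudocount = 0,
                            p_cutoff = 0.05) {
  stopifnot(inherits(x, "matched_expr"))
  expr <- if (use_relative) relative_expression(x, pseudocount)$e else x$tumor
  ids <- intersect(colnames(expr), clinical$patient_id)
  if (length(ids) < 2L) stop("need >= 2 patients with clinical data")
  expr <- expr[, ids, drop = FALSE]

  n_skipped <- 0L
  screen_values <- function(v) {
    tryCatch({
      lr <- km_logrank(clinical, dichotomize_by_mean(v))
      c(lr$statistic, lr$p_value)
    }, error = function(e) {
      message("survival screen: target skipped (", conditionMessage(e), ")")
      n_skipped <<- n_skipped + 1L
      c(NA_real_, NA_real_)
    })
  }

  rows <- list()
  single_p <- stats::setNames(numeric(0), character(0))
  need <- unique(c(genes, if (!is.null(pairs))
    c(pairs$lncrna_id, pairs$pcg_id)))
  for (g in need) {
    if (!g %in% rownames(expr)) {
      if (g %in% genes) {
        message("survival screen: gene not in matrix, skipped: ", g)
        n_skipped <- n_skipped + 1L
      }
      single_p[g] <- NA_real_
      next
    }
    res <- screen_values(expr[g, ])
    single_p[g] <- res[2]
    if (g %in% genes)
      rows[[g]] <- data.frame(target = g, type = "gene",
                              statistic = res[1], p_value = res[2],
                              stringsAsFactors = FALSE)
  }
  if (!is.null(pairs) && nrow(pairs)) {
    for (i in seq_len(nrow(pairs))) {
      l <- pairs$lncrna_id[i]; g <- pairs$pcg_id[i]
      key <- paste0(l, "|", g)
      if (!l %in% rownames(expr) || !g %in% rownames(expr)) {
        message("survival screen: pair gene not in matrix, skipped: ", key)
        n_skipped <- n_skipped + 1L
        next
      }
      res <- screen_values(pair_expression(expr, l, g))
      pb <- !is.na(res[2]) && res[2] < p_cutoff &&
        !is.na(single_p[l]) && single_p[l] >= p_cutoff &&
        !is.na(single_p[g]) && single_p[g] >= p_cutoff
      rows[[key]] <- data.frame(target = key, type = "pair",
                                statistic = res[1], p_value = res[2],
                                pair_better = pb, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) {
    for (i in seq_along(rows))
      if (is.null(rows[[i]]$pair_better)) rows[[i]]$pair_better <- NA
    do.call(rbind, rows)
  } else data.frame(target = character(), type = character(),
                    statistic = numeric(), p_value = numeric(),
                    pair_better = logical(), stringsAsFactors = FALSE)
  out <- out[!is.na(out$p_value), , drop = FALSE]
  out$significant <- out$p_value < p_cutoff
  out <- out[, c("target", "type", "statistic", "p_value",
                 "significant", "pair_better")]
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}
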