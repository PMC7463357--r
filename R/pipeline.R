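# End-to-end orchestration over synthetic inputs: simulate -> pairs ->
# scoring -> network -> enrichment -> survival -> enhancers -> THZ1,
# writing each stage's table and a manifest with row counts and hashes.

#' Configuration of an end-to-end pipeline run
#'
#' @param outdir output directory (created if absent).
#' @param seed integer seed forwarded to the synthetic generator.
#' @param synthetic named list of overrides for [synthetic_config()].
#' @param glocerna named list of overrides for [glocerna_config()].
#' @param stages character vector of stages to run, a subset of
#'   `c("pairs", "glocerna", "network", "enrichment", "survival",
#'   "enhancers", "thz1")`; the simulate stage always runs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, synthetic = list(),
                            glocerna = list(),
                            stages = c("pairs", "glocerna", "network",
                                       "enrichment", "survival",
                                       "enhancers", "thz1")) {
  known <- c("pairs", "glocerna", "network", "enrichment", "survival",
             "enhancers", "thz1")
  if (!all(stages %in% known))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  synthetic$seed <- as.integer(seed)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 synthetic = do.call(synthetic_config, synthetic),
                 glocerna = do.call(glocerna_config, glocerna),
                 stages = stages),
            class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Generates a synthetic cohort and all companion inputs, writes them as
#' plain-text fixtures, then executes the enabled stages in dependency
#' order, writing one result table per stage. A stage failure aborts all
#' downstream stages; the manifest written up to that point is kept.
#' Reruns with the same config and seed are bit-identical.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, the manifest: a data.frame with columns `stage`,
#'   `file`, `rows`, `md5`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  note <- function(stage, file, rows) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(file), rows = rows,
      md5 = unname(tools::md5sum(file)), stringsAsFactors = FALSE)
  }
  out <- function(name) file.path(config$outdir, name)
  finish <- function() {
    mf <- if (length(manifest)) do.call(rbind, manifest) else
      data.frame(stage = character(), file = character(),
                 rows = integer(), md5 = character())
    write_results(mf, out("manifest.tsv"))
    invisible(mf)
  }

  res <- tryCatch({
    cohort <- generate_cohort(config$synthetic)
    write_matched_expression(cohort$matrix, out("expression.tsv"),
                             out("pairing.tsv"))
    note("simulate", out("expression.tsv"), length(cohort$matrix$gene_ids))
    write_results(as.data.frame(cohort$interactions),
                  out("interactions.tsv"))
    note("simulate", out("interactions.tsv"), nrow(cohort$interactions))
    clinical <- generate_clinical(config$synthetic, cohort$matrix,
                                  cohort$truth)
    write_results(as.data.frame(clinical), out("clinical.tsv"))
    note("simulate", out("clinical.tsv"), nrow(clinical))
    coords <- generate_gene_coords(config$synthetic,
                                   cohort$matrix$gene_ids)
    write_results(as.data.frame(coords), out("gene_coords.tsv"))
    note("simulate", out("gene_coords.tsv"), nrow(coords))
    regions <- generate_regions(config$synthetic, coords, cohort$truth)
    utils::write.table(as.data.frame(regions), out("regions.bed"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    note("simulate", out("regions.bed"), nrow(regions))
    tc <- generate_timecourse(config$synthetic, cohort$truth)
    write_results(tc, out("timecourse.tsv"))
    note("simulate", out("timecourse.tsv"), nrow(tc))
    gs <- generate_gene_sets(config$synthetic, cohort$truth)
    write_gene_sets(gs$collection, out("hallmarks.gmt"))
    note("simulate", out("hallmarks.gmt"), length(gs$collection$sets))
    write_results(gs$map, out("hallmark_map.tsv"))
    note("simulate", out("hallmark_map.tsv"), nrow(gs$map))
    list(cohort = cohort, clinical = clinical, coords = coords,
         regions = regions, tc = tc, gs = gs)
  }, error = function(e) {
    message("pipeline: simulate stage failed: ", conditionMessage(e))
    NULL
  })
  if (is.null(res)) return(finish())

  pairs <- NULL; results <- NULL; net <- NULL; labels <- NULL
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(TRUE)
    tryCatch({ fn(); TRUE },
             error = function(e) {
               message("pipeline: stage '", stage, "' failed, ",
                       "aborting downstream stages: ", conditionMessage(e))
               FALSE
             })
  }

  ok <- run_stage("pairs", function() {
    pairs <<- shared_mirna_test(build_candidate_pairs(res$cohort$interactions),
                                res$cohort$interactions)
    write_results(pairs, out("candidate_pairs.tsv"))
    note("pairs", out("candidate_pairs.tsv"), nrow(pairs))
  })
  if (!ok || !"pairs" %in% config$stages) return(finish())

  ok <- run_stage("glocerna", function() {
    results <<- run_glocerna(res$cohort$matrix, pairs, config$glocerna)
    write_results(results, out("cerna_results.tsv"))
    note("glocerna", out("cerna_results.tsv"), nrow(results))
  })
  if (!ok || !"glocerna" %in% config$stages) return(finish())

  ok <- run_stage("network", function() {
    net <<- build_network(results)
    write_network(net, out("network.tsv"))
    note("network", out("network.tsv"), nrow(net$edges))
    topo <- data.frame(node_id = net$nodes$node_id,
                       node_type = net$nodes$node_type,
                       degree = unname(node_degree(net)[net$nodes$node_id]),
                       betweenness =
                         unname(node_betweenness(net)[net$nodes$node_id]),
                       stringsAsFactors = FALSE)
    write_results(topo, out("topology.tsv"))
    note("network", out("topology.tsv"), nrow(topo))
    if (sum(net$nodes$node_type == "lncRNA") >= 2L) {
      sim <- lncrna_similarity(net)
      write_results(sim, out("lncrna_similarity.tsv"))
      note("network", out("lncrna_similarity.tsv"), nrow(sim))
    }
  })
  if (!ok) return(finish())

  if ("enrichment" %in% config$stages && !is.null(net)) {
    ok <- run_stage("enrichment", function() {
      universe <- unique(pairs$pcg_id)
      he <- hallmark_enrichment(net, res$gs$collection, universe,
                                hallmark_map = res$gs$map)
      write_results(he, out("hallmark_enrichment.tsv"))
      note("enrichment", out("hallmark_enrichment.tsv"), nrow(he))
      pl <- per_lncrna_hallmarks(net, res$gs$collection, universe)
      write_results(pl$counts, out("per_lncrna_hallmark_counts.tsv"))
      note("enrichment", out("per_lncrna_hallmark_counts.tsv"),
           nrow(pl$counts))
    })
    if (!ok) return(finish())
  }

  if ("survival" %in% config$stages && !is.null(net)) {
    ok <- run_stage("survival", function() {
      lnc <- net$nodes$node_id[net$nodes$node_type == "lncRNA"]
      surv <- survival_screen(res$cohort$matrix, res$clinical,
                              genes = lnc, pairs = net$edges)
      write_results(surv, out("survival_screen.tsv"))
      note("survival", out("survival_screen.tsv"), nrow(surv))
    })
    if (!ok) return(finish())
  }

  if ("enhancers" %in% config$stages && !is.null(net)) {
    ok <- run_stage("enhancers", function() {
      assignments <- assign_enhancers(res$regions, res$coords)
      write_results(assignments, out("enhancer_assignments.tsv"))
      note("enhancers", out("enhancer_assignments.tsv"),
           nrow(assignments))
      lnc <- net$nodes$node_id[net$nodes$node_type == "lncRNA"]
      labels <<- label_se_te_lncrnas(assignments, lnc)
      write_results(labels, out("se_te_labels.tsv"))
      note("enhancers", out("se_te_labels.tsv"), nrow(labels))
    })
    if (!ok) return(finish())
  }

  if ("thz1" %in% config$stages && !is.null(net)) {
    run_stage("thz1", function() {
      sens <- thz1_sensitive(res$tc)
      write_results(sens, out("thz1_sensitivity.tsv"))
      note("thz1", out("thz1_sensitivity.tsv"), nrow(sens))
      subnet <- thz1_network(sens, net, labels = labels,
                             require_shared = FALSE)
      write_network(subnet, out("thz1_network.tsv"))
      note("thz1", out("thz1_network.tsv"), nrow(subnet$edges))
    })
  }
  finish()
}
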