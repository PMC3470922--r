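#' Pipeline configuration
#'
#' Collects every tunable of the screen-to-network analysis in one validated
#' object; unknown keys are rejected. The effective configuration is echoed
#' into the run manifest by [run_pipeline()].
#'
#' @param seed Integer seed driving all randomness.
#' @param sim A [sim_config()] used when `simulate = TRUE`; its seed is
#'   overridden by `seed`.
#' @param simulate Generate all inputs synthetically (the only input mode
#'   shipped; file-based inputs can be read with the `read_*` functions and
#'   passed through the stage functions directly).
#' @param smoothing,prior,clamp_zero Classifier training controls
#'   ([train_classifier()]).
#' @param neg_threshold Most-specific co-annotation size for negative
#'   training pairs (default 1000).
#' @param n_negative_candidates Candidate pairs sampled for the negative set.
#' @param trim_threshold Confidence below which edges are trimmed
#'   (default 0.2).
#' @param phospho_weight,pdna_weight Fixed weights for (de)phosphorylation
#'   and default protein-DNA edges.
#' @param universe_mode Background for enrichment: `screened` (the deletion
#'   collection), `network` (network nodes) or `annotated`.
#' @param complex_correction,go_correction Corrections for complex/pathway
#'   association and hit-set GO enrichment.
#' @param alpha,lfc_min Differential-expression selection thresholds.
#' @param level_window,min_fraction,kappa_threshold,cluego_correction
#'   ClueGO-style settings for the differential-expression GO analysis
#'   (two-sided test, Bonferroni, levels 3-8, 8% minimum coverage, kappa
#'   0.3).
#' @param min_complex_size Smallest in-universe set tested.
#' @param condense_min_size Complex size at which the view condenses a
#'   complex to one node (default 3).
#' @param export_formats Network export formats.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1,
                            sim = sim_config(seed = seed),
                            simulate = TRUE,
                            smoothing = 0.5,
                            prior = NULL,
                            clamp_zero = FALSE,
                            neg_threshold = 1000,
                            n_negative_candidates = 5000,
                            trim_threshold = 0.2,
                            phospho_weight = 0.8,
                            pdna_weight = 0.6,
                            universe_mode = c("screened", "network",
                                              "annotated"),
                            complex_correction = "BH",
                            go_correction = "BH",
                            alpha = 0.05,
                            lfc_min = 1,
                            level_window = c(3, 8),
                            min_fraction = 0.08,
                            kappa_threshold = 0.3,
                            cluego_correction = "bonferroni",
                            min_complex_size = 2,
                            condense_min_size = 3,
                            export_formats = c("sif", "graphml", "json")) {
  universe_mode <- match.arg(universe_mode)
  stopifnot(inherits(sim, "sim_config"))
  sim$seed <- seed
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

#' Run the full screen-to-network pipeline
#'
#' Executes, in order: simulate inputs, score and trim edges, assemble the
#' network with the screen overlay and complexes, complement hit-containing
#' complexes and condense the view, complex/pathway association, GO
#' enrichment of the morphology hits, the two moderated-t expression
#' contrasts with the liquid/solid overlay and ClueGO-style term grouping,
#' and file export. All result tables, network files and a run manifest
#' (effective configuration, seed, versions, configuration hash) are written
#' under `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every intermediate result (`hits`,
#'   `network`, `condensed`, `complex_enrichment`, `pathway_enrichment`,
#'   `go_hits`, `de_liquid`, `de_solid`, `overlay`, `de_go`, `de_go_groups`,
#'   `truth`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!config$simulate) {
    abort("only simulate = TRUE is supported; use the stage functions directly for file inputs")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name,
                    conditionMessage(e)))
    })
  }

  sim <- config$sim
  inter <- stage("simulate", gen_interactome(sim))
  anno <- stage("simulate", gen_go_and_complexes(sim))
  scr <- stage("simulate", gen_screen(sim))
  expr <- stage("simulate", gen_expression(sim))

  ## -- edge confidence ------------------------------------------------
  annset <- stage("score-edges",
                  propagate_annotations(anno$annotations, anno$ontology))
  positives <- stage("score-edges", build_positive_set(inter$records))
  set.seed(config$seed + 101L)
  cand <- sample_pairs(sim_genes(sim), config$n_negative_candidates)
  negatives <- stage("score-edges", suppressWarnings(
    build_negative_set(cand, annset, threshold = config$neg_threshold,
                       positives = positives)))
  classifier <- stage("score-edges",
                      train_classifier(inter$records, positives, negatives,
                                       smoothing = config$smoothing,
                                       prior = config$prior,
                                       clamp_zero = config$clamp_zero))
  edges <- stage("score-edges",
                 score_edges(inter$records, classifier,
                             phospho_weight = config$phospho_weight,
                             pdna_weight = config$pdna_weight))
  edges <- stage("score-edges", trim_network(edges, config$trim_threshold))

  ## -- screen ----------------------------------------------------------
  calls <- stage("screen", screen_consensus(scr$screen))
  hits <- stage("screen", select_hits(calls))

  ## -- network build ---------------------------------------------------
  pheno <- tibble(gene = calls$gene, phenotype = calls$consensus)
  pheno <- left_join(pheno, anno$viability, by = "gene")
  network <- stage("build-network",
                   assemble_network(edges, pheno, anno$complexes))
  network <- stage("overlay",
                   complement_small_complexes(network,
                                              hits$morphology_hits,
                                              anno$viability))
  condensed <- stage("overlay",
                     condense_complexes(network,
                                        min_size = config$condense_min_size,
                                        hits = hits$morphology_hits))

  ## -- enrichment -------------------------------------------------------
  universe <- switch(config$universe_mode,
                     screened = calls$gene,
                     network = network$nodes$gene,
                     annotated = annset$universe)
  universe <- union(universe, hits$morphology_hits)
  cpx_enr <- stage("enrich",
                   complex_association(anno$complexes, hits$morphology_hits,
                                       universe,
                                       correction = config$complex_correction,
                                       min_size = config$min_complex_size))
  path_enr <- stage("enrich",
                    complex_association(anno$pathways, hits$morphology_hits,
                                        universe,
                                        correction = config$complex_correction,
                                        min_size = config$min_complex_size))
  go_hits <- stage("enrich",
                   go_enrichment(intersect(hits$morphology_hits,
                                           annset$universe),
                                 annset, anno$ontology,
                                 universe = annset$universe,
                                 level_window = config$level_window,
                                 correction = config$go_correction,
                                 mode = "enrichment"))

  ## -- differential expression -----------------------------------------
  es <- filter_absent(expr$expression)
  de_liquid <- stage("diffexpr", fit_moderated_t(es, "liquid"))
  de_solid <- stage("diffexpr", fit_moderated_t(es, "solid"))
  overlay <- stage("diffexpr",
                   annotate_liquid_solid(de_liquid, de_solid,
                                         alpha = config$alpha,
                                         lfc_min = config$lfc_min))
  de_genes <- overlay$gene[overlay$category != "neither"]
  expr_universe <- intersect(rownames(expr$expression$values),
                             annset$universe)
  de_go <- stage("enrich",
                 go_enrichment(intersect(de_genes, expr_universe),
                               annset, anno$ontology,
                               universe = expr_universe,
                               level_window = config$level_window,
                               min_fraction = config$min_fraction,
                               correction = config$cluego_correction,
                               mode = "two_sided"))
  de_groups <- stage("enrich",
                     cluego_grouping(de_go,
                                     term_genes(annset, de_go$set_id),
                                     expr_universe,
                                     kappa_threshold = config$kappa_threshold))

  ## -- export -----------------------------------------------------------
  out <- function(...) file.path(out_dir, ...)
  readr::write_tsv(calls, out("screen_calls.tsv"))
  write_enrichment(cpx_enr, out("complex_association.tsv"))
  write_enrichment(path_enr, out("pathway_association.tsv"))
  write_enrichment(go_hits, out("go_enrichment_hits.tsv"))
  write_enrichment(de_go, out("go_enrichment_de.tsv"))
  readr::write_tsv(tidy(de_liquid, config$alpha, config$lfc_min),
                   out("de_liquid.tsv"))
  readr::write_tsv(tidy(de_solid, config$alpha, config$lfc_min),
                   out("de_solid.tsv"))
  readr::write_tsv(overlay, out("de_overlay.tsv"))
  readr::write_tsv(tidyr::unnest(de_groups, "term_ids"),
                   out("de_term_groups.tsv"))
  for (fmt in config$export_formats) {
    export_network(network, out(paste0("network.", fmt)), fmt)
  }
  export_network(condensed, out("network_condensed.json"), "json")

  manifest <- list(
    package = "colonynet",
    package_version = as.character(utils::packageVersion("colonynet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    config = serialize_config(config),
    classifier = list(prior_true = classifier$prior_true,
                      n_pos = classifier$n_pos, n_neg = classifier$n_neg),
    phospho_weight = config$phospho_weight,
    trim_threshold = config$trim_threshold,
    n_edges = nrow(network$edges),
    n_nodes = nrow(network$nodes),
    n_morphology_hits = length(hits$morphology_hits),
    n_size_hits = length(hits$size_hits)
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(classifier = classifier, edges = edges, calls = calls,
                 hits = hits, network = network, condensed = condensed,
                 complex_enrichment = cpx_enr, pathway_enrichment = path_enr,
                 go_hits = go_hits, de_liquid = de_liquid,
                 de_solid = de_solid, overlay = overlay, de_go = de_go,
                 de_go_groups = de_groups,
                 truth = list(interactome = inter$truth,
                              annotation = anno$truth, screen = scr$truth,
                              expression = expr$truth),
                 manifest = manifest))
}

# flatten the config into manifest-friendly scalars
serialize_config <- function(config) {
  cfg <- unclass(config)
  cfg$sim <- unclass(cfg$sim)
  cfg$sim$techniques <- as.data.frame(cfg$sim$techniques)
  cfg$sim$planted_modules <- as.data.frame(cfg$sim$planted_modules)
  cfg
}
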