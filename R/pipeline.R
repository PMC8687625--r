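#' Pipeline configuration
#'
#' Collects the input file paths and tunable parameters of a full run.
#' Can be read from a YAML file ([read_pipeline_config()]); every run
#' writes the resolved configuration beside its outputs.
#'
#' @param study_dir directory holding `ppi.tsv`, `evidence.tsv`,
#'   `ingredients.tsv`, `associations.tsv`, `annotations.gmt` (see
#'   [write_study()]).
#' @param out_dir output directory.
#' @param caco2_min,dl_min ADME thresholds (see [filter_ingredients()]).
#' @param community_method community method for the Nim score.
#' @param threshold_mode FRS threshold rule (see [select_frs()]).
#' @param alpha enrichment significance level.
#' @param coverage_target ICP stopping coverage.
#' @param seed RNG seed (used by the modularity community method).
#' @return list of class `cfig_pipeline_config`.
#' @export
pipeline_config <- function(study_dir, out_dir,
                            caco2_min = -0.4, dl_min = 0.18,
                            community_method = "connected_components",
                            threshold_mode = "midpoint",
                            alpha = 0.05, coverage_target = 0.90,
                            seed = 1L) {
  structure(list(study_dir = study_dir, out_dir = out_dir,
                 caco2_min = caco2_min, dl_min = dl_min,
                 community_method = community_method,
                 threshold_mode = threshold_mode, alpha = alpha,
                 coverage_target = coverage_target, seed = as.integer(seed)),
            class = "cfig_pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of [pipeline_config()]'s fields;
#'   unspecified fields take their defaults.
#' @return a `cfig_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' Run the full pipeline
#'
#' Executes, in order: ingredient ADME filtering, weighted disease-network
#' construction, ingredient-target network construction, network merging,
#' Nim scoring, FRS extraction with key-protein subtyping, UET
#' computation, enrichment-coverage validation, and ICP selection of the
#' critical functional ingredients group.  All intermediates are written
#' as TSV under `out_dir`, plus a JSON run report whose stage counts are
#' cross-checked against the written tables.  Deterministic for a fixed
#' configuration (timestamps aside).
#'
#' @param config a `cfig_pipeline_config`.
#' @param quiet suppress stage messages.
#' @return the run report, invisibly (a list; also written as
#'   `report.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "cfig_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  out <- function(f) file.path(config$out_dir, f)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_cfig("pipeline stage '%s' failed: %s", name, conditionMessage(e),
                class = "cfig_pipeline_error")
    })
  }

  inputs <- stage("read", read_study(config$study_dir))

  decisions <- stage("filter",
    filter_ingredients(inputs$ingredients, config$caco2_min, config$dl_min))
  write_tsv(decisions, out("filter_decisions.tsv"))
  say("filter: retained %d / %d ingredients", sum(decisions$retained),
      nrow(decisions))

  dres <- stage("disease_network",
    build_disease_network(inputs$base_ppi, inputs$evidence))
  disease <- dres$network
  writeLines(dres$dropped, out("dropped_genes.txt"))
  write_tsv(disease$nodes, out("disease_nodes.tsv"))
  write_tsv(disease$edges, out("disease_edges.tsv"))
  say("disease network: %d nodes, %d edges (%d evidence genes dropped)",
      nrow(disease$nodes), nrow(disease$edges), length(dres$dropped))

  retained_ids <- decisions$ingredient_id[decisions$retained]
  assoc <- inputs$associations[
    inputs$associations$ingredient_id %in% retained_ids, , drop = FALSE]
  itres <- stage("it_network", build_it_network(retained_ids, assoc))
  it <- itres$network
  write_tsv(it$edges, out("it_edges.tsv"))
  say("I-T network: %d associations, %.2f mean targets per ingredient",
      itres$n_associations, itres$mean_targets)

  merged <- stage("merge", merge_networks(disease, it,
                                          base_ppi = inputs$base_ppi))
  write_tsv(merged$nodes, out("merged_nodes.tsv"))
  write_tsv(merged$edges, out("merged_edges.tsv"))
  say("merged network: %d nodes, %d edges", nrow(merged$nodes),
      nrow(merged$edges))

  comms <- stage("communities",
    assign_communities(merged, config$community_method, seed = config$seed))
  nim <- stage("nim", compute_nim(merged, comms))

  disease_genes <- disease$nodes$id
  target_genes <- unique(assoc$target_gene)
  frs <- stage("frs", select_frs(nim, merged, mode = config$threshold_mode,
                                 disease_genes = disease_genes,
                                 target_genes = target_genes))
  nim$kept <- nim$id %in% frs$kept
  nim$subtype <- ifelse(nim$id %in% names(frs$subtype),
                        unname(frs$subtype[nim$id]), NA_character_)
  write_tsv(nim, out("nim.tsv"))
  say("FRS: %d / %d nodes kept (%s threshold %.4g), %d key proteins",
      length(frs$kept), nrow(nim), frs$threshold_mode, frs$threshold_value,
      length(frs$key_proteins))

  uet <- stage("uet", compute_uet(disease_genes, target_genes))
  writeLines(uet, out("uet.txt"))

  background <- merged$nodes$id[merged$nodes$role == "gene"]
  validation <- stage("validation",
    evaluate_frs(frs$key_proteins, uet,
                 list(annotations = inputs$annotations),
                 background = background, alpha = config$alpha))
  say("validation: gene coverage %.2f%%, term coverage %.2f%%",
      validation$genes$percent, validation$annotations$percent)

  selection <- stage("icp",
    icp_select(itres, frs$key_proteins,
               coverage_target = config$coverage_target))
  write_tsv(selection$picks, out("icp_picks.tsv"))
  write_tsv(coverage_curve(selection), out("icp_curve.tsv"))
  say("ICP: %d picks, achieved coverage %.2f%%", nrow(selection$picks),
      100 * selection$achieved_coverage)

  report <- list(
    config = unclass(config),
    counts = list(
      n_ingredients = nrow(decisions),
      n_retained = sum(decisions$retained),
      disease_nodes = nrow(disease$nodes),
      disease_edges = nrow(disease$edges),
      dropped_genes = length(dres$dropped),
      it_associations = itres$n_associations,
      mean_targets = itres$mean_targets,
      merged_nodes = nrow(merged$nodes),
      merged_edges = nrow(merged$edges),
      frs_size = length(frs$kept),
      n_key_proteins = length(frs$key_proteins),
      subtype_counts = as.list(table(frs$subtype)),
      n_uet = length(uet),
      uet_gene_coverage_pct = validation$genes$percent,
      term_coverage_pct = validation$annotations$percent,
      cfig_size = nrow(selection$picks),
      achieved_coverage = selection$achieved_coverage
    ),
    frs_threshold = frs$threshold_value,
    timestamp = format(Sys.time(), tz = "UTC")
  )
  check_report(report, config$out_dir)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  yaml::write_yaml(unclass(config), out("config_resolved.yaml"))
  invisible(report)
}

# Cross-check the report's counts against the written intermediates.
check_report <- function(report, out_dir) {
  p <- function(f) file.path(out_dir, f)
  stopifnot(
    report$counts$n_ingredients ==
      nrow(read.delim(p("filter_decisions.tsv"))),
    report$counts$disease_nodes == nrow(read.delim(p("disease_nodes.tsv"))),
    report$counts$merged_edges == nrow(read.delim(p("merged_edges.tsv"))),
    report$counts$cfig_size == nrow(read.delim(p("icp_picks.tsv"))),
    report$counts$frs_size == sum(read.delim(p("nim.tsv"))$kept)
  )
  invisible(TRUE)
}

#' Planted-recovery benchmark over synthetic studies
#'
#' Runs the generator and the full analytical chain (ADME filter,
#' networks, Nim, FRS, ICP) over a series of seeds and measures (a) the
#' recovery of planted critical ingredients among the first `|planted|`
#' ICP picks and (b) whether the planted disease-module hubs (the
#' `n_hubs` module genes of highest base-network degree) land in the top
#' Nim decile of the merged network's gene nodes (proteins are ranked
#' against proteins; ingredient nodes score on a different scale).
#'
#' The FRS step uses the `"mean"` threshold here: the key-protein space
#' must be large enough that several ingredients are needed to cover it,
#' and a mean threshold on the heavy-tailed importance score keeps the
#' informative upper tail without collapsing to a handful of extreme
#' hubs.  ICP runs to exhaustion (`coverage_target = 1`) so the greedy
#' trace is long enough to score.
#'
#' @param config a `cfig_study_config`; its `seed` is replaced by each
#'   benchmark seed in turn.
#' @param seeds integer vector of study seeds.
#' @param n_hubs module hubs checked per study.
#' @return data.frame with one row per seed: `seed`, `recovery`
#'   (fraction of planted ingredients in the first `|planted|` picks),
#'   `hubs_in_top_decile` (logical: all `n_hubs` hubs in the top Nim
#'   decile), `frs_size`, `n_picks`.
#' @export
planted_recovery_benchmark <- function(config = study_config(),
                                       seeds = 1:20, n_hubs = 3) {
  rows <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    study <- generate_study(cfg)
    decisions <- filter_ingredients(study$ingredients)
    retained <- decisions$ingredient_id[decisions$retained]
    assoc <- study$associations[
      study$associations$ingredient_id %in% retained, , drop = FALSE]
    disease <- build_disease_network(study$base_ppi, study$evidence)$network
    itres <- build_it_network(retained, assoc)
    merged <- merge_networks(disease, itres$network,
                             base_ppi = study$base_ppi)
    nim <- compute_nim(merged, assign_communities(merged))
    frs <- select_frs(nim, merged, mode = "mean")
    sel <- icp_select(itres, frs$key_proteins, coverage_target = 1)
    rec <- recovery_score(sel, study$planted_critical_ids)

    deg <- igraph::degree(igraph::graph_from_data_frame(study$base_ppi,
                                                        directed = FALSE))
    hubs <- names(sort(deg[study$planted_disease_module],
                       decreasing = TRUE))[seq_len(n_hubs)]
    gene_nim <- nim[nim$id %in% merged$nodes$id[merged$nodes$role == "gene"], ]
    decile <- gene_nim$id[gene_nim$nim >= stats::quantile(gene_nim$nim, 0.9)]
    data.frame(seed = s, recovery = rec,
               hubs_in_top_decile = all(hubs %in% decile),
               frs_size = length(frs$kept), n_picks = nrow(sel$picks))
  })
  do.call(rbind, rows)
}
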