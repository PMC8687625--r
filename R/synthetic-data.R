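#' Configuration for a synthetic network-pharmacology study
#'
#' Defines the conditions of a generated study: a scale-free base
#' interactome, a disease module with skewed literature evidence, a panel
#' of ingredients whose target sets are either concentrated on the
#' planted disease module (the planted critical ingredients) or diffuse
#' (decoys), and annotation terms aligned to network neighborhoods.
#'
#' Defaults mirror a desk-scale version of a real study, keeping the
#' *proportions* of the full-size setting: a 200-gene interactome, a
#' 60-gene disease module (30% of the universe; in real weighted disease
#' networks the mapped pathogenetic genes are an even larger share of the
#' merged network), 30 ingredients of which 5 are planted critical, ~8
#' targets per ingredient (4% of the gene universe, matching the
#' per-ingredient density of real ingredient-target networks), and about
#' 30% of decoys drawn to fail the ADME filter (retention of candidate
#' ingredients is typically a minority-to-majority split).
#'
#' @param n_genes genes in the base interactome.
#' @param n_disease_genes size of the planted disease module.
#' @param n_ingredients total ingredients.
#' @param n_planted_critical planted critical ingredients
#'   (`<= n_ingredients`; may be 0).
#' @param n_terms annotation terms.
#' @param mean_targets_per_ingredient mean target-set size.
#' @param ppi_attachment preferential-attachment parameter (edges added
#'   per new node); produces the hub-dominated degree distribution the
#'   importance score exploits.
#' @param evidence_dispersion mean of the shifted negative-binomial
#'   literature-count distribution; most genes get 1-2 reports, a few get
#'   many.
#' @param module_cover_fraction fraction of the disease module guaranteed
#'   to be covered by the union of planted-critical target sets.
#' @param adme_fail_rate fraction of decoy ingredients drawn to fail the
#'   ADME filter.
#' @param seed integer RNG seed; the whole study derives from one stream.
#' @return list of class `cfig_study_config`.
#' @export
study_config <- function(n_genes = 200, n_disease_genes = 60,
                         n_ingredients = 30, n_planted_critical = 5,
                         n_terms = 25, mean_targets_per_ingredient = 8,
                         ppi_attachment = 3, evidence_dispersion = 2,
                         module_cover_fraction = 0.9, adme_fail_rate = 0.3,
                         seed = 1L) {
  cfg <- list(n_genes = n_genes, n_disease_genes = n_disease_genes,
              n_ingredients = n_ingredients,
              n_planted_critical = n_planted_critical, n_terms = n_terms,
              mean_targets_per_ingredient = mean_targets_per_ingredient,
              ppi_attachment = ppi_attachment,
              evidence_dispersion = evidence_dispersion,
              module_cover_fraction = module_cover_fraction,
              adme_fail_rate = adme_fail_rate, seed = as.integer(seed))
  for (f in c("n_genes", "n_disease_genes", "n_ingredients", "n_terms")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1) {
      stop_cfig("invalid config: %s must be a count >= 1", f,
                class = "cfig_config_error")
    }
  }
  if (cfg$n_planted_critical < 0) {
    stop_cfig("invalid config: n_planted_critical must be >= 0",
              class = "cfig_config_error")
  }
  if (cfg$n_planted_critical > cfg$n_ingredients) {
    stop_cfig("invalid config: n_planted_critical exceeds n_ingredients",
              class = "cfig_config_error")
  }
  if (cfg$n_disease_genes > cfg$n_genes) {
    stop_cfig("invalid config: n_disease_genes exceeds n_genes",
              class = "cfig_config_error")
  }
  for (f in c("mean_targets_per_ingredient", "ppi_attachment",
              "evidence_dispersion")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop_cfig("invalid config: %s must be positive", f,
                class = "cfig_config_error")
    }
  }
  structure(cfg, class = "cfig_study_config")
}

HERB_CODES <- c("CS", "CX", "DS", "DG", "HH")

#' Generate a synthetic study
#'
#' Deterministic for a fixed config (a single RNG stream seeded once).
#' The base interactome is grown by preferential attachment; the disease
#' module is sampled with degree-proportional probability so it contains
#' hubs; literature counts follow a shifted negative binomial and
#' relevance scores a log-normal; planted critical ingredients split a
#' guaranteed-covered core of the module between them and concentrate
#' their remaining targets on the module, while decoy targets are drawn
#' uniformly from all genes; annotation terms are gene sets of size >= 3
#' drawn from 2-step network neighborhoods, half of them centered inside
#' the module.
#'
#' @param config a `cfig_study_config`.
#' @return list of class `cfig_study` with elements `config`, `base_ppi`
#'   (edge data.frame), `evidence`, `ingredients`, `associations`,
#'   `annotations` (named list), `planted_critical_ids`,
#'   `planted_disease_module`.
#' @export
generate_study <- function(config = study_config()) {
  stopifnot(inherits(config, "cfig_study_config"))
  with_seed(config$seed, generate_study_impl(config))
}

generate_study_impl <- function(cfg) {
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  g <- igraph::sample_pa(cfg$n_genes, m = cfg$ppi_attachment,
                         directed = FALSE)
  igraph::V(g)$name <- genes
  ppi <- igraph::as_data_frame(g, what = "edges")
  names(ppi) <- c("from", "to")
  ppi <- canonical_edges(ppi, warn_loops = FALSE)
  deg <- igraph::degree(g)

  # literature-curated disease-gene sets are strongly biased toward
  # central, well-studied genes (in inflammatory disease the interactome's
  # top hubs are themselves pathogenetic): the module takes the top of the
  # degree distribution plus a degree-squared-weighted sample of the rest
  n_top <- min(ceiling(cfg$n_disease_genes / 4), cfg$n_disease_genes)
  top_hubs <- genes[order(-deg[genes])][seq_len(n_top)]
  rest_pool <- setdiff(genes, top_hubs)
  module <- c(top_hubs,
              sample(rest_pool, cfg$n_disease_genes - n_top,
                     prob = deg[rest_pool]^2))
  n_mod <- length(module)
  evidence <- data.frame(
    gene = module,
    n_reports = 1L + rnbinom(n_mod, size = 0.6, mu = cfg$evidence_dispersion),
    relevance_score = round(rlnorm(n_mod, meanlog = 0.8, sdlog = 0.9), 2),
    source = "synthetic",
    stringsAsFactors = FALSE
  )

  n_ing <- cfg$n_ingredients
  ing_ids <- sprintf("ING%03d", seq_len(n_ing))
  planted <- if (cfg$n_planted_critical > 0) {
    sort(sample(ing_ids, cfg$n_planted_critical))
  } else {
    character(0)
  }
  decoys <- setdiff(ing_ids, planted)

  # planted critical ingredients split a guaranteed-covered module core
  core <- sample(module)[seq_len(ceiling(cfg$module_cover_fraction * n_mod))]
  chunks <- if (length(planted) > 0) {
    split(core, rep_len(seq_along(planted), length(core)))
  } else {
    list()
  }
  sizes <- pmax(1L, rpois(n_ing, cfg$mean_targets_per_ingredient))
  names(sizes) <- ing_ids
  assoc <- lapply(ing_ids, function(id) {
    if (id %in% planted) {
      # an exclusive slice of the module core plus a generic tail: the
      # planted set is concentrated on the module and the slices do not
      # overlap, so each planted ingredient has its own marginal value
      base <- chunks[[match(id, planted)]]
      extra <- max(0L, sizes[[id]] - length(base))
      tgt <- c(base, sample(setdiff(genes, base), extra))
    } else {
      tgt <- sample(genes, min(sizes[[id]], length(genes)))
    }
    data.frame(ingredient_id = id, target_gene = unique(tgt),
               stringsAsFactors = FALSE)
  })
  assoc <- do.call(rbind, assoc)

  fail <- setNames(rep(FALSE, n_ing), ing_ids)
  fail[decoys] <- runif(length(decoys)) < cfg$adme_fail_rate
  caco2 <- ifelse(fail, runif(n_ing, -2, -0.45), runif(n_ing, -0.35, 2))
  dl <- ifelse(fail & runif(n_ing) < 0.5, runif(n_ing, 0, 0.17),
               runif(n_ing, 0.18, 0.85))
  ingredients <- data.frame(
    ingredient_id = ing_ids,
    name = sprintf("compound-%03d", seq_len(n_ing)),
    caco2 = round(caco2, 2),
    dl = round(dl, 2),
    literature_flag = runif(n_ing) < 0.1,
    stringsAsFactors = FALSE
  )
  ingredients$herbs <- lapply(seq_len(n_ing), function(i) {
    sort(sample(HERB_CODES, sample(1:2, 1)))
  })

  annotations <- list()
  for (t in seq_len(cfg$n_terms)) {
    centered_in_module <- t %% 2 == 0 && n_mod > 0
    center <- if (centered_in_module) sample(module, 1) else
      sample(genes, 1, prob = deg[genes])
    ball <- names(igraph::ego(g, order = 2, nodes = center)[[1]])
    if (length(ball) < 3) {
      ball <- unique(c(ball, sample(genes, 3)))
    }
    size <- sample(3:min(15, length(ball)), 1)
    annotations[[sprintf("TERM%03d", t)]] <- sort(sample(ball, size))
  }
  attr(annotations, "description") <- setNames(
    sprintf("synthetic term %d", seq_len(cfg$n_terms)), names(annotations))

  structure(list(
    config = cfg,
    base_ppi = ppi,
    evidence = evidence,
    ingredients = ingredients,
    associations = assoc,
    annotations = annotations,
    planted_critical_ids = planted,
    planted_disease_module = module
  ), class = "cfig_study")
}

#' @export
print.cfig_study <- function(x, ...) {
  cat(sprintf(paste0("<cfig_study> %d genes (%d edges), %d disease genes, ",
                     "%d ingredients (%d planted), %d associations, %d terms\n"),
              x$config$n_genes, nrow(x$base_ppi), nrow(x$evidence),
              nrow(x$ingredients), length(x$planted_critical_ids),
              nrow(x$associations), length(x$annotations)))
  invisible(x)
}

#' Write a study to disk in the pipeline's on-disk formats
#'
#' Emits `ppi.tsv`, `evidence.tsv`, `ingredients.tsv`,
#' `associations.tsv`, and `annotations.gmt` under `directory`; these
#' round-trip losslessly through the `read_*` functions.
#'
#' @param study a `cfig_study`.
#' @param directory output directory (created if needed).
#' @return data.frame manifest (`file`, `bytes`), invisibly.
#' @export
write_study <- function(study, directory) {
  stopifnot(inherits(study, "cfig_study"))
  ok <- dir.exists(directory) || dir.create(directory, recursive = TRUE,
                                            showWarnings = FALSE)
  if (!ok || file.access(directory, 2) != 0) {
    stop_cfig("directory not writable: %s", directory, class = "cfig_io_error")
  }
  p <- function(f) file.path(directory, f)
  write_tsv(study$base_ppi, p("ppi.tsv"))
  write_tsv(study$evidence, p("evidence.tsv"))
  ing <- study$ingredients
  ing$herbs <- vapply(ing$herbs, paste, character(1), collapse = ";")
  ing <- ing[, c("ingredient_id", "name", "herbs", "caco2", "dl",
                 "literature_flag")]
  write_tsv(ing, p("ingredients.tsv"))
  write_tsv(study$associations, p("associations.tsv"))
  write_gmt(study$annotations, p("annotations.gmt"))
  files <- c("ppi.tsv", "evidence.tsv", "ingredients.tsv",
             "associations.tsv", "annotations.gmt")
  manifest <- data.frame(file = files,
                         bytes = file.size(file.path(directory, files)))
  invisible(manifest)
}

#' Read a study directory back into memory
#'
#' Counterpart of [write_study()]; planted-structure metadata is not part
#' of the on-disk formats and is therefore absent from the result.
#'
#' @param directory directory containing the five study files.
#' @return list with `base_ppi`, `evidence`, `ingredients`,
#'   `associations`, `annotations`.
#' @export
read_study <- function(directory) {
  p <- function(f) file.path(directory, f)
  list(
    base_ppi = read_network(p("ppi.tsv")),
    evidence = read_evidence(p("evidence.tsv")),
    ingredients = read_ingredients(p("ingredients.tsv")),
    associations = read_associations(p("associations.tsv")),
    annotations = read_gmt(p("annotations.gmt"))
  )
}
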