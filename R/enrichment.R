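#' Hypergeometric term enrichment
#'
#' For each annotation term, tests over-representation of the query gene
#' set with the exact upper-tail hypergeometric probability
#' `P(X >= k)` where `k` is the query/term overlap, `K` the term size
#' within the background, `n` the query size, and `N` the background
#' size.  No multiple-testing correction is applied by default (raw
#' p-values against `alpha`); Benjamini-Hochberg is available via
#' `adjust = "BH"`.
#'
#' @param query_genes character query gene set; must be a subset of
#'   `background`.
#' @param annotations named list of gene sets (see [read_gmt()]).
#' @param background character background gene universe.
#' @param alpha significance level; significance is strict (`p < alpha`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame sorted by ascending p-value, one row per term with a
#'   nonzero background intersection: `term_id`, `term_size`,
#'   `query_size`, `overlap`, `background_size`, `p_value` (and
#'   `p_adjusted` if requested), `significant`.
#' @export
#' @examples
#' anns <- list(T1 = c("A", "B", "C"), T2 = c("D", "E", "F"))
#' enrich(c("A", "B"), anns, background = LETTERS[1:10])
enrich <- function(query_genes, annotations, background, alpha = 0.05,
                   adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  query_genes <- unique(as.character(query_genes))
  background <- unique(as.character(background))
  if (length(query_genes) == 0 || length(background) == 0) {
    stop_cfig("query and background must be nonempty",
              class = "cfig_validation_error")
  }
  outside <- setdiff(query_genes, background)
  if (length(outside) > 0) {
    stop_cfig("query gene(s) outside the background: %s",
              paste(utils::head(outside, 5), collapse = ", "),
              class = "cfig_validation_error")
  }
  N <- length(background)
  n <- length(query_genes)
  rows <- lapply(names(annotations), function(id) {
    term <- intersect(annotations[[id]], background)
    K <- length(term)
    if (K == 0) return(NULL)
    k <- length(intersect(term, query_genes))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = id, term_size = K, query_size = n, overlap = k,
               background_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(term_id = character(0), term_size = integer(0),
                      query_size = integer(0), overlap = integer(0),
                      background_size = integer(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  if (adjust == "BH") {
    out$p_adjusted <- p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjusted < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out
}

#' Coverage of a reference term (or gene) set by a query set
#'
#' `coverage = |reference ∩ query| / |reference|`, also reported as a
#' percentage rounded to two decimals (the scale on which such coverages
#' are usually quoted).
#'
#' @param reference,query character vectors of identifiers (e.g.
#'   significant term ids, or gene sets).
#' @return list of class `cfig_coverage`: `n_reference`, `n_query`,
#'   `shared`, `coverage` (in `[0, 1]`), `percent`.
#' @export
coverage_report <- function(reference, query) {
  reference <- unique(as.character(reference))
  query <- unique(as.character(query))
  if (length(reference) == 0) {
    warning("empty reference set: coverage is 0", call. = FALSE)
    cov <- 0
    shared <- 0L
  } else {
    shared <- length(intersect(reference, query))
    cov <- shared / length(reference)
  }
  structure(list(n_reference = length(reference), n_query = length(query),
                 shared = shared, coverage = cov,
                 percent = round(100 * cov, 2)),
            class = "cfig_coverage")
}

#' @export
print.cfig_coverage <- function(x, ...) {
  cat(sprintf("<cfig_coverage> %d/%d shared = %.2f%%\n",
              x$shared, x$n_reference, x$percent))
  invisible(x)
}

significant_terms <- function(enrichment) {
  enrichment$term_id[enrichment$significant]
}

#' Validate key response proteins against the UET reference
#'
#' Computes the three evaluation indicators comparing the key response
#' proteins with the un-optimized effective targets (UETs): (1) gene-set
#' coverage `|key ∩ UET| / |UET|`; (2) coverage of the UET-enriched terms
#' of a pathway-like collection by the key-protein-enriched terms; (3) the
#' same for a GO-like collection.
#'
#' @param key_proteins character key response protein set.
#' @param uet character reference set from [compute_uet()].
#' @param annotations named list of two annotation collections, e.g.
#'   `list(pathway = ..., go = ...)`; each as from [read_gmt()].
#' @param background character background gene universe.
#' @param alpha enrichment significance level.
#' @return named list of `cfig_coverage` reports: `genes`, then one per
#'   annotation collection.
#' @export
evaluate_frs <- function(key_proteins, uet, annotations, background,
                         alpha = 0.05) {
  if (length(key_proteins) == 0 || length(uet) == 0) {
    stop_cfig("key proteins and UET must be nonempty",
              class = "cfig_validation_error")
  }
  out <- list(genes = coverage_report(uet, key_proteins))
  for (nm in names(annotations)) {
    ref <- significant_terms(
      enrich(intersect(uet, background), annotations[[nm]], background, alpha))
    qry <- significant_terms(
      enrich(intersect(key_proteins, background), annotations[[nm]],
             background, alpha))
    out[[nm]] <- coverage_report(ref, qry)
  }
  out
}
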