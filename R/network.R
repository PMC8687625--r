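#' Weighted undirected network container
#'
#' A light container used for every network in the pipeline: a node table
#' (`id`, `role`, `weight`) plus an undirected simple edge list.  Self-loops
#' are dropped and duplicate edges (in either orientation) collapsed at
#' construction, so a `cfig_network` is always simple.
#'
#' @param nodes data.frame with columns `id`, `role` (`"gene"` or
#'   `"ingredient"`) and nonnegative `weight`.
#' @param edges data.frame with columns `from`, `to` referencing node ids.
#' @return object of class `cfig_network`.
#' @export
weighted_network <- function(nodes, edges) {
  nodes <- data.frame(
    id = as.character(nodes$id),
    role = as.character(nodes$role),
    weight = as.numeric(nodes$weight),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(nodes$id)) {
    stop_cfig("duplicate node id(s): %s",
              paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "),
              class = "cfig_validation_error")
  }
  if (any(nodes$weight < 0)) {
    stop_cfig("node weights must be nonnegative", class = "cfig_validation_error")
  }
  edges <- canonical_edges(edges, warn_loops = FALSE)
  missing <- setdiff(c(edges$from, edges$to), nodes$id)
  if (length(missing) > 0) {
    stop_cfig("edge endpoint(s) not in node table: %s",
              paste(utils::head(missing, 5), collapse = ", "),
              class = "cfig_validation_error")
  }
  structure(list(nodes = nodes, edges = edges), class = "cfig_network")
}

# Canonicalize an undirected edge list: character endpoints, self-loops
# removed, each unordered pair kept once with from <= to, rows sorted.
canonical_edges <- function(edges, warn_loops = TRUE) {
  from <- as.character(edges$from)
  to <- as.character(edges$to)
  loops <- from == to
  if (any(loops) && warn_loops) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)), call. = FALSE)
  }
  from2 <- pmin(from[!loops], to[!loops])
  to2 <- pmax(from[!loops], to[!loops])
  key <- paste(from2, to2, sep = "\r")
  keep <- !duplicated(key)
  out <- data.frame(from = from2[keep], to = to2[keep], stringsAsFactors = FALSE)
  out[order(out$from, out$to), , drop = FALSE]
}

#' @export
print.cfig_network <- function(x, ...) {
  cat(sprintf("<cfig_network> %d nodes (%d gene, %d ingredient), %d edges\n",
              nrow(x$nodes), sum(x$nodes$role == "gene"),
              sum(x$nodes$role == "ingredient"), nrow(x$edges)))
  invisible(x)
}

#' Convert a cfig_network to an igraph object
#'
#' @param net a `cfig_network`.
#' @return an undirected `igraph` graph with `role` and `weight` vertex
#'   attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "cfig_network"))
  igraph::graph_from_data_frame(net$edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Build the weighted disease gene regulatory network
#'
#' Maps literature-evidence genes onto a base protein-protein interaction
#' network and weights each mapped gene by the product of its degree in the
#' induced subgraph, its relevance score, and its literature report count.
#' Evidence genes absent from the base network are returned in a drop list.
#'
#' A missing relevance score, or a zero report count, is replaced by
#' `default_score` (multiplicative identity by default) so a single missing
#' evidence channel never annihilates the weight.
#'
#' @param base_ppi data.frame edge list (`from`, `to`) of the undirected base
#'   interactome.
#' @param evidence data.frame of gene evidence as returned by
#'   [read_evidence()]: columns `gene`, `n_reports`, `relevance_score`.
#' @param default_score replacement for missing relevance / zero report count.
#' @return list with elements `network` (a `cfig_network` of role-`gene`
#'   nodes) and `dropped` (character vector of unmappable evidence genes).
#' @export
#' @examples
#' ppi <- data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"))
#' ev <- data.frame(gene = c("A", "B", "D"), n_reports = c(2, 0, 1),
#'                  relevance_score = c(5, NA, 1))
#' build_disease_network(ppi, ev)$network$nodes
build_disease_network <- function(base_ppi, evidence, default_score = 1.0) {
  if (is.null(base_ppi) || nrow(base_ppi) == 0) {
    stop_cfig("base PPI network is empty", class = "cfig_validation_error")
  }
  edges <- canonical_edges(base_ppi)
  ppi_nodes <- unique(c(edges$from, edges$to))
  genes <- as.character(evidence$gene)
  mapped <- genes[genes %in% ppi_nodes]
  dropped <- genes[!genes %in% ppi_nodes]
  if (length(mapped) == 0) {
    stop_cfig("no mappable genes: evidence and base PPI do not intersect",
              class = "cfig_no_mappable_genes")
  }
  sub <- edges[edges$from %in% mapped & edges$to %in% mapped, , drop = FALSE]
  deg <- table(factor(c(sub$from, sub$to), levels = mapped))
  ev <- evidence[match(mapped, evidence$gene), , drop = FALSE]
  rel <- ifelse(is.na(ev$relevance_score) | ev$relevance_score <= 0,
                default_score, ev$relevance_score)
  rep_n <- ifelse(is.na(ev$n_reports) | ev$n_reports == 0,
                  default_score, ev$n_reports)
  nodes <- data.frame(
    id = mapped,
    role = "gene",
    weight = as.numeric(deg[mapped]) * rel * rep_n,
    stringsAsFactors = FALSE
  )
  list(network = weighted_network(nodes, sub), dropped = dropped)
}

#' Build the ingredient-target (I-T) bipartite network
#'
#' @param retained character vector of retained ingredient ids (e.g. from
#'   [filter_ingredients()]), or a data.frame of filter decisions with
#'   `ingredient_id` and `retained` columns.
#' @param associations data.frame with columns `ingredient_id`,
#'   `target_gene`.
#' @return list with elements `network` (a strictly bipartite
#'   `cfig_network`), `target_counts` (named integer vector per retained
#'   ingredient with >= 1 target), `mean_targets` (mean target count,
#'   the average I-T degree of an ingredient), and `n_associations`.
#' @export
build_it_network <- function(retained, associations) {
  if (is.data.frame(retained)) {
    retained <- retained$ingredient_id[retained$retained]
  }
  retained <- as.character(retained)
  assoc <- data.frame(
    ingredient_id = as.character(associations$ingredient_id),
    target_gene = as.character(associations$target_gene),
    stringsAsFactors = FALSE
  )
  unknown <- setdiff(assoc$ingredient_id, retained)
  if (length(unknown) > 0) {
    stop_cfig("association(s) reference unknown ingredient(s): %s",
              paste(utils::head(unknown, 5), collapse = ", "),
              class = "cfig_validation_error")
  }
  assoc <- unique(assoc)
  zero <- setdiff(retained, assoc$ingredient_id)
  if (length(zero) > 0) {
    warning(sprintf("%d ingredient(s) with zero targets excluded: %s",
                    length(zero), paste(utils::head(zero, 5), collapse = ", ")),
            call. = FALSE)
  }
  kept <- intersect(retained, assoc$ingredient_id)
  counts <- table(factor(assoc$ingredient_id, levels = kept))
  nodes <- data.frame(
    id = c(kept, unique(assoc$target_gene)),
    role = c(rep("ingredient", length(kept)),
             rep("gene", length(unique(assoc$target_gene)))),
    weight = 0,
    stringsAsFactors = FALSE
  )
  edges <- data.frame(from = assoc$ingredient_id, to = assoc$target_gene,
                      stringsAsFactors = FALSE)
  list(
    network = weighted_network(nodes, edges),
    target_counts = setNames(as.integer(counts), kept),
    mean_targets = nrow(assoc) / length(kept),
    n_associations = nrow(assoc)
  )
}

#' Merge the disease network and the I-T network
#'
#' Node union (gene nodes merged by id, keeping the disease-network weight
#' where one exists) and edge union.  Ingredient nodes keep role
#' `"ingredient"` and weight 0.  The merge is idempotent and commutative in
#' node and edge sets.
#'
#' When the base interactome is supplied, its edges among *all* gene
#' nodes of the merged network are retained (not only the edges induced
#' on the disease set), so ingredient targets outside the disease set stay
#' embedded in their interaction context rather than hanging off
#' ingredient nodes alone.
#'
#' @param disease `cfig_network` from [build_disease_network()].
#' @param it `cfig_network` from [build_it_network()].
#' @param base_ppi optional data.frame edge list of the base interactome;
#'   its edges induced on the merged gene set are added.
#' @param default_weight weight for gene nodes absent from the disease
#'   network.
#' @return a `cfig_network`.
#' @export
merge_networks <- function(disease, it, base_ppi = NULL, default_weight = 0) {
  stopifnot(inherits(disease, "cfig_network"), inherits(it, "cfig_network"))
  ids <- unique(c(disease$nodes$id, it$nodes$id))
  d_idx <- match(ids, disease$nodes$id)
  i_idx <- match(ids, it$nodes$id)
  role <- ifelse(!is.na(d_idx), disease$nodes$role[d_idx],
                 it$nodes$role[i_idx])
  weight <- ifelse(!is.na(d_idx), disease$nodes$weight[d_idx],
                   ifelse(role == "gene", default_weight,
                          it$nodes$weight[i_idx]))
  nodes <- data.frame(id = ids, role = role, weight = weight,
                      stringsAsFactors = FALSE)
  edges <- rbind(disease$edges, it$edges)
  if (!is.null(base_ppi)) {
    ppi <- canonical_edges(base_ppi, warn_loops = FALSE)
    gene_ids <- nodes$id[nodes$role == "gene"]
    edges <- rbind(edges, ppi[ppi$from %in% gene_ids & ppi$to %in% gene_ids,
                              , drop = FALSE])
  }
  weighted_network(nodes, edges)
}
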