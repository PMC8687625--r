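#' Node importance (Nim) scoring and the functional response space
#'
#' The importance of a node `s` is the product of two factors:
#'
#' * a **betweenness term**: the sum over unordered connected pairs
#'   `a != b` (both distinct from `s`) of the fraction of shortest `a`-`b`
#'   paths that pass through `s` (unnormalized betweenness centrality);
#' * a squared **community-proximity factor**:
#'   `[(|C(s)|/|U|) * sum_w (D_s + 1 - dist(s, w)) / D_s]^2`, where `C(s)`
#'   is the community containing `s`, `U` the full node set, `w` ranges
#'   over the reachable members of `C(s)` other than `s`, and `D_s` is the
#'   eccentricity of `s` within its community.  A node rewarded by this
#'   factor sits close to many members of a large community.
#'
#' Pairs in different components contribute nothing to the betweenness
#' term; a node whose community holds no other reachable member gets
#' factor 0.
#'
#' @name node_importance
NULL

# Adjacency list (integer indices) of a cfig_network, in node-table order.
adjacency_list <- function(net) {
  n <- nrow(net$nodes)
  idx <- setNames(seq_len(n), net$nodes$id)
  adj <- vector("list", n)
  if (nrow(net$edges) > 0) {
    f <- idx[net$edges$from]
    t <- idx[net$edges$to]
    for (k in seq_along(f)) {
      adj[[f[k]]] <- c(adj[[f[k]]], t[k])
      adj[[t[k]]] <- c(adj[[t[k]]], f[k])
    }
  }
  adj
}

# Brandes accumulation of the shortest-path pair sum (unordered-pair
# betweenness, unweighted undirected graph).
brandes_betweenness <- function(adj) {
  n <- length(adj)
  btw <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n)
    sigma[s] <- 1
    dist <- rep.int(-1L, n)
    dist[s] <- 0L
    preds <- vector("list", n)
    queue <- integer(n)
    queue[1] <- s
    head <- 1L
    tail <- 1L
    visited <- integer(n)
    nv <- 0L
    while (head <= tail) {
      v <- queue[head]
      head <- head + 1L
      nv <- nv + 1L
      visited[nv] <- v
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (i in rev(seq_len(nv))) {
      w <- visited[i]
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (w != s) btw[w] <- btw[w] + delta[w]
    }
  }
  btw / 2
}

#' Assign nodes to communities
#'
#' Either connected components (deterministic, the default used by the
#' Nim score) or Louvain modularity maximization (seeded).
#'
#' @param network a `cfig_network`.
#' @param method `"connected_components"` or `"modularity"`.
#' @param seed RNG seed used by the modularity method.
#' @return data.frame (`id`, `community`) covering every node, with a
#'   `method` attribute.
#' @export
assign_communities <- function(network,
                               method = c("connected_components", "modularity"),
                               seed = 1L) {
  method <- match.arg(method)
  g <- as_igraph(network)
  membership <- switch(
    method,
    connected_components = igraph::components(g)$membership,
    modularity = with_seed(seed, igraph::membership(igraph::cluster_louvain(g)))
  )
  out <- data.frame(id = network$nodes$id,
                    community = as.integer(membership[network$nodes$id]),
                    stringsAsFactors = FALSE)
  attr(out, "method") <- method
  out
}

#' Compute the Nim node-importance table
#'
#' @param network a `cfig_network`.
#' @param communities assignment from [assign_communities()]; must cover
#'   every network node.
#' @return data.frame with one row per node: `id`, `community`,
#'   `betweenness_term`, `community_factor`, `nim`
#'   (`nim = betweenness_term * community_factor`).
#' @export
#' @examples
#' net <- weighted_network(
#'   data.frame(id = c("A", "B", "C"), role = "gene", weight = 0),
#'   data.frame(from = c("A", "B"), to = c("B", "C")))
#' compute_nim(net, assign_communities(net))  # path center scores 1 x 4
compute_nim <- function(network, communities) {
  ids <- network$nodes$id
  missing <- setdiff(ids, communities$id)
  if (length(missing) > 0) {
    stop_cfig("node(s) missing from community assignment: %s",
              paste(utils::head(missing, 5), collapse = ", "),
              class = "cfig_validation_error")
  }
  n <- length(ids)
  comm <- communities$community[match(ids, communities$id)]
  btw <- brandes_betweenness(adjacency_list(network))
  d <- if (nrow(network$edges) > 0) {
    igraph::distances(as_igraph(network))[ids, ids, drop = FALSE]
  } else {
    m <- matrix(Inf, n, n, dimnames = list(ids, ids))
    diag(m) <- 0
    m
  }
  factor <- numeric(n)
  for (i in seq_len(n)) {
    members <- which(comm == comm[i])
    others <- setdiff(members, i)
    dist_i <- d[i, others]
    reach <- dist_i[is.finite(dist_i)]
    if (length(reach) == 0) {
      factor[i] <- 0
      next
    }
    ecc <- max(reach)
    prox_sum <- sum(ecc + 1 - reach)
    factor[i] <- ((length(members) / n) * prox_sum / ecc)^2
  }
  data.frame(
    id = ids,
    community = comm,
    betweenness_term = btw,
    community_factor = factor,
    nim = btw * factor,
    stringsAsFactors = FALSE
  )
}

#' Baseline node centralities
#'
#' Textbook centralities used to benchmark the Nim score: degree, closeness
#' (Wasserman-Faust component-scaled variant, so disconnected graphs are
#' handled), and the local clustering coefficient (0 for nodes of degree
#' < 2).
#'
#' @param network a `cfig_network`.
#' @param method one of `"degree"`, `"closeness"`,
#'   `"clustering_coefficient"`.
#' @return data.frame (`id`, `score`).
#' @export
baseline_centrality <- function(network,
                                method = c("degree", "closeness",
                                           "clustering_coefficient")) {
  method <- match.arg(method)
  ids <- network$nodes$id
  g <- as_igraph(network)
  score <- switch(
    method,
    degree = as.numeric(igraph::degree(g)[ids]),
    closeness = {
      n <- length(ids)
      d <- igraph::distances(g)[ids, ids, drop = FALSE]
      vapply(seq_len(n), function(i) {
        di <- d[i, -i]
        reach <- di[is.finite(di)]
        if (length(reach) == 0 || n == 1) return(0)
        (length(reach) / (n - 1)) * (length(reach) / sum(reach))
      }, numeric(1))
    },
    clustering_coefficient = {
      tr <- igraph::transitivity(g, type = "local", isolates = "zero")
      as.numeric(tr[match(ids, igraph::V(g)$name)])
    }
  )
  data.frame(id = ids, score = score, stringsAsFactors = FALSE)
}

#' Extract the functional response space (FRS)
#'
#' Thresholds the Nim scores and keeps every node at or above the
#' threshold.  The default threshold is the midpoint of the score range,
#' `(min + max) / 2`; `"mean"` and `"median"` are provided because a
#' central threshold (nodes above the *average* importance) is the other
#' natural reading of the selection rule and yields a roughly half-sized
#' space on heavy-tailed scores.
#'
#' @param nim Nim table from [compute_nim()].
#' @param network optional `cfig_network`; if given, the induced subgraph
#'   edges are returned and kept gene nodes are subtyped.
#' @param mode `"midpoint"` (default), `"mean"`, or `"median"`.
#' @param disease_genes,target_genes optional gene sets used to subtype
#'   kept gene nodes via [classify_key_proteins()].
#' @return list of class `cfig_frs`: `threshold_value`, `threshold_mode`,
#'   `kept` (node ids), `edges` (induced edge list or NULL), `subtype`
#'   (named character vector over kept gene nodes, or NULL), and
#'   `key_proteins` (kept gene-node ids, or `kept` when roles are
#'   unavailable).
#' @export
select_frs <- function(nim, network = NULL,
                       mode = c("midpoint", "mean", "median"),
                       disease_genes = NULL, target_genes = NULL) {
  mode <- match.arg(mode)
  if (nrow(nim) == 0) {
    stop_cfig("empty Nim table", class = "cfig_validation_error")
  }
  threshold <- switch(mode,
    midpoint = (min(nim$nim) + max(nim$nim)) / 2,
    mean = mean(nim$nim),
    median = median(nim$nim)
  )
  kept <- nim$id[nim$nim >= threshold]
  edges <- NULL
  subtype <- NULL
  key <- kept
  if (!is.null(network)) {
    edges <- network$edges[network$edges$from %in% kept &
                             network$edges$to %in% kept, , drop = FALSE]
    roles <- setNames(network$nodes$role, network$nodes$id)
    key <- kept[roles[kept] == "gene"]
    if (!is.null(disease_genes) && !is.null(target_genes)) {
      subtype <- classify_key_proteins(key, disease_genes, target_genes,
                                       network = network)
    }
  }
  structure(list(threshold_value = threshold, threshold_mode = mode,
                 kept = kept, edges = edges, subtype = subtype,
                 key_proteins = key),
            class = "cfig_frs")
}

#' @export
print.cfig_frs <- function(x, ...) {
  cat(sprintf("<cfig_frs> %d kept node(s) at %s threshold %.4g\n",
              length(x$kept), x$threshold_mode, x$threshold_value))
  if (!is.null(x$subtype)) print(table(x$subtype, useNA = "ifany"))
  invisible(x)
}

#' Classify key response proteins into three subtypes
#'
#' Kept gene nodes in both the pathogenetic-gene set and the
#' ingredient-target set are *essential common* targets (they directly
#' link disease genes and ingredient targets); genes only in the disease
#' set are *disease specific*; genes only in the target set are
#' *ingredient specific*.  A kept gene in neither set is labelled
#' ingredient-specific when it is reachable from an ingredient node of the
#' supplied network, otherwise it gets `NA` with a warning.
#'
#' @param kept_genes character vector of kept gene-node ids.
#' @param disease_genes,target_genes character gene sets.
#' @param network optional `cfig_network` for the reachability fallback.
#' @return named character vector (`essential_common`,
#'   `disease_specific`, `ingredient_specific`, or `NA`).
#' @export
classify_key_proteins <- function(kept_genes, disease_genes, target_genes,
                                  network = NULL) {
  in_d <- kept_genes %in% disease_genes
  in_t <- kept_genes %in% target_genes
  subtype <- ifelse(in_d & in_t, "essential_common",
             ifelse(in_d, "disease_specific",
             ifelse(in_t, "ingredient_specific", NA_character_)))
  orphan <- which(is.na(subtype))
  if (length(orphan) > 0 && !is.null(network)) {
    memb <- igraph::components(as_igraph(network))$membership
    ing_comps <- unique(memb[network$nodes$id[network$nodes$role == "ingredient"]])
    reachable <- memb[kept_genes[orphan]] %in% ing_comps
    subtype[orphan[reachable]] <- "ingredient_specific"
    orphan <- orphan[!reachable]
  }
  if (length(orphan) > 0) {
    warning(sprintf(
      "%d kept gene(s) in neither disease nor target set and not reachable from an ingredient: %s",
      length(orphan), paste(utils::head(kept_genes[orphan], 5), collapse = ", ")),
      call. = FALSE)
  }
  setNames(subtype, kept_genes)
}

#' Un-optimized effective targets (UET)
#'
#' The plain intersection of the pathogenetic-gene set and the ingredient
#' target set, used as the reference set when validating the functional
#' response space.
#'
#' @param disease_genes,target_genes character gene sets (normalized
#'   symbols).
#' @return character vector.
#' @export
compute_uet <- function(disease_genes, target_genes) {
  if (length(disease_genes) == 0 || length(target_genes) == 0) {
    stop_cfig("both gene sets must be nonempty", class = "cfig_validation_error")
  }
  intersect(disease_genes, target_genes)
}
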