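# Independent oracles used to validate the package's own implementations.
# They deliberately take different algorithmic routes: path enumeration
# instead of Brandes accumulation, draw enumeration instead of the
# hypergeometric tail, and a from-scratch greedy trace instead of the
# package's incremental bookkeeping.

# Build a bare gene network from an edge data.frame (and optional extra
# isolated nodes).
mk_net <- function(from, to, extra_nodes = character(0)) {
  ids <- unique(c(from, to, extra_nodes))
  weighted_network(
    data.frame(id = ids, role = "gene", weight = 0),
    data.frame(from = from, to = to)
  )
}

# Shortest-path pair-sum betweenness by explicit enumeration of all
# shortest paths between every unordered pair.
oracle_betweenness <- function(net) {
  g <- as_igraph(net)
  ids <- net$nodes$id
  n <- length(ids)
  btw <- setNames(numeric(n), ids)
  if (n < 3) return(btw)
  for (a in seq_len(n - 1)) {
    for (b in seq.int(a + 1, n)) {
      paths <- suppressWarnings(
        igraph::all_shortest_paths(g, from = ids[a], to = ids[b])$vpaths %||%
          igraph::all_shortest_paths(g, from = ids[a], to = ids[b])$res)
      if (length(paths) == 0) next
      sigma <- length(paths)
      for (p in paths) {
        inner <- setdiff(names(p), c(ids[a], ids[b]))
        btw[inner] <- btw[inner] + 1 / sigma
      }
    }
  }
  btw
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Upper-tail overlap probabilities P(X >= k) by enumerating every possible
# draw of size n from a background of size N whose first K elements form
# the term.
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  ov <- colSums(draws <= K)
  if (is.null(dim(draws))) ov <- sum(draws <= K)  # n == 1 edge case
  mean(ov >= k)
}

# From-scratch greedy trace: largest marginal gain, ties by raw target
# count then id.
oracle_greedy_trace <- function(target_sets, key, cov_target = 1) {
  key <- unique(key)
  covered <- setNames(rep(FALSE, length(key)), key)
  raw <- vapply(target_sets, length, integer(1))
  picks <- character(0)
  gains <- integer(0)
  remaining <- names(target_sets)
  repeat {
    if (length(remaining) == 0) break
    g <- vapply(remaining, function(i) {
      hits <- intersect(target_sets[[i]], key)
      sum(!covered[hits])
    }, integer(1))
    if (max(g) == 0) break
    cands <- remaining[g == max(g)]
    cands <- cands[order(-raw[cands], cands)]
    best <- cands[1]
    covered[intersect(target_sets[[best]], key)] <- TRUE
    picks <- c(picks, best)
    gains <- c(gains, max(g))
    remaining <- setdiff(remaining, best)
    if (mean(covered) >= cov_target) break
  }
  list(picks = picks, gains = gains, coverage = mean(covered))
}

# Exhaustive optimum: best coverage of `key` achievable with exactly k
# ingredients.
oracle_best_k_coverage <- function(target_sets, key, k) {
  key <- unique(key)
  ids <- names(target_sets)
  if (k >= length(ids)) {
    return(length(intersect(unique(unlist(target_sets)), key)) / length(key))
  }
  best <- 0
  combos <- utils::combn(ids, k)
  for (j in seq_len(ncol(combos))) {
    cov <- length(intersect(unique(unlist(target_sets[combos[, j]])), key))
    best <- max(best, cov)
  }
  best / length(key)
}

# Random ingredient-target instance for greedy testing.
random_icp_instance <- function(n_ing, n_prot) {
  prots <- sprintf("P%02d", seq_len(n_prot))
  sets <- lapply(seq_len(n_ing), function(i) {
    sample(prots, sample.int(n_prot, 1))
  })
  names(sets) <- sprintf("I%02d", seq_len(n_ing))
  sets
}

sets_to_assoc <- function(sets) {
  do.call(rbind, lapply(names(sets), function(i) {
    data.frame(ingredient_id = i, target_gene = sets[[i]],
               stringsAsFactors = FALSE)
  }))
}

# --- exhaustive graph enumeration ------------------------------------------

# All connected labeled graphs on n nodes, as edge matrices.
all_connected_labeled_graphs <- function(n) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  out <- list()
  for (mask in seq_len(2^m - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) != 0)
    e <- pairs[sel, , drop = FALSE]
    if (is_connected_edges(n, e)) out[[length(out) + 1L]] <- e
  }
  out
}

is_connected_edges <- function(n, e) {
  if (n == 1) return(TRUE)
  adj <- vector("list", n)
  for (i in seq_len(nrow(e))) {
    adj[[e[i, 1]]] <- c(adj[[e[i, 1]]], e[i, 2])
    adj[[e[i, 2]]] <- c(adj[[e[i, 2]]], e[i, 1])
  }
  seen <- logical(n)
  stack <- 1L
  seen[1] <- TRUE
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        stack <- c(stack, w)
      }
    }
  }
  all(seen)
}

# One representative per isomorphism class of connected graphs on n nodes.
connected_graphs_up_to_iso <- function(n) {
  reps <- list()
  keys <- character(0)
  for (e in all_connected_labeled_graphs(n)) {
    g <- igraph::graph_from_edgelist(e, directed = FALSE)
    if (igraph::vcount(g) < n) {
      g <- igraph::add_vertices(g, n - igraph::vcount(g))
    }
    cp <- igraph::canonical_permutation(g)$labeling
    gc <- igraph::permute(g, cp)
    el <- igraph::as_edgelist(gc)
    el <- cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
    key <- paste(as.vector(t(el)), collapse = ",")
    if (!key %in% keys) {
      keys <- c(keys, key)
      reps[[length(reps) + 1L]] <- e
    }
  }
  reps
}

edges_to_net <- function(e, n) {
  ids <- sprintf("N%d", seq_len(n))
  weighted_network(
    data.frame(id = ids, role = "gene", weight = 0),
    data.frame(from = ids[e[, 1]], to = ids[e[, 2]])
  )
}

# Random connected graph on n nodes (spanning tree plus extra edges).
random_connected_graph <- function(n, extra = n) {
  e <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1, 1), integer(1)))
  all_pairs <- t(utils::combn(n, 2))
  add <- all_pairs[sample.int(nrow(all_pairs), min(extra, nrow(all_pairs))),
                   , drop = FALSE]
  e <- unique(rbind(e[, c(2, 1)], add))
  edges_to_net(e, n)
}
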