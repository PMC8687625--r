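test_that("disease-network weight is degree x relevance x report count", {
  # a hub with induced degree 37, relevance 31.51, 85 reports -> 99,098.95
  others <- sprintf("P%02d", 1:37)
  ppi <- data.frame(from = "TNF", to = others)
  ev <- data.frame(gene = c("TNF", others),
                   n_reports = c(85, rep(1, 37)),
                   relevance_score = c(31.51, rep(1, 37)))
  res <- build_disease_network(ppi, ev)
  w <- res$network$nodes
  expect_equal(w$weight[w$id == "TNF"], 99098.95)
  expect_equal(w$weight[w$id == "P01"], 1)  # degree 1 x 1 x 1
})

test_that("missing relevance and zero reports default to the identity", {
  ppi <- data.frame(from = c("A", "B"), to = c("B", "C"))
  ev <- data.frame(gene = c("A", "B", "C"),
                   n_reports = c(4, 0, 2),
                   relevance_score = c(NA, 3, 5))
  w <- build_disease_network(ppi, ev)$network$nodes
  expect_equal(w$weight[w$id == "A"], 1 * 1 * 4)
  expect_equal(w$weight[w$id == "B"], 2 * 3 * 1)
  expect_equal(w$weight[w$id == "C"], 1 * 5 * 2)
})

test_that("evidence genes absent from the PPI are dropped and reported", {
  ppi <- data.frame(from = "A", to = "B")
  ev <- data.frame(gene = c("A", "B", "Z"), n_reports = c(1, 1, 9),
                   relevance_score = c(1, 1, 9))
  res <- build_disease_network(ppi, ev)
  expect_equal(res$dropped, "Z")
  expect_equal(sort(res$network$nodes$id), c("A", "B"))
  ev2 <- data.frame(gene = "Q", n_reports = 1, relevance_score = 1)
  expect_error(build_disease_network(ppi, ev2), "no mappable",
               class = "cfig_no_mappable_genes")
})

test_that("the I-T network is bipartite with per-ingredient counts", {
  assoc <- data.frame(ingredient_id = c("I1", "I2"),
                      target_gene = c("G1", "G1"))
  res <- build_it_network(c("I1", "I2"), assoc)
  expect_equal(nrow(res$network$nodes), 3)
  expect_equal(nrow(res$network$edges), 2)
  expect_equal(res$target_counts, c(I1 = 1L, I2 = 1L))
  # mean targets per ingredient is total associations over ingredients
  expect_equal(res$mean_targets, 1)
  expect_error(build_it_network("I1", assoc), "unknown ingredient",
               class = "cfig_validation_error")
  expect_warning(
    build_it_network(c("I1", "I2", "I3"), assoc), "zero targets")
})

test_that("merging takes the node and edge union, disease weights winning", {
  dis <- weighted_network(
    data.frame(id = c("A", "B"), role = "gene", weight = c(10, 20)),
    data.frame(from = "A", to = "B"))
  it <- weighted_network(
    data.frame(id = c("I1", "B", "C"), role = c("ingredient", "gene", "gene"),
               weight = 0),
    data.frame(from = c("I1", "I1"), to = c("B", "C")))
  mg <- merge_networks(dis, it)
  expect_equal(nrow(mg$nodes), 4)  # A, B, C, I1
  expect_equal(mg$nodes$weight[mg$nodes$id == "B"], 20)
  expect_equal(mg$nodes$role[mg$nodes$id == "I1"], "ingredient")
  # disjoint gene sets: node count is the plain sum
  it2 <- weighted_network(
    data.frame(id = c("I9", "X"), role = c("ingredient", "gene"), weight = 0),
    data.frame(from = "I9", to = "X"))
  expect_equal(nrow(merge_networks(dis, it2)$nodes), 4)
  # idempotent and commutative in node/edge sets
  mg2 <- merge_networks(dis, it)
  expect_identical(mg$nodes, mg2$nodes)
})

test_that("merged counts on a generated study match set-union arithmetic", {
  st <- generate_study(study_config(n_genes = 100, n_disease_genes = 25,
                                    n_ingredients = 10, seed = 5))
  dec <- filter_ingredients(st$ingredients)
  ret <- dec$ingredient_id[dec$retained]
  assoc <- st$associations[st$associations$ingredient_id %in% ret, ]
  dis <- build_disease_network(st$base_ppi, st$evidence)$network
  it <- build_it_network(ret, assoc)$network
  mg <- merge_networks(dis, it, base_ppi = st$base_ppi)

  node_union <- union(dis$nodes$id, it$nodes$id)
  expect_setequal(mg$nodes$id, node_union)
  gene_union <- union(dis$nodes$id,
                      it$nodes$id[it$nodes$role == "gene"])
  ekey <- function(f, t) paste(pmin(f, t), pmax(f, t))
  ppi_within <- st$base_ppi[st$base_ppi$from %in% gene_union &
                              st$base_ppi$to %in% gene_union, ]
  edge_union <- unique(c(ekey(dis$edges$from, dis$edges$to),
                         ekey(it$edges$from, it$edges$to),
                         ekey(ppi_within$from, ppi_within$to)))
  expect_setequal(ekey(mg$edges$from, mg$edges$to), edge_union)
})

test_that("node weight is monotone in the report count", {
  ppi <- data.frame(from = c("A", "B"), to = c("B", "C"))
  w_of <- function(n_rep) {
    ev <- data.frame(gene = c("A", "B", "C"), n_reports = c(1, n_rep, 1),
                     relevance_score = 1)
    nodes <- build_disease_network(ppi, ev)$network$nodes
    nodes$weight[nodes$id == "B"]
  }
  ws <- vapply(c(1, 2, 5, 50), w_of, numeric(1))
  expect_true(all(diff(ws) > 0))
})

test_that("networks are simple: no self-loops, no duplicate edges", {
  net <- weighted_network(
    data.frame(id = c("A", "B"), role = "gene", weight = 0),
    data.frame(from = c("A", "B", "A", "A"), to = c("B", "A", "A", "B")))
  expect_equal(nrow(net$edges), 1)
})
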