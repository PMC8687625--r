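path3 <- function() mk_net(c("A", "B"), c("B", "C"))

test_that("worked examples: path center, star leaves and star center", {
  nim <- compute_nim(path3(), assign_communities(path3()))
  expect_equal(nim$nim[nim$id == "B"], 4)        # 1 x [(3/3) * 2/1]^2
  expect_equal(nim$nim[nim$id == "A"], 0)        # leaves carry no paths

  star3 <- mk_net(rep("C0", 3), c("L1", "L2", "L3"))
  n3 <- compute_nim(star3, assign_communities(star3))
  expect_true(all(n3$nim[n3$id != "C0"] == 0))

  star4 <- mk_net(rep("C0", 4), c("L1", "L2", "L3", "L4"))
  n4 <- compute_nim(star4, assign_communities(star4))
  expect_equal(n4$nim[n4$id == "C0"], 96)        # 6 x [(5/5) * 4/1]^2
  expect_equal(n4$betweenness_term[n4$id == "C0"], 6)
})

test_that("community assignment is total and component-wise deterministic", {
  two_tri <- mk_net(c("A", "B", "C", "X", "Y", "Z"),
                    c("B", "C", "A", "Y", "Z", "X"))
  cc <- assign_communities(two_tri)
  expect_equal(sort(table(cc$community), decreasing = TRUE),
               sort(table(c(1, 1, 1, 2, 2, 2)), decreasing = TRUE),
               ignore_attr = TRUE)
  one <- assign_communities(path3())
  expect_equal(unique(one$community), 1L)
  # modularity mode is reproducible under a fixed seed
  net <- random_connected_graph(30, extra = 40)
  m1 <- assign_communities(net, "modularity", seed = 5)
  m2 <- assign_communities(net, "modularity", seed = 5)
  expect_identical(m1, m2)
})

test_that("a singleton community contributes factor zero", {
  net <- mk_net("A", "B", extra_nodes = "LONE")
  nim <- compute_nim(net, assign_communities(net))
  expect_equal(nim$community_factor[nim$id == "LONE"], 0)
  expect_equal(nim$nim[nim$id == "LONE"], 0)
  expect_error(compute_nim(net, data.frame(id = c("A", "B"), community = 1)),
               "missing", class = "cfig_validation_error")
})

test_that("the betweenness term agrees with two independent routes", {
  # route 1: explicit enumeration of all shortest paths
  # route 2: the reference Brandes implementation in igraph
  set.seed(31)
  for (rep in 1:8) {
    net <- random_connected_graph(sample(5:9, 1))
    nim <- compute_nim(net, assign_communities(net))
    expect_equal(setNames(nim$betweenness_term, nim$id),
                 oracle_betweenness(net), tolerance = 1e-12)
    ig <- as_igraph(net)
    expect_equal(nim$betweenness_term,
                 as.numeric(igraph::betweenness(ig)[nim$id]),
                 tolerance = 1e-12)
  }
})

test_that("nim is invariant under node relabeling", {
  set.seed(17)
  net <- random_connected_graph(8)
  nim <- compute_nim(net, assign_communities(net))
  perm <- sample(net$nodes$id)
  relabel <- setNames(sprintf("R%02d", seq_along(perm)), perm)
  net2 <- weighted_network(
    data.frame(id = unname(relabel[net$nodes$id]), role = "gene", weight = 0),
    data.frame(from = unname(relabel[net$edges$from]),
               to = unname(relabel[net$edges$to])))
  nim2 <- compute_nim(net2, assign_communities(net2))
  expect_equal(setNames(nim2$nim, nim2$id)[unname(relabel[nim$id])],
               setNames(nim$nim, unname(relabel[nim$id])), tolerance = 1e-12)
})

test_that("baseline centralities match their closed forms and brute force", {
  k3 <- mk_net(c("A", "A", "B"), c("B", "C", "C"))
  expect_equal(baseline_centrality(k3, "degree")$score, rep(2, 3))
  expect_equal(baseline_centrality(k3, "clustering_coefficient")$score,
               rep(1, 3))
  p3 <- path3()
  cl <- baseline_centrality(p3, "closeness")
  expect_equal(cl$score[cl$id == "B"], 1)
  # component-scaled closeness on a disconnected graph, vs direct formula
  net <- mk_net(c("A", "B", "X"), c("B", "C", "Y"))
  got <- baseline_centrality(net, "closeness")
  d <- igraph::distances(as_igraph(net))[got$id, got$id]
  n <- nrow(d)
  want <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]; r <- sum(is.finite(di))
    if (r == 0) 0 else (r / (n - 1)) * (r / sum(di[is.finite(di)]))
  }, numeric(1))
  expect_equal(got$score, want)
})

test_that("FRS thresholding follows the stated modes and keeps ties", {
  nim <- data.frame(id = c("a", "b", "c", "d"), community = 1,
                    betweenness_term = 1, community_factor = 1,
                    nim = c(1, 2, 3, 10))
  expect_equal(select_frs(nim, mode = "midpoint")$kept, "d")     # thr 5.5
  expect_equal(select_frs(nim, mode = "mean")$kept, "d")         # thr 4
  expect_equal(select_frs(nim, mode = "median")$kept, c("c", "d"))
  flat <- transform(nim, nim = 7)
  for (m in c("midpoint", "mean", "median")) {
    expect_equal(select_frs(flat, mode = m)$kept, flat$id)
  }
})

test_that("every threshold mode keeps at least one node", {
  set.seed(9)
  for (rep in 1:10) {
    scores <- rlnorm(sample(2:40, 1), 0, 3)
    nim <- data.frame(id = seq_along(scores), community = 1,
                      betweenness_term = scores, community_factor = 1,
                      nim = scores)
    for (m in c("midpoint", "mean", "median")) {
      expect_gte(length(select_frs(nim, mode = m)$kept), 1)
    }
  }
})

test_that("key response proteins are subtyped by set membership", {
  sub <- classify_key_proteins(c("A", "B", "C"),
                               disease_genes = c("A", "B"),
                               target_genes = c("A", "C"))
  expect_equal(unname(sub), c("essential_common", "disease_specific",
                              "ingredient_specific"))
  # a kept gene in neither set: labelled via reachability, else warned
  net <- weighted_network(
    data.frame(id = c("I1", "G1", "G2"),
               role = c("ingredient", "gene", "gene"), weight = 0),
    data.frame(from = "I1", to = "G1"))
  s2 <- classify_key_proteins("G1", "ZZ", "YY", network = net)
  expect_equal(unname(s2), "ingredient_specific")
  expect_warning(classify_key_proteins("G2", "ZZ", "YY", network = net),
                 "not reachable")
})

test_that("UET is the plain intersection", {
  expect_setequal(compute_uet(c("A", "B"), c("A", "B")), c("A", "B"))
  expect_length(compute_uet(c("A", "B"), c("C")), 0)
  st <- generate_study(study_config(n_genes = 80, n_disease_genes = 20,
                                    n_ingredients = 8, seed = 2))
  uet <- compute_uet(st$evidence$gene, unique(st$associations$target_gene))
  expect_setequal(uet, st$evidence$gene[st$evidence$gene %in%
                                          st$associations$target_gene])
  expect_error(compute_uet(character(0), "A"), "nonempty",
               class = "cfig_validation_error")
})

test_that("module hubs of a synthetic study land in the top Nim decile", {
  b <- planted_recovery_benchmark(study_config(), seeds = c(3, 11), n_hubs = 3)
  expect_true(all(b$hubs_in_top_decile))
})
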