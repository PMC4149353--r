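test_that("a hub whose out-neighbours are all DEGs gets the enumerated p-value", {
  # 9 nodes: hub H -> D1..D4 (all DEGs), bystanders X1..X4
  edges <- data.frame(source = "H", target = paste0("D", 1:4),
                      effect = "activation", mechanism = "binding",
                      stringsAsFactors = FALSE)
  nw <- interaction_network(edges, nodes = c("H", paste0("D", 1:4),
                                             paste0("X", 1:4)))
  res <- direct_regulators(nw, paste0("D", 1:4))
  h <- res[res$gene == "H", ]
  expect_equal(h$r, 4); expect_equal(h$n, 4)
  expect_equal(h$R, 4); expect_equal(h$N, 8)
  expect_equal(h$p, 1 / 70, tolerance = 1e-12)
  expect_equal(h$p, enum_hyper_tail(4, 4, 4, 8), tolerance = 1e-12)
  # nodes touching no DEG are never significant
  expect_true(all(res$p[res$r == 0] == 1))
})

test_that("direct regulator p-values are equivariant under gene relabelling", {
  nw <- random_digraph(12, 30, seed = 5)
  degs <- nw$nodes[1:5]
  res <- direct_regulators(nw, degs)
  perm <- setNames(sprintf("Z%02d", sample(12)), nw$nodes)
  ed2 <- nw$edges
  ed2$source <- unname(perm[ed2$source]); ed2$target <- unname(perm[ed2$target])
  res2 <- direct_regulators(interaction_network(ed2, nodes = unname(perm)),
                            unname(perm[degs]))
  p1 <- setNames(res$p, res$gene)
  p2 <- setNames(res2$p, res2$gene)
  expect_equal(unname(p2[unname(perm[res$gene])]), unname(p1))
})

test_that("planted regulators are recovered by over-connectivity", {
  in_top5 <- vapply(1:25, function(seed) {
    s <- simulate_study(sim_config(seed = seed))
    dl <- call_degs(moderated_t(s$expression))
    dr <- direct_regulators(s$network, deg_genes(dl))
    all(dr$rank[match(s$truth$planted_regulators, dr$gene)] <= 5)
  }, TRUE)
  expect_gte(mean(in_top5), 0.9)
})

test_that("traversal counts on hand-checkable graphs are exact", {
  chain <- interaction_network(
    data.frame(source = c("A", "B", "C"), target = c("B", "C", "D"),
               effect = "activation", mechanism = "binding"))
  cc <- ddshortest_path_counts(chain, cbind("A", "D"))
  expect_equal(cc[["B"]], 1); expect_equal(cc[["C"]], 1)
  expect_equal(attr(cc, "n_paths"), 1)

  diamond <- interaction_network(
    data.frame(source = c("A", "A", "B", "C"), target = c("B", "C", "D", "D"),
               effect = "activation", mechanism = "binding"))
  cd <- ddshortest_path_counts(diamond, cbind("A", "D"))
  expect_equal(cd[["B"]], 1); expect_equal(cd[["C"]], 1)
  expect_equal(attr(cd, "n_paths"), 2)

  # self-pairs and unreachable pairs contribute nothing
  cn <- ddshortest_path_counts(chain, rbind(c("A", "A"), c("D", "A")))
  expect_true(all(cn == 0))
  expect_equal(attr(cn, "n_paths"), 0)
})

test_that("traversal counts equal brute-force all-shortest-path expansion", {
  for (seed in 1:25) {
    n_nodes <- sample(5:15, 1)
    nw <- random_digraph(n_nodes, sample(n_nodes:(3 * n_nodes), 1), seed)
    pairs <- as.matrix(expand.grid(nw$nodes, nw$nodes,
                                   stringsAsFactors = FALSE))
    fast <- ddshortest_path_counts(nw, pairs)
    slow <- brute_sp_counts(nw, pairs)
    expect_equal(unclass(fast)[nw$nodes], slow[nw$nodes])
    expect_equal(attr(fast, "n_paths"), attr(slow, "n_paths"))
  }
})

test_that("total traversals obey the path-length conservation identity", {
  for (seed in 31:40) {
    nw <- random_digraph(10, 25, seed)
    degs <- nw$nodes[1:4]
    pairs <- as.matrix(expand.grid(degs, degs, stringsAsFactors = FALSE))
    cc <- ddshortest_path_counts(nw, pairs)
    # sum of interior traversals = sum over pairs' shortest paths of (len-1)
    g <- nw$graph
    total <- 0
    for (i in seq_len(nrow(pairs))) {
      if (pairs[i, 1] == pairs[i, 2]) next
      sp <- suppressWarnings(igraph::all_shortest_paths(
        g, from = pairs[i, 1], to = pairs[i, 2], mode = "out"))$vpaths
      total <- total + sum(vapply(sp, function(p) length(p) - 2, 0))
    }
    expect_equal(sum(cc), total)
  }
})

test_that("hidden nodes reproduce the worked chain statistics", {
  chain <- interaction_network(
    data.frame(source = c("A", "B", "C"), target = c("B", "C", "D"),
               effect = "activation", mechanism = "binding"))
  hn <- hidden_nodes(chain, c("A", "D"))
  b <- hn[hn$gene == "B", ]
  expect_equal(b$k, 1); expect_equal(b$m, 2)
  expect_equal(b$K, 1); expect_equal(b$M, 6)
  expect_equal(b$p, hypergeom_tail(1, 2, 1, 6))
  expect_equal(b$p, 1 / 3, tolerance = 1e-12)
})

test_that("declaring every node differentially expressed flattens the statistic", {
  for (seed in c(2, 3)) {
    nw <- random_digraph(10, 30, seed)
    hn <- hidden_nodes(nw, nw$nodes)
    expect_true(all(hn$p == 1))
  }
})

test_that("a disconnected DEG set yields an empty result with a warning", {
  nw <- interaction_network(
    data.frame(source = c("A", "C"), target = c("B", "D"),
               effect = "activation", mechanism = "binding"))
  expect_warning(hn <- hidden_nodes(nw, c("A", "C")), "no DEG pair")
  expect_equal(nrow(hn), 0)
})

test_that("a remote regulator acting through two-step cascades is recovered", {
  in_top10 <- vapply(1:25, function(seed) {
    cfg <- sim_config(n_genes = 300, network_size = 300, n_edges = 450,
                      n_regulators = 1, target_path_len = 2, seed = seed)
    s <- simulate_study(cfg)
    dl <- call_degs(moderated_t(s$expression), p_cut = 0.05)
    hn <- hidden_nodes(s$network, deg_genes(dl))
    hn$rank[match(s$truth$planted_regulators, hn$gene)] <= 10
  }, TRUE)
  expect_gte(mean(in_top10), 0.8)
})

test_that("the permutation null agrees with the analytic ranking on planted signal", {
  cfg <- sim_config(n_genes = 300, network_size = 300, n_edges = 450,
                    n_regulators = 1, target_path_len = 2, seed = 8)
  s <- simulate_study(cfg)
  dl <- call_degs(moderated_t(s$expression), p_cut = 0.05)
  hz <- hidden_nodes(s$network, deg_genes(dl), null = "permutation",
                     n_perm = 100, perm_seed = 1, tail = "normal")
  expect_lte(hz$rank[match(s$truth$planted_regulators, hz$gene)], 10)
  he <- hidden_nodes(s$network, deg_genes(dl), null = "permutation",
                     n_perm = 100, perm_seed = 1, tail = "empirical")
  expect_true(all(he$p >= 1 / 101 - 1e-12))
})
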