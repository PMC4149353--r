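test_that("the synergy rule is applied exactly as defined", {
  mk <- function(p) data.frame(set = c("P1", "P2"), r = 1, n = 5, R = 5,
                               N = 50, p = p, fdr = p,
                               stringsAsFactors = FALSE)
  # P1: combo strictly below both and all gated -> key
  # P2: combo not below both -> not key
  kp <- identify_key_pathways(mk(c(0.01, 0.01)), mk(c(0.02, 0.02)),
                              mk(c(0.001, 0.015)))
  expect_true(kp$is_key[kp$set == "P1"])
  expect_false(kp$is_key[kp$set == "P2"])
  # failing the significance gate vetoes synergy
  kp2 <- identify_key_pathways(mk(c(0.01, 0.01)), mk(c(0.2, 0.2)),
                               mk(c(0.001, 0.001)))
  expect_false(any(kp2$is_key))
  expect_error(identify_key_pathways(mk(c(0.1, 0.1))[1, ], mk(c(0.1, 0.1)),
                                     mk(c(0.1, 0.1))), "different collections")
})

test_that("key-pathway decisions follow exact-oracle hypergeometric p-values", {
  # toy universe N = 30, pathway of 10; DEGs 6 overlap 4; regulators 5
  # overlap 3; combination 11 overlap 7
  universe <- sprintf("u%02d", 1:30)
  pw <- universe[1:10]
  degs <- c(universe[1:4], universe[21:22])
  regs <- c(universe[5:7], universe[23:24])
  combo <- union(degs, regs)
  gs <- gene_sets(list(PW = pw), universe = universe)
  e_deg <- enrich(degs, gs); e_reg <- enrich(regs, gs)
  e_combo <- enrich(combo, gs)
  expect_equal(e_deg$p, enum_hyper_tail(4, 10, 6, 30), tolerance = 1e-12)
  expect_equal(e_reg$p, enum_hyper_tail(3, 10, 5, 30), tolerance = 1e-12)
  expect_equal(e_combo$p, enum_hyper_tail(7, 10, 11, 30), tolerance = 1e-12)
  kp <- identify_key_pathways(e_deg, e_reg, e_combo)
  expect_equal(kp$is_key,
               e_combo$p < e_deg$p & e_combo$p < e_reg$p &
                 max(e_deg$p, e_reg$p, e_combo$p) <= 0.05)
})

test_that("cascade extraction honours stretch and gap semantics", {
  toy <- toy_topology()
  # fully affected chain to TF1
  cas <- find_affected_cascades(toy$topology, toy$roles,
                                c("L", "R", "K1", "K2", "TF1"))
  expect_length(cas, 1)
  expect_identical(cas[[1]], c("L", "R", "K1", "K2", "TF1"))
  # K2 unaffected: rejected at max_gap 0, accepted at max_gap 1
  aff <- c("L", "R", "K1", "TF1")
  expect_length(find_affected_cascades(toy$topology, toy$roles, aff), 0)
  cas2 <- find_affected_cascades(toy$topology, toy$roles, aff, max_gap = 1)
  expect_length(cas2, 1)
  # only the branch ending at an affected TF is returned
  aff3 <- c("L", "R", "K1", "K3", "TF2")
  cas3 <- find_affected_cascades(toy$topology, toy$roles, aff3)
  expect_length(cas3, 1)
  expect_identical(cas3[[1]], c("L", "R", "K1", "K3", "TF2"))
  # an unaffected trigger can never start a cascade
  expect_length(find_affected_cascades(toy$topology, toy$roles,
                                       c("R", "K1", "K2", "TF1")), 1)
  expect_length(find_affected_cascades(toy$topology, toy$roles,
                                       c("K1", "K2", "TF1")), 0)
})

test_that("enlarging the affected set never removes a cascade", {
  toy <- toy_topology()
  all_nodes <- toy$roles$gene
  set.seed(13)
  for (i in 1:20) {
    aff <- sample(all_nodes, sample(2:6, 1))
    bigger <- union(aff, sample(all_nodes, 2))
    c1 <- find_affected_cascades(toy$topology, toy$roles, aff)
    c2 <- find_affected_cascades(toy$topology, toy$roles, bigger)
    # every cascade survives, possibly absorbed into a longer maximal one
    for (p in c1)
      expect_true(any(vapply(c2, function(q)
        length(q) >= length(p) &&
          identical(q[(length(q) - length(p) + 1L):length(q)], p), TRUE)))
  }
})

test_that("causal networks merge cascades with provenance and invent no edges", {
  toy <- toy_topology()
  map1 <- structure(list(name = "PW1", members = toy$roles$gene,
                         topology = toy$topology, roles = toy$roles),
                    class = "pathway_map")
  # second pathway shares the TF
  top2 <- data.frame(source = c("L2", "R2", "K9"), target = c("R2", "K9", "TF1"),
                     effect = "activation", mechanism = "other",
                     stringsAsFactors = FALSE)
  roles2 <- data.frame(gene = c("L2", "R2", "K9", "TF1"),
                       role = c("ligand", "receptor", "transducer",
                                "transcription-factor"),
                       blood_expressed = FALSE, stringsAsFactors = FALSE)
  map2 <- structure(list(name = "PW2", members = roles2$gene,
                         topology = top2, roles = roles2),
                    class = "pathway_map")
  key <- data.frame(set = c("PW1", "PW2"), p_deg = 0.01, p_reg = 0.01,
                    p_combo = 0.001, is_key = TRUE, stringsAsFactors = FALSE)
  affected <- c("L", "R", "K1", "K2", "TF1", "L2", "R2", "K9")
  cn <- reconstruct_causal_network(key, list(map1, map2), affected,
                                   character())
  expect_s3_class(cn, "causal_network")
  expect_length(cn$cascades, 2)
  tf_row <- cn$nodes[cn$nodes$gene == "TF1", ]
  expect_identical(tf_row$pathways, "PW1;PW2")
  # every edge exists in a source topology
  all_top <- rbind(cbind(toy$topology, pathway = "PW1"),
                   cbind(top2, pathway = "PW2"))
  expect_true(all(paste(cn$edges$source, cn$edges$target, cn$edges$pathway) %in%
                    paste(all_top$source, all_top$target, all_top$pathway)))
  # trigger and TF annotations present
  expect_true(grepl("trigger", cn$nodes$annotation[cn$nodes$gene == "L"]))
  expect_true(grepl("transcription-factor",
                    cn$nodes$annotation[cn$nodes$gene == "TF1"]))
})

test_that("no affected trigger anywhere yields an empty network with a warning", {
  toy <- toy_topology()
  map1 <- structure(list(name = "PW1", members = toy$roles$gene,
                         topology = toy$topology, roles = toy$roles),
                    class = "pathway_map")
  key <- data.frame(set = "PW1", p_deg = 0.01, p_reg = 0.01, p_combo = 0.001,
                    is_key = TRUE, stringsAsFactors = FALSE)
  expect_warning(cn <- reconstruct_causal_network(key, list(map1),
                                                  c("K1", "K2", "TF1"),
                                                  character()),
                 "no affected trigger")
  expect_equal(nrow(cn$edges), 0)
  # a key pathway without topology is skipped with a warning
  map0 <- structure(list(name = "PW1", members = "X", topology = NULL,
                         roles = NULL), class = "pathway_map")
  expect_warning(reconstruct_causal_network(key, list(map0), "X", character()),
                 "without topology")
})

test_that("module groups join the network when a member is affected", {
  toy <- toy_topology()
  map1 <- structure(list(name = "PW1", members = toy$roles$gene,
                         topology = toy$topology, roles = toy$roles,
                         groups = list(complex1 = c("K1", "Q1"),
                                       complex2 = c("Q2", "Q3"))),
                    class = "pathway_map")
  key <- data.frame(set = "PW1", p_deg = 0.01, p_reg = 0.01, p_combo = 0.001,
                    is_key = TRUE, stringsAsFactors = FALSE)
  cn <- reconstruct_causal_network(key, list(map1),
                                   c("L", "R", "K1", "K2", "TF1"), character())
  expect_named(cn$module_groups, "PW1:complex1")
  expect_true("Q1" %in% cn$nodes$gene)
  expect_true(grepl("module-group",
                    cn$nodes$annotation[cn$nodes$gene == "Q1"]))
})

test_that("flagged key pathways always satisfy their defining inequality end to end", {
  for (seed in c(4, 9)) {
    s <- simulate_study(sim_config(seed = seed))
    dl <- call_degs(moderated_t(s$expression))
    dr <- direct_regulators(s$network, deg_genes(dl))
    regs <- regulator_genes(dr)
    e_deg <- suppressMessages(enrich(deg_genes(dl), s$collection))
    e_reg <- suppressMessages(enrich(regs, s$collection))
    e_combo <- suppressMessages(enrich(union(deg_genes(dl), regs),
                                       s$collection))
    kp <- identify_key_pathways(e_deg, e_reg, e_combo)
    keys <- kp[kp$is_key, ]
    expect_true(all(keys$p_combo < pmin(keys$p_deg, keys$p_reg)))
    expect_true(all(keys$p_combo <= 0.05 & keys$p_deg <= 0.05 &
                      keys$p_reg <= 0.05))
    cn <- reconstruct_causal_network(kp, s$maps, deg_genes(dl), regs)
    # no invented edges: every causal edge is in some source topology
    topo <- do.call(rbind, lapply(s$maps, function(m)
      if (is.null(m$topology)) NULL else cbind(m$topology, pathway = m$name)))
    expect_true(all(paste(cn$edges$source, cn$edges$target) %in%
                      paste(topo$source, topo$target)))
  }
})
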