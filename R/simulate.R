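#' Synthetic-study configuration
#'
#' Bundles every knob of the synthetic-data generator. The defaults describe
#' the reference study conditions used throughout the test suite: a
#' 1000-gene universe measured in two groups of 10 samples, three planted
#' regulators each driving 20 target genes by one log2 unit against a
#' residual noise SD of 0.5, a 1000-node/3000-edge scale-free interaction
#' network, and a 20-pathway ontology of 30-gene sets.
#'
#' @param n_genes number of genes in the measured universe.
#' @param n_per_group samples per group (control / disease).
#' @param effect_log2fc planted shift (log2 units) of regulator targets in
#'   the disease group; sign per target is recorded in the truth.
#' @param noise_sd residual SD of each measurement (log2 units).
#' @param n_regulators number of planted regulators.
#' @param targets_per_regulator planted targets per regulator.
#' @param network_size nodes in the interaction network (first
#'   `network_size` genes of the universe).
#' @param n_edges directed edges in the scale-free backbone (>=
#'   `network_size - 1`).
#' @param pathway_count number of background pathways in the ontology.
#' @param pathway_size genes per pathway.
#' @param n_planted_enriched background pathways seeded with planted DEG
#'   targets (60% seeding).
#' @param chain_length upstream cascade length per regulator (ligand,
#'   receptor, then transducers), minimum 3.
#' @param target_path_len 1 (default): regulators act on their targets by a
#'   direct edge; 2: each regulator reaches its targets through
#'   intermediate transducer nodes (one per five targets), the remote-
#'   regulator scenario.
#' @param blood_fraction fraction of genes marked blood-expressed.
#' @param seed integer seed; per-stage sub-seeds are derived from it so
#'   stages can be re-run independently.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 1000, n_per_group = 10, effect_log2fc = 1,
                       noise_sd = 0.5, n_regulators = 3,
                       targets_per_regulator = 20, network_size = n_genes,
                       n_edges = 3000, pathway_count = 20, pathway_size = 30,
                       n_planted_enriched = 2, chain_length = 4,
                       target_path_len = 1, blood_fraction = 0.5, seed = 1) {
  cfg <- list(n_genes = n_genes, n_per_group = n_per_group,
              effect_log2fc = effect_log2fc, noise_sd = noise_sd,
              n_regulators = n_regulators,
              targets_per_regulator = targets_per_regulator,
              network_size = network_size, n_edges = n_edges,
              pathway_count = pathway_count, pathway_size = pathway_size,
              n_planted_enriched = n_planted_enriched,
              chain_length = chain_length,
              target_path_len = target_path_len,
              blood_fraction = blood_fraction,
              seed = as.integer(seed))
  if (!target_path_len %in% c(1, 2)) stop("target_path_len must be 1 or 2")
  counts <- cfg[c("n_genes", "n_per_group", "network_size", "pathway_count",
                  "pathway_size", "chain_length")]
  if (any(unlist(counts) <= 0)) stop("all counts must be positive")
  if (effect_log2fc < 0 || noise_sd < 0)
    stop("effect_log2fc and noise_sd must be non-negative")
  if (targets_per_regulator > n_genes)
    stop("targets_per_regulator cannot exceed n_genes")
  if (chain_length < 3) stop("chain_length must be >= 3 (ligand, receptor, transducer)")
  if (network_size > n_genes) stop("network_size cannot exceed n_genes")
  if (pathway_size > n_genes) stop("pathway_size cannot exceed n_genes")
  class(cfg) <- "sim_config"
  cfg
}

# deterministic per-stage sub-seed, kept inside 32-bit integer range
stage_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 48271 + stage * 1000003) %% 2147483647)
}

sim_gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Simulate a scale-free interaction network with planted regulators
#'
#' Builds a directed preferential-attachment backbone over the first
#' `network_size` genes, then plants `n_regulators` regulators: each is
#' given directed transcription-regulation edges to `targets_per_regulator`
#' target genes (activation for targets planted up, inhibition for targets
#' planted down) and an upstream signalling chain
#' ligand -> receptor -> transducer(s) -> regulator whose members are also
#' planted as up-regulated DEGs (the affected cascade a causal
#' reconstruction should recover). Node roles and a blood-expression flag
#' are recorded for every gene.
#'
#' @param config a [sim_config].
#' @return list with `network` (an [interaction_network]) and `truth` (class
#'   `sim_truth`): `planted_deg_up`, `planted_deg_down`,
#'   `planted_regulators`, `planted_targets` (named list per regulator),
#'   `chains` (named list per regulator, ligand first),
#'   `planted_enriched_pathways`, `blood_genes`, `seed`.
#' @export
simulate_network <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$network_size
  if (config$n_edges < n - 1) stop("infeasible edge count: need >= nodes - 1")
  if (config$n_edges > n * (n - 1)) stop("infeasible edge count: too many edges")
  genes <- sim_gene_ids(config$n_genes)
  nodes <- genes[seq_len(n)]
  set.seed(stage_seed(config$seed, 1L))

  m <- max(1L, floor(config$n_edges / (n - 1)))
  g0 <- igraph::sample_pa(n, m = m, directed = TRUE)
  el <- igraph::as_edgelist(g0, names = FALSE)
  # sample_pa points every edge towards earlier (hub) nodes; flip a random
  # half so information can also flow out of hubs
  flip <- sample(c(TRUE, FALSE), nrow(el), replace = TRUE)
  el[flip, ] <- el[flip, 2:1]
  key <- paste(el[, 1], el[, 2])
  el <- el[!duplicated(key) & el[, 1] != el[, 2], , drop = FALSE]
  # top up (degree-biased, mirroring preferential attachment) or thin to
  # the requested edge count
  while (nrow(el) < config$n_edges) {
    need <- config$n_edges - nrow(el)
    deg <- tabulate(c(el[, 1], el[, 2]), nbins = n) + 1
    s <- sample.int(n, 2 * need, replace = TRUE, prob = deg)
    t <- sample.int(n, 2 * need, replace = TRUE, prob = deg)
    cand <- cbind(s, t)
    cand <- cand[cand[, 1] != cand[, 2], , drop = FALSE]
    el <- rbind(el, cand)
    el <- el[!duplicated(paste(el[, 1], el[, 2])), , drop = FALSE]
    if (nrow(el) > config$n_edges)
      el <- el[seq_len(config$n_edges), , drop = FALSE]
  }
  if (nrow(el) > config$n_edges)
    el <- el[sort(sample.int(nrow(el), config$n_edges)), , drop = FALSE]

  n_chain <- config$chain_length
  n_mid <- if (config$target_path_len == 2)
    ceiling(config$targets_per_regulator / 5) else 0L
  n_special <- config$n_regulators *
    (1 + config$targets_per_regulator + n_chain + n_mid)
  if (n_special > n)
    stop("network too small for the requested regulators, targets and chains")
  special <- sample(nodes, n_special)
  regulators <- special[seq_len(config$n_regulators)]
  rest <- special[-seq_len(config$n_regulators)]

  planted_up <- character(); planted_down <- character()
  targets <- list(); chains <- list()
  extra <- list()
  roles <- setNames(rep("other", config$n_genes), genes)
  pos <- 0L
  for (i in seq_len(config$n_regulators)) {
    reg <- regulators[i]
    tg <- rest[pos + seq_len(config$targets_per_regulator)]
    pos <- pos + config$targets_per_regulator
    ch <- rest[pos + seq_len(n_chain)]
    pos <- pos + n_chain
    up <- tg[seq_len(ceiling(length(tg) / 2))]
    down <- setdiff(tg, up)
    planted_up <- c(planted_up, up, ch)
    planted_down <- c(planted_down, down)
    targets[[reg]] <- tg
    chains[[reg]] <- ch
    roles[ch[1]] <- "ligand"
    roles[ch[2]] <- "receptor"
    roles[ch[-(1:2)]] <- "transducer"
    roles[reg] <- "transcription-factor"
    chain_edges <- data.frame(
      source = c(ch[-n_chain], ch[n_chain]),
      target = c(ch[-1], reg),
      effect = "activation",
      mechanism = c("binding", rep("other", n_chain - 1)),
      stringsAsFactors = FALSE)
    if (n_mid == 0L) {
      reg_edges <- data.frame(
        source = reg, target = tg,
        effect = ifelse(tg %in% up, "activation", "inhibition"),
        mechanism = "transcription-regulation", stringsAsFactors = FALSE)
    } else {
      mids <- rest[pos + seq_len(n_mid)]
      pos <- pos + n_mid
      roles[mids] <- "transducer"
      mid_of <- mids[((seq_along(tg) - 1L) %% n_mid) + 1L]
      reg_edges <- rbind(
        data.frame(source = reg, target = mids, effect = "activation",
                   mechanism = "other", stringsAsFactors = FALSE),
        data.frame(source = mid_of, target = tg,
                   effect = ifelse(tg %in% up, "activation", "inhibition"),
                   mechanism = "transcription-regulation",
                   stringsAsFactors = FALSE))
    }
    extra[[i]] <- rbind(chain_edges, reg_edges)
  }
  backbone <- data.frame(source = nodes[el[, 1]], target = nodes[el[, 2]],
                         effect = sample(c("activation", "inhibition"),
                                         nrow(el), replace = TRUE),
                         mechanism = "binding", stringsAsFactors = FALSE)
  edges <- rbind(backbone, do.call(rbind, extra))
  edges <- edges[!duplicated(paste(edges$source, edges$target, edges$mechanism)), ]
  blood <- genes[stats::runif(config$n_genes) < config$blood_fraction]
  roles_df <- data.frame(gene = genes, role = unname(roles),
                         blood_expressed = genes %in% blood,
                         stringsAsFactors = FALSE)
  network <- interaction_network(edges, nodes = nodes, roles = roles_df)
  planted_enr <- character()
  if (config$n_planted_enriched > 0)
    planted_enr <- sprintf("PW_ENR_%02d", seq_len(config$n_planted_enriched))
  truth <- structure(list(
    planted_deg_up = unique(planted_up),
    planted_deg_down = unique(planted_down),
    planted_regulators = regulators,
    planted_targets = targets,
    chains = chains,
    planted_enriched_pathways = c(planted_enr,
                                  paste0("PW_CAUSAL_", regulators)),
    blood_genes = blood,
    genes = genes,
    seed = config$seed), class = "sim_truth")
  list(network = network, truth = truth)
}

#' Simulate two-group log2 expression with planted fold changes
#'
#' Per-gene baselines are Normal(8, 1) on the log2 scale; genes planted up
#' (down) in the truth are shifted by `+effect_log2fc` (`-effect_log2fc`) in
#' the disease group; every measurement gets i.i.d. Normal(0, `noise_sd`)
#' noise. Groups are labelled `control` and `disease`.
#'
#' @param config a [sim_config].
#' @param truth a `sim_truth` from [simulate_network()].
#' @return an [expression_matrix] over all `n_genes` genes.
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(stage_seed(config$seed, 2L))
  genes <- truth$genes
  ng <- length(genes)
  npg <- config$n_per_group
  baseline <- rnorm(ng, mean = 8, sd = 1)
  delta <- numeric(ng)
  delta[genes %in% truth$planted_deg_up] <- config$effect_log2fc
  delta[genes %in% truth$planted_deg_down] <- -config$effect_log2fc
  vals <- matrix(rnorm(ng * 2 * npg, sd = config$noise_sd), nrow = ng)
  vals <- vals + baseline
  vals[, npg + seq_len(npg)] <- vals[, npg + seq_len(npg)] + delta
  samples <- c(sprintf("ctrl_%02d", seq_len(npg)),
               sprintf("dis_%02d", seq_len(npg)))
  dimnames(vals) <- list(genes, samples)
  groups <- setNames(rep(c("control", "disease"), each = npg), samples)
  expression_matrix(vals, groups)
}

#' Simulate a pathway ontology with planted enrichment and causal maps
#'
#' Background pathways are uniform samples from the gene universe. The
#' planted-enriched pathways are seeded with 60% planted DEG targets (the
#' rest uniform from unplanted genes). One causal pathway per planted
#' regulator contains its upstream chain, the regulator and its targets,
#' padded to `pathway_size`, and carries a directed
#' ligand -> receptor -> transducer(s) -> TF topology with the TF wired to
#' the targets, plus node roles.
#'
#' @param config a [sim_config].
#' @param truth a `sim_truth` from [simulate_network()].
#' @return list with `collection` (a [gene_sets] over all pathways) and
#'   `maps` (list of `pathway_map`: `name`, `members`, `topology` edge data
#'   frame or `NULL`, `roles` data frame or `NULL`).
#' @export
simulate_ontology <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "sim_truth"))
  set.seed(stage_seed(config$seed, 3L))
  genes <- truth$genes
  planted_targets <- unique(unlist(truth$planted_targets, use.names = FALSE))
  planted_all <- unique(c(truth$planted_deg_up, truth$planted_deg_down))
  unplanted <- setdiff(genes, planted_all)
  sz <- config$pathway_size
  sets <- list(); maps <- list()

  # pathway_count is the total collection size: background + planted
  # enriched + one causal map per regulator
  n_bg <- config$pathway_count - config$n_planted_enriched -
    length(truth$planted_regulators)
  if (n_bg < 0)
    stop("pathway_count too small for the planted and causal pathways")
  for (i in seq_len(n_bg)) {
    nm <- sprintf("PW_BG_%02d", i)
    sets[[nm]] <- sample(genes, sz)
    maps[[nm]] <- structure(list(name = nm, members = sets[[nm]],
                                 topology = NULL, roles = NULL),
                            class = "pathway_map")
  }
  for (i in seq_len(config$n_planted_enriched)) {
    nm <- sprintf("PW_ENR_%02d", i)
    n_seed <- ceiling(0.6 * sz)
    n_seed <- min(n_seed, length(planted_targets))
    sets[[nm]] <- c(sample(planted_targets, n_seed),
                    sample(unplanted, sz - n_seed))
    maps[[nm]] <- structure(list(name = nm, members = sets[[nm]],
                                 topology = NULL, roles = NULL),
                            class = "pathway_map")
  }
  for (reg in truth$planted_regulators) {
    nm <- paste0("PW_CAUSAL_", reg)
    ch <- truth$chains[[reg]]
    tg <- truth$planted_targets[[reg]]
    # every causal map carries the full planted TF panel: canonical
    # signalling maps share their transcription-factor layer, and at desk
    # scale a pathway can only be measurably regulator-enriched if
    # regulators co-occur on maps
    core <- unique(c(ch, truth$planted_regulators, reg, tg))
    pad <- if (length(core) < sz) sample(unplanted, sz - length(core)) else character()
    members <- c(core, pad)
    n_chain <- length(ch)
    up <- intersect(tg, truth$planted_deg_up)
    topology <- data.frame(
      source = c(ch[-n_chain], ch[n_chain], rep(reg, length(tg))),
      target = c(ch[-1], reg, tg),
      effect = c(rep("activation", n_chain),
                 ifelse(tg %in% up, "activation", "inhibition")),
      mechanism = c("binding", rep("other", n_chain - 1),
                    rep("transcription-regulation", length(tg))),
      stringsAsFactors = FALSE)
    roles <- data.frame(
      gene = members,
      role = ifelse(members == ch[1], "ligand",
             ifelse(members == ch[2], "receptor",
             ifelse(members %in% ch[-(1:2)], "transducer",
             ifelse(members %in% truth$planted_regulators,
                    "transcription-factor", "other")))),
      blood_expressed = members %in% truth$blood_genes,
      stringsAsFactors = FALSE)
    sets[[nm]] <- members
    maps[[nm]] <- structure(list(name = nm, members = members,
                                 topology = topology, roles = roles),
                            class = "pathway_map")
  }
  collection <- gene_sets(sets, universe = sort(unique(unlist(sets))))
  list(collection = collection, maps = maps)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [simulate_network()],
#' [simulate_expression()] and [simulate_ontology()].
#'
#' @param config a [sim_config].
#' @return list with `network`, `truth`, `expression`, `collection`, `maps`.
#' @export
simulate_study <- function(config = sim_config()) {
  net <- simulate_network(config)
  expr <- simulate_expression(config, net$truth)
  ont <- simulate_ontology(config, net$truth)
  list(network = net$network, truth = net$truth, expression = expr,
       collection = ont$collection, maps = ont$maps)
}
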