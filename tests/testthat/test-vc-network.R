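test_that("protein clustering recovers planted pangenome families", {
  cfg <- small_cfg(seed = 2, n_genera = 2, species_per_genus = 3,
                   variants_per_species = 1,
                   genome_len_range = c(300L, 400L), pangenome_size = 8L)
  comm <- generate_community(cfg)
  pc <- cluster_proteins(comm$proteins)
  fam <- comm$truth$protein_family
  expect_equal(ari(pc$pc_id[match(fam$protein_id, pc$protein_id)],
                   fam$family), 1)
  # identical proteins collapse; unrelated random proteins split
  same <- data.frame(protein_id = c("p1", "p2"),
                     sequence = rep(strrep("MKV", 40), 2))
  expect_equal(length(unique(cluster_proteins(same)$pc_id)), 1)
  set.seed(301)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rnd <- data.frame(
    protein_id = c("q1", "q2"),
    sequence = c(paste(sample(aas, 120, TRUE), collapse = ""),
                 paste(sample(aas, 120, TRUE), collapse = "")))
  expect_equal(length(unique(cluster_proteins(rnd)$pc_id)), 2)
  expect_equal(nrow(cluster_proteins(rnd[0, ])), 0)
})

test_that("hypergeometric pair score matches enumeration oracles", {
  # identical profiles, closed form cross-checked by exhaustive summation
  pa <- paste0("pc", 1:10)
  s_self <- pair_score(pa, pa, universe_size = 1000, n_pairs = 1)
  p_enum <- hyper_tail_enum(10, 10, 1000, 10)
  expect_equal(s_self, -log10(p_enum))
  # sweep of small universes against the summation oracle
  set.seed(302)
  for (i in 1:30) {
    N <- sample(8:25, 1)
    ka <- sample(2:(N - 2), 1); kb <- sample(2:(N - 2), 1)
    univ <- paste0("u", 1:N)
    A <- sample(univ, ka); B <- sample(univ, kb)
    cc <- length(intersect(A, B))
    s <- pair_score(A, B, N, 1)
    if (cc == 0) {
      expect_equal(s, 0)
    } else {
      expect_equal(10^(-s), min(1, hyper_tail_enum(cc, ka, N, kb)),
                   tolerance = 1e-10)
    }
  }
  # one shared PC out of 10 vs 10 in a universe of 20 is unremarkable
  s1 <- pair_score(paste0("x", 1:10), c("x1", paste0("y", 1:9)), 20, 1)
  expect_lt(s1, 0.05)
  expect_equal(pair_score(paste0("a", 1:3), paste0("b", 1:3), 100), 0)
  expect_error(pair_score(paste0("a", 1:3), paste0("a", 1:3), 2), "universe")
})

test_that("MCL separates weakly joined cliques and matches brute-force bipartition", {
  g <- igraph::make_full_graph(4) + igraph::make_full_graph(4)
  g <- igraph::add_edges(g, c(1, 5))
  igraph::E(g)$weight <- c(rep(1, 12), 1e-3)
  igraph::V(g)$name <- letters[1:8]
  part <- mcl(g)
  got <- split(part$genome, part$vc_id)
  # exhaustive best-modularity bipartition over all 2^7 splits
  best <- NULL; best_q <- -Inf
  for (mask in 0:127) {
    memb <- c(1, as.integer(intToBits(mask))[1:7] + 1)
    q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
    if (q > best_q) { best_q <- q; best <- memb }
  }
  expect_equal(length(got), 2)
  expect_setequal(got[[which(vapply(got, function(x) "a" %in% x, TRUE))]],
                  igraph::V(g)$name[best == best[1]])
  # edgeless graph -> all singletons; single clique -> one cluster
  g0 <- igraph::make_empty_graph(4, directed = FALSE)
  igraph::V(g0)$name <- paste0("n", 1:4)
  expect_equal(length(unique(mcl(g0)$vc_id)), 4)
  gk <- igraph::make_full_graph(5)
  igraph::V(gk)$name <- paste0("k", 1:5)
  expect_equal(length(unique(mcl(gk)$vc_id)), 1)
})

test_that("MCL on disconnected components equals MCL per component", {
  set.seed(303)
  g1 <- igraph::sample_gnp(6, 0.8); igraph::V(g1)$name <- paste0("a", 1:6)
  g2 <- igraph::sample_gnp(5, 0.8); igraph::V(g2)$name <- paste0("b", 1:5)
  joint <- igraph::disjoint_union(g1, g2)
  pj <- mcl(joint)
  p1 <- mcl(g1); p2 <- mcl(g2)
  p1$vc_id <- paste0("L", p1$vc_id)  # keep component labels distinct
  p2$vc_id <- paste0("R", p2$vc_id)
  sep <- rbind(p1, p2)
  expect_equal(ari(pj$vc_id[match(sep$genome, pj$genome)], sep$vc_id), 1)
})

test_that("taxonomy transfers from reference members, with ambiguity handling", {
  vcs <- data.frame(genome = c("v1", "v2", "ref1", "v3", "v4", "ref2",
                               "ref3", "v5"),
                    vc_id = c("VC1", "VC1", "VC1", "VC2", "VC3", "VC3",
                              "VC3", "VC4"),
                    stringsAsFactors = FALSE)
  refs <- data.frame(genome = c("ref1", "ref2", "ref3"),
                     label = c("Myoviridae", "Podoviridae", "Siphoviridae"),
                     stringsAsFactors = FALSE)
  out <- assign_taxonomy(vcs, refs)
  expect_equal(unique(out$taxonomy[out$vc_id == "VC1"]), "Myoviridae")
  expect_true(is.na(unique(out$taxonomy[out$vc_id == "VC2"])))
  expect_equal(unique(out$taxonomy[out$vc_id == "VC3"]), "ambiguous")
})

test_that("within-VC AAI behaves on identical genomes and planted divergence", {
  prot <- data.frame(protein_id = c("a1", "a2", "b1", "b2"),
                     sequence = c(strrep("MKVL", 30), strrep("ACDE", 25),
                                  strrep("MKVL", 30), strrep("ACDE", 25)))
  gmap <- data.frame(protein_id = c("a1", "a2", "b1", "b2"),
                     genome_id = c("gA", "gA", "gB", "gB"))
  expect_equal(mean_pairwise_aai(c("gA", "gB"), prot, gmap), 1.0)
  expect_true(is.na(mean_pairwise_aai("gA", prot, gmap)))
  # planted divergence: expected pairwise AA identity (1-a)^2 + a^2/19
  cfg <- small_cfg(seed = 12, n_genera = 1, species_per_genus = 3,
                   variants_per_species = 1,
                   genome_len_range = c(300L, 400L), pangenome_size = 10L,
                   core_fraction = 1)
  comm <- generate_community(cfg)
  aai <- mean_pairwise_aai(comm$truth$votus$votu, comm$proteins,
                           comm$genome_map)
  a <- cfg$aa_divergence
  expect_lt(abs(aai - ((1 - a)^2 + a^2 / 19)), 0.02)
})

test_that("clustering summary reproduces partition arithmetic on random partitions", {
  set.seed(304)
  for (i in 1:50) {
    n <- sample(1:400, 1)
    memb <- paste0("VC", sample.int(max(1, n %/% 2), n, replace = TRUE))
    s <- summarize_clustering(memb)
    expect_equal(s$n_vcs, s$n_multi_vcs + s$n_singleton_vcs)
    expect_equal(s$votus_in_multi, s$n_votus - s$n_singleton_vcs)
    expect_equal(s$pct_singleton_vcs,
                 as.integer(floor(100 * s$n_singleton_vcs / s$n_vcs + 0.5)))
  }
  one <- summarize_clustering("VC1")
  expect_equal(one$n_singleton_vcs, 1)
  expect_equal(one$pct_singleton_vcs, 100)
  expect_equal(one$pct_votus_in_singletons, 100)
})

test_that("habitat overlap and the aquatic-like rule follow VC membership", {
  vcs <- data.frame(genome = c("v1", "v2", "v3", "v4", "v5"),
                    vc_id = c("VC1", "VC1", "VC2", "VC3", "VC3"))
  hab <- data.frame(votu = paste0("v", 1:5),
                    habitat = c("peat", "marine", "soil", "peat", "peat"))
  ov <- habitat_overlap(vcs, hab)
  expect_equal(sum(ov$combination_counts), 3)
  expect_equal(unname(ov$combination_counts[["marine+peat"]]), 1)
  expect_equal(ov$pct_soil_vcs_sharing_aquatic, 100 / 3)
  expect_setequal(aquatic_like_votus(vcs, hab), c("v1", "v2"))
  # soil vOTU alone in a VC is not aquatic-like
  expect_false("v3" %in% aquatic_like_votus(vcs, hab))
  empty <- habitat_overlap(vcs[0, ], hab)
  expect_equal(sum(empty$combination_counts), 0)
})

test_that("VC pipeline on the synthetic community recovers planted genera", {
  cfg <- small_cfg(seed = 2)
  comm <- generate_community(cfg)
  pc <- cluster_proteins(comm$proteins)
  prof <- genome_profiles(pc, comm$genome_map)
  vc <- mcl(build_vc_graph(prof))
  truth_g <- comm$truth$species2genus$genus[
    match(vc$genome, comm$truth$species2genus$votu)]
  expect_gte(ari(vc$vc_id, truth_g), 0.9)
  # recovered aquatic-like set equals the planted truth flags
  aq <- aquatic_like_votus(vc, comm$habitats)
  expect_setequal(aq,
                  comm$truth$votus$votu[comm$truth$votus$aquatic_like])
  # merging habitats never shrinks a VC habitat set (refinement property)
  ov_all <- habitat_overlap(vc, comm$habitats)
  sub <- comm$habitats[comm$habitats$habitat != "marine", , drop = FALSE]
  ov_sub <- habitat_overlap(vc[vc$genome %in% sub$votu, , drop = FALSE],
                            sub)
  for (v in ov_sub$vc_habitats$vc_id) {
    s_sub <- strsplit(ov_sub$vc_habitats$habitat_set[
      ov_sub$vc_habitats$vc_id == v], "+", fixed = TRUE)[[1]]
    s_all <- strsplit(ov_all$vc_habitats$habitat_set[
      ov_all$vc_habitats$vc_id == v], "+", fixed = TRUE)[[1]]
    expect_true(all(s_sub %in% s_all))
  }
})
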