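test_that("config validation enforces the species-boundary invariants", {
  expect_error(truth_config(between_species_ani = 0.92), "between_species")
  expect_error(truth_config(within_species_ani = 0.93), "within_species")
  expect_error(truth_config(n_genera = -1L), "counts")
  expect_error(generate_community(truth_config(n_genera = 0L)),
               "degenerate")
  cfg <- truth_config(n_habitats = 2L)
  expect_equal(cfg$habitats, c("peat", "marine"))
})

test_that("minimal community has one contig from one pangenome", {
  cfg <- truth_config(seed = 5, n_genera = 1L, species_per_genus = 1L,
                      variants_per_species = 1L,
                      genome_len_range = c(500L, 600L))
  comm <- generate_community(cfg)
  expect_equal(length(comm$contigs), 1)
  expect_equal(unique(comm$proteins$genome_id), names(comm$contigs))
  expect_equal(length(unique(comm$truth$protein_family$family)),
               nrow(comm$proteins))
})

test_that("community respects planted identity bounds (full-DP oracle on all pairs)", {
  cfg <- truth_config(seed = 7, n_genera = 3, species_per_genus = 4,
                      variants_per_species = 3,
                      genome_len_range = c(400L, 600L))
  comm <- generate_community(cfg)
  expect_equal(length(comm$contigs), 36)
  c2s <- stats::setNames(comm$truth$contig2species$votu,
                         comm$truth$contig2species$contig)
  s2g <- stats::setNames(comm$truth$species2genus$genus,
                         comm$truth$species2genus$votu)
  ids <- names(comm$contigs)
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      pi <- pair_identity(comm$contigs[[ids[i]]], comm$contigs[[ids[j]]])
      if (c2s[ids[i]] == c2s[ids[j]]) {
        expect_gte(pi$identity, 0.95)
        expect_gte(pi$shorter_cov, 0.85)
      } else {
        # cross-species pairs must fail the 0.95/85% species gate; for
        # same-genus pairs the near-full-length alignment also stays
        # below 0.90 identity (cross-genus pairs instead fail on
        # coverage: unrelated sequences only share tiny perfect seeds)
        expect_false(pi$identity >= 0.95 && pi$shorter_cov >= 0.85)
        if (s2g[c2s[ids[i]]] == s2g[c2s[ids[j]]]) {
          expect_lte(pi$identity, 0.90)
        }
      }
    }
  }
})

test_that("generation is deterministic: same seed, identical bytes", {
  cfg <- small_cfg(seed = 13, genome_len_range = c(400L, 500L))
  a <- generate_community(cfg)
  b <- generate_community(cfg)
  expect_identical(a$contigs, b$contigs)
  expect_identical(a$proteins, b$proteins)
  ha <- generate_hosts(cfg, a)
  hb <- generate_hosts(cfg, b)
  expect_identical(ha$mag_contigs, hb$mag_contigs)
  expect_identical(ha$spacers, hb$spacers)
  aa <- generate_abundance(cfg, a)
  ab2 <- generate_abundance(cfg, b)
  expect_identical(aa$counts, ab2$counts)
  ra <- generate_reads(a, aa$counts, cfg)
  rb <- generate_reads(b, ab2$counts, cfg)
  expect_identical(ra, rb)
})

test_that("habitat labels live at the species level and drive aquatic-like truth", {
  cfg <- small_cfg(seed = 21)
  comm <- generate_community(cfg)
  votus <- comm$truth$votus
  expect_equal(sort(votus$votu), sort(comm$habitats$votu))
  by_genus <- split(votus, votus$genus)
  for (g in by_genus) {
    has_aq <- any(g$habitat %in% c("marine", "freshwater"))
    expect_equal(unique(g$aquatic_like), has_aq)
  }
})

test_that("planted spacers have the configured mismatch count (brute-force scan)", {
  for (p in c(0, 1)) {
    cfg <- small_cfg(seed = 31 + p, spacer_mismatch_prob = p,
                     n_hosts = 4L, spacers_per_host = 3L)
    comm <- generate_community(cfg)
    h <- generate_hosts(cfg, comm)
    links <- h$truth$links
    expect_equal(nrow(links), 12)
    expect_true(all(links$mismatches == p))
    for (k in seq_len(nrow(links))) {
      sp <- h$spacers$sequence[h$spacers$array_id == links$mag[k] &
                                 h$spacers$spacer_index ==
                                 links$spacer_index[k]]
      hits <- naive_spacer_scan(sp, comm$contigs[[links$votu[k]]], 1)
      expect_equal(nrow(hits), 1)
      expect_equal(hits$mismatches, p)
      expect_equal(hits$start, links$protospacer_start[k])
      expect_equal(hits$strand, links$strand[k])
    }
  }
})

test_that("host generation edge cases: no spacers, impossible spacer length", {
  cfg0 <- small_cfg(seed = 41, spacers_per_host = 0L)
  comm <- generate_community(cfg0)
  h <- generate_hosts(cfg0, comm)
  expect_equal(nrow(h$spacers), 0)
  expect_equal(nrow(h$truth$links), 0)
  expect_equal(nrow(h$arrays), cfg0$n_hosts)
  cfg_bad <- small_cfg(seed = 41, genome_len_range = c(60L, 80L),
                       spacer_len = 100L)
  comm_bad <- generate_community(cfg_bad)
  expect_error(generate_hosts(cfg_bad, comm_bad), "spacer_len")
})

test_that("abundance design conserves read counts and handles edge configs", {
  cfg <- small_cfg(seed = 51)
  comm <- generate_community(cfg)
  ab <- generate_abundance(cfg, comm)
  expect_identical(unname(colSums(ab$counts)),
                   as.numeric(ab$metadata$library_size))
  reads <- generate_reads(comm, ab$counts, cfg)
  got <- vapply(reads, function(r) nrow(r$reads), 1L)
  expect_identical(unname(got), as.integer(ab$metadata$library_size))
  # zero-count vOTUs yield zero reads
  zero_v <- rownames(ab$counts)[ab$counts[, 1] == 0]
  if (length(zero_v)) {
    expect_false(any(reads[[1]]$aln$contig_id %in% zero_v))
  }
  expect_error(generate_abundance(small_cfg(nb_dispersion = 0), comm),
               "nb_dispersion")
  cfg0 <- small_cfg(seed = 51, n_samples = 0L)
  ab0 <- generate_abundance(cfg0, comm)
  expect_equal(dim(ab0$counts), c(12, 0))
  expect_equal(nrow(ab0$metadata), 0)
})

test_that("read simulation: planted errors match the truth alignments", {
  cfg <- small_cfg(seed = 61, error_rate = 0, n_samples = 4L)
  comm <- generate_community(cfg)
  ab <- generate_abundance(cfg, comm)
  reads <- generate_reads(comm, ab$counts, cfg)
  for (r in reads) {
    if (nrow(r$aln)) expect_true(all(read_identity(r$aln) == 1))
  }
  # substitution errors: mean identity ~ 1 - error_rate
  cfg2 <- small_cfg(seed = 62, error_rate = 0.05, read_len = 100L,
                    n_samples = 6L, nb_mean_range = c(40, 80))
  comm2 <- generate_community(cfg2)
  ab2 <- generate_abundance(cfg2, comm2)
  reads2 <- generate_reads(comm2, ab2$counts, cfg2)
  idents <- unlist(lapply(reads2, function(r) read_identity(r$aln)))
  expect_gt(length(idents), 2000)
  expect_lt(abs(mean(idents) - 0.95), 0.005)
  # reads are faithful copies: planted NM equals direct disagreement count
  a1 <- reads2[[1]]$aln[1:20, ]
  for (k in seq_len(nrow(a1))) {
    src <- substr(comm2$contigs[[a1$contig_id[k]]], a1$start[k] + 1,
                  a1$end[k])
    diff <- sum(strsplit(src, "")[[1]] != strsplit(a1$seq[k], "")[[1]])
    expect_equal(diff, a1$edit_distance[k])
  }
})

test_that("aquatic enrichment odds of 1 leaves the surface group unenriched", {
  # Monte-Carlo: over seeds, the aquatic fraction among surface-group
  # differentials should match the overall planted aquatic fraction
  k_tot <- n_tot <- 0; p_aq <- c()
  for (s in 1:20) {
    cfg <- abundance_cfg(seed = 500 + s, n_genera = 25,
                         aquatic_enrichment_odds = 1)
    comm <- generate_community(cfg)
    ab <- generate_abundance(cfg, comm)
    aq <- stats::setNames(comm$truth$votus$aquatic_like,
                          comm$truth$votus$votu)
    surf <- ab$truth$da_votus$votu[ab$truth$da_votus$group == 1]
    k_tot <- k_tot + sum(aq[surf]); n_tot <- n_tot + length(surf)
    p_aq <- c(p_aq, mean(aq))
  }
  p0 <- mean(p_aq)
  ci <- p0 + c(-1, 1) * 1.96 * sqrt(p0 * (1 - p0) / n_tot)
  expect_gte(k_tot / n_tot, ci[1])
  expect_lte(k_tot / n_tot, ci[2])
})
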