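HABITAT_POOL <- c("peat", "marine", "freshwater", "soil")
DNA <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Per-copy substitution rate s such that two copies mutated independently at
# rate s from a common ancestor have expected pairwise identity `ani`
# (substitutions uniform over the 3 alternative bases):
#   ani = (1-s)^2 + s^2/3  =>  (4/3) s^2 - 2 s + (1 - ani) = 0.
rate_for_pairwise_ani <- function(ani) {
  (2 - sqrt(4 - (16 / 3) * (1 - ani))) / (8 / 3)
}

rand_seq <- function(n, alphabet = DNA) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

mutate_seq <- function(seq, rate, alphabet = DNA) {
  ch <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(ch)) < rate)
  for (i in hit) {
    ch[i] <- sample(setdiff(alphabet, ch[i]), 1L)
  }
  list(seq = paste(ch, collapse = ""), n_sub = length(hit), pos = hit)
}

revcomp <- function(seq) {
  comp <- chartr("ACGTUMRWSYKVHDBNacgtumrwsykvhdbn",
                 "TGCAAKYWSRMBDHVNtgcaakywsrmbdhvn", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Configuration for the synthetic peat virome community
#'
#' The generator plants a genus-structured viral community: each genus has a
#' protein pangenome and a DNA ancestor; species founders diverge to
#' `between_species_ani`, within-species variants to `within_species_ani`
#' (rates solved so that *pairwise* identities, not founder-to-copy
#' identities, hit the targets). Habitats are assigned per species (vOTU),
#' abundances follow a depth-structured negative binomial with a planted
#' aquatic-like enrichment in the surface group, and CRISPR spacers are
#' copied from vOTU protospacers with 0-1 mismatches.
#'
#' @param seed Root seed; per-stage streams use fixed offsets from it.
#' @param n_habitats Number of habitat labels used, drawn in order from
#'   peat, marine, freshwater, soil.
#' @param n_genera,species_per_genus,variants_per_species Community shape.
#' @param genome_len_range Genome length range in bp.
#' @param pangenome_size Protein families per genus.
#' @param core_fraction Fraction of the pangenome carried by every species
#'   of the genus.
#' @param within_species_ani,between_species_ani Target pairwise average
#'   nucleotide identities within species and between species of a genus.
#' @param aa_divergence Per-copy amino-acid substitution rate of a species'
#'   protein copy relative to its family founder.
#' @param aquatic_genus_prob Probability that a genus contains one
#'   marine/freshwater species (making all its members aquatic-like);
#'   remaining species are terrestrial (peat-weighted).
#' @param n_hosts,spacers_per_host,spacer_len,spacer_mismatch_prob,host_len
#'   CRISPR host parameters; each planted spacer carries one substitution
#'   with probability `spacer_mismatch_prob`, otherwise zero.
#' @param n_samples,depth_levels Abundance design (samples are balanced
#'   across the ordered depth levels).
#' @param nb_mean_range,nb_dispersion Negative-binomial abundance model;
#'   `nb_dispersion` is the NB dispersion alpha (variance mu + alpha mu^2).
#' @param da_fraction,da_fold Fraction of vOTUs planted as depth-differential
#'   and their fold elevation at the peak depth.
#' @param aquatic_enrichment_odds Odds multiplier pushing aquatic-like vOTUs
#'   into the surface differential group.
#' @param read_len,error_rate Read simulation parameters.
#' @return A validated list of class `truth_config`.
#' @export
truth_config <- function(seed = 1L,
                         n_habitats = 4L,
                         n_genera = 4L,
                         species_per_genus = 3L,
                         variants_per_species = 3L,
                         genome_len_range = c(1200L, 1800L),
                         pangenome_size = 24L,
                         core_fraction = 0.5,
                         within_species_ani = 0.97,
                         between_species_ani = 0.85,
                         aa_divergence = 0.10,
                         aquatic_genus_prob = 0.25,
                         n_hosts = 6L,
                         spacers_per_host = 4L,
                         spacer_len = 32L,
                         spacer_mismatch_prob = 0.3,
                         host_len = 4000L,
                         n_samples = 20L,
                         depth_levels = c("10-20", "40-50", "100-125",
                                          "150-175"),
                         nb_mean_range = c(5, 50),
                         nb_dispersion = 0.5,
                         da_fraction = 0.4,
                         da_fold = 4,
                         aquatic_enrichment_odds = 4,
                         read_len = 100L,
                         error_rate = 0.005) {
  cfg <- as.list(environment())
  stopifnot(between_species_ani > 0, between_species_ani < 0.90,
            within_species_ani >= 0.95, within_species_ani <= 1)
  counts <- c(n_habitats, n_genera, species_per_genus, variants_per_species,
              pangenome_size, n_hosts, spacers_per_host, n_samples)
  if (any(counts < 0)) stop("truth_config: counts must be >= 0")
  if (n_habitats < 1 || n_habitats > length(HABITAT_POOL)) {
    stop("n_habitats must be between 1 and ", length(HABITAT_POOL))
  }
  cfg$habitats <- HABITAT_POOL[seq_len(n_habitats)]
  class(cfg) <- "truth_config"
  cfg
}

#' Generate the synthetic viral community
#'
#' @param config A [truth_config()].
#' @return A list with `contigs` (named vector, all variants), `proteins`
#'   (data frame `protein_id`, `genome_id`, `sequence`), `genome_map`,
#'   `habitats` (per vOTU), and `truth` tables (species/genus partitions,
#'   protein families, aquatic-like flags, planted identities).
#' @export
generate_community <- function(config) {
  stopifnot(inherits(config, "truth_config"))
  if (config$n_genera < 1 || config$species_per_genus < 1 ||
      config$variants_per_species < 1) {
    stop("degenerate config: need at least one genus, species and variant")
  }
  set.seed(config$seed + 11L)
  r_between <- rate_for_pairwise_ani(config$between_species_ani)
  r_within <- rate_for_pairwise_ani(config$within_species_ani)

  contigs <- character(0)
  contig2species <- species2genus <- character(0)
  prot_rows <- list()
  votu_ids <- character(0)
  votu_habitat <- character(0)
  votu_genus <- character(0)
  aquatic_habs <- intersect(c("marine", "freshwater"), config$habitats)
  terr_habs <- intersect(c("peat", "soil"), config$habitats)
  terr_w <- c(peat = 0.7, soil = 0.3)[terr_habs]
  terr_w <- terr_w / sum(terr_w)

  for (g in seq_len(config$n_genera)) {
    # habitat structure is genus-level: an "aquatic" genus carries one
    # marine/freshwater species, making all its members aquatic-like
    aquatic_genus <- length(aquatic_habs) > 0 &&
      stats::runif(1) < config$aquatic_genus_prob
    aquatic_species <- if (aquatic_genus)
      sample.int(config$species_per_genus, 1L) else 0L
    gid <- sprintf("g%02d", g)
    glen <- sample(seq(config$genome_len_range[1], config$genome_len_range[2]),
                   1L)
    ancestor <- rand_seq(glen)
    fam_len <- sample(80:200, config$pangenome_size, replace = TRUE)
    fam_seq <- vapply(fam_len, rand_seq, "", alphabet = AA20)
    fam_ids <- sprintf("%s_f%02d", gid, seq_len(config$pangenome_size))
    n_core <- ceiling(config$core_fraction * config$pangenome_size)

    for (s in seq_len(config$species_per_genus)) {
      sid <- sprintf("%s_s%02d", gid, s)
      founder <- mutate_seq(ancestor, r_between)$seq
      hab <- if (s == aquatic_species) sample(aquatic_habs, 1L) else
        sample(terr_habs, 1L, prob = terr_w)
      votu_ids <- c(votu_ids, paste0(sid, "_v01"))
      votu_habitat <- c(votu_habitat, hab)
      votu_genus <- c(votu_genus, gid)
      # protein complement: all core families plus a random accessory half
      acc <- which(stats::runif(config$pangenome_size) < 0.5)
      fams <- sort(union(seq_len(n_core), acc))
      for (f in fams) {
        pseq <- mutate_seq(fam_seq[f], config$aa_divergence, AA20)$seq
        prot_rows[[length(prot_rows) + 1L]] <- data.frame(
          protein_id = sprintf("%s_p%02d", sid, f),
          genome_id = paste0(sid, "_v01"),
          family = fam_ids[f], sequence = pseq, stringsAsFactors = FALSE)
      }
      for (v in seq_len(config$variants_per_species)) {
        vid <- sprintf("%s_v%02d", sid, v)
        seq_v <- if (v == 1L) founder else mutate_seq(founder, r_within)$seq
        contigs[vid] <- seq_v
        contig2species <- c(contig2species, stats::setNames(
          paste0(sid, "_v01"), vid))
        species2genus <- c(species2genus, stats::setNames(gid,
                                                          paste0(sid, "_v01")))
      }
    }
  }
  proteins <- do.call(rbind, prot_rows)
  genus_hab <- split(votu_habitat, votu_genus)
  aquatic_like <- vapply(seq_along(votu_ids), function(i) {
    any(genus_hab[[votu_genus[i]]] %in% c("marine", "freshwater"))
  }, TRUE)

  list(contigs = contigs,
       proteins = proteins[, c("protein_id", "genome_id", "sequence")],
       genome_map = proteins[, c("protein_id", "genome_id")],
       habitats = data.frame(votu = votu_ids, habitat = votu_habitat,
                             stringsAsFactors = FALSE),
       truth = list(
         contig2species = data.frame(contig = names(contig2species),
                                     votu = unname(contig2species),
                                     stringsAsFactors = FALSE),
         species2genus = data.frame(votu = names(species2genus)[
           !duplicated(names(species2genus))],
           genus = unname(species2genus)[!duplicated(names(species2genus))],
           stringsAsFactors = FALSE),
         protein_family = proteins[, c("protein_id", "family")],
         votus = data.frame(votu = votu_ids, genus = votu_genus,
                            habitat = votu_habitat,
                            aquatic_like = aquatic_like,
                            stringsAsFactors = FALSE)),
       config = config)
}

#' Generate CRISPR-carrying hosts for a synthetic community
#'
#' Each host MAG carries one CRISPR array (repeat-spacer-repeat-...); every
#' spacer is copied from a protospacer in a chosen vOTU founder sequence
#' with 0 or 1 substitutions, on a random strand, and the array (repeats
#' included) is planted verbatim in the host contig. Host taxonomy strings
#' follow a nested genus/family hierarchy so consensus-host checks are
#' testable.
#'
#' @param config A [truth_config()].
#' @param community Output of [generate_community()].
#' @return A list with `mag_contigs`, `mags` (taxonomy table), `arrays`,
#'   `spacers`, and `truth$links` (planted vOTU-host links with mismatch
#'   counts).
#' @export
generate_hosts <- function(config, community) {
  set.seed(config$seed + 22L)
  votus <- community$truth$votus$votu
  vseq <- community$contigs[votus]
  if (config$spacers_per_host > 0 &&
      config$spacer_len > min(nchar(vseq))) {
    stop("spacer_len longer than the shortest vOTU sequence")
  }
  mags <- arrays <- spacer_rows <- link_rows <- list()
  mag_contigs <- character(0)
  for (h in seq_len(config$n_hosts)) {
    mag_id <- sprintf("mag%02d", h)
    genus_i <- ceiling(h / 2)
    family_i <- ceiling(genus_i / 2)
    tax <- sprintf(
      "d__Bacteria;p__P%02d;c__C%02d;o__O%02d;f__F%02d;g__G%02d;s__S%02d",
      1L, 1L, ceiling(family_i / 2), family_i, genus_i, h)
    rep_seq <- rand_seq(28L)
    spacers <- character(0)
    if (config$spacers_per_host > 0) {
      for (k in seq_len(config$spacers_per_host)) {
        # rejection-sample until the planted spacer matches exactly one
        # protospacer (<= 1 mismatch, both strands) across all vOTUs, so
        # the truth table records a unique source
        for (try in 1:100) {
          v <- sample(votus, 1L)
          L <- nchar(vseq[[v]])
          pos <- sample.int(L - config$spacer_len + 1L, 1L)
          proto <- substr(vseq[[v]], pos, pos + config$spacer_len - 1L)
          n_mm <- as.integer(stats::runif(1) < config$spacer_mismatch_prob)
          sp <- proto
          if (n_mm > 0) {
            i <- sample.int(config$spacer_len, 1L)
            substr(sp, i, i) <- sample(setdiff(DNA, substr(proto, i, i)),
                                       1L)
          }
          hits <- match_pattern_hits(sp, as.list(vseq), max_mismatch = 1L)
          if (nrow(hits) == 1L) break
        }
        if (nrow(hits) != 1L) {
          stop("could not plant a unique spacer; community too repetitive")
        }
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") sp <- revcomp(sp)
        spacers <- c(spacers, sp)
        spacer_rows[[length(spacer_rows) + 1L]] <- data.frame(
          array_id = mag_id, spacer_index = k, sequence = sp,
          stringsAsFactors = FALSE)
        link_rows[[length(link_rows) + 1L]] <- data.frame(
          votu = v, mag = mag_id, spacer_index = k, mismatches = n_mm,
          strand = strand, protospacer_start = pos - 1L,
          stringsAsFactors = FALSE)
      }
    }
    locus <- paste0(rep_seq, paste0(spacers, rep_seq, collapse = ""))
    if (!length(spacers)) locus <- rep_seq
    backbone <- rand_seq(config$host_len)
    at <- sample.int(config$host_len, 1L)
    mag_contigs[mag_id] <- paste0(substr(backbone, 1, at), locus,
                                  substr(backbone, at + 1L, config$host_len))
    mags[[h]] <- data.frame(mag = mag_id, taxonomy = tax,
                            stringsAsFactors = FALSE)
    arrays[[h]] <- data.frame(array_id = mag_id, repeat_seq = rep_seq,
                              source_sample = sprintf("s%02d",
                                                      1L + (h %% 2L)),
                              stringsAsFactors = FALSE)
  }
  list(mag_contigs = mag_contigs,
       mags = do.call(rbind, mags),
       arrays = do.call(rbind, arrays),
       spacers = if (length(spacer_rows)) do.call(rbind, spacer_rows) else
         data.frame(array_id = character(), spacer_index = integer(),
                    sequence = character(), stringsAsFactors = FALSE),
       truth = list(links = if (length(link_rows)) do.call(rbind, link_rows)
                    else data.frame(votu = character(), mag = character(),
                                    spacer_index = integer(),
                                    mismatches = integer(),
                                    strand = character(),
                                    protospacer_start = integer(),
                                    stringsAsFactors = FALSE)))
}

#' Generate a depth-structured negative-binomial abundance design
#'
#' Counts are per-vOTU read counts; the per-sample library size is the
#' column sum. A planted fraction of vOTUs is depth-differential in one of
#' three groups peaking shallow, mid, and deep; aquatic-like vOTUs are
#' pushed into the surface group with odds `aquatic_enrichment_odds`.
#'
#' @param config A [truth_config()].
#' @param community Output of [generate_community()] (only the vOTU truth
#'   table is used).
#' @return List with `counts` (vOTU x sample), `metadata`, and
#'   `truth` (`da_votus` with group labels, `group_peak_level`).
#' @export
generate_abundance <- function(config, community) {
  if (config$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  set.seed(config$seed + 33L)
  votus <- community$truth$votus
  nv <- nrow(votus)
  ns <- config$n_samples
  L <- length(config$depth_levels)
  sample_ids <- sprintf("s%02d", seq_len(ns))
  depth <- config$depth_levels[1L + (seq_len(ns) - 1L) %% L]
  counts <- matrix(0L, nrow = nv, ncol = ns,
                   dimnames = list(votus$votu, sample_ids))
  meta <- data.frame(
    sample_id = sample_ids,
    depth_level = factor(depth, levels = config$depth_levels),
    # two sampling years, balanced across depth levels
    year = 2015L + as.integer(seq_len(ns) > ns / 2),
    temperature_treatment = sample(c("ambient", "+2.25", "+4.5", "+6.75",
                                     "+9"), ns, replace = TRUE),
    stringsAsFactors = FALSE)
  di <- match(meta$depth_level, config$depth_levels)
  meta$moisture <- pmin(0.95, pmax(0.4, 0.9 - 0.08 * (di - 1) +
                                     stats::rnorm(ns, 0, 0.03)))
  meta$ch4 <- exp(0.5 * di + stats::rnorm(ns, 0, 0.2))
  meta$co2 <- exp(0.3 * di + stats::rnorm(ns, 0, 0.2))
  meta$alpha_c <- 1.05 + 0.01 * di + stats::rnorm(ns, 0, 0.005)

  # planted group shapes mirror the depth bands: shallow peak, mid peak,
  # and a deep group elevated across the two deepest levels
  peaks <- if (L >= 4) list(1L, 2L, c(L - 1L, L)) else
    as.list(seq_len(min(3L, L)))
  base_mu <- exp(stats::runif(nv, log(config$nb_mean_range[1]),
                              log(config$nb_mean_range[2])))
  n_da <- round(config$da_fraction * nv)
  da_idx <- if (n_da > 0) sort(sample.int(nv, n_da)) else integer(0)
  grp <- integer(0)
  if (n_da > 0) {
    odds <- config$aquatic_enrichment_odds
    grp <- vapply(da_idx, function(i) {
      w <- rep(1, length(peaks))
      if (votus$aquatic_like[i]) w[1] <- odds
      sample.int(length(peaks), 1L, prob = w)
    }, 1L)
  }
  sf <- exp(stats::rnorm(ns, 0, 0.3))
  if (ns > 0) {
    fold <- matrix(1, nrow = nv, ncol = L)
    if (n_da > 0) {
      for (k in seq_along(da_idx)) {
        fold[da_idx[k], peaks[[grp[k]]]] <- config$da_fold
      }
    }
    for (s in seq_len(ns)) {
      mu <- base_mu * fold[, di[s]] * sf[s]
      counts[, s] <- stats::rnbinom(nv, mu = mu,
                                    size = 1 / config$nb_dispersion)
    }
  }
  meta$library_size <- colSums(counts)
  list(counts = counts, metadata = meta,
       truth = list(
         da_votus = data.frame(votu = votus$votu[da_idx], group = grp,
                               stringsAsFactors = FALSE),
         group_peak_level = lapply(peaks, function(p)
           config$depth_levels[p]),
         size_factors = stats::setNames(sf, sample_ids)))
}

#' Simulate reads and truth alignments from an abundance design
#'
#' Draws exactly `counts[v, s]` reads per vOTU and sample from the vOTU
#' founder sequence, uniform start positions, substitution errors at
#' `error_rate`, random strand. The truth alignment records the generating
#' coordinates and an edit distance equal to the planted substitution
#' count.
#'
#' @param community Output of [generate_community()].
#' @param counts vOTU x sample count matrix (see [generate_abundance()]).
#' @param config A [truth_config()].
#' @return A list per sample, each with `reads` (`id`, `seq` as sequenced)
#'   and `aln` (truth alignment data frame in [read_sam()] layout plus
#'   `seq`).
#' @export
generate_reads <- function(community, counts, config) {
  set.seed(config$seed + 44L)
  votus <- rownames(counts)
  vseq <- community$contigs[votus]
  too_short <- nchar(vseq) < config$read_len
  if (any(too_short)) {
    warning("skipping ", sum(too_short),
            " vOTU(s) shorter than read_len: ",
            paste(votus[too_short], collapse = ", "))
  }
  out <- vector("list", ncol(counts))
  names(out) <- colnames(counts)
  for (s in seq_len(ncol(counts))) {
    rows <- list()
    for (v in seq_along(votus)) {
      n <- counts[v, s]
      if (n == 0 || too_short[v]) next
      L <- nchar(vseq[[v]])
      starts <- sample.int(L - config$read_len + 1L, n, replace = TRUE) - 1L
      for (r in seq_len(n)) {
        frag <- substr(vseq[[v]], starts[r] + 1L,
                       starts[r] + config$read_len)
        mut <- mutate_seq(frag, config$error_rate)
        strand <- sample(c("+", "-"), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          read_id = sprintf("%s_%s_r%05d", colnames(counts)[s], votus[v],
                            length(rows) + 1L),
          contig_id = votus[v], start = starts[r],
          end = starts[r] + config$read_len,
          aligned_ref_len = config$read_len,
          aligned_read_len = config$read_len,
          edit_distance = mut$n_sub, strand = strand, seq = mut$seq,
          stringsAsFactors = FALSE)
      }
    }
    aln <- if (length(rows)) do.call(rbind, rows) else
      data.frame(read_id = character(), contig_id = character(),
                 start = integer(), end = integer(),
                 aligned_ref_len = integer(), aligned_read_len = integer(),
                 edit_distance = integer(), strand = character(),
                 seq = character(), stringsAsFactors = FALSE)
    reads <- aln[, c("read_id", "seq")]
    if (nrow(reads)) {
      flip <- aln$strand == "-"
      reads$seq[flip] <- vapply(reads$seq[flip], revcomp, "")
    }
    names(reads) <- c("id", "seq")
    out[[s]] <- list(reads = reads, aln = aln)
  }
  out
}
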