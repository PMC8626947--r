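---
title: "Methods: from viral contigs to community ecology in peat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from viral contigs to community ecology in peat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the models and procedures the package implements,
the choices behind their tunable parameters, what the synthetic community
generator does and does not emulate, and the numerical conventions that
make every stage deterministic and testable. The `analysis/` scripts in
the source repository run the stages in order on a generated community;
`scripts/acceptance.R` recomputes the dataset-level worked examples.

## The pipeline at a glance

Peat viromics starts from assembled viral contigs and read alignments and
proceeds through:

1. **Screening** — external viral predictors are filtered by their
   published score rules (a DeepVirFinder-style score > 0.9 with p < 0.05,
   or a VirSorter-style category in {1, 2, 4, 5}; contigs ≥ 10 kbp).
   Auxiliary metabolic gene (AMG) candidates are kept when the auxiliary
   score is < 4, none of the flags F/T/P/A is present, and both a gene id
   and description exist. Comparisons are strict exactly as printed;
   boundary values are excluded.
2. **vOTU dereplication** — species-level viral populations are formed
   greedily, longest contig first: a contig joins the first existing
   representative it matches at ≥ 95% nucleotide identity over ≥ 85% of
   the shorter contig's length, otherwise it founds a new cluster. Ties in
   length break lexicographically by id, which makes the partition
   invariant to input order.
3. **Detection** — reads are kept at ≥ 90% read-centric identity
   (1 − NM/aligned read length, so insertions count against identity and
   reference deletions do not); a vOTU is *detected* in a sample when
   ≥ 75% of its positions are covered at least 1×; its abundance is the
   10%-trimmed mean per-base depth ("tpmean": the ⌊0.1 L⌋ highest and
   lowest values are discarded), normalized per 10⁷ library reads. All
   thresholds are inclusive (≥). The fixed 10⁷ scale is arbitrary but
   harmless: every downstream statistic is per-sample scale-robust.
4. **Viral clusters (VCs)** — genus-level groups from shared predicted
   protein content. Proteins are clustered greedily at ≥ 60% amino-acid
   identity over ≥ 80% of the shorter protein; genomes are scored
   pairwise by the upper-tail hypergeometric probability of sharing at
   least the observed number of protein clusters, Bonferroni-corrected by
   the number of genome pairs and expressed as −log₁₀ p; edges with score
   ≥ 1 enter a graph clustered by Markov clustering (MCL, inflation 2).
   Both levels use MCL rather than the two different algorithms the
   field's tool chains combine — MCL is fully specifiable, deterministic,
   and reproduces the planted genus partition. Singleton VCs are counted
   as VCs throughout. Taxonomy transfers to any VC containing a reference
   genome (conflicts yield "ambiguous", still counted classified).
5. **Ecology** — Hellinger standardization, Bray–Curtis dissimilarity,
   principal coordinates, Mantel tests (Pearson, one-sided), PERMANOVA,
   accumulation curves over permuted sample orders, negative-binomial
   likelihood-ratio tests for depth-differential vOTUs, complete-linkage
   grouping of Z-transformed depth profiles, and hypergeometric
   enrichment of the "aquatic-like" trait per group.
6. **Virus–host linkage** — CRISPR repeats anchor arrays to MAGs at 100%
   identity (exact substring, both strands); spacers anchor arrays to
   vOTU protospacers at ≤ 1 mismatch over the full spacer
   (substitution-only Hamming matching; spacers < 20 nt are rejected,
   since one mismatch would already violate a 95% identity rule there).
   A linkage requires both anchors from the same array.
7. **Phylogenetic dispersion** — the Fritz–Purvis D statistic for binary
   traits on a phylogeny, with permutation and Brownian-threshold nulls.

## Alignment and identity conventions

Pairwise identity uses an overlap (free-end-gap) dynamic-programming
alignment: match +1, mismatch −1, gap −2, terminal gaps free on both
sequences. Identity is the fraction of matched columns within the
non-terminal-gap region of the optimal path; coverage is the fraction of
the shorter sequence's bases inside that region. Reverse-complement
orientation is also evaluated for nucleotide input and the better-scoring
orientation kept. Two consequences worth knowing:

* For sequences that differ only by substitutions, the optimum is the
  gapless alignment, and identity equals Hamming identity — this is what
  makes the planted 95% species boundary exactly testable.
* For unrelated sequences the optimizer finds a short, high-identity
  chance region with negligible coverage; such pairs fail the clustering
  gates on *coverage*, not identity. For the same reason, the within-VC
  amino-acid identity (AAI) summary only counts reciprocal best matches
  aligning ≥ 50% of the shorter protein.

Internally all coordinates are 0-based half-open; SAM ingestion is the
single place where 1-based coordinates appear. Mapped SAM records must
carry an NM tag — identity is undefined without it, and the parser fails
loudly rather than guessing.

## The negative-binomial depth test

For each vOTU, counts across samples are modeled as negative binomial
with a per-sample offset given by median-of-ratios size factors (the
geometric-mean reference uses vOTUs with all-positive counts). A single
per-vOTU dispersion is shared between the full model
(log μ = offset + β₀ + β_level) and the intercept-only reduced model, and
the likelihood-ratio statistic is twice the log-likelihood difference.

Two small-sample choices depart from large-panel practice and are made
deliberately, without any dispersion shrinkage or outlier replacement:

* **Dispersion estimation** uses Pearson pseudo-likelihood with a
  residual-degrees-of-freedom correction (the χ² statistic of the full
  model is matched to n − p), iterated a few times with the working NB
  fit; naive full-model maximum likelihood is biased low with tens of
  samples, which inflates the test.
* **Reference distribution**: the LRT over its degrees of freedom is
  referred to F(df, n − levels) rather than χ²(df). With the dispersion
  estimated from ~20 samples and treated as known, the χ² reference
  rejects ~10–11% at nominal 5% under the null; the F-type
  quasi-likelihood reference restores ~5–7% while keeping ~84% power at a
  4-fold single-level effect (dispersion 0.5, five samples per level).

Benjamini–Hochberg adjustment and the padj < 0.05 significance call
follow. Significant vOTUs are grouped by their depth profile: per-level
mean normalized abundance, Z-transformed across levels with the
population (n) standard deviation, complete-linkage clustering on
Euclidean distance, cut at k = 3, and groups labelled 1..k by the depth
of their peak mean Z, shallow to deep — so "group 1" always means the
surface-peaking group. Constant profiles get a zero Z vector and are
logged. Enrichment of a binary trait in each group is the upper-tail
hypergeometric probability against the whole detected set, significant at
p < 0.05 per group (no cross-group correction, matching the reporting
convention the pipeline reproduces; with three groups the familywise
false-flag rate under the null is therefore ≈ 1 − 0.95³ ≈ 0.14, which the
calibration tests account for by checking the per-group rate).

## Fritz–Purvis D

Tips carry 0/1 states; each internal node of the (binary, rooted) tree
takes the unweighted mean of its children, post-order; d is the sum over
edges of |child − parent|. The observed d is standardized between two
n_sim-replicate nulls sharing a seed but using separate substreams:
random tip-label permutations (D ≈ 1) and Brownian motion along branches
(variance ∝ branch length, root 0) thresholded at the rank matching the
observed number of 1-tips (D ≈ 0). Clade-sorted traits give D < 0.
Branch lengths are used only in the Brownian simulation; daughter
averaging ignores them, matching the statistic's standard implementation.
Multifurcations are resolved deterministically with zero-length edges
after missing branch lengths default to 1; unrooted input is rooted as
read. The statistic is undefined for monomorphic traits or degenerate
trees whose two null means coincide; both are reported as errors rather
than numbers.

## What the synthetic community emulates

`truth_config()` → `generate_community()` plants a fully known community:

* **Genus pangenomes.** Each genus has `pangenome_size` protein families
  (founder length 80–200 aa); every species carries all core families
  (`core_fraction`, default 0.5) plus each accessory family with
  probability 0.5, its copies diverged at `aa_divergence` = 0.10 per
  residue, giving within-genus protein identities around
  (1 − a)² + a²/19 ≈ 0.81 — comfortably inside the 0.60 protein-cluster
  gate and far from the ≈ 0.05 identity of unrelated proteins.
* **The species boundary.** Per-copy substitution rates are solved from
  the pairwise identity of two independently mutated copies,
  ani = (1 − r)² + r²/3, so that *pairwise* identities hit the targets:
  within-species pairs ≈ 0.97 (> 0.95), same-genus cross-species pairs
  ≈ 0.85 (< 0.90). Mutations are substitutions only — no indels — so
  planted identities are exactly computable and the 95% boundary is
  analytically testable. Variant 1 of each species is the founder and, by
  construction and naming, the cluster representative.
* **Habitats.** Labels live at the species (vOTU) level. Habitat
  structure is genus-level: with probability `aquatic_genus_prob` (0.25)
  a genus contains one marine/freshwater species, making all its members
  aquatic-like; other species are terrestrial, peat-weighted 0.7/0.3 over
  peat/soil.
* **Abundance.** Counts are per-vOTU read counts (library size = column
  sum), negative binomial with log-uniform base means in `nb_mean_range`,
  dispersion `nb_dispersion` = 0.5, and log-normal per-sample size
  factors. A planted fraction (`da_fraction` = 0.4) of vOTUs is
  depth-differential at `da_fold` = 4 in one of three groups peaking
  shallow, mid, or across the two deepest levels — the third group is a
  band rather than a spike, mirroring the depth-band shape of real
  profiles and keeping the three archetypes separable under complete
  linkage. Aquatic-like vOTUs enter the surface group with odds
  multiplied by `aquatic_enrichment_odds`.
* **Reads.** Exactly `counts[v, s]` reads per vOTU and sample are drawn
  from the vOTU founder sequence (uniform starts, random strand,
  substitution errors at `error_rate`); the truth SAM records generating
  coordinates and an NM tag equal to the planted substitution count.
  Reads come from founders rather than every within-species variant —
  variants exist to exercise dereplication, not read mapping.
* **CRISPR hosts.** Each host MAG carries one array (repeat–spacer–…–
  repeat) planted verbatim into its contig; each spacer copies a vOTU
  protospacer with one substitution at probability
  `spacer_mismatch_prob`, on a random strand, and is rejection-sampled
  until it matches exactly one protospacer across all vOTUs at ≤ 1
  mismatch — the truth table must record a unique source, and related
  species would otherwise offer homologous near-matches. Host taxonomy
  strings follow a nested genus/family hierarchy (hosts 2k−1 and 2k share
  a genus, adjacent genera a family) so consensus-host checks have known
  answers.

One root seed determines every emitted byte; the stages draw from child
streams at fixed offsets (+11 community, +22 hosts, +33 abundance, +44
reads), so regenerating any stage with the same config is byte-identical.

**What it does not emulate:** indels and quality-score error profiles,
proviruses and plasmids, assembly artifacts, uneven genome lengths within
a species, strain mixtures below the species boundary, and real habitat
label noise. Passing tests therefore demonstrate that the *rules* are
implemented exactly and recover planted structure under clean conditions;
they do not certify performance on real assemblies.

## Problem sizes and defaults

The default community (4 genera × 3 species × 3 variants, genomes
1.2–1.8 kb, 20 samples over four depth levels) is deliberately small: the
full pairwise dynamic program is the implementation, not a heuristic, and
the whole default pipeline runs in well under a minute. Statistical
calibrations use sequence-light configs (one variant per species, 300–400
bp genomes): the null and power checks run 200 vOTUs × 20 samples, and
the enrichment recovery runs 500 vOTUs × 40 samples (10 per level) with
odds 4 — a scale-down of a study design with thousands of vOTUs and ~80
metagenomes that keeps the surface-group test adequately powered. The
D-statistic calibration uses a 128-tip tree with 40 trait-positive tips
and 400–1000 simulations per null.

## Known limitations

* Greedy first-match clustering is a convention, not an optimum; a
  contig matching two representatives joins the earlier-founded one.
* The hypergeometric gene-sharing score treats protein clusters as
  exchangeable; shared core functions across genera would need profile
  methods that are out of scope here.
* The NB test assumes a common dispersion per vOTU across levels and
  gains no strength across vOTUs; with very few samples per level its
  power is bounded (~0.84 at the planted 4-fold effect) even with the
  dispersion known.
* Substitution-only spacer matching is the stated equivalent of
  short-sequence alignment searches at ≤ 1 mismatch and 95% identity; it
  does not model indel-containing protospacers.
* Printed fold differences follow a reporting convention (nearest integer
  at ratios ≥ 10, one decimal below, ".0" collapsed); it reproduces the
  published examples but is not a statistical statement.
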