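# peatviromics

Tools and a worked analysis for peat virome ecology: from viral contigs
and read alignments to species-level viral populations (vOTUs),
breadth-gated abundance tables, genus-level gene-sharing viral clusters
(VCs), CRISPR-based virus–host links, depth-differential abundance with
trait enrichment, and phylogenetic dispersion of habitat traits. A seeded
synthetic community generator plants fully known structure so that every
stage is testable end to end without external sequencing data.

The package is aimed at soil/peat viral ecologists who want the standard
viromics decision rules as tested, composable R functions rather than a
chain of ad hoc scripts.

## The rules and models at the core

* **vOTU dereplication.** Contigs are clustered greedily, longest first;
  a contig joins the first representative with nucleotide identity
  ≥ 0.95 over ≥ 85% of the shorter contig (overlap alignment, both
  orientations). Representatives are the longest members.
* **Detection.** A read counts toward coverage at identity
  1 − NM/L_aligned ≥ 0.90; vOTU *v* is detected in sample *s* when its
  breadth (fraction of positions covered ≥ 1×) is ≥ 0.75, and then its
  abundance is the 10%-trimmed mean depth × 10⁷ / library reads.
* **Viral clusters.** Proteins cluster at ≥ 60% identity / ≥ 80%
  coverage; genome pairs are scored by the Bonferroni-corrected
  upper-tail hypergeometric probability of their shared protein-cluster
  count, score = −log₁₀ p; edges with score ≥ 1 are clustered with
  Markov clustering (inflation 2). Singletons count as VCs. A VC is
  taxonomically classified iff it contains a reference genome.
* **Depth-differential abundance.** Per-vOTU negative-binomial GLMs with
  median-of-ratios size factors as offsets; a likelihood-ratio test of
  depth level against an intercept-only model, with a small-sample
  F-type reference and Benjamini–Hochberg adjustment; significant vOTUs
  are grouped by complete-linkage clustering of Z-transformed depth
  profiles, and each group is tested for enrichment of "aquatic-like"
  vOTUs (members of VCs that also contain a marine or freshwater vOTU)
  with an upper-tail hypergeometric test.
* **Virus–host linkage.** CRISPR repeats must match a MAG exactly (both
  strands); spacers must match a vOTU protospacer with ≤ 1 substitution
  over the full spacer; a linkage requires both anchors from one array.
* **Fritz–Purvis D.** For a binary tip trait, d = Σ|child − parent| of
  daughter-averaged node values, standardized between tip-permutation
  (D ≈ 1) and Brownian-threshold (D ≈ 0) nulls; D < 0 indicates
  phylogenetic clumping.

The methods vignette (`vignettes/peat-virome-methods.Rmd`) documents the
conventions, parameter choices, and what the synthetic generator does and
does not emulate.

## Worked example

The numbered scripts under `analysis/` run the whole workflow on a
generated community and write tables under `results/`:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

Selected output (seeds fixed in the scripts):

```
vOTUs: 12 clusters from 36 contigs
species recovery: clusters are internally pure for 100 % of planted species
detection: 123 vOTU-sample detections; per-sample richness 4 - 12 of 12 vOTUs
VCs: 5 ( 4 multi-member, 1 singletons; 20 % singleton VCs)
within-VC AAI: 0.81-0.82
depth: Mantel r = 0.73 (p = 0.001); year PERMANOVA p = 0.961
differential abundance: 206 of 500 vOTUs significant (padj < 0.05);
  98 % of the 200 planted differentials recovered
surface-group aquatic-like: 30/93 vs 120/500 overall (p = 0.029)
linkages: 24 records between 10 vOTUs and 6 MAGs; 16 with 0 mismatches, 8 with 1
truth recovery: 24 of 24 planted links; 0 false positives
aquatic_like: D = -0.99   peat_origin: D = 1.47
```

Reading it: the 36 simulated contigs collapse exactly into the 12
planted species (the 95%/85% rule at work); the gene-sharing network
recovers genus-level clusters whose members share ~81% amino-acid
identity; viral community composition correlates with depth but not
sampling year; the surface-peaking group of depth-differential vOTUs is
enriched in aquatic-like members (30/93 vs a 24% background, p = 0.029);
every planted CRISPR link is recovered with the planted mismatch counts
and no false positives; and the genus-structured aquatic-like trait is
phylogenetically clumped (D < 0) while peat origin, which is assigned
per species, is not.

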