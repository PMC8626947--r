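#!/usr/bin/env Rscript
# Stage 4: from read alignments to the breadth-gated, normalized vOTU
# detection table: reads are kept at >= 90% identity, a vOTU is detected
# in a sample when >= 75% of its length is covered, and its abundance is
# the 10%-trimmed mean depth normalized per 1e7 library reads.

suppressMessages(library(peatviromics))

syn <- "results/synthetic"
out <- "results/detection"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

meta <- read_table_checked(file.path(syn, "sample_metadata.tsv"),
                           required = c("sample_id", "library_size"))
votus <- read_table_checked(file.path(syn, "truth_votus.tsv"),
                            required = "votu")$votu
contigs <- read_fasta(file.path(syn, "contigs.fasta"))
lens <- stats::setNames(nchar(contigs$sequence), contigs$id)[votus]

profiles <- lapply(meta$sample_id, function(s) {
  aln <- read_sam(file.path(syn, paste0(s, ".sam")))
  sample_profiles(aln, lens, min_identity = 0.90)
})
names(profiles) <- meta$sample_id

det <- build_detection_table(
  profiles, stats::setNames(meta$library_size, meta$sample_id),
  breadth_thresh = 0.75, trim = 0.10, scale = 1e7)

ab_df <- data.frame(votu = rownames(det$abundance), det$abundance,
                    check.names = FALSE)
br_df <- data.frame(votu = rownames(det$breadth), round(det$breadth, 4),
                    check.names = FALSE)
write_table_checked(ab_df, file.path(out, "abundance.tsv"))
write_table_checked(br_df, file.path(out, "breadth.tsv"))

rich <- per_sample_richness(det$abundance)
write_table_checked(data.frame(sample_id = names(rich), richness = rich),
                    file.path(out, "richness.tsv"))

# richness contrast between the two deepest and two shallowest levels,
# reported with the fold convention used for virome/metagenome contrasts
lev <- meta$depth_level
shallow <- rich[lev %in% unique(lev)[1:2]]
deep <- rich[!(lev %in% unique(lev)[1:2])]
if (mean(deep) > 0) {
  fd <- fold_difference(mean(shallow), mean(deep))
  cat("richness: shallow mean", round(mean(shallow), 1), "vs deep mean",
      round(mean(deep), 1), "->", fd$printed, "fold\n")
}
cat("detection:", sum(det$abundance > 0), "vOTU-sample detections;",
    "per-sample richness", min(rich), "-", max(rich), "of", length(votus),
    "vOTUs\n")
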