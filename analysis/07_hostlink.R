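#!/usr/bin/env Rscript
# Stage 7: CRISPR-mediated virus-host linkage. Repeats anchor arrays to
# MAGs at 100% identity; spacers anchor arrays to vOTU protospacers at
# <= 1 mismatch; a linkage needs both. Host consistency is summarised by
# the deepest taxonomic rank shared among a vOTU's predicted hosts.

suppressMessages(library(peatviromics))

syn <- "results/synthetic"
out <- "results/hostlink"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

arrays <- read_table_checked(file.path(syn, "crispr_arrays.tsv"),
                             required = c("array_id", "repeat_seq"))
spacers <- read_table_checked(file.path(syn, "crispr_spacers.tsv"),
                              required = c("array_id", "spacer_index",
                                           "sequence"))
mag_fa <- read_fasta(file.path(syn, "mags.fasta"))
mags <- stats::setNames(mag_fa$sequence, mag_fa$id)
tax <- read_table_checked(file.path(syn, "mag_taxonomy.tsv"),
                          required = c("mag", "taxonomy"))
votus <- read_table_checked(file.path(syn, "truth_votus.tsv"),
                            required = "votu")$votu
contigs <- read_fasta(file.path(syn, "contigs.fasta"))
vseq <- stats::setNames(contigs$sequence, contigs$id)[votus]

lk <- crispr_link(arrays, spacers, mags, tax, vseq, max_mismatch = 1L)
write_table_checked(lk, file.path(out, "linkages.tsv"))
cons <- consensus_host_check(lk)
write_table_checked(cons, file.path(out, "host_consensus.tsv"))

truth <- read_table_checked(file.path(syn, "truth_links.tsv"),
                            required = c("votu", "mag", "spacer_index"))
planted <- unique(truth[, c("votu", "mag", "spacer_index")])
got <- unique(lk[, c("votu", "mag", "spacer_index")])
tp <- nrow(merge(planted, got))

cat("linkages:", nrow(lk), "records between", length(unique(lk$votu)),
    "vOTUs and", length(unique(lk$mag)), "MAGs;",
    sum(lk$mismatches == 0), "with 0 mismatches,",
    sum(lk$mismatches == 1), "with 1\n")
cat("truth recovery:", tp, "of", nrow(planted), "planted links;",
    nrow(got) - tp, "false positives\n")
multi <- cons[cons$n_hosts > 1, ]
if (nrow(multi)) {
  cat("multi-host vOTUs share hosts at rank:",
      paste(multi$deepest_shared_rank, collapse = ", "), "\n")
}
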