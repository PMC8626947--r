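#!/usr/bin/env Rscript
# Stage 1: generate the synthetic peat virome study - a genus-structured
# viral community with habitat labels, CRISPR-carrying host MAGs, a
# depth-structured abundance design, and error-bearing reads with truth
# alignments. Everything downstream reads the files written here.

suppressMessages(library(peatviromics))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- truth_config(seed = 31)
comm <- generate_community(cfg)
hosts <- generate_hosts(cfg, comm)
ab <- generate_abundance(cfg, comm)
reads <- generate_reads(comm, ab$counts, cfg)

write_fasta(comm$contigs, file.path(out, "contigs.fasta"))
write_fasta(stats::setNames(comm$proteins$sequence,
                            comm$proteins$protein_id),
            file.path(out, "proteins.faa"))
write_table_checked(comm$genome_map, file.path(out, "genome_map.tsv"))
write_table_checked(comm$habitats, file.path(out, "votu_habitats.tsv"))
write_table_checked(comm$truth$contig2species,
                    file.path(out, "truth_species.tsv"))
write_table_checked(comm$truth$votus, file.path(out, "truth_votus.tsv"))

write_fasta(hosts$mag_contigs, file.path(out, "mags.fasta"))
write_table_checked(hosts$mags, file.path(out, "mag_taxonomy.tsv"))
write_table_checked(hosts$arrays, file.path(out, "crispr_arrays.tsv"))
write_table_checked(hosts$spacers, file.path(out, "crispr_spacers.tsv"))
write_table_checked(hosts$truth$links, file.path(out, "truth_links.tsv"))

counts_df <- data.frame(votu = rownames(ab$counts), ab$counts,
                        check.names = FALSE)
write_table_checked(counts_df, file.path(out, "true_counts.tsv"))
write_table_checked(ab$metadata, file.path(out, "sample_metadata.tsv"))
write_table_checked(ab$truth$da_votus, file.path(out, "truth_da.tsv"))

lens <- vapply(comm$contigs, nchar, 1L)
for (s in names(reads)) {
  write_fastq(reads[[s]]$reads$id, reads[[s]]$reads$seq,
              file.path(out, paste0(s, ".fastq")))
  write_sam(reads[[s]]$aln, lens[rownames(ab$counts)],
            file.path(out, paste0(s, ".sam")))
}

cat("community:", length(comm$contigs), "contigs in",
    nrow(comm$truth$votus), "species across",
    length(unique(comm$truth$votus$genus)), "genera;",
    nrow(comm$proteins), "proteins\n")
cat("hosts:", length(hosts$mag_contigs), "MAGs carrying",
    nrow(hosts$spacers), "spacers (",
    sum(hosts$truth$links$mismatches == 1), "planted with 1 mismatch)\n")
cat("abundance:", nrow(ab$counts), "x", ncol(ab$counts),
    "counts; library sizes", min(ab$metadata$library_size), "-",
    max(ab$metadata$library_size), "reads\n")
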