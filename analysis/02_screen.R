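#!/usr/bin/env Rscript
# Stage 2: viral-prediction and AMG output filtering. External predictors
# are out of scope, so their output tables are emulated here: viral contigs
# receive plausible scores/categories, host MAG contigs receive
# non-passing ones, and the published filtering rules are applied.

suppressMessages(library(peatviromics))
set.seed(42)

syn <- "results/synthetic"
out <- "results/screen"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

contigs <- read_fasta(file.path(syn, "contigs.fasta"))
mags <- read_fasta(file.path(syn, "mags.fasta"))

n_v <- nrow(contigs); n_m <- nrow(mags)
pred <- data.frame(
  contig_id = c(contigs$id, mags$id),
  # scores are reported on a 10 kbp-convention length scale
  length = 10000 + round(runif(n_v + n_m, 0, 30000)),
  dvf_score = c(runif(n_v, 0.85, 1.0), runif(n_m, 0.1, 0.6)),
  dvf_p = c(runif(n_v, 0, 0.06), runif(n_m, 0.2, 1)),
  vs_category = c(sample(c(1, 2, 4, 5, NA), n_v, TRUE),
                  sample(c(3, 6, NA), n_m, TRUE)),
  stringsAsFactors = FALSE)
accepted <- filter_viral_predictions(pred)
write_table_checked(accepted, file.path(out, "viral_contigs.tsv"))

amg <- data.frame(
  gene_id = paste0("gene", 1:40),
  gene_description = ifelse(runif(40) < 0.9, "glycoside hydrolase", ""),
  auxiliary_score = sample(0:6, 40, TRUE),
  flags = sample(c("", "F", "T", "M", "V", "FP"), 40, TRUE),
  stringsAsFactors = FALSE)
kept <- filter_amg_candidates(amg)
write_table_checked(kept, file.path(out, "amg_retained.tsv"))

cat("screen:", nrow(accepted), "of", nrow(pred),
    "contigs accepted as viral (",
    sum(accepted$provenance == "both"), "both,",
    sum(accepted$provenance == "score_only"), "score-only,",
    sum(accepted$provenance == "category_only"), "category-only)\n")
cat("AMG filter retained", nrow(kept), "of", nrow(amg),
    "candidate genes\n")
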