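# Shared fixtures and independent oracles used across test files.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                        collapse = "")

# plant exactly k substitutions into a sequence
substitute_k <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  idx <- sample(length(ch), k)
  for (i in idx) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}

# brute-force per-base depth from half-open intervals
brute_depth <- function(starts, ends, len) {
  d <- integer(len)
  for (k in seq_along(starts)) {
    for (i in seq(starts[k] + 1L, ends[k])) d[i] <- d[i] + 1L
  }
  d
}

# naive O(n*m) sliding-window Hamming scan on both strands
naive_spacer_scan <- function(spacer, subject, max_mm) {
  hits <- list()
  L <- nchar(spacer)
  subj_ch <- strsplit(subject, "")[[1]]
  for (pat in list(c("+", spacer), c("-", rc(spacer)))) {
    p_ch <- strsplit(pat[2], "")[[1]]
    for (s in seq_len(nchar(subject) - L + 1)) {
      mm <- sum(subj_ch[s:(s + L - 1)] != p_ch)
      if (mm <= max_mm) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = s - 1L, strand = pat[1], mismatches = mm,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer()))
  }
  do.call(rbind, hits)
}

# exhaustive hypergeometric upper tail by summation of the pmf
hyper_tail_enum <- function(k, K, N, n) {
  tot <- choose(N, n)
  sum(vapply(k:min(n, K), function(x)
    choose(K, x) * choose(N - K, n - x), 0)) / tot
}

# Biostrings overlap alignment with the same scoring as the package DP
biostrings_overlap <- function(a, b) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(a, b, type = "overlap",
                                substitutionMatrix = mat,
                                gapOpening = 0, gapExtension = 2)
}

# adjusted Rand index between two label vectors (mclust is the oracle)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# tiny default community config used by several files
small_cfg <- function(seed = 7, n_genera = 3, species_per_genus = 4,
                      variants_per_species = 3, ...) {
  truth_config(seed = seed, n_genera = n_genera,
               species_per_genus = species_per_genus,
               variants_per_species = variants_per_species, ...)
}

# sequence-light config for abundance-focused simulations
abundance_cfg <- function(seed, n_genera = 50, n_samples = 20, ...) {
  truth_config(seed = seed, n_genera = n_genera, species_per_genus = 4,
               variants_per_species = 1, genome_len_range = c(300L, 400L),
               pangenome_size = 4L, n_samples = n_samples, ...)
}
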