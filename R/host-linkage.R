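MIN_SPACER_LEN <- 20L

match_pattern_hits <- function(pattern, subjects, max_mismatch) {
  # exact/near-exact substring matching on both strands
  hits <- list()
  pat_f <- Biostrings::DNAString(pattern)
  pat_r <- Biostrings::reverseComplement(pat_f)
  for (id in names(subjects)) {
    subj <- Biostrings::DNAString(subjects[[id]])
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") pat_f else pat_r
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mismatch,
                                    with.indels = FALSE)
      if (length(m)) {
        mm <- Biostrings::neditStartingAt(pat, subj,
                                          starting.at =
                                            Biostrings::start(m))
        hits[[length(hits) + 1L]] <- data.frame(
          subject = id, start = Biostrings::start(m) - 1L,
          end = Biostrings::end(m), strand = strand,
          mismatches = as.integer(mm), stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(subject = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Match a CRISPR repeat against MAG contigs (exact, both strands)
#'
#' Repeats anchor arrays to hosts at 100% identity only.
#'
#' @param repeat_seq Repeat sequence.
#' @param mag_contigs Named character vector of MAG contig sequences.
#' @return Data frame `subject`, `start` (0-based), `end`, `strand`,
#'   `mismatches` (always 0).
#' @export
match_repeat <- function(repeat_seq, mag_contigs) {
  match_pattern_hits(toupper(repeat_seq), as.list(toupper(mag_contigs)),
                     max_mismatch = 0L)
}

#' Match a CRISPR spacer against vOTU sequences (protospacer search)
#'
#' Full-length substitution-only (Hamming) matching on both strands with
#' at most `max_mismatch` mismatches; spacers shorter than 20 nt are
#' rejected with a warning (one mismatch would break the 95% identity
#' rule).
#'
#' @param spacer Spacer sequence (>= 20 nt).
#' @param votu_seqs Named character vector of vOTU sequences.
#' @param max_mismatch Maximum Hamming distance (default 1).
#' @return Data frame `subject`, `start` (0-based), `end`, `strand`,
#'   `mismatches`.
#' @export
match_spacer <- function(spacer, votu_seqs, max_mismatch = 1L) {
  if (nchar(spacer) < MIN_SPACER_LEN) {
    warning("spacer shorter than ", MIN_SPACER_LEN, " nt rejected")
    return(data.frame(subject = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  match_pattern_hits(toupper(spacer), as.list(toupper(votu_seqs)),
                     max_mismatch = as.integer(max_mismatch))
}

#' CRISPR-derived virus-host linkage
#'
#' A linkage is made when one array has (a) an exact repeat match in a MAG
#' and (b) a spacer match in a vOTU. One deduplicated record is emitted per
#' (vOTU, MAG, spacer) triple; arrays whose repeat anchors to more than one
#' MAG have all their linkages flagged `multi_host_anchor`.
#'
#' @param arrays Data frame `array_id`, `repeat_seq`.
#' @param spacers Data frame `array_id`, `spacer_index`, `sequence`.
#' @param mag_contigs Named character vector of MAG contigs (names are MAG
#'   ids).
#' @param mag_taxonomy Data frame `mag`, `taxonomy`.
#' @param votu_seqs Named character vector of vOTU sequences.
#' @param max_mismatch Maximum spacer-protospacer Hamming distance.
#' @return Data frame `votu`, `mag`, `array_id`, `spacer_index`,
#'   `mismatches`, `strand`, `mag_taxonomy`, `multi_host_anchor`.
#' @export
crispr_link <- function(arrays, spacers, mag_contigs, mag_taxonomy,
                        votu_seqs, max_mismatch = 1L) {
  out <- list()
  for (a in seq_len(nrow(arrays))) {
    aid <- arrays$array_id[a]
    rep_hits <- match_repeat(arrays$repeat_seq[a], mag_contigs)
    if (!nrow(rep_hits)) next
    mags <- unique(rep_hits$subject)
    multi <- length(mags) > 1
    sp <- spacers[spacers$array_id == aid, , drop = FALSE]
    for (k in seq_len(nrow(sp))) {
      hits <- match_spacer(sp$sequence[k], votu_seqs, max_mismatch)
      if (!nrow(hits)) next
      for (v in unique(hits$subject)) {
        hv <- hits[hits$subject == v, , drop = FALSE]
        best <- hv[which.min(hv$mismatches), , drop = FALSE]
        for (m in mags) {
          out[[length(out) + 1L]] <- data.frame(
            votu = v, mag = m, array_id = aid,
            spacer_index = sp$spacer_index[k],
            mismatches = best$mismatches, strand = best$strand,
            mag_taxonomy = mag_taxonomy$taxonomy[
              match(m, mag_taxonomy$mag)],
            multi_host_anchor = multi, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out)) {
    return(data.frame(votu = character(), mag = character(),
                      array_id = character(), spacer_index = integer(),
                      mismatches = integer(), strand = character(),
                      mag_taxonomy = character(),
                      multi_host_anchor = logical(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[!duplicated(res[, c("votu", "mag", "spacer_index", "array_id")]), ,
      drop = FALSE]
}

parse_ranks <- function(taxonomy) {
  parts <- strsplit(taxonomy, ";", fixed = TRUE)[[1]]
  stats::setNames(sub("^[a-z]__", "", parts),
                  sub("__.*$", "", parts))
}

#' Consensus-host consistency per vOTU
#'
#' For each vOTU linked to more than one MAG, reports the deepest
#' taxonomic rank shared by all its predicted hosts (GTDB-style
#' rank-prefixed strings).
#'
#' @param linkages Output of [crispr_link()].
#' @return Data frame `votu`, `n_hosts`, `deepest_shared_rank` ("n/a" for
#'   single-host vOTUs, "none" when even the first rank differs).
#' @export
consensus_host_check <- function(linkages) {
  rank_names <- c(d = "domain", p = "phylum", c = "class", o = "order",
                  f = "family", g = "genus", s = "species")
  rows <- lapply(split(linkages, linkages$votu), function(lk) {
    hosts <- unique(lk$mag)
    if (length(hosts) < 2) {
      return(data.frame(votu = lk$votu[1], n_hosts = length(hosts),
                        deepest_shared_rank = "n/a",
                        stringsAsFactors = FALSE))
    }
    tax <- lapply(unique(lk$mag_taxonomy), parse_ranks)
    deepest <- "none"
    for (r in names(rank_names)) {
      vals <- vapply(tax, function(t)
        if (r %in% names(t)) t[[r]] else NA_character_, "")
      if (any(is.na(vals)) || any(!nzchar(vals)) ||
          length(unique(vals)) > 1) break
      deepest <- rank_names[[r]]
    }
    data.frame(votu = lk$votu[1], n_hosts = length(hosts),
               deepest_shared_rank = deepest, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
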