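#' Read identity of an alignment record
#'
#' Identity is read-centric: 1 - edit_distance / aligned_read_len, so
#' insertions in the read count against identity while reference deletions
#' do not.
#'
#' @param aln Alignment data frame (see [read_sam()]).
#' @return Numeric vector of identities.
#' @export
read_identity <- function(aln) {
  if (any(aln$aligned_read_len == 0)) {
    stop("aligned_read_len is zero for read(s): ",
         paste(aln$read_id[aln$aligned_read_len == 0], collapse = ", "))
  }
  1 - aln$edit_distance / aln$aligned_read_len
}

#' Per-base coverage profile of one contig
#'
#' @param aln Alignment records on a single contig (already identity
#'   filtered), with 0-based half-open `start`, `end`.
#' @param contig_len Contig length in bp.
#' @return Integer vector of per-base depth, length `contig_len`.
#' @export
coverage_profile <- function(aln, contig_len) {
  if (nrow(aln) == 0) return(integer(contig_len))
  .depth_from_intervals(as.integer(aln$start), as.integer(aln$end),
                        as.integer(contig_len))
}

#' Breadth of coverage
#' @param profile Per-base depth vector.
#' @return Fraction of positions with depth >= 1.
#' @export
breadth <- function(profile) {
  if (!length(profile)) return(0)
  mean(profile >= 1L)
}

#' Trimmed mean depth ("tpmean")
#'
#' Discards the `floor(trim * L)` highest and lowest per-base depth values
#' and averages the rest; equal to the plain mean when `floor(trim * L)` is
#' zero.
#'
#' @param profile Per-base depth vector (length >= 1).
#' @param trim Trim fraction per tail, in `[0, 0.5)`.
#' @return Trimmed mean depth.
#' @export
trimmed_mean_depth <- function(profile, trim = 0.10) {
  if (trim < 0 || trim >= 0.5) stop("trim must be in [0, 0.5)")
  L <- length(profile)
  if (L < 1) stop("empty coverage profile")
  k <- floor(trim * L)
  if (k == 0) return(mean(profile))
  s <- sort(profile)
  mean(s[(k + 1):(L - k)])
}

#' Build the breadth-gated, normalized vOTU detection table
#'
#' Entry (v, s) is `trimmed_mean_depth * scale / library_size` when the
#' breadth of v in s is at least `breadth_thresh`, else 0 (not detected).
#'
#' @param profiles Named list (per sample) of named lists (per vOTU) of
#'   per-base depth vectors. All samples must share the vOTU universe.
#' @param library_sizes Named numeric vector of per-sample read counts.
#' @param breadth_thresh Breadth gate (default 0.75, inclusive).
#' @param trim Trim fraction for [trimmed_mean_depth()].
#' @param scale Fixed normalization scale (abundance per `scale` reads).
#' @return List with `abundance` (vOTU x sample matrix) and `breadth`
#'   (same shape).
#' @export
build_detection_table <- function(profiles, library_sizes,
                                  breadth_thresh = 0.75, trim = 0.10,
                                  scale = 1e7) {
  samples <- names(profiles)
  votus <- names(profiles[[1]])
  ab <- br <- matrix(0, nrow = length(votus), ncol = length(samples),
                     dimnames = list(votus, samples))
  for (s in samples) {
    stopifnot(identical(names(profiles[[s]]), votus))
    for (v in votus) {
      prof <- profiles[[s]][[v]]
      b <- breadth(prof)
      br[v, s] <- b
      if (b >= breadth_thresh) {
        if (library_sizes[[s]] == 0) {
          stop("library size is zero for sample ", s,
               " but alignments are present")
        }
        ab[v, s] <- trimmed_mean_depth(prof, trim) * scale /
          library_sizes[[s]]
      }
    }
  }
  list(abundance = ab, breadth = br)
}

#' Per-sample richness (detected vOTUs per sample)
#' @param table Abundance matrix (vOTU x sample); zero means not detected.
#' @return Named integer vector of nonzero counts per sample.
#' @export
per_sample_richness <- function(table) {
  if (is.null(dim(table))) stop("expected a matrix")
  colSums(table > 0)
}

#' Fold difference between two mean richness values, with printed form
#'
#' The printed convention reproduces how such folds are reported: nearest
#' integer when the ratio is at least 10, otherwise one decimal (with a
#' trailing ".0" collapsed to the integer).
#'
#' @param mean_a,mean_b Mean values; `mean_b` must be > 0.
#' @return List with `ratio` and `printed`.
#' @export
fold_difference <- function(mean_a, mean_b) {
  if (mean_b == 0) stop("denominator mean is zero")
  ratio <- mean_a / mean_b
  printed <- if (ratio >= 10) {
    sprintf("%d", round(ratio))
  } else {
    r1 <- round(ratio, 1)
    if (r1 == round(r1)) sprintf("%d", as.integer(round(r1)))
    else sprintf("%.1f", r1)
  }
  list(ratio = ratio, printed = printed)
}

#' vOTU-level coverage profiles from alignment records
#'
#' Convenience wrapper: filters alignments at `min_identity` (inclusive)
#' and computes one coverage profile per vOTU for one sample.
#'
#' @param aln Alignment data frame for one sample.
#' @param contig_lengths Named vector of vOTU lengths (the universe).
#' @param min_identity Identity gate, inclusive (default 0.90).
#' @return Named list of depth vectors covering the full universe.
#' @export
sample_profiles <- function(aln, contig_lengths, min_identity = 0.90) {
  if (nrow(aln)) aln <- aln[read_identity(aln) >= min_identity, , drop = FALSE]
  out <- lapply(names(contig_lengths), function(v) {
    coverage_profile(aln[aln$contig_id == v, , drop = FALSE],
                     contig_lengths[[v]])
  })
  names(out) <- names(contig_lengths)
  out
}
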