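#' Pairwise identity and shorter-sequence coverage
#'
#' Computes an overlap (free-end-gap) alignment between two sequences
#' (match +1, mismatch -1, gap -2, terminal gaps free) and summarises the
#' non-terminal-gap region of the optimal path: `identity` is the fraction of
#' matched columns within that region, `shorter_cov` the fraction of the
#' shorter sequence's bases inside it. For nucleotide input the reverse
#' complement of the second sequence is also evaluated and the
#' better-scoring orientation is reported.
#'
#' @param a,b Sequences (character scalars), case-insensitive.
#' @param try_rc Also evaluate the reverse-complement orientation (set to
#'   `FALSE` for protein input).
#' @return A list with `identity`, `shorter_cov`, `score`, `strand`.
#' @export
pair_identity <- function(a, b, try_rc = TRUE) {
  a <- toupper(a); b <- toupper(b)
  if (!nzchar(a) || !nzchar(b)) stop("pair_identity: empty sequence")
  fwd <- .align_overlap(a, b)
  res <- fwd; strand <- "+"
  if (try_rc) {
    rev <- .align_overlap(a, revcomp(b))
    if (rev$score > fwd$score) { res <- rev; strand <- "-" }
  }
  shorter_len <- min(nchar(a), nchar(b))
  shorter_aligned <- if (nchar(a) <= nchar(b)) res$a_aligned else res$b_aligned
  list(identity = if (res$columns > 0) res$matches / res$columns else 0,
       shorter_cov = shorter_aligned / shorter_len,
       score = res$score, strand = strand)
}

#' Greedy species-level dereplication of viral contigs (vOTUs)
#'
#' Contigs are sorted by length (descending), ties broken by id; the first
#' unassigned contig founds a cluster, and each subsequent contig joins the
#' first representative (in creation order) reached at `identity >=
#' id_thresh` over `shorter_cov >= cov_thresh` of the shorter contig —
#' the 0.95 / 85% species rule with greedy centroid semantics.
#'
#' @param contigs Named character vector of sequences (or a [read_fasta()]
#'   data frame).
#' @param id_thresh Identity threshold (default 0.95).
#' @param cov_thresh Coverage-of-shorter threshold (default 0.85).
#' @param try_rc Consider reverse-complement matches.
#' @return A data frame with one row per contig: `member`, `representative`,
#'   `identity`, `coverage`; the representative of a cluster is its longest
#'   member.
#' @export
greedy_cluster <- function(contigs, id_thresh = 0.95, cov_thresh = 0.85,
                           try_rc = TRUE) {
  if (is.data.frame(contigs)) {
    contigs <- stats::setNames(contigs$sequence, contigs$id)
  }
  if (!length(contigs)) stop("greedy_cluster: no contigs")
  ord <- order(-nchar(contigs), names(contigs))
  ids <- names(contigs)[ord]
  seqs <- unname(contigs[ord])
  reps <- character(0)
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    assigned <- FALSE
    for (r in reps) {
      pi <- pair_identity(contigs[[r]], seqs[k], try_rc = try_rc)
      if (pi$identity >= id_thresh && pi$shorter_cov >= cov_thresh) {
        out[[k]] <- data.frame(member = ids[k], representative = r,
                               identity = pi$identity,
                               coverage = pi$shorter_cov,
                               stringsAsFactors = FALSE)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      reps <- c(reps, ids[k])
      out[[k]] <- data.frame(member = ids[k], representative = ids[k],
                             identity = 1, coverage = 1,
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res[order(match(res$representative, reps), res$member), , drop = FALSE]
}

#' Summarise a clustering data frame into vOTU clusters
#' @param clusters Output of [greedy_cluster()].
#' @return Data frame with `representative`, `n_members`, `members`
#'   (comma-separated).
#' @export
votu_table <- function(clusters) {
  sp <- split(clusters$member, clusters$representative)
  data.frame(representative = names(sp),
             n_members = lengths(sp),
             members = vapply(sp, paste, "", collapse = ","),
             row.names = NULL, stringsAsFactors = FALSE)
}
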