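#' @useDynLib peatviromics, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

IUPAC_NUC <- "ACGTUMRWSYKVHDBN"
IUPAC_AA  <- "ABCDEFGHIKLMNPQRSTVWXYZ*"

#' Read a FASTA file into a data frame of sequence records
#'
#' Headers are split at the first whitespace into `id` and `description`;
#' wrapped sequence lines are joined and stored uppercase. Ids must be unique
#' and sequences non-empty.
#'
#' @param path Path to a FASTA file.
#' @param alphabet `"nuc"`, `"aa"`, or `NULL` to skip alphabet validation.
#' @return A data frame with columns `id`, `description`, `sequence`.
#' @export
read_fasta <- function(path, alphabet = "nuc") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(id = character(), description = character(),
                      sequence = character(), stringsAsFactors = FALSE))
  }
  hdr <- startsWith(lines, ">")
  if (!hdr[1L]) stop("FASTA does not start with a '>' header")
  grp <- cumsum(hdr)
  heads <- sub("^>", "", lines[hdr])
  ids <- sub("\\s.*$", "", heads)
  desc <- ifelse(grepl("\\s", heads), sub("^\\S+\\s+", "", heads), "")
  seqs <- vapply(split(lines[!hdr], grp[!hdr]), paste0, "", collapse = "")
  out <- rep("", length(ids))
  out[as.integer(names(seqs))] <- toupper(seqs)
  if (any(out == "")) {
    stop("empty sequence for FASTA record(s): ",
         paste(ids[out == ""], collapse = ", "))
  }
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (!is.null(alphabet)) {
    allowed <- if (alphabet == "nuc") IUPAC_NUC else IUPAC_AA
    bad <- grepl(sprintf("[^%s]", allowed), out)
    if (any(bad)) {
      stop("non-IUPAC characters in record(s): ",
           paste(ids[bad], collapse = ", "))
    }
  }
  data.frame(id = ids, description = desc, sequence = out,
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences, or a data frame as
#'   returned by [read_fasta()].
#' @param path Output path.
#' @param width Line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id
    sq <- seqs$sequence
  } else {
    ids <- names(seqs)
    sq <- unname(seqs)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(sq)) {
    writeLines(paste0(">", ids[k]), con)
    s <- sq[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Write reads to FASTQ (constant quality)
#' @param ids,seqs Read names and sequences.
#' @param path Output path.
#' @param qual_char Quality character applied to every base.
#' @export
write_fastq <- function(ids, seqs, path, qual_char = "I") {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(ids)) {
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                      vapply(nchar(seqs), function(n)
                        strrep(qual_char, n), "")), con)
  }
  invisible(path)
}

cigar_lengths <- function(cigar) {
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  if (!length(ops) || sum(nchar(ops)) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  n <- as.integer(sub("[MIDNSHP=X]", "", ops))
  op <- sub("\\d+", "", ops)
  ref <- sum(n[op %in% c("M", "=", "X", "D", "N")])
  qry <- sum(n[op %in% c("M", "=", "X", "I", "S")])
  aln_read <- sum(n[op %in% c("M", "=", "X", "I")])
  list(ref = ref, read = qry, aligned_read = aln_read)
}

#' Read a SAM text file into alignment records
#'
#' SAM 1-based positions are converted to the package-internal 0-based
#' half-open convention. Unmapped records (FLAG 0x4) are skipped. The NM tag
#' is required on every mapped record because read identity is undefined
#' without it.
#'
#' @param path Path to a SAM file (text).
#' @return A data frame with columns `read_id`, `contig_id`, `start`, `end`,
#'   `aligned_ref_len`, `aligned_read_len`, `edit_distance`, `strand`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  recs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 11L) stop("truncated SAM record: ", substr(l, 1, 60))
    flag <- as.integer(f[2])
    if (bitwAnd(flag, 4L) > 0L) return(NULL)
    nm_field <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (!length(nm_field)) {
      stop("missing NM tag for mapped read '", f[1], "'")
    }
    cl <- cigar_lengths(f[6])
    start <- as.integer(f[4]) - 1L
    data.frame(read_id = f[1], contig_id = f[3], start = start,
               end = start + cl$ref, aligned_ref_len = cl$ref,
               aligned_read_len = cl$aligned_read,
               edit_distance = as.integer(sub("^NM:i:", "", nm_field[1])),
               strand = if (bitwAnd(flag, 16L) > 0L) "-" else "+",
               stringsAsFactors = FALSE)
  })
  recs <- recs[!vapply(recs, is.null, TRUE)]
  if (!length(recs)) {
    return(data.frame(read_id = character(), contig_id = character(),
                      start = integer(), end = integer(),
                      aligned_ref_len = integer(),
                      aligned_read_len = integer(),
                      edit_distance = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, recs)
}

#' Write alignment records as SAM text
#' @param aln Data frame with `read_id`, `contig_id`, `start` (0-based),
#'   `strand`, `seq`, `edit_distance` columns.
#' @param contig_lengths Named integer vector for the `@SQ` header.
#' @param path Output path.
#' @export
write_sam <- function(aln, contig_lengths, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(contig_lengths),
                     as.integer(contig_lengths)), con)
  if (nrow(aln)) {
    flag <- ifelse(aln$strand == "-", 16L, 0L)
    writeLines(sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*\tNM:i:%d",
                       aln$read_id, flag, aln$contig_id, aln$start + 1L,
                       nchar(aln$seq), aln$seq, aln$edit_distance), con)
  }
  invisible(path)
}

#' Parse a Newick tree into a binary rooted `phylo` object
#'
#' Multifurcations are resolved deterministically with zero-length inserted
#' edges; missing branch lengths default to 1. Tip labels are preserved
#' verbatim.
#'
#' @param text A Newick string (or a path when `is_path = TRUE`).
#' @param is_path Treat `text` as a file path.
#' @return An [ape::read.tree()] style `phylo` object, binary, with lengths.
#' @export
read_newick <- function(text, is_path = FALSE) {
  if (is_path) text <- paste(readLines(text), collapse = "")
  open <- cumsum((strsplit(text, "")[[1]] == "(") -
                   (strsplit(text, "")[[1]] == ")"))
  if (any(open < 0) || tail(open, 1) != 0) {
    stop("unbalanced parentheses in newick at position ",
         if (any(open < 0)) which(open < 0)[1] else nchar(text))
  }
  tr <- ape::read.tree(text = text)
  if (is.null(tr)) stop("could not parse newick string")
  # default lengths before resolving, so inserted edges get length 0
  if (is.null(tr$edge.length)) {
    tr$edge.length <- rep(1, nrow(tr$edge))
  } else {
    tr$edge.length[is.na(tr$edge.length)] <- 1
  }
  # rooted-binary representation: a basal trifurcation counts as binary
  # for unrooted trees, so the rootedness check is required too
  if (!ape::is.binary(tr) || !ape::is.rooted(tr)) {
    tr <- ape::multi2di(tr, random = FALSE)
  }
  tr
}

#' Read a TSV with a required schema
#' @param path Path to a tab-separated file with a header row.
#' @param required Character vector of required column names.
#' @return Data frame.
#' @export
read_table_checked <- function(path, required = NULL) {
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) && length(unique(nf)) > 1L) {
    stop("ragged TSV: rows have differing field counts in ", path)
  }
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Write a data frame as TSV (stable column order, header row)
#' @param df Data frame.
#' @param path Output path.
#' @export
write_table_checked <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
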