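#' Filter viral prediction results by the published score rules
#'
#' A contig is accepted when it is at least `min_len` bp long and passes at
#' least one predictor: a DeepVirFinder-style score strictly above 0.9 with
#' p strictly below 0.05, or a VirSorter-style category in \{1, 2, 4, 5\}.
#' Absent fields are treated as non-passing. Provenance records which route
#' accepted each contig (`both`, `score_only`, `category_only`).
#'
#' @param rows Data frame with columns `contig_id`, `length`, and any of
#'   `dvf_score`, `dvf_p`, `vs_category` (NA where absent).
#' @param min_len Minimum contig length in bp (default 10000).
#' @return The accepted subset with an added `provenance` column.
#' @export
filter_viral_predictions <- function(rows, min_len = 10000) {
  need <- c("contig_id", "length")
  if (!all(need %in% names(rows))) {
    stop("rows must have columns: ", paste(need, collapse = ", "))
  }
  score <- if ("dvf_score" %in% names(rows)) rows$dvf_score else
    rep(NA_real_, nrow(rows))
  p <- if ("dvf_p" %in% names(rows)) rows$dvf_p else rep(NA_real_, nrow(rows))
  cat <- if ("vs_category" %in% names(rows)) rows$vs_category else
    rep(NA_integer_, nrow(rows))
  dvf_pass <- !is.na(score) & !is.na(p) & score > 0.9 & p < 0.05
  vs_pass <- !is.na(cat) & cat %in% c(1L, 2L, 4L, 5L)
  keep <- rows$length >= min_len & (dvf_pass | vs_pass)
  out <- rows[keep, , drop = FALSE]
  out$provenance <- ifelse(dvf_pass[keep] & vs_pass[keep], "both",
                           ifelse(dvf_pass[keep], "score_only",
                                  "category_only"))
  rownames(out) <- NULL
  out
}

#' Filter putative auxiliary metabolic genes (AMGs)
#'
#' Retains rows with auxiliary score strictly below 4, none of the flags
#' F (viral), T (transposon), P (viral-like peptidase), A (attachment), and
#' both a gene id and a gene description present.
#'
#' @param rows Data frame with columns `gene_id`, `gene_description`,
#'   `auxiliary_score`, `flags` (string of single-letter flags).
#' @return The retained subset.
#' @export
filter_amg_candidates <- function(rows) {
  need <- c("gene_id", "gene_description", "auxiliary_score", "flags")
  if (!all(need %in% names(rows))) {
    stop("rows must have columns: ", paste(need, collapse = ", "))
  }
  bad_flag <- grepl("[FTPA]", rows$flags)
  keep <- rows$auxiliary_score < 4 & !bad_flag &
    !is.na(rows$gene_id) & nzchar(rows$gene_id) &
    !is.na(rows$gene_description) & nzchar(rows$gene_description)
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
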