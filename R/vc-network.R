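#' Greedy protein clustering into protein clusters (PCs)
#'
#' Longest-first greedy centroid clustering of predicted proteins: a protein
#' joins the first centroid it matches at `aai_thresh` global amino-acid
#' identity over at least `cov_thresh` of the shorter protein.
#'
#' @param proteins Data frame with `protein_id`, `sequence`.
#' @param aai_thresh Identity threshold (default 0.60).
#' @param cov_thresh Coverage-of-shorter threshold (default 0.80).
#' @return Data frame `protein_id`, `pc_id` (centroid protein id).
#' @export
cluster_proteins <- function(proteins, aai_thresh = 0.60, cov_thresh = 0.80) {
  if (nrow(proteins) == 0) {
    return(data.frame(protein_id = character(), pc_id = character(),
                      stringsAsFactors = FALSE))
  }
  cl <- greedy_cluster(stats::setNames(proteins$sequence,
                                       proteins$protein_id),
                       id_thresh = aai_thresh, cov_thresh = cov_thresh,
                       try_rc = FALSE)
  data.frame(protein_id = cl$member, pc_id = cl$representative,
             stringsAsFactors = FALSE)
}

#' Genome profiles: the set of protein clusters present in each genome
#' @param pc_assign Output of [cluster_proteins()].
#' @param genome_map Data frame `protein_id`, `genome_id`.
#' @return Named list of character vectors of PC ids.
#' @export
genome_profiles <- function(pc_assign, genome_map) {
  pc <- pc_assign$pc_id[match(genome_map$protein_id, pc_assign$protein_id)]
  lapply(split(pc, genome_map$genome_id), unique)
}

#' Hypergeometric gene-sharing similarity score between two genomes
#'
#' With `c` shared PCs out of profile sizes `a` and `b` in a universe of
#' `universe_size` PCs, the upper-tail hypergeometric probability
#' P(X >= c) is Bonferroni-corrected by the number of evaluated genome
#' pairs and converted to a score `-log10(p)`. Genomes sharing no PCs score
#' 0.
#'
#' @param pa,pb Character vectors of PC ids.
#' @param universe_size Number of PCs in the universe (>= |pa U pb|).
#' @param n_pairs Number of genome pairs evaluated (Bonferroni factor).
#' @return Non-negative score.
#' @export
pair_score <- function(pa, pb, universe_size, n_pairs = 1) {
  c_shared <- length(intersect(pa, pb))
  if (c_shared == 0) return(0)
  if (universe_size < length(union(pa, pb))) {
    stop("universe_size smaller than |pa U pb|")
  }
  p <- stats::phyper(c_shared - 1, length(pa),
                     universe_size - length(pa), length(pb),
                     lower.tail = FALSE)
  max(0, -log10(min(1, p * n_pairs)))
}

#' Build the weighted gene-sharing genome graph
#'
#' @param profiles Named list of PC-id vectors (one per genome); isolated
#'   genomes stay as isolated nodes.
#' @param min_score Minimum [pair_score()] to draw an edge (default 1).
#' @return An [igraph::graph] with a `weight` edge attribute.
#' @export
build_vc_graph <- function(profiles, min_score = 1.0) {
  genomes <- names(profiles)
  M <- length(unique(unlist(profiles)))
  n <- length(genomes)
  n_pairs <- n * (n - 1) / 2
  edges <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq((i + 1), n)) {
        s <- pair_score(profiles[[i]], profiles[[j]], M, n_pairs)
        if (s >= min_score) {
          edges[[length(edges) + 1L]] <- data.frame(
            from = genomes[i], to = genomes[j], weight = s,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n, name = genomes)
  if (length(edges)) {
    e <- do.call(rbind, edges)
    g <- igraph::add_edges(g, as.vector(rbind(e$from, e$to)),
                           weight = e$weight)
  }
  g
}

#' Markov clustering (MCL) of a weighted undirected graph
#'
#' Column-stochastic flow simulation: expansion (matrix power), inflation
#' (entry-wise power with column renormalization), pruning of small
#' entries, iterated to convergence. Self-loops of weight 1 are added
#' before normalization. Every node lands in exactly one cluster; isolated
#' nodes become singletons.
#'
#' @param graph An [igraph::graph] with optional `weight` attribute.
#' @param inflation Inflation exponent (default 2).
#' @param expansion Expansion power (default 2).
#' @param prune Entries below this are zeroed each iteration.
#' @param max_iter Maximum iterations (warns if reached).
#' @param tol Convergence tolerance on the flow matrix.
#' @return Data frame `genome`, `vc_id` ("VC_0001" style, numbered by first
#'   member in node order).
#' @export
mcl <- function(graph, inflation = 2.0, expansion = 2L, prune = 1e-6,
                max_iter = 100L, tol = 1e-8) {
  n <- igraph::vcount(graph)
  nodes <- igraph::V(graph)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  if (n == 0) {
    return(data.frame(genome = character(), vc_id = character(),
                      stringsAsFactors = FALSE))
  }
  A <- igraph::as_adjacency_matrix(graph, attr =
    if ("weight" %in% igraph::edge_attr_names(graph)) "weight" else NULL,
    sparse = FALSE)
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    Mexp <- M
    for (e in seq_len(expansion - 1L)) Mexp <- Mexp %*% M
    Minf <- Mexp ^ inflation
    Minf[Minf < prune] <- 0
    cs <- colSums(Minf)
    cs[cs == 0] <- 1
    Mnew <- sweep(Minf, 2, cs, "/")
    delta <- max(abs(Mnew - M))
    M <- Mnew
    if (delta < tol) break
  }
  if (delta >= tol) {
    warning("MCL did not converge in ", max_iter,
            " iterations; returning current partition")
  }
  # clusters: columns sharing an attractor row belong together
  memb <- seq_len(n)
  supp <- M > 1e-4
  for (i in seq_len(n)) {
    cols <- which(supp[i, ])
    if (length(cols) > 1) {
      tgt <- min(memb[cols])
      memb[memb %in% memb[cols]] <- tgt
    }
  }
  ids <- match(memb, unique(memb))
  data.frame(genome = nodes, vc_id = sprintf("VC_%04d", ids),
             stringsAsFactors = FALSE)
}

#' Transfer taxonomy to viral clusters from reference members
#'
#' A VC (and all its members) is classified iff it contains at least one
#' reference genome; conflicting reference labels yield "ambiguous" (still
#' counted as classified).
#'
#' @param vcs Data frame `genome`, `vc_id` (see [mcl()]).
#' @param reference_labels Data frame `genome`, `label` for reference
#'   genomes only.
#' @return `vcs` with added `taxonomy` (NA when unclassified).
#' @export
assign_taxonomy <- function(vcs, reference_labels) {
  lab_by_vc <- tapply(
    reference_labels$label[match(vcs$genome, reference_labels$genome)],
    vcs$vc_id, function(x) {
      x <- unique(x[!is.na(x)])
      if (length(x) == 0) NA_character_
      else if (length(x) == 1) x
      else "ambiguous"
    })
  vcs$taxonomy <- as.vector(lab_by_vc[vcs$vc_id])
  vcs
}

#' Mean pairwise amino-acid identity within a viral cluster
#'
#' For each genome pair, proteins are matched by best reciprocal global
#' identity; the pair's AAI is the mean identity of reciprocal matches, and
#' the VC value is the mean over genome pairs. Matches must align at least
#' `min_cov` of the shorter protein — without this gate, chance 2-3 residue
#' overlaps between unrelated proteins score identity 1 and inflate the
#' average. Singleton VCs return NA.
#'
#' @param members Character vector of genome ids in one VC.
#' @param proteins Data frame `protein_id`, `sequence`.
#' @param genome_map Data frame `protein_id`, `genome_id`.
#' @param min_cov Minimum aligned fraction of the shorter protein for a
#'   match to count (default 0.5).
#' @return Mean AAI fraction, or NA for singletons.
#' @export
mean_pairwise_aai <- function(members, proteins, genome_map,
                              min_cov = 0.5) {
  if (length(members) < 2) return(NA_real_)
  seqs <- stats::setNames(proteins$sequence, proteins$protein_id)
  by_genome <- split(genome_map$protein_id, genome_map$genome_id)
  pair_aai <- function(ga, gb) {
    pa <- by_genome[[ga]]; pb <- by_genome[[gb]]
    if (!length(pa) || !length(pb)) return(NA_real_)
    idm <- matrix(0, length(pa), length(pb))
    for (i in seq_along(pa)) {
      for (j in seq_along(pb)) {
        pi <- pair_identity(seqs[[pa[i]]], seqs[[pb[j]]], try_rc = FALSE)
        if (pi$shorter_cov >= min_cov) idm[i, j] <- pi$identity
      }
    }
    best_a <- max.col(idm, ties.method = "first")
    best_b <- max.col(t(idm), ties.method = "first")
    recip <- which(best_b[best_a] == seq_along(pa) &
                     idm[cbind(seq_along(pa), best_a)] > 0)
    if (!length(recip)) return(NA_real_)
    mean(idm[cbind(recip, best_a[recip])])
  }
  vals <- utils::combn(members, 2, function(p) pair_aai(p[1], p[2]))
  mean(vals, na.rm = TRUE)
}

round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Summarise a vOTU-into-VC clustering (Table-1 style arithmetic)
#'
#' @param membership Character vector of VC ids, one entry per vOTU (names
#'   optional), or a [mcl()] data frame.
#' @return One-row data frame: `n_votus`, `n_vcs`, `n_multi_vcs`,
#'   `n_singleton_vcs`, `votus_in_multi`, `pct_singleton_vcs`,
#'   `pct_votus_in_singletons` (percents rounded half away from zero).
#' @export
summarize_clustering <- function(membership) {
  if (is.data.frame(membership)) membership <- membership$vc_id
  sizes <- table(membership)
  n_votus <- length(membership)
  n_vcs <- length(sizes)
  n_singleton <- sum(sizes == 1)
  data.frame(
    n_votus = n_votus,
    n_vcs = n_vcs,
    n_multi_vcs = n_vcs - n_singleton,
    n_singleton_vcs = n_singleton,
    votus_in_multi = n_votus - n_singleton,
    pct_singleton_vcs = as.integer(round_half_away(
      100 * n_singleton / n_vcs)),
    pct_votus_in_singletons = as.integer(round_half_away(
      100 * n_singleton / n_votus)))
}

#' Habitat composition of viral clusters
#'
#' @param vcs Data frame `genome`, `vc_id`.
#' @param habitats Data frame `votu`, `habitat` (genome ids = vOTU ids).
#' @param soil_habitats,aquatic_habitats Label groups used for the
#'   soil-aquatic sharing percentage.
#' @return List with `vc_habitats` (per-VC habitat set, "+"-joined),
#'   `combination_counts`, and `pct_soil_vcs_sharing_aquatic`.
#' @export
habitat_overlap <- function(vcs, habitats,
                            soil_habitats = c("soil", "peat"),
                            aquatic_habitats = c("marine", "freshwater")) {
  if (nrow(vcs) == 0) {
    return(list(vc_habitats = data.frame(vc_id = character(),
                                         habitat_set = character(),
                                         stringsAsFactors = FALSE),
                combination_counts = table(character(0)),
                pct_soil_vcs_sharing_aquatic = NA_real_))
  }
  hab <- habitats$habitat[match(vcs$genome, habitats$votu)]
  sets <- tapply(hab, vcs$vc_id, function(x)
    paste(sort(unique(x[!is.na(x)])), collapse = "+"))
  vc_hab <- data.frame(vc_id = names(sets), habitat_set = unname(sets),
                       stringsAsFactors = FALSE)
  has <- function(set, labels) {
    any(strsplit(set, "+", fixed = TRUE)[[1]] %in% labels)
  }
  soil_vc <- vapply(vc_hab$habitat_set, has, TRUE, labels = soil_habitats)
  aq_vc <- vapply(vc_hab$habitat_set, has, TRUE, labels = aquatic_habitats)
  pct <- if (sum(soil_vc) == 0) NA_real_ else
    100 * sum(soil_vc & aq_vc) / sum(soil_vc)
  list(vc_habitats = vc_hab,
       combination_counts = table(vc_hab$habitat_set),
       pct_soil_vcs_sharing_aquatic = pct)
}

#' Aquatic-like vOTUs: members of VCs containing an aquatic vOTU
#'
#' @inheritParams habitat_overlap
#' @return Character vector of vOTU ids whose VC habitat set intersects
#'   the aquatic habitats.
#' @export
aquatic_like_votus <- function(vcs, habitats,
                               aquatic_habitats = c("marine",
                                                    "freshwater")) {
  hab <- habitats$habitat[match(vcs$genome, habitats$votu)]
  aq_vc <- unique(vcs$vc_id[!is.na(hab) & hab %in% aquatic_habitats])
  sort(vcs$genome[vcs$vc_id %in% aq_vc])
}
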