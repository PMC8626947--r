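#' Hellinger transformation of an abundance table
#'
#' Each sample (column) vector is transformed to sqrt(value / sample
#' total). Zero samples stay zero, with a warning.
#'
#' @param mat vOTU x sample abundance matrix.
#' @return Matrix of the same shape.
#' @export
hellinger <- function(mat) {
  zero <- colSums(mat) == 0
  if (any(zero)) {
    warning("sample(s) with zero total abundance: ",
            paste(colnames(mat)[zero], collapse = ", "))
  }
  out <- t(vegan::decostand(t(mat), method = "hellinger"))
  out[, zero] <- 0
  dimnames(out) <- dimnames(mat)
  out
}

#' Bray-Curtis dissimilarity between samples
#' @param mat vOTU x sample matrix (samples are columns).
#' @return A `dist` object over samples.
#' @export
bray_curtis <- function(mat) {
  vegan::vegdist(t(mat), method = "bray")
}

#' Principal coordinates analysis (PCoA)
#'
#' Classical metric MDS on a distance matrix: eigendecomposition of the
#' double-centred -0.5 * D^2 matrix. Coordinates use the positive axes;
#' all eigenvalues, including negative ones, are reported.
#'
#' @param D A `dist` object.
#' @return List with `coordinates` (samples x axes), `eigenvalues`, and
#'   `relative_eig` (share of the positive eigenvalue total).
#' @export
pcoa_ordination <- function(D) {
  n <- attr(D, "Size")
  fit <- suppressWarnings(stats::cmdscale(D, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  if (length(pos) == 0) {
    coords <- matrix(0, nrow = n, ncol = 1,
                     dimnames = list(attr(D, "Labels"), "Axis1"))
  } else {
    colnames(coords) <- paste0("Axis", seq_along(pos))
  }
  list(coordinates = coords, eigenvalues = eig,
       relative_eig = if (any(eig > 0)) eig / sum(eig[eig > 0]) else eig)
}

#' Mantel test (Pearson, one-sided upper tail)
#'
#' @param D1,D2 `dist` objects over the same samples.
#' @param n_perm Number of permutations (default 999).
#' @param seed Seed for the permutation stream.
#' @return List with `r`, `p`, `n_perm`.
#' @export
mantel_test <- function(D1, D2, n_perm = 999, seed = 1L) {
  v1 <- as.vector(D1); v2 <- as.vector(D2)
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    stop("mantel: a distance matrix has zero variance")
  }
  set.seed(seed)
  fit <- vegan::mantel(D1, D2, method = "pearson", permutations = n_perm)
  list(r = unname(fit$statistic), p = fit$signif, n_perm = n_perm)
}

#' PERMANOVA (adonis) on a distance matrix
#'
#' @param D A `dist` object.
#' @param groups Factor of group labels, one per sample.
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutation stream.
#' @return List with `pseudo_F`, `p`.
#' @export
permanova_test <- function(D, groups, n_perm = 999, seed = 1L) {
  groups <- as.factor(groups)
  n <- attr(D, "Size")
  if (nlevels(droplevels(groups)) < 2) {
    stop("permanova: need at least two groups")
  }
  if (n - nlevels(droplevels(groups)) < 1) {
    stop("permanova: no residual degrees of freedom")
  }
  set.seed(seed)
  df <- data.frame(groups = droplevels(groups))
  fit <- vegan::adonis2(D ~ groups, data = df, permutations = n_perm)
  list(pseudo_F = fit$F[1], p = fit$`Pr(>F)`[1])
}

#' vOTU accumulation curve over permuted sample orders
#'
#' @param presence vOTU x sample matrix; nonzero means detected.
#' @param n_perm Number of sample-order permutations (default 100).
#' @param seed Seed.
#' @return List with `mean_richness` (length = number of samples) and
#'   `perm` (n_perm x samples matrix of per-permutation curves).
#' @export
accumulation_curve <- function(presence, n_perm = 100, seed = 1L) {
  pres <- presence > 0
  ns <- ncol(pres)
  set.seed(seed)
  perm <- matrix(0L, nrow = n_perm, ncol = ns)
  for (b in seq_len(n_perm)) {
    ord <- sample.int(ns)
    seen <- rep(FALSE, nrow(pres))
    for (k in seq_len(ns)) {
      seen <- seen | pres[, ord[k]]
      perm[b, k] <- sum(seen)
    }
  }
  list(mean_richness = colMeans(perm), perm = perm)
}

#' Median-of-ratios size factors
#'
#' Geometric-mean reference over vOTUs with all-positive counts; each
#' sample's factor is the median ratio to that reference.
#'
#' @param counts vOTU x sample count matrix.
#' @return Named numeric vector of size factors.
#' @export
size_factors <- function(counts) {
  allpos <- rowSums(counts == 0) == 0
  if (!any(allpos)) {
    warning("no vOTU with all-positive counts; ",
            "falling back to library-size factors")
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf[sf > 0]))))
  }
  ref <- exp(rowMeans(log(counts[allpos, , drop = FALSE])))
  apply(counts[allpos, , drop = FALSE], 2, function(col)
    stats::median(col / ref))
}

fit_nb_theta <- function(y, design_full, offset) {
  # Shared per-vOTU dispersion by Pearson pseudo-likelihood with
  # residual-df correction (naive full-model ML is biased low with few
  # samples and inflates the LRT); method-of-moments fallback, dispersion
  # floored at 1e-8.
  n <- length(y)
  p <- ncol(design_full)
  mom_alpha <- function() {
    ynorm <- y / exp(offset)
    m <- mean(ynorm); v <- stats::var(ynorm)
    max((v - m) / m^2, 1e-8)
  }
  if (n - p < 1) return(1 / mom_alpha())
  fit0 <- suppressWarnings(
    stats::glm.fit(design_full, y, offset = offset,
                   family = stats::poisson()))
  mu <- pmax(fit0$fitted.values, 1e-8)
  alpha <- max(mom_alpha(), 1e-8)
  for (it in 1:3) {
    fam <- MASS::negative.binomial(1 / alpha)
    mu <- pmax(suppressWarnings(
      stats::glm.fit(design_full, y, offset = offset,
                     family = fam))$fitted.values, 1e-8)
    # solve sum((y-mu)^2 / (mu + a mu^2)) = n - p for a
    f <- function(a) sum((y - mu)^2 / (mu + a * mu^2)) - (n - p)
    if (f(1e-8) <= 0) { alpha <- 1e-8; break }
    if (f(1e4) >= 0) { alpha <- 1e4; break }
    alpha <- stats::uniroot(f, c(1e-8, 1e4), tol = 1e-6)$root
  }
  1 / max(alpha, 1e-8)
}

#' Negative-binomial likelihood-ratio test for depth-differential vOTUs
#'
#' Per vOTU: a shared NB dispersion is estimated by maximum likelihood
#' (method-of-moments fallback, dispersion floored at 1e-8), then the full
#' model `log mu = offset + b0 + b_level` is tested against the
#' intercept-only reduced model by a likelihood-ratio chi-square with
#' (levels - 1) degrees of freedom, with Benjamini-Hochberg adjustment.
#' Size factors come from [size_factors()] and enter as offsets. All-zero
#' rows are dropped (with a message).
#'
#' @param counts vOTU x sample count matrix.
#' @param depth_levels Factor of depth levels, one per sample.
#' @param alpha Adjusted-p significance cutoff (default 0.05).
#' @return Data frame `votu`, `stat`, `df`, `p`, `padj`, `significant`.
#' @export
nb_lrt <- function(counts, depth_levels, alpha = 0.05) {
  depth_levels <- droplevels(as.factor(depth_levels))
  if (nlevels(depth_levels) < 2) stop("need at least two depth levels")
  if (ncol(counts) != length(depth_levels)) {
    stop("depth_levels length must match the number of samples")
  }
  keep <- rowSums(counts) > 0
  if (any(!keep)) {
    message("dropping ", sum(!keep), " all-zero vOTU row(s)")
  }
  counts <- counts[keep, , drop = FALSE]
  sf <- size_factors(counts)
  offset <- log(sf)
  X_full <- stats::model.matrix(~depth_levels)
  X_red <- stats::model.matrix(~1, data = data.frame(x = depth_levels))
  df_test <- nlevels(depth_levels) - 1
  df_resid <- ncol(counts) - nlevels(depth_levels)
  res <- t(apply(counts, 1, function(y) {
    theta <- fit_nb_theta(y, X_full, offset)
    fam <- MASS::negative.binomial(theta)
    full <- suppressWarnings(stats::glm.fit(X_full, y, offset = offset,
                                            family = fam))
    red <- suppressWarnings(stats::glm.fit(X_red, y, offset = offset,
                                           family = fam))
    stat <- max(0, red$deviance - full$deviance)
    # F-type quasi-likelihood p-value: with the dispersion estimated from
    # few samples, referring the LRT to chi-square(df) is anticonservative;
    # LRT/df against F(df, residual df) restores calibration
    p <- if (df_resid >= 1) {
      stats::pf(stat / df_test, df_test, df_resid, lower.tail = FALSE)
    } else {
      stats::pchisq(stat, df_test, lower.tail = FALSE)
    }
    c(stat = stat, p = p)
  }))
  out <- data.frame(votu = rownames(counts), stat = res[, "stat"],
                    df = df_test, p = res[, "p"],
                    padj = stats::p.adjust(res[, "p"], method = "BH"),
                    row.names = NULL, stringsAsFactors = FALSE)
  out$significant <- out$padj < alpha
  out
}

#' Depth-profile groups of differential vOTUs
#'
#' Per-vOTU mean normalized abundance per depth level, Z-transformed
#' across levels (population standard deviation), complete-linkage
#' hierarchical clustering on Euclidean distance, cut into `k` groups.
#' Groups are labelled 1..k by the depth level of their maximal mean Z
#' (shallow to deep). Constant-profile vOTUs get a zero Z vector (logged).
#'
#' @param votus Character vector of (significant) vOTU ids.
#' @param counts vOTU x sample count matrix.
#' @param depth_levels Ordered factor of depth levels per sample.
#' @param k Number of groups (default 3).
#' @return Data frame `votu`, `group`, plus attribute `profiles` (mean-Z
#'   matrix).
#' @export
depth_groups <- function(votus, counts, depth_levels, k = 3) {
  depth_levels <- as.factor(depth_levels)
  sf <- size_factors(counts)
  norm <- sweep(counts[votus, , drop = FALSE], 2, sf, "/")
  lev <- levels(depth_levels)
  prof <- sapply(lev, function(l)
    rowMeans(norm[, depth_levels == l, drop = FALSE]))
  prof <- matrix(prof, nrow = length(votus),
                 dimnames = list(votus, lev))
  zd <- function(x) {
    s <- sqrt(mean((x - mean(x))^2))
    if (s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  flat <- apply(prof, 1, function(x) all(x == x[1]))
  if (any(flat)) {
    message(sum(flat), " constant-profile vOTU(s) assigned the zero-Z ",
            "convention")
  }
  Z <- t(apply(prof, 1, zd))
  k_eff <- min(k, nrow(Z))
  cl <- if (nrow(Z) == 1) 1L else
    stats::cutree(stats::hclust(stats::dist(Z), method = "complete"),
                  k = k_eff)
  # order groups by depth of peak mean Z, shallow to deep
  peak <- vapply(seq_len(k_eff), function(g) {
    zm <- colMeans(Z[cl == g, , drop = FALSE])
    which.max(zm)
  }, 1L)
  relabel <- match(seq_len(k_eff), order(peak))
  out <- data.frame(votu = votus, group = relabel[cl],
                    stringsAsFactors = FALSE)
  attr(out, "profiles") <- Z
  out
}

#' Hypergeometric trait enrichment per group
#'
#' For each group: upper-tail probability of drawing at least the observed
#' number of trait-positive members, given the trait frequency in the
#' universe.
#'
#' @param group_sets Named list of character vectors (group members).
#' @param trait_set Character vector of trait-positive ids.
#' @param universe Character vector of all ids.
#' @param alpha Significance cutoff (default 0.05).
#' @return Data frame `group`, `k`, `n`, `K`, `N`, `p`, `significant`.
#' @export
trait_enrichment <- function(group_sets, trait_set, universe,
                             alpha = 0.05) {
  trait_set <- intersect(trait_set, universe)
  N <- length(universe)
  K <- length(trait_set)
  rows <- lapply(names(group_sets), function(g) {
    members <- intersect(group_sets[[g]], universe)
    n <- length(members)
    k <- length(intersect(members, trait_set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(group = g, k = k, n = n, K = K, N = N, p = p,
               significant = p < alpha, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pooled-variance two-sided Student's t test
#' @param x,y Numeric samples (each of size >= 2).
#' @return List with `t`, `p`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) {
    stop("need at least two observations per group")
  }
  fit <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(fit$statistic), p = fit$p.value)
}
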