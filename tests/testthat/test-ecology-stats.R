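test_that("Hellinger and Bray-Curtis match hand calculations", {
  m <- matrix(c(1, 1, 2), ncol = 1,
              dimnames = list(paste0("v", 1:3), "s1"))
  h <- hellinger(m)
  expect_equal(unname(h[, 1]), c(0.5, 0.5, sqrt(0.5)))
  one <- matrix(4, dimnames = list("v1", "s1"))
  expect_equal(unname(hellinger(one)[1, 1]), 1.0)
  z <- matrix(c(1, 2, 0, 0), ncol = 2,
              dimnames = list(c("v1", "v2"), c("s1", "s2")))
  expect_warning(hz <- hellinger(z), "zero total")
  expect_equal(unname(hz[, "s2"]), c(0, 0))

  m2 <- cbind(a = c(2, 1), b = c(1, 1))
  expect_equal(as.matrix(bray_curtis(m2))["a", "b"], 0.2)
  m3 <- cbind(a = c(1, 0), b = c(0, 1))
  expect_equal(as.matrix(bray_curtis(m3))["a", "b"], 1)
  m4 <- cbind(a = c(3, 4), b = c(3, 4))
  expect_equal(as.matrix(bray_curtis(m4))["a", "b"], 0)
  # bounded in [0, 1] after Hellinger, symmetric, zero diagonal
  set.seed(401)
  r <- matrix(rpois(60, 5), nrow = 10,
              dimnames = list(paste0("v", 1:10), paste0("s", 1:6)))
  D <- as.matrix(bray_curtis(hellinger(r)))
  expect_true(all(D >= 0 & D <= 1))
  expect_equal(D, t(D))
  expect_true(all(diag(D) == 0))
})

test_that("PCoA recovers planar configurations and reports eigenvalues", {
  D2 <- stats::dist(c(0, 1))
  expect_equal(sort(pcoa_ordination(D2)$coordinates[, 1]), c(-0.5, 0.5))
  # identical points give all-zero coordinates
  D0 <- stats::dist(c(1, 1, 1))
  expect_true(all(abs(pcoa_ordination(D0)$coordinates) < 1e-12))
  # Euclidean distances on a known planar configuration come back
  set.seed(402)
  X <- cbind(runif(7), runif(7))
  fit <- pcoa_ordination(stats::dist(X))
  Y <- fit$coordinates[, 1:2]
  pro <- vegan::procrustes(X, Y, symmetric = TRUE)
  expect_lt(pro$ss, 1e-8)
  expect_true(all(fit$relative_eig[1:2] > 0))
})

test_that("Mantel test contracts: self-correlation, zero variance, seeding", {
  set.seed(403)
  m <- matrix(rpois(80, 10), nrow = 10)
  colnames(m) <- paste0("s", 1:8)
  D1 <- bray_curtis(m)
  r1 <- mantel_test(D1, D1, n_perm = 99, seed = 5)
  expect_equal(r1$r, 1)
  expect_equal(r1$p, 1 / 100)
  expect_error(mantel_test(D1, stats::dist(rep(1, 8)) * 0), "variance")
  r2 <- mantel_test(D1, stats::dist(rnorm(8)), n_perm = 99, seed = 9)
  r3 <- mantel_test(D1, stats::dist(rnorm(8)), n_perm = 99, seed = 9)
  expect_false(identical(r2$p, NULL))
  # same seed, same data -> identical permutation p
  set.seed(77); d <- stats::dist(rnorm(8))
  expect_identical(mantel_test(D1, d, n_perm = 99, seed = 3)$p,
                   mantel_test(D1, d, n_perm = 99, seed = 3)$p)
})

test_that("PERMANOVA separates planted clouds and rejects degenerate designs", {
  set.seed(404)
  X <- rbind(matrix(rnorm(40, 0), ncol = 4),
             matrix(rnorm(40, 4), ncol = 4))
  D <- stats::dist(X)
  g <- rep(c("a", "b"), each = 10)
  fit <- permanova_test(D, g, n_perm = 199, seed = 1)
  expect_equal(fit$p, 1 / 200)
  expect_gt(fit$pseudo_F, 1)
  expect_error(permanova_test(D, rep("a", 20)), "two groups")
  expect_error(permanova_test(stats::dist(c(0, 1)), c("a", "b")),
               "degrees of freedom")
})

test_that("accumulation curves: flat for identical samples, linear for disjoint", {
  pres_same <- matrix(1, nrow = 5, ncol = 4,
                      dimnames = list(paste0("v", 1:5), paste0("s", 1:4)))
  acc <- accumulation_curve(pres_same, n_perm = 20, seed = 1)
  expect_equal(acc$mean_richness, rep(5, 4))
  pres_disj <- rbind(cbind(diag(3) * 1), matrix(0, 0, 3))
  dimnames(pres_disj) <- list(paste0("v", 1:3), paste0("s", 1:3))
  acc2 <- accumulation_curve(pres_disj, n_perm = 10, seed = 2)
  expect_equal(acc2$mean_richness, 1:3)
  one <- matrix(c(1, 0, 2), ncol = 1,
                dimnames = list(paste0("v", 1:3), "s1"))
  expect_equal(accumulation_curve(one, n_perm = 5, seed = 3)$mean_richness,
               2)
})

test_that("size factors are exact on scaled duplicate columns", {
  set.seed(405)
  base <- rpois(50, 20) + 1
  counts <- cbind(s1 = base, s2 = base, s3 = base)
  expect_equal(unname(size_factors(counts)), rep(1, 3))
  counts2 <- cbind(s1 = base, s2 = 2 * base)
  sf <- size_factors(counts2)
  expect_equal(unname(sf[2] / sf[1]), 2)
})

test_that("NB-LRT finds planted depth effects and drops all-zero rows", {
  cfg <- abundance_cfg(seed = 406, n_genera = 30)
  comm <- generate_community(cfg)
  ab <- generate_abundance(cfg, comm)
  counts <- ab$counts
  counts <- rbind(counts, zzz_zero = 0)
  expect_message(res <- nb_lrt(counts, ab$metadata$depth_level),
                 "all-zero")
  expect_false("zzz_zero" %in% res$votu)
  expect_true(all(res$padj >= res$p))
  da <- ab$truth$da_votus$votu
  expect_gt(mean(res$p[match(da, res$votu)] < 0.05), 0.6)
  expect_lt(mean(res$p[!(res$votu %in% da)] < 0.05), 0.15)
  expect_error(nb_lrt(counts, rep("one", ncol(counts))), "two depth")
})

test_that("depth groups recover archetypal profiles and order by peak depth", {
  set.seed(407)
  lev <- factor(rep(c("10-20", "40-50", "100-125"), each = 4),
                levels = c("10-20", "40-50", "100-125"))
  archetype <- function(peak) {
    mu <- rep(10, 12); mu[as.integer(lev) == peak] <- 60
    rpois(12, mu)
  }
  counts <- rbind(
    t(sapply(1:10, function(i) archetype(1))),
    t(sapply(1:10, function(i) archetype(2))),
    t(sapply(1:10, function(i) archetype(3))))
  rownames(counts) <- paste0("v", 1:30)
  colnames(counts) <- paste0("s", 1:12)
  gr <- depth_groups(rownames(counts), counts, lev, k = 3)
  expect_equal(gr$group, rep(1:3, each = 10))
  # k = 1 puts everything in one group; constant profiles are logged
  g1 <- depth_groups(rownames(counts), counts, lev, k = 1)
  expect_equal(unique(g1$group), 1L)
  # constant profile after normalization: all rows constant -> unit size
  # factors, so the probe row's per-level means coincide
  cc <- matrix(rep(c(7, 12), 12), nrow = 2,
               dimnames = list(c("v1", "v2"), paste0("s", 1:12)))
  expect_message(depth_groups("v1", cc, lev, k = 1), "constant-profile")
})

test_that("hypergeometric enrichment matches the closed form and summation", {
  groups <- list(g = paste0("x", 1:10))
  univ <- c(paste0("x", 1:10), paste0("y", 1:90))
  trait <- paste0("x", 1:10)  # all successes inside the group
  en <- trait_enrichment(groups, trait, univ)
  expect_equal(en$p, 1 / choose(100, 10), tolerance = 1e-12)
  expect_equal(en$p, hyper_tail_enum(10, 10, 100, 10), tolerance = 1e-12)
  # k at its expectation is unremarkable
  trait2 <- c(paste0("x", 1:2), paste0("y", 1:18))  # K = 20, E[k] = 2
  en2 <- trait_enrichment(groups, trait2, univ)
  expect_gt(en2$p, 0.2)
  expect_false(en2$significant)
  # K = 0 forces k = 0 and p = 1
  en3 <- trait_enrichment(groups, character(0), univ)
  expect_equal(en3$p, 1)
})

test_that("pooled t test matches the closed form", {
  x <- c(5.1, 4.9, 5.3, 5.0)
  y <- c(6.2, 6.0, 6.4)
  got <- two_sample_t(x, y)
  sp2 <- ((3) * var(x) + (2) * var(y)) / 5
  t_manual <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 3))
  expect_equal(got$t, t_manual)
  expect_equal(got$p, 2 * pt(-abs(t_manual), 5))
  same <- two_sample_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_t(1, c(1, 2)), "two observations")
})
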