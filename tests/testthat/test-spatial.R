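test_that("pairwise Moran's I satisfies the centring identity exactly", {
  for (seed in 1:4) {
    gt <- toy_table(n = 10 + seed, L = 3, K = 4, patches = 3, seed = seed)
    M <- pairwise_moran(gt)
    n <- nrow(M)
    off <- M[upper.tri(M) | lower.tri(M)]
    expect_equal(mean(off), -1 / (n - 1), tolerance = 1e-12)
    expect_true(isSymmetric(M))
  }
})

test_that("pairwise Moran's I matches a brute-force computation on 4 individuals", {
  ind <- data.frame(id = letters[1:4], clutch_id = letters[1:4],
                    patch_id = "p1", species = "target")
  a1 <- matrix(c(101L, 101L, 101L, 102L), 4, 1)
  a2 <- matrix(c(101L, 102L, 102L, 102L), 4, 1)
  gt <- genotype_table(ind, "L1", a1, a2)
  M <- pairwise_moran(gt)
  # by hand: x = (1, .5, .5, 0) per allele column
  x <- c(1, 0.5, 0.5, 0)
  z <- x - mean(x)
  V <- (sum(z^2) + sum((-z)^2)) / 4     # both allele columns, mean over inds
  want <- outer(z, z) * 2 / V           # two mirrored allele columns
  expect_equal(unname(M), unname(want), tolerance = 1e-12)
  # two identical individuals dominate the matrix
  gt2 <- toy_table(n = 8, L = 4, K = 4, patches = 1, seed = 9)
  gt2$a1[2, ] <- gt2$a1[1, ]; gt2$a2[2, ] <- gt2$a2[1, ]
  gt2 <- genotype_table(gt2$ind, gt2$loci, gt2$a1, gt2$a2)
  M2 <- pairwise_moran(gt2)
  diag(M2) <- -Inf
  expect_equal(which(M2 == max(M2), arr.ind = TRUE)[1, ], c(row = 2, col = 1),
               ignore_attr = TRUE)
})

test_that("one-class autocorrelogram equals the overall pair mean -1/(n-1)", {
  gt <- toy_table(n = 12, L = 3, K = 4, patches = 4, seed = 3)
  ds <- toy_dataset(gt)
  ac <- autocorrelogram(ds, n_classes = 1, n_perm = 20, seed = 1)
  expect_equal(ac$classes$mean_I, -1 / (nrow(gt$ind) - 1), tolerance = 1e-10)
  expect_error(autocorrelogram(ds, n_classes = 50), "fewer distinct")
})

test_that("autocorrelogram permutation test holds nominal type-I error", {
  set.seed(12)
  n_rep <- 60
  false_pos <- vapply(seq_len(n_rep), function(r) {
    gt <- toy_table(n = 24, L = 4, K = 4, patches = 6, seed = 5000 + r)
    ds <- toy_dataset(gt, coords = cbind(runif(6, 0, 1000), runif(6, 0, 1000)))
    ac <- autocorrelogram(ds, n_classes = 4, n_perm = 99, seed = r)
    ac$classes$p[1] <= 0.10
  }, logical(1))
  ci <- binom.test(sum(false_pos), n_rep, p = 0.10)$conf.int
  expect_true(ci[1] <= 0.10 && 0.10 <= ci[2])
})

test_that("sPCA eigenvalues factor into variance times Moran's I", {
  gt <- toy_table(n = 24, L = 4, K = 4, patches = 6, seed = 2)
  ds <- toy_dataset(gt)
  sp <- spca(ds, d_max = 2000, n_perm = 19, seed = 1)
  L <- sp$L
  for (ax in c(1, 2, ncol(sp$scores))) {
    s <- sp$scores[, ax]
    lam <- (crossprod(s, L %*% s) / length(s))
    expect_equal(as.numeric(lam), sp$eigenvalues[ax], tolerance = 1e-8)
  }
})

test_that("sPCA detects a simulated north-south cline", {
  cfg <- sim_config(n_patches = 12, extent = 2000, adults_per_patch = 40,
                    sigma = 60, n_generations = 15, n_loci = 10, n_alleles = 6)
  sim <- simulate_metapopulation(cfg, seed = 19)
  ds <- sim$dataset
  set.seed(1)
  keep <- sort(sample(nrow(ds$genotypes$ind), 250))
  ds$genotypes <- subset_genotypes(ds$genotypes, individuals = keep)
  sp <- suppressWarnings(spca(ds, d_max = 1000, n_perm = 199, seed = 1))
  expect_lte(sp$global_p, 0.01)
  j <- match(ds$genotypes$ind$patch_id, ds$patches$id)
  expect_gt(abs(cor(sp$scores[, 1], ds$patches$y[j])) +
              abs(cor(sp$scores[, 1], ds$patches$x[j])), 0.5)
})

test_that("patch grouping recovers well-separated clusters and handles edge k", {
  # four clusters of three patches each, far apart
  centres <- rbind(c(0, 0), c(5000, 0), c(0, 5000), c(5000, 5000))
  xy <- do.call(rbind, lapply(1:4, function(g)
    sweep(matrix(runif(6, -150, 150), 3, 2), 2, centres[g, ], "+")))
  cfg <- sim_config(n_patches = 12, extent = 6000, patch_xy = xy,
                    adults_per_patch = 30, sigma = 120, n_generations = 12,
                    n_loci = 10, n_alleles = 6)
  sim <- simulate_metapopulation(cfg, seed = 23)
  sp <- spca(sim$dataset, d_max = 1200, n_perm = 19, seed = 1)
  grp <- group_patches(sp, sim$dataset, k = 4)
  truth <- rep(1:4, each = 3)[match(names(grp), sim$dataset$patches$id)]
  tab <- table(grp, truth)
  expect_equal(sum(apply(tab, 1, max)), length(grp))  # pure clusters
  expect_equal(length(unique(grp)), 4)
  # k = n patches -> singletons; k too large -> error
  grp_all <- group_patches(sp, sim$dataset, k = length(grp))
  expect_equal(length(unique(grp_all)), length(grp))
  expect_error(group_patches(sp, sim$dataset, k = 99), "k exceeds")
  expect_gte(propose_k(sp), 1)
})

test_that("Weir-Cockerham theta: fixed differences give 1, oracle matches to 1e-10", {
  ind <- data.frame(id = sprintf("i%d", 1:12), clutch_id = sprintf("c%d", 1:12),
                    patch_id = rep(c("A", "B"), each = 6), species = "target")
  gt <- genotype_table(ind, "L1",
                       matrix(rep(c(101L, 102L), each = 6)),
                       matrix(rep(c(101L, 102L), each = 6)))
  ds <- toy_dataset(gt)
  r <- wc_fst(ds, min_n = 2, n_boot = 50, seed = 1)
  expect_equal(r$theta, 1)
  for (seed in 1:5) {
    gt2 <- toy_table(n = 21, L = 3, K = 4, patches = 3, clutch_size = 1,
                     seed = 40 + seed)
    ds2 <- toy_dataset(gt2)
    r2 <- wc_fst(ds2, min_n = 2, n_boot = 25, seed = 1)
    expect_equal(r2$theta, theta_oracle(gt2, sort(unique(gt2$ind$patch_id))),
                 tolerance = 1e-10)
    expect_true(all(r2$pairwise$patch_a != r2$pairwise$patch_b))
  }
  expect_error(wc_fst(ds, min_n = 50), "fewer than 2 patches")
})

test_that("theta is invariant to allele relabeling", {
  gt <- toy_table(n = 20, L = 2, K = 3, patches = 2, clutch_size = 1, seed = 77)
  ds <- toy_dataset(gt)
  th1 <- wc_fst(ds, min_n = 2, n_boot = 10, seed = 1)$theta
  relab <- function(m) { m2 <- m; m2[m == 101L] <- 900L; m2 }
  gt2 <- genotype_table(gt$ind, gt$loci, relab(gt$a1), relab(gt$a2))
  ds$genotypes <- gt2
  expect_equal(wc_fst(ds, min_n = 2, n_boot = 10, seed = 1)$theta, th1,
               tolerance = 1e-12)
})

test_that("theta on panmictic samples is near zero with covering CIs", {
  cover <- vapply(1:10, function(r) {
    gt <- toy_table(n = 60, L = 8, K = 6, patches = 3, clutch_size = 1,
                    seed = 600 + r)
    ds <- toy_dataset(gt)
    res <- wc_fst(ds, min_n = 5, n_boot = 200, seed = r)
    res$ci[1] <= 0 && res$ci[2] >= 0
  }, logical(1))
  expect_gte(sum(cover), 9)
})

test_that("Nei FIS: heterozygote excess negative, HWE near zero, Wahlund positive", {
  ind <- data.frame(id = sprintf("i%d", 1:40), clutch_id = sprintf("c%d", 1:40),
                    patch_id = "p1", species = "target")
  gt <- genotype_table(ind, "L1", matrix(rep(101L, 40)), matrix(rep(102L, 40)))
  expect_lt(nei_fis(gt), -0.9)
  gt2 <- toy_table(n = 200, L = 8, K = 4, patches = 1, seed = 13)
  expect_lt(abs(nei_fis(gt2)), 0.05)
  wahlund <- vapply(1:10, function(r) {
    g1 <- deme_genotypes(700 + 2 * r, n_gen = 20)
    g2 <- deme_genotypes(701 + 2 * r, n_gen = 20)
    nei_fis(pool_tables(g1, g2)) > max(nei_fis(g1), nei_fis(g2))
  }, logical(1))
  expect_gte(sum(wahlund), 9)
  expect_error(nei_fis(genotype_table(ind[1:2, ], "L1",
                                      matrix(c(101L, 101L)),
                                      matrix(c(101L, 101L)))),
               "no heterozygosity")
})
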