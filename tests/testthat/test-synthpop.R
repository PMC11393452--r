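test_that("single-patch census identity: all adults parent the egg census", {
  cfg <- sim_config(n_patches = 1, extent = 100, adults_per_patch = 50,
                    sigma = 115, n_generations = 3, n_loci = 5, n_alleles = 6,
                    lambda_polyandry = 12, eggs_per_clutch = 30,
                    eggs_sampled_per_clutch = 30, max_clutches_sampled = 50)
  sim <- simulate_metapopulation(cfg, seed = 11)
  ped <- sim$truth$pedigree
  # every female breeds one clutch; with strong polyandry and a full egg
  # census every male sires: distinct parents = all 50 adults
  expect_equal(length(unique(ped$mother)), sum(sim$truth$adults$sex == "F"))
  expect_equal(length(unique(ped$father)), sum(sim$truth$adults$sex == "M"))
  expect_equal(length(unique(ped$mother)) + length(unique(ped$father)), 50)
  expect_true(all(c(ped$mother, ped$father) %in% sim$truth$adults$id))
})

test_that("panmixia limit: huge sigma leaves no distance-genetic correlation", {
  r <- vapply(1:6, function(s) {
    cfg <- sim_config(n_patches = 9, extent = 500, adults_per_patch = 30,
                      sigma = 1e6, n_generations = 8, n_loci = 8,
                      n_alleles = 6)
    sim <- simulate_metapopulation(cfg, seed = s)
    ds <- sim$dataset
    X <- dosage_matrix(ds$genotypes)
    X[is.na(X)] <- 0
    gd <- as.matrix(dist(X))
    j <- match(ds$genotypes$ind$patch_id, ds$patches$id)
    dd <- as.matrix(dist(cbind(ds$patches$x[j], ds$patches$y[j])))
    lt <- lower.tri(gd)
    cor(gd[lt], dd[lt])   # plain Mantel statistic
  }, numeric(1))
  expect_lt(mean(abs(r)), 0.05)
})

test_that("isolation by distance emerges: nearest distance class has positive Moran I", {
  pos <- vapply(1:10, function(s) {
    cfg <- sim_config(n_patches = 12, extent = 2000, adults_per_patch = 30,
                      sigma = 50, n_generations = 12, n_loci = 8, n_alleles = 6)
    sim <- simulate_metapopulation(cfg, seed = 100 + s)
    ac <- autocorrelogram(sim$dataset, n_perm = 1, seed = 1)
    ac$classes$mean_I[1] > 0
  }, logical(1))
  expect_gte(sum(pos), 9)
})

test_that("egg sampling respects caps and is seed-deterministic", {
  cfg <- sim_config(n_patches = 2, extent = 500, adults_per_patch = 160,
                    sigma = 115, n_generations = 2, n_loci = 4, n_alleles = 4)
  sim <- simulate_metapopulation(cfg, seed = 5)
  # ~80 clutches per patch, capped at 50 sampled
  expect_true(all(sim$dataset$patches$n_sampled <= 50))
  expect_true(any(sim$dataset$patches$n_counted > 50))
  s1 <- sample_eggs(sim, max_clutches = 10, eggs_per_clutch = 2, seed = 7)
  s2 <- sample_eggs(sim, max_clutches = 10, eggs_per_clutch = 2, seed = 7)
  expect_identical(s1$dataset$genotypes$ind$id, s2$dataset$genotypes$ind$id)
  s3 <- sample_eggs(sim, max_clutches = 10, eggs_per_clutch = 2, seed = 8)
  expect_false(identical(s1$dataset$genotypes$ind$id,
                         s3$dataset$genotypes$ind$id))
  # a patch with fewer clutches than the cap is sampled in full
  few <- sample_eggs(sim, max_clutches = 500, eggs_per_clutch = 2, seed = 1)
  expect_equal(few$dataset$patches$n_sampled, few$dataset$patches$n_counted)
  expect_error(sample_eggs(sim, eggs_per_clutch = 10, seed = 1),
               "exceeds clutch size")
})

test_that("artifact injection: identity at zero rates, nu^2 missing, chance at eps=1", {
  cfg <- sim_config(n_patches = 1, extent = 100, adults_per_patch = 60,
                    sigma = 115, n_generations = 2, n_loci = 6, n_alleles = 5,
                    eggs_sampled_per_clutch = 4)
  sim <- simulate_metapopulation(cfg, seed = 3)
  ds <- sim$dataset
  same <- inject_artifacts(ds, epsilon = 0, null_freq = 0, seed = 1)
  expect_identical(same$genotypes$a1, ds$genotypes$a1)
  expect_identical(same$genotypes$a2, ds$genotypes$a2)
  nulled <- inject_artifacts(ds, null_freq = 0.5, seed = 2)
  miss <- mean(is.na(nulled$genotypes$a1))
  n_calls <- length(ds$genotypes$a1)
  expect_lt(abs(miss - 0.25), 3 * sqrt(0.25 * 0.75 / n_calls) + 0.02)
  expect_error(inject_artifacts(ds, epsilon = 1.5), "rates")
})

test_that("allele frequencies drift without trend and patch truth is monotone in radius", {
  cfg <- sim_config(n_patches = 4, extent = 800, adults_per_patch = 40,
                    sigma = 200, n_generations = 6, n_loci = 6, n_alleles = 4,
                    init_freqs = replicate(6, rep(0.25, 4), simplify = FALSE))
  delta <- vapply(1:8, function(s) {
    sim <- simulate_metapopulation(cfg, seed = 200 + s)
    fr <- allele_freqs(sim$dataset$genotypes)
    mean(vapply(fr, function(f) {
      full <- rep(0, 4); full[as.integer(names(f)) - 100] <- f
      mean(full - 0.25)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(mean(delta)), 0.02)   # drift has no directional trend

  sim <- simulate_metapopulation(cfg, seed = 33)
  gt <- sim$dataset$genotypes
  ctr <- 1
  tp <- vapply(c(200, 400, 800, 1600), function(r) {
    mem <- sim$dataset$patches$id[
      sqrt((sim$dataset$patches$x - sim$dataset$patches$x[ctr])^2 +
             (sim$dataset$patches$y - sim$dataset$patches$y[ctr])^2) <= r]
    true_parent_count(sim$truth, gt$ind$id[gt$ind$patch_id %in% mem])
  }, numeric(1))
  expect_true(all(diff(tp) >= 0))
})

test_that("heterozygosity under single-patch panmixia matches Hardy-Weinberg", {
  cfg <- sim_config(n_patches = 1, extent = 50, adults_per_patch = 200,
                    sigma = 115, n_generations = 2, n_loci = 10, n_alleles = 6)
  sim <- simulate_metapopulation(cfg, seed = 17)
  gt <- sim$dataset$genotypes
  fr <- allele_freqs(gt)
  for (l in seq_along(gt$loci)) {
    hexp <- 1 - sum(fr[[l]]^2)
    hobs <- mean(gt$a1[, l] != gt$a2[, l], na.rm = TRUE)
    expect_lt(abs(hobs - hexp), 4 * sqrt(hexp * (1 - hexp) / nrow(gt$ind)))
  }
})
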