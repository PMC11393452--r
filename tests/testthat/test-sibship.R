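test_that("dyad likelihoods match hand-computed k-coefficient values", {
  ind <- data.frame(id = c("a", "b"), clutch_id = c("c1", "c2"),
                    patch_id = "p1", species = "target")
  gt <- genotype_table(ind, "L1", matrix(c(101L, 101L)), matrix(c(101L, 101L)))
  fr <- list(c("101" = 0.5, "102" = 0.5))
  d <- dyad_likelihood(gt, "a", "b", freqs = fr, epsilon = 0)
  # pair (AA, AA), p = 0.5: U = p^4; FS = 0.25 p^4 + 0.5 p^3 + 0.25 p^2
  expect_equal(unname(d$likelihood["U"]), 0.0625)
  expect_equal(unname(d$likelihood["FS"]), 0.140625)
  expect_equal(unname(d$likelihood["HS"]), 0.09375)
  expect_equal(unname(d$likelihood["FS"] / d$likelihood["U"]), 2.25)
  # eps = 1: data carry no information, posterior equals the prior
  d1 <- dyad_likelihood(gt, "a", "b", freqs = fr, epsilon = 1,
                        prior = c(FS = 0.2, HS = 0.3, U = 0.5))
  expect_equal(unname(d1$posterior), c(0.2, 0.3, 0.5))
})

test_that("identical multilocus genotypes at informative loci give posterior(FS) near 1", {
  set.seed(5)
  L <- 13
  calls <- matrix(sample(101:108, 2 * L, TRUE), 2, L)
  ind <- data.frame(id = c("a", "b"), clutch_id = c("c1", "c2"),
                    patch_id = "p1", species = "target")
  gt <- genotype_table(ind, sprintf("L%02d", 1:L),
                       rbind(calls[1, ], calls[1, ]),
                       rbind(calls[2, ], calls[2, ]))
  fr <- lapply(1:L, function(l) setNames(rep(1 / 8, 8), 101:108))
  d <- dyad_likelihood(gt, "a", "b", freqs = fr, epsilon = 0)
  expect_gt(d$posterior["FS"], 0.99)
  # no shared typed loci is an error
  gt2 <- gt; gt2$a1[1, ] <- NA_integer_; gt2$a2[1, ] <- NA_integer_
  gt2 <- genotype_table(gt2$ind, gt2$loci, gt2$a1, gt2$a2)
  expect_error(dyad_likelihood(gt2, "a", "b", freqs = fr), "no shared typed loci")
})

test_that("per-locus pair probability tables are coherent", {
  p <- c(0.5, 0.3, 0.2)
  tb <- spatNb:::pair_tables(p, 0)
  pg <- ifelse(tb$codes[, 1] == tb$codes[, 2], p[tb$codes[, 1]]^2,
               2 * p[tb$codes[, 1]] * p[tb$codes[, 2]])
  for (R in c("FS", "HS", "U")) {
    expect_equal(rowSums(tb[[R]]), pg, tolerance = 1e-12)   # marginals
    expect_true(isSymmetric(tb[[R]]))
  }
})

test_that("monandrous clutches yield the combinatorial Q_FS identity", {
  # C unrelated clutches, one father each, 2 eggs per clutch. Eggs of a
  # clutch are made genotypically identical so the full-sib call is
  # certain and only the dyad combinatorics are under test:
  # Q_FS = C / choose(2C, 2), Q_HS = 0.
  set.seed(6)
  C <- 12; L <- 13; K <- 8
  a1 <- a2 <- matrix(NA_integer_, 2 * C, L)
  for (cc in seq_len(C)) {
    g1 <- sample(101:(100 + K), L, TRUE); g2 <- sample(101:(100 + K), L, TRUE)
    for (e in 1:2) {
      a1[2 * (cc - 1) + e, ] <- pmin(g1, g2)
      a2[2 * (cc - 1) + e, ] <- pmax(g1, g2)
    }
  }
  ind <- data.frame(id = sprintf("e%02d", 1:(2 * C)),
                    clutch_id = sprintf("c%02d", rep(1:C, each = 2)),
                    patch_id = "p1", species = "target")
  gt <- genotype_table(ind, sprintf("L%02d", 1:L), a1, a2)
  fr <- lapply(1:L, function(l) setNames(rep(1 / K, K), 101:(100 + K)))
  sib <- reconstruct_families(gt, threshold = 0.9, freqs = fr)
  expect_equal(sib$Nf, C)
  expect_equal(sib$Q_FS, C / choose(2 * C, 2), tolerance = 1e-12)
  expect_equal(sib$Q_HS, 0)
  expect_equal(sib$Nm, C)
  # threshold 1.0 admits no full-sib pairs at all
  sib1 <- reconstruct_families(gt, threshold = 1.0, freqs = fr)
  expect_equal(sib1$Q_FS, 0)
  expect_equal(sib1$Nm, 2 * C)
})

test_that("sibship Nb closed form: alpha = 0 random mating reduces to 4NmNf/(Nm+Nf)", {
  for (Nm in c(2:50, seq(60, 500, by = 20))) for (Nf in c(2, 17, 100, 500)) {
    q_fs <- 1 / (Nm * Nf)
    q_hs <- 1 / Nm + 1 / Nf - 2 / (Nm * Nf)
    expect_equal(sibship_nb(q_hs, q_fs), 4 * Nm * Nf / (Nm + Nf),
                 tolerance = 1e-10)
  }
  expect_equal(sibship_nb(0, 0), Inf)
  # alpha term: 1/Nb = 1.3/4 * 0.04 - 0.05 * (2/50) = 0.011
  expect_equal(sibship_nb(0.02, 0.01, alpha = 0.1, Nm = 50, Nf = 50),
               1 / 0.011, tolerance = 1e-10)
  expect_error(sibship_nb(0.02, 0.01, alpha = 0.1), "Nm and Nf")
  expect_error(sibship_nb(0.9, 0.2), "dyad frequencies")
})

test_that("parent counts and sex ratio summaries behave", {
  mk <- function(Nf, Nm) structure(list(Nf = Nf, Nm = Nm, Np = Nf + Nm),
                                   class = "sibship_result")
  r <- estimate_parents_and_sexratio(list(mk(10, 11)))
  expect_equal(r$female_fraction, 10 / 21, tolerance = 1e-12)
  r2 <- estimate_parents_and_sexratio(list(mk(5, 5), mk(20, 20)))
  expect_equal(r2$female_fraction, 0.5)
  expect_equal(unname(r2$np), c(10, 40))
  # strong polyandry forces the ratio below one half
  expect_lt(estimate_parents_and_sexratio(list(mk(10, 30)))$female_fraction, 0.5)
  expect_error(estimate_parents_and_sexratio(list()), ">= 1 window")
})

test_that("sibship Nb tracks sample size across windows on simulated data", {
  cfg <- sim_config(n_patches = 9, extent = 1200, adults_per_patch = 40,
                    sigma = 200, n_generations = 8, n_loci = 13, n_alleles = 8)
  sim <- simulate_metapopulation(cfg, seed = 14)
  ds <- sim$dataset
  gt <- ds$genotypes
  ctr <- which.min((ds$patches$x - mean(ds$patches$x))^2 +
                     (ds$patches$y - mean(ds$patches$y))^2)
  res <- t(vapply(c(300, 600, 900, 1600), function(r) {
    mem <- ds$patches$id[sqrt((ds$patches$x - ds$patches$x[ctr])^2 +
                                (ds$patches$y - ds$patches$y[ctr])^2) <= r]
    ri <- which(gt$ind$patch_id %in% mem)
    sib <- reconstruct_families(subset_genotypes(gt, individuals = ri))
    c(n = length(ri), nb = sibship_nb(sib$Q_HS, sib$Q_FS))
  }, numeric(2)))
  res <- res[!duplicated(res[, "n"]), , drop = FALSE]   # identical windows
  expect_gte(nrow(res), 3)
  expect_true(all(diff(res[, "n"]) > 0))
  expect_gt(cor(res[, "n"], res[, "nb"], method = "spearman"), 0.9)
})

test_that("clutch bootstrap CI brackets the point estimate", {
  cfg <- sim_config(n_patches = 1, extent = 100, adults_per_patch = 50,
                    sigma = 115, n_generations = 5, n_loci = 13, n_alleles = 8)
  sim <- simulate_metapopulation(cfg, seed = 8)
  sib <- reconstruct_families(sim$dataset)
  est <- sibship_nb_estimate(sib, n_boot = 200, seed = 1)
  expect_true(est$ci_low <= est$nb_point)
  expect_true(est$ci_high >= est$nb_point)
  expect_gt(est$ci_low, 0)
})
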