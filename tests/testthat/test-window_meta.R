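test_that("build_windows reproduces the collinear hand enumeration and dedups", {
  patches <- data.frame(id = c("A", "B", "C"), x = c(0, 250, 600), y = 0,
                        n_counted = 5L, n_sampled = 2L, pct_target = 1)
  w <- build_windows(patches, radii = seq(100, 600, by = 100))
  sets <- lapply(w$patch_ids, paste, collapse = "")
  expect_equal(nrow(w), 6)
  expect_setequal(unlist(sets), c("A", "B", "C", "AB", "ABC", "BC"))
  # smallest radius retained; ties keep the lexicographically first focal
  ab <- w[sapply(w$patch_ids, function(s) identical(s, c("A", "B"))), ]
  expect_equal(ab$radius, 300)
  expect_equal(ab$focal, "A")
  abc <- w[sapply(w$patch_ids, function(s) identical(s, c("A", "B", "C"))), ]
  expect_equal(abc$radius, 400)   # via focal B; the full window deduplicated
  # idempotence
  expect_identical(build_windows(patches, radii = seq(100, 600, by = 100)), w)
  # single patch: one unique window (full window is a duplicate)
  w1 <- build_windows(patches[1, ], radii = c(100, 200))
  expect_equal(nrow(w1), 1)
  expect_error(build_windows(patches[0, ]), "no patches")
})

test_that("window membership is monotone in radius per focal patch", {
  set.seed(3)
  patches <- data.frame(id = sprintf("P%02d", 1:8), x = runif(8, 0, 1500),
                        y = runif(8, 0, 1500), n_counted = 10L,
                        n_sampled = 5L, pct_target = 1)
  D <- as.matrix(dist(cbind(patches$x, patches$y)))
  for (f in 1:8) {
    sets <- lapply(c(200, 500, 900, 1400), function(r)
      patches$id[D[f, ] <= r])
    for (i in 1:3) expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("potential breeding adults from clutch counts and sex ratio", {
  p <- data.frame(id = "02", x = 0, y = 0, n_counted = 70, n_sampled = 31,
                  pct_target = 0.10)
  expect_equal(estimate_na(p, female_fraction = 0.48), 7 / 0.48,
               tolerance = 1e-12)   # ~14.6 adults
  p$pct_target <- 0
  expect_equal(estimate_na(p, 0.48), 0)
  p2 <- data.frame(id = c("a", "b"), x = 0, y = 0, n_counted = c(30, 20),
                   n_sampled = 5, pct_target = 1)
  expect_equal(estimate_na(p2, 0.5), 100)
  expect_error(estimate_na(p2, 0), "female_fraction")
  p2$n_counted[1] <- NA
  expect_true(is.na(estimate_na(p2, 0.5)))
})

test_that("meta-Nb estimators: island correction, degenerate modes, survey values", {
  t1 <- read.csv(survey_path())
  locals <- t1$ld_nb[is.finite(t1$ld_nb)]
  isl <- meta_nb(locals, fst = 0.0162, mode = "island")
  expect_equal(isl$value, sum(locals) / (1 - 0.0162), tolerance = 1e-12)
  expect_equal(isl$value, 688, tolerance = 0.5)
  expect_equal(meta_nb(locals, fst = 0, mode = "island")$value,
               meta_nb(locals, mode = "sum_local")$value)
  expect_equal(meta_nb(150, k = 4, mode = "extrapolation")$value, 600)
  expect_error(meta_nb(locals, fst = 1, mode = "island"), "fst")
  expect_error(meta_nb(c(100, 200), k = 4, mode = "extrapolation"),
               "exactly one")
  # island exceeds the plain sum whenever fst > 0
  expect_gt(meta_nb(locals, fst = 0.01, mode = "island")$value,
            meta_nb(locals, mode = "sum_local")$value)
})

test_that("neighbourhood size and breeding window follow the closed forms", {
  expect_equal(neighbourhood_size(0, 1), 0)
  expect_equal(neighbourhood_size(100, 0.005), 4 * pi * 100^2 * 0.005,
               tolerance = 1e-12)               # ~628.3
  expect_equal(neighbourhood_size(200, 1) / neighbourhood_size(100, 1), 4)
  expect_error(neighbourhood_size(-1, 1), "must be")
  ac <- structure(list(zero_crossing = 460, first_class_positive = TRUE),
                  class = "autocorrelogram")
  bw <- breeding_window_from_autocorr(ac)
  expect_equal(bw$radius, 230)
  ac$first_class_positive <- FALSE
  expect_error(breeding_window_from_autocorr(ac), "no positive autocorrelation")
  ac$first_class_positive <- TRUE; ac$zero_crossing <- NA_real_
  expect_error(breeding_window_from_autocorr(ac), "never crosses")
})

test_that("window profile: purity, skip reasons, identical sets identical estimates", {
  cfg <- sim_config(n_patches = 4, extent = 600, adults_per_patch = 40,
                    sigma = 150, n_generations = 5, n_loci = 8, n_alleles = 6)
  sim <- simulate_metapopulation(cfg, seed = 31)
  ds <- sim$dataset
  w <- build_windows(ds$patches, radii = c(200, 700))
  prof <- window_profile(ds, w, female_fraction = 0.5, min_ind = 6)
  expect_equal(nrow(prof), nrow(w))
  full_rows <- which(vapply(w$patch_ids, length, integer(1)) == 4)
  if (length(full_rows) >= 1) {
    # same individual set -> same estimate regardless of window identity
    p2 <- window_profile(ds, w[c(full_rows[1], full_rows[1]), ],
                         female_fraction = 0.5)
    expect_equal(p2$ld_nb[1], p2$ld_nb[2])
    expect_equal(p2$sib_nb[1], p2$sib_nb[2])
  }
  # a starving window is skipped with a reason
  tiny <- w[1, ]; tiny$patch_ids <- list(character(0))
  expect_match(window_profile(ds, tiny, 0.5)$skipped, "fewer than")
})

test_that("random breeding-window sampling is deterministic and counts non-finite", {
  cfg <- sim_config(n_patches = 9, extent = 900, adults_per_patch = 60,
                    sigma = 150, n_generations = 5, n_loci = 10, n_alleles = 6)
  sim <- simulate_metapopulation(cfg, seed = 41)
  r1 <- random_window_sampling(sim$dataset, radius = 300, n_samples = 40,
                               n_buffers = 3, n_reps = 2, seed = 5)
  r2 <- random_window_sampling(sim$dataset, radius = 300, n_samples = 40,
                               n_buffers = 3, n_reps = 2, seed = 5)
  expect_identical(r1$estimates, r2$estimates)
  expect_equal(nrow(r1$estimates), 6)
  expect_true(all(r1$buffers$n_patches >= 2))
  expect_true(all(r1$buffers$n_ind >= 40))
  expect_true(r1$summary$frac_nonfinite >= 0 && r1$summary$frac_nonfinite <= 1)
  expect_error(random_window_sampling(sim$dataset, radius = 1,
                                      n_samples = 40, seed = 1, max_tries = 50),
               "qualifying buffers")
  expect_gte(default_k_neighbourhoods(sim$dataset$patches, 230), 1)
})
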