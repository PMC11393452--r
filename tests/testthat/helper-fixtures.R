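# Shared fixtures and independent oracles, all built in code.

# small genotype table: n individuals, L loci, K alleles, one patch per
# `patches` split, clutches of `clutch_size`
toy_table <- function(n = 12, L = 3, K = 4, patches = 2, clutch_size = 2,
                      seed = 1) {
  set.seed(seed)
  ind <- data.frame(
    id = sprintf("i%03d", seq_len(n)),
    clutch_id = sprintf("c%03d", ceiling(seq_len(n) / clutch_size)),
    patch_id = sprintf("p%d", rep(seq_len(patches),
      each = ceiling(ceiling(n / clutch_size) / patches))[
        ceiling(seq_len(n) / clutch_size)]),
    species = "target", stringsAsFactors = FALSE)
  a1 <- matrix(sample(100L + seq_len(K), n * L, TRUE), n, L)
  a2 <- matrix(sample(100L + seq_len(K), n * L, TRUE), n, L)
  genotype_table(ind, sprintf("L%02d", seq_len(L)), a1, a2)
}

toy_dataset <- function(gt, coords = NULL) {
  ids <- unique(gt$ind$patch_id)
  if (is.null(coords)) {
    set.seed(42)
    coords <- cbind(runif(length(ids), 0, 1000), runif(length(ids), 0, 1000))
  }
  structure(list(
    genotypes = gt,
    patches = data.frame(id = ids, x = coords[, 1], y = coords[, 2],
                         n_counted = 10L, n_sampled = 5L, pct_target = 1,
                         stringsAsFactors = FALSE),
    provenance = list()), class = "nb_dataset")
}

# --- independent HWE oracle: enumerate all perfect matchings ------------
# of the allele multiset into unordered pairs; p-value = probability mass
# of tables whose matching count is <= that of the observed table.
hwe_oracle <- function(a1, a2) {
  alleles <- c(a1, a2)
  n <- length(a1)
  tab_key <- function(g1, g2) paste(sort(paste(pmin(g1, g2), pmax(g1, g2))),
                                    collapse = "/")
  counts <- new.env()
  match_rec <- function(pool) {
    if (!length(pool)) return(list(character(0)))
    first <- pool[1]
    out <- list()
    rest <- pool[-1]
    for (m in seq_along(rest)) {
      # avoid double counting identical partners: pair "first" with each
      # *position*; matchings are over labelled gene copies
      sub <- match_rec(rest[-m])
      pr <- paste(min(first, rest[m]), max(first, rest[m]))
      for (s in sub) out[[length(out) + 1L]] <- c(pr, s)
    }
    out
  }
  all_m <- match_rec(alleles)
  keys <- vapply(all_m, function(m) paste(sort(m), collapse = "/"), character(1))
  tab <- table(keys)
  probs <- as.numeric(tab) / length(all_m)
  obs_key <- tab_key(a1, a2)
  obs_p <- probs[match(obs_key, names(tab))]
  sum(probs[probs <= obs_p + 1e-12])
}

# --- independent Weir-Cockerham oracle: ANOVA mean squares --------------
theta_oracle <- function(gt, patches) {
  num <- den <- 0
  for (l in seq_along(gt$loci)) {
    al <- sort(unique(stats::na.omit(c(gt$a1[, l], gt$a2[, l]))))
    for (A in al) {
      pij <- ((gt$a1[, l] == A) + (gt$a2[, l] == A)) / 2
      ok <- !is.na(pij)
      pop <- gt$ind$patch_id
      ni <- tapply(ok, pop, sum)[patches]
      ntot <- sum(ni); r <- length(patches)
      if (any(ni < 2)) next
      pbar_i <- tapply(pij[ok], pop[ok], mean)[patches]
      pbar <- sum(ni * pbar_i) / ntot
      SSP <- sum(2 * ni * (pbar_i - pbar)^2)
      SSI <- sum(vapply(patches, function(p) {
        v <- pij[ok & pop == p]; sum(2 * (v - mean(v))^2)
      }, numeric(1)))
      SSG <- 0.5 * sum(pij[ok] == 0.5)
      MSP <- SSP / (r - 1); MSI <- SSI / (ntot - r); MSG <- SSG / ntot
      nc <- (ntot - sum(ni^2) / ntot) / (r - 1)
      sP <- (MSP - MSI) / (2 * nc)
      num <- num + sP
      den <- den + sP + (MSI - MSG) / 2 + MSG
    }
  }
  num / den
}

# pedigree-true dyad-frequency Nb of a sampled cohort
pedigree_dyad_nb <- function(ped) {
  n <- nrow(ped)
  sm <- sum(choose(table(ped$mother), 2))
  sf <- sum(choose(table(ped$father), 2))
  4 / ((sm + sf) / (n * (n - 1) / 2))
}

# the acceptance scenario for single-window parameter recovery: one
# panmictic patch whose ~50 adults all parent the 100 sampled offspring
panmictic50_config <- function() {
  sim_config(n_patches = 1, extent = 100, adults_per_patch = 70, sigma = 115,
             n_generations = 20, n_loci = 13, n_alleles = 8,
             eggs_per_clutch = 6, lambda_polyandry = 2,
             max_clutches_sampled = 25, eggs_sampled_per_clutch = 4)
}

# small isolated deme for Wahlund / pooling experiments
deme_genotypes <- function(seed, n_gen = 25) {
  cfg <- sim_config(n_patches = 1, extent = 100, adults_per_patch = 50,
                    sigma = 115, n_generations = n_gen, n_loci = 13,
                    n_alleles = 8)
  simulate_metapopulation(cfg, seed = seed)$dataset$genotypes
}

# pool two genotype tables as two patches of one population
pool_tables <- function(g1, g2) {
  g2$ind$patch_id <- "pB"
  g1$ind$patch_id <- "pA"
  g2$ind$id <- paste0("b_", g2$ind$id)
  g2$ind$clutch_id <- paste0("b_", g2$ind$clutch_id)
  genotype_table(rbind(g1$ind, g2$ind), g1$loci,
                 rbind(g1$a1, g2$a1), rbind(g1$a2, g2$a2))
}

survey_path <- function() {
  system.file("extdata", "moorfrog_patch_survey.csv", package = "spatNb")
}
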