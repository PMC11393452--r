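#' Configuration for the spatial metapopulation simulator
#'
#' Defaults emulate a pond-breeding amphibian metapopulation sampled as an
#' egg cohort: ~25 breeding patches scattered over a ~2 km extent, weak
#' global differentiation with isolation-by-distance, one clutch per
#' female per season, occasional multiple paternity, and a sampling scheme
#' of at most 50 clutches per patch with 2 genotyped eggs per clutch.
#'
#' @param n_patches number of breeding patches.
#' @param extent side (metres) of the square study area.
#' @param patch_xy optional matrix/data.frame of patch coordinates
#'   (metres); random uniform within the extent when `NULL`.
#' @param adults_per_patch carrying capacity (adults) of each patch.
#' @param sigma axial parent-offspring dispersal SD in metres; also the
#'   scale of the Gaussian mating kernel.
#' @param n_generations burn-in generations before the sampled season.
#' @param n_loci,n_alleles microsatellite panel size.
#' @param init_freqs optional list of per-locus allele-frequency vectors;
#'   drawn from a flat Dirichlet when `NULL`.
#' @param lambda_polyandry fathers per clutch are `1 + Poisson(lambda)`.
#' @param eggs_per_clutch eggs laid per clutch (before survival).
#' @param max_clutches_sampled,eggs_sampled_per_clutch sampling scheme.
#' @param pct_target probability that a clutch belongs to the target
#'   species (non-target clutches are labels only, never genotyped).
#' @param epsilon,null_freq genotyping artifact rates applied by
#'   [inject_artifacts()] when non-zero.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patches = 25, extent = 2000, patch_xy = NULL,
                       adults_per_patch = 160, sigma = 115,
                       n_generations = 20, n_loci = 13, n_alleles = 8,
                       init_freqs = NULL, lambda_polyandry = 0.5,
                       eggs_per_clutch = 6,
                       max_clutches_sampled = 50, eggs_sampled_per_clutch = 2,
                       pct_target = 1, epsilon = 0, null_freq = 0) {
  stopifnot(sigma > 0, n_patches >= 1, adults_per_patch >= 2,
            eggs_per_clutch >= eggs_sampled_per_clutch,
            lambda_polyandry >= 0, n_loci >= 1, n_alleles >= 2)
  if (any(c(pct_target, epsilon, null_freq) < 0) ||
      any(c(pct_target, epsilon, null_freq) > 1))
    stop_spat("pct_target, epsilon and null_freq must lie in [0,1]")
  structure(as.list(environment()), class = "sim_config")
}

# draw a Dirichlet(1,...,1) frequency vector
rdirichlet1 <- function(k) { g <- stats::rexp(k); g / sum(g) }

nearest_patch <- function(x, y, patches) {
  d <- dist_xy(x, y, patches$x, patches$y)
  max.col(-d, ties.method = "first")
}

#' Simulate a spatially structured metapopulation with known truth
#'
#' Forward-time, discrete non-overlapping generations. Each season every
#' female breeds at the patch nearest to her location; she mates with
#' `1 + Poisson(lambda)` males drawn with probability proportional to the
#' Gaussian kernel `exp(-d^2 / (2 sigma^2))` of the male's distance to her
#' breeding patch; offspring are placed at the mother's patch plus a
#' bivariate Gaussian(0, sigma^2 I) displacement; local carrying capacities
#' keep total size roughly constant through random survival. After the
#' burn-in, one egg cohort is laid with full pedigree bookkeeping and
#' sampled per the configured scheme (see [sample_eggs()]).
#'
#' @param config a [sim_config()].
#' @param seed integer seed; every random draw flows from it.
#' @return A list of class `sim_metapop` with elements `dataset` (an
#'   `nb_dataset` of the sampled eggs), `truth` (pedigree, per-patch
#'   parent counts, sigma, density, adult roster), `census` (the full
#'   final-season egg cohort) and `patches`.
#' @export
simulate_metapopulation <- function(config, seed) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(seed, "simulate"), {
    cf <- config
    patches <- if (is.null(cf$patch_xy)) {
      data.frame(id = sprintf("P%02d", seq_len(cf$n_patches)),
                 x = stats::runif(cf$n_patches, 0, cf$extent),
                 y = stats::runif(cf$n_patches, 0, cf$extent))
    } else {
      data.frame(id = sprintf("P%02d", seq_len(nrow(cf$patch_xy))),
                 x = cf$patch_xy[, 1], y = cf$patch_xy[, 2])
    }
    np <- nrow(patches)
    freqs <- cf$init_freqs %||% replicate(cf$n_loci, rdirichlet1(cf$n_alleles),
                                          simplify = FALSE)
    loci <- sprintf("L%02d", seq_len(cf$n_loci))

    # initial adults: capacity per patch, alleles iid from init freqs
    N0 <- np * cf$adults_per_patch
    draw_alleles <- function(n) {
      m <- matrix(NA_integer_, n, cf$n_loci)
      for (l in seq_len(cf$n_loci)) {
        k <- length(freqs[[l]])
        m[, l] <- sample.int(k, n, replace = TRUE, prob = freqs[[l]]) + 100L
      }
      m
    }
    ad <- list(
      x = rep(patches$x, each = cf$adults_per_patch),
      y = rep(patches$y, each = cf$adults_per_patch),
      sex = rep(rep(c("F", "M"), length.out = cf$adults_per_patch), np),
      a1 = draw_alleles(N0), a2 = draw_alleles(N0),
      id = sprintf("A0_%05d", seq_len(N0))
    )

    breed <- function(ad, gen_tag) {
      fem <- which(ad$sex == "F"); mal <- which(ad$sex == "M")
      if (!length(fem) || !length(mal))
        stop_spat("population lost one sex entirely; increase adults_per_patch")
      bp <- nearest_patch(ad$x[fem], ad$y[fem], patches)
      # Gaussian mating kernel: male distance to the female's breeding patch
      dk <- dist_xy(patches$x[bp], patches$y[bp], ad$x[mal], ad$y[mal])
      wk <- exp(-dk^2 / (2 * cf$sigma^2)) + 1e-12
      n_fathers <- 1L + stats::rpois(length(fem), cf$lambda_polyandry)
      n_fathers <- pmin(n_fathers, length(mal))
      clutch_fathers <- lapply(seq_along(fem), function(i)
        mal[sample.int(length(mal), n_fathers[i], prob = wk[i, ])])
      ne <- cf$eggs_per_clutch
      n_eggs <- length(fem) * ne
      egg_mother <- rep(fem, each = ne)
      egg_clutch <- rep(seq_along(fem), each = ne)
      egg_father <- unlist(lapply(clutch_fathers, function(f)
        f[sample.int(length(f), ne, replace = TRUE)]))
      # Mendelian inheritance, vectorized over eggs x loci
      pick <- function(par_idx) {
        u <- matrix(stats::runif(n_eggs * cf$n_loci), n_eggs)
        ifelse(u < 0.5, ad$a1[par_idx, , drop = FALSE],
               ad$a2[par_idx, , drop = FALSE])
      }
      list(mother = ad$id[egg_mother], father = ad$id[egg_father],
           mother_idx = egg_mother, father_idx = egg_father,
           clutch = egg_clutch, clutch_patch = bp[egg_clutch],
           x = patches$x[bp[egg_clutch]] + stats::rnorm(n_eggs, 0, cf$sigma),
           y = patches$y[bp[egg_clutch]] + stats::rnorm(n_eggs, 0, cf$sigma),
           a1 = pick(egg_mother), a2 = pick(egg_father),
           id = sprintf("%s_%06d", gen_tag, seq_len(n_eggs)),
           n_clutches = length(fem), clutch_mother = ad$id[fem],
           clutch_patch_of = bp)
    }

    for (g in seq_len(cf$n_generations)) {
      eggs <- breed(ad, sprintf("G%d", g))
      # density regulation: per-patch survival to carrying capacity
      ep <- nearest_patch(eggs$x, eggs$y, patches)
      keep <- unlist(lapply(seq_len(np), function(p) {
        at <- which(ep == p)
        if (length(at) <= cf$adults_per_patch) at
        else at[sample.int(length(at), cf$adults_per_patch)]
      }))
      ad <- list(x = eggs$x[keep], y = eggs$y[keep],
                 sex = sample(c("F", "M"), length(keep), replace = TRUE),
                 a1 = eggs$a1[keep, , drop = FALSE],
                 a2 = eggs$a2[keep, , drop = FALSE],
                 id = eggs$id[keep])
    }

    census <- breed(ad, "EGG")
    sim <- structure(list(config = cf, patches = patches, adults = ad,
                          census = census, loci = loci,
                          density = length(ad$id) / cf$extent^2,
                          seed = seed),
                     class = "sim_metapop")
    out <- sample_eggs(sim, max_clutches = cf$max_clutches_sampled,
                       eggs_per_clutch = cf$eggs_sampled_per_clutch,
                       seed = derive_seed(seed, "sample"))
    sim$dataset <- out$dataset
    sim$truth <- out$truth
    sim
  })
}

#' Sample egg clutches from a simulated cohort
#'
#' Draws a uniform random subset of at most `max_clutches` clutches per
#' patch and a fixed number of eggs per sampled clutch, mirroring a field
#' protocol that caps clutch sampling per breeding patch. Clutches are
#' labelled target / non-target species with the configured probability;
#' non-target clutches are counted but never genotyped.
#'
#' @param sim a `sim_metapop` from [simulate_metapopulation()].
#' @param max_clutches cap on sampled clutches per patch.
#' @param eggs_per_clutch genotyped eggs per sampled clutch.
#' @param seed integer seed.
#' @return list with `dataset` (class `nb_dataset`) and `truth` (class
#'   `sim_truth`: pedigree of sampled eggs, per-patch `Nm`, `Nf`, `Np`,
#'   `sigma`, realized adult density, adult roster and clutch species
#'   labels).
#' @export
sample_eggs <- function(sim, max_clutches = 50, eggs_per_clutch = 2, seed) {
  stopifnot(inherits(sim, "sim_metapop"))
  cf <- sim$config
  ce <- sim$census
  if (eggs_per_clutch > cf$eggs_per_clutch)
    stop_spat("eggs_per_clutch exceeds clutch size (%d)", cf$eggs_per_clutch)
  with_seed(derive_seed(seed, "eggsample"), {
    n_clutch <- ce$n_clutches
    clutch_patch <- ce$clutch_patch_of
    species <- ifelse(stats::runif(n_clutch) < cf$pct_target, "target", "non_target")
    rows <- list(); sampled_clutches <- integer(0)
    for (p in seq_len(nrow(sim$patches))) {
      cl <- which(clutch_patch == p)
      if (!length(cl)) next
      if (length(cl) > max_clutches)
        cl <- cl[sample.int(length(cl), max_clutches)]
      sampled_clutches <- c(sampled_clutches, cl)
      for (cc in cl[species[cl] == "target"]) {
        eg <- which(ce$clutch == cc)
        eg <- eg[sample.int(length(eg), eggs_per_clutch)]
        rows[[length(rows) + 1L]] <- eg
      }
    }
    eg <- unlist(rows)
    patch_tab <- data.frame(
      id = sim$patches$id, x = sim$patches$x, y = sim$patches$y,
      n_counted = as.integer(tabulate(clutch_patch, nrow(sim$patches))),
      n_sampled = as.integer(tabulate(clutch_patch[sampled_clutches],
                                      nrow(sim$patches))),
      pct_target = NA_real_, stringsAsFactors = FALSE)
    st <- tapply(species[sampled_clutches] == "target",
                 clutch_patch[sampled_clutches], mean)
    patch_tab$pct_target[as.integer(names(st))] <- as.numeric(st)
    patch_tab$pct_target[is.na(patch_tab$pct_target)] <- 0

    if (!length(eg)) warning("no target-species clutches sampled")
    ind <- data.frame(
      id = ce$id[eg],
      clutch_id = sprintf("C%05d", ce$clutch[eg]),
      patch_id = sim$patches$id[ce$clutch_patch[eg]],
      species = "target", stringsAsFactors = FALSE)
    gt <- genotype_table(ind, sim$loci,
                         ce$a1[eg, , drop = FALSE], ce$a2[eg, , drop = FALSE])
    ds <- structure(list(genotypes = gt, patches = patch_tab,
                         provenance = list(simulated = TRUE, seed = sim$seed)),
                    class = "nb_dataset")
    ped <- data.frame(id = ce$id[eg], mother = ce$mother[eg],
                      father = ce$father[eg],
                      clutch_id = sprintf("C%05d", ce$clutch[eg]),
                      patch_id = sim$patches$id[ce$clutch_patch[eg]],
                      stringsAsFactors = FALSE)
    per_patch <- do.call(rbind, lapply(split(ped, ped$patch_id), function(d)
      data.frame(patch_id = d$patch_id[1],
                 Nf = length(unique(d$mother)),
                 Nm = length(unique(d$father)),
                 Np = length(unique(d$mother)) + length(unique(d$father)))))
    truth <- structure(list(pedigree = ped, per_patch = per_patch,
                            sigma = cf$sigma, density = sim$density,
                            adults = data.frame(id = sim$adults$id,
                                                x = sim$adults$x,
                                                y = sim$adults$y,
                                                sex = sim$adults$sex),
                            clutch_species = species),
                       class = "sim_truth")
    list(dataset = ds, truth = truth)
  })
}

#' Count true parents of the sampled eggs inside a window
#'
#' @param truth a `sim_truth`.
#' @param individual_ids ids of sampled eggs in the window.
#' @return number of distinct true parents (mothers + fathers).
#' @export
true_parent_count <- function(truth, individual_ids) {
  d <- truth$pedigree[truth$pedigree$id %in% individual_ids, ]
  length(unique(d$mother)) + length(unique(d$father))
}

#' Inject genotyping artifacts into a dataset
#'
#' Two artifact processes: (i) with probability `epsilon` a call is
#' replaced by a random genotype drawn from its patch's allele
#' frequencies; (ii) each allele copy is independently replaced by a null
#' (non-amplifying) allele with probability `null_freq`, so a
#' null/visible heterozygote is scored as a visible homozygote and a
#' null/null genotype as missing.
#'
#' @param dataset an `nb_dataset`.
#' @param epsilon per-call mistyping rate.
#' @param null_freq per-locus null-allele frequency (scalar or one value
#'   per locus).
#' @param seed integer seed.
#' @return The dataset with perturbed genotype calls.
#' @export
inject_artifacts <- function(dataset, epsilon = 0, null_freq = 0, seed = 1) {
  stopifnot(inherits(dataset, "nb_dataset"))
  if (any(c(epsilon, null_freq) < 0) || any(c(epsilon, null_freq) > 1))
    stop_spat("rates must lie in [0,1]")
  gt <- dataset$genotypes
  L <- length(gt$loci)
  nu <- rep(null_freq, length.out = L)
  with_seed(derive_seed(seed, "artifacts"), {
    if (epsilon > 0) {
      for (p in unique(gt$ind$patch_id)) {
        ri <- which(gt$ind$patch_id == p)
        fr <- allele_freqs(subset_genotypes(gt, individuals = ri))
        for (l in seq_len(L)) {
          if (!length(fr[[l]])) next
          hit <- ri[stats::runif(length(ri)) < epsilon]
          if (!length(hit)) next
          al <- as.integer(names(fr[[l]]))
          g1 <- al[sample.int(length(al), length(hit), TRUE, prob = fr[[l]])]
          g2 <- al[sample.int(length(al), length(hit), TRUE, prob = fr[[l]])]
          gt$a1[hit, l] <- pmin(g1, g2); gt$a2[hit, l] <- pmax(g1, g2)
        }
      }
    }
    if (any(nu > 0)) {
      for (l in seq_len(L)) {
        if (nu[l] == 0) next
        n1 <- stats::runif(nrow(gt$a1)) < nu[l]
        n2 <- stats::runif(nrow(gt$a1)) < nu[l]
        both <- n1 & n2 & !is.na(gt$a1[, l])
        one1 <- n1 & !n2 & !is.na(gt$a1[, l])
        one2 <- n2 & !n1 & !is.na(gt$a1[, l])
        gt$a1[one1, l] <- gt$a2[one1, l]      # surviving copy looks homozygous
        gt$a2[one2, l] <- gt$a1[one2, l]
        gt$a1[both, l] <- NA_integer_; gt$a2[both, l] <- NA_integer_
      }
    }
  })
  dataset$genotypes <- genotype_table(gt$ind, gt$loci, gt$a1, gt$a2)
  dataset
}
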