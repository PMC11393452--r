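# Sibship reconstruction from pairwise likelihoods and the dyad-frequency
# estimator of the effective number of breeders. Full-likelihood
# partition annealing is deliberately not used: with two eggs per clutch
# and known maternity the pairwise information is nearly sufficient, and
# a pairwise classifier with graph clustering is transparent and fast.

# ---- per-locus genotype-pair probability tables -------------------------

# genotype codes at one locus: unordered pairs (i <= j) of allele indices
geno_codes <- function(k) {
  g <- which(upper.tri(matrix(0, k, k), diag = TRUE), arr.ind = TRUE)
  g[order(g[, "row"], g[, "col"]), , drop = FALSE]
}

# P(G1, G2 | R) tables for R = FS, HS, U at one locus with freqs p,
# mixed with the mistyping rate eps (a mistyped call is a random
# Hardy-Weinberg genotype, independent of the pedigree).
pair_tables <- function(p, eps) {
  k <- length(p)
  g <- geno_codes(k)
  ng <- nrow(g)
  pg <- ifelse(g[, 1] == g[, 2], p[g[, 1]]^2, 2 * p[g[, 1]] * p[g[, 2]])
  # T[g1, g2]: probability of G2 given it shares exactly one IBD allele
  # drawn uniformly from G1's two gene copies
  cond <- function(s, g2) {       # P(G2 | shared allele index s)
    x <- g[g2, 1]; y <- g[g2, 2]
    ifelse(x == s & y == s, p[s], ifelse(x == s, p[y], ifelse(y == s, p[x], 0)))
  }
  Tm <- matrix(0, ng, ng)
  for (g1 in seq_len(ng)) {
    a <- g[g1, 1]; b <- g[g1, 2]
    Tm[g1, ] <- if (a == b) cond(a, seq_len(ng))
                else 0.5 * (cond(a, seq_len(ng)) + cond(b, seq_len(ng)))
  }
  PU <- outer(pg, pg)
  ident <- diag(ng)
  PFS <- 0.25 * PU + 0.5 * pg * Tm + 0.25 * pg * ident
  PHS <- 0.5 * PU + 0.5 * pg * Tm
  w <- (1 - eps)^2
  list(FS = w * PFS + (1 - w) * PU,
       HS = w * PHS + (1 - w) * PU,
       U = PU, codes = g)
}

# map calls at locus l to genotype codes (NA for missing)
code_calls <- function(gt, l, alleles) {
  i <- match(gt$a1[, l], alleles); j <- match(gt$a2[, l], alleles)
  k <- length(alleles)
  # index of unordered pair (i,j), i<=j, in row-major upper triangle order
  (i - 1L) * k - (i - 1L) * i / 2L + j
}

#' Pairwise dyad likelihoods and posterior over FS / HS / U
#'
#' Per-locus genotype-pair probabilities under the IBD-coefficient models
#' full sib (k0, k1, k2) = (0.25, 0.5, 0.25), half sib (0.5, 0.5, 0) and
#' unrelated (1, 0, 0), with mistyping rate `epsilon` mixing in random
#' genotypes, multiplied across the loci where both individuals are
#' typed, and converted to a posterior under `prior`.
#'
#' @param gt a [genotype_table()].
#' @param id1,id2 individual ids.
#' @param freqs per-locus allele-frequency list (defaults to the sample
#'   frequencies of `gt`).
#' @param epsilon per-call mistyping rate.
#' @param prior prior over (FS, HS, U); same-clutch pairs should use a
#'   maternal-sib-at-least prior `c(0.5, 0.5, 0)`.
#' @return list with `likelihood` (per-relationship product over loci)
#'   and `posterior` (named vector over FS, HS, U).
#' @export
dyad_likelihood <- function(gt, id1, id2, freqs = NULL, epsilon = 1e-4,
                            prior = c(FS = 1, HS = 1, U = 1) / 3) {
  freqs <- freqs %||% allele_freqs(gt)
  i <- match(id1, gt$ind$id); j <- match(id2, gt$ind$id)
  if (anyNA(c(i, j))) stop_spat("unknown individual id")
  lik <- c(FS = 1, HS = 1, U = 1)
  shared <- 0L
  for (l in seq_along(gt$loci)) {
    if (is.na(gt$a1[i, l]) || is.na(gt$a1[j, l])) next
    shared <- shared + 1L
    al <- as.integer(names(freqs[[l]]))
    tb <- pair_tables(as.numeric(freqs[[l]]), epsilon)
    ci <- code_calls(gt, l, al)[c(i, j)]
    lik <- lik * c(tb$FS[ci[1], ci[2]], tb$HS[ci[1], ci[2]], tb$U[ci[1], ci[2]])
  }
  if (shared == 0L) stop_spat("no shared typed loci for this pair")
  post <- prior * lik
  list(likelihood = lik, posterior = post / sum(post))
}

# bulk posterior(FS) and posterior(HS) for all pairs; returns data.frame
# (i, j, post_fs, post_hs) using log-likelihood accumulation
all_pair_posteriors <- function(gt, freqs, epsilon) {
  n <- n_ind(gt)
  pr <- t(utils::combn(n, 2))
  i <- pr[, 1]; j <- pr[, 2]
  logl <- matrix(0, nrow(pr), 3)
  shared <- integer(nrow(pr))
  for (l in seq_along(gt$loci)) {
    al <- as.integer(names(freqs[[l]]))
    if (length(al) < 1) next
    tb <- pair_tables(as.numeric(freqs[[l]]), epsilon)
    cc <- code_calls(gt, l, al)
    ok <- !is.na(cc[i]) & !is.na(cc[j])
    if (!any(ok)) next
    idx <- (cc[i[ok]] - 1L) * nrow(tb$codes) + cc[j[ok]]
    logl[ok, 1] <- logl[ok, 1] + log(tb$FS[idx])
    logl[ok, 2] <- logl[ok, 2] + log(tb$HS[idx])
    logl[ok, 3] <- logl[ok, 3] + log(tb$U[idx])
    shared <- shared + ok
  }
  same_clutch <- !is.na(gt$ind$clutch_id[i]) &
    gt$ind$clutch_id[i] == gt$ind$clutch_id[j]
  m <- apply(logl, 1, max)
  w <- exp(logl - m)
  prior <- matrix(1 / 3, nrow(pr), 3)
  prior[same_clutch, ] <- rep(c(0.5, 0.5, 0), each = sum(same_clutch))
  pw <- prior * w
  pw[shared == 0L, ] <- prior[shared == 0L, ]  # uninformative pair
  tot <- rowSums(pw)
  data.frame(i = i, j = j, same_clutch = same_clutch,
             post_fs = pw[, 1] / tot, post_hs = pw[, 2] / tot)
}

#' Reconstruct sib families and dyad frequencies
#'
#' Classifies every pair with posterior(FS) above `threshold` as full
#' sibs; full-sib links define paternal clusters (connected components).
#' Mothers are clutches (one clutch per female, so clutches are never
#' merged); a full-sib link across clutches would imply a shared mother
#' across clutches and is therefore demoted to a paternal half-sib link
#' (shared father only). Dyads are then classified from the final parent
#' assignment: full sib = same mother and father, half sib = exactly one
#' shared parent. Dyad frequencies are hard-classification counts over
#' all pairs.
#'
#' @param x an `nb_dataset` or [genotype_table()].
#' @param threshold posterior(FS) cut-off for a full-sib call.
#' @param epsilon per-call mistyping rate for the likelihoods.
#' @param alpha deviation-from-HWE coefficient carried into
#'   [sibship_nb()]; defaults to 0 (random mating).
#' @param freqs optional per-locus allele frequencies.
#' @return A `sibship_result`: `Nm`, `Nf`, `Np`, `Q_FS`, `Q_HS`,
#'   `alpha`, `n`, per-egg parent assignment (`assign`), the full-sib
#'   `families` partition and the pair posteriors (`pairs`).
#' @export
reconstruct_families <- function(x, threshold = 0.90, epsilon = 1e-4,
                                 alpha = 0, freqs = NULL) {
  gt <- if (inherits(x, "nb_dataset")) x$genotypes else x
  stopifnot(inherits(gt, "genotype_table"))
  n <- n_ind(gt)
  if (n < 2) stop_spat("need >= 2 individuals")
  freqs <- freqs %||% allele_freqs(gt)
  pp <- all_pair_posteriors(gt, freqs, epsilon)

  fs_edge <- pp$post_fs > threshold
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (any(fs_edge))
    g <- igraph::add_edges(g, rbind(pp$i[fs_edge], pp$j[fs_edge]))
  father <- igraph::components(g)$membership

  clutch <- gt$ind$clutch_id
  clutch[is.na(clutch)] <- paste0(".solo", seq_len(n)[is.na(clutch)])
  mother <- match(clutch, unique(clutch))

  sm <- mother[pp$i] == mother[pp$j]
  sf <- father[pp$i] == father[pp$j]
  n_fs <- sum(sm & sf); n_hs <- sum(xor(sm, sf))
  npairs <- nrow(pp)
  fam <- split(gt$ind$id, paste(mother, father))
  structure(list(
    Nm = length(unique(father)), Nf = length(unique(mother)),
    Np = length(unique(father)) + length(unique(mother)),
    Q_FS = n_fs / npairs, Q_HS = n_hs / npairs, alpha = alpha, n = n,
    assign = data.frame(id = gt$ind$id, mother = mother, father = father),
    families = fam[order(-lengths(fam))],
    pairs = pp, threshold = threshold),
    class = "sibship_result")
}

#' @export
print.sibship_result <- function(x, ...) {
  cat(sprintf("sibship_result: n=%d, Nf=%d, Nm=%d, Np=%d, Q_FS=%.4g, Q_HS=%.4g\n",
              x$n, x$Nf, x$Nm, x$Np, x$Q_FS, x$Q_HS))
  invisible(x)
}

#' Dyad-frequency estimate of the effective number of breeders
#'
#' Solves `1/Nb = ((1 + 3 alpha)/4) (Q_HS + 2 Q_FS) - (alpha/2) (1/Nm +
#' 1/Nf)` for Nb, where `Q_FS` and `Q_HS` are the sample frequencies of
#' full- and half-sib dyads, `alpha` the deviation from Hardy-Weinberg
#' (correlation of genes within individuals) and `Nm`, `Nf` the numbers
#' of breeding males and females. Under random mating (`alpha = 0`) and
#' random-mating dyad frequencies this reduces to `4 Nm Nf / (Nm + Nf)`.
#'
#' @param Q_HS,Q_FS half- and full-sib dyad frequencies in `[0,1]`.
#' @param alpha deviation-from-HWE coefficient (0 under random mating).
#' @param Nm,Nf breeding male / female counts; required when
#'   `alpha != 0`.
#' @return Nb, a positive number or `Inf` when the right-hand side is
#'   non-positive (no detectable relatives).
#' @export
sibship_nb <- function(Q_HS, Q_FS, alpha = 0, Nm = NULL, Nf = NULL) {
  if (any(c(Q_HS, Q_FS) < 0) || any(c(Q_HS, Q_FS) > 1) || Q_HS + Q_FS > 1)
    stop_spat("dyad frequencies must satisfy Q_FS, Q_HS in [0,1], Q_FS + Q_HS <= 1")
  inv <- (1 + 3 * alpha) / 4 * (Q_HS + 2 * Q_FS)
  if (alpha != 0) {
    if (is.null(Nm) || is.null(Nf))
      stop_spat("Nm and Nf are required when alpha != 0")
    if (Nm <= 0 || Nf <= 0) stop_spat("Nm and Nf must be positive")
    inv <- inv - alpha / 2 * (1 / Nm + 1 / Nf)
  }
  if (inv <= 0) Inf else 1 / inv
}

#' Sibship Nb with a clutch bootstrap confidence interval
#'
#' Applies [sibship_nb()] to a [reconstruct_families()] result and
#' attaches a nonparametric 95% CI from resampling clutches with
#' replacement (each resampled clutch copy is treated as a distinct
#' mother, and its paternal cluster as a distinct father, preserving the
#' within-clutch dyad composition).
#'
#' @param sib a `sibship_result`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed.
#' @return list `nb_point`, `ci_low`, `ci_high`, `n`.
#' @export
sibship_nb_estimate <- function(sib, n_boot = 500, seed = 1) {
  stopifnot(inherits(sib, "sibship_result"))
  nb <- sibship_nb(sib$Q_HS, sib$Q_FS, sib$alpha, sib$Nm, sib$Nf)
  asg <- sib$assign
  cl <- split(seq_len(nrow(asg)), asg$mother)
  boot <- with_seed(derive_seed(seed, "sibboot"), {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(length(cl), replace = TRUE)
      mo <- fa <- integer(0)
      for (r in seq_along(pick)) {
        rows <- cl[[pick[r]]]
        mo <- c(mo, rep(r, length(rows)))
        fa <- c(fa, asg$father[rows] + r * 1e6)  # copy-local father ids
      }
      nn <- length(mo)
      if (nn < 2) return(NA_real_)
      nfs <- sum(choose(table(paste(mo, fa)), 2))
      nsm <- sum(choose(table(mo), 2)); nsf <- sum(choose(table(fa), 2))
      nhs <- nsm + nsf - 2 * nfs
      np <- nn * (nn - 1) / 2
      sibship_nb(nhs / np, nfs / np, sib$alpha,
                 length(unique(fa)), length(unique(mo)))
    }, numeric(1))
  })
  ci <- stats::quantile(boot[is.finite(boot)], c(0.025, 0.975),
                        na.rm = TRUE, names = FALSE)
  if (mean(!is.finite(boot)) > 0.025) ci[2] <- Inf
  # the percentile interval is widened to contain the point estimate
  # (clutch resampling shifts the dyad composition slightly)
  list(nb_point = nb, ci_low = min(ci[1], nb), ci_high = max(ci[2], nb),
       n = sib$n)
}

#' Per-window parent counts and the maternal fraction
#'
#' Summarizes a set of sibship reconstructions (one per sampling window):
#' the number of inferred parents per window and the pooled mean ratio of
#' mothers to parents, used downstream as the population's female
#' fraction when converting clutch counts to potential breeding adults.
#'
#' @param results list of `sibship_result` objects.
#' @return list with `np` (named vector of per-window Np) and
#'   `female_fraction` (mean of Nf/Np over windows).
#' @export
estimate_parents_and_sexratio <- function(results) {
  if (!length(results)) stop_spat("need >= 1 window result")
  np <- vapply(results, function(r) r$Np, numeric(1))
  if (any(np == 0)) stop_spat("window with zero inferred parents")
  ratio <- vapply(results, function(r) r$Nf / r$Np, numeric(1))
  list(np = np, female_fraction = mean(ratio))
}
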