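# Bias-adjusted linkage-disequilibrium estimator of the effective number
# of breeders, in the single-sample random-mating tradition: Burrows
# composite r-squared between unlinked loci, screening of rare alleles at
# a minimum frequency Pcrit, subtraction of the sampling expectation
# E[r2], and a delete-one-locus jackknife for the confidence interval.

#' Burrows composite r-squared for one allele pair
#'
#' Computes the squared correlation of allele dosages (0/1/2) between one
#' allele of locus A and one allele of locus B over the pairwise-complete
#' individuals. The composite (Burrows) disequilibrium convention is
#' adopted: `Delta = cov(X, Y) / 2` and `r2 = Delta^2 / (var(X)/2 *
#' var(Y)/2)`, i.e. the squared Pearson correlation of the dosage vectors.
#'
#' @param gt a [genotype_table()].
#' @param locus_a,locus_b locus names.
#' @param allele_a,allele_b integer allele labels.
#' @return list with `r2` and `S` (number of pairwise-complete
#'   individuals).
#' @export
composite_r2 <- function(gt, locus_a, allele_a, locus_b, allele_b) {
  la <- match(locus_a, gt$loci); lb <- match(locus_b, gt$loci)
  if (anyNA(c(la, lb))) stop_spat("unknown locus name")
  x <- (gt$a1[, la] == allele_a) + (gt$a2[, la] == allele_a)
  y <- (gt$a1[, lb] == allele_b) + (gt$a2[, lb] == allele_b)
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 2) stop_spat("fewer than 2 pairwise-complete individuals")
  x <- x[ok]; y <- y[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop_spat("monomorphic comparison: zero dosage variance")
  list(r2 = stats::cor(x, y)^2, S = sum(ok))
}

#' Expected r-squared under sampling and the Nb solve
#'
#' The sampling expectation of the composite r-squared for S diploid
#' individuals under random mating, and the drift solve for Nb, using the
#' standard bias-corrected constants: for `S >= 30`,
#' `E[r2] = 1/S + 3.19/S^2` and `Nb = (1/3 + sqrt(1/9 - 2.76 r2'))/(2 r2')`;
#' for `S < 30`, `E[r2] = 0.0018 + 0.907/S + 4.44/S^2` and
#' `Nb = (0.308 + sqrt(0.308^2 - 2.08 r2'))/(2 r2')`, with
#' `r2' = mean_r2 - E[r2]`. A non-positive `r2'` yields `Inf` (no
#' detectable drift signal). The inverted expectation
#' `r2'(Nb) = a/Nb - (b/4)/Nb^2` attains its maximum `a^2/b` at the
#' double root; an observed `r2'` beyond it (an extreme drift or
#' mixture-LD signal) returns the continuous extension `a/(2 r2')`, a
#' very small Nb, keeping the solve monotone decreasing in `r2'`.
#'
#' @param mean_r2 weighted mean composite r-squared.
#' @param S (weighted harmonic) mean number of individuals per comparison.
#' @return `nb_point`, a positive number or `Inf`.
#' @export
ne_from_r2 <- function(mean_r2, S) {
  if (S < 2) stop_spat("S must be >= 2")
  r2p <- mean_r2 - expected_r2(S)
  if (!is.finite(r2p) || r2p <= 0) return(Inf)
  if (S >= 30) { a <- 1 / 3; b <- 2.76 } else { a <- 0.308; b <- 2.08 }
  disc <- a^2 - b * r2p
  if (disc < 0) return(a / (2 * r2p))   # beyond the representable maximum
  nb <- (a + sqrt(disc)) / (2 * r2p)
  if (nb <= 0) Inf else nb
}

#' @rdname ne_from_r2
#' @export
expected_r2 <- function(S) {
  if (S >= 30) 1 / S + 3.19 / S^2 else 0.0018 + 0.907 / S + 4.44 / S^2
}

# per-locus-pair r2 aggregates used by the point estimate and the
# jackknife; one row per locus pair with usable allele comparisons
ld_pair_table <- function(gt, pcrit) {
  X <- dosage_matrix(gt)
  loc <- attr(X, "locus")
  loci <- unique(loc)
  L <- length(loci)
  if (L < 2) stop_spat("need >= 2 loci for the LD estimator")
  typed <- !is.na(X[, match(loci, loc)])   # n x L: typed at locus?
  out <- list()
  for (i in seq_len(L - 1)) for (j in seq((i + 1), L)) {
    ok <- typed[, i] & typed[, j]
    S <- sum(ok)
    if (S < 2) next
    ai <- which(loc == loci[i]); aj <- which(loc == loci[j])
    fi <- colMeans(X[ok, ai, drop = FALSE]) / 2
    fj <- colMeans(X[ok, aj, drop = FALSE]) / 2
    ai <- ai[fi >= pcrit & fi < 1]; aj <- aj[fj >= pcrit & fj < 1]
    if (!length(ai) || !length(aj)) next
    A <- X[ok, ai, drop = FALSE]; B <- X[ok, aj, drop = FALSE]
    keep_a <- apply(A, 2, stats::var) > 0
    keep_b <- apply(B, 2, stats::var) > 0
    if (!any(keep_a) || !any(keep_b)) next
    r2 <- stats::cor(A[, keep_a, drop = FALSE], B[, keep_b, drop = FALSE])^2
    out[[length(out) + 1L]] <- data.frame(
      locus_i = loci[i], locus_j = loci[j], S = S,
      n_comp = length(r2), sum_r2 = sum(r2))
  }
  if (!length(out)) stop_spat("no usable locus pairs after Pcrit screening")
  do.call(rbind, out)
}

# weighted summaries from a pair table (weights = S per comparison)
ld_summarize <- function(pt) {
  w <- pt$S * pt$n_comp
  mean_r2 <- sum(pt$sum_r2 * pt$S) / sum(w)
  S <- sum(w) / sum(w / pt$S)   # weighted harmonic mean of S
  list(mean_r2 = mean_r2, S = S)
}

#' LD estimate of the effective number of breeders
#'
#' Screens alleles at the minimum frequency `pcrit` within each locus
#' pair's pairwise-complete subset, computes the composite r-squared for
#' every passing allele pair of every locus pair, forms the S-weighted
#' mean r-squared and weighted harmonic mean S, subtracts the sampling
#' expectation and solves for Nb ([ne_from_r2()]). The 95% confidence
#' interval comes from a delete-one-locus jackknife on the weighted mean
#' r-squared (t quantile on the jackknife variance), mapped through the
#' monotone r2-to-Nb solve; bounds at or below the sampling expectation
#' propagate as `Inf`.
#'
#' @param x an `nb_dataset` or [genotype_table()].
#' @param pcrit minimum allele frequency (0.02 and 0.05 are conventional).
#' @return An `ld_nb_estimate`: `nb_point`, `ci_low`, `ci_high`,
#'   `mean_r2`, `expected_r2`, `S`, `pcrit`, `n_locus_pairs`,
#'   `n_allele_comparisons`, `n`.
#' @export
ld_nb <- function(x, pcrit = 0.02) {
  gt <- if (inherits(x, "nb_dataset")) x$genotypes else x
  stopifnot(inherits(gt, "genotype_table"))
  pt <- ld_pair_table(gt, pcrit)
  if (length(unique(c(pt$locus_i, pt$locus_j))) < 2)
    stop_spat("fewer than 2 usable loci")
  s <- ld_summarize(pt)
  nb <- ne_from_r2(s$mean_r2, s$S)

  loci <- unique(c(pt$locus_i, pt$locus_j))
  theta_l <- vapply(loci, function(l) {
    keep <- pt$locus_i != l & pt$locus_j != l
    if (!any(keep)) return(NA_real_)
    ld_summarize(pt[keep, ])$mean_r2
  }, numeric(1))
  theta_l <- theta_l[is.finite(theta_l)]
  Lj <- length(theta_l)
  ci <- c(NA_real_, NA_real_)
  if (Lj >= 3) {
    vj <- (Lj - 1) / Lj * sum((theta_l - mean(theta_l))^2)
    half <- stats::qt(0.975, Lj - 1) * sqrt(vj)
    r2_lo <- s$mean_r2 - half; r2_hi <- s$mean_r2 + half
    ci <- c(ne_from_r2(r2_hi, s$S),            # high r2 -> low Nb
            if (r2_lo > expected_r2(s$S)) ne_from_r2(r2_lo, s$S) else Inf)
  }
  structure(list(nb_point = nb, ci_low = ci[1], ci_high = ci[2],
                 mean_r2 = s$mean_r2, expected_r2 = expected_r2(s$S),
                 S = s$S, pcrit = pcrit, n_locus_pairs = nrow(pt),
                 n_allele_comparisons = sum(pt$n_comp), n = n_ind(gt)),
            class = "ld_nb_estimate")
}

#' @export
print.ld_nb_estimate <- function(x, ...) {
  cat(sprintf("LD Nb = %s  (95%% CI %s-%s)  [r2=%.5f, E[r2]=%.5f, S=%.1f, Pcrit=%.2f]\n",
              formatC(x$nb_point, digits = 1, format = "f"),
              formatC(x$ci_low, digits = 1, format = "f"),
              formatC(x$ci_high, digits = 1, format = "f"),
              x$mean_r2, x$expected_r2, x$S, x$pcrit))
  invisible(x)
}
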