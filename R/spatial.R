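# Spatial genetic structure: individual pairwise Moran's I and its
# distance-class autocorrelogram, spatial PCA on the allele-frequency
# matrix, contiguity-constrained patch grouping, Weir-Cockerham theta
# with bootstrap CIs over loci, and Nei's multilocus FIS.

# individual coordinates: each individual inherits its patch's centroid
ind_coords <- function(dataset) {
  j <- match(dataset$genotypes$ind$patch_id, dataset$patches$id)
  cbind(x = dataset$patches$x[j], y = dataset$patches$y[j])
}

# centred individual allele-frequency matrix; missing calls imputed at
# the column mean so the centring identity sum_a z_a = 0 holds exactly
centred_freq_matrix <- function(gt) {
  X <- dosage_matrix(gt, as_freq = TRUE)
  mu <- colMeans(X, na.rm = TRUE)
  for (c in seq_len(ncol(X))) X[is.na(X[, c]), c] <- mu[c]
  keep <- apply(X, 2, stats::var) > 0
  if (!any(keep)) stop_spat("no polymorphic alleles")
  sweep(X[, keep, drop = FALSE], 2, colMeans(X[, keep, drop = FALSE]))
}

#' Pairwise Moran's I between individuals
#'
#' With `x[a, li]` the within-individual allele frequency (0, 0.5, 1) and
#' `p[li]` the sample frequency, the pairwise statistic is
#' `I_ab = sum_li (x_a - p)(x_b - p) / V`, normalized by the mean
#' individual variance term `V = (1/n) sum_c sum_li (x_c - p)^2`. Under
#' this convention the mean over all ordered pairs `a != b` is exactly
#' `-1/(n-1)`.
#'
#' @param x an `nb_dataset` or [genotype_table()].
#' @return symmetric n x n matrix (diagonal included but unused).
#' @export
pairwise_moran <- function(x) {
  gt <- if (inherits(x, "nb_dataset")) x$genotypes else x
  n <- n_ind(gt)
  if (n < 3) stop_spat("need >= 3 individuals")
  Z <- centred_freq_matrix(gt)
  V <- sum(Z^2) / n
  M <- tcrossprod(Z) / V
  dimnames(M) <- list(gt$ind$id, gt$ind$id)
  M
}

#' Spatial autocorrelogram of pairwise Moran's I
#'
#' Distance classes are set at deciles of the observed pairwise distance
#' distribution (default 10 classes with approximately equal pair
#' counts); same-patch pairs (distance 0) fall in the first class. Each
#' class reports the mean pairwise Moran's I and a two-sided permutation
#' p-value obtained by shuffling individual locations. The zero-crossing
#' distance is interpolated linearly between the last class with
#' positive mean I and the first with non-positive mean I, on class mean
#' distances.
#'
#' @param dataset an `nb_dataset` with patch coordinates.
#' @param n_classes number of distance classes.
#' @param n_perm permutations for the per-class test.
#' @param seed integer seed.
#' @return An `autocorrelogram`: data.frame `classes` (bounds, mean
#'   distance, n pairs, mean I, p), `zero_crossing` (metres, `NA` if I
#'   never crosses), `max_sig_positive` (largest class mean distance
#'   with positive mean I and p <= 0.05).
#' @export
autocorrelogram <- function(dataset, n_classes = 10, n_perm = 10000, seed = 1) {
  M <- pairwise_moran(dataset)
  xy <- ind_coords(dataset)
  n <- nrow(xy)
  pr <- which(upper.tri(M), arr.ind = TRUE)
  d <- sqrt((xy[pr[, 1], 1] - xy[pr[, 2], 1])^2 +
              (xy[pr[, 1], 2] - xy[pr[, 2], 2])^2)
  if (length(unique(d)) < n_classes)
    stop_spat("fewer distinct pairwise distances (%d) than classes (%d)",
              length(unique(d)), n_classes)
  br <- unique(stats::quantile(d, probs = seq(0, 1, length.out = n_classes + 1)))
  cl <- cut(d, breaks = br, include.lowest = TRUE, labels = FALSE)
  n_classes <- length(br) - 1
  iv <- M[pr]
  obs <- tapply(iv, cl, mean)
  dbar <- tapply(d, cl, mean)
  np <- tabulate(cl, n_classes)

  lo <- hi <- rep(1L, n_classes)
  with_seed(derive_seed(seed, "autocorr"), {
    for (b in seq_len(n_perm)) {
      prm <- sample.int(n)
      pv <- M[cbind(prm[pr[, 1]], prm[pr[, 2]])]
      pm <- tapply(pv, cl, mean)
      lo <- lo + (pm <= obs + 1e-12)
      hi <- hi + (pm >= obs - 1e-12)
    }
  })
  p <- pmin(1, 2 * pmin(lo, hi) / (n_perm + 1))

  zc <- NA_real_
  first_np <- which(obs <= 0)[1]
  if (!is.na(first_np) && first_np > 1) {
    i0 <- first_np - 1
    zc <- dbar[i0] + obs[i0] * (dbar[first_np] - dbar[i0]) /
      (obs[i0] - obs[first_np])
  }
  sig_pos <- which(obs > 0 & p <= 0.05)
  structure(list(
    classes = data.frame(lower = br[-length(br)], upper = br[-1],
                         mean_dist = as.numeric(dbar), n_pairs = np,
                         mean_I = as.numeric(obs), p = as.numeric(p)),
    zero_crossing = as.numeric(zc),
    max_sig_positive = if (length(sig_pos)) as.numeric(dbar[max(sig_pos)]) else NA_real_,
    first_class_positive = obs[[1]] > 0),
    class = "autocorrelogram")
}

# Moran's I of a score vector under the symmetrized connection matrix L,
# scaled so the spectral identity lambda = var * I holds when sum(L) = n
moran_index <- function(s, L) {
  as.numeric((crossprod(s, L %*% s) / crossprod(s, s)) * (length(s) / sum(L)))
}

#' Spatial principal component analysis
#'
#' Eigen-decomposition of `(1/n) X' ((W + W')/2) X` where `X` is the
#' column-centred individual allele-frequency matrix and `W` the
#' row-normalized adjacency of the neighbourhood-by-distance graph (edge
#' iff `0 < d <= d_max`). Axes with large positive eigenvalues capture
#' global structure (clines, isolation-by-distance); large negative
#' eigenvalues capture local structure (neighbour contrasts). Each
#' eigenvalue factors as `var(score) * MoranI(score)`. Monte Carlo
#' permutation of individual locations tests the largest positive and
#' largest absolute negative eigenvalue.
#'
#' @param dataset an `nb_dataset` with patch coordinates.
#' @param d_max connection-graph distance ceiling in metres.
#' @param n_perm Monte Carlo permutations.
#' @param seed integer seed.
#' @return An `spca_result`: `eigenvalues` (signed, decreasing),
#'   `scores`, `lagged_scores`, `global_p`, `local_p`, `d_max`, `L`
#'   (symmetrized weight matrix).
#' @export
spca <- function(dataset, d_max = 1000, n_perm = 999, seed = 1) {
  gt <- dataset$genotypes
  X <- centred_freq_matrix(gt)
  xy <- ind_coords(dataset)
  n <- nrow(X)
  D <- dist_xy(xy[, 1], xy[, 2])
  W <- (D > 0 & D <= d_max) * 1
  rs <- rowSums(W)
  if (any(rs == 0))
    warning(sprintf("connection graph: %d isolated individual(s)", sum(rs == 0)))
  W <- W / pmax(rs, 1)
  L <- (W + t(W)) / 2
  C <- crossprod(X, L %*% X) / n
  eg <- eigen((C + t(C)) / 2, symmetric = TRUE)
  scores <- X %*% eg$vectors
  lagged <- L %*% scores
  colnames(scores) <- colnames(lagged) <- paste0("Axis", seq_len(ncol(scores)))

  stat <- function(Xp) {
    ev <- eigen(crossprod(Xp, L %*% Xp) / n, symmetric = TRUE,
                only.values = TRUE)$values
    c(max(ev), max(-ev))
  }
  s_obs <- stat(X)
  hits <- with_seed(derive_seed(seed, "spca"), {
    h <- c(1L, 1L)
    for (b in seq_len(n_perm)) {
      sp <- stat(X[sample.int(n), , drop = FALSE])
      h <- h + (sp >= s_obs - 1e-12)
    }
    h
  })
  structure(list(eigenvalues = eg$values, scores = scores,
                 lagged_scores = lagged,
                 global_p = hits[1] / (n_perm + 1),
                 local_p = hits[2] / (n_perm + 1),
                 d_max = d_max, L = L, ind = gt$ind$id),
            class = "spca_result")
}

#' Propose a number of patch groups from the eigenvalue screen
#'
#' Heuristic only: one group per detectably distinct level of local
#' structure, taken as 1 plus the position of the largest gap in the
#' leading positive eigenvalues. Never applied silently; pass the result
#' (or your own choice) to [group_patches()].
#'
#' @param sp an `spca_result`.
#' @param max_k largest k considered.
#' @return integer proposal for k.
#' @export
propose_k <- function(sp, max_k = 8) {
  ev <- sort(sp$eigenvalues[sp$eigenvalues > 0], decreasing = TRUE)
  ev <- ev[seq_len(min(length(ev), max_k))]
  if (length(ev) < 2) return(1L)
  which.max(-diff(ev)) + 1L
}

#' Group breeding patches from sPCA scores
#'
#' Averages each patch's lagged scores on the leading global and leading
#' local axis and clusters patches agglomeratively (average linkage on
#' the score distance) under a spatial-contiguity constraint: only
#' clusters containing patches within `d_max` of each other may merge.
#'
#' @param sp an `spca_result`.
#' @param dataset the `nb_dataset` the sPCA was run on.
#' @param k number of groups (explicit; see [propose_k()]).
#' @return named character vector: patch id -> group label `"g1"`...`"gk"`.
#' @export
group_patches <- function(sp, dataset, k) {
  patches <- dataset$patches
  if (k > nrow(patches)) stop_spat("k exceeds number of patches")
  pid <- dataset$genotypes$ind$patch_id
  ax_local <- which.min(sp$eigenvalues)
  sc <- cbind(sp$lagged_scores[, 1], sp$lagged_scores[, ax_local])
  ps <- apply(sc, 2, function(col) tapply(col, pid, mean))
  ps <- ps[match(patches$id, rownames(ps)), , drop = FALSE]
  present <- !is.na(ps[, 1])
  ids <- patches$id[present]
  S <- ps[present, , drop = FALSE]
  D <- dist_xy(patches$x[present], patches$y[present])
  if (k > length(ids)) stop_spat("k exceeds number of patches with samples")

  cl <- as.list(seq_along(ids))
  while (length(cl) > k) {
    best <- NULL; best_d <- Inf
    for (a in seq_len(length(cl) - 1)) for (b in seq(a + 1, length(cl))) {
      if (min(D[cl[[a]], cl[[b]]]) > sp$d_max) next    # not contiguous
      dd <- mean(as.matrix(stats::dist(S))[cl[[a]], cl[[b]]])
      if (dd < best_d) { best_d <- dd; best <- c(a, b) }
    }
    if (is.null(best)) {      # disconnected: relax to nearest clusters
      for (a in seq_len(length(cl) - 1)) for (b in seq(a + 1, length(cl))) {
        dd <- min(D[cl[[a]], cl[[b]]])
        if (dd < best_d) { best_d <- dd; best <- c(a, b) }
      }
    }
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
  }
  out <- character(length(ids))
  for (g in seq_along(cl)) out[cl[[g]]] <- paste0("g", g)
  stats::setNames(out, ids)
}

# Weir-Cockerham variance components (a, b, c) summed over alleles for
# one locus across r patches. p: r x k freq matrix, h: r x k observed
# heterozygote frequencies (carrying exactly one copy), nvec: r sizes.
wc_components <- function(p, h, nvec) {
  r <- length(nvec)
  nbar <- mean(nvec)
  nc <- (r * nbar - sum(nvec^2) / (r * nbar)) / (r - 1)
  a <- b <- cc <- 0
  for (al in seq_len(ncol(p))) {
    pbar <- sum(nvec * p[, al]) / (r * nbar)
    s2 <- sum(nvec * (p[, al] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(nvec * h[, al]) / (r * nbar)
    a <- a + nbar / nc *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    b <- b + nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- cc + hbar / 2
  }
  c(a = a, b = b, c = cc)
}

# per-locus (a, b, c) for a set of patches; returns L x 3 matrix
wc_locus_components <- function(gt, patch_ids) {
  L <- length(gt$loci)
  out <- matrix(NA_real_, L, 3, dimnames = list(gt$loci, c("a", "b", "c")))
  for (l in seq_len(L)) {
    al <- sort(unique(stats::na.omit(c(gt$a1[, l], gt$a2[, l]))))
    if (length(al) < 2) next
    p <- h <- matrix(0, length(patch_ids), length(al))
    nvec <- numeric(length(patch_ids))
    for (pi in seq_along(patch_ids)) {
      ri <- which(gt$ind$patch_id == patch_ids[pi])
      x1 <- gt$a1[ri, l]; x2 <- gt$a2[ri, l]
      ok <- !is.na(x1)
      nvec[pi] <- sum(ok)
      if (!sum(ok)) next
      for (ai in seq_along(al)) {
        dos <- (x1[ok] == al[ai]) + (x2[ok] == al[ai])
        p[pi, ai] <- mean(dos) / 2
        h[pi, ai] <- mean(dos == 1)
      }
    }
    use <- nvec >= 2
    if (sum(use) < 2) next
    out[l, ] <- wc_components(p[use, , drop = FALSE], h[use, , drop = FALSE],
                              nvec[use])
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

theta_from_components <- function(comp) {
  s <- colSums(comp)
  as.numeric(s["a"] / sum(s))
}

# bias-corrected percentile bootstrap over loci of the theta ratio
bc_ci <- function(comp, n_boot, seed, label) {
  L <- nrow(comp)
  th <- theta_from_components(comp)
  boot <- with_seed(derive_seed(seed, label), {
    vapply(seq_len(n_boot), function(b) {
      theta_from_components(comp[sample.int(L, replace = TRUE), , drop = FALSE])
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  if (length(boot) < 10) return(c(NA_real_, NA_real_))
  z0 <- stats::qnorm(pmin(pmax(mean(boot < th), 1 / length(boot)),
                          1 - 1 / length(boot)))
  probs <- stats::pnorm(2 * z0 + stats::qnorm(c(0.025, 0.975)))
  as.numeric(stats::quantile(boot, probs, names = FALSE))
}

#' Weir-Cockerham FST with bootstrap confidence intervals
#'
#' Multilocus ratio-of-sums theta over the variance components a (among
#' patches), b (among individuals within patches) and c (within
#' individuals), globally and for every pair of eligible patches
#' (those with at least `min_n` individuals). Confidence intervals are
#' bias-corrected percentile bootstraps over loci; a pair is flagged
#' significant when its CI excludes zero.
#'
#' @param dataset an `nb_dataset`.
#' @param min_n minimum individuals per patch.
#' @param n_boot bootstrap replicates over loci.
#' @param seed integer seed.
#' @return A `differentiation_result`: `theta` (global), `ci`,
#'   `pairwise` (data.frame patch_a, patch_b, theta, ci_low, ci_high,
#'   significant), `patches_used`, `fis` (multilocus Nei FIS of the
#'   pooled eligible sample).
#' @export
wc_fst <- function(dataset, min_n = 5, n_boot = 1000, seed = 1) {
  gt <- dataset$genotypes
  cnt <- table(gt$ind$patch_id)
  use <- names(cnt)[cnt >= min_n]
  if (length(use) < 2) stop_spat("fewer than 2 patches with >= %d samples", min_n)
  gt2 <- subset_genotypes(gt, individuals = which(gt$ind$patch_id %in% use))
  comp <- wc_locus_components(gt2, use)
  if (!nrow(comp)) stop_spat("no polymorphic loci for FST")
  th <- theta_from_components(comp)
  ci <- bc_ci(comp, n_boot, seed, "fstboot")

  pw <- list()
  for (a in seq_len(length(use) - 1)) for (b in seq(a + 1, length(use))) {
    cab <- wc_locus_components(gt2, use[c(a, b)])
    if (!nrow(cab)) next
    tab <- theta_from_components(cab)
    cci <- bc_ci(cab, n_boot, seed, paste0("fstpair", a, "_", b))
    pw[[length(pw) + 1L]] <- data.frame(
      patch_a = use[a], patch_b = use[b], theta = tab,
      ci_low = cci[1], ci_high = cci[2],
      significant = is.finite(cci[1]) && cci[1] > 0)
  }
  structure(list(theta = th, ci = ci, pairwise = do.call(rbind, pw),
                 patches_used = use, loci_used = rownames(comp),
                 fis = nei_fis(gt2)),
            class = "differentiation_result")
}

#' Nei's multilocus inbreeding coefficient FIS
#'
#' `FIS = 1 - Hobs / Hexp` with `Hexp` the unbiased within-sample gene
#' diversity `(2n/(2n-1)) (1 - sum p^2)` and multilocus pooling of
#' numerator and denominator across loci. Optionally prunes full-sib
#' redundancy by keeping one individual per (mother, father) family of a
#' [reconstruct_families()] result before computing.
#'
#' @param x an `nb_dataset` or [genotype_table()].
#' @param sib optional `sibship_result` used to keep one individual per
#'   full-sib family.
#' @return multilocus FIS (numeric scalar).
#' @export
nei_fis <- function(x, sib = NULL) {
  gt <- if (inherits(x, "nb_dataset")) x$genotypes else x
  if (!is.null(sib)) {
    keep <- vapply(sib$families, function(f) f[1], character(1))
    gt <- subset_genotypes(gt, individuals = intersect(keep, gt$ind$id))
  }
  ho <- he <- 0
  for (l in seq_along(gt$loci)) {
    a1 <- gt$a1[, l]; a2 <- gt$a2[, l]
    ok <- !is.na(a1)
    n <- sum(ok)
    if (n < 2) next
    p <- as.numeric(table(c(a1[ok], a2[ok]))) / (2 * n)
    if (length(p) < 2) next
    he <- he + (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    ho <- ho + mean(a1[ok] != a2[ok])
  }
  if (he == 0) stop_spat("no heterozygosity definable")
  1 - ho / he
}
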