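# Marker quality control: exact Hardy-Weinberg tests per locus and patch,
# null-allele frequency estimation by EM, interlocus LD permutation
# tests, and Bonferroni-based locus filtering.

# log conditional probability of a genotype-count table given allele counts
# (multivariate hypergeometric pairing distribution):
#   log P = log n! + H log 2 + sum log a_i! - log (2n)! - sum log n_ij!
# cnt: k x k matrix of genotype counts in (min, max) cells (upper triangle)
lp_table <- function(cnt_upper, n, H, lfa_sum, lf2n) {
  lgamma(n + 1) + H * log(2) + lfa_sum - lf2n - sum(lgamma(cnt_upper + 1))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test: the p-value is the total probability, under
#' the random-pairing (multivariate hypergeometric) distribution of
#' genotype tables given the observed allele counts, of all tables at
#' most as probable as the observed one. The table space is enumerated
#' completely when it contains at most `max_enum` tables, otherwise the
#' p-value is estimated by Monte Carlo shuffling of the allele vector
#' into pairs.
#'
#' @param a1,a2 integer allele vectors (one entry per individual;
#'   `NA` pairs are dropped).
#' @param n_mc Monte Carlo draws when enumeration is infeasible.
#' @param max_enum enumeration budget (number of tables).
#' @param seed integer seed (Monte Carlo path only).
#' @return p-value in `[0,1]`, with attributes `method`
#'   (`"enumeration"`/`"monte-carlo"`) and `monomorphic`.
#' @export
hwe_exact_test <- function(a1, a2, n_mc = 1e5, max_enum = 1e5, seed = 1) {
  ok <- !is.na(a1) & !is.na(a2)
  a1 <- a1[ok]; a2 <- a2[ok]
  n <- length(a1)
  if (n < 2) stop_spat("need >= 2 individuals with calls")
  al <- sort(unique(c(a1, a2)))
  k <- length(al)
  if (k == 1)
    return(structure(1.0, monomorphic = TRUE, method = "degenerate"))
  i <- match(pmin(a1, a2), al); j <- match(pmax(a1, a2), al)
  code <- (i - 1L) * k + j
  obs <- tabulate(code, k * k)
  acnt <- tabulate(c(i, j), k)          # allele counts (copies)
  H_obs <- sum(i != j)
  lfa_sum <- sum(lgamma(acnt + 1)); lf2n <- lgamma(2 * n + 1)
  lp_obs <- lp_table(obs[obs > 0], n, H_obs, lfa_sum, lf2n)

  enum <- enumerate_hwe_tables(acnt, max_enum)
  if (!is.null(enum)) {
    lps <- vapply(enum, function(tab) {
      lp_table(tab$cnt[tab$cnt > 0], n, tab$H, lfa_sum, lf2n)
    }, numeric(1))
    p <- sum(exp(lps[lps <= lp_obs + 1e-9]))
    p <- min(1, p / sum(exp(lps)))      # guard rounding
    return(structure(p, monomorphic = FALSE, method = "enumeration"))
  }
  pool <- c(i, j)
  hits <- with_seed(derive_seed(seed, "hwe-mc"), {
    if (k == 2) {
      # vectorized over draws: B simultaneous Fisher-Yates shuffles of the
      # allele pool, pairing consecutive slots
      m <- 2L * n
      P <- matrix(pool, n_mc, m, byrow = TRUE)
      for (s in m:2) {
        jj <- floor(stats::runif(n_mc) * s) + 1
        tmp <- P[, s]
        P[, s] <- P[cbind(seq_len(n_mc), jj)]
        P[cbind(seq_len(n_mc), jj)] <- tmp
      }
      A <- P[, seq(1, m, 2), drop = FALSE]; B <- P[, seq(2, m, 2), drop = FALSE]
      n_het <- rowSums(A != B)
      n_11 <- rowSums(A == 1L & B == 1L)
      n_22 <- n - n_het - n_11
      lp <- lgamma(n + 1) + n_het * log(2) + lfa_sum - lf2n -
        lgamma(n_11 + 1) - lgamma(n_het + 1) - lgamma(n_22 + 1)
      sum(lp <= lp_obs + 1e-9)
    } else {
      sum(vapply(seq_len(n_mc), function(b) {
        perm <- sample(pool)
        pi <- perm[seq(1, 2 * n, 2)]; pj <- perm[seq(2, 2 * n, 2)]
        cc <- (pmin(pi, pj) - 1L) * k + pmax(pi, pj)
        cnt <- tabulate(cc, k * k)
        lp <- lp_table(cnt[cnt > 0], n, sum(pi != pj), lfa_sum, lf2n)
        lp <= lp_obs + 1e-9
      }, logical(1)))
    }
  })
  structure((hits + 1) / (n_mc + 1), monomorphic = FALSE, method = "monte-carlo")
}

# complete enumeration of genotype tables with fixed allele counts; NULL
# when the table space exceeds the budget. Each element: list(cnt = k*k
# upper-coded count vector, H = heterozygote count).
enumerate_hwe_tables <- function(acnt, max_enum) {
  k <- length(acnt)
  # cheap upper bound on the table space; skip straight to Monte Carlo
  # when it cannot fit the budget (bound is conservative, so some small
  # spaces fall through to MC -- accuracy is unaffected)
  bound <- 1
  for (i in seq_len(k)) for (j in i:k) {
    cap <- if (i == j) acnt[i] %/% 2L else min(acnt[i], acnt[j])
    bound <- bound * (cap + 1)
    if (bound > max_enum) return(NULL)
  }
  res <- vector("list", 0)
  overflow <- FALSE
  cnt <- integer(k * k)
  rec <- function(i, j, rem) {
    if (overflow) return()
    if (i > k) {
      if (length(res) >= max_enum) { overflow <<- TRUE; return() }
      diag_codes <- (seq_len(k) - 1L) * k + seq_len(k)
      res[[length(res) + 1L]] <<- list(cnt = cnt, H = sum(cnt) - sum(cnt[diag_codes]))
      return()
    }
    if (j > k) {                       # row i done: all copies of i used?
      if (rem[i] != 0L) return()
      rec(i + 1L, i + 1L, rem); return()
    }
    if (i == j) {
      for (m in 0:(rem[i] %/% 2L)) {
        cnt[(i - 1L) * k + i] <<- m
        r2 <- rem; r2[i] <- r2[i] - 2L * m
        rec(i, j + 1L, r2)
        if (overflow) break
      }
      cnt[(i - 1L) * k + i] <<- 0L
    } else {
      for (m in 0:min(rem[i], rem[j])) {
        cnt[(i - 1L) * k + j] <<- m
        r2 <- rem; r2[i] <- r2[i] - m; r2[j] <- r2[j] - m
        rec(i, j + 1L, r2)
        if (overflow) break
      }
      cnt[(i - 1L) * k + j] <<- 0L
    }
  }
  rec(1L, 1L, acnt)
  if (overflow) NULL else res
}

#' Null-allele frequency by expectation-maximisation
#'
#' Fits, per locus, an allele-frequency model with one extra
#' non-amplifying (null) allele under Hardy-Weinberg proportions.
#' Apparent homozygotes are mixtures of true homozygotes and
#' visible/null heterozygotes; missing genotypes are null homozygotes
#' when `include_missing = TRUE`, otherwise the likelihood is truncated
#' to observable genotypes. EM iterates until the largest frequency
#' change is below `tol` or `max_iter` iterations.
#'
#' @param a1,a2 integer allele vectors; `NA` pairs are missing genotypes.
#' @param include_missing treat missing genotypes as potential null
#'   homozygotes.
#' @param tol,max_iter convergence controls.
#' @return estimated null-allele frequency, with attributes `freqs`
#'   (visible allele frequencies), `loglik` (per-iteration trace) and
#'   `iterations`.
#' @export
null_allele_em <- function(a1, a2, include_missing = TRUE,
                           tol = 1e-8, max_iter = 1e4) {
  miss <- is.na(a1) & is.na(a2)
  M <- sum(miss)
  a1 <- a1[!miss]; a2 <- a2[!miss]
  if (!length(a1)) stop_spat("all observations missing at this locus")
  al <- sort(unique(c(a1, a2)))
  k <- length(al)
  i <- match(pmin(a1, a2), al); j <- match(pmax(a1, a2), al)
  hom <- tabulate(i[i == j], k)                      # apparent homozygotes
  het_copies <- tabulate(c(i[i != j], j[i != j]), k) # copies in clear hets
  n_het <- sum(i != j)
  N <- length(i) + if (include_missing) M else 0L

  p <- as.numeric(tabulate(c(i, j), k)); p <- p / sum(p) * 0.95
  pn <- 0.05
  ll <- numeric(0)
  for (it in seq_len(max_iter)) {
    qh <- p^2 + 2 * p * pn                 # apparent-homozygote class prob
    f_true <- ifelse(qh > 0, p^2 / qh, 1)  # fraction true homozygote
    e_vis <- het_copies + hom * (2 * f_true + (1 - f_true)) # visible copies
    e_null <- sum(hom * (1 - f_true))
    m_eff <- if (include_missing) M else {
      if (pn^2 < 1) length(i) * pn^2 / (1 - pn^2) else 0
    }
    e_null <- e_null + 2 * m_eff
    tot <- sum(e_vis) + e_null
    p_new <- e_vis / tot; pn_new <- e_null / tot
    # observed-data log likelihood (multinomial over scored categories)
    ll_it <- sum(hom * log(pmax(qh, 1e-300)))
    if (n_het > 0) {
      hij <- table(factor(i[i != j], levels = 1:k),
                   factor(j[i != j], levels = 1:k))
      ll_it <- ll_it + sum(hij * log(pmax(2 * outer(p, p), 1e-300)))
    }
    ll_it <- ll_it + if (include_missing) M * log(max(pn^2, 1e-300))
                     else -length(i) * log(max(1 - pn^2, 1e-300))
    ll <- c(ll, ll_it)
    delta <- max(abs(c(p_new - p, pn_new - pn)))
    p <- p_new; pn <- pn_new
    if (delta < tol) break
  }
  structure(pn, freqs = stats::setNames(p, al), loglik = ll, iterations = it)
}

#' Permutation test for interlocus linkage disequilibrium
#'
#' Tests association between two loci with the composite r-squared
#' statistic (S-weighted mean over allele pairs, as in the LD Nb
#' estimator with `pcrit = 0`), against its permutation distribution
#' under shuffling one locus's genotypes across individuals.
#'
#' @param gt a [genotype_table()].
#' @param locus_a,locus_b locus names.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed.
#' @return p-value with attribute `statistic` (observed mean r-squared).
#' @export
interlocus_ld_test <- function(gt, locus_a, locus_b, n_perm = 10000, seed = 1) {
  if (n_perm < 1) stop_spat("n_perm must be >= 1")
  la <- match(locus_a, gt$loci); lb <- match(locus_b, gt$loci)
  if (anyNA(c(la, lb))) stop_spat("unknown locus name")
  ok <- !is.na(gt$a1[, la]) & !is.na(gt$a1[, lb])
  if (sum(ok) < 5) stop_spat("fewer than 5 overlapping individuals")
  dos_cols <- function(l) {
    al <- sort(unique(c(gt$a1[ok, l], gt$a2[ok, l])))
    X <- vapply(al, function(a) (gt$a1[ok, l] == a) + (gt$a2[ok, l] == a),
                numeric(sum(ok)))
    X[, apply(X, 2, stats::var) > 0, drop = FALSE]
  }
  A <- dos_cols(la); B <- dos_cols(lb)
  if (!ncol(A) || !ncol(B))
    stop_spat("statistic undefined (monomorphic locus?)")
  s_obs <- mean(stats::cor(A, B)^2)
  hits <- with_seed(derive_seed(seed, "ldperm"), {
    sum(vapply(seq_len(n_perm), function(b) {
      prm <- sample.int(nrow(B))
      mean(stats::cor(A, B[prm, , drop = FALSE])^2) >= s_obs - 1e-12
    }, logical(1)))
  })
  structure((hits + 1) / (n_perm + 1), statistic = s_obs)
}

#' Quality-control report over loci and patches
#'
#' Runs the exact HWE test and the null-allele EM per (locus, patch) for
#' patches with at least `min_n` genotyped individuals, and the
#' interlocus LD permutation test per locus pair on the pooled sample.
#'
#' @param dataset an `nb_dataset`.
#' @param min_n minimum individuals per patch for per-patch tests.
#' @param n_mc Monte Carlo draws for the HWE test.
#' @param n_perm permutations for the interlocus LD test (0 skips the
#'   LD screen, e.g. for speed in exploratory runs).
#' @param include_missing passed to [null_allele_em()].
#' @param seed integer seed.
#' @return A `qc_report`: data.frames `hwe` (locus, patch, n, p,
#'   monomorphic), `null_freq` (locus, patch, nu) and `ld` (locus_a,
#'   locus_b, p), plus `loci` and the monomorphic flag per locus.
#' @export
qc_report <- function(dataset, min_n = 5, n_mc = 10000, n_perm = 1000,
                      include_missing = TRUE, seed = 1) {
  gt <- dataset$genotypes
  patches <- unique(gt$ind$patch_id)
  hwe <- null_f <- list()
  for (l in seq_along(gt$loci)) {
    mono_all <- length(unique(stats::na.omit(c(gt$a1[, l], gt$a2[, l])))) < 2
    for (p in patches) {
      ri <- which(gt$ind$patch_id == p)
      a1 <- gt$a1[ri, l]; a2 <- gt$a2[ri, l]
      ok <- sum(!is.na(a1))
      if (ok < min_n) next
      pv <- hwe_exact_test(a1, a2, n_mc = n_mc,
                           seed = derive_seed(seed, paste0("hwe", l, p)))
      hwe[[length(hwe) + 1L]] <- data.frame(
        locus = gt$loci[l], patch = p, n = ok, p = as.numeric(pv),
        monomorphic = isTRUE(attr(pv, "monomorphic")))
      nu <- if (isTRUE(attr(pv, "monomorphic"))) 0 else
        as.numeric(null_allele_em(a1, a2, include_missing = include_missing))
      null_f[[length(null_f) + 1L]] <- data.frame(
        locus = gt$loci[l], patch = p, nu = nu)
    }
  }
  ld <- list()
  if (n_perm > 0 && length(gt$loci) >= 2) {
    for (a in seq_len(length(gt$loci) - 1)) for (b in seq(a + 1, length(gt$loci))) {
      pv <- tryCatch(interlocus_ld_test(gt, gt$loci[a], gt$loci[b],
                                        n_perm = n_perm,
                                        seed = derive_seed(seed, paste0("ld", a, b))),
                     error = function(e) NA_real_)
      ld[[length(ld) + 1L]] <- data.frame(locus_a = gt$loci[a],
                                          locus_b = gt$loci[b],
                                          p = as.numeric(pv))
    }
  }
  mono <- vapply(seq_along(gt$loci), function(l)
    length(unique(stats::na.omit(c(gt$a1[, l], gt$a2[, l])))) < 2, logical(1))
  uncallable <- vapply(seq_along(gt$loci), function(l)
    all(is.na(gt$a1[, l])), logical(1))
  structure(list(hwe = do.call(rbind, hwe) %||% data.frame(),
                 null_freq = do.call(rbind, null_f) %||% data.frame(),
                 ld = do.call(rbind, ld) %||% data.frame(),
                 loci = gt$loci, monomorphic = mono, uncallable = uncallable),
            class = "qc_report")
}

#' Apply locus filters from a QC report
#'
#' Drops monomorphic or uncallable loci, loci failing the
#' Bonferroni-corrected HWE test in more than `max_hwe_patches` patches,
#' and loci with estimated null-allele frequency above `null_thresh` in
#' more than `max_null_patches` patches. The Bonferroni denominator is
#' the number of (locus, patch) tests actually performed on
#' polymorphic data, at family-wise level `fwer`.
#'
#' @param report a [qc_report()].
#' @param max_hwe_patches,max_null_patches tolerated failure counts.
#' @param null_thresh null-allele frequency cut-off.
#' @param fwer family-wise error level for the Bonferroni correction.
#' @return character vector of retained locus names, with attribute
#'   `decisions` (data.frame of per-locus decisions and reasons).
#' @export
apply_locus_filters <- function(report, max_hwe_patches = 2,
                                max_null_patches = 1, null_thresh = 0.20,
                                fwer = 0.05) {
  stopifnot(inherits(report, "qc_report"))
  hwe <- report$hwe
  n_tests <- if (nrow(hwe)) sum(!hwe$monomorphic) else 0L
  alpha <- if (n_tests > 0) fwer / n_tests else fwer
  dec <- data.frame(locus = report$loci, retained = TRUE, reason = "",
                    stringsAsFactors = FALSE)
  for (l in seq_along(report$loci)) {
    nm <- report$loci[l]
    if (report$uncallable[l]) {
      dec$retained[l] <- FALSE; dec$reason[l] <- "uncallable"; next
    }
    if (report$monomorphic[l]) {
      dec$retained[l] <- FALSE; dec$reason[l] <- "monomorphic"; next
    }
    n_hwe_fail <- if (nrow(hwe)) sum(hwe$locus == nm & !hwe$monomorphic &
                                       hwe$p < alpha) else 0L
    n_null_fail <- if (nrow(report$null_freq))
      sum(report$null_freq$locus == nm & report$null_freq$nu > null_thresh)
    else 0L
    if (n_hwe_fail > max_hwe_patches) {
      dec$retained[l] <- FALSE
      dec$reason[l] <- sprintf("HWE failures in %d patches", n_hwe_fail)
    } else if (n_null_fail > max_null_patches) {
      dec$retained[l] <- FALSE
      dec$reason[l] <- sprintf("null-allele frequency > %.2f in %d patches",
                               null_thresh, n_null_fail)
    }
  }
  structure(report$loci[dec$retained], decisions = dec, alpha = alpha)
}
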