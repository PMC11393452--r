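# Buffer windows around breeding patches, per-window estimates, the
# window-size bias curves, metapopulation-Nb estimators, random
# breeding-window resampling and Wright's neighbourhood size.

#' Build deduplicated buffer windows around breeding patches
#'
#' For every (focal patch, radius) combination the window contains the
#' patches whose centroids lie within the radius of the focal centroid
#' (the focal patch always included). Windows with identical patch sets
#' are deduplicated keeping the smallest radius (ties broken by the
#' lexicographically smallest focal patch id), and one full window
#' containing all patches is appended (dropped again if it duplicates an
#' existing set).
#'
#' @param patches patch table (`id`, `x`, `y`, ...).
#' @param radii buffer radii in metres.
#' @param full_radius nominal radius recorded for the full window.
#' @return data.frame of windows: `window_id`, `focal`, `radius`,
#'   `patch_ids` (list column).
#' @export
build_windows <- function(patches, radii = seq(100, 1000, by = 100),
                          full_radius = 1500) {
  if (!nrow(patches)) stop_spat("no patches")
  D <- dist_xy(patches$x, patches$y)
  rows <- list()
  for (f in order(patches$id)) for (r in sort(radii)) {
    mem <- sort(patches$id[D[f, ] <= r | seq_len(nrow(patches)) == f])
    rows[[length(rows) + 1L]] <- list(focal = patches$id[f], radius = r,
                                      patch_ids = mem)
  }
  rows[[length(rows) + 1L]] <- list(focal = "full", radius = full_radius,
                                    patch_ids = sort(patches$id))
  keysets <- vapply(rows, function(w) paste(w$patch_ids, collapse = "|"),
                    character(1))
  ord <- order(vapply(rows, `[[`, numeric(1), "radius"),
               vapply(rows, `[[`, character(1), "focal"))
  keep <- ord[!duplicated(keysets[ord])]
  keep <- sort(keep)
  out <- data.frame(
    window_id = sprintf("W%03d", seq_along(keep)),
    focal = vapply(rows[keep], `[[`, character(1), "focal"),
    radius = vapply(rows[keep], `[[`, numeric(1), "radius"),
    stringsAsFactors = FALSE)
  out$patch_ids <- lapply(rows[keep], `[[`, "patch_ids")
  out
}

#' Potential breeding adults in a window
#'
#' Clutch counts stand in for mothers (one clutch per female per
#' season): mothers = sum over member patches of counted clutches times
#' the fraction of sampled clutches identified as the target species;
#' the count of adults follows by dividing by the population's female
#' fraction.
#'
#' @param patches patch table rows for the window's member patches.
#' @param female_fraction proportion of breeders that are female, in
#'   (0, 1); typically the mothers:parents ratio from
#'   [estimate_parents_and_sexratio()].
#' @return `NA_real_` if any member patch lacks a clutch count,
#'   otherwise the (real-valued, unrounded) number of potential breeding
#'   adults.
#' @export
estimate_na <- function(patches, female_fraction) {
  if (female_fraction <= 0 || female_fraction >= 1)
    stop_spat("female_fraction must lie in (0,1)")
  if (any(is.na(patches$n_counted)) || any(is.na(patches$pct_target)))
    return(NA_real_)
  mothers <- sum(patches$n_counted * patches$pct_target)
  mothers / female_fraction
}

#' Per-window Nb estimates and window-size curves
#'
#' For every window: the LD Nb ([ld_nb()]), the sibship reconstruction
#' and dyad-frequency Nb ([reconstruct_families()], [sibship_nb()]),
#' the inferred parent count Np, the potential breeding adults NA
#' ([estimate_na()]), the multilocus FIS and the ratio LD-Nb/NA.
#' Windows with fewer than `min_ind` individuals are skipped with a
#' reason; estimates without a finite upper confidence limit are
#' flagged (`finite_ci`) so downstream curve fits can exclude them.
#'
#' @param dataset an `nb_dataset`.
#' @param windows window table from [build_windows()].
#' @param female_fraction female fraction for the NA conversion.
#' @param pcrit minimum allele frequency for the LD estimator.
#' @param min_ind minimum individuals per estimable window.
#' @param methods subset of `c("ld", "sibship")` to run.
#' @param sib_threshold full-sib posterior threshold.
#' @return data.frame, one row per window, with estimate columns and a
#'   `skipped` reason column (`NA` when estimated).
#' @export
window_profile <- function(dataset, windows, female_fraction = 0.48,
                           pcrit = 0.02, min_ind = 6,
                           methods = c("ld", "sibship"),
                           sib_threshold = 0.90) {
  gt <- dataset$genotypes
  out <- list()
  for (w in seq_len(nrow(windows))) {
    mem <- windows$patch_ids[[w]]
    ri <- which(gt$ind$patch_id %in% mem)
    row <- data.frame(window_id = windows$window_id[w],
                      focal = windows$focal[w], radius = windows$radius[w],
                      n = length(ri), n_patches = length(mem),
                      ld_nb = NA_real_, ld_lo = NA_real_, ld_hi = NA_real_,
                      finite_ci = NA, sib_nb = NA_real_, Np = NA_integer_,
                      Nf = NA_integer_, Nm = NA_integer_,
                      na_adults = NA_real_, fis = NA_real_,
                      ratio_nb_na = NA_real_, skipped = NA_character_,
                      stringsAsFactors = FALSE)
    if (length(ri) < min_ind) {
      row$skipped <- sprintf("fewer than %d individuals", min_ind)
      out[[w]] <- row; next
    }
    sub <- subset_genotypes(gt, individuals = ri)
    if ("ld" %in% methods) {
      est <- tryCatch(ld_nb(sub, pcrit = pcrit), error = function(e) NULL)
      if (!is.null(est)) {
        row$ld_nb <- est$nb_point; row$ld_lo <- est$ci_low
        row$ld_hi <- est$ci_high
        row$finite_ci <- is.finite(est$nb_point) && is.finite(est$ci_high)
      }
    }
    if ("sibship" %in% methods) {
      sib <- tryCatch(reconstruct_families(sub, threshold = sib_threshold),
                      error = function(e) NULL)
      if (!is.null(sib)) {
        row$sib_nb <- sibship_nb(sib$Q_HS, sib$Q_FS, sib$alpha, sib$Nm, sib$Nf)
        row$Np <- sib$Np; row$Nf <- sib$Nf; row$Nm <- sib$Nm
      }
    }
    row$na_adults <- estimate_na(
      dataset$patches[dataset$patches$id %in% mem, , drop = FALSE],
      female_fraction)
    row$fis <- tryCatch(nei_fis(sub), error = function(e) NA_real_)
    if (is.finite(row$ld_nb) && is.finite(row$na_adults) && row$na_adults > 0)
      row$ratio_nb_na <- row$ld_nb / row$na_adults
    out[[w]] <- row
  }
  do.call(rbind, out)
}

#' Metapopulation Nb estimators
#'
#' Three ways to scale local Nb estimates up to the metapopulation:
#' `sum_local` adds the finite local estimates; `island` divides that
#' sum by `1 - FST` (subdivided-population correction under an island
#' model); `extrapolation` multiplies a single local (breeding-window)
#' estimate by the number of neighbourhoods `k`.
#'
#' @param local_nb numeric vector of local Nb estimates (non-finite
#'   entries are excluded with a count).
#' @param fst global FST among the local units (island mode).
#' @param k number of neighbourhoods (extrapolation mode).
#' @param mode one of `"sum_local"`, `"island"`, `"extrapolation"`.
#' @return A `meta_nb_estimate`: `value`, `mode`, `inputs`.
#' @export
meta_nb <- function(local_nb, fst = NULL, k = NULL,
                    mode = c("sum_local", "island", "extrapolation")) {
  mode <- match.arg(mode)
  finite <- local_nb[is.finite(local_nb)]
  value <- switch(mode,
    sum_local = sum(finite),
    island = {
      if (is.null(fst)) stop_spat("island mode needs fst")
      if (fst >= 1 || fst < 0) stop_spat("fst must lie in [0,1)")
      sum(finite) / (1 - fst)
    },
    extrapolation = {
      if (is.null(k)) stop_spat("extrapolation mode needs k")
      if (length(finite) != 1)
        stop_spat("extrapolation mode takes exactly one finite local estimate")
      finite * k
    })
  structure(list(value = value, mode = mode,
                 inputs = list(local_nb = local_nb, fst = fst, k = k,
                               n_nonfinite = sum(!is.finite(local_nb)))),
            class = "meta_nb_estimate")
}

#' Wright's neighbourhood size
#'
#' `Nn = 4 pi sigma^2 D`: the effective number of individuals in a
#' circle of radius `2 sigma` (the breeding window) at effective density
#' `D`, within which mating is approximately random under Gaussian
#' dispersal with axial SD `sigma`.
#'
#' @param sigma axial parent-offspring dispersal SD (metres).
#' @param density effective adults per square metre.
#' @return neighbourhood size (dimensionless).
#' @export
neighbourhood_size <- function(sigma, density) {
  if (sigma < 0 || density < 0) stop_spat("sigma and density must be >= 0")
  4 * pi * sigma^2 * density
}

#' Breeding-window diameter from the autocorrelogram
#'
#' The distance at which positive spatial autocorrelation decays to zero
#' approximates `4 sigma`; it is taken as the diameter of the breeding
#' window, within which mating is treated as random.
#'
#' @param ac an [autocorrelogram()].
#' @return list `diameter`, `radius` (metres).
#' @export
breeding_window_from_autocorr <- function(ac) {
  stopifnot(inherits(ac, "autocorrelogram"))
  if (!isTRUE(ac$first_class_positive))
    stop_spat("no positive autocorrelation in the first distance class")
  if (is.na(ac$zero_crossing))
    stop_spat("autocorrelation never crosses zero; no breeding window defined")
  list(diameter = ac$zero_crossing, radius = ac$zero_crossing / 2)
}

#' Number of neighbourhoods covering the occupied area
#'
#' Default `k` for the extrapolation meta-Nb: the ratio of the occupied
#' area (convex hull of the patch centroids) to the breeding-window
#' area, rounded up. Always overridable.
#'
#' @param patches patch table.
#' @param window_radius breeding-window radius (metres).
#' @return integer `k >= 1`.
#' @export
default_k_neighbourhoods <- function(patches, window_radius) {
  hull <- grDevices::chull(patches$x, patches$y)
  hx <- patches$x[hull]; hy <- patches$y[hull]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  max(1L, as.integer(ceiling(area / (pi * window_radius^2))))
}

#' Random breeding-window resampling
#'
#' Places candidate circular buffers of the breeding-window radius
#' uniformly at random in the patch bounding box, keeps the first
#' `n_buffers` whose window holds at least `n_samples` genotyped
#' individuals from more than `min_patches - 1` patches, and within each
#' draws `n_samples` individuals at random `n_reps` times, estimating
#' the LD Nb each time. Non-finite estimates are counted and excluded
#' from summaries; each finite estimate is extrapolated to a meta-Nb by
#' multiplying with `k` neighbourhoods.
#'
#' @param dataset an `nb_dataset`.
#' @param radius buffer radius (metres).
#' @param n_samples samples per replicate.
#' @param n_buffers,n_reps buffers and replicates per buffer.
#' @param min_patches minimum breeding patches per buffer.
#' @param k number of neighbourhoods for the extrapolation (default
#'   [default_k_neighbourhoods()]).
#' @param pcrit minimum allele frequency for the LD estimator.
#' @param max_tries rejection-sampling budget for buffer centres.
#' @param seed integer seed.
#' @return list with `estimates` (data.frame buffer, rep, nb, meta_nb,
#'   finite), `summary` (mean/sd of finite meta estimates,
#'   fraction non-finite), `k`, `buffers` (centres and member counts).
#' @export
random_window_sampling <- function(dataset, radius = 230, n_samples = 50,
                                   n_buffers = 10, n_reps = 10,
                                   min_patches = 2, k = NULL, pcrit = 0.02,
                                   max_tries = 2000, seed = 1) {
  gt <- dataset$genotypes
  pt <- dataset$patches
  k <- k %||% default_k_neighbourhoods(pt, radius)
  with_seed(derive_seed(seed, "randwin"), {
    buffers <- list()
    tries <- 0
    while (length(buffers) < n_buffers && tries < max_tries) {
      tries <- tries + 1
      cx <- stats::runif(1, min(pt$x), max(pt$x))
      cy <- stats::runif(1, min(pt$y), max(pt$y))
      mem <- pt$id[sqrt((pt$x - cx)^2 + (pt$y - cy)^2) <= radius]
      ri <- which(gt$ind$patch_id %in% mem)
      if (length(mem) < min_patches || length(ri) < n_samples) next
      buffers[[length(buffers) + 1L]] <- list(x = cx, y = cy, members = mem,
                                              ind = ri)
    }
    if (length(buffers) < n_buffers)
      stop_spat("only %d qualifying buffers found after %d tries",
                length(buffers), max_tries)
    rows <- list()
    for (b in seq_along(buffers)) for (r in seq_len(n_reps)) {
      ri <- sample(buffers[[b]]$ind, n_samples)
      est <- tryCatch(ld_nb(subset_genotypes(gt, individuals = ri),
                            pcrit = pcrit),
                      error = function(e) NULL)
      nb <- if (is.null(est)) NA_real_ else est$nb_point
      hi <- if (is.null(est)) NA_real_ else est$ci_high
      fin <- is.finite(nb) && is.finite(hi)
      rows[[length(rows) + 1L]] <- data.frame(
        buffer = b, rep = r, nb = nb, ci_high = hi,
        meta_nb = if (fin) nb * k else NA_real_, finite = fin)
    }
    est <- do.call(rbind, rows)
    structure(list(
      estimates = est,
      summary = list(mean_meta = mean(est$meta_nb, na.rm = TRUE),
                     sd_meta = stats::sd(est$meta_nb, na.rm = TRUE),
                     mean_nb = mean(est$nb[est$finite]),
                     frac_nonfinite = mean(!est$finite)),
      k = k,
      buffers = data.frame(
        buffer = seq_along(buffers),
        x = vapply(buffers, `[[`, numeric(1), "x"),
        y = vapply(buffers, `[[`, numeric(1), "y"),
        n_patches = vapply(buffers, function(b) length(b$members), integer(1)),
        n_ind = vapply(buffers, function(b) length(b$ind), integer(1)))),
      class = "random_window_result")
  })
}
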