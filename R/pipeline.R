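# End-to-end orchestration: QC -> sibship -> LD -> spatial structure ->
# buffer windows -> meta-Nb, with CSV/JSON outputs and a run manifest.
# The functions here are the package's command surface; every stage is
# also callable on its own.

#' Pipeline configuration
#'
#' Collects all stage parameters with the field-standard defaults:
#' full-sib posterior threshold 0.90, Bonferroni family-wise level 0.05,
#' null-allele cut-off 0.20, LD Pcrit 0.02, buffer radii 100-1000 m,
#' minimum window size 6.
#'
#' @param simulate simulate the input dataset (`TRUE`) or read it from
#'   `genepop_path` + `patch_path` + `clutch_path`.
#' @param sim a [sim_config()] when simulating.
#' @param genepop_path,patch_path,clutch_path input files when not.
#' @param seed master seed; all stage streams derive from it.
#' @param out_dir output directory (created); `NULL` disables file output.
#' @param pcrit,radii,sib_threshold,min_window_n,null_thresh,fwer stage
#'   parameters.
#' @param n_perm_qc,n_perm_autocorr,n_perm_spca,n_boot_fst permutation /
#'   bootstrap sizes (reduce for smoke tests).
#' @param run_spca include the sPCA stage.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulate = TRUE, sim = sim_config(),
                            genepop_path = NULL, patch_path = NULL,
                            clutch_path = NULL, seed = 1, out_dir = NULL,
                            pcrit = 0.02, radii = seq(100, 1000, by = 100),
                            sib_threshold = 0.90, min_window_n = 6,
                            null_thresh = 0.20, fwer = 0.05,
                            n_perm_qc = 200, n_perm_autocorr = 999,
                            n_perm_spca = 199, n_boot_fst = 200,
                            run_spca = TRUE) {
  structure(as.list(environment()), class = "pipeline_config")
}

read_dataset_files <- function(genepop_path, patch_path, clutch_path) {
  for (f in c(genepop_path, patch_path, clutch_path))
    if (!file.exists(f)) stop_spat("input file not found: %s", f)
  gt <- read_genepop(genepop_path)
  patch <- utils::read.csv(patch_path, stringsAsFactors = FALSE)
  names(patch)[names(patch) == "n_counted"] <- "n_counted"
  clutch <- utils::read.csv(clutch_path, stringsAsFactors = FALSE)
  # genepop rows carry no clutch ids; join via the clutch table's ids
  j <- match(gt$ind$id, clutch$individual_id %||% clutch$clutch_id)
  gt$ind$clutch_id <- clutch$clutch_id[j]
  assemble_dataset(gt, patch, clutch)
}

#' Run the full Nb-estimation pipeline
#'
#' Executes marker QC, per-patch sibship and LD Nb estimation, spatial
#' structure diagnostics, buffer-window profiling and the meta-Nb
#' estimators, in that order. A failing stage aborts with the stage
#' name; partial outputs written so far are retained. All randomness
#' derives from `config$seed`, so a rerun with the same configuration is
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return list of stage results (`dataset`, `qc`, `retained_loci`,
#'   `per_patch`, `pooled`, `sexratio`, `fst`, `autocorr`, `spca`,
#'   `windows`, `window_estimates`, `meta`, `manifest`), invisibly
#'   written to `config$out_dir` when set.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- list()
  emit <- function(name, obj) {
    if (is.null(config$out_dir)) return(invisible())
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    if (is.data.frame(obj)) {
      df <- obj
      df[] <- lapply(df, function(c) if (is.list(c))
        vapply(c, paste, character(1), collapse = ";") else c)
      utils::write.csv(df, file.path(config$out_dir, paste0(name, ".csv")),
                       row.names = FALSE)
    } else {
      writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                                  pretty = TRUE, na = "string"),
                 file.path(config$out_dir, paste0(name, ".json")))
    }
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_spat("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  out$dataset <- stage("input", {
    if (config$simulate) {
      sim <- simulate_metapopulation(config$sim, seed = config$seed)
      out$truth <- sim$truth
      sim$dataset
    } else {
      read_dataset_files(config$genepop_path, config$patch_path,
                         config$clutch_path)
    }
  })
  ds <- out$dataset

  out$qc <- stage("qc", qc_report(ds, n_mc = 2000, n_perm = config$n_perm_qc,
                                  seed = derive_seed(config$seed, "qc")))
  out$retained_loci <- stage("qc", apply_locus_filters(
    out$qc, null_thresh = config$null_thresh, fwer = config$fwer))
  ds$genotypes <- subset_genotypes(ds$genotypes, loci = out$retained_loci)
  emit("qc_hwe", out$qc$hwe); emit("qc_null", out$qc$null_freq)
  emit("qc_ld", out$qc$ld)

  out <- c(out, stage("per_patch", {
    per_patch_estimates(ds, pcrit = config$pcrit,
                        min_n = config$min_window_n,
                        sib_threshold = config$sib_threshold,
                        seed = derive_seed(config$seed, "perpatch"))
  }))
  emit("per_patch", out$per_patch)

  out$fst <- stage("spatial", tryCatch(
    wc_fst(ds, n_boot = config$n_boot_fst,
           seed = derive_seed(config$seed, "fst")),
    error = function(e) NULL))
  out$autocorr <- stage("spatial", tryCatch(
    autocorrelogram(ds, n_perm = config$n_perm_autocorr,
                    seed = derive_seed(config$seed, "ac")),
    error = function(e) NULL))
  if (isTRUE(config$run_spca))
    out$spca <- stage("spatial", tryCatch(
      spca(ds, n_perm = config$n_perm_spca,
           seed = derive_seed(config$seed, "spca")),
      error = function(e) NULL))
  if (!is.null(out$autocorr)) emit("autocorrelogram", out$autocorr$classes)

  ff <- out$sexratio
  if (is.null(ff) || !is.finite(ff) || ff <= 0 || ff >= 1) ff <- 0.48
  out$windows <- stage("windows", build_windows(ds$patches, radii = config$radii))
  out$window_estimates <- stage("windows", window_profile(
    ds, out$windows, female_fraction = ff,
    pcrit = config$pcrit, min_ind = config$min_window_n))
  emit("windows", out$windows)
  emit("window_estimates", out$window_estimates)

  out$meta <- stage("meta", {
    locals <- out$per_patch$ld_nb[is.finite(out$per_patch$ld_nb) &
                                    out$per_patch$finite_ci]
    fst <- if (!is.null(out$fst)) out$fst$theta else 0
    list(sum_local = meta_nb(locals, mode = "sum_local")$value,
         island = meta_nb(locals, fst = fst, mode = "island")$value,
         fst = fst, n_local = length(locals))
  })
  emit("meta", out$meta)

  out$manifest <- list(seed = config$seed, pcrit = config$pcrit,
                       sib_threshold = config$sib_threshold,
                       radii = config$radii,
                       simulate = config$simulate,
                       n_individuals = nrow(ds$genotypes$ind),
                       retained_loci = out$retained_loci,
                       package_version = as.character(utils::packageVersion("spatNb")))
  emit("manifest", out$manifest)
  invisible(out)
}

# per-patch LD and sibship estimates plus the pooled row and sex ratio
per_patch_estimates <- function(ds, pcrit, min_n, sib_threshold, seed) {
  gt <- ds$genotypes
  sibs <- list(); rows <- list()
  for (p in ds$patches$id) {
    ri <- which(gt$ind$patch_id == p)
    row <- data.frame(patch = p, n = length(ri), ld_nb = NA_real_,
                      ld_lo = NA_real_, ld_hi = NA_real_, finite_ci = FALSE,
                      sib_nb = NA_real_, sib_lo = NA_real_, sib_hi = NA_real_,
                      Np = NA_integer_, stringsAsFactors = FALSE)
    if (length(ri) >= min_n) {
      sub <- subset_genotypes(gt, individuals = ri)
      est <- tryCatch(ld_nb(sub, pcrit = pcrit), error = function(e) NULL)
      if (!is.null(est)) {
        row$ld_nb <- est$nb_point; row$ld_lo <- est$ci_low
        row$ld_hi <- est$ci_high
        row$finite_ci <- is.finite(est$nb_point) && is.finite(est$ci_high)
      }
      sib <- tryCatch(reconstruct_families(sub, threshold = sib_threshold),
                      error = function(e) NULL)
      if (!is.null(sib)) {
        sibs[[p]] <- sib
        sb <- sibship_nb_estimate(sib, n_boot = 200,
                                  seed = derive_seed(seed, paste0("sb", p)))
        row$sib_nb <- sb$nb_point; row$sib_lo <- sb$ci_low
        row$sib_hi <- sb$ci_high; row$Np <- sib$Np
      }
    }
    rows[[length(rows) + 1L]] <- row
  }
  pooled <- list(
    ld = tryCatch(ld_nb(gt, pcrit = pcrit), error = function(e) NULL),
    sib = tryCatch(reconstruct_families(gt, threshold = sib_threshold),
                   error = function(e) NULL))
  sexratio <- if (length(sibs))
    estimate_parents_and_sexratio(sibs)$female_fraction else NA_real_
  list(per_patch = do.call(rbind, rows), pooled = pooled,
       sexratio = sexratio, patch_sibs = sibs)
}

#' Format a per-patch Nb summary table
#'
#' Renders per-patch rows plus a `Sum` row (sum of finite point
#' estimates per method) and a pooled all-samples row, formatting LD Nb
#' to one decimal and sibship Nb to integers.
#'
#' @param per_patch data.frame with columns `patch`, `ld_nb`, `sib_nb`
#'   (other columns are carried through); e.g. from [run_pipeline()].
#' @param pooled optional list with elements `ld_nb`, `sib_nb` for the
#'   all-samples row.
#' @return data.frame with formatted character columns `LD_Nb` and
#'   `Sibship_Nb`, and attributes `ld_sum`, `sib_sum` (numeric sums of
#'   the finite estimates).
#' @export
make_table1 <- function(per_patch, pooled = NULL) {
  fmt_ld <- function(v) ifelse(is.finite(v), formatC(v, format = "f", digits = 1),
                               ifelse(is.na(v), "", "Inf"))
  fmt_sib <- function(v) ifelse(is.finite(v), formatC(round(v), format = "d"),
                                ifelse(is.na(v), "", "Inf"))
  if (!nrow(per_patch)) {
    out <- data.frame(patch = character(), LD_Nb = character(),
                      Sibship_Nb = character(), stringsAsFactors = FALSE)
    attr(out, "ld_sum") <- 0; attr(out, "sib_sum") <- 0
    return(out)
  }
  ld_sum <- sum(per_patch$ld_nb[is.finite(per_patch$ld_nb)])
  sib_sum <- sum(round(per_patch$sib_nb[is.finite(per_patch$sib_nb)]))
  out <- data.frame(patch = per_patch$patch,
                    LD_Nb = fmt_ld(per_patch$ld_nb),
                    Sibship_Nb = fmt_sib(per_patch$sib_nb),
                    stringsAsFactors = FALSE)
  out <- rbind(out, data.frame(patch = "Sum", LD_Nb = fmt_ld(ld_sum),
                               Sibship_Nb = fmt_sib(sib_sum)))
  if (!is.null(pooled))
    out <- rbind(out, data.frame(patch = "Pooled",
                                 LD_Nb = fmt_ld(pooled$ld_nb %||% NA_real_),
                                 Sibship_Nb = fmt_sib(pooled$sib_nb %||% NA_real_)))
  attr(out, "ld_sum") <- ld_sum
  attr(out, "sib_sum") <- sib_sum
  out
}
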