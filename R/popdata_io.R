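#' Construct a genotype table
#'
#' The central genotype container: diploid, codominant allele calls
#' (microsatellite fragment sizes) for a set of individuals at a set of
#' loci, with an explicit missing-data mask (`NA` in both allele matrices).
#' Allele pairs are unphased and stored canonically with the smaller allele
#' first.
#'
#' @param ind data.frame with columns `id`, `clutch_id`, `patch_id`,
#'   `species` (`"target"`/`"non_target"`) and optionally `sex`
#'   (simulated truth only). `id` must be unique.
#' @param loci character vector of locus names.
#' @param a1,a2 integer matrices (individuals x loci) holding the two
#'   allele labels of each call; `NA` in both marks a missing call.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(ind, loci, a1, a2) {
  stopifnot(is.data.frame(ind), is.character(loci))
  need <- c("id", "clutch_id", "patch_id", "species")
  miss <- setdiff(need, names(ind))
  if (length(miss)) stop_spat("individual table lacks columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(ind$id)) stop_spat("duplicated individual ids")
  if (!"sex" %in% names(ind)) ind$sex <- NA_character_
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (!all(dim(a1) == c(nrow(ind), length(loci))) || !all(dim(a1) == dim(a2)))
    stop_spat("allele matrices must be %d x %d", nrow(ind), length(loci))
  if (any(xor(is.na(a1), is.na(a2))))
    stop_spat("half-missing calls are not allowed: missing must blank both alleles")
  # canonicalize unordered pairs: smaller allele first
  swap <- !is.na(a1) & a1 > a2
  if (any(swap)) {
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(ind$id, loci)
  # one clutch -> one patch
  cp <- unique(ind[!is.na(ind$clutch_id), c("clutch_id", "patch_id")])
  if (anyDuplicated(cp$clutch_id))
    stop_spat("a clutch maps to more than one patch")
  structure(list(ind = ind, loci = loci, a1 = a1, a2 = a2),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d individuals x %d loci (%.1f%% missing), %d patches\n",
              nrow(x$ind), length(x$loci), 100 * mean(is.na(x$a1)),
              length(unique(x$ind$patch_id))))
  invisible(x)
}

n_ind <- function(gt) nrow(gt$ind)

#' Subset a genotype table by individuals and/or loci
#'
#' @param gt a `genotype_table`.
#' @param individuals individual ids (or logical/integer index) to keep.
#' @param loci locus names (or index) to keep.
#' @return A `genotype_table`.
#' @export
subset_genotypes <- function(gt, individuals = NULL, loci = NULL) {
  ri <- seq_len(nrow(gt$ind))
  if (!is.null(individuals)) {
    ri <- if (is.character(individuals)) match(individuals, gt$ind$id)
          else seq_len(nrow(gt$ind))[individuals]
    if (anyNA(ri)) stop_spat("unknown individual id(s)")
  }
  ci <- seq_along(gt$loci)
  if (!is.null(loci)) {
    ci <- if (is.character(loci)) match(loci, gt$loci) else ci[loci]
    if (anyNA(ci)) stop_spat("unknown locus name(s)")
  }
  genotype_table(gt$ind[ri, , drop = FALSE], gt$loci[ci],
                 gt$a1[ri, ci, drop = FALSE], gt$a2[ri, ci, drop = FALSE])
}

#' Read a genepop file
#'
#' Parses the classic genepop dialect: a title line, locus names (one per
#' line or comma-separated on one line), `Pop` separators, and individual
#' rows `id , a1a2 a1a2 ...` with fixed-width 2- or 3-digit allele codes
#' (auto-detected) where an all-zero code means missing.
#'
#' @param path file path.
#' @param patch_names optional character vector renaming the `Pop`
#'   sections in file order; defaults to `pop1`, `pop2`, ...
#' @return A [genotype_table()]; individuals are grouped into patches by
#'   `Pop` section in file order, `clutch_id` is left `NA` (genepop does
#'   not carry clutch membership; see [assemble_dataset()]).
#' @export
read_genepop <- function(path, patch_names = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3) stop_spat("genepop parse error: file too short")
  is_pop <- function(s) tolower(trimws(s)) == "pop"
  # locus header: lines 2.. until first Pop
  first_pop <- which(vapply(lines, is_pop, logical(1)))[1]
  if (is.na(first_pop)) stop_spat("genepop parse error: no 'Pop' line found")
  locus_lines <- lines[2:(first_pop - 1)]
  loci <- trimws(unlist(strsplit(locus_lines, ",")))
  loci <- loci[nzchar(loci)]
  if (!length(loci)) stop_spat("genepop parse error: no locus names")

  ids <- character(); patch <- character(); rows <- list()
  pop_i <- 0L; n_in_pop <- 0L; width <- NA_integer_
  for (ln in seq(first_pop, length(lines))) {
    s <- trimws(lines[ln])
    if (!nzchar(s)) next
    if (is_pop(s)) {
      if (pop_i > 0L && n_in_pop == 0L)
        stop_spat("genepop parse error at line %d: empty Pop section", ln)
      pop_i <- pop_i + 1L; n_in_pop <- 0L
      next
    }
    parts <- strsplit(s, ",")[[1]]
    if (length(parts) < 2)
      stop_spat("genepop parse error at line %d: expected 'id , genotypes'", ln)
    id <- trimws(parts[1])
    calls <- strsplit(trimws(paste(parts[-1], collapse = ",")), "[[:space:]]+")[[1]]
    if (length(calls) != length(loci))
      stop_spat("genepop parse error at line %d: %d calls for %d loci",
                ln, length(calls), length(loci))
    w <- unique(nchar(calls))
    if (length(w) != 1 || !w %in% c(4L, 6L))
      stop_spat("genepop parse error at line %d: allele strings must be uniformly 4 or 6 characters", ln)
    if (is.na(width)) width <- w
    if (w != width)
      stop_spat("genepop parse error at line %d: mixed allele widths", ln)
    n_in_pop <- n_in_pop + 1L
    ids <- c(ids, id); patch <- c(patch, as.character(pop_i))
    rows[[length(rows) + 1L]] <- calls
  }
  if (pop_i == 0L || n_in_pop == 0L)
    stop_spat("genepop parse error: empty Pop section at end of file")
  half <- width %/% 2L
  m <- do.call(rbind, rows)
  a1 <- matrix(as.integer(substr(m, 1L, half)), nrow(m), ncol(m))
  a2 <- matrix(as.integer(substr(m, half + 1L, width)), nrow(m), ncol(m))
  missing <- a1 == 0L & a2 == 0L
  if (any((a1 == 0L | a2 == 0L) & !missing))
    stop_spat("genepop parse error: allele code 0 paired with a non-zero allele")
  a1[missing] <- NA_integer_; a2[missing] <- NA_integer_
  pn <- patch_names %||% paste0("pop", seq_len(pop_i))
  if (length(pn) < pop_i) stop_spat("patch_names shorter than number of Pop sections (%d)", pop_i)
  ind <- data.frame(id = ids, clutch_id = NA_character_,
                    patch_id = pn[as.integer(patch)],
                    species = "target", stringsAsFactors = FALSE)
  genotype_table(ind, loci, a1, a2)
}

#' Write a genepop file
#'
#' Emits the 3-digit (by default) genepop dialect with one locus name per
#' line, individuals grouped into `Pop` sections by patch in input order,
#' missing calls encoded as zeros and each unphased pair written smaller
#' allele first.
#'
#' @param gt a [genotype_table()].
#' @param path output path.
#' @param digits allele-code width (3 covers microsatellite fragment sizes).
#' @param title title line.
#' @return `path`, invisibly.
#' @export
write_genepop <- function(gt, path, digits = 3, title = "spatNb genotype export") {
  if (n_ind(gt) == 0) stop_spat("cannot write a genepop file with zero individuals")
  mx <- suppressWarnings(max(gt$a1, gt$a2, na.rm = TRUE))
  if (is.finite(mx) && mx >= 10^digits)
    stop_spat("allele label %d does not fit in %d digits", mx, digits)
  fmt <- function(a) formatC(a, width = digits, flag = "0")
  out <- c(title, gt$loci)
  for (p in unique(gt$ind$patch_id)) {
    out <- c(out, "Pop")
    for (i in which(gt$ind$patch_id == p)) {
      call <- ifelse(is.na(gt$a1[i, ]), strrep("0", 2 * digits),
                     paste0(fmt(gt$a1[i, ]), fmt(gt$a2[i, ])))
      out <- c(out, paste0(gt$ind$id[i], " ,  ", paste(call, collapse = " ")))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Assemble a validated dataset from genotypes and side tables
#'
#' Joins the genotype table to the clutch table (clutch -> patch, species)
#' and the patch table (coordinates in planar metres, clutch counts,
#' fraction of clutches belonging to the target species), drops
#' individuals whose clutch belongs to the non-target species (with a
#' message giving the count), and validates all join keys.
#'
#' @param gt a [genotype_table()].
#' @param patch_table data.frame with columns `id`, `x`, `y`,
#'   `n_counted`, `n_sampled`, `pct_target`.
#' @param clutch_table optional data.frame with columns `clutch_id`,
#'   `patch_id`, `species`; when `NULL` the genotype table's own clutch
#'   and species columns are used.
#' @return An object of class `nb_dataset` with elements `genotypes`,
#'   `patches` and `provenance`.
#' @export
assemble_dataset <- function(gt, patch_table, clutch_table = NULL) {
  need <- c("id", "x", "y", "n_counted", "n_sampled", "pct_target")
  miss <- setdiff(need, names(patch_table))
  if (length(miss)) stop_spat("patch table lacks columns: %s", paste(miss, collapse = ", "))
  if (any(!is.finite(patch_table$x)) || any(!is.finite(patch_table$y)))
    stop_spat("patch coordinates must be finite planar metres")
  ok <- !is.na(patch_table$n_counted)
  if (any(patch_table$n_sampled[ok] > patch_table$n_counted[ok]))
    stop_spat("n_sampled exceeds n_counted for some patch")
  if (any(patch_table$pct_target < 0 | patch_table$pct_target > 1, na.rm = TRUE))
    stop_spat("pct_target must lie in [0,1]")

  ind <- gt$ind
  if (!is.null(clutch_table)) {
    need_c <- c("clutch_id", "patch_id", "species")
    if (length(setdiff(need_c, names(clutch_table))))
      stop_spat("clutch table lacks columns: %s",
                paste(setdiff(need_c, names(clutch_table)), collapse = ", "))
    j <- match(ind$clutch_id, clutch_table$clutch_id)
    if (anyNA(j)) stop_spat("orphan clutch id(s): %s",
                            paste(unique(ind$clutch_id[is.na(j)]), collapse = ", "))
    ind$patch_id <- clutch_table$patch_id[j]
    ind$species <- clutch_table$species[j]
  }
  if (!all(ind$patch_id %in% patch_table$id))
    stop_spat("orphan patch id(s): %s",
              paste(setdiff(unique(ind$patch_id), patch_table$id), collapse = ", "))
  drop <- ind$species != "target"
  if (any(drop))
    message(sprintf("species filter: dropping %d non-target individual(s)", sum(drop)))
  if (all(drop)) warning("no target-species individuals remain")
  gt2 <- genotype_table(ind[!drop, , drop = FALSE], gt$loci,
                        gt$a1[!drop, , drop = FALSE], gt$a2[!drop, , drop = FALSE])
  structure(list(genotypes = gt2,
                 patches = patch_table,
                 provenance = list(created = format(Sys.time(), "%Y-%m-%d"),
                                   n_dropped_non_target = sum(drop))),
            class = "nb_dataset")
}

#' @export
print.nb_dataset <- function(x, ...) {
  cat(sprintf("nb_dataset: %d individuals, %d loci, %d patches\n",
              nrow(x$genotypes$ind), length(x$genotypes$loci), nrow(x$patches)))
  invisible(x)
}
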