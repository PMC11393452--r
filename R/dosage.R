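# Allele-dosage expansion of a genotype table, shared by the LD estimator,
# Moran's I and the spatial PCA.

#' Expand genotypes to an allele dosage matrix
#'
#' Each locus is expanded into one column per observed allele; entry (i, a)
#' counts how many copies (0, 1 or 2) of allele a individual i carries, or
#' `NA` where the call is missing. With `as_freq = TRUE` dosages are halved
#' to within-individual allele frequencies (0, 0.5, 1).
#'
#' @param gt a [genotype_table()].
#' @param as_freq return within-individual frequencies instead of counts.
#' @return numeric matrix with attributes `locus` and `allele` mapping
#'   columns back to loci and allele labels.
#' @export
dosage_matrix <- function(gt, as_freq = FALSE) {
  L <- length(gt$loci)
  cols <- vector("list", L)
  locus_of <- allele_of <- list()
  for (l in seq_len(L)) {
    al <- sort(unique(c(gt$a1[, l], gt$a2[, l])))
    al <- al[!is.na(al)]
    if (!length(al)) next
    m <- matrix(0, nrow(gt$a1), length(al))
    m[is.na(gt$a1[, l]), ] <- NA
    for (k in seq_along(al)) {
      m[, k] <- m[, k] + (gt$a1[, l] == al[k]) + (gt$a2[, l] == al[k])
    }
    cols[[l]] <- m
    locus_of[[l]] <- rep(gt$loci[l], length(al))
    allele_of[[l]] <- al
  }
  X <- do.call(cbind, cols)
  if (is.null(X)) stop_spat("no scorable alleles in genotype table")
  if (as_freq) X <- X / 2
  attr(X, "locus") <- unlist(locus_of)
  attr(X, "allele") <- unlist(allele_of)
  rownames(X) <- gt$ind$id
  X
}

# per-locus allele frequency list from a genotype table
allele_freqs <- function(gt) {
  lapply(seq_along(gt$loci), function(l) {
    a <- c(gt$a1[, l], gt$a2[, l])
    a <- a[!is.na(a)]
    if (!length(a)) return(numeric(0))
    tab <- table(a)
    setNames(as.numeric(tab) / sum(tab), names(tab))
  })
}
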