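# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_spat <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Derive a reproducible sub-seed from a master seed and a stage label.
#'
#' Stage-local substreams are derived from stable labels so that adding a
#' stage never perturbs the random stream of earlier stages.
#' @keywords internal
#' @noRd
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * (seq_along(utf8ToInt(label)) %% 31L + 1L))
  as.integer((as.numeric(seed) * 69069 + h * 7901 + 1) %% 2147483587)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Euclidean distance matrix between two sets of planar points (metres).
dist_xy <- function(x1, y1, x2 = x1, y2 = y1) {
  sqrt(outer(x1, x2, "-")^2 + outer(y1, y2, "-")^2)
}

# weighted mean that tolerates empty input
wmean <- function(x, w) {
  if (!length(x)) return(NA_real_)
  sum(x * w) / sum(w)
}
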