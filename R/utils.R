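#' @import methods
#' @importFrom stats quantile setNames phyper dhyper hclust cutree as.dist runif
#' @importFrom utils read.delim write.table head
NULL

RNA_BASES <- c("a", "c", "g", "u")

#' Convert a DNA character string to lowercase RNA
#'
#' Lowercases the input and renders thymine as uracil. Any IUPAC symbol other
#' than A/C/G/T is passed through lowercased (N stays n), so callers can
#' detect ambiguous bases downstream.
#'
#' @param x character vector of DNA or RNA strings.
#' @return character vector over the lowercase RNA alphabet.
#' @examples
#' dnaToRna("GTAAGT")
#' @export
dnaToRna <- function(x) {
  chartr("t", "u", tolower(x))
}

#' Reverse-complement an RNA string
#'
#' @param x character vector of lowercase RNA strings.
#' @return reverse complement, lowercase RNA.
#' @examples
#' rnaReverseComplement("guaagu")
#' @export
rnaReverseComplement <- function(x) {
  vapply(x, function(s) {
    comp <- chartr("acgun", "ugcan", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' @keywords internal
hasAmbiguousBase <- function(x) {
  grepl("[^acgu]", x)
}

#' @keywords internal
checkRnaAlphabet <- function(x, what = "sequence") {
  bad <- hasAmbiguousBase(x)
  if (any(bad)) {
    stop(sprintf("%s contains symbols outside {a,c,g,u}: e.g. '%s'",
                 what, x[which(bad)[1]]), call. = FALSE)
  }
  invisible(TRUE)
}

## Empirical quantile, inverse-CDF form (type 1), used for the probability and
## entropy percentile cuts so that the threshold is always an observed value
## and ties at the threshold can be kept.
#' @keywords internal
empiricalQuantile <- function(x, p) {
  unname(quantile(x, probs = p, type = 1, names = FALSE))
}

## Shannon entropy (bits) of a count vector; zero counts contribute nothing.
#' @keywords internal
shannonEntropy <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) <= 1L) return(0)
  p <- counts / sum(counts)
  -sum(p * log2(p))
}

## Seed handling: run `expr` under a temporary RNG state derived from `seed`,
## restoring the caller's stream afterwards.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
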