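#' Fisher exact enrichment of every consensus in every intron class
#'
#' For each (motif rank, intron class) cell, forms the 2x2 table over the
#' full intron universe — introns matching no consensus stay in the universe
#' and contribute to the complementary margins — and computes the exact
#' hypergeometric tails with the table's margins fixed:
#' \code{p_up = P(X >= a)} (enrichment, upper tail) and
#' \code{p_down = P(X <= a)} (depletion, lower tail), where \code{a} is the
#' observed overlap. No approximation is used, and no multiple-testing
#' correction is applied by default, matching the raw alpha = 0.001
#' reporting rule; Benjamini-Hochberg adjustment is available via
#' \code{adjust}.
#'
#' @param assignments integer vector of motif ranks per intron (NA = no
#'   consensus), as from \code{assignMotifs}.
#' @param labels character vector of intron class labels, same length.
#' @param ranks ranks to test (default: all ranks present in
#'   \code{assignments}); classes default to the 36-class enumeration.
#' @param classes class labels to test.
#' @param alpha significance threshold for the flags (default 0.001).
#' @param adjust \code{"none"} (default) or \code{"BH"}: apply
#'   Benjamini-Hochberg across all cells, per tail, before flagging.
#' @return data.frame(motif_rank, upstream, downstream, class, a, motif_n,
#'   class_n, total, p_up, p_down, sig_up, sig_down).
#' @export
fisherEnrichment <- function(assignments, labels, ranks = NULL,
                             classes = enumerateIntronClasses(),
                             alpha = 0.001, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(length(assignments) == length(labels))
  N <- length(assignments)
  if (N == 0L) stop("empty intron universe")
  if (is.null(ranks)) ranks <- sort(unique(assignments[!is.na(assignments)]))

  grid <- expand.grid(motif_rank = ranks, class = classes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  motifN <- vapply(ranks, function(r)
    sum(assignments == r, na.rm = TRUE), integer(1))
  classN <- vapply(classes, function(cl)
    sum(labels == cl, na.rm = TRUE), integer(1))
  grid$motif_n <- motifN[match(grid$motif_rank, ranks)]
  grid$class_n <- classN[match(grid$class, classes)]
  grid$a <- mapply(function(r, cl)
    sum(assignments == r & labels == cl, na.rm = TRUE),
    grid$motif_rank, grid$class)
  grid$total <- N

  ## X ~ Hypergeometric(N, class_n, motif_n): overlap of the motif's introns
  ## with the class
  grid$p_up <- phyper(grid$a - 1L, grid$class_n, N - grid$class_n,
                      grid$motif_n, lower.tail = FALSE)
  grid$p_down <- phyper(grid$a, grid$class_n, N - grid$class_n,
                        grid$motif_n, lower.tail = TRUE)
  pu <- grid$p_up
  pd <- grid$p_down
  if (adjust == "BH") {
    pu <- p.adjust(pu, method = "BH")
    pd <- p.adjust(pd, method = "BH")
  }
  grid$sig_up <- pu < alpha
  grid$sig_down <- pd < alpha
  parts <- strsplit(grid$class, "-", fixed = TRUE)
  grid$upstream <- vapply(parts, `[`, character(1), 1)
  grid$downstream <- vapply(parts, `[`, character(1), 2)
  grid[, c("motif_rank", "upstream", "downstream", "class", "a", "motif_n",
           "class_n", "total", "p_up", "p_down", "sig_up", "sig_down")]
}

#' @importFrom stats p.adjust
NULL

#' Assemble the splicing code table
#'
#' Filters a \code{fisherEnrichment} matrix to the significant cells at
#' \code{alpha} and wraps it as a \code{\linkS4class{SplicingCodeTable}}.
#' All ranks passing alpha are listed per class; classes with no significant
#' motif render as \code{"None"} in the grid.
#'
#' @param matrix data.frame from \code{fisherEnrichment}.
#' @param alpha significance threshold (default 0.001).
#' @return a \code{SplicingCodeTable}.
#' @export
buildCodeTable <- function(matrix, alpha = 0.001) {
  e <- matrix
  e$sig_up <- e$p_up < alpha
  e$sig_down <- e$p_down < alpha
  e <- e[e$sig_up | e$sig_down, , drop = FALSE]
  cols <- c("motif_rank", "upstream", "downstream", "class",
            "p_up", "p_down", "sig_up", "sig_down")
  e <- e[order(e$class, e$motif_rank), cols, drop = FALSE]
  rownames(e) <- NULL
  new("SplicingCodeTable", entries = e, alpha = alpha)
}

#' Render a splicing code table as a printed grid
#'
#' Rows are upstream exon types, columns downstream types; each cell lists
#' the enriched ranks over the depleted ranks, \code{"None"} when a tail has
#' no significant motif and \code{"."} for invalid cells.
#'
#' @param code a \code{SplicingCodeTable}.
#' @return character matrix (12 rows: up/down line per upstream type).
#' @export
formatCodeGrid <- function(code) {
  e <- codeEntries(code)
  up <- c("APr", "A3", "A5", "ME", "R", "S")
  dn <- c("A3", "A5", "ME", "R", "S", "APA")
  fmt <- function(ranks) {
    if (!length(ranks)) return("None")
    paste(sort(unique(ranks)), collapse = ",")
  }
  out <- matrix("", nrow = 2L * length(up), ncol = length(dn),
                dimnames = list(
                  paste(rep(up, each = 2), c("up", "down"), sep = "."), dn))
  for (i in seq_along(up)) for (j in seq_along(dn)) {
    sel <- e$upstream == up[i] & e$downstream == dn[j]
    out[2L * i - 1L, j] <- fmt(e$motif_rank[sel & e$sig_up %in% TRUE])
    out[2L * i, j] <- fmt(e$motif_rank[sel & e$sig_down %in% TRUE])
  }
  out
}

#' Serialize / read a splicing code table as long TSV
#'
#' @param code a \code{SplicingCodeTable}.
#' @param path file path.
#' @return \code{writeCodeTsv}: path invisibly; \code{readCodeTsv}: a
#'   \code{SplicingCodeTable}.
#' @export
writeCodeTsv <- function(code, path) {
  e <- codeEntries(code)
  e$alpha <- rep(code@alpha, nrow(e))
  write.table(e, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' @rdname writeCodeTsv
#' @export
readCodeTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  alpha <- if ("alpha" %in% names(df)) df$alpha[1] else 0.001
  cols <- c("motif_rank", "upstream", "downstream", "class",
            "p_up", "p_down", "sig_up", "sig_down")
  df <- df[, cols, drop = FALSE]
  df$p_up <- as.numeric(df$p_up)
  df$p_down <- as.numeric(df$p_down)
  df$sig_up <- as.logical(df$sig_up)
  df$sig_down <- as.logical(df$sig_down)
  new("SplicingCodeTable", entries = df, alpha = as.numeric(alpha))
}
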