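#' Collect the set of consensus ranks per gene
#'
#' @param introns an \code{IntronSet}.
#' @param assignments integer ranks from \code{assignMotifs}.
#' @return named list: gene id -> sorted unique ranks (genes with no
#'   assigned intron are dropped).
#' @export
geneRankSets <- function(introns, assignments) {
  byGene <- split(assignments, geneIds(introns))
  sets <- lapply(byGene, function(r) sort(unique(r[!is.na(r)])))
  sets[lengths(sets) > 0]
}

#' Within-gene co-occurrence of consensus ranks
#'
#' \code{value[i, j]} is the Jaccard association of ranks i and j across
#' genes: genes containing both ranks over genes containing either. The
#' diagonal is unity for every rank present in at least one gene.
#'
#' @param geneRanks named list, gene -> integer vector of ranks (from
#'   \code{geneRankSets}).
#' @return square numeric matrix with rank labels as dimnames.
#' @export
buildCooccurrence <- function(geneRanks) {
  if (!length(geneRanks)) stop("empty input: no genes with assigned ranks")
  ranks <- sort(unique(unlist(geneRanks, use.names = FALSE)))
  ## gene x rank incidence
  inc <- vapply(ranks, function(r)
    vapply(geneRanks, function(s) r %in% s, logical(1)),
    logical(length(geneRanks)))
  inc <- matrix(inc, nrow = length(geneRanks))
  both <- crossprod(inc)                      # genes containing i and j
  ni <- diag(both)
  either <- outer(ni, ni, "+") - both
  mat <- ifelse(either > 0, both / either, 0)
  diag(mat) <- 1
  dimnames(mat) <- list(ranks, ranks)
  mat
}

#' Cluster consensus ranks by co-occurrence
#'
#' Agglomerative clustering with average linkage on distance
#' \code{1 - value}. With \code{k = NULL} the number of clusters is chosen
#' automatically by maximizing the mean silhouette width over
#' \code{2..min(8, n - 1)} clusters. Deterministic given the input matrix.
#'
#' @param matrix co-occurrence matrix from \code{buildCooccurrence}.
#' @param k number of clusters, or NULL for automatic selection.
#' @return list with \code{membership} (named integer vector rank ->
#'   cluster), \code{k}, and \code{hclust} (the dendrogram object).
#' @export
clusterRanks <- function(matrix, k = NULL) {
  n <- nrow(matrix)
  if (!is.null(k) && k > n) stop("more clusters requested than ranks")
  d <- as.dist(1 - matrix)
  hc <- hclust(d, method = "average")
  if (is.null(k)) {
    ks <- seq(2L, max(2L, min(8L, n - 1L)))
    sil <- vapply(ks, function(kk)
      meanSilhouette(cutree(hc, k = kk), as.matrix(d)), numeric(1))
    k <- ks[which.max(sil)]
  }
  membership <- cutree(hc, k = k)
  list(membership = membership, k = k, hclust = hc)
}

## Mean silhouette width of a flat clustering given a distance matrix.
#' @keywords internal
meanSilhouette <- function(membership, dmat) {
  n <- length(membership)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- membership == membership[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(dmat[i, own]) else 0
    bs <- vapply(setdiff(unique(membership), membership[i]), function(cl)
      mean(dmat[i, membership == cl]), numeric(1))
    if (!length(bs)) return(0)
    b <- min(bs)
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Distribution of intron counts per gene
#'
#' Summary analogous to the per-gene intron-count report: fraction of genes
#' (and of assigned-rank introns) falling into intron-count bins.
#'
#' @param introns an \code{IntronSet}.
#' @param breaks right-closed bin edges (default 0,1,5,10,15,Inf).
#' @return data.frame(bin, genes, fraction_genes).
#' @export
intronsPerGeneSummary <- function(introns,
                                  breaks = c(0, 1, 5, 10, 15, Inf)) {
  counts <- table(geneIds(introns))
  bins <- cut(as.integer(counts), breaks = breaks)
  tab <- table(bins)
  data.frame(bin = names(tab), genes = as.integer(tab),
             fraction_genes = as.numeric(tab) / length(counts),
             stringsAsFactors = FALSE)
}
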