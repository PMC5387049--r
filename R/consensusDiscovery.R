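#' Build a quaternary prefix/suffix count tree
#'
#' Inserts splice-site sequences into a quaternary tree over \{a,c,g,u\}.
#' Donor sequences are indexed from the intron 5' end outward-in
#' (prefix tree); acceptor sequences are indexed from the 3' end inward
#' (suffix tree), so that for the acceptor direction a node at depth 2 with
#' path \code{"ag"} counts sequences ending in \code{ag}. Each branch gets a
#' conditional probability (node count / parent count) and the Shannon
#' entropy (bits) of its children's count distribution.
#'
#' @param sequences character vector of lowercase RNA strings.
#' @param direction \code{"donor-prefix"} or \code{"acceptor-suffix"}.
#' @param maxDepth maximum motif length tracked (default 10).
#' @return a \code{\linkS4class{QuaternaryTree}}.
#' @examples
#' tr <- buildQuaternaryTree(rep("guaagu", 300), "donor-prefix")
#' treeNodes(tr)
#' @export
buildQuaternaryTree <- function(sequences,
                                direction = c("donor-prefix",
                                              "acceptor-suffix"),
                                maxDepth = 10L) {
  direction <- match.arg(direction)
  if (!length(sequences)) stop("empty input: no sequences to insert")
  checkRnaAlphabet(sequences, "splice-site sequence")
  internal <- if (direction == "acceptor-suffix") {
    vapply(strsplit(sequences, "", fixed = TRUE), function(ch)
      paste(rev(ch), collapse = ""), character(1))
  } else sequences

  maxDepth <- min(maxDepth, max(nchar(internal)))
  n <- length(internal)
  perDepth <- vector("list", maxDepth)
  for (d in seq_len(maxDepth)) {
    pref <- substr(internal[nchar(internal) >= d], 1L, d)
    if (!length(pref)) { perDepth[[d]] <- integer(0); next }
    perDepth[[d]] <- c(table(pref))
  }

  rows <- vector("list", maxDepth)
  for (d in seq_len(maxDepth)) {
    cnt <- perDepth[[d]]
    if (!length(cnt)) next
    keys <- names(cnt)
    parentCnt <- if (d == 1L) rep(n, length(keys)) else {
      unname(perDepth[[d - 1L]][substr(keys, 1L, d - 1L)])
    }
    ## children entropy from the next depth's counts
    ent <- rep(0, length(keys))
    if (d < maxDepth && length(perDepth[[d + 1L]])) {
      childCnt <- perDepth[[d + 1L]]
      parentOfChild <- substr(names(childCnt), 1L, d)
      entMap <- vapply(split(unname(childCnt), parentOfChild),
                       shannonEntropy, numeric(1))
      hit <- match(keys, names(entMap))
      ent[!is.na(hit)] <- entMap[hit[!is.na(hit)]]
    }
    rows[[d]] <- data.frame(
      key = keys, depth = d, count = as.integer(cnt),
      parent_count = as.integer(parentCnt),
      prob = as.numeric(cnt) / parentCnt, entropy = ent,
      stringsAsFactors = FALSE)
  }
  nodes <- do.call(rbind, rows)
  rownames(nodes) <- NULL
  nodes$path <- if (direction == "acceptor-suffix") {
    vapply(strsplit(nodes$key, "", fixed = TRUE), function(ch)
      paste(rev(ch), collapse = ""), character(1))
  } else nodes$key
  nodes <- nodes[, c("path", "key", "depth", "count", "parent_count",
                     "prob", "entropy")]
  new("QuaternaryTree", nodes = nodes, direction = direction,
      nSequences = as.integer(n), maxDepth = as.integer(maxDepth))
}

#' Select conserved branches of a quaternary tree
#'
#' Among branches carrying at least \code{minCount} sequences, keeps those
#' whose conditional probability is at or above the
#' \code{probPercentile} empirical quantile of all eligible branch
#' probabilities and whose child entropy is at or below the
#' \code{entropyPercentile} quantile (inverse-CDF quantiles, ties at the
#' threshold kept). The deepest kept node on each root-to-leaf path — a kept
#' node with no kept descendant — is returned as a motif, spelled in natural
#' orientation (intron prefix for donors, intron suffix for acceptors).
#'
#' @param tree a \code{QuaternaryTree}.
#' @param minCount minimum sequences through a branch (default 100).
#' @param probPercentile,entropyPercentile percentile cuts (defaults 0.95
#'   and 0.05).
#' @return character vector of motifs (possibly empty).
#' @export
selectConservedBranches <- function(tree, minCount = 100L,
                                    probPercentile = 0.95,
                                    entropyPercentile = 0.05) {
  elig <- treeNodes(tree)
  elig <- elig[elig$count >= minCount, , drop = FALSE]
  if (!nrow(elig)) return(character(0))
  pThr <- empiricalQuantile(elig$prob, probPercentile)
  eThr <- empiricalQuantile(elig$entropy, entropyPercentile)
  kept <- elig[elig$prob >= pThr & elig$entropy <= eThr, , drop = FALSE]
  if (!nrow(kept)) return(character(0))
  hasKeptDescendant <- vapply(kept$key, function(k) {
    any(startsWith(kept$key, k) & nchar(kept$key) > nchar(k))
  }, logical(1))
  sort(kept$path[!hasKeptDescendant])
}

## Internal: order candidate pairs by specificity (donor length, acceptor
## length, then lexicographic donor/acceptor — equivalently ascending rank
## for a ranked table).
#' @keywords internal
orderBySpecificity <- function(donor, acceptor) {
  order(-nchar(donor), -nchar(acceptor), donor, acceptor)
}

## Internal: exclusive most-specific assignment of introns to candidate
## pairs. Returns an integer index into (donor, acceptor) per intron, NA for
## unmatched.
#' @keywords internal
assignToPairs <- function(donorSeq, acceptorSeq, donor, acceptor) {
  ord <- orderBySpecificity(donor, acceptor)
  assign <- rep(NA_integer_, length(donorSeq))
  for (j in ord) {
    open <- which(is.na(assign))
    if (!length(open)) break
    hit <- startsWith(donorSeq[open], donor[j]) &
      endsWith(acceptorSeq[open], acceptor[j])
    assign[open[hit]] <- j
  }
  assign
}

#' Build the ranked paired-consensus table
#'
#' Builds donor and acceptor quaternary trees from all introns, selects
#' conserved branches on each side, forms candidate pairs as the Cartesian
#' product of conserved donor and acceptor motifs (restricted to motifs with
#' a valid splice core: donors starting gu/gc/au, acceptors ending ag/ac),
#' assigns every intron exclusively to the most specific candidate pair it
#' matches, drops pairs assigned fewer than \code{minCount} introns, and
#' iterates re-assignment until the candidate set is stable. Surviving pairs
#' are ranked by descending count (ties broken lexicographically by donor
#' then acceptor motif).
#'
#' @param introns an \code{\linkS4class{IntronSet}}, or a list with
#'   character elements \code{donor} and \code{acceptor}. Introns flagged
#'   \code{has_n} are excluded.
#' @param minCount minimum introns per consensus pair (default 100).
#' @param probPercentile,entropyPercentile,maxDepth tree parameters.
#' @return a \code{\linkS4class{PairedConsensusTable}}.
#' @export
buildPairedConsensusTable <- function(introns, minCount = 100L,
                                      probPercentile = 0.95,
                                      entropyPercentile = 0.05,
                                      maxDepth = 10L) {
  if (is(introns, "IntronSet")) {
    keep <- !mcols(intronRanges(introns))$has_n
    donorSeq <- donorSeqs(introns)[keep]
    acceptorSeq <- acceptorSeqs(introns)[keep]
  } else {
    donorSeq <- introns$donor
    acceptorSeq <- introns$acceptor
  }
  n <- length(donorSeq)
  if (n < minCount)
    stop(sprintf("need at least minCount = %d introns, got %d", minCount, n))

  donorTree <- buildQuaternaryTree(donorSeq, "donor-prefix", maxDepth)
  acceptorTree <- buildQuaternaryTree(acceptorSeq, "acceptor-suffix",
                                      maxDepth)
  dMotifs <- selectConservedBranches(donorTree, minCount, probPercentile,
                                     entropyPercentile)
  aMotifs <- selectConservedBranches(acceptorTree, minCount, probPercentile,
                                     entropyPercentile)
  dMotifs <- dMotifs[nchar(dMotifs) >= 2 & grepl("^(gu|gc|au)", dMotifs)]
  aMotifs <- aMotifs[nchar(aMotifs) >= 2 & grepl("(ag|ac)$", aMotifs)]
  if (!length(dMotifs) || !length(aMotifs))
    return(PairedConsensusTable(
      data.frame(rank = integer(), donor = character(),
                 acceptor = character(), count = integer()), n))

  cand <- expand.grid(donor = dMotifs, acceptor = aMotifs,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  repeat {
    assign <- assignToPairs(donorSeq, acceptorSeq, cand$donor, cand$acceptor)
    counts <- tabulate(assign, nbins = nrow(cand))
    keepPair <- counts >= minCount
    if (all(keepPair)) break
    cand <- cand[keepPair, , drop = FALSE]
    if (!nrow(cand)) break
  }
  if (!nrow(cand))
    return(PairedConsensusTable(
      data.frame(rank = integer(), donor = character(),
                 acceptor = character(), count = integer()), n))
  cand$count <- counts[keepPair]
  PairedConsensusTable(cand, n)
}

#' Assign a splice pair to its most specific consensus
#'
#' Implements the exclusive matching convention: the underscore in a paired
#' consensus such as \code{guaagu_ag} stands for any sequence except one
#' matching a more specific consensus on the table. A pair matches when the
#' donor sequence starts with the donor motif and the acceptor sequence ends
#' with the acceptor motif; among matches the pair maximizing donor motif
#' length, then acceptor motif length, then lower rank wins.
#'
#' @param donorSeq,acceptorSeq lowercase RNA strings (intron 5' prefix and
#'   3' suffix; any length at least the motif lengths of interest).
#' @param table a \code{\linkS4class{PairedConsensusTable}}.
#' @return a one-row data.frame (rank, donor, acceptor, count), or
#'   \code{NULL} when no consensus on the table matches.
#' @examples
#' tab <- PairedConsensusTable(
#'   data.frame(donor = c("gu", "guaagu"), acceptor = c("ag", "ag"),
#'              count = c(500L, 300L)), 1000L)
#' assignMotif("guaagucuca", "uuuuccucag", tab)
#' @export
assignMotif <- function(donorSeq, acceptorSeq, table) {
  m <- consensusMotifs(table)
  if (!nrow(m)) stop("consensus table is empty")
  hit <- startsWith(donorSeq, m$donor) & endsWith(acceptorSeq, m$acceptor)
  if (!any(hit)) return(NULL)
  mh <- m[hit, , drop = FALSE]
  mh <- mh[order(-nchar(mh$donor), -nchar(mh$acceptor), mh$rank), ,
           drop = FALSE]
  mh[1, , drop = FALSE]
}

#' Assign every intron of a set to a consensus rank
#'
#' Vectorized exclusive assignment; introns flagged \code{has_n} get NA.
#'
#' @param introns an \code{IntronSet}.
#' @param table a \code{PairedConsensusTable}.
#' @return integer vector of ranks (NA = matches no consensus).
#' @export
assignMotifs <- function(introns, table) {
  m <- consensusMotifs(table)
  donorSeq <- donorSeqs(introns)
  acceptorSeq <- acceptorSeqs(introns)
  idx <- assignToPairs(donorSeq, acceptorSeq, m$donor, m$acceptor)
  rank <- m$rank[idx]
  rank[mcols(intronRanges(introns))$has_n] <- NA_integer_
  rank
}

#' Compare two paired-consensus tables
#'
#' Shared motifs are donor_acceptor strings present in both tables.
#'
#' @param tableA,tableB \code{PairedConsensusTable} objects.
#' @return list with \code{shared} (character), \code{fractionA} = shared /
#'   motifs of A, \code{fractionB}, and \code{jaccard}.
#' @export
compareMotifTables <- function(tableA, tableB) {
  a <- motifStrings(tableA)
  b <- motifStrings(tableB)
  if (!length(a) || !length(b)) stop("both tables must be non-empty")
  shared <- intersect(a, b)
  list(shared = shared,
       fractionA = length(shared) / length(a),
       fractionB = length(shared) / length(b),
       jaccard = length(shared) / length(union(a, b)))
}

#' Serialize / read a consensus table as TSV
#'
#' The printed-format table: columns rank, motif (donor_acceptor), count,
#' with a rank-0 ALL row giving the intron universe size.
#'
#' @param table a \code{PairedConsensusTable}.
#' @param path file path.
#' @return \code{writeConsensusTsv}: the path, invisibly;
#'   \code{readConsensusTsv}: a \code{PairedConsensusTable}.
#' @export
writeConsensusTsv <- function(table, path) {
  m <- consensusMotifs(table)
  df <- data.frame(
    rank = c(0L, m$rank),
    motif = c("ALL", paste(m$donor, m$acceptor, sep = "_")),
    count = c(totalIntrons(table), m$count))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeConsensusTsv
#' @export
readConsensusTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  allRow <- df$rank == 0L
  if (!any(allRow)) stop("consensus TSV lacks the rank-0 ALL row")
  total <- df$count[allRow][1]
  df <- df[!allRow, , drop = FALSE]
  parts <- strsplit(df$motif, "_", fixed = TRUE)
  motifs <- data.frame(
    donor = vapply(parts, `[`, character(1), 1),
    acceptor = vapply(parts, `[`, character(1), 2),
    count = as.integer(df$count), stringsAsFactors = FALSE)
  tab <- PairedConsensusTable(motifs, total)
  stopifnot(identical(consensusMotifs(tab)$count, motifs$count))
  tab
}
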