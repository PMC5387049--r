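#' The seven exon splicing types
#'
#' \code{R} retained/invariant, \code{S} skipped, \code{A3}/\code{A5}
#' alternative 3'/5' splice-site exon, \code{ME} mutually exclusive,
#' \code{APr} alternative promoter, \code{APA} alternative poly-A.
#'
#' @return character vector of the 7 type codes.
#' @export
exonTypes <- function() EXON_TYPES

#' Classify the unique exons of one gene
#'
#' Evaluates the seven splicing-type rules on the full transcript set of a
#' gene. Exons are keyed by (contig, strand, start, end). Rules, evaluated on
#' the transcribed strand:
#' \itemize{
#' \item \strong{APr}: the exon is the 5'-most exon of some transcript and
#'   the gene has at least two distinct transcription start positions.
#' \item \strong{APA}: mirror rule at the 3' end.
#' \item \strong{ME}: the exon belongs to a non-overlapping pair, each member
#'   present in at least one transcript, never co-occurring in any
#'   transcript, with at least one shared flanking (adjacent) exon.
#' \item \strong{S}: an internal exon absent from some transcript in which
#'   its two adjacent exons are both present and directly joined.
#' \item \strong{A5}: another exon exists with the same acceptor-side (5')
#'   boundary but a different donor-side (3') boundary.
#' \item \strong{A3}: mirror at the acceptor side.
#' \item \strong{R}: none of the above.
#' }
#' When several rules match, precedence is APr > APA > ME > S > A5 > A3 > R
#' (terminal types first, then the most specific internal patterns). The
#' precedence order is configurable.
#'
#' @param transcripts \code{GRangesList} of exons, all transcripts of one
#'   gene (same contig and strand).
#' @param precedence character vector ordering the 7 types.
#' @return named character vector: exon key -> type.
#' @export
classifyExons <- function(transcripts,
                          precedence = c("APr", "APA", "ME", "S",
                                         "A5", "A3", "R")) {
  if (!length(transcripts)) stop("empty transcript set")
  ## per-transcript exon keys in transcription order
  txKeys <- lapply(transcripts, function(gr) {
    txo <- orderExonsTx(gr)
    intervalKey(as.character(seqnames(txo)), as.character(strand(txo)),
                start(txo), end(txo))
  })
  classifyExonKeys(txKeys, precedence)
}

## Core of the classifier, operating on per-transcript exon-key lists in
## transcription order (see classifyExons for the rules).
#' @keywords internal
classifyExonKeys <- function(txKeys,
                             precedence = c("APr", "APA", "ME", "S",
                                            "A5", "A3", "R")) {
  stopifnot(setequal(precedence, EXON_TYPES))
  allKeys <- unique(unlist(txKeys, use.names = FALSE))
  n <- length(allKeys)

  ## exon geometry parsed back from the keys
  parse <- regmatches(allKeys,
                      regexec("^(.+):([+-]):(\\d+)-(\\d+)$", allKeys))
  strandv <- vapply(parse, `[`, character(1), 3)
  startv <- as.integer(vapply(parse, `[`, character(1), 4))
  endv <- as.integer(vapply(parse, `[`, character(1), 5))
  ## boundaries on the transcribed strand: acceptor side is the exon 5' edge,
  ## donor side the exon 3' edge
  plus <- strandv == "+"
  acc <- ifelse(plus, startv, endv)
  don <- ifelse(plus, endv, startv)

  txIdx <- lapply(txKeys, match, table = allKeys)
  matchMat <- matrix(FALSE, nrow = n, ncol = length(EXON_TYPES),
                     dimnames = list(allKeys, EXON_TYPES))

  ## APr / APA
  first <- vapply(txIdx, `[`, integer(1), 1)
  last <- vapply(txIdx, function(v) v[length(v)], integer(1))
  if (length(unique(acc[first])) >= 2L) matchMat[unique(first), "APr"] <- TRUE
  if (length(unique(don[last])) >= 2L) matchMat[unique(last), "APA"] <- TRUE

  ## co-occurrence, adjacency and overlap matrices
  co <- adj <- matrix(FALSE, n, n)
  for (v in txIdx) {
    co[v, v] <- TRUE
    if (length(v) > 1L) {
      p <- v[-length(v)]; q <- v[-1L]
      adj[cbind(p, q)] <- TRUE
      adj[cbind(q, p)] <- TRUE
    }
  }
  ov <- outer(startv, endv, "<=") & t(outer(startv, endv, "<="))

  ## ME: non-overlapping, never co-occurring, sharing a flanking exon
  if (n > 1L) {
    sharedFlank <- (adj %*% adj) > 0
    me <- !ov & !co & sharedFlank
    matchMat[apply(me, 1, any), "ME"] <- TRUE
  }

  ## S: internal exon skipped with its neighbours directly joined elsewhere
  for (v in txIdx) {
    if (length(v) < 3L) next
    for (i in seq(2L, length(v) - 1L)) {
      joined <- any(vapply(txIdx, function(other) {
        ip <- which(other == v[i - 1L])
        length(ip) > 0 && ip < length(other) && other[ip + 1L] == v[i + 1L]
      }, logical(1)))
      if (joined) matchMat[v[i], "S"] <- TRUE
    }
  }

  ## A5 / A3 from boundary sharing
  sameAcc <- outer(acc, acc, "==") & outer(don, don, "!=")
  sameDon <- outer(don, don, "==") & outer(acc, acc, "!=")
  matchMat[apply(sameAcc, 1, any), "A5"] <- TRUE
  matchMat[apply(sameDon, 1, any), "A3"] <- TRUE

  matches <- lapply(seq_len(n), function(i) EXON_TYPES[matchMat[i, ]])
  names(matches) <- allKeys
  res <- vapply(matches, function(hit) {
    precedence[min(match(c(hit, "R"), precedence))]
  }, character(1))
  ## full match sets kept so intron labeling can resolve positional conflicts
  ## (an exon terminal in one transcript but internal in another)
  attr(res, "matches") <- matches
  res
}

#' Label an intron by its flanking exon types
#'
#' An intron flanked by exon types \code{Xa} (upstream in transcription
#' order) and \code{Xb} (downstream) is labeled \code{"Xa-Xb"}. An
#' alternative poly-A exon can never be upstream of an intron and an
#' alternative-promoter exon can never be downstream, which is why only 36
#' of the 49 ordered pairs are valid.
#'
#' @param upstreamType,downstreamType exon type codes.
#' @return class label string, e.g. \code{"R-S"}.
#' @export
labelIntron <- function(upstreamType, downstreamType) {
  stopifnot(upstreamType %in% EXON_TYPES, downstreamType %in% EXON_TYPES)
  if (upstreamType == "APA")
    stop("invalid intron class: APA cannot flank an intron upstream")
  if (downstreamType == "APr")
    stop("invalid intron class: APr cannot flank an intron downstream")
  paste(upstreamType, downstreamType, sep = "-")
}

#' Enumerate the 36 valid intron classes
#'
#' Fixed order: upstream types APr, A3, A5, ME, R, S (rows) crossed with
#' downstream types A3, A5, ME, R, S, APA (columns), row-major — the layout
#' of the printed code grid.
#'
#' @return character vector of 36 class labels.
#' @export
enumerateIntronClasses <- function() {
  up <- c("APr", "A3", "A5", "ME", "R", "S")
  dn <- c("A3", "A5", "ME", "R", "S", "APA")
  as.vector(t(outer(up, dn, paste, sep = "-")))
}

#' Assign class labels to the introns of an IntronSet
#'
#' Classifies the exons of every gene and labels each unique intron with the
#' types of its flanking exons. If different transcripts give the same
#' intron different flanking pairs, the lexicographically smallest label is
#' kept and a warning is issued.
#'
#' @param introns an \code{IntronSet} from \code{extractIntrons}.
#' @param transcripts the \code{GRangesList} the introns came from (with
#'   \code{gene_id} metadata).
#' @param precedence passed to \code{classifyExons}.
#' @return the \code{IntronSet} with \code{upstream_type},
#'   \code{downstream_type} and \code{intron_class} filled in.
#' @export
labelIntrons <- function(introns, transcripts,
                         precedence = c("APr", "APA", "ME", "S",
                                        "A5", "A3", "R")) {
  gr <- intronRanges(introns)
  if (!length(gr)) return(introns)
  geneOf <- mcols(transcripts)$gene_id
  if (is.null(geneOf)) geneOf <- names(transcripts)

  ## flatten once: per-transcript key lists in transcription order
  u <- unlist(transcripts, use.names = FALSE)
  txIdx <- rep(seq_along(transcripts), S4Vectors::elementNROWS(transcripts))
  key <- intervalKey(as.character(seqnames(u)), as.character(strand(u)),
                     start(u), end(u))
  ord <- order(txIdx, start(u))
  txKeysAll <- split(key[ord], factor(txIdx[ord],
                                      levels = seq_along(transcripts)))
  strandOfTx <- as.character(strand(u))[!duplicated(txIdx)][
    order(unique(txIdx))]
  minusTx <- strandOfTx == "-"
  txKeysAll[minusTx] <- lapply(txKeysAll[minusTx], rev)

  upT <- dnT <- lab <- rep(NA_character_, length(gr))
  nConflict <- 0L
  geneCol <- mcols(gr)$gene_id
  flankPairs <- mcols(gr)$flank_pairs
  idxByGene <- split(seq_along(gr), geneCol)
  txByGene <- split(seq_along(transcripts), geneOf)
  for (g in names(idxByGene)) {
    types <- classifyExonKeys(txKeysAll[txByGene[[g]]],
                              precedence = precedence)
    matches <- attr(types, "matches")
    ## contextual type: an exon flanking an intron upstream cannot be APA
    ## (it is internal there), and a downstream flank cannot be APr
    typeFor <- function(key, exclude) {
      hit <- setdiff(c(matches[[key]], "R"), exclude)
      precedence[min(match(hit, precedence))]
    }
    idx <- idxByGene[[g]]
    for (i in idx) {
      pairs <- strsplit(strsplit(flankPairs[i], ";",
                                 fixed = TRUE)[[1]], "|", fixed = TRUE)
      labs <- vapply(pairs, function(p)
        labelIntron(typeFor(p[1], "APA"), typeFor(p[2], "APr")),
        character(1))
      if (length(unique(labs)) > 1L) nConflict <- nConflict + 1L
      best <- which(labs == min(labs))[1]
      lab[i] <- labs[best]
      upT[i] <- typeFor(pairs[[best]][1], "APA")
      dnT[i] <- typeFor(pairs[[best]][2], "APr")
    }
  }
  if (nConflict > 0L)
    warning(sprintf(
      "%d intron(s) had conflicting flanking-exon pairs across transcripts; kept the lexicographically smallest class label",
      nConflict))
  mcols(gr)$upstream_type <- upT
  mcols(gr)$downstream_type <- dnT
  mcols(gr)$intron_class <- lab
  IntronSet(gr)
}

#' Write exon types as TSV
#'
#' @param types named vector from \code{classifyExons} (or a concatenation
#'   over genes).
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeExonTypeTsv <- function(types, path) {
  df <- data.frame(exon = names(types), type = unname(types),
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
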