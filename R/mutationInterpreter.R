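#' Parse an IVS-style splice-site mutation
#'
#' Accepts the intronic-variant nomenclature
#' \code{IVS<intron><offset><REF>><ALT>}, e.g. \code{"IVS6+5G>A"}:
#' intron ordinal (1-based, transcription order), signed offset (+k is the
#' k-th intron base from the donor, +1 the first intron base; -k the k-th
#' base from the acceptor end), and reference/alternate bases. DNA letters
#' are normalized to lowercase RNA.
#'
#' @param text mutation string.
#' @return list with \code{intron_ordinal}, \code{offset}, \code{ref_base},
#'   \code{alt_base}.
#' @examples
#' parseIvsMutation("IVS6+5G>A")
#' @export
parseIvsMutation <- function(text) {
  text <- gsub("−", "-", trimws(text))  # tolerate typographic minus
  m <- regexec("^IVS([0-9]+)([+-])([0-9]+)([ACGTUacgtu])>([ACGTUacgtu])$",
               text)
  parts <- regmatches(text, m)[[1]]
  if (!length(parts))
    stop("malformed IVS mutation: '", text,
         "' (expected IVS<intron>[+|-]<pos><REF>><ALT>)")
  offset <- as.integer(parts[4])
  if (offset == 0L) stop("IVS offset must be non-zero")
  if (parts[3] == "-") offset <- -offset
  list(intron_ordinal = as.integer(parts[2]),
       offset = offset,
       ref_base = dnaToRna(parts[5]),
       alt_base = dnaToRna(parts[6]))
}

## Apply a point mutation to the donor/acceptor pair of sequences.
#' @keywords internal
applyMutation <- function(donorSeq, acceptorSeq, spec, checkRef = TRUE) {
  if (spec$offset > 0) {
    pos <- spec$offset
    if (pos > nchar(donorSeq))
      stop(sprintf("offset +%d beyond the extracted donor window (%d bases)",
                   pos, nchar(donorSeq)))
    obs <- substr(donorSeq, pos, pos)
    if (checkRef && obs != spec$ref_base)
      stop(sprintf(
        "reference mismatch at +%d: annotation has '%s', mutation says '%s'",
        pos, obs, spec$ref_base))
    substr(donorSeq, pos, pos) <- spec$alt_base
  } else {
    pos <- nchar(acceptorSeq) + spec$offset + 1L
    if (pos < 1L)
      stop(sprintf(
        "offset %d beyond the extracted acceptor window (%d bases)",
        spec$offset, nchar(acceptorSeq)))
    obs <- substr(acceptorSeq, pos, pos)
    if (checkRef && obs != spec$ref_base)
      stop(sprintf(
        "reference mismatch at %d: annotation has '%s', mutation says '%s'",
        spec$offset, obs, spec$ref_base))
    substr(acceptorSeq, pos, pos) <- spec$alt_base
  }
  list(donor = donorSeq, acceptor = acceptorSeq)
}

#' Interpret a splice-site point mutation against the splicing code
#'
#' Re-assigns the mutated intron to its most specific paired consensus and
#' compares the intron classes enriched for the wild-type and mutant motifs:
#' classes enriched only in the mutant (\code{gained}) predict the
#' alternative-splicing events the mutation induces. A mutant sequence that
#' matches no consensus on the table is itself informative (aberrant or
#' cryptic splicing expected); the 5' intron region is therefore also
#' scanned for cryptic donor candidates.
#'
#' @param donorSeq intron 5' sequence, lowercase RNA (at least as long as
#'   the donor motifs of interest; a longer region allows a wider cryptic
#'   scan). May also be an \code{\linkS4class{IntronSet}}, in which case
#'   \code{intron} selects the record and its donor/acceptor sequences are
#'   used.
#' @param acceptorSeq intron 3' sequence (ignored when \code{donorSeq} is an
#'   \code{IntronSet}).
#' @param spec parsed mutation from \code{parseIvsMutation} (or the string).
#' @param table a \code{\linkS4class{PairedConsensusTable}}.
#' @param code optional \code{\linkS4class{SplicingCodeTable}} for the
#'   enriched-class lookup (without it, class sets are empty).
#' @param intron index into the \code{IntronSet} (default 1).
#' @param crypticWindow bases of the donor-side sequence scanned for
#'   cryptic donor motifs (default 100, truncated to the available length).
#' @return a \code{\linkS4class{MutationReport}}.
#' @export
interpretMutation <- function(donorSeq, acceptorSeq = NULL, spec, table,
                              code = NULL, intron = 1L,
                              crypticWindow = 100L) {
  if (is(donorSeq, "IntronSet")) {
    acceptorSeq <- acceptorSeqs(donorSeq)[intron]
    donorSeq <- donorSeqs(donorSeq)[intron]
  }
  if (is.character(spec)) spec <- parseIvsMutation(spec)
  checkRnaAlphabet(c(donorSeq, acceptorSeq), "splice sequence")

  mut <- applyMutation(donorSeq, acceptorSeq, spec,
                       checkRef = spec$ref_base != spec$alt_base)
  wild <- assignMotif(donorSeq, acceptorSeq, table)
  mutant <- assignMotif(mut$donor, mut$acceptor, table)

  classesOf <- function(m) {
    if (is.null(m) || is.null(code)) character(0)
    else enrichedClasses(code, m$rank)
  }
  wildEnr <- classesOf(wild)
  mutEnr <- classesOf(mutant)
  cryptic <- crypticSiteScan(mut$donor, table,
                             window = min(crypticWindow, nchar(mut$donor)))
  new("MutationReport", spec = spec,
      wildMotif = wild, mutantMotif = mutant,
      wildEnriched = wildEnr, mutantEnriched = mutEnr,
      gained = setdiff(mutEnr, wildEnr), lost = setdiff(wildEnr, mutEnr),
      cryptic = cryptic)
}

#' Scan an intron 5' region for cryptic donor motifs
#'
#' Reports every position p in \code{[1, window]} (1 = the authentic donor
#' position) where the substring starting at p matches a donor motif of the
#' consensus table; the most specific (longest) donor motif is reported per
#' position. Acceptor-side scanning of the 3' region is available with
#' \code{side = "acceptor"} (positions then count from the 3' end, motif
#' ends at the reported position).
#'
#' @param intronSequence lowercase RNA string (5' region for donor scans).
#' @param table a \code{PairedConsensusTable}.
#' @param window number of start positions scanned (default 100; truncated
#'   to the sequence length).
#' @param side \code{"donor"} (default) or \code{"acceptor"}.
#' @return data.frame(position, motif), sorted by position.
#' @export
crypticSiteScan <- function(intronSequence, table, window = 100L,
                            side = c("donor", "acceptor")) {
  side <- match.arg(side)
  stopifnot(window <= nchar(intronSequence))
  m <- consensusMotifs(table)
  motifs <- if (side == "donor") sort(unique(m$donor)) else
    sort(unique(m$acceptor))
  motifs <- motifs[order(-nchar(motifs))]
  if (side == "acceptor") {
    ## scan for motif ends at positions counted from the 3' end
    intronSequence <- paste(rev(strsplit(intronSequence, "",
                                         fixed = TRUE)[[1]]), collapse = "")
    motifs <- vapply(strsplit(motifs, "", fixed = TRUE), function(ch)
      paste(rev(ch), collapse = ""), character(1))
  }
  pos <- integer(0)
  hit <- character(0)
  for (p in seq_len(window)) {
    for (mo in motifs) {
      if (p + nchar(mo) - 1L > nchar(intronSequence)) next
      if (substr(intronSequence, p, p + nchar(mo) - 1L) == mo) {
        pos <- c(pos, p)
        hit <- c(hit, if (side == "acceptor")
          paste(rev(strsplit(mo, "", fixed = TRUE)[[1]]), collapse = "")
          else mo)
        break
      }
    }
  }
  data.frame(position = pos, motif = hit, stringsAsFactors = FALSE)
}
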