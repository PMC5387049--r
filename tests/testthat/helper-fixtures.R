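## Shared helpers: tiny hand-built transcript models and brute-force oracles
## kept deliberately naive and independent of the package implementation.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
})

## A GRangesList gene from a list of exon coordinate matrices.
makeGene <- function(exonList, contig = "chr1", strand = "+",
                     gene = "g1") {
  grl <- GenomicRanges::GRangesList(lapply(exonList, function(m)
    GRanges(contig, IRanges(m[, 1], m[, 2]), strand = strand)))
  names(grl) <- paste0(gene, ".t", seq_along(exonList))
  S4Vectors::mcols(grl)$gene_id <- gene
  grl
}

## A one-contig genome of given length with fixed bases.
makeGenome <- function(seq, contig = "chr1") {
  DNAStringSet(setNames(toupper(chartr("u", "t", seq)), contig))
}

randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

## ---- brute-force oracles -------------------------------------------------

## Hypergeometric tails by direct combinatorial enumeration.
oracleHyperTails <- function(a, K, n, N) {
  ks <- max(0L, K + n - N):min(K, n)
  pmfs <- choose(n, ks) * choose(N - n, K - ks) / choose(N, K)
  c(up = sum(pmfs[ks >= a]), down = sum(pmfs[ks <= a]))
}

## Enumerate every prefix (or suffix) of a set of sequences with counts,
## conditional probabilities and child entropies, then apply the percentile
## selection rule; completely independent of the tree implementation.
oracleConservedMotifs <- function(seqs, direction, minCount = 100,
                                  probPct = 0.95, entPct = 0.05,
                                  maxDepth = 10) {
  piece <- function(s, d) {
    if (direction == "donor-prefix") substr(s, 1, d)
    else substr(s, nchar(s) - d + 1, nchar(s))
  }
  rows <- list()
  for (d in seq_len(min(maxDepth, max(nchar(seqs))))) {
    withLen <- seqs[nchar(seqs) >= d]
    for (p in unique(piece(withLen, d))) {
      cnt <- sum(piece(withLen, d) == p)
      parent <- if (d == 1) length(seqs) else {
        pp <- if (direction == "donor-prefix") substr(p, 1, d - 1) else
          substr(p, 2, d)
        withP <- seqs[nchar(seqs) >= (d - 1)]
        sum(piece(withP, d - 1) == pp)
      }
      kids <- seqs[nchar(seqs) >= d + 1]
      kids <- kids[piece(kids, d) == p]
      ent <- 0
      if (length(kids)) {
        kc <- table(piece(kids, d + 1))
        if (d + 1 <= maxDepth && length(kc) > 1) {
          pr <- kc / sum(kc)
          ent <- -sum(pr * log2(pr))
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        motif = p, depth = d, count = cnt, prob = cnt / parent,
        entropy = ent, stringsAsFactors = FALSE)
    }
  }
  df <- do.call(rbind, rows)
  elig <- df[df$count >= minCount, , drop = FALSE]
  if (!nrow(elig)) return(character(0))
  pThr <- quantile(elig$prob, probPct, type = 1, names = FALSE)
  eThr <- quantile(elig$entropy, entPct, type = 1, names = FALSE)
  kept <- elig[elig$prob >= pThr & elig$entropy <= eThr, , drop = FALSE]
  if (!nrow(kept)) return(character(0))
  isDesc <- function(long, short) {
    nchar(long) > nchar(short) &&
      (if (direction == "donor-prefix") startsWith(long, short)
       else endsWith(long, short))
  }
  deepest <- vapply(kept$motif, function(m)
    !any(vapply(kept$motif, isDesc, logical(1), short = m)), logical(1))
  sort(kept$motif[deepest])
}

## Exhaustive most-specific pair assignment (naive per-intron loop).
oracleAssign <- function(donor, acceptor, pairs) {
  out <- rep(NA_integer_, length(donor))
  for (i in seq_along(donor)) {
    best <- NA_integer_
    for (j in seq_len(nrow(pairs))) {
      if (startsWith(donor[i], pairs$donor[j]) &&
          endsWith(acceptor[i], pairs$acceptor[j])) {
        if (is.na(best)) best <- j
        else {
          better <-
            nchar(pairs$donor[j]) > nchar(pairs$donor[best]) ||
            (nchar(pairs$donor[j]) == nchar(pairs$donor[best]) &&
             nchar(pairs$acceptor[j]) > nchar(pairs$acceptor[best])) ||
            (nchar(pairs$donor[j]) == nchar(pairs$donor[best]) &&
             nchar(pairs$acceptor[j]) == nchar(pairs$acceptor[best]) &&
             j < best)
          if (better) best <- j
        }
      }
    }
    out[i] <- best
  }
  out
}

## Exhaustive best PWM window score.
oracleBestWindow <- function(seq, pwm) {
  L <- ncol(pwm)
  best <- -Inf
  for (p in seq_len(nchar(seq) - L + 1)) {
    w <- substr(seq, p, p + L - 1)
    ch <- strsplit(w, "")[[1]]
    sc <- sum(pwm[cbind(match(ch, c("a", "c", "g", "u")), seq_len(L))])
    if (sc > best) best <- sc
  }
  best
}

## Random noisy sequences around a motif (per-base substitution rate).
noisySeqs <- function(motif, n, noise, alphabet = c("a", "c", "g", "u")) {
  vapply(seq_len(n), function(i) {
    ch <- strsplit(motif, "")[[1]]
    flip <- runif(length(ch)) < noise
    ch[flip] <- sample(alphabet, sum(flip), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
}
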