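#' Build a position weight matrix in log2-odds
#'
#' From either a base-count matrix (4 x L, rows a/c/g/u) or a consensus
#' string. Counts are smoothed with a pseudocount and converted to
#' \code{log2((count + pseudocount) / colSum / background)} bits. A
#' consensus string is expanded to one-hot counts of weight
#' \code{consensusWeight}.
#'
#' @param x 4 x L numeric matrix with rownames a,c,g,u, or a consensus
#'   string over \{a,c,g,u\}.
#' @param pseudocount smoothing added to every cell (default 1).
#' @param background base frequencies, length 4 summing to 1 (default
#'   uniform).
#' @param consensusWeight count given to the consensus base when \code{x}
#'   is a string (default 10).
#' @return a 4 x L weight matrix (bits) with the background stored as an
#'   attribute.
#' @export
buildPwm <- function(x, pseudocount = 1, background = rep(0.25, 4),
                     consensusWeight = 10) {
  stopifnot(length(background) == 4, abs(sum(background) - 1) < 1e-8)
  if (is.character(x)) {
    checkRnaAlphabet(x, "consensus")
    ch <- strsplit(x, "", fixed = TRUE)[[1]]
    counts <- matrix(0, nrow = 4, ncol = length(ch),
                     dimnames = list(RNA_BASES, NULL))
    counts[cbind(match(ch, RNA_BASES), seq_along(ch))] <- consensusWeight
    x <- counts
  }
  stopifnot(is.matrix(x), nrow(x) == 4)
  if (is.null(rownames(x))) rownames(x) <- RNA_BASES
  x <- x[RNA_BASES, , drop = FALSE]
  if (ncol(x) < 4) stop("PWM must have length >= 4")
  sm <- x + pseudocount
  freq <- sweep(sm, 2, colSums(sm), "/")
  w <- log2(freq / background)
  if (any(!is.finite(w))) stop("PWM weights must be finite")
  attr(w, "background") <- background
  w
}

#' Default U12 branch-point PWM
#'
#' Built from the U12-type branch-point consensus \code{uuccuuaac} (branch
#' adenosine at position 8) with pseudocount 1 and a uniform background.
#' This is a documented default, not a matrix taken from any publication;
#' supply your own counts via \code{buildPwm}, \code{readPwmTsv} or
#' \code{readPwmMeme} for production scans.
#'
#' @return 4 x 9 log2-odds matrix.
#' @export
u12BranchPwm <- function() {
  buildPwm("uuccuuaac", pseudocount = 1, consensusWeight = 10)
}

#' Read a PWM from 4-column TSV or MEME minimal format
#'
#' \code{readPwmTsv}: a header line \code{a c g u} and one row per
#' position (counts or frequencies). \code{readPwmMeme}: the first
#' \code{letter-probability matrix} block of a MEME minimal motif file
#' (columns in A C G U/T order).
#'
#' @param path file path.
#' @param pseudocount,background passed to \code{buildPwm}.
#' @return log2-odds matrix.
#' @export
readPwmTsv <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  stopifnot(all(RNA_BASES %in% names(df)))
  buildPwm(t(as.matrix(df[, RNA_BASES])) * 100, pseudocount = pseudocount,
           background = background)
}

#' @rdname readPwmTsv
#' @export
readPwmMeme <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  lines <- readLines(path)
  i <- grep("^letter-probability matrix", lines)
  if (!length(i)) stop("no letter-probability matrix block found")
  w <- as.integer(sub(".*w=\\s*([0-9]+).*", "\\1", lines[i[1]]))
  block <- lines[(i[1] + 1L):(i[1] + w)]
  vals <- do.call(rbind, lapply(strsplit(trimws(block), "\\s+"), as.numeric))
  buildPwm(t(vals) * 100, pseudocount = pseudocount, background = background)
}

#' Score a sequence window against a PWM
#'
#' Sum over positions of the weight of the observed base; the window length
#' must equal the PWM length.
#'
#' @param sequenceWindow lowercase RNA string of length \code{ncol(pwm)}.
#' @param pwm log2-odds matrix from \code{buildPwm}.
#' @return score in bits.
#' @export
scorePwm <- function(sequenceWindow, pwm) {
  L <- ncol(pwm)
  if (nchar(sequenceWindow) != L)
    stop(sprintf("window length %d does not match PWM length %d",
                 nchar(sequenceWindow), L))
  ch <- strsplit(sequenceWindow, "", fixed = TRUE)[[1]]
  idx <- match(ch, RNA_BASES)
  if (anyNA(idx))
    stop("window contains symbols outside the PWM alphabet {a,c,g,u}")
  sum(pwm[cbind(idx, seq_len(L))])
}

## Best PWM window per sequence; returns score and 1-based start offset.
#' @keywords internal
bestWindowScores <- function(seqs, pwm) {
  L <- ncol(pwm)
  best <- rep(-Inf, length(seqs))
  bestAt <- rep(NA_integer_, length(seqs))
  chars <- strsplit(seqs, "", fixed = TRUE)
  for (i in seq_along(seqs)) {
    idx <- match(chars[[i]], RNA_BASES)
    n <- length(idx)
    if (n < L) stop("sequence shorter than the PWM")
    nOff <- n - L + 1L
    sc <- numeric(nOff)
    for (j in seq_len(L)) {
      b <- idx[seq_len(nOff) + j - 1L]
      w <- pwm[, j][b]
      w[is.na(w)] <- -Inf        # ambiguous base disqualifies the window
      sc <- sc + w
    }
    k <- which.max(sc)
    best[i] <- sc[k]
    bestAt[i] <- k
  }
  list(score = best, offset = bestAt)
}

#' Scan intron 3' regions for U12-type branch points
#'
#' Takes, per intron, the best-scoring PWM window within the last
#' \code{window} bases, computes the empirical distribution of best scores,
#' and flags introns whose best score reaches the
#' \code{1 - topFraction} quantile (ties at the threshold are kept). When
#' class labels are supplied, a per-class observed/expected summary is
#' attached, with expected = class share of introns x total hits.
#'
#' @param x character vector of intron 3' sequences (each at least PWM
#'   length), or an \code{\linkS4class{IntronSet}} plus \code{genome} from
#'   which the last \code{window} intron bases are extracted.
#' @param pwm log2-odds matrix from \code{buildPwm}.
#' @param window bases scanned at the 3' end (default 60).
#' @param topFraction fraction of best scores flagged (default 0.05).
#' @param classes optional class label per intron.
#' @param genome named \code{DNAStringSet}/character, required when \code{x}
#'   is an \code{IntronSet}.
#' @return list with \code{hits} (data.frame intron, best_score, position —
#'   window start relative to the 3' end, negative —, passes), \code{threshold},
#'   and \code{summary} (per class: n, observed, expected, ratio) when
#'   \code{classes} is given.
#' @export
scanBranchpoints <- function(x, pwm, window = 60L, topFraction = 0.05,
                             classes = NULL, genome = NULL) {
  if (is(x, "IntronSet")) {
    if (is.null(genome))
      stop("genome is required to extract 3' sequences from an IntronSet")
    genomeChar <- if (is.character(genome)) genome else
      setNames(as.character(genome), names(genome))
    gr <- intronRanges(x)
    if (is.null(classes)) classes <- intronClasses(x)
    w <- pmin(window, width(gr))
    plus <- as.character(strand(gr)) == "+"
    seqs <- character(length(gr))
    seqs[plus] <- senseSubseq(genomeChar,
                              as.character(seqnames(gr))[plus],
                              end(gr)[plus] - w[plus] + 1L, end(gr)[plus],
                              "+")
    seqs[!plus] <- senseSubseq(genomeChar,
                               as.character(seqnames(gr))[!plus],
                               start(gr)[!plus],
                               start(gr)[!plus] + w[!plus] - 1L, "-")
    ids <- intervalKey(as.character(seqnames(gr)),
                       as.character(strand(gr)), start(gr), end(gr))
  } else {
    seqs <- substr(x, pmax(1L, nchar(x) - window + 1L), nchar(x))
    ids <- if (is.null(names(x))) as.character(seq_along(x)) else names(x)
  }
  L <- ncol(pwm)
  bw <- bestWindowScores(seqs, pwm)
  threshold <- empiricalQuantile(bw$score, 1 - topFraction)
  passes <- bw$score >= threshold
  ## position of the best window start relative to the intron 3' end
  position <- -(nchar(seqs) - bw$offset + 1L)
  hits <- data.frame(intron = ids, best_score = bw$score,
                     position = position, passes = passes,
                     stringsAsFactors = FALSE)
  out <- list(hits = hits, threshold = threshold, summary = NULL)
  if (!is.null(classes)) {
    stopifnot(length(classes) == length(seqs))
    totalHits <- sum(passes)
    tab <- table(classes)
    obs <- vapply(names(tab), function(cl)
      sum(passes[classes == cl]), numeric(1))
    expd <- as.numeric(tab) / length(seqs) * totalHits
    out$summary <- data.frame(
      class = names(tab), n = as.integer(tab), observed = obs,
      expected = expd,
      ratio = ifelse(expd > 0, obs / expd, NA_real_),
      row.names = NULL, stringsAsFactors = FALSE)
  }
  out
}
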