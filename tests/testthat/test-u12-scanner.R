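test_that("PWM scores are the per-position weight sums", {
  pwm <- u12BranchPwm()
  ## the consensus attains the maximum possible score
  expect_equal(scorePwm("uuccuuaac", pwm), sum(apply(pwm, 2, max)),
               tolerance = 1e-12)
  ## a uniform PWM scores every window identically
  uni <- buildPwm(matrix(5, 4, 6, dimnames = list(c("a", "c", "g", "u"),
                                                  NULL)))
  expect_equal(scorePwm("aaaaaa", uni), scorePwm("gucgua", uni),
               tolerance = 1e-12)
  ## manual dot-product oracle on a random matrix
  set.seed(77)
  counts <- matrix(rpois(36, 5), 4, 9,
                   dimnames = list(c("a", "c", "g", "u"), NULL))
  p <- buildPwm(counts)
  w <- "uuccuuaac"
  ch <- strsplit(w, "")[[1]]
  manual <- sum(vapply(seq_len(9), function(i)
    p[ch[i], i], numeric(1)))
  expect_equal(scorePwm(w, p), manual, tolerance = 1e-12)
  expect_error(scorePwm("uucc", p), "length")
  expect_error(scorePwm("uuccuuaaX", p) , "alphabet")
})

test_that("best-window search equals exhaustive enumeration", {
  set.seed(4)
  pwm <- u12BranchPwm()
  seqs <- vapply(sample(60:200, 30, replace = TRUE), function(n)
    paste(sample(c("a", "c", "g", "u"), n, replace = TRUE), collapse = ""),
    character(1))
  res <- scanBranchpoints(seqs, pwm, window = 200)
  want <- vapply(seqs, oracleBestWindow, numeric(1), pwm = pwm)
  expect_equal(res$hits$best_score, unname(want), tolerance = 1e-10)
})

test_that("identical introns all tie at the threshold and are kept", {
  pwm <- u12BranchPwm()
  seqs <- rep(paste(rep("cugu", 15), collapse = ""), 40)
  res <- scanBranchpoints(seqs, pwm)
  expect_equal(length(unique(res$hits$best_score)), 1L)
  expect_true(all(res$hits$passes))
})

test_that("a planted branch point among random introns is flagged", {
  set.seed(10)
  mk <- function() paste(sample(c("a", "c", "g", "u"), 60, replace = TRUE,
                                prob = c(.2, .3, .2, .3)), collapse = "")
  seqs <- vapply(seq_len(999), function(i) mk(), character(1))
  planted <- mk()
  substr(planted, 30, 38) <- "uuccuuaac"
  seqs <- c(seqs, planted)
  res <- scanBranchpoints(seqs, u12BranchPwm(), topFraction = 0.05)
  expect_true(res$hits$passes[1000])
  expect_equal(res$hits$best_score[1000], sum(apply(u12BranchPwm(), 2,
                                                    max)),
               tolerance = 1e-10)
})

test_that("lowering the top fraction never increases the hit count", {
  set.seed(20)
  seqs <- vapply(seq_len(300), function(i)
    paste(sample(c("a", "c", "g", "u"), 60, replace = TRUE),
          collapse = ""), character(1))
  pwm <- u12BranchPwm()
  hits <- vapply(c(0.2, 0.1, 0.05, 0.01), function(f)
    sum(scanBranchpoints(seqs, pwm, topFraction = f)$hits$passes),
    numeric(1))
  expect_true(all(diff(hits) <= 0))
})

test_that("per-class expectations conserve the total hit count", {
  set.seed(30)
  seqs <- vapply(seq_len(400), function(i)
    paste(sample(c("a", "c", "g", "u"), 60, replace = TRUE),
          collapse = ""), character(1))
  classes <- sample(c("R-R", "S-S", "R-S"), 400, replace = TRUE)
  res <- scanBranchpoints(seqs, u12BranchPwm(), classes = classes)
  expect_equal(sum(res$summary$expected), sum(res$hits$passes),
               tolerance = 1e-9)
  expect_equal(sum(res$summary$observed), sum(res$hits$passes))
})

test_that("random hit placement gives observed/expected near unity", {
  set.seed(55)
  ratios <- replicate(20, {
    n <- 2000
    classes <- sample(c("R-R", "S-S"), n, replace = TRUE, prob = c(.7, .3))
    hits <- sample(n, 100)                # uniform placement
    obs <- vapply(c("R-R", "S-S"), function(cl)
      sum(classes[hits] == cl), numeric(1))
    expd <- table(classes)[c("R-R", "S-S")] / n * 100
    obs / as.numeric(expd)
  })
  expect_equal(mean(ratios), 1, tolerance = 0.1)
})

test_that("generator-planted U12 branch points score above background", {
  sim <- simulateGenome(simulationConfig(seed = 61, nGenes = 80))
  introns <- extractIntrons(sim$transcripts, sim$genome)
  res <- scanBranchpoints(introns, u12BranchPwm(), genome = sim$genome)
  tr <- sim$truth$introns
  gr <- intronRanges(introns)
  key <- paste(S4Vectors::mcols(gr)$gene_id, start(gr), end(gr))
  isU12 <- tr$group[match(key, paste(tr$gene_id, tr$start, tr$end))] ==
    "u12"
  ## every U12-group intron carries the exact consensus in its 3' window
  expect_true(all(res$hits$best_score[isU12] >=
                    max(res$hits$best_score[!isU12]) - 1e-9))
  expect_gt(mean(res$hits$passes[isU12]), mean(res$hits$passes[!isU12]))
})

test_that("PWMs read from TSV and MEME minimal agree with buildPwm", {
  counts <- matrix(c(8, 1, 1, 2, 1, 9, 1, 1, 2, 1, 7, 2, 1, 1, 2, 8,
                     3, 3, 3, 3), 4, 5,
                   dimnames = list(c("a", "c", "g", "u"), NULL))
  want <- buildPwm(counts * 10)
  freq <- sweep(counts, 2, colSums(counts), "/")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(a = freq[1, ], c = freq[2, ], g = freq[3, ],
                         u = freq[4, ]),
              tsv, sep = "\t", row.names = FALSE)
  got <- readPwmTsv(tsv)
  expect_equal(unclass(got), unclass(want), tolerance = 1e-2,
               ignore_attr = TRUE)
  meme <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("MEME version 4", "", "ALPHABET= ACGU", "",
               "MOTIF bp", "letter-probability matrix: alength= 4 w= 5",
               apply(freq, 2, function(col)
                 paste(sprintf("%.6f", col), collapse = " "))), meme)
  gotM <- readPwmMeme(meme)
  expect_equal(unclass(gotM), unclass(want), tolerance = 1e-2,
               ignore_attr = TRUE)
})
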