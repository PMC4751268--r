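# Anchoring, chaining, banded gap closure, SNP extraction and identity
# accounting.

test_that("identical sequences give a single full-length forward anchor", {
  s <- rdna(5000, seed = 1)
  a <- find_anchors(s, s, k = 20)
  expect_equal(nrow(a), 1)
  expect_equal(a$posA, 0)
  expect_equal(a$posB, 0)
  expect_equal(a$length, 5000)
  expect_equal(a$orientation, "forward")
})

test_that("a reverse-complemented genome gives a single reverse anchor", {
  s <- rdna(5000, seed = 2)
  a <- find_anchors(s, revcomp_chr(s), k = 20)
  expect_equal(nrow(a), 1)
  expect_equal(a$orientation, "reverse")
  expect_equal(a$length, 5000)
})

test_that("anchors avoid multi-copy sequence via k-mer uniqueness", {
  rep1 <- rdna(800, seed = 3)
  uA <- rdna(2000, seed = 4); uB <- rdna(2000, seed = 5)
  s <- paste0(uA, rep1, uB, rep1, rdna(2000, seed = 6))
  a <- find_anchors(s, s, k = 20)
  # self-alignment: one anchor spanning everything is expected (identical),
  # but no anchor may pair the two repeat copies
  off_diag <- a[a$posA != a$posB, ]
  expect_equal(nrow(off_diag), 0)
})

# brute-force maximum-weight collinear chain for small anchor sets
brute_chain <- function(anch) {
  n <- nrow(anch)
  best_w <- -1; best <- integer(0)
  for (mask in seq_len(2^n) - 1) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < 1) next
    pa <- anch$posA[idx]; pb <- anch$posB[idx]
    if (all(diff(pa) > 0) && all(diff(pb) > 0)) {
      w <- sum(anch$length[idx])
      if (w > best_w) { best_w <- w; best <- idx }
    }
  }
  best_w
}

test_that("chaining matches brute force on small anchor sets", {
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(5:13, 1)
    anch <- data.frame(posA = sort(sample(0:5000, n)),
                       posB = sample(0:5000, n),
                       length = sample(20:200, n, replace = TRUE),
                       orientation = "forward", stringsAsFactors = FALSE)
    attr(anch, "lenA") <- 6000; attr(anch, "lenB") <- 6000
    ch <- chain_anchors(anch, min_weight = 1)
    got <- max(vapply(ch, function(x) sum(x$length), 0))
    expect_equal(got, brute_chain(anch))
  }
})

test_that("one off-diagonal anchor among collinear anchors is discarded", {
  anch <- data.frame(posA = seq(0, 9900, by = 100),
                     posB = seq(0, 9900, by = 100),
                     length = 50, orientation = "forward",
                     stringsAsFactors = FALSE)
  anch$posB[50] <- 20  # conflicts with the diagonal
  attr(anch, "lenA") <- 10000; attr(anch, "lenB") <- 10000
  ch <- chain_anchors(anch, min_weight = 40)
  expect_length(ch, 1)
  expect_equal(nrow(ch[[1]]), 99)
})

test_that("a planted inversion produces chains of opposite orientation", {
  p <- derive_sisters(small_ancestor(), mutation_spec(inversions = "rrn",
                                                      seed = 9))
  a <- find_anchors(p$A$seq, p$B$seq)
  ch <- chain_anchors(a)
  oris <- vapply(ch, function(x) attr(x, "orientation"), "")
  expect_true("forward" %in% oris && "reverse" %in% oris)
  # the reverse chain sits at the planted segment; breakpoints are only
  # defined up to the mediating repeat (anchors extend through identical
  # repeat copies), so allow half the 4 kb operon length of slop
  ev <- p$truth$events
  rev_ch <- ch[[which(oris == "reverse")[1]]]
  expect_gte(min(rev_ch$posB), ev$posB - 2100)
  expect_lte(max(rev_ch$posB + rev_ch$length), ev$posB + ev$length + 2100)
})

test_that("banded gap closure equals full dynamic programming", {
  set.seed(21)
  submat <- Biostrings::nucleotideSubstitutionMatrix(1, -1)
  for (i in 1:30) {
    a <- rdna(sample(100:2000, 1))
    b <- mutate_dna(a, nsub = sample(0:15, 1), nindel = sample(0:3, 1))
    got <- sistercomp:::cpp_banded_global(a, b, 200L)$score
    oracle <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
      substitutionMatrix = submat, gapOpening = 0, gapExtension = 2,
      scoreOnly = TRUE)
    expect_equal(got, oracle)
  }
})

test_that("substitution-only sisters give one block and the exact SNP set", {
  p <- sub_pair()
  aln <- aligned_sub_pair()
  expect_length(aln$blocks, 1)
  expect_equal(nrow(aln$unaligned), 0)
  sn <- call_snps(aln)
  expect_setequal(snp_key(sn), snp_key(p$truth$snps))
  # every genome position in at most one block
  iv <- t(vapply(aln$blocks, function(b) b$intervalA, c(0, 0)))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  if (nrow(iv) > 1) expect_true(all(iv[-1, 1] >= iv[-nrow(iv), 2]))
})

test_that("alignment is symmetric in match counts", {
  p <- sub_pair()
  ab <- aligned_sub_pair()
  ba <- align_genomes(p$B, p$A)
  expect_equal(identity_report(ab, mode = "core")$matches,
               identity_report(ba, mode = "core")$matches)
  expect_equal(identity_report(ab, mode = "core")$pct,
               identity_report(ba, mode = "core")$pct)
})

test_that("N columns are excluded from SNP calls and counted", {
  a <- rdna(3000, seed = 31)
  b <- a
  substr(b, 1501, 1501) <- "N"
  substr(b, 1601, 1601) <- switch(substr(a, 1601, 1601),
                                  A = "G", G = "A", C = "T", T = "C")
  aln <- align_genomes(a, b)
  sn <- call_snps(aln)
  expect_equal(nrow(sn), 1)
  expect_equal(sn$posA, 1600)
  expect_equal(attr(sn, "n_excluded"), 1)
})

test_that("identity arithmetic follows the two denominator conventions", {
  s <- rdna(4000, seed = 41)
  aln <- align_genomes(s, s)
  expect_equal(identity_report(aln, mode = "core")$pct, 100)
  expect_equal(identity_report(aln, mode = "whole")$pct, 100)

  b <- alignment_block(c(0, 10), c(0, 10), "forward",
                       data.frame(type = c("M", "X", "M"),
                                  length = c(5L, 1L, 4L),
                                  basesA = c("", "A", ""),
                                  basesB = c("", "G", ""),
                                  stringsAsFactors = FALSE))
  expect_equal(identity_report(list(b), mode = "core")$pct, 90)
  expect_error(identity_report(list(), mode = "core"), "empty")
})

test_that("a large planted island becomes an exact unaligned segment", {
  anc <- small_ancestor()
  p <- derive_sisters(anc, mutation_spec(
    snps = list(genome = list(n = 80, nonsyn_fraction = 0.5)),
    islands = list(list(length = 12000, gc = 0.40, strain = "A")),
    seed = 31))
  aln <- align_genomes(p$A, p$B)
  ins <- aln$unaligned[aln$unaligned$reason == "strain_specific_insertion", ]
  expect_equal(nrow(ins), 1)
  expect_equal(ins$genome, "A")
  expect_equal(ins$end - ins$start, 12000)
  expect_lt(identity_report(aln, mode = "whole")$pct,
            identity_report(aln, mode = "core")$pct)
})
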