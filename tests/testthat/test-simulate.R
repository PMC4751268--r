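# The synthetic sister-genome generator: determinism, planted structure and
# the exactness of planted mutation counts.

test_that("ancestor carries the requested elements and is deterministic", {
  g <- small_ancestor()
  f <- g$features
  expect_equal(sum(grepl("^IS1_c", f$locus_tag)), 9)
  expect_equal(sum(grepl("^IS2_c", f$locus_tag)), 2)
  expect_equal(sum(grepl("^IS3_c", f$locus_tag)), 1)
  rr <- f[f$ftype == "rRNA", ]
  expect_equal(nrow(rr), 3)
  expect_equal(sum(rr$strand == "-"), 1)
  expect_true(any(grepl("rdhA-like", f$product)))
  g2 <- simulate_ancestor(n_genes = 40, seed = 5,
                          is_copy_counts = c(IS1 = 9L, IS2 = 2L, IS3 = 1L))
  expect_identical(g2$seq, g$seq)
  expect_identical(g2$features, g$features)
})

test_that("IS copies are exact copies (inverted copy reverse-complemented)", {
  g <- small_ancestor()
  el <- g$meta$is_elements$IS2
  f <- g$features[grepl("^IS2_c", g$features$locus_tag), ]
  for (i in seq_len(nrow(f))) {
    s <- substr(g$seq, f$start[i] + 1, f$end[i])
    if (f$strand[i] == "-") s <- revcomp_chr(s)
    expect_identical(s, el)
  }
})

test_that("zero-mutation spec returns the ancestor twice with empty truth", {
  anc <- small_ancestor()
  p <- derive_sisters(anc, mutation_spec(seed = 1))
  expect_identical(p$A$seq, anc$seq)
  expect_identical(p$B$seq, anc$seq)
  expect_equal(nrow(p$truth$snps), 0)
  expect_equal(nrow(p$truth$events), 0)
})

test_that("planted SNP counts and non-synonymous fractions are exact", {
  anc <- small_ancestor()
  rg <- local({
    cds <- anc$features[anc$features$ftype == "CDS", ]
    c(cds$start[5], cds$end[12])
  })
  p <- derive_sisters(anc, mutation_spec(
    regions = list(hotspot = rg),
    snps = list(hotspot = list(n = 70, nonsyn_fraction = 67 / 70),
                genome = list(n = 25, nonsyn_fraction = 7 / 25)),
    seed = 23))
  tr <- p$truth$snps
  hs <- tr[tr$region == "hotspot", ]
  bg <- tr[tr$region == "genome", ]
  expect_equal(nrow(hs), 70)
  expect_equal(sum(hs$class == "nonsynonymous"), 67)
  expect_equal(nrow(bg), 25)
  expect_equal(sum(bg$class == "nonsynonymous"), 7)
  expect_true(all(hs$posA >= rg[1] & hs$posA < rg[2]))
})

test_that("planted classes agree with independent whole-CDS translation", {
  p <- sub_pair()
  anc <- small_ancestor()
  tr <- p$truth$snps
  cds <- anc$features[anc$features$ftype == "CDS", ]
  code <- Biostrings::getGeneticCode("11")
  for (i in sample(nrow(tr), 40)) {
    row <- cds[cds$locus_tag == tr$locus_tag[i], ]
    ntA <- substr(p$A$seq, row$start + 1, row$end)
    ntB <- substr(p$B$seq, row$start + 1, row$end)
    if (row$strand == "-") { ntA <- revcomp_chr(ntA); ntB <- revcomp_chr(ntB) }
    aaA <- as.character(Biostrings::translate(Biostrings::DNAString(ntA),
                                              genetic.code = code))
    aaB <- as.character(Biostrings::translate(Biostrings::DNAString(ntB),
                                              genetic.code = code))
    # CDS may carry several SNPs; the planted class concerns this one site
    expect_equal(tr$class[i] == "synonymous",
                 {
                   offA <- if (row$strand == "+") tr$posA[i] - row$start
                     else row$end - 1 - tr$posA[i]
                   ci <- offA %/% 3
                   substr(aaA, ci + 1, ci + 1) == substr(aaB, ci + 1, ci + 1)
                 })
  }
})

test_that("planted inversion yields the reverse complement in the sister", {
  anc <- small_ancestor()
  p <- derive_sisters(anc, mutation_spec(inversions = "rrn", seed = 9))
  ev <- p$truth$events
  expect_equal(ev$type, "inversion")
  i <- ev$posB; j <- ev$posB + ev$length
  segB <- substr(p$B$seq, i + 1, j)
  segA <- substr(p$A$seq, i + 1, j)  # A untouched, same coordinates
  expect_identical(segB, revcomp_chr(segA))
  expect_identical(p$B$seq, {
    g <- apply_inversion(p$A, i, j); g$seq
  })
})

test_that("island insertions hit their specified GC within tolerance", {
  anc <- small_ancestor()
  p <- derive_sisters(anc, mutation_spec(
    islands = list(list(length = 6000, gc = 0.35, strain = "A")), seed = 3))
  ev <- p$truth$events
  isl <- substr(p$A$seq, ev$posA - ev$length + 1, ev$posA)
  gc <- mean(strsplit(isl, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc - 0.35), 0.02)
  expect_equal(nchar(p$A$seq), nchar(anc$seq) + 6000)
  expect_equal(nchar(p$B$seq), nchar(anc$seq))
})

test_that("infeasible specs are rejected", {
  anc <- small_ancestor()
  # a region without CDSs cannot receive coding SNPs
  inter <- c(0, 50)
  expect_error(derive_sisters(anc, mutation_spec(
    regions = list(bad = inter),
    snps = list(bad = list(n = 5, nonsyn_fraction = 1)), seed = 1)),
    "no CDS")
  expect_error(mutation_spec(snps = list(g = list(n = 5, nonsyn_fraction = 2))))
})

test_that("fixtures round-trip and are byte-identical across identical seeds", {
  anc <- small_ancestor()
  spec <- mutation_spec(snps = list(genome = list(n = 40,
                                                  nonsyn_fraction = 0.5)),
                        seed = 12)
  p <- derive_sisters(anc, spec)
  p$spec <- spec
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_fixture(p, file.path(d1, "fx"))
  expect_error(write_fixture(p, file.path(d1, "fx")), "not empty")
  p2 <- derive_sisters(anc, spec)
  p2$spec <- spec
  write_fixture(p2, file.path(d2, "fx"))
  f1 <- list.files(file.path(d1, "fx"), full.names = TRUE)
  f2 <- list.files(file.path(d2, "fx"), full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  for (i in seq_along(f1))
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  fx <- read_fixture(file.path(d1, "fx"))
  expect_identical(fx$A$seq, p$A$seq)
  expect_identical(fx$B$seq, p$B$seq)
  expect_equal(nrow(fx$truth$snps), nrow(p$truth$snps))
})

test_that("proteome pair generator plants orthologs and decoys", {
  pp <- simulate_proteome_pair(n = 30, decoy_fraction = 0.1, seed = 4)
  expect_length(pp$A, 30)
  expect_length(pp$B, 33)
  expect_equal(nrow(pp$map), 30)
  pp2 <- simulate_proteome_pair(n = 30, decoy_fraction = 0.1, seed = 4)
  expect_identical(pp, pp2)
})

test_that("skewed-genome generator places opposite-signed arms and repeats", {
  g <- simulate_skewed_genome(length = 60000, skew = 0.15, seed = 8,
                              repeat_positions = list(c(10000, 40000)))
  prof <- gc_skew(g, 1000, 500)
  first_arm <- prof$skew[prof$pos < 25000]
  second_arm <- prof$skew[prof$pos > 35000 & prof$pos < 55000]
  expect_gt(mean(first_arm), 0.05)
  expect_lt(mean(second_arm), -0.05)
  rp <- g$meta$repeat_pairs
  seg1 <- substr(g$seq, rp$startA + 1, rp$endA)
  seg2 <- substr(g$seq, rp$startB + 1, rp$endB)
  expect_identical(seg2, revcomp_chr(seg1))
})
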