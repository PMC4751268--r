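# Codon-aware SNP classification, regional summaries and gene-pair metrics.

# build a tiny annotated genome with one CDS per strand
toy_two_cds <- function() {
  cds1 <- "ATGAAATGGCTGTAA"             # + strand at 10
  cds2 <- "ATGCCCAAAGGGTAA"             # - strand at 40
  seq <- paste0(rdna(10, seed = 1), cds1, rdna(15, seed = 2),
                revcomp_chr(cds2), rdna(10, seed = 3))
  feats <- data.frame(
    locus_tag = c("p1", "m1"), ftype = "CDS",
    start = c(10L, 40L), end = c(25L, 55L), strand = c("+", "-"),
    product = "x", translation = NA_character_, pseudo = FALSE,
    codon_ok = TRUE, broken = FALSE, stringsAsFactors = FALSE)
  genome_record("toy", seq, topology = "linear", features = feats)
}

mk_snp <- function(posA, baseA, baseB) {
  data.frame(posA = posA, posB = posA, baseA = baseA, baseB = baseB,
             orientation = "forward", stringsAsFactors = FALSE)
}

test_that("canonical codon changes classify per the genetic code", {
  g <- toy_two_cds()
  # codon 2 of p1 is AAA (positions 13-15); AAA->AAG synonymous (K)
  r <- classify_snp(mk_snp(15, "A", "G"), g)
  expect_equal(r$klass, "synonymous")
  expect_equal(r$codonA, "AAA"); expect_equal(r$codonB, "AAG")
  expect_equal(r$aaA, "K"); expect_equal(r$aaB, "K")
  # AAA->GAA non-synonymous (K->E)
  r <- classify_snp(mk_snp(13, "A", "G"), g)
  expect_equal(r$klass, "nonsynonymous")
  expect_equal(r$aaB, "E")
  # codon 3 TGG->TGA nonsense (W->*)
  r <- classify_snp(mk_snp(18, "G", "A"), g)
  expect_equal(r$codonA, "TGG"); expect_equal(r$codonB, "TGA")
  expect_equal(r$klass, "nonsense")
})

test_that("minus-strand classification equals the reverse-complement frame", {
  g <- toy_two_cds()
  # m1 codon 2 is CCC (cds offsets 3-5); genome positions 49..51 on '-'
  # cds offset 3 -> genome pos end-1-3 = 51; C on cds = G on genome fwd
  r <- classify_snp(mk_snp(51, "G", "C"), g)  # cds C->G: CCC->GCC (P->A)
  expect_equal(r$locus_tag, "m1")
  expect_equal(r$codonA, "CCC")
  expect_equal(r$klass, "nonsynonymous")
  r <- classify_snp(mk_snp(49, "G", "A"), g)  # cds C->T: CCC->CCT (P->P)
  expect_equal(r$klass, "synonymous")
})

test_that("intergenic and multi-hit codons get their own classes", {
  g <- toy_two_cds()
  r <- classify_snp(mk_snp(2, "A", "G"), g)
  expect_true(r$klass %in% c("intergenic"))
  # two SNPs in the same codon
  sn <- rbind(mk_snp(13, "A", "G"), mk_snp(14, "A", "C"))
  sn$baseA <- c(substr(g$seq, 14, 14), substr(g$seq, 15, 15))
  r <- classify_snps(sn, g)
  expect_true(all(r$klass == "multi_hit_codon"))
})

test_that("classification agrees with whole-CDS translation on planted SNPs", {
  p <- sub_pair()
  aln <- aligned_sub_pair()
  cl <- classify_snps(call_snps(aln), p$A)
  tr <- p$truth$snps
  m <- merge(cl, tr, by = c("posA", "posB"))
  expect_equal(nrow(m), nrow(tr))
  single <- !m$klass %in% "multi_hit_codon"
  expect_true(all(m$klass[single] == m$class[single]))
})

test_that("strand invariance: classes survive reverse-complementing the frame", {
  p <- sub_pair()
  cl <- classify_snps(call_snps(aligned_sub_pair()), p$A)
  minus <- cl[!is.na(cl$locus_tag), ]
  strands <- p$A$features$strand[match(minus$locus_tag,
                                       p$A$features$locus_tag)]
  # classes on '-' CDSs agree with the planted oracle just as '+' ones do
  tr <- p$truth$snps
  m <- merge(minus, tr, by = c("posA", "posB"))
  for (s in c("+", "-")) {
    idx <- strands[match(m$posA, minus$posA)] == s
    expect_true(all(m$klass[idx] == m$class[idx]))
  }
})

test_that("region summaries count exactly and conserve totals", {
  g <- toy_two_cds()
  # distinct codons: pos 15 (codon 1, syn), pos 19 (codon 3, nonsyn),
  # pos 18 (codon 2, nonsense), pos 2 (intergenic)
  sn <- rbind(mk_snp(15, "A", "G"), mk_snp(19, "C", "G"),
              mk_snp(18, "G", "A"), mk_snp(2, substr(g$seq, 3, 3), "G"))
  cl <- classify_snps(sn, g)
  rs <- region_summary(cl, c(0, 60))
  expect_equal(rs$n_snps, 4)
  expect_equal(rs$n_syn, 1)
  expect_equal(rs$n_nonsyn, 1)
  expect_equal(rs$n_other, 2)  # nonsense + intergenic
  rs2 <- region_summary(cl, c(0, 60), fold_nonsense = TRUE)
  expect_equal(rs2$n_nonsyn, 2)
  expect_equal(rs2$n_snps, rs2$n_syn + rs2$n_nonsyn + rs2$n_other)
  # empty region
  rs0 <- region_summary(cl, c(58, 60))
  expect_equal(unlist(rs0[, c("n_snps", "n_syn", "n_nonsyn", "n_other")]),
               c(n_snps = 0L, n_syn = 0L, n_nonsyn = 0L, n_other = 0L))
})

test_that("locus-pair regions span the two loci inclusively", {
  g <- toy_two_cds()
  sn <- mk_snp(15, "A", "G")
  cl <- classify_snps(sn, g)
  rs <- region_summary(cl, c("p1", "m1"), genomeA = g)
  expect_equal(rs$start, 10)
  expect_equal(rs$end, 55)
  expect_equal(rs$n_snps, 1)
  expect_error(region_summary(cl, c("p1", "nope"), genomeA = g), "unknown locus")
})

test_that("hotspot fixture reproduces the planted regional signal", {
  anc <- small_ancestor()
  cds <- anc$features[anc$features$ftype == "CDS", ]
  rg <- c(cds$start[5], cds$end[12])
  p <- derive_sisters(anc, mutation_spec(
    regions = list(hotspot = rg),
    snps = list(hotspot = list(n = 70, nonsyn_fraction = 67 / 70)),
    seed = 23))
  cl <- classify_snps(call_snps(align_genomes(p$A, p$B)), p$A)
  rs <- region_summary(cl, rg, label = "hotspot")
  expect_equal(rs$n_snps, 70)
  expect_equal(rs$n_nonsyn, 67)
  expect_equal(rs$n_syn, 3)
})

test_that("gene pair differences: identity, planted substitutions, errors", {
  set.seed(71)
  codons <- as.vector(outer(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                  paste0), c("A", "C", "G", "T"), paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  nt <- paste0("ATG", paste(sample(codons, 100, replace = TRUE),
                            collapse = ""), "TAA")
  d <- gene_pair_diff(nt, nt)
  expect_equal(d$nt_diffs, 0)
  expect_equal(d$aa_diffs, 0)
  expect_equal(d$nt_pct_id, 100)
  expect_equal(d$aa_pct_id, 100)

  # plant substitutions with a known positionwise answer
  v <- strsplit(nt, "")[[1]]
  at <- c(10, 50, 100, 150, 200, 250)
  v[at] <- vapply(v[at], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  nt2 <- paste(v, collapse = "")
  pos_diffs <- sum(strsplit(nt, "")[[1]] != v)
  d <- gene_pair_diff(nt, nt2)
  expect_equal(d$nt_diffs, pos_diffs)
  code <- Biostrings::getGeneticCode("11")
  aa1 <- as.character(Biostrings::translate(Biostrings::DNAString(nt),
                                            genetic.code = code))
  aa2 <- as.character(Biostrings::translate(Biostrings::DNAString(nt2),
                                            genetic.code = code))
  expect_equal(d$aa_diffs,
               sum(strsplit(aa1, "")[[1]] != strsplit(aa2, "")[[1]]))
  expect_error(gene_pair_diff("", nt), "empty")
})

test_that("marker comparison masks long one-sided insertions", {
  base <- rdna(1500, seed = 61)
  with_ins <- paste0(substr(base, 1, 80), rdna(100, seed = 62),
                     substr(base, 81, 1500))
  v <- strsplit(base, "")[[1]]
  v[c(300, 700, 1100)] <- vapply(v[c(300, 700, 1100)], function(x)
    setdiff(c("A", "C", "G", "T"), x)[1], "")
  mutated <- paste(v, collapse = "")

  m0 <- compare_marker_genes(c(a = base, b = base))
  expect_equal(m0["a", "b"], 0)
  m1 <- compare_marker_genes(c(a = base, b = with_ins),
                             mask_insertions = TRUE)
  expect_equal(m1["a", "b"], 0)
  m2 <- compare_marker_genes(c(a = base, b = with_ins),
                             mask_insertions = FALSE)
  expect_equal(m2["a", "b"], 100)
  m3 <- compare_marker_genes(c(a = base, b = mutated))
  expect_equal(m3["a", "b"], 3)
})

test_that("VCF output carries class annotations", {
  g <- toy_two_cds()
  cl <- classify_snps(mk_snp(15, "A", "G"), g)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_snps_vcf(cl, g, f)
  lines <- readLines(f)
  expect_true(any(grepl("CLASS=synonymous", lines)))
  expect_true(any(grepl("^##fileformat=VCF", lines)))
})
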