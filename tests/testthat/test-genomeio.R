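# Format readers/writers and the shared genome data model.

test_that("FASTA reading normalizes case and ambiguity codes", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g", "ACGT"), f)
  g <- read_fasta(f)
  expect_length(g, 1)
  expect_equal(g[[1]]$id, "g")
  expect_equal(g[[1]]$seq, "ACGT")

  writeLines(c(">g", "acgt"), f)
  expect_equal(read_fasta(f)[[1]]$seq, "ACGT")

  writeLines(c(">g", "ACRT"), f)
  expect_warning(g <- read_fasta(f), "1 non-ACGTN")
  expect_equal(g[[1]]$seq, "ACNT")
})

test_that("FASTA errors: empty file, duplicate ids", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "format error")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), f)
  expect_error(read_fasta(f), "duplicate.*a")
})

toy_genbank <- function(extra_feat = character()) {
  c("LOCUS       toy 30 bp    DNA     circular   BCT",
    "FEATURES             Location/Qualifiers",
    "     CDS             10..18",
    "                     /locus_tag=\"c1\"",
    "     CDS             complement(4..12)",
    "                     /locus_tag=\"c2\"",
    extra_feat,
    "ORIGIN",
    "        1 atgaaatgaa tgaaatgaaa tgaaatgaaa",
    "//")
}

test_that("GenBank coordinates convert to 0-based half-open", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(toy_genbank(), f)
  g <- read_genbank(f)
  expect_equal(g$topology, "circular")
  expect_equal(nchar(g$seq), 30)
  c1 <- g$features[g$features$locus_tag == "c1", ]
  expect_equal(c(c1$start, c1$end), c(9, 18))
  expect_equal(c1$strand, "+")
  c2 <- g$features[g$features$locus_tag == "c2", ]
  expect_equal(c(c2$start, c2$end), c(3, 12))
  expect_equal(c2$strand, "-")
})

test_that("GenBank compound locations are kept but excluded from codon analyses", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(toy_genbank(c("     CDS             join(1..6,10..15)",
                           "                     /locus_tag=\"cj\"")), f)
  g <- read_genbank(f)
  cj <- g$features[g$features$locus_tag == "cj", ]
  expect_false(cj$codon_ok)
  expect_equal(c(cj$start, cj$end), c(0, 15))
})

test_that("GenBank structural errors are reported", {
  f <- withr::local_tempfile(fileext = ".gbk")
  writeLines(c("LOCUS       toy 30 bp DNA linear BCT",
               "FEATURES             Location/Qualifiers"), f)
  expect_error(read_genbank(f), "ORIGIN")
  writeLines(toy_genbank(c("     CDS             10..99",
                           "                     /locus_tag=\"far\"")), f)
  expect_error(read_genbank(f), "beyond sequence end")
})

test_that("GenBank round-trip preserves feature intervals", {
  g <- small_ancestor()
  f <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g, f)
  g2 <- read_genbank(f)
  expect_identical(g2$seq, g$seq)
  expect_identical(g2$features[, c("locus_tag", "start", "end", "strand")],
                   g$features[, c("locus_tag", "start", "end", "strand")])
  # byte-stable writer
  f2 <- withr::local_tempfile(fileext = ".gbk")
  write_genbank(g2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("GFF3 reading: coordinates, phase flag, synthetic locus tags", {
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">g", strrep("ACGT", 10)), fa)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "g\tx\tCDS\t4\t12\t.\t-\t0\tID=f1;locus_tag=f1",
               "g\tx\tCDS\t13\t21\t.\t+\t1\tID=f2;locus_tag=f2",
               "g\tx\tCDS\t22\t30\t.\t+\t0\tID=noname"), gff)
  expect_warning(g <- read_gff3(gff, fa), NA)  # ID fallback, no warning
  f1 <- g$features[g$features$locus_tag == "f1", ]
  expect_equal(c(f1$start, f1$end), c(3, 12))
  expect_equal(f1$strand, "-")
  expect_false(g$features$codon_ok[g$features$locus_tag == "f2"])
  expect_true("noname" %in% g$features$locus_tag)
})

test_that("GFF3 round-trip preserves the feature table", {
  g <- small_ancestor()
  d <- withr::local_tempdir()
  write_gff3(g, file.path(d, "a.gff3"))
  write_fasta(g, file.path(d, "a.fasta"))
  g2 <- read_gff3(file.path(d, "a.gff3"), file.path(d, "a.fasta"))
  expect_identical(g2$features[, c("locus_tag", "start", "end", "strand")],
                   g$features[, c("locus_tag", "start", "end", "strand")])
})

test_that("XMFA: minimal blocks, gap columns, round-trip, track-count guard", {
  f <- withr::local_tempfile(fileext = ".xmfa")
  writeLines(c("> a:1-10 + x", "ACGTACGTAC", "> b:1-10 + x", "ACGTACGTAC",
               "="), f)
  bl <- read_xmfa(f)
  expect_length(bl, 1)
  expect_equal(bl[[1]]$edits$type, "M")
  expect_equal(bl[[1]]$intervalA, c(0, 10))

  writeLines(c("> a:1-11 + x", "ACGTTACGTAC", "> b:1-10 + x", "ACG-TACGTAC",
               "="), f)
  bl <- read_xmfa(f)
  expect_true("IA" %in% bl[[1]]$edits$type)
  expect_equal(sum(bl[[1]]$edits$length[bl[[1]]$edits$type == "IA"]), 1)

  writeLines(c("> a:1-4 + x", "ACGT", "> b:1-4 + x", "ACGT",
               "> c:1-4 + x", "ACGT", "="), f)
  expect_error(read_xmfa(f), "pairwise")

  p <- sub_pair()
  aln <- aligned_sub_pair()
  f2 <- withr::local_tempfile(fileext = ".xmfa")
  write_xmfa(aln$blocks, p$A, p$B, f2)
  bl2 <- read_xmfa(f2)
  expect_identical(lapply(bl2, function(b) b[c("intervalA", "intervalB", "edits")]),
                   lapply(aln$blocks, function(b) b[c("intervalA", "intervalB", "edits")]))
})

test_that("12-column tabular hits parse strictly", {
  f <- withr::local_tempfile()
  writeLines("a\tb\t100.0\t50\t0\t0\t1\t50\t1\t50\t1e-30\t100", f)
  h <- read_search_tab(f)
  expect_equal(h$evalue, 1e-30)
  expect_equal(h$subject, "b")

  writeLines(character(0), f)
  expect_equal(nrow(read_search_tab(f)), 0)

  writeLines("a\tb\t100.0\t50", f)
  expect_error(read_search_tab(f), "line 1")

  writeLines("a\tb\t100.0\t50\t0\t0\t1\t50\t1\t50\t0.0\t100", f)
  h <- read_search_tab(f)
  expect_identical(h$evalue, 0)
  expect_true(h$evalue <= 1e-10)  # zero passes any cutoff
})

test_that("pfam_scan tables parse with comments and strict rows", {
  f <- withr::local_tempfile()
  writeLines(c("# comment line",
               "X 5 100 4 101 PF00027.29 cNMP_binding Domain 1 91 91 70.2 1e-10",
               "Y 5 100 4 101 PF13463.6 HTH_Crp_2 Domain 1 70 70 50.1 2.2e-08"),
             f)
  h <- read_domtab(f)
  expect_equal(nrow(h), 2)
  expect_equal(h$domain_name, c("cNMP_binding", "HTH_Crp_2"))
  expect_equal(h$env_start, c(3L, 3L))  # 1-based inclusive -> 0-based half-open
  expect_equal(h$evalue[1], 1e-10)

  writeLines(c("X 5 100 4"), f)
  expect_error(read_domtab(f), "line 1")

  # round trip through the writer
  f2 <- withr::local_tempfile()
  writeLines(c("X 5 100 4 101 PF00027.29 cNMP_binding Domain 1 91 91 70.2 1e-10"), f)
  h <- read_domtab(f)
  write_domtab(h, f2)
  expect_equal(read_domtab(f2)[, c("locus_tag", "domain_name", "evalue")],
               h[, c("locus_tag", "domain_name", "evalue")])
})

test_that("stored CDS translations match strand-aware re-translation", {
  g <- small_ancestor()
  prot <- extract_proteome(g)
  cds <- g$features[g$features$ftype == "CDS", ]
  for (i in sample(nrow(cds), 10)) {
    nt <- if (cds$strand[i] == "+")
      substr(g$seq, cds$start[i] + 1, cds$end[i])
    else revcomp_chr(substr(g$seq, cds$start[i] + 1, cds$end[i]))
    aa <- sub("\\*$", "", as.character(Biostrings::translate(
      Biostrings::DNAString(nt), genetic.code = Biostrings::getGeneticCode("11"))))
    expect_equal(unname(prot[cds$locus_tag[i]]), aa)
  }
})
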