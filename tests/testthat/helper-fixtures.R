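# Shared fixtures, built once per test run and cached. All fixtures are
# generated in code under fixed seeds; nothing is read from disk.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# small annotated ancestor with the canonical IS copy-number layout
small_ancestor <- function() {
  cached("ancestor40", function()
    simulate_ancestor(n_genes = 40, seed = 5,
                      is_copy_counts = c(IS1 = 9L, IS2 = 2L, IS3 = 1L)))
}

# substitution-only sister pair on the small ancestor
sub_pair <- function() {
  cached("subpair", function()
    derive_sisters(small_ancestor(),
                   mutation_spec(snps = list(genome = list(
                     n = 300, nonsyn_fraction = 0.4)), seed = 17)))
}

aligned_sub_pair <- function() {
  cached("subpair_aln", function() {
    p <- sub_pair()
    align_genomes(p$A, p$B)
  })
}

# random DNA/protein helpers
rdna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rprot <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

revcomp_chr <- function(s) {
  rawToChar(rev(charToRaw(chartr("ACGTN", "TGCAN", s))))
}

# apply point substitutions / short indels to a sequence (for aligner tests)
mutate_dna <- function(s, nsub = 0, nindel = 0, max_indel = 20) {
  v <- strsplit(s, "")[[1]]
  if (nsub > 0) {
    at <- sample(length(v), nsub)
    v[at] <- vapply(v[at], function(x)
      sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
  }
  for (i in seq_len(nindel)) {
    p <- sample(length(v) - max_indel, 1)
    l <- sample(max_indel, 1)
    if (runif(1) < 0.5) v <- append(v, sample(c("A", "C", "G", "T"), l,
                                              replace = TRUE), p)
    else v <- v[-(p:(p + l - 1))]
  }
  paste(v, collapse = "")
}

snp_key <- function(df) paste(df$posA, df$posB, df$baseA, df$baseB)
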