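# Shared low-level helpers: DNA string manipulation on raw vectors, the
# bacterial genetic code, and stable table writers.

DNA_BASES <- c("A", "C", "G", "T")

SENSE_CODONS <- local({
  all <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0), DNA_BASES, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
})

#' Random DNA sequence
#'
#' @param n length in bp
#' @param gc target G+C fraction
#' @param skew GC skew (G-C)/(G+C) of the generated strand; 0 for none
#' @return a single uppercase character string
#' @keywords internal
rand_dna <- function(n, gc = 0.5, skew = 0) {
  pg <- gc * (1 + skew) / 2
  pc <- gc * (1 - skew) / 2
  pat <- (1 - gc) / 2
  paste(sample(DNA_BASES, n, replace = TRUE, prob = c(pat, pc, pg, pat)),
        collapse = "")
}

#' Reverse complement of a DNA string
#' @param s DNA string over ACGTN
#' @keywords internal
revcomp <- function(s) {
  rawToChar(rev(charToRaw(chartr("ACGTN", "TGCAN", s))))
}

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

# substring in 0-based half-open coordinates
sub0 <- function(s, start, end) substr(s, start + 1L, end)

# bacterial genetic code (translation table 11); same codon->aa map as the
# standard code, alternative initiators handled by the caller at position 0
GENCODE11 <- Biostrings::getGeneticCode("11")

#' Translate a coding sequence under translation table 11
#'
#' Alternative start codons (GTG, TTG, ATT, CTG) are rendered as M at the
#' first position only.
#' @param nt in-frame coding nucleotide string (may include the stop codon)
#' @param init treat the first codon as an initiator
#' @return amino-acid string, stop rendered as `*`
#' @keywords internal
translate_cds_seq <- function(nt, init = TRUE) {
  n <- nchar(nt) - nchar(nt) %% 3
  if (n < 3) return("")
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substr(nt, 1, n)),
    genetic.code = GENCODE11, if.fuzzy.codon = "X"))
  if (init && substr(nt, 1, 3) %in% c("ATG", "GTG", "TTG", "ATT", "CTG"))
    substr(aa, 1, 1) <- "M"
  aa
}

# extract the coding-strand nucleotide sequence of a feature row
feature_nt <- function(seq, start, end, strand) {
  s <- sub0(seq, start, end)
  if (strand == "-") revcomp(s) else s
}

# deterministic seed scoping: run expr with a fixed seed, restore RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# byte-stable TSV writer used by all external interfaces
write_tsv_stable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_plain <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
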