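# Protein-level reciprocal-best-hit ortholog calling. A built-in k-mer
# seeded, BLOSUM62-scored local-alignment search serves synthetic,
# desk-scale inputs; externally computed 12-column tabular hits (BLASTP
# "outfmt 6") are accepted in its place and are authoritative when given.
# E-values use fixed Karlin-Altschul parameters (lambda = 0.267, K = 0.041,
# the ungapped defaults for BLOSUM62), recorded in output headers, so that
# e-values are reproducible and their provenance explicit.

AA_ALPHABET <- strsplit("ARNDCQEGHILKMFPSTWYVBZX*", "")[[1]]

KA_LAMBDA <- 0.267
KA_K <- 0.041

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      data("BLOSUM62", package = "Biostrings", envir = environment())
      m <- get("BLOSUM62", envir = environment())
      cache <<- m[AA_ALPHABET, AA_ALPHABET]
    }
    cache
  }
})

encode_aa <- function(s) {
  v <- match(strsplit(s, "")[[1]], AA_ALPHABET) - 1L
  v[is.na(v)] <- match("X", AA_ALPHABET) - 1L
  v
}

#' Built-in protein similarity search
#'
#' Exact 5-mer seeds locate candidate subject proteins; each candidate pair
#' is scored by Smith-Waterman local alignment under BLOSUM62 with affine
#' gaps (open 11, extend 1). Bit scores are `(lambda*S - ln K)/ln 2` with
#' the fixed ungapped BLOSUM62 parameters; e-values are `m*n*2^(-S')` with
#' m the query length and n the summed subject length.
#'
#' @param queries,targets named character vectors of protein sequences
#' @param k seed length
#' @param max_hits top hits returned per query
#' @return hit data frame in 12-column tabular layout, sorted per query by
#'   e-value (ties by subject id)
#' @export
protein_search <- function(queries, targets, k = 5, max_hits = 25) {
  stopifnot(length(queries) > 0, length(targets) > 0)
  sub <- blosum62_matrix()
  n_db <- sum(nchar(targets))
  # subject seed index
  idx <- new.env(parent = emptyenv())
  for (t in seq_along(targets)) {
    s <- targets[[t]]
    if (nchar(s) < k) next
    kmers <- unique(substring(s, 1:(nchar(s) - k + 1), k:nchar(s)))
    for (km in kmers) idx[[km]] <- c(idx[[km]], t)
  }
  enc_t <- lapply(targets, encode_aa)
  rows <- list()
  for (q in seq_along(queries)) {
    qs <- queries[[q]]
    if (nchar(qs) < k) next
    qk <- unique(substring(qs, 1:(nchar(qs) - k + 1), k:nchar(qs)))
    cand <- unique(unlist(lapply(qk, function(km) idx[[km]]), use.names = FALSE))
    if (is.null(cand) || !length(cand)) next
    eq <- encode_aa(qs)
    hits <- lapply(cand, function(t) {
      al <- cpp_sw_align(eq, enc_t[[t]], sub, 11L, 1L)
      bits <- (KA_LAMBDA * al$score - log(KA_K)) / log(2)
      ev <- nchar(qs) * n_db * 2^(-bits)
      data.frame(query = names(queries)[q], subject = names(targets)[t],
                 pct_id = if (al$length > 0) 100 * al$matches / al$length else 0,
                 length = al$length, mismatches = al$mismatches,
                 gapopen = al$gaps, qstart = al$qstart, qend = al$qend,
                 sstart = al$sstart, send = al$send, evalue = ev,
                 bitscore = bits, stringsAsFactors = FALSE)
    })
    h <- do.call(rbind, hits)
    h <- h[order(h$evalue, h$subject), , drop = FALSE]
    rows[[q]] <- utils::head(h, max_hits)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(query = character(), subject = character(), pct_id = numeric(),
               length = integer(), mismatches = integer(), gapopen = integer(),
               qstart = integer(), qend = integer(), sstart = integer(),
               send = integer(), evalue = numeric(), bitscore = numeric(),
               stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "ka_params") <- c(lambda = KA_LAMBDA, K = KA_K)
  out
}

#' Smith-Waterman score of one protein pair
#'
#' BLOSUM62, affine gaps (open 11, extend 1); optionally banded around a
#' diagonal offset range `d = j - i` in `[dlo, dhi]`.
#'
#' @param a,b protein sequences
#' @param dlo,dhi diagonal band; omit for full dynamic programming
#' @return integer alignment score
#' @export
protein_align_score <- function(a, b, dlo = NULL, dhi = NULL) {
  sub <- blosum62_matrix()
  if (is.null(dlo) || is.null(dhi)) { dlo <- 1L; dhi <- 0L }  # band disabled
  cpp_sw_score(encode_aa(a), encode_aa(b), sub, 11L, 1L,
               as.integer(dlo), as.integer(dhi))
}

best_hits <- function(hits, evalue_cutoff) {
  h <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  if (nrow(h) == 0) return(h)
  # best = lowest e-value, tie -> highest bitscore, tie -> lexicographic id
  h <- h[order(h$query, h$evalue, -h$bitscore, h$subject), , drop = FALSE]
  h[!duplicated(h$query), , drop = FALSE]
}

#' Reciprocal-best-hit ortholog pairs
#'
#' A pair (a, b) is accepted when b is a's best hit, a is b's best hit, and
#' both e-values pass the cutoff (the e-value filter is applied before
#' best-hit selection). Deterministic: ties resolved by bitscore, then
#' lexicographic subject id.
#'
#' @param hitsAB hits of proteome A against proteome B (12-column layout)
#' @param hitsBA hits of proteome B against proteome A
#' @param evalue_cutoff e-value threshold applied in both directions
#' @return data frame of ortholog pairs: locusA, locusB, evalueAB, evalueBA,
#'   bitscoreAB, bitscoreBA, sorted by locusA
#' @export
reciprocal_best_hits <- function(hitsAB, hitsBA, evalue_cutoff = 1e-10) {
  bAB <- best_hits(hitsAB, evalue_cutoff)
  bBA <- best_hits(hitsBA, evalue_cutoff)
  if (nrow(bAB) == 0 || nrow(bBA) == 0)
    return(data.frame(locusA = character(), locusB = character(),
                      evalueAB = numeric(), evalueBA = numeric(),
                      bitscoreAB = numeric(), bitscoreBA = numeric(),
                      stringsAsFactors = FALSE))
  back <- setNames(bBA$subject, bBA$query)
  recip <- !is.na(back[bAB$subject]) & back[bAB$subject] == bAB$query
  sel <- bAB[recip, , drop = FALSE]
  m <- match(sel$subject, bBA$query)
  out <- data.frame(locusA = sel$query, locusB = sel$subject,
                    evalueAB = sel$evalue, evalueBA = bBA$evalue[m],
                    bitscoreAB = sel$bitscore, bitscoreBA = bBA$bitscore[m],
                    stringsAsFactors = FALSE)
  out <- out[order(out$locusA), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extract the proteome of an annotated genome
#'
#' Translates every clean CDS (table 11); stored translations are preferred
#' when present.
#'
#' @param genome a [genome_record()]
#' @return named character vector of protein sequences (stop trimmed)
#' @export
extract_proteome <- function(genome) {
  cds <- cds_features(genome)
  cds <- cds[cds$codon_ok, , drop = FALSE]
  out <- vapply(seq_len(nrow(cds)), function(i) {
    if (!is.na(cds$translation[i]) && nzchar(cds$translation[i]))
      return(cds$translation[i])
    nt <- feature_nt(genome$seq, cds$start[i], cds$end[i], cds$strand[i])
    sub("\\*$", "", translate_cds_seq(nt))
  }, "")
  names(out) <- cds$locus_tag
  out[nzchar(out)]
}
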