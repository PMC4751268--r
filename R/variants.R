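# Codon-aware SNP classification and substitution summaries. Synonymy is
# judged against the genome-A codon with the single alternate base
# substituted (a mutation-path-free definition); codons carrying more than
# one SNP get their own class (`multi_hit_codon`) instead of an arbitrary
# pathway assumption, because SNPs are counted as sites, not codon events.

SNP_CLASSES <- c("synonymous", "nonsynonymous", "nonsense", "intergenic",
                 "rna", "multi_hit_codon", "ambiguous")

#' Classify called SNPs against the genome-A annotation
#'
#' Each SNP is located in the genome-A feature table (strand-aware). For a
#' SNP inside a clean CDS the codon is read from genome A, the single
#' alternate base substituted, and the two codons compared under translation
#' table 11. SNPs in rRNA/tRNA features are classed `rna`, outside features
#' `intergenic`. A SNP falling in two overlapping CDSs yields one record per
#' locus_tag. CDSs flagged un-translatable (compound location, nonzero
#' phase, length not divisible by 3) yield class `ambiguous` rather than
#' being dropped.
#'
#' @param snps data frame from [call_snps()] (posA, posB, baseA, baseB,
#'   orientation)
#' @param genomeA annotated [genome_record()] providing the coordinate frame
#' @return data frame of SNP records: the input columns plus context,
#'   locus_tag, codon_index, codon_pos, codonA, codonB, aaA, aaB, klass
#' @export
classify_snps <- function(snps, genomeA) {
  f <- genomeA$features
  base_cols <- c("posA", "posB", "baseA", "baseB", "orientation")
  empty <- cbind(snps[0, base_cols, drop = FALSE],
                 data.frame(context = character(), locus_tag = character(),
                            codon_index = integer(), codon_pos = integer(),
                            codonA = character(), codonB = character(),
                            aaA = character(), aaB = character(),
                            klass = character(), stringsAsFactors = FALSE))
  if (nrow(snps) == 0) return(empty)
  # effective alternate base on A's forward strand
  altA <- ifelse(snps$orientation == "reverse", comp_base(snps$baseB),
                 snps$baseB)

  cds <- f[f$ftype == "CDS", , drop = FALSE]
  rna <- f[f$ftype %in% c("rRNA", "tRNA"), , drop = FALSE]
  out <- vector("list", nrow(snps))
  cds_seq_cache <- new.env(parent = emptyenv())
  get_cds_nt <- function(i) {
    key <- as.character(i)
    v <- cds_seq_cache[[key]]
    if (is.null(v)) {
      v <- feature_nt(genomeA$seq, cds$start[i], cds$end[i], cds$strand[i])
      cds_seq_cache[[key]] <- v
    }
    v
  }
  for (s in seq_len(nrow(snps))) {
    p <- snps$posA[s]
    hit <- which(cds$start <= p & p < cds$end)
    if (length(hit) == 0) {
      in_rna <- nrow(rna) > 0 && any(rna$start <= p & p < rna$end)
      out[[s]] <- data.frame(
        snps[s, base_cols, drop = FALSE],
        context = if (in_rna) "RNA" else "intergenic",
        locus_tag = NA_character_, codon_index = NA_integer_,
        codon_pos = NA_integer_, codonA = NA_character_,
        codonB = NA_character_, aaA = NA_character_, aaB = NA_character_,
        klass = if (in_rna) "rna" else "intergenic",
        stringsAsFactors = FALSE)
      next
    }
    recs <- lapply(hit, function(i) {
      if (!cds$codon_ok[i]) {
        return(data.frame(snps[s, base_cols, drop = FALSE], context = "CDS",
                          locus_tag = cds$locus_tag[i],
                          codon_index = NA_integer_, codon_pos = NA_integer_,
                          codonA = NA_character_, codonB = NA_character_,
                          aaA = NA_character_, aaB = NA_character_,
                          klass = "ambiguous", stringsAsFactors = FALSE))
      }
      if (cds$strand[i] == "+") {
        off <- p - cds$start[i]
        refc <- snps$baseA[s]; altc <- altA[s]
      } else {
        off <- cds$end[i] - 1L - p
        refc <- comp_base(snps$baseA[s]); altc <- comp_base(altA[s])
      }
      nt <- get_cds_nt(i)
      ci <- off %/% 3L
      cp <- off %% 3L
      codonA <- substr(nt, ci * 3L + 1L, ci * 3L + 3L)
      codonB <- codonA
      substr(codonB, cp + 1L, cp + 1L) <- altc
      aaA <- unname(GENCODE11[codonA])
      aaB <- unname(GENCODE11[codonB])
      klass <- if (is.na(aaA) || is.na(aaB)) "ambiguous"
        else if (aaA == aaB) "synonymous"
        else if (aaA == "*" || aaB == "*") "nonsense"
        else "nonsynonymous"
      data.frame(snps[s, base_cols, drop = FALSE], context = "CDS",
                 locus_tag = cds$locus_tag[i], codon_index = ci,
                 codon_pos = cp, codonA = codonA, codonB = codonB,
                 aaA = aaA, aaB = aaB, klass = klass,
                 stringsAsFactors = FALSE)
    })
    out[[s]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  # multi-hit codons: more than one SNP in the same codon of the same locus
  key <- paste(res$locus_tag, res$codon_index, sep = ":")
  coding <- res$context == "CDS" & !is.na(res$codon_index)
  multi <- coding & key %in% names(which(table(key[coding]) > 1))
  res$klass[multi] <- "multi_hit_codon"
  res
}

#' Classify a single SNP
#' @inheritParams classify_snps
#' @param snp one-row data frame (or list) with posA, posB, baseA, baseB,
#'   orientation
#' @return one-or-more-row SNP record data frame
#' @export
classify_snp <- function(snp, genomeA) {
  classify_snps(as.data.frame(snp, stringsAsFactors = FALSE), genomeA)
}

#' Summarize SNP classes over a region
#'
#' @param snps classified SNP data frame from [classify_snps()]
#' @param region either a numeric `c(start, end)` 0-based half-open interval
#'   on genome A, or a character `c(from_locus, to_locus)` pair interpreted
#'   as the inclusive span from the 5'-most to the 3'-most coordinate of the
#'   two loci
#' @param genomeA required when `region` is a locus pair
#' @param label region label for the output
#' @param fold_nonsense count nonsense substitutions as non-synonymous
#'   (two-way synonymous/non-synonymous accounting); otherwise they are
#'   reported separately in `n_other`
#' @return one-row data frame: region, start, end, n_snps, n_syn, n_nonsyn,
#'   n_other
#' @export
region_summary <- function(snps, region, genomeA = NULL, label = "region",
                           fold_nonsense = FALSE) {
  if (is.character(region)) {
    if (is.null(genomeA)) stop("genomeA required for a locus-pair region")
    f <- genomeA$features
    hit <- f[f$locus_tag %in% region, , drop = FALSE]
    if (nrow(hit) < length(unique(region)))
      stop("unknown locus in region spec: ",
           paste(setdiff(region, f$locus_tag), collapse = ", "))
    region <- c(min(hit$start), max(hit$end))
  }
  inside <- snps$posA >= region[1] & snps$posA < region[2]
  sub <- snps[inside, , drop = FALSE]
  # a SNP in overlapping CDSs contributes once: count sites, preferring the
  # coding record (non-synonymous > nonsense > synonymous > rest)
  if (nrow(sub)) {
    prio <- match(sub$klass, c("nonsynonymous", "nonsense", "multi_hit_codon",
                               "synonymous", "ambiguous", "rna", "intergenic"))
    sub <- sub[order(sub$posA, prio), , drop = FALSE]
    sub <- sub[!duplicated(sub$posA), , drop = FALSE]
  }
  n_syn <- sum(sub$klass == "synonymous")
  n_nonsyn <- sum(sub$klass == "nonsynonymous")
  n_nonsense <- sum(sub$klass == "nonsense")
  if (fold_nonsense) { n_nonsyn <- n_nonsyn + n_nonsense; n_nonsense <- 0L }
  n <- nrow(sub)
  data.frame(region = label, start = region[1], end = region[2],
             n_snps = n, n_syn = n_syn, n_nonsyn = n_nonsyn,
             n_other = n - n_syn - n_nonsyn, stringsAsFactors = FALSE)
}

#' Nucleotide- and protein-level differences between one gene pair
#'
#' Global end-free alignment (match +1, mismatch -1, gap -2) of the
#' nucleotide sequences and of their translations; differences are mismatch
#' plus internal gap columns. For equal-length inputs at high identity this
#' reduces to positionwise comparison.
#'
#' @param cdsA,cdsB in-frame coding nucleotide strings (stop codon optional)
#' @param locusA,locusB labels for the report
#' @return one-row data frame with nt/aa aligned lengths, difference counts
#'   and percent identities
#' @export
gene_pair_diff <- function(cdsA, cdsB, locusA = "A", locusB = "B") {
  if (!nzchar(cdsA) || !nzchar(cdsB)) stop("empty sequence")
  strip_stop <- function(nt) {
    n <- nchar(nt)
    if (n %% 3 == 0 && substr(nt, n - 2, n) %in% c("TAA", "TAG", "TGA"))
      substr(nt, 1, n - 3) else nt
  }
  nt <- cpp_endfree_align(cdsA, cdsB, TRUE, TRUE)
  aaA <- translate_cds_seq(strip_stop(cdsA))
  aaB <- translate_cds_seq(strip_stop(cdsB))
  aa <- cpp_endfree_align(aaA, aaB, TRUE, TRUE, treat_n_mismatch = FALSE)
  nt_len <- nt$matches + nt$mismatches + nt$gaps
  aa_len <- aa$matches + aa$mismatches + aa$gaps
  nt_diffs <- nt$mismatches + nt$gaps
  aa_diffs <- aa$mismatches + aa$gaps
  data.frame(locusA = locusA, locusB = locusB,
             nt_len_aligned = nt_len, nt_diffs = nt_diffs,
             aa_len_aligned = aa_len, aa_diffs = aa_diffs,
             nt_pct_id = 100 * (nt_len - nt_diffs) / nt_len,
             aa_pct_id = 100 * (aa_len - aa_diffs) / aa_len,
             stringsAsFactors = FALSE)
}

#' Pairwise differences between marker genes (16S rRNA style)
#'
#' Extracts one marker copy per genome (the first feature of the requested
#' type whose product matches `product_pattern`), aligns each pair end-free,
#' and counts differences. With `mask_insertions`, gap runs of at least
#' `min_insertion` columns — segments present in only one of the two
#' sequences, such as 5' insertions — are excluded from the count.
#'
#' @param genomes list of annotated [genome_record()]s, or a named character
#'   vector of marker sequences
#' @param product_pattern regular expression selecting the marker feature
#' @param mask_insertions exclude long one-sided insertions from the count
#' @param min_insertion minimum gap-run length treated as an insertion
#' @return symmetric matrix of pairwise difference counts
#' @export
compare_marker_genes <- function(genomes, product_pattern = "16S",
                                 mask_insertions = TRUE, min_insertion = 10) {
  if (is.character(genomes)) {
    seqs <- genomes
  } else {
    seqs <- character(0)
    for (g in genomes) {
      f <- g$features
      hit <- which(f$ftype == "rRNA" &
                     (is.na(f$product) | grepl(product_pattern, f$product)))
      if (!length(hit)) {
        warning("genome ", g$id, " lacks the marker; omitted")
        next
      }
      i <- hit[1]
      seqs[[g$id]] <- feature_nt(g$seq, f$start[i], f$end[i], f$strand[i])
    }
  }
  if (length(seqs) < 2) stop("need at least two genomes with the marker")
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # true global alignment: free overhangs would let a near-terminal
    # insertion (the typical 5' case) be absorbed into an unaligned end
    # instead of forming the contiguous gap run that masking relies on
    al <- cpp_endfree_align(seqs[[i]], seqs[[j]], FALSE, FALSE)
    ops <- al$ops
    r <- rle(ops)
    ends <- cumsum(r$lengths)
    diffs <- sum(r$lengths[r$values == 1])
    gapruns <- which(r$values %in% c(2L, 3L))
    for (gr in gapruns) {
      if (!mask_insertions || r$lengths[gr] < min_insertion)
        diffs <- diffs + r$lengths[gr]
    }
    m[i, j] <- m[j, i] <- diffs
  }
  m
}

#' Write classified SNPs as a minimal VCF (genome A as reference)
#' @param snps classified SNP data frame
#' @param genomeA reference [genome_record()]
#' @param path output file
#' @export
write_snps_vcf <- function(snps, genomeA, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s,length=%d>", genomeA$id,
                       nchar(genomeA$seq)),
               "##INFO=<ID=CLASS,Number=1,Type=String,Description=\"SNP synonymy class\">",
               "##INFO=<ID=LOCUS,Number=1,Type=String,Description=\"locus tag\">",
               "##INFO=<ID=CODON,Number=1,Type=String,Description=\"ref/alt codon\">",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(snps)) {
    altA <- ifelse(snps$orientation == "reverse", comp_base(snps$baseB),
                   snps$baseB)
    info <- sprintf("CLASS=%s;LOCUS=%s;CODON=%s/%s", snps$klass,
                    ifelse(is.na(snps$locus_tag), ".", snps$locus_tag),
                    ifelse(is.na(snps$codonA), ".", snps$codonA),
                    ifelse(is.na(snps$codonB), ".", snps$codonB))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s", genomeA$id,
                       snps$posA + 1L, snps$baseA, altA, info), con)
  }
  invisible(path)
}
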