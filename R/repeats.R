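# Maximal direct/inverted repeat discovery (seed-and-extend with x-drop),
# insertion-sequence copy-number counting, and flanking direct-repeat
# detection around candidate horizontally transferred cassettes.

#' Find maximal intra-genomic repeat pairs
#'
#' Exact 16-mer seeds in both orientations are extended by ungapped x-drop
#' extension; overlapping reported pairs on the same diagonal are merged to
#' their maximal extent. The two copies of a pair never overlap.
#'
#' @param genome a [genome_record()] or DNA string
#' @param min_len minimum repeat length (>= 24)
#' @param min_id minimum identity of the two copies (0-1)
#' @param k seed length
#' @param max_occ skip seeds occurring more often than this (repeat-family
#'   explosion guard)
#' @return data frame of repeat pairs: startA, endA, startB, endB,
#'   orientation ("direct"/"inverted"), length, pct_id
#' @export
maximal_repeats <- function(genome, min_len = 24, min_id = 0.9, k = 16,
                            max_occ = 80) {
  if (inherits(genome, "GenomeRecord")) genome <- genome$seq
  stopifnot(min_len >= 24)
  d <- cpp_self_repeats(genome, as.integer(k), as.integer(min_len),
                        as.integer(max_occ))
  if (nrow(d) == 0)
    return(data.frame(startA = integer(), endA = integer(),
                      startB = integer(), endB = integer(),
                      orientation = character(), length = integer(),
                      pct_id = numeric(), stringsAsFactors = FALSE))
  out <- data.frame(startA = d$startA, endA = d$startA + d$length,
                    startB = d$startB, endB = d$startB + d$length,
                    orientation = ifelse(d$inverted == 1, "inverted", "direct"),
                    length = d$length,
                    pct_id = 100 * (1 - d$mismatches / d$length),
                    stringsAsFactors = FALSE)
  out <- out[out$pct_id >= 100 * min_id, , drop = FALSE]
  # drop pairs wholly contained in a longer pair of the same orientation
  out <- out[order(-out$length), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    contained <- keep & seq_len(nrow(out)) > i &
      out$orientation == out$orientation[i] &
      out$startA >= out$startA[i] & out$endA <= out$endA[i] &
      out$startB >= out$startB[i] & out$endB <= out$endB[i]
    keep[contained] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$startA, out$startB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Verify a repeat pair by direct comparison of its two spans
#' @param genome DNA string or [genome_record()]
#' @param pair one row of a [maximal_repeats()] data frame
#' @return realized identity (0-1) of the two spans
#' @export
verify_repeat <- function(genome, pair) {
  if (inherits(genome, "GenomeRecord")) genome <- genome$seq
  a <- sub0(genome, pair$startA, pair$endA)
  b <- sub0(genome, pair$startB, pair$endB)
  if (pair$orientation == "inverted") b <- revcomp(b)
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  mean(va == vb)
}

#' Count copies of an element in a genome
#'
#' Candidate placements are located by exact 16-mer seeds on both strands,
#' grouped by diagonal, and each candidate window is aligned to the element
#' (element ends fixed, window ends free). Placements are accepted greedily
#' by score, without overlap, when the identity over the aligned element
#' span is at least `min_id` and the span covers at least `min_cov` of the
#' element.
#'
#' @param element_seq element sequence (>= 100 bp)
#' @param genome a [genome_record()] or DNA string
#' @param min_id minimum identity over the aligned element span
#' @param min_cov minimum fraction of the element aligned
#' @param element_id label for the report
#' @return object of class `CopyNumberReport`: list with element_id, count,
#'   copies (data frame: start, end, strand, pct_id, coverage)
#' @export
count_element_copies <- function(element_seq, genome, min_id = 0.95,
                                 min_cov = 0.90, element_id = "element") {
  if (inherits(genome, "GenomeRecord")) genome <- genome$seq
  elen <- nchar(element_seq)
  if (elen < 100) stop("element shorter than 100 bp")
  if (elen > nchar(genome)) stop("element longer than genome")
  L <- nchar(genome)
  cands <- list()
  for (strand in c("+", "-")) {
    g <- if (strand == "+") genome else revcomp(genome)
    hits <- cpp_cross_repeats(element_seq, g, 16L, 16L)
    if (nrow(hits) == 0) next
    # project the element start into the genome and cluster by position
    proj <- hits$start2 - hits$start1
    o <- order(proj)
    proj <- proj[o]
    grp <- cumsum(c(1L, diff(proj) > elen %/% 2L))
    for (gidx in unique(grp)) {
      p0 <- round(stats::median(proj[grp == gidx]))
      ws <- max(0L, p0 - 50L)
      we <- min(nchar(g), p0 + elen + 50L)
      al <- cpp_endfree_align(element_seq, sub0(g, ws, we), TRUE, FALSE)
      core <- if (al$core_end > al$core_start)
        al$ops[(al$core_start + 1):al$core_end] else integer(0)
      cols <- length(core)
      matches <- sum(core == 0L)
      el_span <- sum(core %in% c(0L, 1L, 2L))
      if (cols == 0) next
      ident <- matches / cols
      cov <- el_span / elen
      if (ident < min_id || cov < min_cov) next
      # genome interval of the aligned span (convert from rc frame if needed)
      lead_b <- sum(al$ops[seq_len(al$core_start)] == 3L)
      span_b <- sum(core %in% c(0L, 1L, 3L))
      gs <- ws + lead_b
      ge <- gs + span_b
      if (strand == "-") { tmp <- L - ge; ge <- L - gs; gs <- tmp }
      cands[[length(cands) + 1]] <- data.frame(
        start = gs, end = ge, strand = strand, pct_id = 100 * ident,
        coverage = cov, score = matches, stringsAsFactors = FALSE)
    }
  }
  copies <- if (length(cands)) do.call(rbind, cands) else
    data.frame(start = integer(), end = integer(), strand = character(),
               pct_id = numeric(), coverage = numeric(), score = numeric(),
               stringsAsFactors = FALSE)
  # greedy non-overlapping acceptance by score
  copies <- copies[order(-copies$score, copies$start), , drop = FALSE]
  acc <- logical(nrow(copies))
  for (i in seq_len(nrow(copies))) {
    ok <- TRUE
    for (j in which(acc)) {
      if (copies$start[i] < copies$end[j] && copies$end[i] > copies$start[j]) {
        ok <- FALSE; break
      }
    }
    acc[i] <- ok
  }
  copies <- copies[acc, , drop = FALSE]
  copies <- copies[order(copies$start), , drop = FALSE]
  copies$score <- NULL
  rownames(copies) <- NULL
  structure(list(element_id = element_id, count = nrow(copies),
                 copies = copies), class = "CopyNumberReport")
}

#' @export
print.CopyNumberReport <- function(x, ...) {
  cat(sprintf("CopyNumberReport %s: %d copies\n", x$element_id, x$count))
  invisible(x)
}

#' Find direct repeats flanking an interval
#'
#' Searches for direct repeat pairs with one copy within `search_span` bp
#' upstream of the interval start and the other within `search_span` bp
#' downstream of the interval end — the signature of an integration event
#' that duplicated its target site.
#'
#' @param genome a [genome_record()] or DNA string
#' @param interval 0-based half-open `c(start, end)`
#' @param search_span flank width in bp
#' @param min_len minimum repeat length
#' @param min_id minimum identity
#' @return data frame of repeat pairs as in [maximal_repeats()] (direct
#'   orientation only), coordinates on the genome
#' @export
find_flanking_repeats <- function(genome, interval, search_span = 5000,
                                  min_len = 100, min_id = 0.9) {
  if (inherits(genome, "GenomeRecord")) genome <- genome$seq
  L <- nchar(genome)
  s <- interval[1]; e <- interval[2]
  stopifnot(s >= 0, e <= L, s < e)
  ls <- max(0L, s - search_span)
  re <- min(L, e + search_span)
  left <- sub0(genome, ls, s)
  right <- sub0(genome, e, re)
  if (!nzchar(left) || !nzchar(right))
    return(data.frame(startA = integer(), endA = integer(),
                      startB = integer(), endB = integer(),
                      orientation = character(), length = integer(),
                      pct_id = numeric(), stringsAsFactors = FALSE))
  d <- cpp_cross_repeats(left, right, 16L, as.integer(min_len))
  if (nrow(d)) {
    out <- data.frame(startA = ls + d$start1, endA = ls + d$start1 + d$length,
                      startB = e + d$start2, endB = e + d$start2 + d$length,
                      orientation = "direct", length = d$length,
                      pct_id = 100 * (1 - d$mismatches / d$length),
                      stringsAsFactors = FALSE)
    out <- out[out$pct_id >= 100 * min_id & out$length >= min_len, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    data.frame(startA = integer(), endA = integer(), startB = integer(),
               endB = integer(), orientation = character(),
               length = integer(), pct_id = numeric(),
               stringsAsFactors = FALSE)
  }
}

#' Group IS elements into families and summarize copy numbers
#'
#' Elements are clustered into families at `min_id` identity over at least
#' `min_cov` of their length (single-linkage), and each family's copies are
#' counted with [count_element_copies()].
#'
#' @param elements named character vector of element sequences
#' @param genome a [genome_record()] or DNA string
#' @param min_id,min_cov family clustering thresholds
#' @return data frame: family representative, members, copy count
#' @export
is_family_summary <- function(elements, genome, min_id = 0.90,
                              min_cov = 0.90) {
  n <- length(elements)
  if (n == 0) return(data.frame(family = character(), members = character(),
                                copies = integer(), stringsAsFactors = FALSE))
  sim <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    al <- cpp_endfree_align(elements[[i]], elements[[j]], TRUE, TRUE)
    core <- al$ops[(al$core_start + 1):al$core_end]
    ident <- if (length(core)) sum(core == 0L) / length(core) else 0
    cov <- length(core) / max(nchar(elements[[i]]), nchar(elements[[j]]))
    sim[i, j] <- sim[j, i] <- ident >= min_id && cov >= min_cov
  }
  fam <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (sim[i, j] && fam[j] != fam[i]) {
        fam[fam == fam[j]] <- fam[i]; changed <- TRUE
      }
    }
    if (!changed) break
  }
  out <- lapply(unique(fam), function(fi) {
    members <- names(elements)[fam == fi]
    rep_el <- elements[[which(fam == fi)[1]]]
    cn <- count_element_copies(rep_el, genome, element_id = members[1])
    data.frame(family = members[1],
               members = paste(members, collapse = ","),
               copies = cn$count, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
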