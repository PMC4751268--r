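# Anchor-based collinear pairwise whole-genome alignment. Anchors are maximal
# exact matches seeded by k-mers unique (over both strands) in each genome;
# chained by weighted longest-increasing-subsequence per orientation; the gaps
# between chained anchors are closed by banded global alignment with unit
# scores (match +1, mismatch -1, gap -2). One-sided gaps larger than `max_gap`
# become unaligned strain-specific-insertion segments instead of being forced
# into an alignment.

#' Find maximal unique exact matches between two genomes
#'
#' MUM-like anchors seeded by k-mers whose occurrence count (forward and
#' reverse strand combined) is exactly one in each genome, then extended to
#' maximal exact matches. Multi-copy sequence (IS elements, rRNA operons)
#' carries no unique k-mers and is naturally anchor-free.
#'
#' @param seqA,seqB DNA strings (or [genome_record()]s)
#' @param k seed length, at least 12
#' @return data frame with columns posA, posB (0-based starts on the forward
#'   strands), length, orientation ("forward"/"reverse"); attributes `lenA`,
#'   `lenB` carry the genome lengths
#' @export
find_anchors <- function(seqA, seqB, k = 20) {
  if (inherits(seqA, "GenomeRecord")) seqA <- seqA$seq
  if (inherits(seqB, "GenomeRecord")) seqB <- seqB$seq
  stopifnot(k >= 12, k <= 31, nchar(seqA) > 0, nchar(seqB) > 0)
  d <- cpp_find_anchors(seqA, seqB, as.integer(k))
  out <- data.frame(posA = d$posA, posB = d$posB, length = d$length,
                    orientation = ifelse(d$reverse == 1, "reverse", "forward"),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$posA, out$posB), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lenA") <- nchar(seqA)
  attr(out, "lenB") <- nchar(seqB)
  out
}

#' Chain anchors into collinear runs
#'
#' Repeatedly extracts the maximum-weight collinear chain (weight = summed
#' anchor length, via weighted longest-increasing-subsequence) per
#' orientation, discarding anchors that conflict with an accepted chain,
#' until no chain of weight at least `min_weight` remains. Ties are broken
#' towards the smaller `posA`.
#'
#' @param anchors data frame from [find_anchors()]
#' @param min_weight minimum summed anchor length for a chain to be kept
#' @return list of chains; each chain is an anchor data frame with an
#'   `orientation` attribute, ordered by posA. Chains are sorted by their
#'   first posA.
#' @export
chain_anchors <- function(anchors, min_weight = NULL) {
  lenB <- attr(anchors, "lenB")
  if (is.null(min_weight)) min_weight <- 40L
  k_min_anchor <- 20L  # smallest useful anchor remnant after trimming
  remaining <- anchors
  chains <- list()
  while (nrow(remaining) > 0) {
    best <- NULL
    for (ori in c("forward", "reverse")) {
      sub <- remaining[remaining$orientation == ori, , drop = FALSE]
      if (nrow(sub) == 0) next
      y <- if (ori == "forward") sub$posB else -(sub$posB + sub$length)
      ord <- order(sub$posA, y)
      sub <- sub[ord, , drop = FALSE]
      y <- y[ord]
      idx <- cpp_chain_lis(sub$posA, as.integer(y), sub$length)
      cand <- sub[idx, , drop = FALSE]
      w <- sum(cand$length)
      if (is.null(best) || w > attr(best, "weight")) {
        attr(cand, "weight") <- w
        attr(cand, "orientation") <- ori
        best <- cand
      }
    }
    if (is.null(best) || attr(best, "weight") < min_weight) break
    chains[[length(chains) + 1]] <- best
    # anchors conflicting with the accepted chain are trimmed to their
    # non-overlapping part (anchors extending through identical repeat
    # copies overlap chains at repeat boundaries); fully covered anchors
    # are discarded
    ivA <- cbind(best$posA, best$posA + best$length)
    ivB <- cbind(best$posB, best$posB + best$length)
    trims <- function(starts, ends, iv) {
      tl <- rep(0L, length(starts)); tr <- rep(0L, length(starts))
      for (r in seq_len(nrow(iv))) {
        inL <- starts >= iv[r, 1] & starts < iv[r, 2]
        tl[inL] <- pmax(tl[inL], iv[r, 2] - starts[inL])
        inR <- ends > iv[r, 1] & ends <= iv[r, 2]
        tr[inR] <- pmax(tr[inR], ends[inR] - iv[r, 1])
        spans <- starts < iv[r, 1] & ends > iv[r, 2]
        tr[spans] <- pmax(tr[spans], ends[spans] - iv[r, 1])
      }
      list(tl = tl, tr = tr)
    }
    tA <- trims(remaining$posA, remaining$posA + remaining$length, ivA)
    tB <- trims(remaining$posB, remaining$posB + remaining$length, ivB)
    fwd <- remaining$orientation == "forward"
    tl <- ifelse(fwd, pmax(tA$tl, tB$tl), pmax(tA$tl, tB$tr))
    tr <- ifelse(fwd, pmax(tA$tr, tB$tr), pmax(tA$tr, tB$tl))
    newlen <- remaining$length - tl - tr
    keep <- newlen >= k_min_anchor
    remaining$posA <- remaining$posA + tl
    remaining$posB <- remaining$posB + ifelse(fwd, tl, tr)
    remaining$length <- newlen
    remaining <- remaining[keep, , drop = FALSE]
    if (length(chains) > 100) break
  }
  ord <- order(vapply(chains, function(ch) ch$posA[1], 0))
  chains <- chains[ord]
  attr(chains, "lenA") <- attr(anchors, "lenA")
  attr(chains, "lenB") <- lenB
  chains
}

#' Close inter-anchor gaps and assemble alignment blocks
#'
#' Within each chain, the gap between consecutive anchors is aligned by
#' banded global alignment when both sides are at most `max_gap` long; a
#' larger gap interrupts the block and its intervals are reported as
#' unaligned segments (the longer side as a strain-specific insertion, a
#' short opposite side as below-threshold). Leading/trailing genome ends are
#' closed the same way for the outermost forward chain.
#'
#' @param chains list from [chain_anchors()]
#' @param seqA,seqB DNA strings (or [genome_record()]s)
#' @param max_gap largest gap side closed by alignment (also the
#'   "large insertion" threshold for identity accounting)
#' @param band alignment band half-width
#' @return list with `blocks` (list of [alignment_block()]) and `unaligned`
#'   (data frame: genome, start, end, reason)
#' @export
close_gaps <- function(chains, seqA, seqB, max_gap = 5000, band = 200) {
  if (inherits(seqA, "GenomeRecord")) seqA <- seqA$seq
  if (inherits(seqB, "GenomeRecord")) seqB <- seqB$seq
  stopifnot(max_gap >= band, band >= 1)
  nA <- nchar(seqA); nB <- nchar(seqB)
  blocks <- list()
  unaligned <- data.frame(genome = character(), start = integer(),
                          end = integer(), reason = character(),
                          stringsAsFactors = FALSE)
  add_unaligned <- function(genome, start, end, reason) {
    if (end > start)
      unaligned[nrow(unaligned) + 1, ] <<- list(genome, start, end, reason)
  }
  first_fwd <- which(vapply(chains, function(ch) attr(ch, "orientation"), "") == "forward")

  for (ci in seq_along(chains)) {
    ch <- chains[[ci]]
    ori <- attr(ch, "orientation")
    if (ori == "forward") {
      sA <- seqA; sB <- seqB
      a <- ch
    } else {
      # work in the reverse-complement frame of B
      sA <- seqA; sB <- revcomp(seqB)
      a <- ch
      a$posB <- nB - (ch$posB + ch$length)
      a <- a[order(a$posA), , drop = FALSE]
    }
    # virtual terminal anchors close the genome ends once (outermost forward chain)
    lead <- length(first_fwd) && ci == first_fwd[1] && ori == "forward"
    trail <- length(first_fwd) && ci == first_fwd[length(first_fwd)] && ori == "forward"
    if (lead) a <- rbind(data.frame(posA = 0L, posB = 0L, length = 0L,
                                    orientation = ori), a)
    if (trail) a <- rbind(a, data.frame(posA = nA, posB = nB, length = 0L,
                                        orientation = ori))

    ops_l <- list(); colsA_l <- list(); colsB_l <- list()
    blkA <- NA_integer_; blkB <- NA_integer_
    endA <- NA_integer_; endB <- NA_integer_
    flush_block <- function() {
      if (length(ops_l) == 0) return(NULL)
      b <- block_from_ops(unlist(ops_l, use.names = FALSE),
                          unlist(colsA_l, use.names = FALSE),
                          unlist(colsB_l, use.names = FALSE),
                          startA = blkA, startB = blkB, orientation = ori)
      if (ori == "reverse") {
        # convert interval B back to forward-strand coordinates
        rcs <- nB - b$intervalB[2]; rce <- nB - b$intervalB[1]
        b$intervalB <- c(rcs, rce)
      }
      blocks[[length(blocks) + 1]] <<- b
      ops_l <<- list(); colsA_l <<- list(); colsB_l <<- list()
      blkA <<- NA_integer_; blkB <<- NA_integer_
    }
    push_ops <- function(op, ca, cb) {
      n <- length(ops_l) + 1L
      ops_l[[n]] <<- op; colsA_l[[n]] <<- ca; colsB_l[[n]] <<- cb
    }

    for (i in seq_len(nrow(a))) {
      pA <- a$posA[i]; pB <- a$posB[i]; ln <- a$length[i]
      if (!is.na(endA)) {
        # trim overlap with the previous anchor
        if (pA < endA) { d <- endA - pA; pA <- pA + d; pB <- pB + d; ln <- ln - d }
        if (!is.na(endB) && pB < endB) { d <- endB - pB; pA <- pA + d; pB <- pB + d; ln <- ln - d }
        if (ln < 0) { ln <- 0; pA <- max(pA, endA); pB <- max(pB, endB) }
        gA <- pA - endA; gB <- pB - endB
        if (gA < 0 || gB < 0) next
        if (gA <= max_gap && gB <= max_gap) {
          if (gA > 0 || gB > 0) {
            ga <- sub0(sA, endA, pA); gb <- sub0(sB, endB, pB)
            al <- cpp_banded_global(ga, gb, as.integer(band))
            gops <- al$ops
            ca <- strsplit(ga, "")[[1]]; cb <- strsplit(gb, "")[[1]]
            fullA <- fullB <- character(length(gops))
            fullA[gops %in% c(0L, 1L, 2L)] <- ca
            fullB[gops %in% c(0L, 1L, 3L)] <- cb
            fullA[gops == 3L] <- "-"; fullB[gops == 2L] <- "-"
            push_ops(gops, fullA, fullB)
          }
        } else {
          # large one-sided gap: emit unaligned segments, break the block
          flush_block()
          if (gA > 0)
            add_unaligned("A", endA, pA,
                          if (gA > max_gap) "strain_specific_insertion" else "below_threshold")
          if (gB > 0) {
            st0 <- endB; en0 <- pB
            if (ori == "reverse") { tmp <- nB - en0; en0 <- nB - st0; st0 <- tmp }
            add_unaligned("B", st0, en0,
                          if (gB > max_gap) "strain_specific_insertion" else "below_threshold")
          }
        }
      }
      if (ln > 0) {
        if (is.na(blkA)) { blkA <- pA; blkB <- pB }
        push_ops(rep(0L, ln), rep("", ln), rep("", ln))
      } else if (is.na(blkA) && length(ops_l) == 0) {
        blkA <- pA; blkB <- pB
      }
      endA <- pA + ln; endB <- pB + ln
    }
    flush_block()
  }
  # a gap in one chain may be explained by a block of another chain (e.g. an
  # inversion): remove block-covered regions from the unaligned segments so
  # that every position is covered by at most one block or one segment
  if (nrow(unaligned) && length(blocks)) {
    cov <- list(A = do.call(rbind, lapply(blocks, function(b) b$intervalA)),
                B = do.call(rbind, lapply(blocks, function(b) b$intervalB)))
    pieces <- list()
    for (r in seq_len(nrow(unaligned))) {
      segs <- matrix(c(unaligned$start[r], unaligned$end[r]), ncol = 2)
      cv <- cov[[unaligned$genome[r]]]
      for (ci in seq_len(nrow(cv))) {
        keep <- list()
        for (si in seq_len(nrow(segs))) {
          s <- segs[si, 1]; e <- segs[si, 2]
          cs <- cv[ci, 1]; ce <- cv[ci, 2]
          if (ce <= s || cs >= e) { keep[[length(keep) + 1]] <- c(s, e); next }
          if (cs > s) keep[[length(keep) + 1]] <- c(s, cs)
          if (ce < e) keep[[length(keep) + 1]] <- c(ce, e)
        }
        segs <- if (length(keep)) do.call(rbind, keep) else
          matrix(integer(0), ncol = 2)
        if (nrow(segs) == 0) break
      }
      if (nrow(segs))
        pieces[[length(pieces) + 1]] <- data.frame(
          genome = unaligned$genome[r], start = segs[, 1], end = segs[, 2],
          reason = unaligned$reason[r], stringsAsFactors = FALSE)
    }
    unaligned <- if (length(pieces)) do.call(rbind, pieces) else
      unaligned[0, , drop = FALSE]
    rownames(unaligned) <- NULL
  }
  list(blocks = blocks, unaligned = unaligned)
}

#' Align two genomes end to end
#'
#' Convenience wrapper: [find_anchors()], [chain_anchors()], [close_gaps()].
#'
#' @inheritParams find_anchors
#' @inheritParams close_gaps
#' @return as [close_gaps()], plus `anchors` and `chains`
#' @export
align_genomes <- function(seqA, seqB, k = 20, max_gap = 5000, band = 200) {
  if (inherits(seqA, "GenomeRecord")) seqA <- seqA$seq
  if (inherits(seqB, "GenomeRecord")) seqB <- seqB$seq
  anchors <- find_anchors(seqA, seqB, k)
  chains <- chain_anchors(anchors)
  res <- close_gaps(chains, seqA, seqB, max_gap = max_gap, band = band)
  res$anchors <- anchors
  res$chains <- chains
  res
}

#' Extract substitution records from alignment blocks
#'
#' One record per mismatch column. Positions are reported on the forward
#' strand of both genomes; in reverse-orientation blocks `baseB` is the
#' forward-strand base at `posB`. Columns involving N are excluded and
#' counted in the `n_excluded` attribute.
#'
#' @param blocks list of [alignment_block()]s (or the list from
#'   [close_gaps()]/[align_genomes()])
#' @return data frame: posA, posB, baseA, baseB, orientation; attribute
#'   `n_excluded` counts N-containing mismatch columns
#' @export
call_snps <- function(blocks) {
  if (!is.null(blocks$blocks)) blocks <- blocks$blocks
  out <- list()
  n_excl <- 0L
  for (b in blocks) {
    ed <- b$edits
    consA <- ifelse(ed$type %in% c("M", "X", "IA"), ed$length, 0L)
    consB <- ifelse(ed$type %in% c("M", "X", "IB"), ed$length, 0L)
    offA <- cumsum(c(0L, consA))[seq_len(nrow(ed))]
    offB <- cumsum(c(0L, consB))[seq_len(nrow(ed))]
    xs <- which(ed$type == "X")
    if (!length(xs)) next
    for (i in xs) {
      ln <- ed$length[i]
      ba <- strsplit(ed$basesA[i], "")[[1]]
      bb <- strsplit(ed$basesB[i], "")[[1]]
      posA <- b$intervalA[1] + offA[i] + 0:(ln - 1)
      if (b$orientation == "forward") {
        posB <- b$intervalB[1] + offB[i] + 0:(ln - 1)
        baseB_fwd <- bb
      } else {
        posB <- b$intervalB[2] - 1L - (offB[i] + 0:(ln - 1))
        baseB_fwd <- comp_base(bb)
      }
      keepN <- ba != "N" & bb != "N"
      n_excl <- n_excl + sum(!keepN)
      if (any(keepN))
        out[[length(out) + 1]] <- data.frame(
          posA = posA[keepN], posB = posB[keepN], baseA = ba[keepN],
          baseB = baseB_fwd[keepN], orientation = b$orientation,
          stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(posA = integer(), posB = integer(), baseA = character(),
               baseB = character(), orientation = character(),
               stringsAsFactors = FALSE)
  res <- res[order(res$posA), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_excluded") <- n_excl
  res
}

#' Alignment identity report
#'
#' Two denominator conventions are provided. `core`: matches over
#' match+mismatch columns only, i.e. unaligned segments and indel columns
#' excluded — the convention behind a "large insertions removed" core
#' identity. `whole`: gap columns and unaligned segment lengths (both
#' genomes) join the denominator — a whole-genome average-identity figure.
#'
#' @param aln result of [close_gaps()]/[align_genomes()], or a list of blocks
#' @param unaligned unaligned-segment data frame (ignored when `aln` carries
#'   one)
#' @param mode `"core"` or `"whole"`
#' @return list with aligned_len, matches, pct
#' @export
identity_report <- function(aln, unaligned = NULL, mode = c("core", "whole")) {
  mode <- match.arg(mode)
  if (!is.null(aln$blocks)) {
    unaligned <- aln$unaligned
    blocks <- aln$blocks
  } else blocks <- aln
  if (length(blocks) == 0) stop("empty alignment")
  m <- mm <- gp <- 0
  for (b in blocks) {
    ed <- b$edits
    m <- m + sum(ed$length[ed$type == "M"])
    mm <- mm + sum(ed$length[ed$type == "X"])
    gp <- gp + sum(ed$length[ed$type %in% c("IA", "IB")])
  }
  un <- if (is.null(unaligned) || nrow(unaligned) == 0) 0 else
    sum(unaligned$end - unaligned$start)
  denom <- if (mode == "core") m + mm else m + mm + gp + un
  if (denom == 0) stop("empty alignment")
  list(mode = mode, aligned_len = denom, matches = m,
       pct = 100 * m / denom)
}
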