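# GC-skew profiling, replication origin/terminus prediction from the
# cumulative skew curve, and ranking of repeat-mediated inversion scenarios
# by the symmetry they restore.

#' Windowed and cumulative GC skew
#'
#' Windowed skew is (G-C)/(G+C) per window; the cumulative curve is the
#' running sum of per-base increments (+1 for G, -1 for C, 0 otherwise).
#' For circular genomes windows wrap around the origin of the coordinate
#' system. Windows without G or C yield 0 and are flagged degenerate.
#'
#' @param genome a [genome_record()] or DNA string
#' @param window window size in bp (>= 100)
#' @param step step between window starts (<= window)
#' @return object of class `SkewProfile`: list with pos (window starts),
#'   skew, degenerate, cumulative (length L+1, cumulative[1] == 0), window,
#'   step, length
#' @export
gc_skew <- function(genome, window = 10000, step = 1000) {
  circular <- TRUE
  if (inherits(genome, "GenomeRecord")) {
    circular <- genome$topology == "circular"
    genome <- genome$seq
  }
  L <- nchar(genome)
  stopifnot(window >= 100, step <= window, step >= 1)
  if (window > L) stop("window larger than genome")
  v <- charToRaw(genome)
  inc <- integer(L)
  inc[v == charToRaw("G")] <- 1L
  inc[v == charToRaw("C")] <- -1L
  gcm <- integer(L)
  gcm[inc != 0L] <- 1L
  cum <- c(0, cumsum(inc))
  cgc <- c(0, cumsum(gcm))
  starts <- seq(0L, if (circular) L - 1L else L - window, by = step)
  ends <- starts + window
  wsum <- function(cs, s, e) {
    # circular-aware window sum over [s, e)
    over <- pmax(e - L, 0L)
    cs[pmin(e, L) + 1L] - cs[s + 1L] + ifelse(over > 0, cs[over + 1L], 0)
  }
  gc_n <- wsum(cgc, starts, ends)
  sk_n <- wsum(cum, starts, ends)
  degenerate <- gc_n == 0
  skew <- ifelse(degenerate, 0, sk_n / pmax(gc_n, 1L))
  structure(list(pos = starts, skew = skew, degenerate = degenerate,
                 cumulative = cum, window = window, step = step,
                 length = L, circular = circular),
            class = "SkewProfile")
}

#' Predict replication origin and terminus from cumulative GC skew
#'
#' The origin is called at the global minimum of the cumulative curve and
#' the terminus at the global maximum. When a dnaA locus position is given
#' and lies within `dnaa_radius` of a local minimum, that minimum is
#' preferred (and the choice reported).
#'
#' @param profile a [gc_skew()] profile
#' @param dnaA_pos optional position of the dnaA gene
#' @param dnaa_radius search radius around dnaA in bp
#' @return list with origin, terminus, confident, and note
#' @export
predict_origin <- function(profile, dnaA_pos = NULL, dnaa_radius = 50000) {
  cum <- profile$cumulative
  L <- profile$length
  if ((max(cum) - min(cum)) < 0.001 * L)
    return(list(origin = NA_integer_, terminus = NA_integer_,
                confident = FALSE, note = "no confident call: flat cumulative skew"))
  origin <- which.min(cum) - 1L
  terminus <- which.max(cum) - 1L
  note <- "global extrema of cumulative skew"
  if (!is.null(dnaA_pos)) {
    # local minima on the window grid
    grid <- unique(pmin(profile$pos, L))
    gv <- cum[grid + 1L]
    n <- length(gv)
    if (n >= 3) {
      loc <- which(gv < c(Inf, gv[-n]) & gv < c(gv[-1], Inf))
      cand <- grid[loc]
      circ_d <- pmin(abs(cand - dnaA_pos), L - abs(cand - dnaA_pos))
      near <- which(circ_d <= dnaa_radius)
      if (length(near)) {
        pick <- cand[near[which.min(gv[loc][near])]]
        # refine the grid point to the exact minimum within one window
        lo <- max(0L, pick - profile$window)
        hi <- min(L, pick + profile$window)
        pick <- lo + which.min(cum[(lo + 1L):(hi + 1L)]) - 1L
        if (pick != origin) {
          origin <- pick
          note <- sprintf("local minimum within %d bp of dnaA preferred",
                          as.integer(dnaa_radius))
        }
      }
    }
  }
  list(origin = origin, terminus = terminus, confident = TRUE, note = note)
}

#' Replichore symmetry score
#'
#' Pearson correlation between the cumulative-skew curve of arm 1 (origin to
#' terminus) and the negated, reversed curve of arm 2 (terminus back to the
#' origin), after resampling both arms to a common number of points. Both
#' traversals then rise from the origin minimum to the terminus maximum, so
#' two clean opposite-signed arms score near 1, while an inversion inside an
#' arm produces a kink that lowers the correlation. (Correlating raw
#' per-window increments instead would carry no signal for clean arms: the
#' increment expectation is constant within an arm, leaving only sampling
#' noise.)
#'
#' @param profile a [gc_skew()] profile
#' @param origin,terminus positions from [predict_origin()]
#' @param npoints resampling resolution
#' @return numeric score in `[-1, 1]`
#' @export
symmetry_score <- function(profile, origin, terminus, npoints = 200) {
  L <- profile$length
  if (origin == terminus) stop("origin and terminus coincide")
  arm1_len <- (terminus - origin) %% L
  arm2_len <- L - arm1_len
  if (min(arm1_len, arm2_len) < 10 * profile$window)
    stop("arm shorter than 10 windows")
  cum_at <- function(p) profile$cumulative[(p %% L) + 1L]
  samp <- function(from, len) {
    at <- from + round(seq(0, len, length.out = npoints + 1))
    vapply(at, cum_at, 0)
  }
  v1 <- samp(origin, arm1_len)
  v2 <- samp(terminus, arm2_len)
  # mirroring arm 2 (origin-wards traversal) already absorbs the negation:
  # both curves then rise from the origin minimum to the terminus maximum
  stats::cor(v1, rev(v2))
}

#' Apply a sequence inversion in place
#'
#' Reverse-complements `[i, j)`, remaps features inside (strand flipped) and
#' flags features straddling a breakpoint as broken. Applying the same
#' inversion twice restores the input.
#'
#' @param genome a [genome_record()]
#' @param i,j 0-based half-open breakpoints, `0 <= i < j <= length`
#' @return the modified [genome_record()]
#' @export
apply_inversion <- function(genome, i, j) {
  L <- nchar(genome$seq)
  stopifnot(i >= 0, i < j, j <= L)
  seg <- revcomp(sub0(genome$seq, i, j))
  seq <- paste0(sub0(genome$seq, 0, i), seg, sub0(genome$seq, j, L))
  f <- genome$features
  if (nrow(f)) {
    inside <- f$start >= i & f$end <= j
    straddle <- (f$start < i & f$end > i) | (f$start < j & f$end > j)
    ns <- i + j - f$end[inside]
    ne <- i + j - f$start[inside]
    f$start[inside] <- ns
    f$end[inside] <- ne
    f$strand[inside] <- ifelse(f$strand[inside] == "+", "-", "+")
    f$broken <- f$broken | straddle
    f <- f[order(f$start, f$end), , drop = FALSE]
    rownames(f) <- NULL
  }
  genome$seq <- seq
  genome$features <- f
  genome
}

#' Rank repeat-mediated inversion scenarios
#'
#' For every inverted repeat pair, the segment between the pair's midpoints
#' is tentatively inverted and the candidate scored by (a) the change in
#' replichore symmetry and (b), when a reference genome is supplied, the
#' change in anchor-chain collinearity against it (fraction of total
#' anchor weight captured by the single best collinear chain). The two
#' improvements get equal weight. Ordering is deterministic; ties break
#' towards the smaller first breakpoint.
#'
#' @param genome a [genome_record()]
#' @param repeat_pairs data frame of repeat pairs (see [maximal_repeats()]);
#'   only `orientation == "inverted"` rows are considered
#' @param reference_genome optional [genome_record()] for the collinearity
#'   component
#' @param window,step skew profile parameters
#' @return data frame of candidates ranked best-first: breakpoints,
#'   symmetry before/after, collinearity deltas, combined score, rank
#' @export
rank_rearrangements <- function(genome, repeat_pairs, reference_genome = NULL,
                                window = 10000, step = 1000) {
  inv <- repeat_pairs[repeat_pairs$orientation == "inverted", , drop = FALSE]
  if (nrow(inv) == 0)
    return(data.frame(b1 = integer(), b2 = integer(),
                      symmetry_before = numeric(), symmetry_after = numeric(),
                      collinearity_delta = numeric(), score = numeric(),
                      rank = integer(), stringsAsFactors = FALSE))
  prof <- gc_skew(genome, window, step)
  oc <- predict_origin(prof)
  sym0 <- if (oc$confident)
    tryCatch(symmetry_score(prof, oc$origin, oc$terminus),
             error = function(e) NA_real_) else NA_real_
  collin <- function(g) {
    a <- find_anchors(g$seq, reference_genome$seq, 20)
    if (nrow(a) == 0) return(0)
    ch <- chain_anchors(a)
    if (length(ch) == 0) return(0)
    best <- max(vapply(ch, function(x) sum(x$length), 0))
    best / sum(a$length)
  }
  col0 <- if (!is.null(reference_genome)) collin(genome) else NA_real_
  rows <- lapply(seq_len(nrow(inv)), function(r) {
    m1 <- (inv$startA[r] + inv$endA[r]) %/% 2L
    m2 <- (inv$startB[r] + inv$endB[r]) %/% 2L
    b1 <- min(m1, m2); b2 <- max(m1, m2)
    g2 <- apply_inversion(genome, b1, b2)
    p2 <- gc_skew(g2, window, step)
    oc2 <- predict_origin(p2)
    sym2 <- if (oc2$confident)
      tryCatch(symmetry_score(p2, oc2$origin, oc2$terminus),
               error = function(e) NA_real_) else NA_real_
    dsym <- if (!is.na(sym2) && !is.na(sym0)) sym2 - sym0 else 0
    dcol <- if (!is.null(reference_genome)) collin(g2) - col0 else NA_real_
    score <- if (is.na(dcol)) dsym else (dsym + dcol) / 2
    data.frame(b1 = b1, b2 = b2, symmetry_before = sym0,
               symmetry_after = sym2, collinearity_delta = dcol,
               score = score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$score, out$b1, out$b2)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write a skew profile as TSV (position, windowed skew, cumulative)
#' @param profile a [gc_skew()] profile
#' @param path output file
#' @export
write_skew_tsv <- function(profile, path) {
  df <- data.frame(pos = profile$pos, skew = profile$skew,
                   cumulative = profile$cumulative[profile$pos + 1L])
  write_tsv_stable(df, path)
}
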