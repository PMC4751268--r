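# Genome data model and readers/writers for the external formats the pipeline
# consumes: FASTA, GenBank flat files, GFF3 (+FASTA), XMFA alignment blocks,
# 12-column tabular protein-search hits and pfam_scan-style domain tables.
#
# All internal coordinates are 0-based half-open on the forward strand; strand
# is carried as a flag and feature sequences are never stored reverse
# complemented.

#' Feature table skeleton
#'
#' Features are stored as a plain data frame with 0-based half-open
#' `[start, end)` intervals on the forward strand.
#'
#' @return an empty feature data frame with the canonical columns
#' @export
empty_features <- function() {
  data.frame(locus_tag = character(), ftype = character(),
             start = integer(), end = integer(), strand = character(),
             product = character(), translation = character(),
             pseudo = logical(), codon_ok = logical(), broken = logical(),
             stringsAsFactors = FALSE)
}

normalize_features <- function(features, seqlen) {
  tmpl <- empty_features()
  for (cn in names(tmpl)) {
    if (is.null(features[[cn]])) {
      features[[cn]] <- if (cn == "codon_ok") rep(TRUE, nrow(features))
        else if (cn %in% c("pseudo", "broken")) rep(FALSE, nrow(features))
        else rep(vector(class(tmpl[[cn]]), 1), nrow(features))
    }
  }
  features <- features[, names(tmpl), drop = FALSE]
  if (nrow(features)) {
    stopifnot(all(features$start < features$end),
              all(features$start >= 0), all(features$end <= seqlen),
              all(features$strand %in% c("+", "-")))
    features <- features[order(features$start, features$end), , drop = FALSE]
    rownames(features) <- NULL
  }
  features
}

#' Construct a GenomeRecord
#'
#' The shared container for a (usually circular) bacterial replicon: an
#' uppercase DNA sequence over `{A,C,G,T,N}` plus an ordered, typed, stranded
#' feature table.
#'
#' @param id nonempty record identifier
#' @param seq DNA string; lowercase is uppercased, characters outside ACGTN
#'   are replaced by N (a warning reports the count)
#' @param topology `"circular"` or `"linear"`
#' @param features feature data frame (see [empty_features()])
#' @param meta free-form list for simulator bookkeeping
#' @return an object of class `GenomeRecord`
#' @export
genome_record <- function(id, seq, topology = c("circular", "linear"),
                          features = empty_features(), meta = list()) {
  topology <- match.arg(topology)
  if (!nzchar(id)) stop("genome id must be nonempty")
  seq <- toupper(seq)
  bad <- nchar(seq) - sum(charToRaw(seq) %in% charToRaw("ACGTN"))
  if (bad > 0) {
    warning(sprintf("%s: %d non-ACGTN characters replaced by N", id, bad))
    seq <- gsub("[^ACGTN]", "N", seq)
  }
  features <- normalize_features(features, nchar(seq))
  structure(list(id = id, topology = topology, seq = seq,
                 features = features, meta = meta),
            class = "GenomeRecord")
}

#' @export
print.GenomeRecord <- function(x, ...) {
  cat(sprintf("GenomeRecord %s: %s, %d bp, %d features (%d CDS)\n",
              x$id, x$topology, nchar(x$seq), nrow(x$features),
              sum(x$features$ftype == "CDS")))
  invisible(x)
}

#' @export
length.GenomeRecord <- function(x) nchar(x$seq)

cds_features <- function(genome) {
  genome$features[genome$features$ftype == "CDS", , drop = FALSE]
}

# ---------------------------------------------------------------------------
# FASTA
# ---------------------------------------------------------------------------

#' Read a FASTA file into GenomeRecords
#'
#' @param path FASTA file
#' @param topology applied to every record
#' @return list of [genome_record()]s with empty feature tables
#' @export
read_fasta <- function(path, topology = "circular") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("FASTA format error in ", path, ": ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("FASTA format error: no records in ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id: ", dup[1])
  lapply(seq_along(set), function(i)
    genome_record(ids[i], as.character(set[[i]]), topology = topology))
}

#' Write GenomeRecords (or named sequences) as FASTA
#' @param x list of GenomeRecords, a single GenomeRecord, or a named
#'   character vector of sequences
#' @param path output file
#' @param width line width
#' @export
write_fasta <- function(x, path, width = 70) {
  if (inherits(x, "GenomeRecord")) x <- list(x)
  if (is.list(x)) {
    seqs <- vapply(x, function(g) g$seq, "")
    names(seqs) <- vapply(x, function(g) g$id, "")
  } else seqs <- x
  con <- file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# GenBank flat file (single locus). Hand-parsed: only the feature keys and
# qualifiers the pipeline uses are retained.
# ---------------------------------------------------------------------------

GB_FTYPES <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
               repeat_region = "repeat_region", mobile_element = "mobile_element")

parse_gb_location <- function(loc) {
  strand <- "+"
  compound <- FALSE
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    compound <- TRUE
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  if (grepl("complement", loc)) { compound <- TRUE; loc <- gsub("complement\\(|\\)", "", loc) }
  parts <- strsplit(loc, ",", fixed = TRUE)[[1]]
  nums <- suppressWarnings(lapply(strsplit(gsub("[<>]", "", parts), "\\.\\."),
                                  as.integer))
  lo <- min(vapply(nums, min, 1L))
  hi <- max(vapply(nums, max, 1L))
  if (is.na(lo) || is.na(hi)) stop("unparseable GenBank location: ", loc)
  list(start = lo - 1L, end = hi, strand = strand,
       compound = compound || length(parts) > 1)
}

#' Read a single-locus GenBank flat file
#'
#' CDS/rRNA/tRNA/repeat_region/mobile_element features are retained with
#' coordinates converted to 0-based half-open. Compound (join) locations are
#' kept for neighborhood purposes but flagged (`codon_ok = FALSE`) and
#' excluded from codon-level analyses.
#'
#' @param path GenBank flat file
#' @return a [genome_record()]
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)[1]
  if (is.na(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  toks <- strsplit(trimws(locus), "\\s+")[[1]]
  id <- toks[2]
  topo <- if (any(tolower(toks) == "circular")) "circular" else "linear"
  ofs <- grep("^ORIGIN", lines)
  if (length(ofs) == 0) stop("GenBank file has no ORIGIN section: ", path)
  ofs <- ofs[1]
  seq_lines <- lines[(ofs + 1):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  seq <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))

  ffs <- grep("^FEATURES", lines)
  feats <- empty_features()
  if (length(ffs)) {
    body <- lines[(ffs[1] + 1):(ofs - 1)]
    # a new feature starts at column 6; qualifiers are further indented
    starts <- grep("^ {5}\\S", body)
    for (si in seq_along(starts)) {
      from <- starts[si]
      to <- if (si < length(starts)) starts[si + 1] - 1 else length(body)
      key <- sub("^ {5}(\\S+).*$", "\\1", body[from])
      if (!key %in% names(GB_FTYPES)) next
      chunk <- body[from:to]
      # location may continue over lines until the first qualifier
      qual_at <- grep("^\\s+/", chunk)
      loc_end <- if (length(qual_at)) qual_at[1] - 1 else length(chunk)
      loc <- paste(trimws(sub("^ {5}\\S+\\s*", "", chunk[1])),
                   if (loc_end > 1) paste(trimws(chunk[2:loc_end]), collapse = "") else "",
                   sep = "")
      pl <- parse_gb_location(loc)
      if (pl$end > nchar(seq))
        stop(sprintf("feature %s..%d beyond sequence end in %s",
                     key, pl$end, path))
      qual <- function(name) {
        hit <- grep(paste0("^\\s+/", name, "="), chunk)
        if (!length(hit)) return(NA_character_)
        val <- sub(paste0("^\\s+/", name, "="), "", chunk[hit[1]])
        # multiline quoted values
        if (startsWith(val, "\"") && !grepl("\"$", sub("^\"", "", val))) {
          j <- hit[1] + 1
          while (j <= length(chunk) && !grepl("\"\\s*$", chunk[j - 1])) {
            val <- paste0(val, if (name == "translation") "" else " ",
                          trimws(chunk[j]))
            j <- j + 1
          }
        }
        gsub("^\"|\"$", "", val)
      }
      pseudo <- any(grepl("^\\s+/pseudo\\s*$", chunk))
      tag <- qual("locus_tag")
      if (is.na(tag)) tag <- sprintf("%s_%d_%d", GB_FTYPES[[key]], pl$start, pl$end)
      codon_ok <- !pl$compound && !pseudo &&
        (key != "CDS" || (pl$end - pl$start) %% 3 == 0)
      feats <- rbind(feats, data.frame(
        locus_tag = tag, ftype = GB_FTYPES[[key]],
        start = pl$start, end = pl$end, strand = pl$strand,
        product = qual("product") %||% NA_character_,
        translation = qual("translation"),
        pseudo = pseudo, codon_ok = codon_ok, broken = FALSE,
        stringsAsFactors = FALSE))
    }
  }
  genome_record(id, seq, topology = topo, features = feats)
}

#' Write a GenomeRecord as a minimal GenBank flat file
#' @param genome a [genome_record()]
#' @param path output file
#' @export
write_genbank <- function(genome, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s   BCT",
                     genome$id, nchar(genome$seq), genome$topology), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", f$ftype[i], loc), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"", f$locus_tag[i]), con)
    if (!is.na(f$product[i]) && nzchar(f$product[i]))
      writeLines(sprintf("                     /product=\"%s\"", f$product[i]), con)
    if (isTRUE(f$pseudo[i]))
      writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(genome$seq)
  pos <- seq(1, nchar(s), by = 60)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59, nchar(s)))
    parts <- substring(chunk, seq(1, nchar(chunk), 10),
                       pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(parts, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

# ---------------------------------------------------------------------------
# GFF3 (+FASTA)
# ---------------------------------------------------------------------------

GFF_FTYPES <- c(CDS = "CDS", rRNA = "rRNA", tRNA = "tRNA",
                repeat_region = "repeat_region",
                mobile_genetic_element = "mobile_element",
                mobile_element = "mobile_element")

#' Read a GFF3 annotation plus its FASTA sequence
#'
#' GFF 1-based inclusive coordinates are converted to 0-based half-open.
#' CDS rows with nonzero phase are flagged and excluded from codon-level
#' analyses; rows lacking a locus_tag get a deterministic synthetic id.
#'
#' @param gff_path GFF3 file
#' @param fasta_path FASTA file with the record's sequence
#' @return a [genome_record()]
#' @export
read_gff3 <- function(gff_path, fasta_path) {
  gen <- read_fasta(fasta_path)[[1]]
  gr <- rtracklayer::import.gff3(gff_path)
  keep <- as.character(gr$type) %in% names(GFF_FTYPES)
  gr <- gr[keep]
  if (length(gr) == 0)
    return(genome_record(gen$id, gen$seq, topology = gen$topology))
  start <- BiocGenerics::start(gr) - 1L
  end <- BiocGenerics::end(gr)
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  ftype <- unname(GFF_FTYPES[as.character(gr$type)])
  attr_chr <- function(x, n) {
    if (is.null(x)) return(rep(NA_character_, n))
    vapply(as.list(x), function(v)
      if (length(v) && !all(is.na(v))) paste(v, collapse = ",")
      else NA_character_, "")
  }
  tag <- attr_chr(gr$locus_tag, length(gr))
  if (anyNA(tag)) {
    miss <- is.na(tag)
    alt <- attr_chr(gr$ID, length(gr))
    tag[miss] <- alt[miss]
    still <- is.na(tag)
    if (any(still)) {
      warning(sprintf("%d features lack locus_tag; synthetic ids assigned",
                      sum(still)))
      tag[still] <- sprintf("%s_%d_%d", ftype[still], start[still], end[still])
    }
  }
  phase <- if (!is.null(gr$phase)) as.integer(gr$phase) else rep(0L, length(gr))
  phase[is.na(phase)] <- 0L
  codon_ok <- ftype != "CDS" | (phase == 0L & (end - start) %% 3 == 0L)
  product <- attr_chr(gr$product, length(gr))
  feats <- data.frame(locus_tag = tag, ftype = ftype, start = start, end = end,
                      strand = strand, product = product,
                      translation = NA_character_, pseudo = FALSE,
                      codon_ok = codon_ok, broken = FALSE,
                      stringsAsFactors = FALSE)
  genome_record(gen$id, gen$seq, topology = gen$topology, features = feats)
}

#' Write a GenomeRecord annotation as GFF3 (sequence written separately)
#' @param genome a [genome_record()]
#' @param path output GFF3 file
#' @export
write_gff3 <- function(genome, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", genome$id, nchar(genome$seq)), con)
  f <- genome$features
  gfft <- names(GFF_FTYPES)[match(f$ftype, GFF_FTYPES)]
  for (i in seq_len(nrow(f))) {
    attrs <- sprintf("ID=%s;locus_tag=%s", f$locus_tag[i], f$locus_tag[i])
    if (!is.na(f$product[i]) && nzchar(f$product[i]))
      attrs <- paste0(attrs, ";product=", gsub("[;=\t]", " ", f$product[i]))
    if (isTRUE(f$pseudo[i])) attrs <- paste0(attrs, ";pseudo=true")
    writeLines(paste(genome$id, "sistercomp", gfft[i], f$start[i] + 1L,
                     f$end[i], ".", f$strand[i], "0", attrs, sep = "\t"), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# XMFA (pairwise blocks only)
# ---------------------------------------------------------------------------

#' Read a pairwise XMFA alignment
#'
#' Each block must contain exactly two tracks. Coordinates are converted to
#' 0-based half-open on the forward strand; reverse-strand tracks are stored
#' via the block orientation flag.
#'
#' @param path XMFA file
#' @return list of alignment blocks (see [alignment_block()])
#' @export
read_xmfa <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  blocks <- list()
  cur_hdr <- character()
  cur_seq <- character()
  flush <- function() {
    if (length(cur_hdr) == 0) return(NULL)
    if (length(cur_hdr) != 2)
      stop("XMFA block with ", length(cur_hdr), " tracks; pairwise only")
    m <- regmatches(cur_hdr, regexec("^>\\s*(\\S+):(\\d+)-(\\d+)\\s+([+-])", cur_hdr))
    info <- lapply(m, function(x) {
      if (length(x) != 5) stop("unparseable XMFA header: ", x[1] %||% "?")
      list(id = x[2], start = as.integer(x[3]) - 1L, end = as.integer(x[4]),
           strand = x[5])
    })
    gapped_to_block(cur_seq[1], cur_seq[2], info[[1]], info[[2]])
  }
  i <- 1
  seqbuf <- NULL
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      cur_hdr <- c(cur_hdr, ln)
      cur_seq <- c(cur_seq, "")
    } else if (startsWith(ln, "=")) {
      b <- flush()
      if (!is.null(b)) blocks[[length(blocks) + 1]] <- b
      cur_hdr <- character(); cur_seq <- character()
    } else if (nzchar(ln)) {
      if (length(cur_seq)) cur_seq[length(cur_seq)] <- paste0(cur_seq[length(cur_seq)], ln)
    }
  }
  b <- flush()
  if (!is.null(b)) blocks[[length(blocks) + 1]] <- b
  blocks
}

# convert two gapped strings into a run-length edit list
gapped_to_block <- function(ga, gb, infoA, infoB) {
  a <- strsplit(toupper(ga), "")[[1]]
  b <- strsplit(toupper(gb), "")[[1]]
  if (length(a) != length(b)) stop("XMFA tracks of unequal alignment length")
  op <- ifelse(a == "-", 3L, ifelse(b == "-", 2L, ifelse(a == b, 0L, 1L)))
  orientation <- if (infoA$strand == infoB$strand) "forward" else "reverse"
  block_from_ops(op, a, b,
                 startA = infoA$start, startB = infoB$start,
                 orientation = orientation)
}

#' Alignment block constructor
#'
#' A collinear aligned segment pair with base-level edits. `edits` is a
#' run-length data frame with `type` in `M` (match run), `X` (mismatch run),
#' `IA` (bases present in A only), `IB` (bases present in B only); `basesA`
#' and `basesB` carry the literal bases for non-match runs. For
#' `orientation == "reverse"`, edits follow A's forward strand against the
#' reverse complement of B, and `intervalB` is on B's forward strand.
#'
#' @param intervalA,intervalB 0-based half-open intervals
#' @param orientation `"forward"` or `"reverse"`
#' @param edits run-length edit data frame
#' @return an object of class `AlignmentBlock`
#' @export
alignment_block <- function(intervalA, intervalB, orientation, edits) {
  consA <- sum(edits$length[edits$type %in% c("M", "X", "IA")])
  consB <- sum(edits$length[edits$type %in% c("M", "X", "IB")])
  stopifnot(consA == intervalA[2] - intervalA[1],
            consB == intervalB[2] - intervalB[1])
  structure(list(intervalA = intervalA, intervalB = intervalB,
                 orientation = orientation, edits = edits),
            class = "AlignmentBlock")
}

# build an AlignmentBlock from per-column integer ops
# (0 match, 1 mismatch, 2 A-only, 3 B-only), with literal column bases
block_from_ops <- function(op, a_cols, b_cols, startA, startB,
                           orientation = "forward") {
  r <- rle(op)
  type <- c("M", "X", "IA", "IB")[r$values + 1L]
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  basesA <- basesB <- rep("", length(r$lengths))
  nonm <- which(r$values != 0L)
  for (i in nonm) {
    cols <- starts[i]:ends[i]
    if (r$values[i] != 3L) basesA[i] <- paste(a_cols[cols], collapse = "")
    if (r$values[i] != 2L) basesB[i] <- paste(b_cols[cols], collapse = "")
    basesA[i] <- gsub("-", "", basesA[i])
    basesB[i] <- gsub("-", "", basesB[i])
  }
  edits <- data.frame(type = type, length = r$lengths, basesA = basesA,
                      basesB = basesB, stringsAsFactors = FALSE)
  lenA <- sum(edits$length[edits$type %in% c("M", "X", "IA")])
  lenB <- sum(edits$length[edits$type %in% c("M", "X", "IB")])
  alignment_block(c(startA, startA + lenA), c(startB, startB + lenB),
                  orientation, edits)
}

# reconstruct the two gapped strings of a block from the genome sequences
block_gapped <- function(block, seqA, seqB) {
  sa <- sub0(seqA, block$intervalA[1], block$intervalA[2])
  sb <- sub0(seqB, block$intervalB[1], block$intervalB[2])
  if (block$orientation == "reverse") sb <- revcomp(sb)
  ga <- character(nrow(block$edits))
  gb <- character(nrow(block$edits))
  pa <- 0L; pb <- 0L
  for (i in seq_len(nrow(block$edits))) {
    ty <- block$edits$type[i]; ln <- block$edits$length[i]
    if (ty %in% c("M", "X", "IA")) { ga[i] <- sub0(sa, pa, pa + ln); pa <- pa + ln }
    else ga[i] <- strrep("-", ln)
    if (ty %in% c("M", "X", "IB")) { gb[i] <- sub0(sb, pb, pb + ln); pb <- pb + ln }
    else gb[i] <- strrep("-", ln)
  }
  list(a = paste(ga, collapse = ""), b = paste(gb, collapse = ""))
}

#' Write alignment blocks as XMFA
#' @param blocks list of [alignment_block()]s
#' @param genomeA,genomeB the aligned [genome_record()]s
#' @param path output file
#' @export
write_xmfa <- function(blocks, genomeA, genomeB, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("#FormatVersion Mauve1", con)
  for (b in blocks) {
    g <- block_gapped(b, genomeA$seq, genomeB$seq)
    writeLines(sprintf("> %s:%d-%d + pairwise", genomeA$id,
                       b$intervalA[1] + 1L, b$intervalA[2]), con)
    writeLines(wrap_seq(g$a), con)
    sB <- if (b$orientation == "reverse") "-" else "+"
    writeLines(sprintf("> %s:%d-%d %s pairwise", genomeB$id,
                       b$intervalB[1] + 1L, b$intervalB[2], sB), con)
    writeLines(wrap_seq(g$b), con)
    writeLines("=", con)
  }
  invisible(path)
}

wrap_seq <- function(s, width = 80) {
  starts <- seq(1, nchar(s), by = width)
  substring(s, starts, pmin(starts + width - 1, nchar(s)))
}

# ---------------------------------------------------------------------------
# 12-column tabular search hits ("outfmt 6" dialect)
# ---------------------------------------------------------------------------

#' Read 12-column tabular protein-search hits
#'
#' @param path tab-separated file with the standard 12 columns
#'   (query, subject, pct_id, length, mismatches, gapopen, qstart, qend,
#'   sstart, send, evalue, bitscore)
#' @return data frame of hits, rows in file order
#' @export
read_search_tab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  cols <- c("query", "subject", "pct_id", "length", "mismatches", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  if (length(lines) == 0) {
    out <- as.data.frame(setNames(rep(list(character()), 12), cols))
    out[3:12] <- lapply(out[3:12], as.numeric)
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(parts)
  if (any(nc != 12))
    stop(sprintf("line %d: expected 12 tab-separated columns, got %d",
                 which(nc != 12)[1], nc[nc != 12][1]))
  m <- do.call(rbind, parts)
  out <- data.frame(query = m[, 1], subject = m[, 2], stringsAsFactors = FALSE)
  num <- apply(m[, 3:12, drop = FALSE], 2, as.numeric)
  if (is.null(dim(num))) num <- matrix(num, nrow = 1)
  colnames(num) <- cols[3:12]
  cbind(out, as.data.frame(num))
}

#' Write hits in the 12-column tabular dialect
#' @param hits data frame as returned by [read_search_tab()]
#' @param path output file
#' @export
write_search_tab <- function(hits, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  if (nrow(hits)) {
    lines <- sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
                     hits$query, hits$subject, hits$pct_id,
                     as.integer(hits$length), as.integer(hits$mismatches),
                     as.integer(hits$gapopen), as.integer(hits$qstart),
                     as.integer(hits$qend), as.integer(hits$sstart),
                     as.integer(hits$send),
                     formatC(hits$evalue, format = "e", digits = 2),
                     hits$bitscore)
    writeLines(lines, con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# pfam_scan-style domain table
# ---------------------------------------------------------------------------

#' Read pfam_scan-style domain hits
#'
#' Whitespace-delimited rows; `#` comment lines skipped. Envelope
#' coordinates (columns 2-3) are converted from 1-based inclusive to
#' 0-based half-open; the hmm-name column supplies `domain_name`.
#'
#' @param path pfam_scan output file
#' @return data frame of `DomainHit`s: locus_tag, env_start, env_end,
#'   domain_name, evalue
#' @export
read_domtab <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (!length(lines))
    return(data.frame(locus_tag = character(), env_start = integer(),
                      env_end = integer(), domain_name = character(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  parts <- strsplit(trimws(lines), "\\s+")
  bad <- which(lengths(parts) < 13)
  if (length(bad))
    stop(sprintf("line %d: unparseable pfam_scan row", lineno[bad[1]]))
  m <- do.call(rbind, lapply(parts, function(p) p[1:13]))
  ev <- suppressWarnings(as.numeric(m[, 13]))
  es <- suppressWarnings(as.integer(m[, 4]))
  ee <- suppressWarnings(as.integer(m[, 5]))
  bad <- which(is.na(ev) | is.na(es) | is.na(ee))
  if (length(bad))
    stop(sprintf("line %d: unparseable pfam_scan row", lineno[bad[1]]))
  data.frame(locus_tag = m[, 1], env_start = es - 1L, env_end = ee,
             domain_name = m[, 7], evalue = ev, stringsAsFactors = FALSE)
}

#' Write domain hits in the pfam_scan-style layout
#' @param hits data frame as from [read_domtab()]
#' @param path output file
#' @export
write_domtab <- function(hits, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines("# <seq id> <aln st> <aln en> <env st> <env en> <hmm acc> <hmm name> <type> <hmm st> <hmm en> <hmm ln> <bit score> <E-value>", con)
  if (nrow(hits)) {
    writeLines(sprintf("%s %d %d %d %d PF00000.0 %s Domain 1 1 1 0.0 %s",
                       hits$locus_tag, hits$env_start + 1L, hits$env_end,
                       hits$env_start + 1L, hits$env_end, hits$domain_name,
                       formatC(hits$evalue, format = "e", digits = 2)), con)
  }
  invisible(path)
}
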