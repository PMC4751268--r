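# Synthetic sister-genome generator. An ancestral circular genome is built
# with non-overlapping random-codon CDSs, rRNA-operon placeholders (one
# inverted pair), multi-copy IS elements and an rdhA-like anchor gene with a
# neighboring regulator. Two sisters are then derived by planting mutations
# (region-specific SNP counts with exact non-synonymous fractions,
# strain-specific IS transpositions, low-GC islands, deletions, and
# repeat-mediated inversions), all recorded in a truth table in the final
# coordinates of both strains. The synonymy class of every planted coding
# SNP is verified at planting time by translating the full unmutated and
# mutated CDS and comparing — a code path independent of the codon-local
# classifier in the variants stage.

#' Simulate an ancestral circular genome
#'
#' @param n_genes number of protein-coding genes (>= 1)
#' @param n_rrna_operons rRNA operon placeholder copies; when more than one,
#'   the last copy is placed inverted so an inverted repeat pair exists
#' @param n_is_elements number of distinct IS element families
#' @param is_copy_counts named integer vector of copies per element (names
#'   default to IS1..ISn); for families with at least two copies, one copy is
#'   placed inverted
#' @param seed integer seed; the same seed reproduces the genome byte for byte
#' @param gc ancestral G+C fraction
#' @param rrna_len,is_len element lengths in bp
#' @return a [genome_record()]; `meta` carries the IS element sequences, the
#'   rdhA-like anchor tag and the rRNA operon sequence
#' @export
simulate_ancestor <- function(n_genes = 200, n_rrna_operons = 3,
                              n_is_elements = 3, is_copy_counts = NULL,
                              seed = 1, gc = 0.45, rrna_len = 4000,
                              is_len = 1000) {
  stopifnot(n_genes >= 1, n_rrna_operons >= 1, n_is_elements >= 1)
  if (is.null(is_copy_counts)) {
    is_copy_counts <- rep(2L, n_is_elements)
    names(is_copy_counts) <- paste0("IS", seq_len(n_is_elements))
  }
  if (is.null(names(is_copy_counts)))
    names(is_copy_counts) <- paste0("IS", seq_along(is_copy_counts))
  stopifnot(length(is_copy_counts) == n_is_elements)
  with_seed(seed, {
    n_codons <- sample(150:400, n_genes, replace = TRUE)
    strands <- sample(c("+", "-"), n_genes, replace = TRUE)
    genes <- vapply(n_codons, function(nc) {
      paste0("ATG", paste(sample(SENSE_CODONS, nc - 2, replace = TRUE),
                          collapse = ""), sample(c("TAA", "TAG", "TGA"), 1))
    }, "")
    spacers_len <- sample(80:250, n_genes + 1, replace = TRUE)

    rrna_seq <- rand_dna(rrna_len, gc = gc)
    is_seqs <- lapply(seq_len(n_is_elements), function(i) {
      tir <- rand_dna(25, gc = gc)
      core <- rand_dna(is_len - 50, gc = gc)
      paste0(tir, core, revcomp(tir))
    })
    names(is_seqs) <- names(is_copy_counts)

    # mid-genome anchor gene and its regulator neighbor
    anchor_idx <- max(1L, n_genes %/% 2L)
    reg_idx <- min(n_genes, anchor_idx + 1L)

    # interleave: spacer, gene, spacer, gene, ...; extra elements are placed
    # at randomly chosen gene boundaries
    n_extra <- n_rrna_operons + sum(is_copy_counts)
    slots <- sort(sample(seq_len(n_genes + 1), n_extra,
                         replace = n_extra > n_genes))
    extra <- character(0)
    extra_type <- character(0); extra_tag <- character(0); extra_strand <- character(0)
    for (r in seq_len(n_rrna_operons)) {
      inv <- (n_rrna_operons > 1 && r == n_rrna_operons)
      extra <- c(extra, if (inv) revcomp(rrna_seq) else rrna_seq)
      extra_type <- c(extra_type, "rRNA")
      extra_tag <- c(extra_tag, sprintf("rrn%d", r))
      extra_strand <- c(extra_strand, if (inv) "-" else "+")
    }
    for (e in names(is_copy_counts)) {
      nc <- is_copy_counts[[e]]
      if (nc < 1) next
      for (ci in seq_len(nc)) {
        inv <- (nc > 1 && ci == nc)
        extra <- c(extra, if (inv) revcomp(is_seqs[[e]]) else is_seqs[[e]])
        extra_type <- c(extra_type, "mobile_element")
        extra_tag <- c(extra_tag, sprintf("%s_c%d", e, ci))
        extra_strand <- c(extra_strand, if (inv) "-" else "+")
      }
    }
    # shuffle extra elements over their slots
    perm <- sample(length(extra))
    extra <- extra[perm]; extra_type <- extra_type[perm]
    extra_tag <- extra_tag[perm]; extra_strand <- extra_strand[perm]

    segs <- character(0)
    feats <- list()
    pos <- 0L
    ei <- 1L
    add_seg <- function(s) { segs[[length(segs) + 1]] <<- s; pos <<- pos + nchar(s) }
    add_feat <- function(tag, ftype, len, strand, product) {
      feats[[length(feats) + 1]] <<- data.frame(
        locus_tag = tag, ftype = ftype, start = pos, end = pos + len,
        strand = strand, product = product, translation = NA_character_,
        pseudo = FALSE, codon_ok = TRUE, broken = FALSE,
        stringsAsFactors = FALSE)
    }
    for (i in seq_len(n_genes + 1)) {
      add_seg(rand_dna(spacers_len[i], gc = gc))
      while (ei <= length(slots) && slots[ei] == i) {
        add_feat(extra_tag[ei], extra_type[ei], nchar(extra[ei]),
                 extra_strand[ei],
                 if (extra_type[ei] == "rRNA") "rRNA operon (16S-23S-5S)"
                 else "transposase, insertion sequence element")
        add_seg(extra[ei])
        add_seg(rand_dna(60, gc = gc))
        ei <- ei + 1L
      }
      if (i <= n_genes) {
        product <- if (i == anchor_idx)
          "reductive dehalogenase catalytic subunit, rdhA-like"
        else if (i == reg_idx)
          "Crp/Fnr family transcriptional regulator"
        else "hypothetical protein"
        g <- genes[i]
        add_feat(sprintf("g%04d", i), "CDS", nchar(g), strands[i], product)
        add_seg(if (strands[i] == "-") revcomp(g) else g)
      }
    }
    features <- do.call(rbind, feats)
    genome_record("ancestor", paste(segs, collapse = ""),
                  topology = "circular", features = features,
                  meta = list(is_elements = is_seqs, rrna_seq = rrna_seq,
                              anchor = sprintf("g%04d", anchor_idx),
                              regulator = sprintf("g%04d", reg_idx),
                              is_copy_counts = is_copy_counts))
  })
}

#' Mutation specification for sister derivation
#'
#' @param regions named list of 0-based half-open ancestor intervals; the
#'   label `"genome"` (whole genome) is always available
#' @param snps named list, one entry per region label, each
#'   `list(n =, nonsyn_fraction =)`; the realized counts are exact:
#'   `round(n * nonsyn_fraction)` non-synonymous (amino-acid-changing,
#'   non-stop) and the rest synonymous
#' @param n_is_transpositions named integer vector `c(A =, B =)`: number of
#'   strain-specific IS copy insertions per strain
#' @param islands list of `list(length =, gc =, strain =)` low-GC island
#'   insertions
#' @param inversions character vector of repeat labels ("rrn" or an IS
#'   element name); each is applied between the midpoints of an inverted
#'   copy pair, in strain B
#' @param deletions list of `list(length =, strain =)` intergenic deletions
#' @param seed integer; all stochastic draws flow from this one seed
#' @return an object of class `MutationSpec`
#' @export
mutation_spec <- function(regions = list(), snps = list(),
                          n_is_transpositions = c(A = 0L, B = 0L),
                          islands = list(), inversions = character(),
                          deletions = list(), seed = 1) {
  for (s in snps) {
    stopifnot(s$n >= 0, s$nonsyn_fraction >= 0, s$nonsyn_fraction <= 1)
  }
  for (isl in islands) stopifnot(isl$gc > 0, isl$gc < 1, isl$length > 0)
  structure(list(regions = regions, snps = snps,
                 n_is_transpositions = n_is_transpositions,
                 islands = islands, inversions = inversions,
                 deletions = deletions, seed = seed),
            class = "MutationSpec")
}

# planting-time synonymy oracle: translate the full CDS before and after the
# substitution and compare the two protein sequences
oracle_snp_class <- function(cds_nt, off, alt_cds_base) {
  mut <- cds_nt
  substr(mut, off + 1L, off + 1L) <- alt_cds_base
  aa0 <- translate_cds_seq(cds_nt)
  aa1 <- translate_cds_seq(mut)
  if (aa0 == aa1) return("synonymous")
  d <- which(strsplit(aa0, "")[[1]] != strsplit(aa1, "")[[1]])
  if (any(substr(aa0, d, d) == "*") || any(substr(aa1, d, d) == "*"))
    return("nonsense")
  "nonsynonymous"
}

# sample exactly n_syn synonymous and n_nonsyn (missense) SNPs among the CDSs
# listed in cds_idx; returns a data frame in ancestor genome coordinates.
# Classes come from the batch translate-and-compare oracle: the full CDS is
# translated before and after the substitution (internal stops are excluded
# from the reference by construction, so a change in stop count means a
# nonsense substitution).
plant_region_snps <- function(ancestor, cds, cds_nt, region_label, n_syn,
                              n_nonsyn, used_codons) {
  need <- c(synonymous = n_syn, nonsynonymous = n_nonsyn)
  got <- list(synonymous = list(), nonsynonymous = list())
  ref_aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(cds_nt), genetic.code = GENCODE11))
  ref_stars <- lengths(regmatches(ref_aa, gregexpr("*", ref_aa, fixed = TRUE)))
  guard <- 0L
  while (sum(need) > 0) {
    guard <- guard + 1L
    if (guard > 200)
      stop("infeasible SNP spec for region '", region_label,
           "': could not realize counts (no eligible CDS sites left?)")
    batch <- max(64L, 4L * sum(need))
    ci <- sample(nrow(cds), batch, replace = TRUE)
    lens <- nchar(cds_nt[ci])
    # skip the initiator codon and the stop codon
    off <- vapply(lens, function(L) sample(3:(L - 4), 1), 0L)
    ref <- substr(cds_nt[ci], off + 1L, off + 1L)
    alt <- vapply(ref, function(r) sample(setdiff(DNA_BASES, r), 1), "")
    muts <- cds_nt[ci]
    substr(muts, off + 1L, off + 1L) <- alt
    mut_aa <- as.character(Biostrings::translate(
      Biostrings::DNAStringSet(muts), genetic.code = GENCODE11))
    mut_stars <- lengths(regmatches(mut_aa, gregexpr("*", mut_aa, fixed = TRUE)))
    klass_batch <- ifelse(mut_aa == ref_aa[ci], "synonymous",
                          ifelse(mut_stars == ref_stars[ci],
                                 "nonsynonymous", "nonsense"))
    for (j in seq_len(batch)) {
      if (sum(need) == 0) break
      key <- paste0(cds$locus_tag[ci[j]], ":", off[j] %/% 3L)
      if (!is.null(used_codons[[key]])) next
      kl <- klass_batch[j]
      if (kl %in% names(need) && need[[kl]] > 0) {
        used_codons[[key]] <- TRUE
        need[[kl]] <- need[[kl]] - 1L
        # genome coordinates (strand-aware)
        if (cds$strand[ci[j]] == "+") {
          gpos <- cds$start[ci[j]] + off[j]
          galt <- alt[j]; gref <- ref[j]
        } else {
          gpos <- cds$end[ci[j]] - 1L - off[j]
          galt <- comp_base(alt[j]); gref <- comp_base(ref[j])
        }
        got[[kl]][[length(got[[kl]]) + 1]] <- data.frame(
          pos = gpos, ref = gref, alt = galt, class = kl,
          locus_tag = cds$locus_tag[ci[j]], region = region_label,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, c(got$synonymous, got$nonsynonymous))
}

# intergenic intervals (outside all features, with a safety margin)
intergenic_intervals <- function(features, seqlen, margin = 30L,
                                 min_len = 80L) {
  if (nrow(features) == 0) return(cbind(0L, seqlen))
  s <- features$start; e <- features$end
  o <- order(s)
  s <- s[o]; e <- cummax(e[o])
  gaps_start <- c(0L, e + margin)
  gaps_end <- c(s - margin, seqlen)
  keep <- gaps_end - gaps_start >= min_len
  cbind(gaps_start[keep], gaps_end[keep])
}

#' Derive two sister genomes from an ancestor with planted, recorded mutations
#'
#' @param ancestor a [simulate_ancestor()] genome
#' @param spec a [mutation_spec()]
#' @return list with `A`, `B` ([genome_record()]s) and `truth` (class
#'   `TruthTable`: `$snps`, `$events`, `$ortholog_map`)
#' @export
derive_sisters <- function(ancestor, spec) {
  stopifnot(inherits(spec, "MutationSpec"))
  L <- nchar(ancestor$seq)
  regions <- spec$regions
  regions$genome <- c(0L, L)
  with_seed(spec$seed, {
    feats <- ancestor$features
    repeatish <- feats$ftype %in% c("rRNA", "mobile_element", "repeat_region")

    # ---- SNPs -------------------------------------------------------------
    snp_rows <- list()
    used_codons <- new.env(parent = emptyenv())
    for (lab in names(spec$snps)) {
      sp <- spec$snps[[lab]]
      if (sp$n == 0) next
      if (is.null(regions[[lab]])) stop("unknown region label: ", lab)
      rg <- regions[[lab]]
      cds <- feats[feats$ftype == "CDS" & feats$codon_ok &
                     feats$start >= rg[1] & feats$end <= rg[2], , drop = FALSE]
      if (nrow(cds) == 0)
        stop("infeasible SNP spec: region '", lab, "' contains no CDS")
      n_nonsyn <- round(sp$n * sp$nonsyn_fraction)
      n_syn <- sp$n - n_nonsyn
      cds_nt <- vapply(seq_len(nrow(cds)), function(i)
        feature_nt(ancestor$seq, cds$start[i], cds$end[i], cds$strand[i]), "")
      snp_rows[[lab]] <- plant_region_snps(ancestor, cds, cds_nt, lab,
                                           n_syn, n_nonsyn, used_codons)
    }
    snps <- if (length(snp_rows)) do.call(rbind, snp_rows) else
      data.frame(pos = integer(), ref = character(), alt = character(),
                 class = character(), locus_tag = character(),
                 region = character(), stringsAsFactors = FALSE)
    rownames(snps) <- NULL
    snps$strain <- if (nrow(snps)) sample(c("A", "B"), nrow(snps), replace = TRUE)
      else character(0)

    # ---- structural events (ancestor coordinates) ------------------------
    inter <- intergenic_intervals(feats, L)
    used_sites <- integer(0)
    pick_site <- function(min_clearance = 100L) {
      for (try in 1:200) {
        row <- sample(nrow(inter), 1)
        p <- inter[row, 1] + sample.int(max(1L, inter[row, 2] - inter[row, 1]), 1) - 1L
        if (!length(used_sites) || min(abs(used_sites - p)) > min_clearance) {
          used_sites <<- c(used_sites, p)
          return(p)
        }
      }
      stop("could not place a structural event in intergenic space")
    }
    events <- list()
    add_event <- function(type, strain, pos, len, detail = "", seq = NULL) {
      events[[length(events) + 1]] <<- list(type = type, strain = strain,
                                            pos = as.integer(pos),
                                            len = as.integer(len),
                                            detail = detail, seq = seq)
    }
    for (isl in spec$islands) {
      strain <- isl$strain %||% "A"
      p <- pick_site()
      s <- rand_dna(isl$length, gc = isl$gc)
      # harden the junctions: the island's terminal bases must differ from
      # the ancestral bases they abut, so alignment anchors stop exactly at
      # the insertion boundaries
      right_of <- substr(ancestor$seq, p + 1L, p + 1L)
      left_of <- substr(ancestor$seq, p, p)
      substr(s, 1L, 1L) <- setdiff(DNA_BASES, c(substr(s, 1, 1), right_of))[1]
      substr(s, isl$length, isl$length) <-
        setdiff(DNA_BASES, c(substr(s, isl$length, isl$length), left_of))[1]
      add_event("island", strain, p, isl$length,
                detail = sprintf("gc=%.3f", isl$gc), seq = s)
    }
    el_names <- names(ancestor$meta$is_elements)
    for (strain in c("A", "B")) {
      n_tr <- spec$n_is_transpositions[[strain]] %||% 0L
      if (is.na(n_tr)) n_tr <- 0L
      if (n_tr > 0) for (t in seq_len(n_tr)) {
        el <- el_names[(t - 1) %% length(el_names) + 1]
        es <- ancestor$meta$is_elements[[el]]
        add_event("IS_transposition", strain, pick_site(), nchar(es),
                  detail = el, seq = es)
      }
    }
    for (del in spec$deletions) {
      strain <- del$strain %||% "B"
      for (try in 1:200) {
        row <- sample(nrow(inter), 1)
        p <- inter[row, 1] + 1L
        clear <- !length(used_sites) ||
          min(abs(used_sites - p)) > del$length + 100L
        if (inter[row, 2] - inter[row, 1] >= del$length + 2L && clear) {
          used_sites <- c(used_sites, p)
          add_event("deletion", strain, p, del$length)
          break
        }
      }
    }

    # ---- build each sister ------------------------------------------------
    build_strain <- function(strain) {
      raw <- charToRaw(ancestor$seq)
      sn <- snps[snps$strain == strain, , drop = FALSE]
      if (nrow(sn)) raw[sn$pos + 1L] <- charToRaw(paste(sn$alt, collapse = ""))
      evs <- Filter(function(e) e$strain == strain, events)
      if (length(evs)) {
        ord <- order(-vapply(evs, function(e) e$pos, 0))
        evs <- evs[ord]
      }
      f <- feats
      extra_feats <- list()
      for (e in evs) {
        if (e$type == "deletion") {
          raw <- raw[-((e$pos + 1L):(e$pos + e$len))]
        } else {
          ins <- charToRaw(e$seq)
          raw <- c(raw[seq_len(e$pos)], ins,
                   if (e$pos < length(raw) - length(ins) + length(ins)) raw[(e$pos + 1L):length(raw)] else raw(0))
        }
      }
      # coordinate map ancestor -> strain (positions outside deleted spans)
      evs_asc <- Filter(function(e) e$strain == strain, events)
      posmap <- function(p) {
        off <- 0L
        for (e in evs_asc) {
          if (e$type == "deletion") { if (e$pos + e$len <= p) off <- off - e$len }
          else if (e$pos <= p) off <- off + e$len
        }
        p + off
      }
      # remap features; add features for inserted elements
      if (length(evs_asc)) {
        news <- as.integer(vapply(f$start, posmap, numeric(1)))
        newe <- as.integer(vapply(f$end, posmap, numeric(1)))
        f$start <- news; f$end <- newe
        for (e in evs_asc) {
          if (e$type == "deletion") next
          p2 <- posmap(e$pos)  # includes its own shift
          st <- p2 - e$len
          extra_feats[[length(extra_feats) + 1]] <- data.frame(
            locus_tag = sprintf("%s_%s_%d", strain,
                                if (e$type == "island") "island" else e$detail, st),
            ftype = if (e$type == "island") "other" else "mobile_element",
            start = st, end = st + e$len, strand = "+",
            product = if (e$type == "island") "genomic island (planted)"
              else "transposase, insertion sequence element (transposed copy)",
            translation = NA_character_, pseudo = FALSE, codon_ok = TRUE,
            broken = FALSE, stringsAsFactors = FALSE)
        }
        if (length(extra_feats)) f <- rbind(f, do.call(rbind, extra_feats))
      }
      g <- genome_record(strain, rawToChar(raw), topology = ancestor$topology,
                         features = f, meta = ancestor$meta)
      list(genome = g, posmap = posmap)
    }
    A <- build_strain("A")
    B <- build_strain("B")

    # ---- inversions (applied to strain B, between inverted repeat pairs) --
    inv_records <- list()
    for (lab in spec$inversions) {
      fB <- B$genome$features
      if (lab == "rrn") {
        cand <- fB[fB$ftype == "rRNA", , drop = FALSE]
      } else {
        cand <- fB[grepl(paste0("^", lab, "_c"), fB$locus_tag), , drop = FALSE]
      }
      plus <- cand[cand$strand == "+", , drop = FALSE]
      minus <- cand[cand$strand == "-", , drop = FALSE]
      if (nrow(plus) == 0 || nrow(minus) == 0)
        stop("no inverted repeat pair for label '", lab, "'")
      m1 <- (plus$start[1] + plus$end[1]) %/% 2L
      m2 <- (minus$start[1] + minus$end[1]) %/% 2L
      i <- min(m1, m2); j <- max(m1, m2)
      B$genome <- apply_inversion(B$genome, i, j)
      inv_records[[length(inv_records) + 1]] <- c(i, j)
      add_event("inversion", "B", i, j - i, detail = lab)
    }

    # ---- truth table in final coordinates ---------------------------------
    map_through_inversions <- function(p) {
      for (iv in inv_records) if (p >= iv[1] && p < iv[2]) p <- iv[1] + iv[2] - 1L - p
      p
    }
    if (nrow(snps)) {
      snps$posA <- as.integer(vapply(snps$pos, A$posmap, numeric(1)))
      posB0 <- as.integer(vapply(snps$pos, B$posmap, numeric(1)))
      snps$posB <- as.integer(vapply(posB0, map_through_inversions, numeric(1)))
      snps$baseA <- substring(A$genome$seq, snps$posA + 1L, snps$posA + 1L)
      snps$baseB <- substring(B$genome$seq, snps$posB + 1L, snps$posB + 1L)
    } else {
      snps$posA <- snps$posB <- integer(0)
      snps$baseA <- snps$baseB <- character(0)
    }
    ev_df <- if (length(events)) do.call(rbind, lapply(events, function(e) {
      if (e$type == "inversion") {
        # recorded after structural remapping, already in strain-B coordinates
        return(data.frame(type = e$type, strain = e$strain,
                          pos_ancestor = NA_integer_, length = e$len,
                          detail = e$detail, posA = NA_integer_,
                          posB = e$pos, stringsAsFactors = FALSE))
      }
      pA <- A$posmap(e$pos); pB <- B$posmap(e$pos)
      data.frame(type = e$type, strain = e$strain, pos_ancestor = e$pos,
                 length = e$len, detail = e$detail,
                 posA = pA, posB = pB, stringsAsFactors = FALSE)
    })) else data.frame(type = character(), strain = character(),
                        pos_ancestor = integer(), length = integer(),
                        detail = character(), posA = integer(),
                        posB = integer(), stringsAsFactors = FALSE)
    cds_tags <- feats$locus_tag[feats$ftype == "CDS"]
    truth <- structure(list(
      snps = snps[, c("posA", "posB", "ref", "alt", "baseA", "baseB",
                      "class", "strain", "locus_tag", "region")],
      events = ev_df,
      ortholog_map = data.frame(locusA = cds_tags, locusB = cds_tags,
                                stringsAsFactors = FALSE)),
      class = "TruthTable")
    list(A = A$genome, B = B$genome, truth = truth)
  })
}

#' Write a simulated sister pair as a reloadable fixture
#'
#' FASTA and GFF3 per strain, truth tables as TSV, and the mutation spec
#' echoed as YAML.
#'
#' @param pair result of [derive_sisters()]
#' @param outdir output directory
#' @param overwrite allow writing into an existing non-empty directory
#' @export
write_fixture <- function(pair, outdir, overwrite = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !overwrite)
    stop("output directory exists and is not empty: ", outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (strain in c("A", "B")) {
    g <- pair[[strain]]
    write_fasta(g, file.path(outdir, paste0(strain, ".fasta")))
    write_gff3(g, file.path(outdir, paste0(strain, ".gff3")))
  }
  write_tsv_stable(pair$truth$snps, file.path(outdir, "truth_snps.tsv"))
  write_tsv_stable(pair$truth$events, file.path(outdir, "truth_events.tsv"))
  write_tsv_stable(pair$truth$ortholog_map,
                   file.path(outdir, "ortholog_map.tsv"))
  if (!is.null(pair$spec))
    writeLines(yaml::as.yaml(unclass(pair$spec)),
               file.path(outdir, "config.yml"))
  invisible(outdir)
}

#' Load a fixture written by [write_fixture()]
#' @param dir fixture directory
#' @return list with `A`, `B`, `truth`
#' @export
read_fixture <- function(dir) {
  A <- read_gff3(file.path(dir, "A.gff3"), file.path(dir, "A.fasta"))
  B <- read_gff3(file.path(dir, "B.gff3"), file.path(dir, "B.fasta"))
  truth <- structure(list(
    snps = read_tsv_plain(file.path(dir, "truth_snps.tsv")),
    events = read_tsv_plain(file.path(dir, "truth_events.tsv")),
    ortholog_map = read_tsv_plain(file.path(dir, "ortholog_map.tsv"))),
    class = "TruthTable")
  list(A = A, B = B, truth = truth)
}

# ---------------------------------------------------------------------------
# auxiliary planted-truth generators
# ---------------------------------------------------------------------------

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

mutate_protein <- function(aa, frac) {
  v <- strsplit(aa, "")[[1]]
  n <- max(1L, round(length(v) * frac))
  at <- sample(length(v), n)
  v[at] <- vapply(v[at], function(x) sample(setdiff(AA20, x), 1), "")
  paste(v, collapse = "")
}

#' Simulate a proteome pair with a planted ortholog map and paralog decoys
#'
#' Proteome B contains one close homolog (about 2% divergence) of every A
#' protein — the planted orthologs — plus `decoy_fraction * n` paralog decoys
#' at about 80% identity to randomly chosen A proteins.
#'
#' @param n number of ortholog pairs
#' @param decoy_fraction fraction of additional decoy paralogs in B
#' @param seed integer seed
#' @return list with `A`, `B` (named character vectors) and `map` (data
#'   frame locusA, locusB)
#' @export
simulate_proteome_pair <- function(n = 100, decoy_fraction = 0.1, seed = 1) {
  with_seed(seed, {
    lens <- sample(100:400, n, replace = TRUE)
    A <- vapply(lens, function(L)
      paste(sample(AA20, L, replace = TRUE), collapse = ""), "")
    names(A) <- sprintf("a%04d", seq_len(n))
    B <- vapply(A, mutate_protein, "", frac = 0.02)
    names(B) <- sprintf("b%04d", seq_len(n))
    n_decoy <- round(n * decoy_fraction)
    if (n_decoy > 0) {
      src <- sample(n, n_decoy, replace = TRUE)
      dec <- vapply(A[src], mutate_protein, "", frac = 0.20)
      names(dec) <- sprintf("b_decoy%03d", seq_len(n_decoy))
      B <- c(B, dec)
    }
    list(A = A, B = B,
         map = data.frame(locusA = sprintf("a%04d", seq_len(n)),
                          locusB = sprintf("b%04d", seq_len(n)),
                          stringsAsFactors = FALSE))
  })
}

#' Construct a genome with two GC-skew arms and planted inverted repeats
#'
#' The forward strand is G-rich from the origin to the terminus and C-rich on
#' the other arm, giving the canonical V-shaped cumulative skew with its
#' minimum at the origin. Optionally, pairs of inverted repeats are planted
#' so that repeat-mediated inversions can be simulated and ranked.
#'
#' @param length genome length in bp
#' @param origin,terminus arm boundaries (0-based positions)
#' @param skew per-arm GC skew magnitude of the generated strand
#' @param gc G+C fraction
#' @param repeat_positions list of length-2 integer vectors: positions at
#'   which to plant an inverted repeat pair (copy 2 is the reverse
#'   complement of copy 1)
#' @param repeat_len planted repeat length
#' @param seed integer seed
#' @return a [genome_record()]; `meta$repeat_pairs` records the planted pairs
#' @export
simulate_skewed_genome <- function(length = 100000, origin = 0,
                                   terminus = length %/% 2, skew = 0.1,
                                   gc = 0.5, repeat_positions = list(),
                                   repeat_len = 1500, seed = 1) {
  with_seed(seed, {
    arm1 <- rand_dna(terminus - origin, gc = gc, skew = skew)
    arm2 <- rand_dna(length - (terminus - origin), gc = gc, skew = -skew)
    seq <- paste0(arm1, arm2)
    if (origin > 0) { # rotate so the origin sits at `origin`
      seq <- paste0(sub0(seq, length - origin, length), sub0(seq, 0, length - origin))
    }
    feats <- empty_features()
    pairs <- list()
    for (rp in repeat_positions) {
      rep1 <- rand_dna(repeat_len, gc = gc)
      p1 <- rp[1]; p2 <- rp[2]
      substr(seq, p1 + 1, p1 + repeat_len) <- rep1
      substr(seq, p2 + 1, p2 + repeat_len) <- revcomp(rep1)
      pairs[[length(pairs) + 1]] <- data.frame(
        startA = p1, endA = p1 + repeat_len, startB = p2,
        endB = p2 + repeat_len, orientation = "inverted",
        length = repeat_len, pct_id = 100, stringsAsFactors = FALSE)
    }
    genome_record("skewed", seq, topology = "circular", features = feats,
                  meta = list(repeat_pairs = if (length(pairs))
                    do.call(rbind, pairs) else NULL,
                    origin = origin, terminus = terminus))
  })
}

#' Plant regulator-domain hits for a simulated rdhA neighborhood
#'
#' Assigns Pfam-style domain names to neighborhood members so the census can
#' be checked against planted truth.
#'
#' @param members character vector of member locus_tags
#' @param categories character vector (same length) of planted categories
#'   among `CrpFnr`, `HK_RR`, `MarR`, `OtherRegulatory`, or `none`
#' @param evalue e-value assigned to every planted hit
#' @param seed integer seed
#' @return data frame of domain hits as from [read_domtab()]
#' @export
simulate_domain_hits <- function(members, categories, evalue = 1e-20,
                                 seed = 1) {
  stopifnot(length(members) == length(categories))
  pool <- list(CrpFnr = c("cNMP_binding", "HTH_Crp_2"),
               HK_RR = c("HisKA", "Response_reg", "ATPase_c"),
               MarR = "MarR_2", OtherRegulatory = "GerE")
  with_seed(seed, {
    rows <- lapply(seq_along(members), function(i) {
      if (categories[i] == "none") return(NULL)
      dom <- sample(pool[[categories[i]]], 1)
      data.frame(locus_tag = members[i], env_start = 10L, env_end = 110L,
                 domain_name = dom, evalue = evalue, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(locus_tag = character(), env_start = integer(),
                        env_end = integer(), domain_name = character(),
                        evalue = numeric(), stringsAsFactors = FALSE)
    out
  })
}
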