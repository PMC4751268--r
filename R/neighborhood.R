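# Gene-neighborhood extraction around rdhA-like anchor genes and the
# transcriptional-regulator protein-domain census. The window is defined in
# gene-order space over protein-coding genes only: "fewer than 5
# protein-coding genes up- or downstream" means gene-order distance <= 4 on
# each side; RNA genes and repeat features do not consume a position.
# The domain-to-category map is configuration, not code: regulator family
# definitions evolve, so the mapping ships as an editable default.

#' Default regulator-domain category map
#'
#' Categories follow the major bacterial regulator families distinguished
#' by Pfam domain content: Crp/Fnr (cNMP_binding, HTH_Crp_2), two-component
#' histidine-kinase/response-regulator systems, MarR-family repressors, and
#' a configurable list of other signal-transduction and gene-regulatory
#' domains.
#'
#' @return named list: category -> character vector of Pfam domain names
#' @export
default_category_map <- function() {
  list(CrpFnr = c("cNMP_binding", "HTH_Crp_2"),
       HK_RR = c("HisKA", "ATPase_c", "Response_reg", "Trans_reg_C", "PAS"),
       MarR = c("MarR_2"),
       OtherRegulatory = c("GerE", "HTH_1", "HTH_3", "HTH_8", "LytTR",
                           "Sigma54_activat", "GntR", "TetR_N", "AraC",
                           "Fe_dep_repress", "Rrf2", "ROK", "DeoR", "IclR",
                           "PadR", "ArsR", "Sigma70_r4", "Sigma70_r2",
                           "GAF", "HAMP", "PocR", "SpoIIE", "HATPase_c"))
}

#' Read / write a category map as YAML
#' @param path YAML file: category names mapping to domain-name lists
#' @return named list as [default_category_map()]
#' @export
read_category_map <- function(path) {
  m <- yaml::read_yaml(path)
  lapply(m, as.character)
}

#' @rdname read_category_map
#' @param map category map list
#' @export
write_category_map <- function(map, path) {
  writeLines(yaml::as.yaml(map), path)
  invisible(path)
}

#' Extract the gene neighborhood of an anchor CDS
#'
#' Members are the protein-coding genes strictly fewer than `radius`
#' gene-order positions away on each side of the anchor, regardless of
#' strand or intergenic distance. Circular genomes wrap; linear contigs
#' truncate at the ends.
#'
#' @param genome annotated [genome_record()]
#' @param anchor_tag locus_tag of the anchor CDS
#' @param radius window: members at gene-order distance `1 .. radius-1`
#' @return list with anchor, upstream (tags, nearest first), downstream,
#'   members (all tags)
#' @export
extract_neighborhood <- function(genome, anchor_tag, radius = 5) {
  cds <- cds_features(genome)
  n <- nrow(cds)
  at <- which(cds$locus_tag == anchor_tag)
  if (length(at) == 0) {
    if (anchor_tag %in% genome$features$locus_tag)
      stop("anchor is not a CDS feature: ", anchor_tag)
    stop("anchor not found: ", anchor_tag)
  }
  at <- at[1]
  span <- radius - 1L
  circular <- genome$topology == "circular"
  take <- function(offsets) {
    pos <- at + offsets
    if (circular) {
      pos <- ((pos - 1L) %% n) + 1L
      pos <- pos[pos != at]
    } else {
      pos <- pos[pos >= 1 & pos <= n & pos != at]
    }
    cds$locus_tag[unique(pos)]
  }
  upstream <- if (span >= 1) take(-(1:span)) else character(0)
  downstream <- if (span >= 1) take(1:span) else character(0)
  list(anchor = anchor_tag, upstream = upstream, downstream = downstream,
       members = unique(c(upstream, downstream)))
}

#' Regulatory-domain census of a neighborhood
#'
#' A member counts towards a category when it carries at least one
#' qualifying domain (e-value below `evalue_cutoff`) from that category's
#' domain list. A member with domains from several categories increments
#' each (the multi-counts are reported). Domains absent from the configured
#' map are ignored.
#'
#' @param neighborhood result of [extract_neighborhood()] (or a character
#'   vector of member locus_tags)
#' @param domain_hits data frame from [read_domtab()] /
#'   [simulate_domain_hits()]
#' @param evalue_cutoff significance threshold on the domain e-value
#' @param category_map see [default_category_map()]
#' @return object of class `NeighborhoodCensus`: list with anchor, members,
#'   counts (named integer per category), multi_counted (tags in more than
#'   one category), member_categories
#' @export
census <- function(neighborhood, domain_hits, evalue_cutoff = 0.001,
                   category_map = default_category_map()) {
  if (is.character(neighborhood))
    neighborhood <- list(anchor = NA_character_, members = neighborhood)
  members <- neighborhood$members
  counts <- setNames(integer(length(category_map)), names(category_map))
  member_cat <- list()
  h <- domain_hits[domain_hits$evalue < evalue_cutoff &
                     domain_hits$locus_tag %in% members, , drop = FALSE]
  for (m in members) {
    doms <- unique(h$domain_name[h$locus_tag == m])
    if (!length(doms)) next
    cats <- names(category_map)[vapply(category_map, function(d)
      any(doms %in% d), TRUE)]
    if (!length(cats)) next
    counts[cats] <- counts[cats] + 1L
    member_cat[[m]] <- cats
  }
  multi <- names(member_cat)[lengths(member_cat) > 1]
  structure(list(anchor = neighborhood$anchor, members = members,
                 counts = counts, multi_counted = multi,
                 member_categories = member_cat),
            class = "NeighborhoodCensus")
}

#' @export
print.NeighborhoodCensus <- function(x, ...) {
  cat(sprintf("NeighborhoodCensus (anchor %s, %d members): %s\n",
              x$anchor, length(x$members),
              paste(sprintf("%s=%d", names(x$counts), x$counts),
                    collapse = ", ")))
  invisible(x)
}

#' Compare regulator censuses across groups
#'
#' Sums category counts per group and reports per-group fractions.
#'
#' @param censuses list of [census()] results
#' @param group_labels character vector, one label per census
#' @return list with `counts` (group x category matrix) and `fractions`
#'   (rows normalized; zero rows stay zero)
#' @export
compare_groups <- function(censuses, group_labels) {
  stopifnot(length(censuses) == length(group_labels))
  cats <- names(censuses[[1]]$counts)
  groups <- unique(group_labels)
  m <- matrix(0L, length(groups), length(cats),
              dimnames = list(groups, cats))
  for (i in seq_along(censuses))
    m[group_labels[i], ] <- m[group_labels[i], ] + censuses[[i]]$counts[cats]
  fr <- m / pmax(rowSums(m), 1L)
  list(counts = m, fractions = fr)
}

#' Census every rdhA-like anchor of a genome
#'
#' Anchors are CDSs whose product matches `anchor_pattern`.
#'
#' @param genome annotated [genome_record()]
#' @param domain_hits domain-hit data frame
#' @param anchor_pattern regular expression on the product field
#' @param radius,evalue_cutoff,category_map passed through
#' @return list of [census()] results, one per anchor
#' @export
census_genome <- function(genome, domain_hits,
                          anchor_pattern = "rdhA|reductive dehalogenase",
                          radius = 5, evalue_cutoff = 0.001,
                          category_map = default_category_map()) {
  cds <- cds_features(genome)
  anchors <- cds$locus_tag[!is.na(cds$product) &
                             grepl(anchor_pattern, cds$product)]
  lapply(anchors, function(a)
    census(extract_neighborhood(genome, a, radius), domain_hits,
           evalue_cutoff, category_map))
}
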