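#' Link co-observed allele variants into allele pairs
#'
#' Every fragment (a read plus its mate) that covers two called variant
#' sites with quality-passing bases is an observation of physical linkage.
#' For each ordered site pair, `span_count` counts the fragments covering
#' both sites with any base, and for each pair of called alleles,
#' `co_count` counts the fragments carrying both alleles; `pair_freq =
#' co_count / span_count` estimates the joint frequency of the strain
#' subset carrying both alleles, which is what the hexamodal peak model
#' scores. The two mates of a fragment are one observation; a site covered
#' by both mates with conflicting bases is dropped for that fragment.
#'
#' @param aln Alignments from [load_alignments()].
#' @param variants Called variants from [call_variants()].
#' @param db A `gene_db`.
#' @param min_pair_reads Minimum `co_count` for a pair to be kept
#'   (default 3); single-read pairs are typically sequencing-error
#'   chimeras and would otherwise poison the model score.
#' @param min_pair_span Minimum number of spanning fragments
#'   (default 20): a pair frequency estimated from fewer fragments is
#'   too noisy to assign to a peak, and the `co_count` floor would turn
#'   such pairs into a spurious high-frequency cluster.
#' @param min_base_qual Minimum phred base quality for an observation
#'   (default 30, matching the pileup filter).
#' @return `data.table` of allele pairs: allele identities (`a_id`,
#'   `b_id`, with `a/b_gene`, `a/b_pos`, `a/b_base`), `co_count`,
#'   `span_count`, `pair_freq`. Canonically ordered with `a_id < b_id`.
#' @export
extract_pairs <- function(aln, variants, db, min_pair_reads = 3L,
                          min_pair_span = 20L, min_base_qual = 30L) {
  obs <- site_observations(aln, variants, db, min_base_qual)
  if (nrow(obs) == 0L) {
    return(data.table::data.table(
      a_id = integer(), b_id = integer(), co_count = integer(),
      span_count = integer(), pair_freq = numeric()))
  }
  pr <- merge(obs, obs, by = "frag_id", allow.cartesian = TRUE,
              suffixes = c("_a", "_b"))
  pr <- pr[site_id_a < site_id_b]
  if (nrow(pr) == 0L) {
    return(data.table::data.table(
      a_id = integer(), b_id = integer(), co_count = integer(),
      span_count = integer(), pair_freq = numeric()))
  }
  span <- pr[, .(span_count = .N), by = .(site_id_a, site_id_b)]
  co <- pr[!is.na(allele_id_a) & !is.na(allele_id_b),
           .(co_count = .N), by = .(site_id_a, site_id_b,
                                    allele_id_a, allele_id_b)]
  pairs <- merge(co, span, by = c("site_id_a", "site_id_b"))
  pairs <- pairs[co_count >= min_pair_reads & span_count >= min_pair_span]
  pairs[, pair_freq := co_count / span_count]
  data.table::setnames(pairs, c("allele_id_a", "allele_id_b"),
                       c("a_id", "b_id"))
  key <- variants[, .(allele_id, gene_id, pos, base)]
  pairs <- merge(pairs, key[, .(a_id = allele_id, a_gene = gene_id,
                                a_pos = pos, a_base = base)], by = "a_id")
  pairs <- merge(pairs, key[, .(b_id = allele_id, b_gene = gene_id,
                                b_pos = pos, b_base = base)], by = "b_id")
  data.table::setorder(pairs, a_id, b_id)
  data.table::setcolorder(pairs, c("a_id", "b_id", "a_gene", "a_pos",
                                   "a_base", "b_gene", "b_pos", "b_base",
                                   "co_count", "span_count", "pair_freq"))
  pairs[]
}

# Per-fragment base observations at called variant sites. One row per
# (fragment, site); `allele_id` is NA when the observed base is not a
# called allele at that site.
site_observations <- function(aln, variants, db, min_base_qual = 30L) {
  aln <- mask_low_qual(aln, min_base_qual)
  sites <- unique(variants[, .(site_id, gene_id, pos)])
  fl <- setNames(db$flank_left, db$gene_id)
  sites[, ext_pos := pos + fl[gene_id]]
  res <- vector("list", length(unique(sites$gene_id)))
  k <- 0L
  for (gid in unique(sites$gene_id)) {
    g <- aln[gene_id == gid]
    s <- sites[gene_id == gid]
    if (nrow(g) == 0L) next
    hits <- IRanges::findOverlaps(IRanges::IRanges(g$start, g$end),
                                  IRanges::IRanges(s$ext_pos, s$ext_pos))
    if (!length(hits)) next
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    off <- s$ext_pos[sh] - g$start[qh] + 1L
    k <- k + 1L
    res[[k]] <- data.table::data.table(
      frag_id = g$frag_id[qh],
      site_id = s$site_id[sh],
      base = substring(g$seq[qh], off, off))
  }
  obs <- data.table::rbindlist(res)
  if (nrow(obs) == 0L) return(obs)
  obs <- obs[base %in% c("A", "C", "G", "T")]
  # collapse mates; conflicting mate bases void the observation
  obs <- obs[, .(base = base[1L], n_distinct = data.table::uniqueN(base)),
             by = .(frag_id, site_id)][n_distinct == 1L]
  obs[, n_distinct := NULL]
  obs <- merge(obs, variants[, .(site_id, base, allele_id)],
               by = c("site_id", "base"), all.x = TRUE)
  obs[]
}

#' Join allele pairs into linkage groups
#'
#' Linkage groups are the connected components of the graph whose vertices
#' are called alleles and whose edges are allele pairs; because mate pairs
#' bridge neighbouring genes, groups can span multiple genes. Alleles with
#' no retained pair form singleton groups.
#'
#' @param pairs From [extract_pairs()].
#' @param variants Called variants (supplies the full allele set).
#' @return `data.table` with `allele_id` and `group_id`; groups partition
#'   the allele set.
#' @export
build_groups <- function(pairs, variants) {
  ids <- variants$allele_id
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(pairs$a_id),
                   to = as.character(pairs$b_id)),
    directed = FALSE, vertices = data.frame(name = as.character(ids)))
  memb <- igraph::components(g)$membership
  data.table::data.table(allele_id = as.integer(names(memb)),
                         group_id = as.integer(memb))[order(allele_id)]
}

#' Export allele pairs and linkage groups as a TSV table
#'
#' @param pairs From [extract_pairs()].
#' @param groups From [build_groups()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_linkage <- function(pairs, groups, path) {
  out <- merge(pairs, groups[, .(a_id = allele_id, group_id)], by = "a_id")
  data.table::setcolorder(out, "group_id")
  data.table::fwrite(out[order(group_id, a_id, b_id)], path, sep = "\t")
  invisible(path)
}
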