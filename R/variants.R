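#' Build per-position pileups over core gene positions
#'
#' Tallies A/C/G/T counts at every core gene position from the
#' reference-layout alignments, after discarding bases below the minimum
#' base quality. Flank positions are excluded entirely: they exist only to
#' stabilize mapping near gene ends.
#'
#' @param aln Alignments from [load_alignments()].
#' @param db A `gene_db`.
#' @param min_base_qual Minimum phred base quality (default 30).
#' @return `data.table` with columns `gene_id`, `pos` (1-based core
#'   position), `ref` (reference base), `A`, `C`, `G`, `T` and `depth`
#'   (sum of the four quality-passing base counts); positions with zero
#'   depth are omitted.
#' @export
build_pileup <- function(aln, db, min_base_qual = 30L) {
  aln <- mask_low_qual(aln, min_base_qual)
  cores <- core_seq(db)
  res <- vector("list", nrow(db))
  for (i in seq_len(nrow(db))) {
    gid <- db$gene_id[i]
    g <- aln[gene_id == gid]
    if (nrow(g) == 0L) next
    ext_len <- nchar(db$ext_seq[i])
    cm <- Biostrings::consensusMatrix(
      Biostrings::DNAStringSet(g$seq), shift = g$start - 1L, width = ext_len)
    bases <- c("A", "C", "G", "T")
    cm <- cm[bases, , drop = FALSE]
    lo <- db$flank_left[i] + 1L
    hi <- db$flank_left[i] + db$core_len[i]
    cm <- cm[, lo:hi, drop = FALSE]
    depth <- colSums(cm)
    keep <- which(depth > 0L)
    if (!length(keep)) next
    res[[i]] <- data.table::data.table(
      gene_id = gid, pos = keep,
      ref = substring(cores[[gid]], keep, keep),
      A = cm["A", keep], C = cm["C", keep],
      G = cm["G", keep], T = cm["T", keep],
      depth = as.integer(depth[keep]))
  }
  out <- data.table::rbindlist(res)
  if (nrow(out) == 0L) {
    stop("empty pileup: no aligned bases over core gene positions")
  }
  out[]
}

#' Exclude columns of abnormal sequencing depth
#'
#' Positions with abnormally high or low coverage — the footprint of gene
#' duplications, deletions and cross-mapping from related taxa — are
#' removed. The mean and standard deviation of depth are computed
#' genome-wide over all covered core positions, and columns outside
#' `mean +/- n_sd * SD` are dropped. Perfectly uniform coverage (SD = 0)
#' disables the filter.
#'
#' @param pileup From [build_pileup()].
#' @param n_sd Width of the retained band in standard deviations
#'   (default 1.5).
#' @return The retained pileup columns.
#' @export
depth_filter <- function(pileup, n_sd = 1.5) {
  if (nrow(pileup) < 2L || !is.finite(n_sd)) return(pileup)
  m <- mean(pileup$depth)
  s <- stats::sd(pileup$depth)
  if (s == 0) return(pileup)
  out <- pileup[depth >= m - n_sd * s & depth <= m + n_sd * s]
  if (nrow(out) == 0L) {
    stop("all pileup columns fall outside the depth band (mean ", round(m, 1),
         ", sd ", round(s, 1), "); coverage is too irregular to genotype")
  }
  out
}

#' Call allele variants and reference-specific fixed differences
#'
#' At every retained column with sufficient read coverage, each base whose
#' frequency lies within `[freq_lo, freq_hi]` becomes an allele variant —
#' the atom of the strain model. Non-reference bases at 100% frequency are
#' tracked separately as fixed differences: alleles private to the mapping
#' reference, carried by every strain in the sample. Monoallelic
#' reference-matching columns yield nothing. Only substitutions are
#' modeled.
#'
#' Every allele call requires a minimum read support of 20 quality-passing
#' reads (`min_allele_reads`); together with the 1% frequency floor this
#' suppresses alleles created by isolated sequencing errors.
#'
#' Fixed differences are scanned on the unfiltered pileup (`pileup_all`)
#' when supplied: the depth band exists to protect the frequency model
#' from copy-number artifacts, whereas fixed differences are not model
#' input — they are reference-private alleles written verbatim into every
#' reconstructed strain. Operationally a fixed difference is a
#' non-reference allele above the variant band (`freq > freq_hi`), so a
#' stray error read does not demote a fixed difference to nothing.
#'
#' @param pileup Depth-filtered pileup columns.
#' @param pileup_all Optional unfiltered pileup used for the fixed-
#'   difference scan (defaults to `pileup`).
#' @param min_allele_reads Minimum reads supporting an allele
#'   (default 20).
#' @param freq_lo,freq_hi Inclusive allele-frequency bounds
#'   (defaults 0.01 and 0.99).
#' @return `list(variants=, fixed=)`: `variants` has one row per allele
#'   (`gene_id`, `pos`, `base`, `count`, `depth`, `freq`, `is_ref`,
#'   `allele_id`, `site_id`); `fixed` has one row per fixed difference.
#' @export
call_variants <- function(pileup, pileup_all = NULL, min_allele_reads = 20L,
                          freq_lo = 0.01, freq_hi = 0.99) {
  melt_counts <- function(cols) {
    long <- data.table::melt(
      cols, id.vars = c("gene_id", "pos", "ref", "depth"),
      measure.vars = c("A", "C", "G", "T"),
      variable.name = "base", value.name = "count",
      variable.factor = FALSE)
    long <- long[count > 0L]
    long[, freq := count / depth]
    long[, is_ref := base == ref]
    long
  }
  long <- melt_counts(pileup)
  variants <- long[count >= min_allele_reads &
                   freq >= freq_lo & freq <= freq_hi]
  # a column is a variant site only if a non-reference allele was called;
  # the reference base at a column whose minor bases failed the filters
  # (isolated sequencing errors) is not a variant
  variants <- variants[, if (any(!is_ref)) .SD else .SD[0L],
                       by = .(gene_id, pos)]
  fixed_src <- if (is.null(pileup_all)) long else melt_counts(pileup_all)
  fixed <- fixed_src[!is_ref & count >= min_allele_reads & freq > freq_hi,
                     .(gene_id, pos, base, count, depth)]
  data.table::setorder(variants, gene_id, pos, base)
  variants[, site_id := .GRP, by = .(gene_id, pos)]
  variants[, allele_id := .I]
  list(variants = variants[], fixed = fixed[])
}

#' Export called variants as a TSV table
#'
#' @param variants The `variants` table from [call_variants()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  data.table::fwrite(variants[, .(gene_id, pos, ref, base, count, depth,
                                  freq, is_ref)], path, sep = "\t")
  invisible(path)
}
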