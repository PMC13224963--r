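#' Map paired reads against the gene database with an external mapper
#'
#' Thin wrapper around `bowtie2` run with `--very-sensitive --no-unal`
#' (extensive alignment search; unmapped reads suppressed). The mapper is
#' optional at runtime: when it is not on the `PATH`, supply a pre-computed
#' SAM/BAM to [load_alignments()] instead.
#'
#' @param db_fasta Gene-database FASTA from [write_gene_db()].
#' @param fastq1,fastq2 Paired FASTQ files.
#' @param out_sam Output SAM path.
#' @param threads Mapper threads.
#' @return Path to the SAM file.
#' @export
run_mapper <- function(db_fasta, fastq1, fastq2,
                       out_sam = tempfile(fileext = ".sam"), threads = 1L) {
  bt2 <- Sys.which("bowtie2")
  bt2b <- Sys.which("bowtie2-build")
  if (!nzchar(bt2) || !nzchar(bt2b)) {
    stop("bowtie2 was not found on the PATH; either install it or supply a ",
         "pre-computed alignment (SAM/BAM) to load_alignments() / the ",
         "`sam` argument of run_pipeline()")
  }
  for (f in c(db_fasta, fastq1, fastq2)) {
    if (!file.exists(f)) stop("input not found: ", f)
  }
  idx <- tempfile("btidx")
  st <- system2(bt2b, c("-q", shQuote(db_fasta), shQuote(idx)),
                stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(st, "status"))) {
    stop("bowtie2-build failed:\n", paste(st, collapse = "\n"))
  }
  args <- c("--very-sensitive", "--no-unal", "-p", threads,
            "-x", shQuote(idx), "-1", shQuote(fastq1), "-2", shQuote(fastq2),
            "-S", shQuote(out_sam))
  message("bowtie2 ", paste(args, collapse = " "))
  err <- system2(bt2, args, stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(err, "status"))) {
    stop("bowtie2 failed:\n", paste(err, collapse = "\n"))
  }
  out_sam
}

#' Load paired-read alignments against the gene database
#'
#' Reads a SAM or BAM file of alignments against the flank-extended gene
#' database, expands each alignment's CIGAR so that its bases and base
#' qualities are laid out in reference coordinates (soft clips and inserted
#' bases removed, deleted positions gap-filled with `-`), and pairs mates by
#' read name. Only primary alignments of mapped reads are kept, so each
#' fragment contributes at most one observation per position.
#'
#' @param path SAM or BAM file. SAM references must match the database.
#' @param db A `gene_db`.
#' @param min_mapq Minimum mapping quality (default 0, i.e. no MAPQ filter;
#'   the variant filters are base-quality based).
#' @return A `data.table` with one row per aligned mate: `frag_id` (read
#'   name shared by mates), `gene_id`, `start`/`end` (1-based, ext-sequence
#'   coordinates), `seq` and `qual` (reference-layout strings), `mapq`.
#' @export
load_alignments <- function(path, db, min_mapq = 0L) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (!grepl("\\.bam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flag,
                                   what = c("qname", "seq", "qual", "mapq"))
  ga <- GenomicAlignments::readGAlignments(bam, param = param)
  refs <- as.character(GenomeInfoDb::seqnames(ga))
  lut <- setNames(db$gene_id, db_names(db))
  # accept either full database headers or bare gene ids as SAM references
  lut2 <- setNames(db$gene_id, db$gene_id)
  gene <- lut[refs]
  gene[is.na(gene)] <- lut2[refs[is.na(gene)]]
  if (anyNA(gene)) {
    stop("SAM reference absent from the gene database: ",
         paste(unique(refs[is.na(gene)])[1:5], collapse = ", "))
  }
  mcols <- S4Vectors::mcols(ga)
  seqs <- GenomicAlignments::sequenceLayer(
    mcols$seq, GenomicAlignments::cigar(ga), from = "query", to = "reference")
  quals <- GenomicAlignments::sequenceLayer(
    methods::as(mcols$qual, "BStringSet"), GenomicAlignments::cigar(ga),
    from = "query", to = "reference")
  aln <- data.table::data.table(
    frag_id = as.character(mcols$qname),
    gene_id = unname(gene),
    start = BiocGenerics::start(ga),
    end = BiocGenerics::end(ga),
    seq = as.character(seqs),
    qual = as.character(quals),
    mapq = as.integer(mcols$mapq)
  )
  aln <- aln[is.na(mapq) | mapq >= min_mapq]
  ext_len <- setNames(nchar(db$ext_seq), db$gene_id)
  if (aln[, any(start < 1L | end > ext_len[gene_id])]) {
    stop("alignment outside the extended gene bounds; SAM does not match ",
         "this gene database")
  }
  aln[]
}

# Replace bases whose phred score is below `min_base_qual` with N so that
# they drop out of pileups and linkage observations. Gap characters from
# deletions are untouched. Fast no-op when every base passes.
mask_low_qual <- function(aln, min_base_qual = 30L) {
  if (min_base_qual <= 0L || nrow(aln) == 0L) return(aln)
  thr <- as.raw(33L + as.integer(min_base_qual))
  qraw <- charToRaw(paste(aln$qual, collapse = ""))
  sraw <- charToRaw(paste(aln$seq, collapse = ""))
  gap <- charToRaw("-")
  low <- qraw < thr & sraw != gap & qraw != gap
  if (!any(low)) return(aln)
  sraw[low] <- charToRaw("N")
  lens <- nchar(aln$seq)
  offs <- cumsum(c(0L, lens[-length(lens)]))
  full <- rawToChar(sraw)
  out <- data.table::copy(aln)
  out[, seq := substring(full, offs + 1L, offs + lens)]
  out
}

#' Fraction of core gene positions covered by at least one read
#'
#' @param aln Alignments from [load_alignments()].
#' @param db A `gene_db`.
#' @return Proportion of core positions (flanks excluded) with depth >= 1.
#' @export
reference_coverage <- function(aln, db) {
  total <- sum(db$core_len)
  if (nrow(aln) == 0L) return(0)
  covered <- 0L
  for (i in seq_len(nrow(db))) {
    g <- aln[gene_id == db$gene_id[i]]
    if (nrow(g) == 0L) next
    core <- IRanges::IRanges(db$flank_left[i] + 1L,
                             db$flank_left[i] + db$core_len[i])
    r <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
    covered <- covered + sum(IRanges::width(IRanges::intersect(r, core)))
  }
  covered / total
}

#' Enforce the minimum reference-coverage gate
#'
#' Processing is interrupted when less than `min_fraction` (default 60%) of
#' the core gene positions are covered: such samples typically indicate a
#' mapping reference too distant to yield accurate genotypes (for example a
#' different species). The gate is a strict less-than, so exactly 60%
#' coverage passes.
#'
#' @inheritParams reference_coverage
#' @param min_fraction Abort threshold (default 0.60).
#' @return The covered fraction, invisibly.
#' @export
enforce_reference_coverage <- function(aln, db, min_fraction = 0.60) {
  frac <- reference_coverage(aln, db)
  if (frac < min_fraction) {
    stop(sprintf(paste0(
      "only %.1f%% of the reference gene positions are covered ",
      "(minimum %.0f%%); the mapping reference is likely too distant to ",
      "yield accurate genotypes"), 100 * frac, 100 * min_fraction))
  }
  invisible(frac)
}
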