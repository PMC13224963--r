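#' Describe a synthetic strain-mixture sequencing experiment
#'
#' Captures the design of one simulated sample: a random multi-gene
#' reference genome, `n_strains` derived strain genomes at a controlled
#' nucleotide identity to the reference, and a paired-end read mixture at
#' the stated strain frequencies. Defaults mirror a typical bacterial
#' short-read experiment: 150 bp paired reads, fragment sizes
#' Normal(300, 30), and a uniform substitution error rate of 0.1%.
#'
#' `identity` is the per-strain identity to the reference; because strains
#' mutate independently, the pairwise identity between two strains is
#' approximately `2 * identity - 1` (e.g. 0.99 per strain gives ~98%
#' strain-to-strain ANI).
#'
#' @param n_genes,gene_length Genes in the reference and their length (bp).
#' @param n_strains Number of strains (1-4).
#' @param frequencies Strain relative frequencies (sum to 1).
#' @param identity Per-strain nucleotide identity to the reference.
#' @param coverage Total expected read-base depth across the genome.
#' @param read_length,fragment_mean,fragment_sd Read geometry (bp).
#' @param error_rate Per-base substitution sequencing-error rate.
#' @param intergenic Spacer length between genes (bp); the default 200
#'   lets flank-extended gene regions overlap so mate pairs can bridge
#'   adjacent genes while read placement stays unambiguous.
#' @return A validated `sim_design` list.
#' @export
sim_design <- function(n_genes = 50L, gene_length = 900L, n_strains = 3L,
                       frequencies = c(0.7, 0.2, 0.1), identity = 0.99,
                       coverage = 60, read_length = 150L,
                       fragment_mean = 300, fragment_sd = 30,
                       error_rate = 0.001, intergenic = 200L) {
  frequencies <- as.numeric(frequencies)
  stopifnot(n_genes >= 1L, gene_length >= 1L,
            n_strains >= 1L, n_strains <= 4L,
            length(frequencies) == n_strains,
            all(frequencies > 0), abs(sum(frequencies) - 1) < 1e-8,
            identity > 0, identity <= 1, coverage > 0,
            read_length >= 50L, fragment_mean >= read_length,
            fragment_sd >= 0, error_rate >= 0, error_rate < 0.5)
  structure(list(n_genes = as.integer(n_genes),
                 gene_length = as.integer(gene_length),
                 n_strains = as.integer(n_strains),
                 frequencies = frequencies, identity = identity,
                 coverage = coverage, read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 error_rate = error_rate, intergenic = as.integer(intergenic)),
            class = "sim_design")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a random annotated reference genome
#'
#' One contig of `n_genes` genes of length `gene_length`, separated (and
#' bordered) by intergenic spacers, with uniform base composition.
#'
#' @param design A `sim_design`.
#' @param seed Optional integer seed.
#' @return `list(contig=, genes=)` where `genes` is a `gene_db` laid out
#'   with the design's read length.
#' @export
sim_reference <- function(design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sp <- design$intergenic
  gl <- design$gene_length
  L <- design$n_genes * gl + (design$n_genes + 1L) * sp
  contig <- .random_dna(L)
  starts <- sp + 1L + (seq_len(design$n_genes) - 1L) * (gl + sp)
  feats <- data.frame(
    key = "CDS", start = starts, end = starts + gl - 1L,
    strand = rep(c("+", "-"), length.out = design$n_genes),
    id = sprintf("gene_%03d", seq_len(design$n_genes)),
    pseudo = FALSE, contig_id = "simcontig1", contig_len = L,
    contig_seq = contig, stringsAsFactors = FALSE)
  genes <- .build_gene_db(feats, design$read_length)
  list(contig = contig, genes = genes)
}

#' Write a contig and its gene annotations as a GenBank flat file
#'
#' @param contig Contig sequence (single string).
#' @param genes A `gene_db` for this contig.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(contig, genes, path) {
  L <- nchar(contig)
  con <- file(path, "w")
  on.exit(close(con))
  cid <- genes$contig_id[1]
  writeLines(sprintf(
    "LOCUS       %s %d bp    DNA     linear   BCT 01-JAN-2026", cid, L), con)
  writeLines(sprintf("DEFINITION  synthetic reference %s.", cid), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  for (i in seq_len(nrow(genes))) {
    loc <- sprintf("%d..%d", genes$gene_start[i], genes$gene_end[i])
    if (genes$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     gene            %s", loc), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"",
                       genes$gene_id[i]), con)
    writeLines(sprintf("     CDS             %s", loc), con)
    writeLines(sprintf("                     /locus_tag=\"%s\"",
                       genes$gene_id[i]), con)
  }
  writeLines("ORIGIN", con)
  lower <- tolower(contig)
  for (off in seq(1L, L, by = 60L)) {
    chunk <- substring(lower, off, min(off + 59L, L))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Derive strain genomes from a reference at a controlled identity
#'
#' Each strain receives independent random substitutions at rate
#' `1 - identity` across the contig; positions and alleles are recorded
#' in a truth table (annotated with the gene and core position when the
#' substitution falls inside a gene).
#'
#' @param reference From [sim_reference()].
#' @param design A `sim_design`.
#' @param seed Optional integer seed.
#' @return `list(seqs=, truth=)`: strain contig sequences and a
#'   `data.table` of substitutions (`strain`, `contig_pos`, `ref`, `alt`,
#'   `gene_id`, `pos` — NA outside genes).
#' @export
sim_strains <- function(reference, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  contig <- reference$contig
  genes <- reference$genes
  L <- nchar(contig)
  bases <- c("A", "C", "G", "T")
  seqs <- character(design$n_strains)
  truth <- list()
  for (s in seq_len(design$n_strains)) {
    n_sub <- rbinom(1L, L, 1 - design$identity)
    if (n_sub == 0L) {
      seqs[s] <- contig
      truth[[s]] <- data.table::data.table(
        strain = integer(), contig_pos = integer(), ref = character(),
        alt = character(), gene_id = character(), pos = integer())
      next
    }
    pos <- sort(sample.int(L, n_sub))
    refb <- substring(contig, pos, pos)
    alt <- vapply(refb, function(b) sample(setdiff(bases, b), 1L),
                  character(1), USE.NAMES = FALSE)
    chars <- strsplit(contig, "", fixed = TRUE)[[1]]
    chars[pos] <- alt
    seqs[s] <- paste(chars, collapse = "")
    gi <- findInterval(pos, genes$gene_start)
    in_gene <- gi >= 1L & pos <= ifelse(gi >= 1L, genes$gene_end[pmax(gi, 1L)],
                                        0L)
    truth[[s]] <- data.table::data.table(
      strain = s, contig_pos = pos, ref = refb, alt = alt,
      gene_id = ifelse(in_gene, genes$gene_id[pmax(gi, 1L)], NA_character_),
      pos = ifelse(in_gene, pos - genes$gene_start[pmax(gi, 1L)] + 1L,
                   NA_integer_))
  }
  list(seqs = seqs, truth = data.table::rbindlist(truth))
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# inject uniform substitution errors into a vector of read sequences
.add_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  rl <- nchar(reads[1])
  n_err <- rbinom(length(reads), rl, rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    at <- sample.int(rl, n_err[i])
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    ch[at] <- vapply(ch[at], function(b) sample(setdiff(bases, b), 1L),
                     character(1), USE.NAMES = FALSE)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Simulate a paired-end read mixture (and its perfect alignment)
#'
#' Fragments are drawn from the strain genomes in proportion to the design
#' frequencies (multinomial), with lengths Normal(fragment_mean,
#' fragment_sd) truncated at the read length; the forward read is the
#' fragment's 5' end and the reverse read the reverse complement of its
#' 3' end. Substitution errors are injected uniformly at `error_rate` and
#' each base is given the phred score implied by that rate. Because the
#' strains differ from the reference only by substitutions, each read's
#' true placement against the flank-extended gene database is known, and
#' a "perfect" SAM (computed placements, no mapper) is produced for reads
#' that fall entirely within one extended gene region — mimicking an
#' end-to-end mapper that suppresses unaligned reads.
#'
#' @param strains From [sim_strains()].
#' @param reference From [sim_reference()].
#' @param design A `sim_design`.
#' @param seed Optional integer seed.
#' @return `list(reads=, sam=)`: a `data.table` of fragments (`frag_id`,
#'   `strain`, `start`, `frag_len`, `read1`, `read2`, `qual`) and a
#'   character vector of SAM lines (header included).
#' @export
sim_reads <- function(strains, reference, design, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- reference$genes
  L <- nchar(reference$contig)
  rl <- design$read_length
  n_frag <- max(1L, round(design$coverage * L / (2 * rl)))
  counts <- as.integer(rmultinom(1L, n_frag, design$frequencies))
  strain_of <- rep(seq_len(design$n_strains), counts)
  n <- length(strain_of)
  frag_len <- pmax(rl, pmin(L, round(rnorm(n, design$fragment_mean,
                                           design$fragment_sd))))
  start <- 1L + floor(runif(n) * (L - frag_len + 1))
  end <- start + frag_len - 1L

  src <- strains$seqs[strain_of]
  read1 <- substring(src, start, start + rl - 1L)
  read2_fwd <- substring(src, end - rl + 1L, end)
  read1 <- .add_errors(read1, design$error_rate)
  read2_fwd <- .add_errors(read2_fwd, design$error_rate)
  read2 <- .revcomp(read2_fwd)

  q <- if (design$error_rate > 0) {
    min(40L, as.integer(round(-10 * log10(design$error_rate))))
  } else 40L
  qual <- strrep(rawToChar(as.raw(33L + q)), rl)

  reads <- data.table::data.table(
    frag_id = sprintf("frag_%06d", seq_len(n)), strain = strain_of,
    start = as.integer(start), frag_len = as.integer(frag_len),
    read1 = read1, read2 = read2, qual = qual)

  # perfect placements: a mate maps iff one extended gene region fully
  # contains it; neighbouring regions overlap by less than a read length,
  # so the containing region is unique when it exists
  ext_start <- genes$gene_start - genes$flank_left
  ext_end <- genes$gene_end + genes$flank_right
  place <- function(rs, re) {
    gi <- findInterval(rs, ext_start)
    ok <- gi >= 1L & re <= ifelse(gi >= 1L, ext_end[pmax(gi, 1L)], 0L)
    list(gene = ifelse(ok, gi, NA_integer_),
         pos = ifelse(ok, rs - ext_start[pmax(gi, 1L)] + 1L, NA_integer_))
  }
  p1 <- place(start, start + rl - 1L)
  p2 <- place(end - rl + 1L, end)

  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", db_names(genes), nchar(genes$ext_seq)))
  refnames <- db_names(genes)
  cigar <- sprintf("%dM", rl)
  recs <- character(0)
  m1 <- !is.na(p1$gene)
  m2 <- !is.na(p2$gene)
  mk <- function(sel, mate) {
    if (mate == 1L) {
      g <- p1$gene[sel]; pp <- p1$pos[sel]
      og <- p2$gene[sel]; op <- p2$pos[sel]
      sq <- read1[sel]
      flag <- 0x1 + 0x40 + 0x20
    } else {
      g <- p2$gene[sel]; pp <- p2$pos[sel]
      og <- p1$gene[sel]; op <- p1$pos[sel]
      sq <- read2_fwd[sel]            # reference orientation in SAM
      flag <- 0x1 + 0x80 + 0x10
    }
    both <- !is.na(og)
    flags <- flag + ifelse(both, 0x2, 0x8)
    rnext <- ifelse(!both, "*",
                    ifelse(og == g, "=", refnames[pmax(og, 1L)]))
    pnext <- ifelse(both, op, 0L)
    sprintf("%s\t%d\t%s\t%d\t42\t%s\t%s\t%d\t0\t%s\t%s",
            reads$frag_id[sel], flags, refnames[g], pp, cigar, rnext,
            pnext, sq, qual)
  }
  if (any(m1)) recs <- c(recs, mk(which(m1), 1L))
  if (any(m2)) recs <- c(recs, mk(which(m2), 2L))
  list(reads = reads, sam = c(hdr, recs))
}

#' Write simulated reads as a paired FASTQ (phred+33)
#'
#' @param reads The `reads` table from [sim_reads()].
#' @param fastq1,fastq2 Output paths.
#' @return Invisibly, the two paths.
#' @export
write_fastq_pair <- function(reads, fastq1, fastq2) {
  writeLines(as.vector(rbind(paste0("@", reads$frag_id, "/1"), reads$read1,
                             "+", reads$qual)), fastq1)
  writeLines(as.vector(rbind(paste0("@", reads$frag_id, "/2"), reads$read2,
                             "+", reads$qual)), fastq2)
  invisible(c(fastq1, fastq2))
}

#' Simulate one complete strain-mixture sample
#'
#' Convenience wrapper chaining [sim_reference()], [sim_strains()] and
#' [sim_reads()] under one seed, optionally writing all artifacts
#' (GenBank reference, strain FASTAs, paired FASTQ, perfect SAM, truth
#' TSV) to a directory.
#'
#' @param design A `sim_design`.
#' @param seed Integer seed controlling the whole sample.
#' @param dir Optional output directory.
#' @return `list(design, reference, strains, reads, sam, truth, files)`;
#'   `truth` is restricted to substitutions inside gene cores (the
#'   positions the pipeline can genotype).
#' @export
simulate_sample <- function(design, seed = 0L, dir = NULL) {
  set.seed(seed)
  reference <- sim_reference(design)
  strains <- sim_strains(reference, design)
  rd <- sim_reads(strains, reference, design)
  truth <- strains$truth[!is.na(gene_id)]
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    files <- list(
      genbank = file.path(dir, "reference.gb"),
      fastq1 = file.path(dir, "reads_1.fastq"),
      fastq2 = file.path(dir, "reads_2.fastq"),
      sam = file.path(dir, "alignment.sam"),
      truth = file.path(dir, "truth.tsv"))
    write_genbank(reference$contig, reference$genes, files$genbank)
    write_fastq_pair(rd$reads, files$fastq1, files$fastq2)
    writeLines(rd$sam, files$sam)
    data.table::fwrite(truth, files$truth, sep = "\t")
    for (s in seq_len(design$n_strains)) {
      f <- file.path(dir, sprintf("true_strain_%d.fasta", s))
      Biostrings::writeXStringSet(Biostrings::DNAStringSet(
        setNames(strains$seqs[s], sprintf("strain_%d", s))), f, width = 80L)
      files[[sprintf("strain_%d", s)]] <- f
    }
  }
  list(design = design, reference = reference, strains = strains,
       reads = rd$reads, sam = rd$sam, truth = truth, files = files)
}
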