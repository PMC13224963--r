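#' Pipeline configuration with the method's defaults
#'
#' All tunable parameters of the pipeline, validated at construction.
#' Defaults: 150 bp reads, 60% reference-coverage gate, phred >= 30 bases,
#' depth band of 1.5 SD, a 20-read minimum support per allele,
#' allele frequencies within \[1%, 99%\], pair support >= 3, 500 walkers,
#' convergence after 100 non-improving iterations, big jumps every 10
#' iterations and after 20 stalled ones, 99.5% ANI strain merging, 1%
#' minimum strain frequency.
#'
#' @param read_length,ref_coverage_min,min_base_qual,depth_sd,min_allele_reads,freq_lo,freq_hi,min_pair_reads,min_pair_span,min_mapq,walkers,converge,stall,jump_every,ani_merge,min_strain_freq,seed
#'   See the corresponding stage functions for the meaning of each value.
#' @return A validated `run_config` list.
#' @export
run_config <- function(read_length = 150L, ref_coverage_min = 0.60,
                       min_base_qual = 30L, depth_sd = 1.5,
                       min_allele_reads = 20L, freq_lo = 0.01, freq_hi = 0.99,
                       min_pair_reads = 3L, min_pair_span = 20L, min_mapq = 0L, walkers = 500L,
                       converge = 100L, stall = 20L, jump_every = 10L,
                       ani_merge = 0.995, min_strain_freq = 0.01, seed = 0L) {
  cfg <- list(read_length = as.integer(read_length),
              ref_coverage_min = ref_coverage_min,
              min_base_qual = as.integer(min_base_qual),
              depth_sd = depth_sd,
              min_allele_reads = as.integer(min_allele_reads),
              freq_lo = freq_lo, freq_hi = freq_hi,
              min_pair_reads = as.integer(min_pair_reads),
              min_pair_span = as.integer(min_pair_span),
              min_mapq = as.integer(min_mapq),
              walkers = as.integer(walkers), converge = as.integer(converge),
              stall = as.integer(stall), jump_every = as.integer(jump_every),
              ani_merge = ani_merge, min_strain_freq = min_strain_freq,
              seed = as.integer(seed))
  stopifnot(cfg$read_length > 0L, cfg$ref_coverage_min >= 0,
            cfg$ref_coverage_min <= 1, cfg$min_base_qual >= 0L,
            cfg$depth_sd > 0, cfg$min_allele_reads >= 1L,
            cfg$freq_lo >= 0, cfg$freq_hi <= 1, cfg$freq_lo < cfg$freq_hi,
            cfg$min_pair_reads >= 1L, cfg$min_pair_span >= 1L, cfg$walkers >= 1L, cfg$converge >= 1L,
            cfg$stall >= 1L, cfg$jump_every >= 1L, cfg$ani_merge > 0,
            cfg$ani_merge <= 1, cfg$min_strain_freq >= 0,
            cfg$min_strain_freq < 1)
  structure(cfg, class = "run_config")
}

#' Run the full strain-deconvolution pipeline
#'
#' Executes, in order: gene-database construction (unless a `gene_db` is
#' supplied), read mapping (unless an alignment is supplied), the
#' reference-coverage gate, pileup and variant calling under the quality /
#' depth / frequency filters, allele-pair linkage, the stochastic
#' hexamodal-peak search, genotype phasing with N-masking, and ANI
#' merging. A sample with no intermediate-frequency allele variants is
#' reported as a single strain (the reference plus any fixed
#' differences).
#'
#' @param genbank Path to the GenBank reference, or a `gene_db`.
#' @param sam Path to a SAM/BAM of reads mapped against the gene
#'   database (from [run_mapper()] or an external run), or an alignment
#'   table from [load_alignments()].
#' @param fastq1,fastq2 Paired FASTQ files; used only when `sam` is
#'   missing, in which case `bowtie2` must be available.
#' @param config A [run_config()].
#' @param out_dir Optional directory for all outputs (strain FASTAs,
#'   variant/linkage TSVs, JSON summary, run log).
#' @return A `straindecon_result` list: `genotypes`
#'   (`strain_genotypes`), `freqs`, `fit`, `variants`, `fixed`, `pairs`,
#'   `groups`, `assignments`, `coverage`, `config`.
#' @export
run_pipeline <- function(genbank, sam = NULL, fastq1 = NULL, fastq2 = NULL,
                         config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  db <- if (inherits(genbank, "gene_db")) genbank
        else read_genbank_genes(genbank, config$read_length)
  message(sprintf("[refdb] %d genes, %d core bp", nrow(db),
                  sum(db$core_len)))
  if (is.null(sam)) {
    if (is.null(fastq1) || is.null(fastq2)) {
      stop("[alignio] supply either `sam` or both fastq files")
    }
    db_fa <- tempfile(fileext = ".fasta")
    write_gene_db(db, db_fa)
    sam <- run_mapper(db_fa, fastq1, fastq2)
  }
  aln <- if (is.data.frame(sam)) data.table::as.data.table(sam)
         else load_alignments(sam, db, config$min_mapq)
  cov <- enforce_reference_coverage(aln, db, config$ref_coverage_min)
  message(sprintf("[alignio] %d aligned mates; %.1f%% of core positions covered",
                  nrow(aln), 100 * cov))
  aln <- mask_low_qual(aln, config$min_base_qual)
  pile <- build_pileup(aln, db, min_base_qual = 0L)
  pile_kept <- depth_filter(pile, config$depth_sd)
  calls <- call_variants(pile_kept, pileup_all = pile,
                         min_allele_reads = config$min_allele_reads,
                         freq_lo = config$freq_lo, freq_hi = config$freq_hi)
  variants <- calls$variants
  fixed <- calls$fixed
  message(sprintf("[variants] %d allele variants at %d sites; %d fixed differences",
                  nrow(variants), data.table::uniqueN(variants$site_id),
                  nrow(fixed)))

  if (nrow(variants) == 0L) {
    # no intermediate-frequency alleles: a single strain explains the sample
    message("[search] no allele variants in (freq_lo, freq_hi); ",
            "reporting a single strain")
    fit <- structure(list(freqs = c(1, 0, 0), score = 0, trace = NULL),
                     class = "strain_fit")
    assignments <- data.table::data.table(allele_id = integer(),
                                          subset_id = integer(),
                                          confidence = numeric(),
                                          masked = logical())
    genotypes <- build_genotypes(assignments, variants, fixed, db, fit,
                                 config$min_strain_freq)
    pairs <- data.table::data.table()
    groups <- data.table::data.table()
  } else {
    pairs <- extract_pairs(aln, variants, db, config$min_pair_reads,
                           config$min_pair_span, min_base_qual = 0L)
    groups <- build_groups(pairs, variants)
    message(sprintf("[linkage] %d allele pairs in %d linkage groups",
                    nrow(pairs), data.table::uniqueN(groups$group_id)))
    fit_input <- if (nrow(pairs) > 0L) pairs else variants$freq
    fit <- run_search(fit_input, n_walkers = config$walkers,
                      converge = config$converge, stall_jump = config$stall,
                      jump_every = config$jump_every)
    message(sprintf("[search] fitted frequencies %s (S = %.3f)",
                    paste(sprintf("%.3f", fit$freqs), collapse = "/"),
                    fit$score))
    assignments <- assign_alleles(variants, pairs, fit,
                                  config$min_strain_freq)
    genotypes <- build_genotypes(assignments, variants, fixed, db, fit,
                                 config$min_strain_freq)
  }
  genotypes <- merge_genotypes(genotypes, config$ani_merge)
  freqs <- vapply(genotypes$strains, `[[`, numeric(1), "freq")
  message(sprintf("[genotype] %d strain(s) at %s after ANI merging",
                  length(freqs),
                  paste(sprintf("%.3f", freqs), collapse = "/")))
  result <- structure(list(genotypes = genotypes, freqs = freqs, fit = fit,
                           variants = variants, fixed = fixed, pairs = pairs,
                           groups = groups, assignments = assignments,
                           coverage = cov, config = config),
                      class = "straindecon_result")
  if (!is.null(out_dir)) write_result(result, out_dir)
  result
}

#' @export
print.straindecon_result <- function(x, ...) {
  cat("straindecon result\n")
  cat(sprintf("  reference coverage: %.1f%%\n", 100 * x$coverage))
  cat(sprintf("  %d allele variants, %d pairs, %d fixed differences\n",
              nrow(x$variants), nrow(x$pairs), nrow(x$fixed)))
  print(x$genotypes)
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Emits per-strain FASTAs and a summary TSV ([write_genotypes()]), the
#' variant and linkage tables, the assignment table, a JSON summary and a
#' run log of the configuration and session.
#'
#' @param result A `straindecon_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(result$genotypes, dir)
  if (nrow(result$variants)) {
    write_variants(result$variants, file.path(dir, "variants.tsv"))
  }
  if (!is.null(result$pairs) && nrow(result$pairs)) {
    write_linkage(result$pairs, result$groups, file.path(dir, "linkage.tsv"))
    data.table::fwrite(result$assignments,
                       file.path(dir, "assignments.tsv"), sep = "\t")
  }
  summary <- list(
    n_strains = length(result$freqs),
    frequencies = result$freqs,
    fitted = unname(result$fit$freqs),
    score = result$fit$score,
    reference_coverage = result$coverage,
    n_variants = nrow(result$variants),
    n_fixed_differences = nrow(result$fixed),
    config = unclass(result$config))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log <- c(sprintf("straindecon %s", as.character(utils::packageVersion(
             "straindecon"))),
           sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           sprintf("%s = %s", names(result$config),
                   vapply(result$config, function(v)
                     paste(format(v), collapse = ","), character(1))))
  writeLines(log, file.path(dir, "run_log.txt"))
  invisible(dir)
}
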