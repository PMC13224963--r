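#' Genome-wide variant positions implied by a simulation truth table
#'
#' Variant positions are the sites (gene, core position) where at least
#' one truth strain differs from the mapping reference; accuracy metrics
#' are computed over exactly these sites.
#'
#' @param truth Truth table from [simulate_sample()] (`strain`, `gene_id`,
#'   `pos`, `ref`, `alt`).
#' @return `data.table` of unique `gene_id`, `pos`, `ref`.
#' @export
truth_variant_sites <- function(truth) {
  unique(truth[, .(gene_id, pos, ref)])
}

#' Genotype accuracy of one reconstructed strain against one truth strain
#'
#' The proportion of variant positions at which the reconstruction carries
#' the truth strain's allele. Positions where the reconstruction is "N"
#' (or a gap) are excluded from both numerator and denominator; positions
#' the reconstruction never predicted carry the mapping-reference base and
#' are scored as such.
#'
#' Reconstructions are normally compared in reference coordinates (the
#' simulator path needs no realignment); a gene whose reconstructed
#' length differs from the truth gene — an externally produced genotype
#' — is first aligned globally and positions falling on alignment gaps
#' are excluded, as gap positions are in general.
#'
#' @param recon_seqs Named character vector of reconstructed gene (core)
#'   sequences.
#' @param truth_seqs Named character vector of the truth strain's gene
#'   core sequences.
#' @param sites Variant sites from [truth_variant_sites()].
#' @return `list(accuracy=, n_eval=, n_correct=, n_masked=)`; accuracy is
#'   `NA` when every site is masked.
#' @export
genotype_accuracy <- function(recon_seqs, truth_seqs, sites) {
  mismatched <- names(truth_seqs)[
    names(truth_seqs) %in% names(recon_seqs) &
    nchar(recon_seqs[names(truth_seqs)]) != nchar(truth_seqs)]
  for (g in mismatched) {
    recon_seqs[g] <- .project_onto(recon_seqs[[g]], truth_seqs[[g]])
  }
  rb <- substring(recon_seqs[sites$gene_id], sites$pos, sites$pos)
  tb <- substring(truth_seqs[sites$gene_id], sites$pos, sites$pos)
  ok <- !(rb %in% c("N", "-")) & !(tb %in% c("N", "-"))
  n_eval <- sum(ok)
  n_correct <- sum(rb[ok] == tb[ok])
  list(accuracy = if (n_eval) n_correct / n_eval else NA_real_,
       n_eval = n_eval, n_correct = n_correct,
       n_masked = sum(rb %in% c("N", "-")))
}

# Globally align a reconstructed gene to the truth gene and express it
# in the truth's coordinates; positions deleted in the reconstruction
# become "-" (excluded from scoring, like "N").
.project_onto <- function(recon, truth) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(recon),
    Biostrings::DNAString(truth), type = "global",
    gapOpening = 10, gapExtension = 0.5)
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  keep <- sub != "-"
  paste(pat[keep], collapse = "")
}

# truth strain gene-core sequences from strain contigs
truth_gene_seqs <- function(sim) {
  g <- sim$reference$genes
  lapply(seq_len(sim$design$n_strains), function(s) {
    setNames(substring(sim$strains$seqs[s], g$gene_start, g$gene_end),
             g$gene_id)
  })
}

#' Match reconstructed strains to truth strains
#'
#' With `injective = TRUE` (default), finds the injective assignment of
#' reconstructed to truth strains maximizing the summed genotype accuracy
#' (ties broken by closest frequencies) by exhaustive enumeration — exact
#' for the <= 4 strains handled here. With `injective = FALSE` each
#' reconstructed strain is simply matched to its best truth strain
#' (several reconstructions may share one truth strain), the appropriate
#' reading when more strains were simulated than the model can represent.
#'
#' @param acc Accuracy matrix (reconstructed x truth), e.g. built from
#'   [genotype_accuracy()].
#' @param f_est,f_true Frequency vectors of reconstructed/truth strains.
#' @param injective Whether the mapping must be injective.
#' @return `data.table` with `recon`, `truth`, `accuracy`, `f_est`,
#'   `f_true`.
#' @export
match_strains <- function(acc, f_est, f_true, injective = TRUE) {
  m <- nrow(acc)
  n <- ncol(acc)
  score <- ifelse(is.na(acc), 0, acc)
  if (!injective) {
    j <- apply(score, 1L, which.max)
    return(data.table::data.table(recon = seq_len(m), truth = j,
                                  accuracy = acc[cbind(seq_len(m), j)],
                                  f_est = f_est, f_true = f_true[j]))
  }
  stopifnot(m <= n)
  perms <- .permutations(n)
  best <- NULL
  best_key <- c(-Inf, Inf)
  for (r in seq_len(nrow(perms))) {
    j <- perms[r, seq_len(m)]
    tot <- sum(score[cbind(seq_len(m), j)])
    df <- sum(abs(f_est - f_true[j]))
    if (tot > best_key[1] + 1e-12 ||
        (abs(tot - best_key[1]) <= 1e-12 && df < best_key[2] - 1e-12)) {
      best_key <- c(tot, df)
      best <- j
    }
  }
  data.table::data.table(recon = seq_len(m), truth = best,
                         accuracy = acc[cbind(seq_len(m), best)],
                         f_est = f_est, f_true = f_true[best])
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Mean strain-frequency accuracy of matched strains
#'
#' Per matched strain the accuracy is `1 - |f_est - f_true|`; the mean
#' over matched strains is reported.
#'
#' @param matches From [match_strains()].
#' @return Proportion in `[0, 1]`.
#' @export
frequency_accuracy <- function(matches) {
  mean(1 - abs(matches$f_est - matches$f_true))
}

#' Evaluate a pipeline result against its simulation truth
#'
#' Computes the evaluation metrics: strain-count
#' correctness, mean genotype accuracy over matched strains, mean
#' frequency accuracy, and the fraction of variant positions left
#' uncalled ("N") in the reconstructions.
#'
#' @param result A `straindecon_result` from [run_pipeline()] (or a
#'   `strain_genotypes`).
#' @param sim A simulation from [simulate_sample()].
#' @param injective Passed to [match_strains()]; use `FALSE` when more
#'   strains were simulated than the model reconstructs.
#' @return List with `n_true`, `n_inferred`, `matches`, `genotype_acc`,
#'   `freq_acc`, `uncalled_frac`, `dominant_acc` (accuracy of the strain
#'   matched to the most abundant truth strain, `NA` if unmatched).
#' @export
evaluate_sample <- function(result, sim, injective = TRUE) {
  genotypes <- if (inherits(result, "strain_genotypes")) result
               else result$genotypes
  sites <- truth_variant_sites(sim$truth)
  tseqs <- truth_gene_seqs(sim)
  f_true <- sim$design$frequencies
  m <- length(genotypes$strains)
  n <- length(tseqs)
  acc <- matrix(NA_real_, m, n)
  masked <- numeric(m)
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      ga <- genotype_accuracy(genotypes$strains[[i]]$seqs, tseqs[[j]], sites)
      acc[i, j] <- ga$accuracy
      masked[i] <- ga$n_masked
    }
  }
  f_est <- vapply(genotypes$strains, `[[`, numeric(1), "freq")
  injective <- injective && m <= n
  matches <- match_strains(acc, f_est, f_true, injective = injective)
  dom <- which.max(f_true)
  dom_row <- matches[matches$truth == dom]
  list(n_true = n, n_inferred = m, matches = matches,
       genotype_acc = mean(matches$accuracy, na.rm = TRUE),
       freq_acc = frequency_accuracy(matches),
       uncalled_frac = mean(masked) / max(1L, nrow(sites)),
       dominant_acc = if (nrow(dom_row)) max(dom_row$accuracy) else NA_real_)
}
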