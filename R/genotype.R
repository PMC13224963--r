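# Canonical, live-strain-aware peak votes. A frequency's vote is the set
# of strains (restricted to live strains) shared by every peak tied at
# the minimal distance; when the tied peaks disagree about a live strain
# the vote carries no phasing information and is discarded (NA). Votes
# are reported as the smallest canonical subset with that live
# membership, so e.g. votes for {1} and {1,3} pool once strain 3 is dead.
vote_subset <- function(freq, dist, live) {
  p <- unname(peaks_from(dist))
  n <- length(freq)
  d <- abs(outer(freq, p, "-"))
  dmin <- do.call(pmin, as.data.frame(d))
  tied <- d <= dmin + 1e-9
  sig <- as.integer(MEMBER %*% (as.numeric(live) * 2^(0:2)))  # per subset
  canon <- match(sig, sig)            # first subset with each signature
  sm <- matrix(rep(sig, each = n), n, 6)
  sm[!tied] <- NA_integer_
  lo <- do.call(pmin, c(as.data.frame(sm), na.rm = TRUE))
  hi <- do.call(pmax, c(as.data.frame(sm), na.rm = TRUE))
  first_tied <- max.col(tied, ties.method = "first")
  out <- canon[first_tied]
  out[lo != hi | lo == 0L] <- NA_integer_
  out
}

#' Assign alleles to strain subsets with a local confidence score
#'
#' Every allele pair an allele participates in is a vote: the pair's
#' frequency is assigned to its nearest hexamodal peak, and the peak's
#' strain subset (the strains carrying both alleles of the pair) is the
#' vote, weighted by the pair's read support (`co_count`). Votes tied
#' across peaks of identical frequency are kept when the tied peaks
#' agree about every live strain (e.g. peaks 1 and 1+3 once strain 3 is
#' fitted at zero) and discarded as uninformative otherwise (e.g. all
#' peaks of an exactly equal-frequency fit). The allele's subset is the
#' plurality vote and its confidence the plurality share among
#' informative votes; because votes pool fragments across the whole
#' linkage neighbourhood, this is far more robust to binomial frequency
#' noise than the allele's own site frequency. An allele assigned to a
#' different peak more than half of the time (confidence <= 0.5), or
#' with no informative vote at all, is considered ambiguous and masked.
#' Alleles with no retained pair are assigned by their own site
#' frequency with confidence 1.
#'
#' @param variants Called variants from [call_variants()].
#' @param pairs Allele pairs from [extract_pairs()].
#' @param fit A `strain_fit` from [run_search()] (or a frequency vector).
#' @param min_strain_freq Strains fitted below this frequency are
#'   ignored when judging whether tied peaks disagree (default 0.01).
#' @return `data.table` with `allele_id`, `subset_id` (1..6, canonical
#'   peak order), `confidence` and `masked`.
#' @export
assign_alleles <- function(variants, pairs, fit, min_strain_freq = 0.01) {
  dist <- if (inherits(fit, "strain_fit")) fit$freqs else fit
  live <- dist >= min_strain_freq
  if (!any(live)) live[which.max(dist)] <- TRUE
  own <- vote_subset(variants$freq, dist, live)
  out <- data.table::data.table(
    allele_id = variants$allele_id,
    subset_id = ifelse(is.na(own), assign_peak(variants$freq, dist)$subset,
                       own),
    confidence = ifelse(is.na(own), 0, 1))
  if (nrow(pairs) > 0L) {
    psub <- vote_subset(pairs$pair_freq, dist, live)
    votes <- data.table::rbindlist(list(
      data.table::data.table(allele_id = pairs$a_id, peak_subset = psub,
                             w = pairs$co_count),
      data.table::data.table(allele_id = pairs$b_id, peak_subset = psub,
                             w = pairs$co_count)))
    informative <- votes[!is.na(peak_subset),
                         .(w = sum(w)), by = .(allele_id, peak_subset)]
    informative[, total := sum(w), by = allele_id]
    data.table::setorder(informative, allele_id, -w, peak_subset)
    top <- informative[, .SD[1L], by = allele_id]
    out[top, on = "allele_id",
        `:=`(subset_id = i.peak_subset, confidence = i.w / i.total)]
    # alleles whose every vote was uninformative
    paired <- unique(c(pairs$a_id, pairs$b_id))
    voteless <- setdiff(paired, informative$allele_id)
    out[allele_id %in% voteless, confidence := 0]
  }
  out[, masked := confidence <= 0.5]
  data.table::setorder(out, allele_id)
  out[]
}

#' Reconstruct per-strain genotype sequences
#'
#' For each retained strain, every core gene position carries the mapping
#' reference base unless evidence overrides it: fixed differences are
#' written into all strains; at called variant sites, each unmasked
#' non-reference allele is written into the strains of its subset. A
#' position becomes "N" for a strain when the evidence is ambiguous:
#' two unmasked alleles with different bases claim the strain at one
#' site (both are masked and a warning is issued), or a masked
#' (low-confidence) non-reference allele plausibly belongs to the
#' strain. Strains not claimed by any non-reference allele keep the
#' reference base — the mapping-reference default that evaluation
#' conventions also assume for unpredicted positions.
#'
#' @param assignments From [assign_alleles()].
#' @param variants,fixed From [call_variants()].
#' @param db A `gene_db`.
#' @param fit A `strain_fit` (or frequency vector); supplies the
#'   per-strain frequency estimates.
#' @param min_strain_freq Strains fitted below this frequency are dropped
#'   (default 0.01).
#' @return A `strain_genotypes` object: list with `strains` (each a list
#'   of `freq`, `seqs` — named character per gene — `n_variant`, `n_N`)
#'   plus the gene order.
#' @export
build_genotypes <- function(assignments, variants, fixed, db, fit,
                            min_strain_freq = 0.01) {
  dist <- if (inherits(fit, "strain_fit")) fit$freqs else fit
  keep <- which(dist >= min_strain_freq)
  if (!length(keep)) keep <- which.max(dist)

  asg <- merge(variants[, .(allele_id, site_id, gene_id, pos, base, is_ref)],
               assignments, by = "allele_id")
  alts <- asg[is_ref == FALSE]

  # conflicting unmasked claims (same site, same strain, different bases)
  if (nrow(alts)) {
    long <- data.table::rbindlist(lapply(1:3, function(i) {
      alts[masked == FALSE & MEMBER[subset_id, i],
           .(site_id, base, allele_id, strain = i)]
    }))
    if (nrow(long)) {
      confl <- long[, .(nb = data.table::uniqueN(base)),
                    by = .(site_id, strain)][nb > 1L]
      if (nrow(confl)) {
        bad <- long[confl, on = .(site_id, strain)][, unique(allele_id)]
        warning(length(bad), " allele(s) masked due to conflicting strain ",
                "claims at ", data.table::uniqueN(confl$site_id), " site(s)")
        asg[allele_id %in% bad, masked := TRUE]
        alts <- asg[is_ref == FALSE]
      }
    }
  }

  cores <- core_seq(db)
  strains <- list()
  for (i in keep) {
    chars <- lapply(cores, function(s) strsplit(s, "", fixed = TRUE)[[1]])
    if (nrow(fixed)) {
      for (r in seq_len(nrow(fixed))) {
        chars[[fixed$gene_id[r]]][fixed$pos[r]] <- fixed$base[r]
      }
    }
    n_var <- 0L
    n_N <- 0L
    if (nrow(alts)) {
      claims <- alts[MEMBER[subset_id, i] == TRUE,
                     .(bases = list(unique(base[!masked])),
                       any_masked = any(masked),
                       gene_id = gene_id[1L], pos = pos[1L]),
                     by = site_id]
      for (r in seq_len(nrow(claims))) {
        b <- claims$bases[[r]]
        g <- claims$gene_id[r]
        p <- claims$pos[r]
        if (length(b) == 1L && !claims$any_masked[r]) {
          chars[[g]][p] <- b
          n_var <- n_var + 1L
        } else if (length(b) >= 1L || claims$any_masked[r]) {
          chars[[g]][p] <- "N"
          n_N <- n_N + 1L
        }
      }
    }
    strains[[length(strains) + 1L]] <- list(
      freq = unname(dist[i]),
      seqs = vapply(chars, paste, character(1), collapse = ""),
      n_variant = n_var, n_N = n_N)
  }
  structure(list(strains = strains, gene_ids = db$gene_id),
            class = "strain_genotypes")
}

#' Pairwise nucleotide identity between two genotype sequences
#'
#' Identity is computed over positions where neither sequence carries an
#' "N"; the denominator therefore differs between genotype pairs.
#'
#' @param x,y Character vectors of gene sequences (same genes, same order)
#'   or single strings.
#' @return Proportion identical, or `NA` when no position is comparable.
#' @export
seq_identity <- function(x, y) {
  a <- charToRaw(paste(x, collapse = ""))
  b <- charToRaw(paste(y, collapse = ""))
  stopifnot(length(a) == length(b))
  nraw <- charToRaw("N")
  use <- a != nraw & b != nraw
  if (!any(use)) return(NA_real_)
  mean(a[use] == b[use])
}

#' Collapse near-identical genotypes by average nucleotide identity
#'
#' Reconstructed genotypes at or above the strain-delineation identity
#' threshold (default 99.5% genome-wide) are merged transitively
#' (single linkage), keeping the most abundant member's sequence and
#' summing frequencies; surviving frequencies are renormalized. This
#' prevents overestimating the strain count from minor genotype
#' differences.
#'
#' @param genotypes A `strain_genotypes` from [build_genotypes()].
#' @param ani_threshold Merge threshold (default 0.995).
#' @return A `strain_genotypes` with `merged_from` counts per survivor,
#'   strains ordered by decreasing frequency.
#' @export
merge_genotypes <- function(genotypes, ani_threshold = 0.995) {
  st <- genotypes$strains
  n <- length(st)
  if (n == 0L) stop("no genotypes to merge")
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      ident <- seq_identity(st[[i]]$seqs, st[[j]]$seqs)
      if (!is.na(ident) && ident >= ani_threshold) {
        parent[find(j)] <- find(i)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  out <- list()
  for (cid in unique(comp)) {
    members <- which(comp == cid)
    freqs <- vapply(st[members], `[[`, numeric(1), "freq")
    # most abundant member survives; frequency ties go to the member
    # with the fewest masked positions (the most informative sequence)
    nN <- vapply(st[members], `[[`, integer(1), "n_N")
    lead <- members[order(-freqs, nN)[1L]]
    g <- st[[lead]]
    g$freq <- sum(freqs)
    g$merged_from <- length(members)
    out[[length(out) + 1L]] <- g
  }
  tot <- sum(vapply(out, `[[`, numeric(1), "freq"))
  out <- lapply(out, function(g) { g$freq <- g$freq / tot; g })
  ord <- order(vapply(out, `[[`, numeric(1), "freq"), decreasing = TRUE)
  structure(list(strains = out[ord], gene_ids = genotypes$gene_ids),
            class = "strain_genotypes")
}

#' @export
print.strain_genotypes <- function(x, ...) {
  cat(length(x$strains), "strain genotype(s) over", length(x$gene_ids),
      "genes\n")
  for (i in seq_along(x$strains)) {
    g <- x$strains[[i]]
    cat(sprintf("  strain %d: frequency %.4f, %d variant base(s), %d N\n",
                i, g$freq, g$n_variant, g$n_N))
  }
  invisible(x)
}

#' Write strain genotypes, one multi-FASTA per strain, plus a summary TSV
#'
#' @param genotypes A `strain_genotypes`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_genotypes <- function(genotypes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- data.table::data.table(
    strain = seq_along(genotypes$strains),
    frequency = vapply(genotypes$strains, `[[`, numeric(1), "freq"),
    n_variant = vapply(genotypes$strains, `[[`, integer(1), "n_variant"),
    n_N = vapply(genotypes$strains, `[[`, integer(1), "n_N"),
    merged_from = vapply(genotypes$strains, function(g) {
      if (is.null(g$merged_from)) 1L else as.integer(g$merged_from)
    }, integer(1)))
  for (i in seq_along(genotypes$strains)) {
    seqs <- Biostrings::DNAStringSet(genotypes$strains[[i]]$seqs)
    Biostrings::writeXStringSet(seqs, file.path(dir,
                                                sprintf("strain_%d.fasta", i)),
                                width = 80L)
  }
  data.table::fwrite(summ, file.path(dir, "strain_summary.tsv"), sep = "\t")
  invisible(dir)
}
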