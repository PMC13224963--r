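# minimal variant/pair scaffolding for assignment tests
mk_variants <- function(freqs, is_ref = rep(FALSE, length(freqs))) {
  data.table::data.table(
    gene_id = "g1", pos = seq_along(freqs) * 10L,
    base = rep(c("A", "C", "G", "T"), length.out = length(freqs)),
    count = 50L, depth = 100L, freq = freqs, is_ref = is_ref,
    site_id = seq_along(freqs), allele_id = seq_along(freqs))
}

mk_pairs <- function(a, b, freq, co = 10L, span = 100L) {
  data.table::data.table(a_id = a, b_id = b, co_count = co,
                         span_count = span, pair_freq = freq)
}

test_that("unanimous pair votes give full confidence", {
  dist <- c(0.7, 0.2, 0.1)
  v <- mk_variants(c(0.7, 0.7))
  # ten pairs all at the {1} peak
  p <- mk_pairs(rep(1L, 10), rep(2L, 10), freq = 0.7)
  asg <- assign_alleles(v, p, dist)
  expect_equal(asg$subset_id, c(1L, 1L))
  expect_equal(asg$confidence, c(1, 1))
  expect_false(any(asg$masked))
})

test_that("plurality vote wins and its share is the confidence", {
  dist <- c(0.7, 0.2, 0.1)
  v <- mk_variants(c(0.8, rep(0.5, 10)))
  # allele 1: 4 pairs voting {1} (0.7), 6 pairs voting {1,3} (0.8)
  p <- mk_pairs(rep(1L, 10), 2:11, freq = c(rep(0.7, 4), rep(0.8, 6)),
                co = 10L)
  asg <- assign_alleles(v, p, dist)
  expect_equal(asg$subset_id[1], 5L)          # {1,3}
  expect_equal(asg$confidence[1], 0.6)
  expect_false(asg$masked[1])

  # an exact split is ambiguous: strict majority is required
  p2 <- mk_pairs(rep(1L, 10), 2:11, freq = c(rep(0.7, 5), rep(0.8, 5)))
  asg2 <- assign_alleles(v, p2, dist)
  expect_equal(asg2$confidence[1], 0.5)
  expect_true(asg2$masked[1])
})

test_that("votes are weighted by pair read support", {
  dist <- c(0.7, 0.2, 0.1)
  v <- mk_variants(c(0.7, 0.5, 0.5))
  # one heavy pair voting {1} against two light pairs voting {1,3}
  p <- mk_pairs(c(1L, 1L, 1L), c(2L, 3L, 2L), freq = c(0.7, 0.8, 0.8),
                co = c(30L, 5L, 5L))
  asg <- assign_alleles(v, p, dist)
  expect_equal(asg$subset_id[1], 1L)
  expect_equal(asg$confidence[1], 0.75)
})

test_that("unpaired alleles fall back to their site frequency", {
  dist <- c(0.7, 0.2, 0.1)
  v <- mk_variants(c(0.31, 0.89))
  asg <- assign_alleles(v, mk_pairs(integer(), integer(), numeric()), dist)
  expect_equal(asg$subset_id, c(6L, 4L))      # {2,3} and {1,2}
  expect_equal(asg$confidence, c(1, 1))
})

test_that("votes tied across equal-value peaks are uninformative", {
  # at the exact equal-frequency fit every peak coincides at 1/3 or 2/3
  dist <- rep(1 / 3, 3)
  v <- mk_variants(c(1 / 3, 1 / 3))
  p <- mk_pairs(1L, 2L, freq = 1 / 3, co = 20L)
  asg <- assign_alleles(v, p, dist)
  expect_true(all(asg$masked))
  expect_equal(asg$confidence, c(0, 0))

  # but ties that only disagree about a dead strain stay informative:
  # under (0.8, 0.2, 0) peaks {1} and {1,3} coincide at 0.8
  dist2 <- c(0.8, 0.2, 0)
  v2 <- mk_variants(c(0.8, 0.8))
  p2 <- mk_pairs(1L, 2L, freq = 0.8, co = 20L)
  asg2 <- assign_alleles(v2, p2, dist2)
  expect_false(any(asg2$masked))
  expect_equal(asg2$subset_id, c(1L, 1L))
})

test_that("genotypes carry alleles by subset, N for ambiguity, reference
           elsewhere", {
  db <- toy_db()$db
  ref <- core_seq(db)[[1]]
  rb <- function(p) substr(ref, p, p)
  alt_of <- function(p) setdiff(c("A", "C", "G", "T"), rb(p))[1]
  dist <- c(0.5, 0.3, 0.2)
  v <- data.table::data.table(
    gene_id = "g1", pos = c(5L, 5L, 12L, 20L),
    base = c(alt_of(5), rb(5), alt_of(12), alt_of(20)),
    count = 50L, depth = 100L, freq = c(0.5, 0.5, 0.3, 0.2),
    is_ref = c(FALSE, TRUE, FALSE, FALSE),
    site_id = c(1L, 1L, 2L, 3L), allele_id = 1:4)
  asg <- data.table::data.table(
    allele_id = 1:4, subset_id = c(1L, 6L, 2L, 3L),
    confidence = c(1, 1, 1, 0.4), masked = c(FALSE, FALSE, FALSE, TRUE))
  fixed_base <- setdiff(c("A", "C", "G", "T"), rb(30))[1]
  fixed <- data.table::data.table(gene_id = "g1", pos = 30L,
                                  base = fixed_base,
                                  count = 100L, depth = 100L)
  gt <- build_genotypes(asg, v, fixed, db, dist)
  expect_length(gt$strains, 3L)
  s <- lapply(gt$strains, function(x) strsplit(x$seqs[[1]], "")[[1]])
  # biallelic site 5: the alt goes to strain 1; strains 2 and 3 keep the
  # reference allele (which is the complementary called allele)
  expect_equal(s[[1]][5], alt_of(5))
  expect_equal(s[[2]][5], rb(5))
  expect_equal(s[[3]][5], rb(5))
  # site 12: the alt belongs to strain 2 only
  expect_equal(s[[2]][12], alt_of(12))
  expect_equal(s[[1]][12], rb(12))
  # site 20: the masked alt claims strain 3 -> N there, reference else
  expect_equal(s[[3]][20], "N")
  expect_equal(s[[1]][20], rb(20))
  # the fixed difference is written into every strain
  expect_true(all(vapply(s, `[`, "", 30L) == fixed_base))
  # untouched positions equal the reference everywhere
  expect_equal(s[[1]][1:4], strsplit(substr(ref, 1, 4), "")[[1]])
})

test_that("conflicting unmasked claims mask both alleles with a warning", {
  db <- toy_db()$db
  dist <- c(0.6, 0.3, 0.1)
  v <- data.table::data.table(
    gene_id = "g1", pos = c(5L, 5L), base = c("A", "C"),
    count = 50L, depth = 100L, freq = c(0.6, 0.4),
    is_ref = FALSE, site_id = 1L, allele_id = 1:2)
  # both alleles unmasked and claiming strain 1
  asg <- data.table::data.table(
    allele_id = 1:2, subset_id = c(1L, 4L),
    confidence = 1, masked = FALSE)
  fixed <- data.table::data.table(gene_id = character(), pos = integer(),
                                  base = character(), count = integer(),
                                  depth = integer())
  expect_warning(gt <- build_genotypes(asg, v, fixed, db, dist),
                 "conflicting")
  s1 <- strsplit(gt$strains[[1]]$seqs[[1]], "")[[1]]
  expect_equal(s1[5], "N")
})

test_that("sequence identity ignores N positions pairwise", {
  x <- c("ACGTACGTAC")
  y <- c("ACGTACGTAC")
  expect_equal(seq_identity(x, y), 1)
  y2 <- "ACGAACGTAC"
  expect_equal(seq_identity(x, y2), 0.9)
  y3 <- "ACGNACGTAC"
  expect_equal(seq_identity(x, y3), 1)       # N excluded from denominator
  expect_true(is.na(seq_identity("NNN", "AAA")))
})

test_that("ANI merging collapses duplicates and renormalizes frequencies", {
  seqs <- strrep("ACGT", 500)             # 2000 bp
  mk <- function(freq, seq, nN = 0L) list(freq = freq, seqs = c(g1 = seq),
                                          n_variant = 0L, n_N = nN)
  # two identical genotypes merge, keeping the more abundant
  same <- structure(list(strains = list(mk(0.6, seqs), mk(0.4, seqs)),
                         gene_ids = "g1"), class = "strain_genotypes")
  m <- merge_genotypes(same, 0.995)
  expect_length(m$strains, 1L)
  expect_equal(m$strains[[1]]$freq, 1)
  expect_equal(m$strains[[1]]$merged_from, 2L)

  # identity just below the threshold is kept apart (99.4% vs 99.5%)
  v <- strsplit(seqs, "")[[1]]
  v[seq(1, by = 4, length.out = 12)] <- "T"   # 12 A->T: 0.6% difference
  other <- paste(v, collapse = "")
  expect_lt(seq_identity(seqs, other), 0.995)
  apart <- structure(list(strains = list(mk(0.6, seqs), mk(0.4, other)),
                          gene_ids = "g1"), class = "strain_genotypes")
  m2 <- merge_genotypes(apart, 0.995)
  expect_length(m2$strains, 2L)
  expect_equal(vapply(m2$strains, `[[`, 0, "freq"), c(0.6, 0.4))

  # transitive (single-linkage) merging: a~b and b~c merge all three
  v2 <- strsplit(seqs, "")[[1]]
  v2[seq(1, by = 4, length.out = 6)] <- "T"     # 0.3% from seqs
  v3 <- strsplit(seqs, "")[[1]]
  v3[seq(41, by = 4, length.out = 6)] <- "T"    # 0.3% from seqs, 0.6% v2
  chain <- structure(list(strains = list(
    mk(0.5, seqs), mk(0.3, paste(v2, collapse = "")),
    mk(0.2, paste(v3, collapse = ""))), gene_ids = "g1"),
    class = "strain_genotypes")
  m3 <- merge_genotypes(chain, 0.995)
  expect_length(m3$strains, 1L)
  expect_equal(m3$strains[[1]]$freq, 1)
})
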