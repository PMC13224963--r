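# Build a controlled alignment set in which fragments carry chosen bases
# at two variant sites of one gene.
two_site_fixture <- function(haps, n_each, toy = toy_db()) {
  db <- toy$db
  cs <- db$flank_left + 1L
  s1 <- cs + 5L                      # ext positions of the two sites
  s2 <- cs + 25L
  recs <- list()
  k <- 0L
  for (h in seq_along(haps)) {
    for (i in seq_len(n_each[h])) {
      sq <- substr(db$ext_seq, s1, s2)
      substr(sq, 1L, 1L) <- haps[[h]][1]
      substr(sq, s2 - s1 + 1L, s2 - s1 + 1L) <- haps[[h]][2]
      k <- k + 1L
      recs[[k]] <- list(qname = sprintf("f%03d", k), gene = "g1", pos = s1,
                        cigar = sprintf("%dM", s2 - s1 + 1L), seq = sq)
    }
  }
  aln <- load_alignments(write_toy_sam(db, recs), db)
  variants <- data.table::data.table(
    gene_id = "g1", pos = c(6L, 6L, 26L, 26L),
    base = c(haps[[1]][1], haps[[2]][1], haps[[1]][2], haps[[2]][2]),
    count = 10L, depth = sum(n_each), freq = 0.5, is_ref = FALSE,
    site_id = c(1L, 1L, 2L, 2L), allele_id = 1:4)
  list(db = db, aln = aln, variants = variants)
}

test_that("pair frequencies are co-occurrence over spanning fragments", {
  fx <- two_site_fixture(haps = list(c("A", "C"), c("G", "T")),
                         n_each = c(12L, 8L))
  pairs <- extract_pairs(fx$aln, fx$variants, fx$db, min_pair_reads = 3,
                         min_pair_span = 5)
  expect_equal(nrow(pairs), 2L)
  ac <- pairs[pairs$a_base == "A"]
  expect_equal(ac$co_count, 12L)
  expect_equal(ac$span_count, 20L)
  expect_equal(ac$pair_freq, 0.6)
  gt <- pairs[pairs$a_base == "G"]
  expect_equal(gt$pair_freq, 0.4)
})

test_that("pair counts equal a brute-force double loop over fragments", {
  set.seed(21)
  haps <- list(c("A", "C"), c("G", "T"), c("A", "T"))
  n_each <- c(9L, 6L, 5L)
  fx <- two_site_fixture(haps = haps, n_each = n_each)
  pairs <- extract_pairs(fx$aln, fx$variants, fx$db, min_pair_reads = 1,
                         min_pair_span = 1)
  # oracle: enumerate fragments x allele pairs
  frag_b1 <- rep(vapply(haps, `[`, "", 1), n_each)
  frag_b2 <- rep(vapply(haps, `[`, "", 2), n_each)
  for (r in seq_len(nrow(pairs))) {
    co <- sum(frag_b1 == pairs$a_base[r] & frag_b2 == pairs$b_base[r])
    expect_equal(pairs$co_count[r], co)
    expect_equal(pairs$span_count[r], sum(n_each))
  }
  # complementary pair frequencies sum to at most 1
  expect_lte(sum(pairs$pair_freq), 1)
})

test_that("conflicting mate observations void the fragment's site", {
  toy <- toy_db()
  db <- toy$db
  cs <- db$flank_left + 1L
  sq <- substr(db$ext_seq, cs, cs + 9L)
  sq_a <- sq; substr(sq_a, 3L, 3L) <- "A"
  sq_c <- sq; substr(sq_c, 3L, 3L) <- "C"
  aln <- load_alignments(write_toy_sam(db, list(
    list(qname = "f1", gene = "g1", pos = cs, cigar = "10M", seq = sq_a),
    list(qname = "f1", gene = "g1", pos = cs, cigar = "10M", seq = sq_c))),
    db)
  variants <- data.table::data.table(
    gene_id = "g1", pos = 3L, base = c("A", "C"), count = 5L, depth = 10L,
    freq = 0.5, is_ref = FALSE, site_id = 1L, allele_id = 1:2)
  obs <- straindecon:::site_observations(aln, variants, db)
  expect_equal(nrow(obs), 0L)
})

test_that("linkage groups are the connected components of the pair graph", {
  variants <- data.table::data.table(allele_id = 1:6)
  pairs <- data.table::data.table(a_id = c(1L, 2L, 4L), b_id = c(2L, 3L, 5L))
  groups <- build_groups(pairs, variants)
  expect_equal(nrow(groups), 6L)
  g <- setNames(groups$group_id, groups$allele_id)
  expect_equal(g[["1"]], g[["2"]])
  expect_equal(g[["2"]], g[["3"]])
  expect_equal(g[["4"]], g[["5"]])
  expect_false(g[["1"]] == g[["4"]])
  expect_false(g[["6"]] %in% g[c("1", "4")])
})

test_that("components match a breadth-first-search oracle on random graphs", {
  set.seed(22)
  for (rep in 1:5) {
    n <- sample(50:200, 1)
    m <- sample(20:150, 1)
    edges <- data.table::data.table(
      from = sample.int(n, m, replace = TRUE),
      to = sample.int(n, m, replace = TRUE))
    edges <- edges[from != to]
    variants <- data.table::data.table(allele_id = seq_len(n))
    pairs <- data.table::data.table(a_id = edges$from, b_id = edges$to)
    groups <- build_groups(pairs, variants)
    oracle <- bfs_components(seq_len(n), edges)
    got <- setNames(groups$group_id, groups$allele_id)
    # same partition: equal group labels iff equal oracle labels
    for (k in seq_len(20)) {
      i <- sample.int(n, 1); j <- sample.int(n, 1)
      expect_equal(got[[as.character(i)]] == got[[as.character(j)]],
                   oracle[[as.character(i)]] == oracle[[as.character(j)]])
    }
  }
})

test_that("two-strain linkage spans neighbouring genes", {
  sim <- small_sim(n_strains = 2, frequencies = c(0.7, 0.3), coverage = 100,
                   error_rate = 0, seed = 23)
  db <- read_genbank_genes(sim$files$genbank)
  aln <- load_alignments(sim$files$sam, db)
  pile <- build_pileup(aln, db)
  calls <- call_variants(depth_filter(pile), pileup_all = pile)
  pairs <- extract_pairs(aln, calls$variants, db)
  expect_gt(nrow(pairs), 0)
  cross <- pairs[pairs$a_gene != pairs$b_gene]
  expect_gt(nrow(cross), 0)      # mate pairs bridge adjacent genes
  groups <- build_groups(pairs, calls$variants)
  # groups partition the allele set
  expect_equal(sort(groups$allele_id), sort(calls$variants$allele_id))
})
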