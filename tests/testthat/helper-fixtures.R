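# Shared fixtures: all synthetic, generated in code at test time.

# a small annotated reference written to a temporary GenBank file
small_sim <- function(n_genes = 8L, gene_length = 600L, n_strains = 2L,
                      frequencies = c(0.7, 0.3), coverage = 80,
                      identity = 0.99, error_rate = 0.001, seed = 101L,
                      dir = tempfile("sim_")) {
  d <- sim_design(n_genes = n_genes, gene_length = gene_length,
                  n_strains = n_strains, frequencies = frequencies,
                  coverage = coverage, identity = identity,
                  error_rate = error_rate)
  simulate_sample(d, seed = seed, dir = dir)
}

# a hand-constructed single-gene database: one contig, one gene
toy_db <- function(contig = NULL, gene_start = 31L, gene_end = 90L,
                   read_length = 20L, seed = 7L) {
  if (is.null(contig)) {
    set.seed(seed)
    contig <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                    collapse = "")
  }
  gb <- tempfile(fileext = ".gb")
  feats <- data.frame(gene_id = "g1", contig_id = "toy", gene_start = gene_start,
                      gene_end = gene_end, strand = "+",
                      flank_left = 0L, flank_right = 0L,
                      core_len = gene_end - gene_start + 1L,
                      ext_seq = "")
  class(feats) <- c("gene_db", "data.frame")
  write_genbank(contig, feats, gb)
  list(genbank = gb, contig = contig,
       db = read_genbank_genes(gb, read_length = read_length))
}

# write a SAM file for a list of alignments against a gene db
write_toy_sam <- function(db, recs, path = tempfile(fileext = ".sam")) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", straindecon:::db_names(db),
                   nchar(db$ext_seq)))
  names <- setNames(straindecon:::db_names(db), db$gene_id)
  lines <- vapply(recs, function(r) {
    qual <- if (is.null(r$qual)) strrep("I", nchar(r$seq)) else r$qual
    flag <- if (is.null(r$flag)) 0L else r$flag
    sprintf("%s\t%d\t%s\t%d\t42\t%s\t*\t0\t0\t%s\t%s",
            r$qname, flag, names[[r$gene]], r$pos, r$cigar, r$seq, qual)
  }, character(1))
  writeLines(c(hdr, lines), path)
  path
}

# brute-force pileup oracle: per-position base tally from explicit reads
brute_pileup <- function(reads) {
  # reads: list of list(pos=, seq=) already in reference layout
  tal <- list()
  for (r in reads) {
    ch <- strsplit(r$seq, "")[[1]]
    for (i in seq_along(ch)) {
      if (!ch[i] %in% c("A", "C", "G", "T")) next
      key <- as.character(r$pos + i - 1L)
      if (is.null(tal[[key]])) tal[[key]] <- c(A = 0, C = 0, G = 0, T = 0)
      tal[[key]][ch[i]] <- tal[[key]][ch[i]] + 1
    }
  }
  tal
}

# breadth-first connected components, independent of igraph
bfs_components <- function(vertices, edges) {
  adj <- setNames(vector("list", length(vertices)), as.character(vertices))
  for (i in seq_len(nrow(edges))) {
    a <- as.character(edges$from[i]); b <- as.character(edges$to[i])
    adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
  }
  comp <- setNames(rep(NA_integer_, length(vertices)),
                   as.character(vertices))
  k <- 0L
  for (v in as.character(vertices)) {
    if (!is.na(comp[[v]])) next
    k <- k + 1L
    queue <- v
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      if (!is.na(comp[[u]])) next
      comp[[u]] <- k
      queue <- c(queue, setdiff(unlist(adj[[u]]), names(which(!is.na(comp)))))
    }
  }
  comp
}
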