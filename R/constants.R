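# The six strain subsets of the hexamodal model, in canonical order:
# smallest subsets first, lexicographic within size. Peak k carries the
# summed frequency of the strains in subset k; subset k and subset 7-k
# are complementary.
SUBSETS <- list(1L, 2L, 3L, c(1L, 2L), c(1L, 3L), c(2L, 3L))
SUBSET_LABELS <- c("1", "2", "3", "1+2", "1+3", "2+3")
COMPLEMENT <- c(6L, 5L, 4L, 3L, 2L, 1L)

# subset containment matrix: SUB_OF[p, t] is TRUE when subset p is
# contained in subset t (a pair's peak must be carried by a sub-set of the
# strains carrying either of its alleles)
SUB_OF <- local({
  m <- matrix(FALSE, 6, 6)
  for (p in 1:6) for (t in 1:6) {
    m[p, t] <- all(SUBSETS[[p]] %in% SUBSETS[[t]])
  }
  m
})

# strain membership: MEMBER[s, i] is TRUE when strain i belongs to subset s
MEMBER <- local({
  m <- matrix(FALSE, 6, 3)
  for (s in 1:6) m[s, SUBSETS[[s]]] <- TRUE
  m
})
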