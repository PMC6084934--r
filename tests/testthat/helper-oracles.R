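# Independent oracles used across the suite.  They deliberately avoid the
# package's pair list and cost path: costs are recomputed by a nested loop
# over all ordered codon pairs with direct string comparison.

# squared polarity-difference cost by brute force; position "all" or 1:3
bruteForceCost <- function(code, scale = woesePolarity(), position = "all") {
  tab <- codonTable(code)
  vals <- scaleValues(scale)
  codons <- names(tab)
  s <- c(0, 0, 0)
  for (ci in codons) {
    for (cj in codons) {
      if (tab[ci] == "*" || tab[cj] == "*") next
      a <- strsplit(ci, "")[[1]]
      b <- strsplit(cj, "")[[1]]
      d <- which(a != b)
      if (length(d) != 1L) next
      s[d] <- s[d] + (vals[tab[ci]] - vals[tab[cj]])^2
    }
  }
  s <- s / 2  # ordered pairs counted twice
  if (identical(position, "all")) sum(s) else s[as.integer(position)]
}

# raw-representation validity check, written against the constants only
validRaw <- function(idx, model) {
  if (length(idx) != 61L || !all(idx %in% 1:20)) return(FALSE)
  if (length(unique(idx)) != 20L) return(FALSE)
  counts <- tabulate(idx, nbins = 20L)
  blocks <- codonEvolve:::.BLOCK_OF
  sgcCounts <- codonEvolve:::.SGC_COUNTS
  okBlocks <- all(vapply(split(idx, blocks), function(v)
    length(unique(v)) == 1L, logical(1)))
  switch(model,
         DEG = okBlocks && all(counts == sgcCounts),
         BLO = okBlocks,
         NUM = all(counts == sgcCounts),
         GEN = TRUE)
}

# all permutations of seq_len(n) as an n! x n matrix (insertion build)
allPermutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- allPermutations(n - 1L)
  blocks <- lapply(seq_len(n), function(j) {
    left <- sub[, seq_len(j - 1L), drop = FALSE]
    right <- if (j <= n - 1L) sub[, j:(n - 1L), drop = FALSE] else NULL
    cbind(left, n, right, deparse.level = 0)
  })
  do.call(rbind, blocks)
}

randomCodeOf <- function(model) {
  codonEvolve:::.code_from_idx(codonEvolve:::.random_raw(model))
}
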