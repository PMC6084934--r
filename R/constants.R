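# Fixed alphabets, codon ordering, the standard code and the bundled
# polar-requirement scale.  Everything downstream indexes into these
# constants, so their order is frozen: bases T < C < A < G per position,
# amino acids alphabetical by one-letter symbol.

.BASES <- c("T", "C", "A", "G")

# All 64 codons in canonical order (third base varies fastest):
# TTT, TTC, TTA, TTG, TCT, ...
.CODONS64 <- paste0(
  rep(.BASES, each = 16L),
  rep(rep(.BASES, each = 4L), times = 4L),
  rep(.BASES, times = 16L)
)

.STOPS <- c("TAA", "TAG", "TGA")

.SENSE <- setdiff(.CODONS64, .STOPS)   # 61 sense codons, canonical order

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# The standard genetic code (translation table 1), DNA alphabet.
.SGC_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

# Sense-codon assignment of the SGC as amino-acid indices into .AA20,
# in canonical sense-codon order.
.SGC_IDX <- local({
  aa <- .SGC_TABLE[.SENSE]
  m <- match(aa, .AA20)
  names(m) <- .SENSE
  m
})

# Synonymous blocks of the SGC: block b is the codon set of .AA20[b].
# .BLOCK_OF maps sense-codon index -> block index (1..20).
.BLOCK_OF <- unname(.SGC_IDX)

# Codons per amino acid in the SGC (alphabetical amino-acid order).
.SGC_COUNTS <- tabulate(.SGC_IDX, nbins = 20L)

# Degeneracy class of each amino acid: amino acids sharing a codon count
# form one class (classes 6, 4, 3, 2 and 1 codons in the SGC).
.DEG_CLASSES <- split(seq_len(20L), .SGC_COUNTS)

# Woese polar requirement, transcribed from the AAindex entry WOEC730101.
# Dimensionless chromatographic polarity index; user-overridable.
.POLARITY_WOESE <- c(
  A = 7.0, C = 5.5, D = 13.0, E = 12.5, F = 5.0,
  G = 7.9, H = 8.4, I = 4.9, K = 10.1, L = 4.9,
  M = 5.3, N = 10.0, P = 6.6, Q = 8.6, R = 9.1,
  S = 7.5, T = 6.6, V = 5.6, W = 5.3, Y = 5.7
)

# Mutational-neighbor pairs among the 61 sense codons: all unordered pairs
# differing at exactly one position, stored as indices into .SENSE and
# ordered by (position, i, j) so that position-wise partial sums of the
# cost are reproducible.
.PAIRS <- local({
  split3 <- t(vapply(strsplit(.SENSE, ""), identity, character(3)))
  ii <- integer(0); jj <- integer(0); pp <- integer(0)
  for (i in seq_len(60L)) {
    for (j in (i + 1L):61L) {
      d <- which(split3[i, ] != split3[j, ])
      if (length(d) == 1L) {
        ii <- c(ii, i); jj <- c(jj, j); pp <- c(pp, d)
      }
    }
  }
  o <- order(pp, ii, jj)
  list(i = ii[o], j = jj[o], pos = pp[o])
})
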