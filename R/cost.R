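# The mutational-neighbor pair set D and the squared polarity-difference
# cost evaluated over it, per codon position and in total.

#' Single-nucleotide neighbor pairs among sense codons
#'
#' Enumerates all unordered pairs of codons that differ at exactly one
#' position, excluding any pair that involves a stop codon (polarity is
#' undefined for stops).  With the standard stop set the full set D holds
#' 263 pairs, split 87 / 88 / 88 across the three positions; with no stops
#' excluded there are 288 = 64 x 9 / 2 pairs.
#'
#' @param stops Character vector of codons to exclude (default the three
#'   standard stops; may be empty).
#' @param position `"all"` or one of 1, 2, 3 to restrict to pairs
#'   differing at that position.
#' @return A data frame with columns `i`, `j` (codons, `i` before `j` in
#'   canonical order) and `position`, ordered by (position, i, j).
#' @export
neighborPairs <- function(stops = stopCodons(), position = "all") {
  bad <- setdiff(stops, .CODONS64)
  if (length(bad))
    stop("not a codon: ", paste(bad, collapse = ", "))
  keep <- setdiff(.CODONS64, stops)
  s3 <- t(vapply(strsplit(keep, ""), identity, character(3)))
  n <- length(keep)
  ii <- integer(0); jj <- integer(0); pp <- integer(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- which(s3[i, ] != s3[j, ])
      if (length(d) == 1L) {
        ii <- c(ii, i); jj <- c(jj, j); pp <- c(pp, d)
      }
    }
  }
  o <- order(pp, ii, jj)
  out <- data.frame(i = keep[ii[o]], j = keep[jj[o]], position = pp[o],
                    stringsAsFactors = FALSE)
  if (!identical(position, "all")) {
    position <- as.integer(position)
    stopifnot(position %in% 1:3)
    out <- out[out$position == position, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# 0-based pair-endpoint indices for the C++ evaluator, restricted to a
# criterion ("pos1".."pos3" or "sum").
.pair_idx <- function(criterion) {
  keep <- if (criterion == "sum") rep(TRUE, length(.PAIRS$pos))
          else .PAIRS$pos == match(criterion, c("pos1", "pos2", "pos3"))
  list(i = .PAIRS$i[keep] - 1L, j = .PAIRS$j[keep] - 1L)
}

# Criterion cost of a population: A is an n x 61 integer matrix of
# amino-acid indices in canonical sense-codon order.
.eval_pop <- function(A, pvec, criterion) {
  pd <- .pair_idx(criterion)
  eval_pop_cpp(A, pvec, pd$i, pd$j)
}

.scale_vec <- function(scale) {
  stopifnot(is(scale, "PolarityScale"))
  unname(scale@values)
}

#' Polarity cost of a genetic code
#'
#' The sum of squared polarity differences over the mutational-neighbor
#' pairs: for each unordered pair of sense codons differing at one
#' position, the squared difference between the polarity values of the
#' amino acids they encode, counted once.  `position = "all"` is by
#' definition the sum of the three per-position costs, so the identity
#' FT = F1 + F2 + F3 holds exactly.
#'
#' @param code A \linkS4class{GeneticCode}.
#' @param scale A \linkS4class{PolarityScale} (default the bundled Woese
#'   polar requirement).
#' @param position `"all"` (default) or 1, 2, 3.
#' @return A non-negative number.
#' @examples
#' polarityCost(standardCode(), position = 3)
#' @export
polarityCost <- function(code, scale = woesePolarity(), position = "all") {
  stopifnot(is(code, "GeneticCode"))
  p <- .scale_vec(scale)
  idx <- .idx_of_code(code)
  if (identical(position, "all"))
    return(sum(vapply(1:3, function(k) .cost_one(idx, p, k), numeric(1))))
  position <- as.integer(position)
  stopifnot(position %in% 1:3)
  .cost_one(idx, p, position)
}

.cost_one <- function(idx, p, k) {
  keep <- .PAIRS$pos == k
  d <- p[idx[.PAIRS$i[keep]]] - p[idx[.PAIRS$j[keep]]]
  sum(d * d)
}

#' Position-resolved objective vector
#'
#' The per-position polarity costs (F1, F2, F3) of a code and their total
#' FT = F1 + F2 + F3 (exact by construction).
#'
#' @inheritParams polarityCost
#' @return Named numeric vector `c(F1, F2, F3, FT)`.
#' @examples
#' objectiveVector(standardCode())
#' @export
objectiveVector <- function(code, scale = woesePolarity()) {
  stopifnot(is(code, "GeneticCode"))
  p <- .scale_vec(scale)
  idx <- .idx_of_code(code)
  f <- vapply(1:3, function(k) .cost_one(idx, p, k), numeric(1))
  c(F1 = f[1], F2 = f[2], F3 = f[3], FT = f[1] + f[2] + f[3])
}
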