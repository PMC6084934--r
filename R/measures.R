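# Optimality and structure measures: global distance (GD), Euclidean
# distances to extreme-code sets (ED), the normalized-Hamming structure
# distance (SD), random-code baselines and the binary matrix exported for
# correspondence analysis.

#' Global distance of a reference cost between two extremes
#'
#' Places a reference objective value on the line between the best
#' (0 percent) and worst (100 percent) codes:
#' \deqn{GD = 100 (F^{ref} - F^{best}) / (F^{worst} - F^{best}).}
#' The value is deliberately unclamped: a reference better than the best
#' code yields a negative GD, one beyond the worst exceeds 100.
#'
#' @param fRef,fBest,fWorst Objective values; `fWorst` must differ from
#'   `fBest`.
#' @return Percentage (may be negative or exceed 100).
#' @examples
#' globalDistance(4, 5, 10)  # -20
#' @export
globalDistance <- function(fRef, fBest, fWorst) {
  if (fWorst == fBest)
    stop("degenerate range: fWorst equals fBest")
  100 * (fRef - fBest) / (fWorst - fBest)
}

#' Cross-position global distance
#'
#' GD of the standard code at a codon position j evaluated against codes
#' that were optimized for a different criterion: the numerator compares
#' the standard code's position-j cost with the minimum position-j cost
#' over the supplied optimized codes, while the denominator is the
#' best-worst range from optimizing position j itself.
#'
#' @param bestCodes List of \linkS4class{GeneticCode}s optimized under
#'   some other criterion.
#' @param position Codon position j (1, 2 or 3) or "sum".
#' @param fBest,fWorst Extremes of the position-j objective from its own
#'   optimization.
#' @param scale A \linkS4class{PolarityScale}.
#' @param reference Reference code (default the standard code).
#' @return Percentage; negative when every supplied code is worse than
#'   the reference at position j.
#' @export
crossPositionGD <- function(bestCodes, position, fBest, fWorst,
                            scale = woesePolarity(),
                            reference = standardCode()) {
  if (!length(bestCodes)) stop("empty best-code set")
  if (fWorst == fBest) stop("degenerate range: fWorst equals fBest")
  pos <- if (identical(position, "sum")) "all" else position
  fRef <- polarityCost(reference, scale, pos)
  fMin <- min(vapply(bestCodes, polarityCost, numeric(1),
                     scale = scale, position = pos))
  100 * (fRef - fMin) / (fWorst - fBest)
}

#' Shortest Euclidean distance from a point to a code set
#'
#' @param v Numeric length-3 vector (F1, F2, F3).
#' @param set Numeric matrix with 3 columns, one row per code.
#' @return The minimum Euclidean distance.
#' @examples
#' euclideanToSet(c(0, 0, 0), rbind(c(1, 2, 2)))  # 3
#' @export
euclideanToSet <- function(v, set) {
  set <- rbind(set)
  if (!nrow(set)) stop("empty code set")
  stopifnot(length(v) == 3L, ncol(set) == 3L)
  sqrt(min(colSums((t(set) - v)^2)))
}

#' Structure distance between two genetic codes
#'
#' The Hamming distance between the 1220-bit binary assignment vectors,
#' normalized by 122 (the maximum achievable: all 61 codons reassigned,
#' two bit flips each) and expressed as a percentage.  A scaled Hamming
#' distance, hence a metric: zero on identical codes, symmetric, and
#' satisfying the triangle inequality.
#'
#' @param a,b \linkS4class{GeneticCode}s.
#' @return List with `sd` (percentage in [0, 100]) and `hamming` (even
#'   integer in 0..122).
#' @examples
#' structureDistance(standardCode(),
#'                   swapAminoAcids(standardCode(), "M", "W"))$sd  # 3.28
#' @export
structureDistance <- function(a, b) {
  stopifnot(is(a, "GeneticCode"), is(b, "GeneticCode"))
  h <- 2L * sum(a@assignment != b@assignment)
  list(sd = 100 * h / 122, hamming = h)
}

#' Random-code baseline for the optimality measures
#'
#' Draws `n` random codes under a model, evaluates the criterion cost and
#' the position-resolved objective of each, and summarizes where random
#' codes sit relative to supplied best/worst extremes: the mean objective,
#' the mean GD with the reference replaced by each random code, and the
#' mean nearest Euclidean distances to the best and worst code sets, each
#' with a two-standard-deviation dispersion.
#'
#' @param model One of "DEG", "BLO", "NUM", "GEN".
#' @param criterion "pos1", "pos2", "pos3" or "sum".
#' @param n Number of random codes (>= 2).
#' @param fBest,fWorst Objective extremes for the GD denominator.
#' @param bestSet,worstSet Optional matrices (columns F1, F2, F3) of
#'   extreme-code objective vectors for the ED summaries.
#' @param scale A \linkS4class{PolarityScale}.
#' @return List with `n`, `meanF`, `dispF`, `gdRand`, `dispGD` and, when
#'   the sets are supplied, `meanEDbest`, `meanEDworst`, `dispEDbest`,
#'   `dispEDworst` (disp* are two standard deviations).
#' @export
randomBaseline <- function(model, criterion, n, fBest, fWorst,
                           bestSet = NULL, worstSet = NULL,
                           scale = woesePolarity()) {
  stopifnot(n >= 2L, model %in% .MODELS)
  if (fWorst == fBest) stop("degenerate range: fWorst equals fBest")
  p <- .scale_vec(scale)
  A <- t(vapply(seq_len(n), function(i) .random_raw(model), integer(61L)))
  pd <- .pair_idx(criterion)
  f <- eval_pop_cpp(A, p, pd$i, pd$j)
  gd <- 100 * (f - fBest) / (fWorst - fBest)
  out <- list(n = n, meanF = mean(f), dispF = 2 * stats::sd(f),
              gdRand = mean(gd), dispGD = 2 * stats::sd(gd))
  if (!is.null(bestSet) && !is.null(worstSet)) {
    Fm <- vapply(c("pos1", "pos2", "pos3"), function(cr) {
      pk <- .pair_idx(cr)
      eval_pop_cpp(A, p, pk$i, pk$j)
    }, numeric(n))
    edb <- vapply(seq_len(n), function(i)
      euclideanToSet(Fm[i, ], bestSet), numeric(1))
    edw <- vapply(seq_len(n), function(i)
      euclideanToSet(Fm[i, ], worstSet), numeric(1))
    out <- c(out, list(meanEDbest = mean(edb), meanEDworst = mean(edw),
                       dispEDbest = 2 * stats::sd(edb),
                       dispEDworst = 2 * stats::sd(edw)))
  }
  out
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks on ties, as used to relate
#' structure distances to objective-space distances.
#'
#' @param x,y Equal-length numeric vectors of length >= 3.
#' @return Coefficient in [-1, 1].
#' @examples
#' rankCorrelation(c(1, 2, 3), c(3, 1, 2))  # -0.5
#' @export
rankCorrelation <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least 3 observations")
  stats::cor(x, y, method = "spearman")
}

#' Binary assignment matrix for correspondence analysis
#'
#' Stacks the 1220-bit assignment vectors of a labeled set of codes into
#' a codes x 1220 binary matrix (row sums all 61), the input expected by
#' standard correspondence-analysis routines.  The ordination itself is
#' delegated to any multivariate toolkit.
#'
#' @param codes List of \linkS4class{GeneticCode}s (length >= 2).
#' @param labels Optional row labels (default code1, code2, ...).
#' @return Integer matrix with named rows and `"codon:aa"` columns.
#' @export
caMatrix <- function(codes, labels = NULL) {
  if (length(codes) < 2L) stop("need at least 2 codes")
  m <- t(vapply(codes, assignmentVector, integer(1220L)))
  rownames(m) <- if (is.null(labels))
    paste0("code", seq_along(codes)) else labels
  m
}

#' Write a correspondence-analysis matrix as CSV
#'
#' @param m Matrix from [caMatrix()].
#' @param path Output file.
#' @export
writeCaMatrix <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Percentage distance minimization (pdm)
#'
#' The older reference-based variant of [globalDistance()]: the position
#' of the reference cost between the random-code mean and the best code,
#' `100 * (fRand - fRef) / (fRand - fBest)`.
#'
#' @param fRef Reference (e.g. standard-code) objective value.
#' @param fRand Mean objective of randomized codes.
#' @param fBest Best optimized objective value.
#' @return Percentage.
#' @export
pdm <- function(fRef, fRand, fBest) {
  if (fRand == fBest) stop("degenerate range: fRand equals fBest")
  100 * (fRand - fRef) / (fRand - fBest)
}
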