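# Constructors, accessors and structural operations on GeneticCode objects.
# Internally a code is an integer vector of length 61 (amino-acid indices
# into the alphabetical 20-letter alphabet, in canonical sense-codon
# order); the S4 object stores the equivalent named character vector.

.code_from_idx <- function(idx) {
  a <- .AA20[idx]
  names(a) <- .SENSE
  new("GeneticCode", assignment = a)
}

.idx_of_code <- function(code) {
  match(code@assignment, .AA20)
}

#' Construct a genetic code from a codon table
#'
#' @param assignment Named character vector mapping codons to one-letter
#'   amino-acid codes.  Either the 61 sense codons, or all 64 codons with
#'   `"*"` at the three standard stop codons (TAA, TAG, TGA).
#' @return A validated \linkS4class{GeneticCode}.
#' @examples
#' sgc <- standardCode()
#' geneticCode(codonTable(sgc))
#' @export
geneticCode <- function(assignment) {
  if (is.null(names(assignment)))
    stop("assignment must be a named character vector")
  nm <- names(assignment)
  if (anyDuplicated(nm))
    stop("duplicate codon(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  bad <- setdiff(nm, .CODONS64)
  if (length(bad))
    stop("not a codon: ", paste(bad, collapse = ", "))
  stops <- nm[assignment == "*"]
  if (length(stops) && !setequal(stops, .STOPS))
    stop("stop set mismatch: stops must be exactly TAA, TAG, TGA")
  sense <- assignment[setdiff(nm, .STOPS)]
  missing <- setdiff(.SENSE, names(sense))
  if (length(missing))
    stop("missing codon(s): ", paste(missing, collapse = ", "))
  a <- sense[.SENSE]
  bad <- setdiff(unique(a), .AA20)
  if (length(bad))
    stop("unknown amino-acid symbol(s): ", paste(bad, collapse = ", "))
  obj <- new("GeneticCode", assignment = a)
  validObject(obj)
  obj
}

#' The standard genetic code
#'
#' Translation table 1 with the DNA alphabet; stops TAA, TAG, TGA.
#'
#' @return A \linkS4class{GeneticCode}.
#' @examples
#' degeneracyProfile(standardCode())
#' @export
standardCode <- function() {
  .code_from_idx(unname(.SGC_IDX))
}

#' @describeIn geneticCode The full 64-row codon table of a code, with
#'   `"*"` marking the three stop codons.
#' @param x A \linkS4class{GeneticCode}.
#' @export
codonTable <- function(x) {
  stopifnot(is(x, "GeneticCode"))
  tab <- setNames(rep("*", 64L), .CODONS64)
  tab[.SENSE] <- x@assignment
  tab
}

#' Sense codons, stop codons and the amino-acid alphabet
#'
#' Accessors for the fixed combinatorial frame shared by all codes: the 61
#' sense codons in canonical order, the fixed stop set and the 20-letter
#' amino-acid alphabet (alphabetical).
#' @return Character vectors.
#' @export
senseCodons <- function() .SENSE

#' @rdname senseCodons
#' @export
stopCodons <- function() .STOPS

#' @rdname senseCodons
#' @export
aminoAcids <- function() .AA20

#' Codons assigned to an amino acid
#'
#' @param x A \linkS4class{GeneticCode}.
#' @param aa One-letter amino-acid code.
#' @return Character vector of codons (possibly empty for an invalid
#'   object, never empty for a valid one).
#' @export
codonsOf <- function(x, aa) {
  stopifnot(is(x, "GeneticCode"), aa %in% .AA20)
  names(x@assignment)[x@assignment == aa]
}

setMethod("show", "GeneticCode", function(object) {
  counts <- table(factor(object@assignment, levels = .AA20))
  cat("GeneticCode: 61 sense codons -> 20 amino acids",
      "(stops TAA, TAG, TGA fixed)\n")
  cat("codons per amino acid:\n")
  print(counts)
  invisible(object)
})

#' Degeneracy profile of a genetic code
#'
#' Tabulates amino acids by the number of codons that encode them.  For
#' the standard code the profile is \code{c(`1` = 2, `2` = 9, `3` = 1,
#' `4` = 5, `6` = 3)}: two amino acids with a single codon, nine two-fold
#' degenerate, one three-fold, five four-fold and three six-fold.
#'
#' @param code A \linkS4class{GeneticCode}.
#' @return Named integer vector mapping codon count to the number of
#'   amino acids with that count; the weighted sum is always 61.
#' @examples
#' degeneracyProfile(standardCode())
#' @export
degeneracyProfile <- function(code) {
  stopifnot(is(code, "GeneticCode"))
  counts <- tabulate(.idx_of_code(code), nbins = 20L)
  tab <- table(counts)
  setNames(as.integer(tab), names(tab))
}

#' Binary assignment vector of a genetic code
#'
#' Encodes a code as 1220 binary indicators, one per (codon, amino acid)
#' pair over the 61 sense codons and 20 amino acids.  The order is frozen:
#' codon-major (canonical codon order) with the 20 amino acids alphabetical
#' within each codon, i.e. bit \eqn{(c-1)\cdot 20 + a} indicates that sense
#' codon \eqn{c} encodes amino acid \eqn{a}.  Exactly 61 bits are set.
#'
#' @param code A \linkS4class{GeneticCode}.
#' @return Integer vector of 0/1 of length 1220, named `"codon:aa"`.
#' @seealso [codeFromAssignmentVector()], [structureDistance()], [caMatrix()]
#' @export
assignmentVector <- function(code) {
  stopifnot(is(code, "GeneticCode"))
  idx <- .idx_of_code(code)
  bits <- integer(1220L)
  bits[(seq_len(61L) - 1L) * 20L + idx] <- 1L
  names(bits) <- paste(rep(.SENSE, each = 20L), rep(.AA20, times = 61L),
                       sep = ":")
  bits
}

#' Rebuild a genetic code from its binary assignment vector
#'
#' Inverse of [assignmentVector()]; rejects vectors that do not encode a
#' total, surjective assignment.
#'
#' @param bits Integer/numeric 0/1 vector of length 1220 in the frozen
#'   codon-major order.
#' @return A \linkS4class{GeneticCode}.
#' @export
codeFromAssignmentVector <- function(bits) {
  if (length(bits) != 1220L)
    stop("assignment vector must have length 1220")
  m <- matrix(as.integer(bits), nrow = 20L)
  if (!all(colSums(m) == 1L))
    stop("each codon must have exactly one amino-acid indicator set")
  idx <- max.col(t(m))
  obj <- .code_from_idx(idx)
  validObject(obj)
  obj
}

#' Exchange the codon sets of two amino acids
#'
#' All codons of \code{a1} are reassigned to \code{a2} and vice versa;
#' nothing else changes.  The operation is an involution and preserves the
#' degeneracy profile when the two amino acids have equal codon counts.
#'
#' @param code A \linkS4class{GeneticCode}.
#' @param a1,a2 Distinct one-letter amino-acid codes, both encoded.
#' @return A \linkS4class{GeneticCode}.
#' @examples
#' swapAminoAcids(standardCode(), "M", "W")  # Met at TGG, Trp at ATG
#' @export
swapAminoAcids <- function(code, a1, a2) {
  stopifnot(is(code, "GeneticCode"))
  if (!a1 %in% .AA20 || !a2 %in% .AA20)
    stop("unknown amino-acid symbol")
  if (identical(a1, a2))
    stop("cannot swap an amino acid with itself")
  a <- code@assignment
  i1 <- a == a1
  i2 <- a == a2
  a[i1] <- a2
  a[i2] <- a1
  new("GeneticCode", assignment = a)
}

#' Check a genetic code against a code-model constraint set
#'
#' Reports whether a code satisfies the structural constraints of one of
#' the four code models, relative to the standard code: \describe{
#'   \item{DEG}{the synonymous-block partition equals the standard one and
#'     every amino acid keeps its standard codon count (amino acids may
#'     only have moved within a degeneracy class);}
#'   \item{BLO}{the synonymous-block partition equals the standard one;}
#'   \item{NUM}{every amino acid has its standard codon count;}
#'   \item{GEN}{surjectivity only (any valid \code{GeneticCode} passes).}
#' }
#'
#' @param code A \linkS4class{GeneticCode}.
#' @param model One of "DEG", "BLO", "NUM", "GEN".
#' @return A list with elements \code{valid} (logical) and
#'   \code{violations} (character vector of diagnostics, empty if valid).
#' @export
validateCode <- function(code, model = c("DEG", "BLO", "NUM", "GEN")) {
  model <- match.arg(model)
  stopifnot(is(code, "GeneticCode"))
  idx <- .idx_of_code(code)
  viol <- character(0)
  missing <- setdiff(.AA20, .AA20[idx])
  if (length(missing))
    viol <- c(viol, paste0("missing amino acid: ",
                           paste(missing, collapse = ", ")))
  if (model %in% c("DEG", "BLO")) {
    # same partition: codons in one SGC block must share one amino acid,
    # and distinct blocks must carry distinct amino acids
    blockAA <- split(idx, .BLOCK_OF)
    broken <- names(blockAA)[vapply(blockAA, function(v)
      length(unique(v)) != 1L, logical(1))]
    if (length(broken)) {
      viol <- c(viol, paste0("codon block of ",
                             paste(.AA20[as.integer(broken)], collapse = ", "),
                             " split between amino acids"))
    } else {
      rep20 <- vapply(blockAA, `[`, integer(1), 1L)
      if (anyDuplicated(rep20))
        viol <- c(viol, "two standard blocks carry the same amino acid")
    }
  }
  if (model %in% c("DEG", "NUM")) {
    counts <- tabulate(idx, nbins = 20L)
    off <- which(counts != .SGC_COUNTS)
    if (length(off))
      viol <- c(viol, paste0("codon count changed for ",
                             paste(.AA20[off], collapse = ", ")))
  }
  list(valid = length(viol) == 0L, violations = viol)
}
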