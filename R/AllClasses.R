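#' @import methods
NULL

#' GeneticCode class
#'
#' An assignment of the 61 sense codons to the 20 canonical amino acids.
#' The three stop codons (TAA, TAG, TGA) are fixed and implicit: every
#' \code{GeneticCode} keeps the standard stop set.  Validity requires a
#' total assignment over the canonical sense codons, one-letter amino-acid
#' symbols only, and surjectivity (every amino acid encoded by at least one
#' codon).
#'
#' @slot assignment Named character vector of length 61; names are the
#'   sense codons in canonical order (T < C < A < G per position, third
#'   base fastest), values are one-letter amino-acid codes.
#'
#' @seealso [geneticCode()], [standardCode()], [validateCode()]
#' @export
setClass("GeneticCode", representation(assignment = "character"))

setValidity("GeneticCode", function(object) {
  a <- object@assignment
  if (length(a) != 61L)
    return(sprintf("assignment must cover the 61 sense codons (got %d)",
                   length(a)))
  if (!identical(names(a), .SENSE))
    return("assignment names must be the sense codons in canonical order")
  bad <- setdiff(unique(a), .AA20)
  if (length(bad))
    return(paste0("unknown amino-acid symbol(s): ",
                  paste(bad, collapse = ", ")))
  missing <- setdiff(.AA20, a)
  if (length(missing))
    return(paste0("missing amino acid(s): ",
                  paste(missing, collapse = ", ")))
  TRUE
})

#' PolarityScale class
#'
#' A value of an amino-acid property scale for each of the 20 canonical
#' amino acids, used as the p(.) of the squared-difference cost function.
#' The bundled default is the Woese polar requirement.
#'
#' @slot values Named numeric vector of length 20 (names are one-letter
#'   amino-acid codes, alphabetical); all values finite and positive.
#'
#' @seealso [polarityScale()], [woesePolarity()]
#' @export
setClass("PolarityScale", representation(values = "numeric"))

setValidity("PolarityScale", function(object) {
  v <- object@values
  if (!identical(names(v), .AA20))
    return("values must be named by the 20 amino acids in alphabetical order")
  if (any(!is.finite(v)) || any(v <= 0))
    return("all polarity values must be finite and positive")
  TRUE
})

#' EAConfig class
#'
#' Run configuration for the archive-based evolutionary algorithm.
#' Defaults depend on the code model: DEG/BLO use a parent population of
#' 1000 with mutation probability 0.9 and crossover probability 0.3;
#' NUM/GEN use 2800 parents with probabilities 0.8 and 0.4.  The archive
#' holds the 700 best solutions in all cases.
#'
#' @slot model One of "DEG", "BLO", "NUM", "GEN".
#' @slot criterion One of "pos1", "pos2", "pos3", "sum".
#' @slot direction "min" or "max".
#' @slot generations Number of generations (default 1000).
#' @slot runs Number of independent repeats (default 20).
#' @slot popSize Parent population size.
#' @slot archiveSize Elitist archive size (default 700).
#' @slot pMut Per-individual mutation probability.
#' @slot pCx Per-pair crossover probability.
#' @slot seed Master seed; run r uses seed + r - 1.
#' @slot classes For DEG only: optional custom partition of the amino
#'   acids into exchange classes, as a list of integer vectors indexing
#'   the alphabetical amino-acid order.  \code{NULL} means the degeneracy
#'   classes of the standard code.
#'
#' @seealso [eaConfig()], [runEA()]
#' @export
setClass("EAConfig", representation(
  model = "character", criterion = "character", direction = "character",
  generations = "integer", runs = "integer", popSize = "integer",
  archiveSize = "integer", pMut = "numeric", pCx = "numeric",
  seed = "integer", classes = "ANY"))

setValidity("EAConfig", function(object) {
  if (!object@model %in% c("DEG", "BLO", "NUM", "GEN"))
    return("model must be one of DEG, BLO, NUM, GEN")
  if (!object@criterion %in% c("pos1", "pos2", "pos3", "sum"))
    return("criterion must be one of pos1, pos2, pos3, sum")
  if (!object@direction %in% c("min", "max"))
    return("direction must be 'min' or 'max'")
  if (object@generations < 1L) return("generations must be >= 1")
  if (object@runs < 1L) return("runs must be >= 1")
  if (object@popSize < 2L) return("popSize must be >= 2")
  if (object@archiveSize < 1L) return("archiveSize must be >= 1")
  if (object@pMut < 0 || object@pMut > 1 || object@pCx < 0 || object@pCx > 1)
    return("pMut and pCx must lie in [0, 1]")
  if (!is.null(object@classes)) {
    if (object@model != "DEG")
      return("custom exchange classes are only meaningful for the DEG model")
    cls <- unlist(object@classes)
    if (!setequal(cls, seq_len(20L)) || length(cls) != 20L)
      return("classes must partition the 20 amino acids")
  }
  TRUE
})

#' EARun class
#'
#' The outcome of one evolutionary-algorithm run: the best code found, the
#' per-generation best-objective trajectory, and the final archive.
#'
#' @slot bestCode The best \linkS4class{GeneticCode} in the final archive.
#' @slot bestValue Its objective value.
#' @slot trajectory Numeric vector, one best value per generation;
#'   non-increasing under minimization, non-decreasing under maximization.
#' @slot archive Integer matrix (archive size x 61) of amino-acid indices,
#'   rows in objective order; use [archiveCode()] to materialize a row.
#' @slot archiveValues Objective values of the archive rows.
#' @slot plateau Number of final generations without improvement.
#' @slot seed The run seed.
#' @slot config The \linkS4class{EAConfig} the run was launched with.
#'
#' @export
setClass("EARun", representation(
  bestCode = "GeneticCode", bestValue = "numeric", trajectory = "numeric",
  archive = "matrix", archiveValues = "numeric", plateau = "integer",
  seed = "integer", config = "EAConfig"))
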