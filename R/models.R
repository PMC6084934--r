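# The four code models: constrained random generation and the mutation /
# crossover operators, exposed per code and used in population form by the
# EA.  DEG and BLO codes live on the 20 standard synonymous blocks and are
# represented internally as block permutations; NUM and GEN codes are
# represented as one amino-acid index per sense codon.

.MODELS <- c("DEG", "BLO", "NUM", "GEN")

.default_classes <- function(model, classes = NULL) {
  # exchange classes over amino-acid indices; NULL for codon models
  if (model == "DEG") {
    if (is.null(classes)) unname(.DEG_CLASSES) else classes
  } else if (model == "BLO") list(seq_len(20L)) else NULL
}

# class id per amino acid (and, identically, per standard block)
.class_id <- function(classes) {
  id <- integer(20L)
  for (k in seq_along(classes)) id[classes[[k]]] <- k
  id
}

# ---- raw generators ------------------------------------------------------

.random_perm <- function(classes) {
  perm <- seq_len(20L)
  for (cl in classes) perm[cl] <- cl[sample.int(length(cl))]
  perm
}

.perm_to_idx <- function(perm) perm[.BLOCK_OF]

.random_raw <- function(model, classes = NULL) {
  switch(model,
    DEG = .perm_to_idx(.random_perm(.default_classes("DEG", classes))),
    BLO = .perm_to_idx(sample.int(20L)),
    NUM = {
      idx <- integer(61L)
      idx[sample.int(61L)] <- rep.int(seq_len(20L), .SGC_COUNTS)
      idx
    },
    GEN = {
      repeat {
        idx <- sample.int(20L, 61L, replace = TRUE)
        if (length(unique(idx)) == 20L) return(idx)
      }
    }
  )
}

# block permutation of a DEG/BLO-valid code (errors otherwise)
.perm_of_code <- function(code, model) {
  rep <- validateCode(code, model)
  if (!rep$valid)
    stop("code is not valid under the ", model, " model: ",
         paste(rep$violations, collapse = "; "))
  idx <- .idx_of_code(code)
  vapply(split(idx, .BLOCK_OF), `[`, integer(1), 1L)
}

# ---- exported operators --------------------------------------------------

#' Draw a random genetic code under a code model
#'
#' DEG: a uniform permutation of the amino acids within each degeneracy
#' class, applied to the standard synonymous blocks.  BLO: a uniform
#' permutation of all 20 amino acids over the 20 blocks.  NUM: a uniform
#' random partition of the 61 codons into classes of the standard
#' per-amino-acid sizes.  GEN: each codon drawn uniformly from the 20
#' amino acids, resampled until all 20 are present.
#'
#' Randomness comes from R's global RNG; call `set.seed()` for
#' reproducibility.
#'
#' @param model One of "DEG", "BLO", "NUM", "GEN".
#' @return A \linkS4class{GeneticCode}, valid under `model`.
#' @examples
#' set.seed(1)
#' validateCode(randomCode("NUM"), "NUM")$valid
#' @export
randomCode <- function(model = c("DEG", "BLO", "NUM", "GEN")) {
  model <- match.arg(model)
  .code_from_idx(.random_raw(model))
}

#' Mutate a genetic code under a code model
#'
#' DEG and BLO exchange the whole codon blocks of two distinct amino acids
#' (DEG: drawn from the same degeneracy class, uniformly over admissible
#' pairs).  NUM and GEN pick two distinct amino acids, one codon of each
#' uniformly, and exchange those two codon assignments.  Exactly one
#' exchange is applied; the result is valid under the same model.
#'
#' @param code A \linkS4class{GeneticCode}, valid under `model`.
#' @param model One of "DEG", "BLO", "NUM", "GEN".
#' @return A \linkS4class{GeneticCode}.
#' @export
mutateCode <- function(code, model = c("DEG", "BLO", "NUM", "GEN")) {
  model <- match.arg(model)
  stopifnot(is(code, "GeneticCode"))
  if (model %in% c("DEG", "BLO")) {
    perm <- .perm_of_code(code, model)
    classes <- .default_classes(model)
    pairs <- .class_pairs(classes)
    k <- sample.int(nrow(pairs), 1L)
    .code_from_idx(.perm_to_idx(.swap_perm(perm, pairs[k, 1L], pairs[k, 2L])))
  } else {
    rep <- validateCode(code, model)
    if (!rep$valid)
      stop("code is not valid under the ", model, " model: ",
           paste(rep$violations, collapse = "; "))
    .code_from_idx(mutate_codon_one_cpp(.idx_of_code(code), 20L))
  }
}

# all unordered amino-acid pairs within one exchange class
.class_pairs <- function(classes) {
  out <- matrix(integer(0), ncol = 2L)
  for (cl in classes) {
    if (length(cl) >= 2L)
      out <- rbind(out, t(utils::combn(cl, 2L)))
  }
  out
}

# swap the blocks of amino acids a and b in a permutation
.swap_perm <- function(perm, a, b) {
  pa <- which(perm == a); pb <- which(perm == b)
  perm[pa] <- b; perm[pb] <- a
  perm
}

#' Recombine two genetic codes under a code model
#'
#' DEG and BLO use a position-based crossover on the block permutations:
#' each amino acid is independently retained (probability 0.5) on its
#' own-parent block; the remaining blocks are filled with the unused amino
#' acids of the other parent in that parent's block order, restricted to
#' blocks of the same degeneracy class under DEG.  NUM and GEN use a
#' codon-reassignment crossover: codons of a randomly chosen amino acid
#' that are private to one parent are exchanged between the offspring, and
#' surplus private codons are moved (GEN) or swapped (NUM, preserving the
#' standard codon counts); an amino acid is never stripped of its last
#' codon, so offspring always keep all 20 amino acids.
#'
#' @param p1,p2 Parent \linkS4class{GeneticCode}s, valid under `model`.
#' @param model One of "DEG", "BLO", "NUM", "GEN".
#' @return List of two offspring \linkS4class{GeneticCode}s.
#' @export
crossoverCodes <- function(p1, p2, model = c("DEG", "BLO", "NUM", "GEN")) {
  model <- match.arg(model)
  stopifnot(is(p1, "GeneticCode"), is(p2, "GeneticCode"))
  if (model %in% c("DEG", "BLO")) {
    q1 <- .perm_of_code(p1, model)
    q2 <- .perm_of_code(p2, model)
    id <- .class_id(.default_classes(model))
    off <- pos_crossover_pair_cpp(q1, q2, id)
    lapply(off, function(o) .code_from_idx(.perm_to_idx(o)))
  } else {
    for (p in list(p1, p2)) {
      rep <- validateCode(p, model)
      if (!rep$valid)
        stop("parent is not valid under the ", model, " model: ",
             paste(rep$violations, collapse = "; "))
    }
    off <- crossover_codon_pair_cpp(.idx_of_code(p1), .idx_of_code(p2),
                                    20L, model == "NUM")
    lapply(off, .code_from_idx)
  }
}
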