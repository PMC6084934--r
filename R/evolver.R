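# The archive-based elitist evolutionary algorithm.  Each generation the
# parents and the archive are pooled, the archive is refilled with the
# best solutions (plain objective truncation, duplicates allowed), a
# mating pool of parent-population size is drawn from the archive by
# binary tournament, and crossover and mutation produce the next parents.

#' Build an EA run configuration
#'
#' Fills in the model-dependent defaults: parent population 1000, mutation
#' probability 0.9 and crossover probability 0.3 for DEG/BLO; parent
#' population 2800, mutation 0.8 and crossover 0.4 for NUM/GEN; archive
#' size 700, 1000 generations and 20 repeats everywhere.
#'
#' @param model One of "DEG", "BLO", "NUM", "GEN".
#' @param criterion Objective: "pos1", "pos2", "pos3" or "sum".
#' @param direction "min" or "max".
#' @param generations,runs,popSize,archiveSize,pMut,pCx,seed See
#'   \linkS4class{EAConfig}; `NULL` selects the model default.
#' @param classes Optional custom DEG exchange classes (list of integer
#'   vectors partitioning 1:20 in alphabetical amino-acid order); used to
#'   restrict the search to a subspace.
#' @return An \linkS4class{EAConfig}.
#' @examples
#' eaConfig("DEG", criterion = "pos3", runs = 2, generations = 50)
#' @export
eaConfig <- function(model = c("DEG", "BLO", "NUM", "GEN"),
                     criterion = "sum", direction = "min",
                     generations = 1000L, runs = 20L, popSize = NULL,
                     archiveSize = 700L, pMut = NULL, pCx = NULL,
                     seed = 1L, classes = NULL) {
  model <- match.arg(model)
  simple <- model %in% c("DEG", "BLO")
  if (is.null(popSize)) popSize <- if (simple) 1000L else 2800L
  if (is.null(pMut)) pMut <- if (simple) 0.9 else 0.8
  if (is.null(pCx)) pCx <- if (simple) 0.3 else 0.4
  cfg <- new("EAConfig", model = model, criterion = criterion,
             direction = direction, generations = as.integer(generations),
             runs = as.integer(runs), popSize = as.integer(popSize),
             archiveSize = as.integer(archiveSize), pMut = pMut, pCx = pCx,
             seed = as.integer(seed), classes = classes)
  validObject(cfg)
  cfg
}

setMethod("show", "EAConfig", function(object) {
  cat(sprintf(
    "EAConfig: %s / %s / %s | gens %d, runs %d, pop %d, archive %d,\n",
    object@model, object@criterion, object@direction, object@generations,
    object@runs, object@popSize, object@archiveSize))
  cat(sprintf("  pMut %.2f, pCx %.2f, seed %d\n",
              object@pMut, object@pCx, object@seed))
  invisible(object)
})

#' Binary tournament selection
#'
#' Each mating-pool slot is filled with the objective-better of two
#' archive members drawn uniformly with replacement; exact ties are broken
#' by a fair coin.
#'
#' @param values Objective values of the archive.
#' @param n Pool size.
#' @param direction "min" or "max".
#' @return Integer vector of `n` selected indices into `values`.
#' @export
binaryTournament <- function(values, n, direction = "min") {
  m <- length(values)
  if (m < 1L) stop("empty archive")
  stopifnot(direction %in% c("min", "max"))
  i1 <- sample.int(m, n, replace = TRUE)
  i2 <- sample.int(m, n, replace = TRUE)
  v1 <- values[i1]; v2 <- values[i2]
  first <- if (direction == "min") v1 < v2 else v1 > v2
  tie <- v1 == v2
  if (any(tie)) first[tie] <- stats::runif(sum(tie)) < 0.5
  ifelse(first, i1, i2)
}

# one EA run; returns an EARun
.ea_run_one <- function(config, runSeed) {
  set.seed(runSeed)
  model <- config@model
  simple <- model %in% c("DEG", "BLO")
  classes <- .default_classes(model, config@classes)
  classId <- if (simple) .class_id(classes) else NULL
  pairTab <- if (simple) .class_pairs(classes) else NULL
  pvec <- .ea_scale(config)
  pd <- .pair_idx(config@criterion)
  sgn <- if (config@direction == "min") 1 else -1
  pop <- config@popSize
  asize <- config@archiveSize
  gens <- config@generations

  evalP <- function(P) {
    A <- if (simple) P[, .BLOCK_OF, drop = FALSE] else P
    eval_pop_cpp(A, pvec, pd$i, pd$j)
  }

  P <- if (simple) {
    t(vapply(seq_len(pop), function(i) .random_perm(classes),
             integer(20L)))
  } else {
    t(vapply(seq_len(pop), function(i) .random_raw(model),
             integer(61L)))
  }

  A <- NULL; vA <- numeric(0)
  traj <- numeric(gens)
  for (g in seq_len(gens)) {
    vP <- evalP(P)
    U <- rbind(P, A)
    vU <- c(vP, vA)
    # truncation selection with seeded-uniform tie-breaking
    o <- order(sgn * vU, sample.int(length(vU)))
    keep <- o[seq_len(min(asize, length(vU)))]
    A <- U[keep, , drop = FALSE]
    vA <- vU[keep]
    traj[g] <- vA[1L]
    if (g == gens) break
    pool <- A[binaryTournament(vA, pop, config@direction), , drop = FALSE]
    # crossover on consecutive pool pairs
    npair <- pop %/% 2L
    sel <- which(stats::runif(npair) < config@pCx)
    if (length(sel)) {
      r1 <- 2L * sel - 1L
      r2 <- 2L * sel
      pool <- if (simple) pos_crossover_pop_cpp(pool, r1, r2, classId)
              else crossover_codon_pop_cpp(pool, r1, r2, 20L,
                                           model == "NUM")
    }
    # mutation: one exchange per selected individual
    mut <- stats::runif(pop) < config@pMut
    if (any(mut)) {
      if (simple) {
        rows <- which(mut)
        k <- sample.int(nrow(pairTab), length(rows), replace = TRUE)
        a <- pairTab[k, 1L]; b <- pairTab[k, 2L]
        sub <- pool[rows, , drop = FALSE]
        nr <- length(rows)
        pa <- max.col(sub == matrix(a, nr, 20L), ties.method = "first")
        pb <- max.col(sub == matrix(b, nr, 20L), ties.method = "first")
        sub[cbind(seq_len(nr), pa)] <- b
        sub[cbind(seq_len(nr), pb)] <- a
        pool[rows, ] <- sub
      } else {
        pool <- mutate_codon_pop_cpp(pool, mut, 20L)
      }
    }
    P <- pool
  }
  bestIdx <- if (simple) .perm_to_idx(A[1L, ]) else A[1L, ]
  arch <- if (simple) A[, .BLOCK_OF, drop = FALSE] else A
  improved <- which(diff(traj) != 0)
  plateau <- if (length(improved)) gens - (max(improved) + 1L) else gens - 1L
  new("EARun",
      bestCode = .code_from_idx(bestIdx), bestValue = vA[1L],
      trajectory = traj, archive = arch, archiveValues = vA,
      plateau = as.integer(plateau), seed = as.integer(runSeed),
      config = config)
}

# polarity vector used by a run; configs carry no scale slot, so the
# bundled Woese polar requirement applies unless .ea_run is called with an
# explicit scale via runEA()
.ea_scale <- function(config) {
  sc <- attr(config, "scale")
  if (is.null(sc)) unname(.POLARITY_WOESE) else .scale_vec(sc)
}

#' Run the evolutionary algorithm
#'
#' Executes `config@runs` independent runs (run r seeded with
#' `config@seed + r - 1`) of the archive-based elitist EA and returns one
#' \linkS4class{EARun} per run.  The archive's best objective never
#' worsens between generations, so each trajectory is monotone.
#'
#' @param config An \linkS4class{EAConfig}.
#' @param scale A \linkS4class{PolarityScale} (default the bundled Woese
#'   polar requirement).
#' @return List of \linkS4class{EARun} objects.
#' @examples
#' cfg <- eaConfig("DEG", criterion = "pos3", runs = 1,
#'                 generations = 20, popSize = 50, archiveSize = 30)
#' res <- runEA(cfg)
#' res[[1]]@bestValue <= polarityCost(standardCode(), position = 3)
#' @export
runEA <- function(config, scale = woesePolarity()) {
  validObject(config)
  attr(config, "scale") <- scale
  lapply(seq_len(config@runs), function(r)
    .ea_run_one(config, config@seed + r - 1L))
}

setMethod("show", "EARun", function(object) {
  cat(sprintf("EARun (%s / %s / %s, seed %d): best %.6g after %d generations",
              object@config@model, object@config@criterion,
              object@config@direction, object@seed, object@bestValue,
              length(object@trajectory)),
      sprintf("(plateau %d)\n", object@plateau))
  invisible(object)
})

#' Materialize an archive member of a run
#'
#' @param run An \linkS4class{EARun}.
#' @param i Row of the archive (1 = best).
#' @return A \linkS4class{GeneticCode}.
#' @export
archiveCode <- function(run, i = 1L) {
  stopifnot(is(run, "EARun"), i >= 1L, i <= nrow(run@archive))
  .code_from_idx(run@archive[i, ])
}

#' Extremal code and value across runs
#'
#' @param results List of \linkS4class{EARun} objects from [runEA()].
#' @param direction "min" or "max".
#' @return List with elements `value` (the extremum over runs) and
#'   `codes` (all distinct codes attaining it, pooled over runs).
#' @export
bestOverRuns <- function(results, direction = "min") {
  if (!length(results)) stop("no runs supplied")
  stopifnot(direction %in% c("min", "max"))
  vals <- vapply(results, function(r) r@bestValue, numeric(1))
  ext <- if (direction == "min") min(vals) else max(vals)
  codes <- list()
  seen <- character(0)
  for (r in results[vals == ext]) {
    hit <- which(r@archiveValues == ext)
    for (i in hit) {
      key <- paste(r@archive[i, ], collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        codes[[length(codes) + 1L]] <- .code_from_idx(r@archive[i, ])
      }
    }
  }
  list(value = ext, codes = codes)
}

#' Pooled extreme-code set of a batch of runs
#'
#' Collects, over all runs, the distinct archive members whose objective
#' equals their run's best value, together with their position-resolved
#' objective vectors.  This is the "layer of extreme points" used by the
#' Euclidean-distance measures.
#'
#' @param results List of \linkS4class{EARun} objects.
#' @param scale A \linkS4class{PolarityScale}.
#' @return List with `codes` (list of \linkS4class{GeneticCode}) and
#'   `F` (matrix with columns F1, F2, F3, one row per code).
#' @export
extremeSet <- function(results, scale = woesePolarity()) {
  if (!length(results)) stop("no runs supplied")
  p <- .scale_vec(scale)
  codes <- list(); seen <- character(0)
  for (r in results) {
    hit <- which(r@archiveValues == r@bestValue)
    for (i in hit) {
      key <- paste(r@archive[i, ], collapse = ",")
      if (!key %in% seen) {
        seen <- c(seen, key)
        codes[[length(codes) + 1L]] <- r@archive[i, ]
      }
    }
  }
  Fm <- t(vapply(codes, function(idx)
    vapply(1:3, function(k) .cost_one(idx, p, k), numeric(1)),
    numeric(3)))
  colnames(Fm) <- c("F1", "F2", "F3")
  list(codes = lapply(codes, .code_from_idx), F = Fm)
}
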