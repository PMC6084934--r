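# Plain-text interchange: codon tables (TSV and JSON), polarity scales,
# fixture generation and the end-to-end experiment driver.

#' Read a genetic code from a table file
#'
#' TSV files carry a header `codon<TAB>aa` and 64 rows, with `*` marking
#' the three standard stop codons; JSON files (extension `.json`) carry a
#' single object mapping codons to amino-acid letters (or `*`).  Tables
#' violating the code invariants are rejected with a specific error:
#' missing codons, duplicate codons, a stop set other than TAA/TAG/TGA,
#' or unknown amino-acid symbols.
#'
#' @param path File to read.
#' @return A \linkS4class{GeneticCode}.
#' @seealso [writeCodeTable()], [geneticCode()]
#' @export
readCodeTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    assignment <- unlist(obj)
  } else {
    tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                             colClasses = "character")
    if (!all(c("codon", "aa") %in% names(tab)))
      stop("code table must have columns 'codon' and 'aa'")
    assignment <- stats::setNames(tab$aa, tab$codon)
  }
  geneticCode(assignment)
}

#' Write a genetic code as a 64-row TSV (or JSON) table
#'
#' @param code A \linkS4class{GeneticCode}.
#' @param path Output file; a `.json` extension selects JSON.
#' @export
writeCodeTable <- function(code, path) {
  stopifnot(is(code, "GeneticCode"))
  tab <- codonTable(code)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.list(tab), path, auto_unbox = TRUE)
  } else {
    utils::write.table(
      data.frame(codon = names(tab), aa = unname(tab)),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a polarity scale from a 20-row TSV (`aa<TAB>value`)
#'
#' @param path File with header `aa<TAB>value`.
#' @return A \linkS4class{PolarityScale}.
#' @export
readPolarityScale <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t")
  if (!all(c("aa", "value") %in% names(tab)))
    stop("polarity table must have columns 'aa' and 'value'")
  polarityScale(stats::setNames(tab$value, tab$aa))
}

#' @rdname readPolarityScale
#' @param scale A \linkS4class{PolarityScale}.
#' @export
writePolarityScale <- function(scale, path) {
  v <- scaleValues(scale)
  utils::write.table(data.frame(aa = names(v), value = unname(v)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Generate seeded random-code fixtures
#'
#' Writes `n` validated random code tables for a model plus a JSON
#' manifest recording the model and the seed of each table (seed + i - 1
#' for table i), so the fixture set is reproducible file-for-file.
#'
#' @param model One of "DEG", "BLO", "NUM", "GEN".
#' @param n Number of codes (>= 1).
#' @param seed Base seed.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
makeFixtures <- function(model, n, seed, dir) {
  stopifnot(n >= 1L, model %in% .MODELS)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(n)
  for (i in seq_len(n)) {
    set.seed(seed + i - 1L)
    code <- randomCode(model)
    files[i] <- file.path(dir, sprintf("code_%s_%03d.tsv", model, i))
    writeCodeTable(code, files[i])
  }
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(
    list(model = model, n = n, baseSeed = seed,
         files = basename(files), seeds = seed + seq_len(n) - 1L),
    manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Evaluate a code and serialize the objective record
#'
#' @param code A \linkS4class{GeneticCode}.
#' @param scale A \linkS4class{PolarityScale}.
#' @param id Identifier stored in the record.
#' @param scaleId Identifier of the scale.
#' @return List `(id, F1, F2, F3, FT, scale)` ready for JSON export.
#' @export
evaluateCode <- function(code, scale = woesePolarity(), id = "code",
                         scaleId = "woese") {
  f <- objectiveVector(code, scale)
  list(id = id, F1 = unname(f["F1"]), F2 = unname(f["F2"]),
       F3 = unname(f["F3"]), FT = unname(f["FT"]), scale = scaleId)
}

#' Run a full optimization experiment
#'
#' Runs the EA in both directions for one model and criterion, pools the
#' extreme-code sets, and derives the optimality report: the GD of the
#' reference code, its Euclidean distances to the best and worst sets,
#' and the structure distances between the reference and each
#' best-of-runs code.  When `outDir` is given, per-run best-code tables,
#' trajectory CSVs, the report JSON and the full configuration (with all
#' derived seeds) are written there; every reported number is
#' recomputable from those files.  Minimization runs use seeds
#' `seed ... seed+runs-1`, maximization runs `seed+runs ... seed+2*runs-1`.
#'
#' @param model,criterion,generations,runs,popSize,archiveSize,pMut,pCx
#'   Passed to [eaConfig()] (NULL selects model defaults).
#' @param seed Master seed.
#' @param scale A \linkS4class{PolarityScale}.
#' @param reference Reference code for the measures (default standard).
#' @param outDir Optional output directory.
#' @return List with `minRuns`, `maxRuns`, `fBest`, `fWorst`, `fRef`,
#'   `gd`, `edBest`, `edWorst`, `bestSet`, `worstSet`, `sdBest`
#'   (structure distances reference vs best codes) and `config`.
#' @export
runExperiment <- function(model, criterion = "sum", generations = 1000L,
                          runs = 20L, popSize = NULL, archiveSize = 700L,
                          pMut = NULL, pCx = NULL, seed = 1L,
                          scale = woesePolarity(),
                          reference = standardCode(), outDir = NULL) {
  cfgMin <- eaConfig(model, criterion, "min", generations, runs, popSize,
                     archiveSize, pMut, pCx, seed)
  cfgMax <- eaConfig(model, criterion, "max", generations, runs, popSize,
                     archiveSize, pMut, pCx, seed + runs)
  minRuns <- runEA(cfgMin, scale)
  maxRuns <- runEA(cfgMax, scale)
  fBest <- bestOverRuns(minRuns, "min")$value
  fWorst <- bestOverRuns(maxRuns, "max")$value
  pos <- if (identical(criterion, "sum")) "all"
         else match(criterion, c("pos1", "pos2", "pos3"))
  fRef <- polarityCost(reference, scale, pos)
  gd <- globalDistance(fRef, fBest, fWorst)
  bestSet <- extremeSet(minRuns, scale)
  worstSet <- extremeSet(maxRuns, scale)
  vRef <- objectiveVector(reference, scale)[1:3]
  edBest <- euclideanToSet(vRef, bestSet$F)
  edWorst <- euclideanToSet(vRef, worstSet$F)
  sdBest <- vapply(bestSet$codes, function(cc)
    structureDistance(reference, cc)$sd, numeric(1))
  out <- list(minRuns = minRuns, maxRuns = maxRuns, fBest = fBest,
              fWorst = fWorst, fRef = fRef, gd = gd, edBest = edBest,
              edWorst = edWorst, bestSet = bestSet, worstSet = worstSet,
              sdBest = sdBest,
              config = list(model = model, criterion = criterion,
                            generations = cfgMin@generations,
                            runs = cfgMin@runs, popSize = cfgMin@popSize,
                            archiveSize = cfgMin@archiveSize,
                            pMut = cfgMin@pMut, pCx = cfgMin@pCx,
                            seed = seed,
                            seedsMin = seed + seq_len(runs) - 1L,
                            seedsMax = seed + runs + seq_len(runs) - 1L))
  if (!is.null(outDir)) .write_bundle(out, outDir)
  out
}

.write_bundle <- function(res, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("min", "max")) {
    runs <- if (d == "min") res$minRuns else res$maxRuns
    for (i in seq_along(runs)) {
      writeCodeTable(runs[[i]]@bestCode,
                     file.path(outDir, sprintf("best_%s_run%02d.tsv", d, i)))
    }
    traj <- vapply(runs, function(r) r@trajectory,
                   numeric(length(runs[[1]]@trajectory)))
    utils::write.csv(
      data.frame(generation = seq_len(nrow(traj)), traj),
      file.path(outDir, sprintf("trajectory_%s.csv", d)), row.names = FALSE)
  }
  report <- list(fRef = res$fRef, fBest = res$fBest, fWorst = res$fWorst,
                 gd = res$gd, edBest = res$edBest, edWorst = res$edWorst,
                 sdBest = res$sdBest, config = res$config)
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outDir)
}
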