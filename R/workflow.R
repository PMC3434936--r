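#' Run the full taxon-area analysis workflow
#'
#' Chains the whole pipeline on one matrix: validation, all-zero-outgroup and
#' Lundberg rootings, MP search with tree statistics (length, CI, RI), ML
#' Mk+G search, bootstrap supports, UPGMA dendrogram, extinct-taxa
#' augmentation scenarios, and per-species stochastic maps.  Results are
#' written to `outDir` together with a JSON manifest (command, resolved
#' configuration, seed, input digest, package version) sufficient to re-run
#' the analysis reproducibly.
#'
#' @param x a [TaxonAreaMatrix-class] or path to a matrix file readable by
#'   [readTaxonAreaMatrix()].
#' @param outDir output directory (created if missing).
#' @param seed integer master seed.
#' @param fractions extinct-taxa fractions for [runScenarios()].
#' @param B bootstrap replicates for the MP bootstrap.
#' @param nStarts random-addition replicates for the searches.
#' @param mapSpecies species names to map stochastically (default: first
#'   three species); `character(0)` skips mapping.
#' @param mapSamples stochastic-map samples per species.
#' @param gamma use the +G model (default TRUE).
#' @param invariant additionally fit +I.
#' @param mlControl candidate-scoring control for the likelihood searches
#'   (see [treeSearch()]).
#' @return invisibly, a list with all in-memory results (`mp`, `ml`,
#'   `upgma`, `scenarios`, `maps`, `manifest`).
#' @export
runWorkflow <- function(x, outDir, seed = 1L, fractions = c(0.5, 1, 1.5, 2),
                        B = 100L, nStarts = 5L, mapSpecies = NULL,
                        mapSamples = 1000L, gamma = TRUE, invariant = FALSE,
                        mlControl = list()) {
  inputPath <- NULL
  if (is.character(x)) { inputPath <- x; x <- readTaxonAreaMatrix(x) }
  stopifnot(methods::is(x, "TaxonAreaMatrix"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  step <- function(name, expr) {
    message(sprintf("[%s] ...", name))
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[%s] done in %.1fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  xo <- step("outgroup", addAllZeroOutgroup(x))

  mp <- step("mp-search", bootstrapSearch(xo, objective = "parsimony", B = B,
                                          nStarts = nStarts, seed = seed))
  mpScore <- fitchScore(mp$best, xo)
  writeAreaTree(mp$best, file.path(outDir, "mp_tree.nwk"))

  ml <- step("ml-search", treeSearch(xo, objective = "likelihood",
                                     gamma = gamma, invariant = invariant,
                                     nStarts = max(1L, nStarts %/% 2L),
                                     swap = "nni", seed = seed + 1L,
                                     mlControl = mlControl))
  writeAreaTree(ml$best, file.path(outDir, "ml_tree.nwk"))

  lb <- step("lundberg", {
    unrooted <- ape::unroot(dropOutgroup(ml$best))
    lundbergRoot(unrooted, x)
  })
  writeAreaTree(lb, file.path(outDir, "ml_tree_lundberg.nwk"))

  up <- step("upgma", upgmaTree(areaDistance(x)))
  writeAreaTree(up, file.path(outDir, "upgma.nwk"))

  sc <- step("scenarios", runScenarios(x, fractions = fractions,
                                       gamma = gamma, nStarts = max(1L, nStarts %/% 2L),
                                       swap = "nni", seed = seed + 2L,
                                       mlControl = mlControl))
  scTab <- data.frame(
    nExtinct = vapply(sc, `[[`, integer(1), "nExtinct"),
    logLik = vapply(sc, `[[`, numeric(1), "logLik"),
    rfToBaseline = vapply(sc, `[[`, integer(1), "rfToBaseline"))
  utils::write.table(scTab, file.path(outDir, "scenarios.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (r in sc)
    writeAreaTree(r$tree, file.path(outDir, sprintf("scenario_%d.nwk", r$nExtinct)))

  if (is.null(mapSpecies))
    mapSpecies <- utils::head(speciesNames(x), 3L)
  maps <- step("stochastic-maps", {
    model <- ml$fit$model
    tr <- dropOutgroup(ml$fit$tree)
    out <- lapply(seq_along(mapSpecies), function(i)
      mapCharacter(tr, x, mapSpecies[i], model, nSamples = mapSamples,
                   seed = seed + 10L + i))
    names(out) <- mapSpecies
    out
  })
  if (length(maps)) {
    mapTab <- data.frame(
      species = names(maps),
      rate = vapply(maps, `[[`, numeric(1), "rate"),
      expectedGains = vapply(maps, function(m) sum(m$expectedGains), numeric(1)),
      expectedLosses = vapply(maps, function(m) sum(m$expectedLosses), numeric(1)))
    utils::write.table(mapTab, file.path(outDir, "species_maps.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }

  manifest <- list(
    command = "runWorkflow",
    package = "paeML",
    version = as.character(utils::packageVersion("paeML")),
    seed = seed,
    config = list(fractions = fractions, B = B, nStarts = nStarts,
                  mapSpecies = mapSpecies, mapSamples = mapSamples,
                  gamma = gamma, invariant = invariant),
    input = list(path = inputPath,
                 digest = if (!is.null(inputPath))
                   unname(tools::md5sum(inputPath)) else NA_character_,
                 nAreas = nrow(presence(x)), nSpecies = ncol(presence(x))),
    results = list(mpLength = mpScore$length, mpCI = mpScore$ci,
                   mpRI = mpScore$ri, mlLogLik = ml$score,
                   scenarioLogLik = scTab$logLik),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  .writeJSON(manifest, file.path(outDir, "manifest.json"))

  invisible(list(mp = mp, mpScore = mpScore, ml = ml, lundberg = lb,
                 upgma = up, scenarios = sc, maps = maps,
                 manifest = manifest))
}

# minimal JSON serialiser (atomic vectors, lists); avoids a hard dependency
.writeJSON <- function(x, path) {
  esc <- function(s) gsub('"', '\\\\"', s)
  ser <- function(v) {
    if (is.null(v)) return("null")
    if (is.list(v)) {
      if (!is.null(names(v)) && all(nzchar(names(v))))
        return(paste0("{", paste(sprintf('"%s": %s', esc(names(v)),
                                         vapply(v, ser, character(1))),
                                 collapse = ", "), "}"))
      return(paste0("[", paste(vapply(v, ser, character(1)), collapse = ", "), "]"))
    }
    single <- function(e)
      if (is.na(e)) "null"
      else if (is.character(e)) sprintf('"%s"', esc(e))
      else if (is.logical(e)) tolower(as.character(e))
      else format(e, digits = 15)
    parts <- vapply(v, single, character(1))
    if (length(v) == 1L) parts else paste0("[", paste(parts, collapse = ", "), "]")
  }
  writeLines(ser(x), path)
  invisible(path)
}
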