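#' Cross-species concordance report
#'
#' Joins the human candidate panel to the rat validation results through
#' an explicit ortholog map and classifies each panel gene as
#' \code{concordant} (both directions defined and equal and both p-values
#' at or below the significance threshold), \code{discordant}, or
#' \code{untestable} (unmapped, absent from the rat results, or not
#' analysable there). A separate \code{rat_trend} flag marks rat effects
#' in the same direction with p between the significance and trend
#' thresholds — reported alongside, never conflated with significance.
#' The function is a pure function of its three input tables.
#'
#' @param humanPanel data.frame with columns \code{gene}, \code{p},
#'   \code{direction}, \code{fc} (and optionally \code{branch}), e.g.
#'   from [refinePanel()].
#' @param ratResults data.frame with columns \code{gene}, \code{p},
#'   \code{direction}, \code{fc}, \code{method} (and optionally
#'   \code{analysable}).
#' @param orthologMap data.frame with columns \code{human}, \code{rat};
#'   duplicate human entries are an error.
#' @param pThreshold Significance threshold (default 0.05).
#' @param trendThreshold Trend threshold (default 0.10).
#' @return data.frame with one row per human panel gene.
#' @examples
#' concordance(refinePanel(humanCandidatePanel(), humanCandidatePanel()),
#'             ratValidationResults(), humanRatOrthologs())
#' @export
concordance <- function(humanPanel, ratResults, orthologMap,
                        pThreshold = 0.05, trendThreshold = 0.10) {
  .assertColumns(humanPanel, c("gene", "p", "direction", "fc"),
                 "'humanPanel'")
  .assertColumns(ratResults, c("gene", "p", "direction", "fc", "method"),
                 "'ratResults'")
  .assertColumns(orthologMap, c("human", "rat"), "'orthologMap'")
  dup <- orthologMap$human[duplicated(orthologMap$human)]
  if (length(dup)) {
    stop("duplicate ortholog mapping(s) for: ",
         paste(unique(dup), collapse = ", "))
  }
  if (!"branch" %in% names(humanPanel)) humanPanel$branch <- NA_character_
  if (!"analysable" %in% names(ratResults)) {
    ratResults$analysable <- !is.na(ratResults$p)
  }
  rows <- lapply(seq_len(nrow(humanPanel)), function(i) {
    h <- humanPanel[i, ]
    ratId <- orthologMap$rat[match(h$gene, orthologMap$human)]
    out <- data.frame(human_gene = h$gene, rat_gene = NA_character_,
                      human_direction = h$direction, human_fc = h$fc,
                      human_p = h$p, human_branch = h$branch,
                      rat_direction = NA_character_, rat_fc = NA_real_,
                      rat_p = NA_real_, rat_method = NA_character_,
                      agreement = "untestable", rat_trend = FALSE)
    if (is.na(ratId)) return(out)
    out$rat_gene <- ratId
    r <- ratResults[match(ratId, ratResults$gene), ]
    if (is.na(r$gene) || !isTRUE(r$analysable) || is.na(r$p)) {
      out$rat_method <- if (!is.na(r$gene)) "not_analysable" else NA
      return(out)
    }
    out$rat_direction <- r$direction
    out$rat_fc <- r$fc
    out$rat_p <- r$p
    out$rat_method <- r$method
    sameDir <- !is.na(h$direction) && !is.na(r$direction) &&
      h$direction == r$direction
    significant <- sameDir && h$p <= pThreshold && r$p <= pThreshold
    out$agreement <- if (significant) "concordant" else "discordant"
    out$rat_trend <- sameDir && r$p > pThreshold &&
      r$p <= trendThreshold
    out
  })
  do.call(rbind, rows)
}

.pipelineDefaults <- function() {
  list(seed = 1L, outDir = "transmark-run",
       stages = c("synthesize", "de", "refine", "correlation", "pcr",
                  "ddpcr", "plasma", "concordance"),
       minPairs = 6L, corrThreshold = 0.6, pThreshold = 0.05,
       trendThreshold = 0.10, deResidualSd = 0.35)
}

#' Demo pipeline configuration
#'
#' A complete configuration running every stage on synthetic inputs
#' generated from the calibrated presets; completes in well under a
#' minute on one CPU.
#'
#' @param outDir Output directory.
#' @param seed Integer seed driving every stage.
#' @return A named configuration list for [runPipeline()].
#' @export
demoConfig <- function(outDir, seed = 1L) {
  cfg <- .pipelineDefaults()
  cfg$outDir <- outDir
  cfg$seed <- as.integer(seed)
  cfg
}

.writeTsv <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  path
}

# Gene universe of the demo compendium: the human candidate panel, the
# prior-correlation partner PROX1, four genes that anti-correlate with the
# TIMP1 module in prior experiments, and inert fillers.
.demoCompendiumSpec <- function(seed) {
  panel <- humanCandidatePanel()
  anti <- c("CST1", "SLC12A9", "CDK17", "ARMCX6")
  genes <- c(panel$gene, "PROX1", anti, paste0("FILLER", 1:20))
  moduleGenes <- c("TIMP1", "ORM2", "PROX1", anti)
  compendiumSpec(
    nExperiments = 600, nGenes = length(genes), presenceProb = 0.6,
    modules = list(list(genes = moduleGenes, r = 0.8,
                        sign = c(1, 1, 1, -1, -1, -1, -1))),
    noiseSd = 1, geneNames = genes, seed = .subSeed(seed, 1))
}

#' Run the end-to-end biomarker pipeline
#'
#' Executes the requested stages in order — input synthesis, the
#' differential-expression screen, the refinement gate, the
#' prior-correlation module analysis, qPCR quantification (including
#' reference-gene stability), ddPCR quantification, plasma ELISA
#' statistics and the cross-species concordance report — writing
#' per-stage TSV/JSON outputs plus a manifest with content hashes and
#' per-stage row counts. A stage whose inputs were not produced (because
#' an upstream stage was disabled) fails fast naming the missing
#' dependency. Re-running with an identical configuration reproduces
#' byte-identical outputs (the manifest carries no timestamps).
#'
#' @param config Configuration list from [demoConfig()], or a path to a
#'   JSON file holding one. Unknown keys are rejected.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  defaults <- .pipelineDefaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, config)
  badStages <- setdiff(cfg$stages, defaults$stages)
  if (length(badStages)) {
    stop("unknown stage(s): ", paste(badStages, collapse = ", "))
  }
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(cfg$seed)
  state <- new.env(parent = emptyenv())
  files <- list()
  counts <- list()
  need <- function(what, stage, from) {
    if (!exists(what, envir = state)) {
      stop(sprintf("stage '%s' requires output of stage '%s'",
                   stage, from))
    }
    get(what, envir = state)
  }
  out <- function(name) file.path(cfg$outDir, name)

  if ("synthesize" %in% cfg$stages) {
    panel <- humanCandidatePanel()
    comp <- genCompendium(.demoCompendiumSpec(seed))
    blood <- genBloodExpression(deSpec(
      genes = rbind(panel[c("gene", "fc", "direction")] |>
                      stats::setNames(c("gene", "fold_change",
                                        "direction")),
                    data.frame(gene = paste0("NULLG", 1:10),
                               fold_change = 1, direction = "up")),
      nCases = 10L, nControls = 10L, residualSd = cfg$deResidualSd,
      seed = .subSeed(seed, 2)))
    qpcr <- genCqExperiment(ratQpcrPreset(.subSeed(seed, 3)))
    refpanel <- genCqExperiment(refGeneQpcrPreset(.subSeed(seed, 4)))
    ddpcr <- genDropletCounts(ratDdpcrPreset(.subSeed(seed, 5)))
    plasma <- genPlasmaPanel(plasmaSpecPreset(.subSeed(seed, 6)))
    plate <- genElisaPlate(plasma, noiseSd = 0.01,
                           seed = .subSeed(seed, 7))
    assign("comp", comp, state)
    assign("blood", blood, state)
    assign("qpcr", qpcr, state)
    assign("refpanel", refpanel, state)
    assign("ddpcr", ddpcr, state)
    assign("plasma", plasma, state)
    assign("plate", plate, state)
    files$compendium <- writeCompendium(comp, out("compendium.tsv"))
    files$expression <- writeExpressionMatrix(
      blood$se, out("expression.tsv"), out("groups.tsv"))
    files$cq <- writeCqTable(qpcr$cq, out("cq.tsv"))
    files$refcq <- writeCqTable(refpanel$cq, out("cq_refpanel.tsv"))
    files$droplets <- writeDropletCounts(ddpcr$droplets,
                                         out("droplets.tsv"))
    files$plasma <- writePlasmaPanel(plasma, out("plasma.tsv"))
    files$elisa <- writeElisaPlate(plate, out("elisa.csv"))
    counts$synthesize <- c(
      compendium_cells = sum(!is.na(ratioMatrix(comp))),
      expression_genes = nrow(SummarizedExperiment::assay(blood$se)),
      cq_rows = nrow(tableData(qpcr$cq)),
      droplet_wells = nrow(tableData(ddpcr$droplets)),
      plasma_subjects = nrow(tableData(plasma)))
  }

  if ("de" %in% cfg$stages) {
    blood <- need("blood", "de", "synthesize")
    de <- deTest(blood$se)
    screen <- primaryScreen(de)
    assign("de", de, state)
    assign("screen", screen, state)
    files$de <- .writeTsv(de, out("de.tsv"))
    files$screen <- .writeTsv(screen, out("screen.tsv"))
    counts$de <- c(tested = nrow(de), screened = nrow(screen))
  }

  if ("refine" %in% cfg$stages) {
    screen <- need("screen", "refine", "de")
    evidence <- humanCandidatePanel()[c("gene", "ca", "literature")]
    refined <- refinePanel(screen, evidence)
    assign("refined", refined, state)
    files$panel <- .writeTsv(refined, out("panel.tsv"))
    counts$refine <- table(refined$branch)
  }

  if ("correlation" %in% cfg$stages) {
    comp <- need("comp", "correlation", "synthesize")
    corr <- pairwiseCorrelation(comp, minPairs = cfg$minPairs)
    panel <- humanCandidatePanel()
    upSet <- c(panel$gene[panel$direction == "up"], "PROX1",
               "CST1", "SLC12A9", "CDK17", "ARMCX6")
    downSet <- panel$gene[panel$direction == "down"]
    modules <- correlatedModules(corr, upSet, downSet,
                                 threshold = cfg$corrThreshold)
    files$corr <- .writeTsv(
      data.frame(gene = rownames(corValues(corr)),
                 round(corValues(corr), 6), check.names = FALSE),
      out("correlation.tsv"))
    files$npairs <- .writeTsv(
      data.frame(gene = rownames(copresenceCounts(corr)),
                 copresenceCounts(corr), check.names = FALSE),
      out("npairs.tsv"))
    files$modules <- .writeJson(modules, out("modules.json"))
    writeLines(correlationOrdering(corr), out("ordering.txt"))
    files$ordering <- out("ordering.txt")
    assign("modules", modules, state)
    counts$correlation <- c(
      up_modules = length(modules$up$modules),
      down_modules = length(modules$down$modules))
  }

  if ("pcr" %in% cfg$stages) {
    qpcr <- need("qpcr", "pcr", "synthesize")
    refpanel <- need("refpanel", "pcr", "synthesize")
    stab <- geNorm(relativeQuantities(refpanel$cq))
    rq <- relativeQuantities(qpcr$cq)
    nrq <- normalizeRq(rq)
    qres <- groupStats(nrq[!nrq$is_reference, ], case = "snl",
                       control = "sham")
    qres$method <- "qpcr"
    assign("qpcrResults", qres, state)
    files$genorm <- .writeJson(stab, out("genorm.json"))
    files$nrq <- .writeTsv(nrq, out("nrq.tsv"))
    files$qpcrResults <- .writeTsv(qres, out("qpcr_results.tsv"))
    counts$pcr <- c(genes = nrow(qres),
                    analysable = sum(qres$analysable))
  }

  if ("ddpcr" %in% cfg$stages) {
    ddpcr <- need("ddpcr", "ddpcr", "synthesize")
    copies <- poissonCopies(ddpcr$droplets)
    ncop <- normalizeCopies(copies, references = c("Rpl13a", "Ubc"))
    dres <- groupStats(ncop[!ncop$gene %in% c("Rpl13a", "Ubc"), ],
                       case = "snl", control = "sham")
    dres$method <- "ddpcr"
    assign("ddpcrResults", dres, state)
    files$copies <- .writeTsv(copies, out("copies.tsv"))
    files$ddpcrResults <- .writeTsv(dres, out("ddpcr_results.tsv"))
    counts$ddpcr <- c(genes = nrow(dres),
                      analysable = sum(dres$analysable))
  }

  if ("plasma" %in% cfg$stages) {
    plasma <- need("plasma", "plasma", "synthesize")
    plate <- need("plate", "plasma", "synthesize")
    curve <- fitStandardCurve(plate)
    conc <- elisaConcentrations(curve, plate)
    d <- tableData(plasma)
    concByGroup <- split(conc$conc_ng_ml[match(d$subject, conc$subject)],
                         d$group)
    mw <- list(
      control_vs_cnbp = compareTwoGroups(concByGroup$control,
                                         concByGroup$cnbp),
      cnbp_vs_cibp = compareTwoGroups(concByGroup$cnbp,
                                      concByGroup$cibp),
      control_vs_cibp = compareTwoGroups(concByGroup$control,
                                         concByGroup$cibp))
    kw <- compareKGroups(concByGroup)
    corrPM <- proteinMrnaCorrelation(plasma)
    cov <- covariateCheck(plasma)
    report <- list(groups = plasmaGroupSummary(plasma),
                   mann_whitney = mw, kruskal_wallis = kw,
                   protein_mrna = corrPM, covariates = cov,
                   curve = as.list(curve@params))
    files$concentrations <- .writeTsv(conc, out("concentrations.tsv"))
    files$plasmaReport <- .writeJson(report, out("plasma_report.json"))
    counts$plasma <- c(subjects = nrow(conc))
  }

  if ("concordance" %in% cfg$stages) {
    qres <- need("qpcrResults", "concordance", "pcr")
    dres <- need("ddpcrResults", "concordance", "ddpcr")
    human <- refinePanel(humanCandidatePanel(),
                         humanCandidatePanel()[c("gene", "ca",
                                                 "literature")])
    rat <- rbind(qres, dres)
    conc <- concordance(human, rat, humanRatOrthologs(),
                        pThreshold = cfg$pThreshold,
                        trendThreshold = cfg$trendThreshold)
    files$concordance <- .writeTsv(conc, out("concordance.tsv"))
    counts$concordance <- table(conc$agreement)
  }

  fileVec <- unlist(files, use.names = TRUE)
  manifest <- list(
    package = "TransMark",
    version = as.character(utils::packageVersion("TransMark")),
    config = cfg,
    stage_counts = lapply(counts, function(x) as.list(
      stats::setNames(as.integer(x), names(x)))),
    files = lapply(stats::setNames(as.list(fileVec), names(fileVec)),
                   function(f) list(path = basename(f),
                                    md5 = unname(tools::md5sum(f)))))
  .writeJson(manifest, out("manifest.json"))
  invisible(manifest)
}
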