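#' Specify a synthetic two-colour-array compendium
#'
#' @param nExperiments,nGenes Universe sizes.
#' @param presenceProb Probability that a gene is present on the platform of
#'   any given experiment, in (0, 1].
#' @param modules List of planted correlated modules. Each element is a list
#'   with \code{genes} (ids drawn from \code{geneNames}), \code{r} (target
#'   pairwise correlation) and optionally \code{sign} (per-gene +1/-1
#'   loading signs; genes with opposite signs are anti-correlated at
#'   \code{-r}). A negative \code{r} is accepted for 2-gene modules and is
#'   re-expressed as \code{|r|} with opposite signs.
#' @param noiseSd Residual log2-ratio SD.
#' @param geneNames Optional gene-id universe (default \code{g1..gN}).
#' @param seed Integer seed (mandatory; generators never touch hidden
#'   global RNG state).
#' @return A [CompendiumSpec-class] object.
#' @seealso [genCompendium()]
#' @export
compendiumSpec <- function(nExperiments, nGenes, presenceProb = 1,
                           modules = list(), noiseSd = 1,
                           geneNames = NULL, seed) {
  nExperiments <- .assertCount(nExperiments, "nExperiments")
  nGenes <- .assertCount(nGenes, "nGenes")
  .assertScalar(presenceProb, "presenceProb", 0, 1, open.lower = TRUE)
  .assertScalar(noiseSd, "noiseSd", 0, Inf, open.lower = TRUE)
  seed <- .assertCount(seed, "seed", min = 0L)
  if (is.null(geneNames)) geneNames <- paste0("g", seq_len(nGenes))
  if (length(geneNames) != nGenes || anyDuplicated(geneNames)) {
    stop("'geneNames' must be ", nGenes, " unique ids")
  }
  modules <- lapply(modules, function(m) {
    if (is.null(m$genes) || is.null(m$r)) {
      stop("each module needs 'genes' and 'r'")
    }
    if (!all(m$genes %in% geneNames)) {
      stop("module genes outside the gene universe")
    }
    if (m$r <= -1 || m$r >= 1) stop("module correlation must be in (-1, 1)")
    if (is.null(m$sign)) m$sign <- rep(1, length(m$genes))
    if (m$r < 0) {
      if (length(m$genes) != 2L) {
        stop("negative module correlation only meaningful for 2 genes; ",
             "use per-gene 'sign' for larger modules")
      }
      m$r <- abs(m$r)
      m$sign <- c(1, -1)
    }
    if (length(m$sign) != length(m$genes) || !all(m$sign %in% c(-1, 1))) {
      stop("'sign' must be +1/-1 per module gene")
    }
    m
  })
  new("CompendiumSpec", nExperiments = nExperiments, nGenes = nGenes,
      presenceProb = as.numeric(presenceProb), modules = modules,
      noiseSd = as.numeric(noiseSd), geneNames = as.character(geneNames),
      seed = seed)
}

#' Specify planted two-group differential expression
#'
#' @param genes data.frame with columns \code{gene}, \code{fold_change}
#'   (linear-scale ratio >= 1) and \code{direction} ("up"/"down").
#' @param nCases,nControls Group sizes (>= 2 each).
#' @param baseline Baseline log2 expression (default 8).
#' @param residualSd Residual log2 SD.
#' @param seed Integer seed.
#' @return A [DESpec-class] object.
#' @seealso [genBloodExpression()]
#' @export
deSpec <- function(genes, nCases, nControls, baseline = 8,
                   residualSd = 0.3, seed) {
  .assertColumns(genes, c("gene", "fold_change", "direction"), "'genes'")
  if (any(genes$fold_change < 1)) {
    stop("fold_change must be >= 1 (direction carries the sign)")
  }
  if (!all(genes$direction %in% c("up", "down"))) {
    stop("direction must be 'up' or 'down'")
  }
  if (anyDuplicated(genes$gene)) stop("duplicated gene ids")
  new("DESpec",
      nCases = .assertCount(nCases, "nCases", 2L),
      nControls = .assertCount(nControls, "nControls", 2L),
      genes = as.data.frame(genes),
      baseline = .assertScalar(baseline, "baseline"),
      residualSd = .assertScalar(residualSd, "residualSd", 0, Inf),
      seed = .assertCount(seed, "seed", 0L))
}

#' Specify a synthetic qPCR experiment
#'
#' @param targets data.frame with columns \code{gene}, \code{ratio}
#'   (true case/control quantity ratio, > 0) and \code{noise_sd} (cycles).
#'   May be empty (reference-gene-only panels).
#' @param references data.frame with columns \code{gene}, \code{noise_sd}.
#' @param nControl,nCase Group sizes (>= 2).
#' @param controlLabel,caseLabel Group labels (defaults "sham"/"snl").
#' @param baseCq Baseline Cq (cycles).
#' @param efficiency Amplification factor E in (1, 2]; E = 2 means one
#'   cycle per doubling.
#' @param sizeFactorSd SD of the per-sample shared log2 size factor.
#' @param seed Integer seed.
#' @return A [QpcrSpec-class] object.
#' @seealso [genCqExperiment()]
#' @export
qpcrSpec <- function(targets = data.frame(gene = character(),
                                          ratio = numeric(),
                                          noise_sd = numeric()),
                     references, nControl, nCase,
                     controlLabel = "sham", caseLabel = "snl",
                     baseCq = 24, efficiency = 2, sizeFactorSd = 0.4,
                     seed) {
  .assertColumns(targets, c("gene", "ratio", "noise_sd"), "'targets'")
  .assertColumns(references, c("gene", "noise_sd"), "'references'")
  if (nrow(targets) && any(targets$ratio <= 0)) stop("ratios must be > 0")
  if (anyDuplicated(c(targets$gene, references$gene))) {
    stop("duplicated gene ids across targets/references")
  }
  .assertScalar(efficiency, "efficiency", 1, 2, open.lower = TRUE)
  new("QpcrSpec", targets = as.data.frame(targets),
      references = as.data.frame(references),
      nControl = .assertCount(nControl, "nControl", 2L),
      nCase = .assertCount(nCase, "nCase", 2L),
      controlLabel = as.character(controlLabel),
      caseLabel = as.character(caseLabel),
      baseCq = .assertScalar(baseCq, "baseCq", 0, 40, TRUE, TRUE),
      efficiency = as.numeric(efficiency),
      sizeFactorSd = .assertScalar(sizeFactorSd, "sizeFactorSd", 0, Inf),
      seed = .assertCount(seed, "seed", 0L))
}

#' Specify a synthetic ddPCR experiment
#'
#' @param copies data.frame with columns \code{gene}, \code{sample},
#'   \code{group}, \code{copies} — true copies per reaction (>= 0).
#' @param dropletsPerWell Droplets generated per well.
#' @param wellsPerSample Replicate wells per gene x sample.
#' @param dropletVolumeNl,reactionVolumeUl Physical constants (defaults
#'   0.85 nL and 20 uL).
#' @param seed Integer seed.
#' @return A [DdpcrSpec-class] object.
#' @seealso [genDropletCounts()]
#' @export
ddpcrSpec <- function(copies, dropletsPerWell = 15000, wellsPerSample = 2,
                      dropletVolumeNl = 0.85, reactionVolumeUl = 20,
                      seed) {
  .assertColumns(copies, c("gene", "sample", "group", "copies"), "'copies'")
  if (any(copies$copies < 0)) stop("true copies must be >= 0")
  .assertScalar(dropletVolumeNl, "dropletVolumeNl", 0, Inf,
                open.lower = TRUE)
  .assertScalar(reactionVolumeUl, "reactionVolumeUl", 0, Inf,
                open.lower = TRUE)
  new("DdpcrSpec", copies = as.data.frame(copies),
      dropletsPerWell = .assertCount(dropletsPerWell, "dropletsPerWell"),
      wellsPerSample = .assertCount(wellsPerSample, "wellsPerSample"),
      dropletVolumeNl = as.numeric(dropletVolumeNl),
      reactionVolumeUl = as.numeric(reactionVolumeUl),
      seed = .assertCount(seed, "seed", 0L))
}

#' Specify a synthetic plasma protein panel
#'
#' @param groups data.frame with columns \code{group}, \code{location}
#'   (ng/ml), \code{scale} (ng/ml, > 0) and \code{n} (>= 2).
#' @param correlation Planted protein/mRNA Pearson correlation, strictly
#'   inside (-1, 1).
#' @param pairedGroups Group labels whose subjects carry paired mRNA.
#' @param family Concentration family: "truncnorm" (zero-truncated normal,
#'   default) or "lognormal". For "truncnorm" the \code{location} is the
#'   mean of the truncated distribution; for "lognormal" the
#'   \code{location}/\code{scale} are the distribution mean/SD.
#' @param ageRange,femaleProportion Demographics.
#' @param seed Integer seed.
#' @return A [PlasmaSpec-class] object.
#' @seealso [genPlasmaPanel()], [plasmaSpecPreset()]
#' @export
plasmaSpec <- function(groups, correlation = 0,
                       pairedGroups = character(0),
                       family = c("truncnorm", "lognormal"),
                       ageRange = c(30, 70), femaleProportion = 0.5,
                       seed) {
  .assertColumns(groups, c("group", "location", "scale", "n"), "'groups'")
  if (any(groups$scale <= 0)) stop("group scales must be > 0")
  if (any(groups$location <= 0)) stop("group locations must be > 0")
  if (any(groups$n < 2)) stop("each group needs n >= 2")
  if (anyDuplicated(groups$group)) stop("duplicated group labels")
  .assertScalar(correlation, "correlation", -1, 1, TRUE, TRUE)
  family <- match.arg(family)
  if (!all(pairedGroups %in% groups$group)) {
    stop("pairedGroups must be declared group labels")
  }
  if (length(ageRange) != 2L || ageRange[1] >= ageRange[2]) {
    stop("'ageRange' must be an increasing length-2 range")
  }
  .assertScalar(femaleProportion, "femaleProportion", 0, 1)
  new("PlasmaSpec", groups = as.data.frame(groups),
      correlation = as.numeric(correlation),
      pairedGroups = as.character(pairedGroups), family = family,
      ageRange = as.numeric(ageRange),
      femaleProportion = as.numeric(femaleProportion),
      seed = .assertCount(seed, "seed", 0L))
}

# ---- calibrated presets -------------------------------------------------

#' Calibrated plasma panel preset
#'
#' Three-group plasma TIMP1 panel matching the published clinical summary
#' statistics: healthy controls 157.3 (SD 33.2) ng/ml, n = 10; chronic
#' neuropathic back pain (CNBP) 278.4 (SD 131.4) ng/ml, n = 10; chronic
#' inflammatory back pain (CIBP) 147.8 (SD 75.55) ng/ml, n = 12. Controls
#' and CNBP subjects (20 in all) carry paired whole-blood mRNA levels with
#' a planted Pearson correlation of 0.68 on the raw concentration scale.
#'
#' @param seed Integer seed.
#' @param family Concentration family, see [plasmaSpec()].
#' @return A [PlasmaSpec-class] object.
#' @export
plasmaSpecPreset <- function(seed, family = "truncnorm") {
  plasmaSpec(
    groups = data.frame(
      group = c("control", "cnbp", "cibp"),
      location = c(157.3, 278.4, 147.8),
      scale = c(33.2, 131.4, 75.55),
      n = c(10L, 10L, 12L)),
    correlation = 0.68,
    pairedGroups = c("control", "cnbp"),
    family = family,
    ageRange = c(30, 70), femaleProportion = 0.5, seed = seed)
}

#' Calibrated Timp1 qPCR preset
#'
#' Dorsal-horn validation design: sham n = 8 vs spinal-nerve-ligation (SNL)
#' n = 10 rats, one target gene (Timp1) with a true SNL/sham expression
#' ratio of 2.19, normalized against the Atp5b/Ubc reference pair.
#'
#' @param seed Integer seed.
#' @param targetNoiseSd Per-sample biological + technical Cq noise for the
#'   target, in cycles (default 0.25).
#' @param referenceNoiseSd Reference-gene Cq noise (default 0.15 cycles).
#' @param sizeFactorSd SD of the shared per-sample log2 size factor
#'   (default 0.4; removed by normalization).
#' @return A [QpcrSpec-class] object.
#' @export
timp1QpcrPreset <- function(seed, targetNoiseSd = 0.25,
                            referenceNoiseSd = 0.15, sizeFactorSd = 0.4) {
  qpcrSpec(
    targets = data.frame(gene = "Timp1", ratio = 2.19,
                         noise_sd = targetNoiseSd),
    references = data.frame(gene = c("Atp5b", "Ubc"),
                            noise_sd = referenceNoiseSd),
    nControl = 8L, nCase = 10L, baseCq = 24,
    efficiency = 2, sizeFactorSd = sizeFactorSd, seed = seed)
}

#' Calibrated 12-candidate reference-gene preset
#'
#' Reference-gene stability panel for geNorm: 12 candidates measured on 18
#' samples (8 sham + 10 SNL). Two candidates (Atp5b, Ubc) share a common
#' low noise scale \eqn{\sigma_s} and the remaining ten have noise
#' \eqn{2\sigma_s}. With amplification efficiency 2, cycle noise is log2
#' noise, so the expected geNorm stability of a stable candidate is
#' \deqn{E[M] = c_4(18)\,\sigma_s\,(\sqrt{2} + 10\sqrt{5})/11,}
#' where \eqn{c_4} is the small-sample unbiasing constant of the sample SD.
#' \eqn{\sigma_s} is solved so that this expectation equals the target top
#' pair stability M = 0.419; the same geometry implies a stable-candidate
#' coefficient of variation of normalized quantities of about 0.145.
#'
#' @param seed Integer seed.
#' @param targetM Expected stability of the most stable pair (default
#'   0.419, the published calibration value).
#' @return A [QpcrSpec-class] object with 12 reference genes and no targets.
#' @export
refGeneQpcrPreset <- function(seed, targetM = 0.419) {
  nSamples <- 18L
  sigmaS <- targetM / (.c4(nSamples) * (sqrt(2) + 10 * sqrt(5)) / 11)
  genes <- c("Atp5b", "Ubc", "Actb", "B2m", "Gapdh", "Ywhaz", "Rpl13a",
             "Sdha", "Hprt1", "Tbp", "Cyc1", "Canx")
  qpcrSpec(
    references = data.frame(
      gene = genes,
      noise_sd = c(sigmaS, sigmaS, rep(2 * sigmaS, 10))),
    nControl = 8L, nCase = 10L, baseCq = 22,
    efficiency = 2, sizeFactorSd = 0.5, seed = seed)
}

#' Rat dorsal-horn qPCR validation preset
#'
#' Multi-gene sham vs SNL qPCR design with true expression ratios planted
#' at the published cross-species validation effects for the
#' qPCR-quantified genes (e.g. Timp1 at 2.19, Rnf185 at 1/2.18).
#'
#' @param seed Integer seed.
#' @param targetNoiseSd Target-gene Cq noise in cycles (default 0.45,
#'   biological + technical).
#' @return A [QpcrSpec-class] object.
#' @export
ratQpcrPreset <- function(seed, targetNoiseSd = 0.45) {
  targets <- data.frame(
    gene = c("Clu", "Dpp3", "Icoslg", "Lin28a", "Rnf185", "Timp1", "Tlr5"),
    ratio = c(1.00, 1 / 1.16, 1 / 1.16, 1.30, 1 / 2.18, 2.19, 1.51),
    noise_sd = targetNoiseSd)
  qpcrSpec(
    targets = targets,
    references = data.frame(gene = c("Atp5b", "Ubc"), noise_sd = 0.15),
    nControl = 8L, nCase = 10L, baseCq = 24,
    efficiency = 2, sizeFactorSd = 0.4, seed = seed)
}

#' Rat dorsal-horn ddPCR validation preset
#'
#' Absolute-quantification design for the droplet-digital-quantified genes
#' (Casp4 at 1.22, Mc1r at 2.72, Nlrc4 at 1.15, Arhgap11a at 1/1.03;
#' Rpl13a and Ubc as references at ratio 1). True per-sample copies per
#' reaction carry lognormal biological variability around the group means.
#'
#' @param seed Integer seed (also drives the biological copy-number draw).
#' @param baseCopies Sham-group geometric-mean copies per reaction for
#'   targets (default 1500).
#' @param bioSdLog Biological log-scale SD of per-sample copies (default
#'   0.3 for targets, half that for references).
#' @return A [DdpcrSpec-class] object.
#' @export
ratDdpcrPreset <- function(seed, baseCopies = 1500, bioSdLog = 0.3) {
  genes <- data.frame(
    gene = c("Casp4", "Mc1r", "Nlrc4", "Arhgap11a", "Rpl13a", "Ubc"),
    ratio = c(1.22, 2.72, 1.15, 1 / 1.03, 1, 1),
    base = c(rep(baseCopies, 4), 3000, 3000),
    sdlog = c(rep(bioSdLog, 4), bioSdLog / 2, bioSdLog / 2))
  samples <- data.frame(
    sample = c(paste0("sham", 1:8), paste0("snl", 1:10)),
    group = rep(c("sham", "snl"), c(8, 10)))
  copies <- withr::with_seed(.subSeed(seed, 17), {
    do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      mu <- genes$base[i] * ifelse(samples$group == "snl",
                                   genes$ratio[i], 1)
      data.frame(gene = genes$gene[i], sample = samples$sample,
                 group = samples$group,
                 copies = mu * exp(stats::rnorm(nrow(samples), 0,
                                                genes$sdlog[i])))
    }))
  })
  ddpcrSpec(copies = copies, dropletsPerWell = 15000L, wellsPerSample = 2L,
            seed = seed)
}
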