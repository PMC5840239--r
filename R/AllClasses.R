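#' @import methods
NULL

# ---- central data containers -------------------------------------------

#' Two-colour microarray compendium
#'
#' Holds per-experiment log2 expression ratios for a set of genes across a
#' heterogeneous collection of two-colour array experiments. A gene absent
#' from the platform of a given experiment is stored as \code{NA}; all
#' downstream correlation work is pairwise-complete over the non-missing
#' entries.
#'
#' @slot ratios Numeric matrix, genes x experiments, \code{NA} marking
#'   platform absence; finite values otherwise.
#' @seealso [pairwiseCorrelation()], [genCompendium()], [readCompendium()]
#' @export
setClass("ExpressionCompendium", slots = c(ratios = "matrix"))

setValidity("ExpressionCompendium", function(object) {
  m <- object@ratios
  if (!is.numeric(m)) return("'ratios' must be a numeric matrix")
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    return("'ratios' needs gene rownames and experiment colnames")
  }
  if (anyDuplicated(rownames(m))) return("duplicated gene ids")
  if (anyDuplicated(colnames(m))) return("duplicated experiment ids")
  if (any(is.infinite(m))) return("log2 ratios must be finite or NA")
  TRUE
})

#' Pairwise-complete correlation matrix
#'
#' Pearson correlations computed, per gene pair, over exactly the
#' experiments where both genes were present, together with the co-presence
#' counts. Entries with fewer than \code{minPairs} co-presences (or a
#' degenerate zero-variance subset) are undefined (\code{NA}), never zero.
#'
#' @slot r Symmetric numeric matrix of Pearson coefficients (NA = undefined).
#' @slot nPairs Symmetric integer matrix of co-presence counts.
#' @slot minPairs Minimum co-presence count for a defined coefficient.
#' @seealso [pairwiseCorrelation()], [correlatedModules()]
#' @export
setClass("PairwiseCorrelation",
         slots = c(r = "matrix", nPairs = "matrix", minPairs = "integer"))

setValidity("PairwiseCorrelation", function(object) {
  r <- object@r; np <- object@nPairs
  if (!identical(dim(r), dim(np))) return("'r' and 'nPairs' dims differ")
  if (!identical(rownames(r), colnames(r))) return("'r' must be square with matching dimnames")
  if (!isTRUE(all.equal(r, t(r)))) return("'r' must be symmetric")
  if (!isTRUE(all.equal(np, t(np)))) return("'nPairs' must be symmetric")
  if (any(r < -1 - 1e-12 | r > 1 + 1e-12, na.rm = TRUE)) {
    return("defined correlations must lie in [-1, 1]")
  }
  TRUE
})

#' qPCR quantification-cycle table
#'
#' Tidy Cq measurements: one row per gene x sample (technical replicates
#' already collapsed, or collapse with [collapseTechnicalReplicates()]).
#'
#' @slot data data.frame with columns \code{gene}, \code{sample},
#'   \code{group}, \code{is_reference} (logical), \code{cq} (cycles, in
#'   (0, 45)).
#' @seealso [relativeQuantities()], [genCqExperiment()]
#' @export
setClass("CqTable", slots = c(data = "data.frame"))

setValidity("CqTable", function(object) {
  d <- object@data
  need <- c("gene", "sample", "group", "is_reference", "cq")
  if (!all(need %in% names(d))) {
    return(paste("data needs columns:", paste(need, collapse = ", ")))
  }
  if (!is.logical(d$is_reference)) return("'is_reference' must be logical")
  if (!is.numeric(d$cq)) return("'cq' must be numeric")
  if (any(!is.finite(d$cq)) || any(d$cq <= 0 | d$cq >= 45)) {
    return("Cq values must be finite and inside (0, 45)")
  }
  TRUE
})

#' Digital-droplet PCR droplet counts
#'
#' Per-well positive/total droplet counts plus the physical constants
#' needed to convert droplet occupancy into absolute copies per reaction.
#'
#' @slot data data.frame with columns \code{gene}, \code{sample},
#'   \code{group}, \code{well}, \code{positives}, \code{total}.
#' @slot dropletVolumeNl Droplet volume in nanolitres (> 0).
#' @slot reactionVolumeUl Reaction volume in microlitres (> 0).
#' @seealso [poissonCopies()], [genDropletCounts()]
#' @export
setClass("DropletCounts",
         slots = c(data = "data.frame", dropletVolumeNl = "numeric",
                   reactionVolumeUl = "numeric"))

setValidity("DropletCounts", function(object) {
  d <- object@data
  need <- c("gene", "sample", "group", "well", "positives", "total")
  if (!all(need %in% names(d))) {
    return(paste("data needs columns:", paste(need, collapse = ", ")))
  }
  if (any(d$total <= 0)) return("'total' droplets must be > 0")
  if (any(d$positives < 0 | d$positives > d$total)) {
    return("'positives' must satisfy 0 <= positives <= total")
  }
  if (length(object@dropletVolumeNl) != 1L || object@dropletVolumeNl <= 0) {
    return("'dropletVolumeNl' must be a single value > 0")
  }
  if (length(object@reactionVolumeUl) != 1L || object@reactionVolumeUl <= 0) {
    return("'reactionVolumeUl' must be a single value > 0")
  }
  TRUE
})

#' Plasma protein panel
#'
#' Per-subject plasma protein concentration with group label, demographics
#' and an optional paired whole-blood mRNA level.
#'
#' @slot data data.frame with columns \code{subject}, \code{group},
#'   \code{age}, \code{sex}, \code{conc_ng_ml} (> 0) and \code{mrna_level}
#'   (NA where no paired measurement exists).
#' @seealso [genPlasmaPanel()], [compareTwoGroups()],
#'   [proteinMrnaCorrelation()]
#' @export
setClass("PlasmaPanel", slots = c(data = "data.frame"))

setValidity("PlasmaPanel", function(object) {
  d <- object@data
  need <- c("subject", "group", "age", "sex", "conc_ng_ml", "mrna_level")
  if (!all(need %in% names(d))) {
    return(paste("data needs columns:", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(d$subject)) return("duplicated subject ids")
  if (any(!is.finite(d$conc_ng_ml)) || any(d$conc_ng_ml <= 0)) {
    return("concentrations must be finite and > 0")
  }
  TRUE
})

#' ELISA plate
#'
#' Standards and duplicate sample absorbances from a sandwich ELISA read at
#' 450 nm, plus the plasma dilution factor applied before the assay.
#'
#' @slot standards data.frame with columns \code{conc_known} (ng/ml in the
#'   well), \code{absorbance}, \code{replicate}.
#' @slot samples data.frame with columns \code{subject}, \code{absorbance},
#'   \code{replicate}.
#' @slot dilutionFactor Fold-dilution of plasma before the assay (default
#'   convention: 10 ul diluted to 200 ul gives 20).
#' @seealso [fitStandardCurve()], [elisaConcentrations()], [genElisaPlate()]
#' @export
setClass("ElisaPlate",
         slots = c(standards = "data.frame", samples = "data.frame",
                   dilutionFactor = "numeric"))

setValidity("ElisaPlate", function(object) {
  s <- object@standards
  if (!all(c("conc_known", "absorbance", "replicate") %in% names(s))) {
    return("standards need columns conc_known, absorbance, replicate")
  }
  if (length(unique(s$conc_known)) < 4L) {
    return("need >= 4 distinct standard concentrations")
  }
  if (any(!is.finite(s$absorbance)) || any(s$absorbance < 0)) {
    return("standard absorbances must be finite and >= 0")
  }
  sm <- object@samples
  if (!all(c("subject", "absorbance", "replicate") %in% names(sm))) {
    return("samples need columns subject, absorbance, replicate")
  }
  if (any(!is.finite(sm$absorbance)) || any(sm$absorbance < 0)) {
    return("sample absorbances must be finite and >= 0")
  }
  if (length(object@dilutionFactor) != 1L || object@dilutionFactor <= 0) {
    return("'dilutionFactor' must be a single value > 0")
  }
  TRUE
})

#' Fitted ELISA standard curve
#'
#' Four-parameter logistic response \eqn{A(x) = D + (A0 - D)/(1 + (x/C)^B)}
#' fitted to the plate standards by least squares. \code{A0} is the
#' zero-concentration asymptote, \code{D} the saturating asymptote, \code{C}
#' the midpoint concentration and \code{B} the slope.
#'
#' @slot params Named numeric vector \code{A0}, \code{D}, \code{C}, \code{B}.
#' @slot residuals Fit residuals at the standards.
#' @slot concRange Invertible in-well concentration range (span of the
#'   positive standards).
#' @seealso [fitStandardCurve()], [elisaConcentrations()]
#' @export
setClass("StandardCurve",
         slots = c(params = "numeric", residuals = "numeric",
                   concRange = "numeric"))

# ---- simulation specifications -----------------------------------------

#' Compendium simulation specification
#'
#' Describes a synthetic two-colour-array compendium: universe size,
#' per-experiment gene presence probability, planted correlated modules and
#' residual noise. Within a module, correlation is induced by one shared
#' latent factor per experiment with loading \code{sign * sqrt(r)}, giving
#' an exact expected pairwise correlation of \code{sign_i * sign_j * r}.
#'
#' @slot nExperiments,nGenes Counts.
#' @slot presenceProb Probability a gene is present on a given platform.
#' @slot modules List of planted modules, each
#'   \code{list(genes =, r =, sign =)}.
#' @slot noiseSd Log2-ratio scale.
#' @slot geneNames Gene id universe.
#' @slot seed Mandatory integer seed.
#' @seealso [compendiumSpec()], [genCompendium()]
#' @export
setClass("CompendiumSpec",
         slots = c(nExperiments = "integer", nGenes = "integer",
                   presenceProb = "numeric", modules = "list",
                   noiseSd = "numeric", geneNames = "character",
                   seed = "integer"))

#' Two-group expression simulation specification
#'
#' Planted differential expression for a case/control log2 expression
#' matrix: per-gene true linear-scale fold change with direction, shared
#' baseline and residual noise.
#'
#' @slot nCases,nControls Group sizes (>= 2).
#' @slot genes data.frame with columns \code{gene}, \code{fold_change}
#'   (linear, >= 1) and \code{direction} ("up"/"down").
#' @slot baseline Baseline log2 expression level.
#' @slot residualSd Residual log2 SD.
#' @slot seed Mandatory integer seed.
#' @seealso [deSpec()], [genBloodExpression()]
#' @export
setClass("DESpec",
         slots = c(nCases = "integer", nControls = "integer",
                   genes = "data.frame", baseline = "numeric",
                   residualSd = "numeric", seed = "integer"))

#' qPCR simulation specification
#'
#' Cq-level generative model: \code{Cq = baseCq - log_E(quantity * sizeFactor)
#' + noise}, where the per-sample size factor is shared by every gene in a
#' sample (what multi-reference normalization removes) and noise is
#' per-gene independent, in cycles. Targets carry a true case/control
#' quantity ratio; reference genes have constant true quantity.
#'
#' @slot targets data.frame with columns \code{gene}, \code{ratio}
#'   (case/control, linear) and \code{noise_sd} (cycles). May have 0 rows.
#' @slot references data.frame with columns \code{gene}, \code{noise_sd}.
#' @slot nControl,nCase Group sizes; groups are labelled \code{controlLabel}
#'   and \code{caseLabel} (defaults "sham"/"snl").
#' @slot controlLabel,caseLabel Group labels.
#' @slot baseCq Baseline Cq level (cycles).
#' @slot efficiency Amplification factor E in (1, 2].
#' @slot sizeFactorSd SD of the per-sample log2 size factor.
#' @slot seed Mandatory integer seed.
#' @seealso [qpcrSpec()], [genCqExperiment()]
#' @export
setClass("QpcrSpec",
         slots = c(targets = "data.frame", references = "data.frame",
                   nControl = "integer", nCase = "integer",
                   controlLabel = "character", caseLabel = "character",
                   baseCq = "numeric", efficiency = "numeric",
                   sizeFactorSd = "numeric", seed = "integer"))

#' ddPCR simulation specification
#'
#' True copies per reaction for each gene x sample, plus droplet geometry;
#' droplet counts are generated per well as binomial draws with positive
#' probability \eqn{1 - e^{-\lambda}} under Poisson occupancy.
#'
#' @slot copies data.frame with columns \code{gene}, \code{sample},
#'   \code{group}, \code{copies} (>= 0, per reaction).
#' @slot dropletsPerWell,wellsPerSample Counts.
#' @slot dropletVolumeNl,reactionVolumeUl Physical constants.
#' @slot seed Mandatory integer seed.
#' @seealso [ddpcrSpec()], [genDropletCounts()]
#' @export
setClass("DdpcrSpec",
         slots = c(copies = "data.frame", dropletsPerWell = "integer",
                   wellsPerSample = "integer", dropletVolumeNl = "numeric",
                   reactionVolumeUl = "numeric", seed = "integer"))

#' Plasma panel simulation specification
#'
#' Group-wise location/scale parameters for plasma protein concentration
#' (zero-truncated normal by default, lognormal selectable), the Pearson
#' correlation planted between protein and paired whole-blood mRNA over the
#' paired subjects, and demographics. For the truncated-normal family the
#' \code{location} is the mean of the truncated distribution itself (the
#' underlying Gaussian mean is solved internally), so simulated group means
#' are centred on the preset values.
#'
#' @slot groups data.frame with columns \code{group}, \code{location}
#'   (ng/ml), \code{scale} (ng/ml) and \code{n}.
#' @slot correlation Planted protein/mRNA Pearson correlation in (-1, 1).
#' @slot pairedGroups Groups contributing paired mRNA measurements.
#' @slot family "truncnorm" or "lognormal".
#' @slot ageRange Two-element numeric range (years).
#' @slot femaleProportion Probability a subject is female.
#' @slot seed Mandatory integer seed.
#' @seealso [plasmaSpec()], [genPlasmaPanel()], [plasmaSpecPreset()]
#' @export
setClass("PlasmaSpec",
         slots = c(groups = "data.frame", correlation = "numeric",
                   pairedGroups = "character", family = "character",
                   ageRange = "numeric", femaleProportion = "numeric",
                   seed = "integer"))
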