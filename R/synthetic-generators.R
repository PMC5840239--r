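#' Generate a synthetic expression compendium
#'
#' Draws the per-experiment gene presence mask independently with the
#' spec's presence probability, then fills present cells with log2 ratios
#' carrying the planted module structure: genes of a module load on one
#' shared standard-normal latent factor per experiment with loading
#' \code{sign * sqrt(r)}, plus independent residual noise, all scaled by
#' \code{noiseSd}. Expected pairwise correlation between module genes i, j
#' is \code{sign_i * sign_j * r}. Deterministic under a fixed seed.
#'
#' @param spec A [compendiumSpec()].
#' @return An [ExpressionCompendium-class] object.
#' @examples
#' sp <- compendiumSpec(50, 10, modules = list(
#'   list(genes = c("g1", "g2", "g3"), r = 0.9)), seed = 1)
#' genCompendium(sp)
#' @export
genCompendium <- function(spec) {
  stopifnot(is(spec, "CompendiumSpec"))
  withr::with_seed(spec@seed, {
    nG <- spec@nGenes
    nE <- spec@nExperiments
    present <- matrix(stats::runif(nG * nE) <= spec@presenceProb, nG, nE)
    x <- matrix(stats::rnorm(nG * nE), nG, nE)
    for (m in spec@modules) {
      idx <- match(m$genes, spec@geneNames)
      f <- stats::rnorm(nE)
      x[idx, ] <- outer(m$sign * sqrt(m$r), f) +
        sqrt(1 - m$r) * matrix(stats::rnorm(length(idx) * nE),
                               length(idx), nE)
    }
    x <- x * spec@noiseSd
    x[!present] <- NA_real_
    dimnames(x) <- list(spec@geneNames,
                        paste0("exp", seq_len(nE)))
    ExpressionCompendium(x)
  })
}

#' Generate a synthetic case/control blood expression matrix
#'
#' Log2 expression = baseline + (for case samples) the direction-signed
#' log2 of the planted fold change + independent Gaussian noise.
#'
#' @param spec A [deSpec()].
#' @return A list with \code{se}, a
#'   [SummarizedExperiment::SummarizedExperiment] (assay
#'   \code{"log2expr"}, column data \code{group} = "control"/"case"), and
#'   \code{truth}, the planted per-gene signed fold changes.
#' @export
genBloodExpression <- function(spec) {
  stopifnot(is(spec, "DESpec"))
  withr::with_seed(spec@seed, {
    g <- spec@genes
    nG <- nrow(g)
    n <- spec@nControls + spec@nCases
    group <- rep(c("control", "case"), c(spec@nControls, spec@nCases))
    samples <- paste0(group, c(seq_len(spec@nControls),
                               seq_len(spec@nCases)))
    shift <- ifelse(g$direction == "up", 1, -1) * log2(g$fold_change)
    mu <- matrix(spec@baseline, nG, n) +
      outer(shift, as.numeric(group == "case"))
    x <- mu + matrix(stats::rnorm(nG * n, 0, spec@residualSd), nG, n)
    dimnames(x) <- list(g$gene, samples)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(log2expr = x),
      colData = S4Vectors::DataFrame(group = group, row.names = samples))
    list(se = se, truth = g)
  })
}

#' Generate a synthetic qPCR Cq experiment
#'
#' Implements \code{Cq = baseCq - log_E(quantity x sizeFactor) + noise}:
#' doubling the true quantity at E = 2 lowers the expected Cq by exactly
#' one cycle. All genes of a sample share that sample's size factor
#' (log2-normal with SD \code{sizeFactorSd}); reference genes have true
#' quantity 1 in every sample, targets have quantity \code{ratio} in case
#' samples.
#'
#' @param spec A [qpcrSpec()].
#' @return A list with \code{cq}, a [CqTable-class], and \code{truth}
#'   (planted target ratios and the per-sample size factors).
#' @export
genCqExperiment <- function(spec) {
  stopifnot(is(spec, "QpcrSpec"))
  withr::with_seed(spec@seed, {
    samples <- c(paste0(spec@controlLabel, seq_len(spec@nControl)),
                 paste0(spec@caseLabel, seq_len(spec@nCase)))
    group <- rep(c(spec@controlLabel, spec@caseLabel),
                 c(spec@nControl, spec@nCase))
    sfLog2 <- stats::rnorm(length(samples), 0, spec@sizeFactorSd)
    genes <- rbind(
      data.frame(gene = spec@targets$gene, ratio = spec@targets$ratio,
                 noise_sd = spec@targets$noise_sd,
                 is_reference = rep(FALSE, nrow(spec@targets))),
      data.frame(gene = spec@references$gene, ratio = 1,
                 noise_sd = spec@references$noise_sd,
                 is_reference = rep(TRUE, nrow(spec@references))))
    logE <- log2(spec@efficiency)
    rows <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
      qty <- ifelse(group == spec@caseLabel & !genes$is_reference[i],
                    genes$ratio[i], 1)
      cq <- spec@baseCq - (log2(qty) + sfLog2) / logE +
        stats::rnorm(length(samples), 0, genes$noise_sd[i])
      data.frame(gene = genes$gene[i], sample = samples, group = group,
                 is_reference = genes$is_reference[i], cq = cq)
    }))
    list(cq = CqTable(rows),
         truth = list(ratios = spec@targets,
                      caseLabel = spec@caseLabel,
                      controlLabel = spec@controlLabel,
                      sizeFactorsLog2 = stats::setNames(sfLog2, samples)))
  })
}

#' Generate synthetic ddPCR droplet counts
#'
#' Per well, positives are binomial(\code{dropletsPerWell},
#' \eqn{1 - e^{-\lambda}}) with \eqn{\lambda} = copies x droplet volume /
#' reaction volume (consistent units): Poisson droplet occupancy.
#'
#' @param spec A [ddpcrSpec()].
#' @return A list with \code{droplets}, a [DropletCounts-class], and
#'   \code{truth} (the spec's copies table).
#' @export
genDropletCounts <- function(spec) {
  stopifnot(is(spec, "DdpcrSpec"))
  withr::with_seed(spec@seed, {
    cp <- spec@copies
    lambda <- cp$copies * spec@dropletVolumeNl /
      (spec@reactionVolumeUl * 1000)
    p <- 1 - exp(-lambda)
    rows <- do.call(rbind, lapply(seq_len(spec@wellsPerSample), function(w) {
      data.frame(gene = cp$gene, sample = cp$sample, group = cp$group,
                 well = paste0("w", w),
                 positives = stats::rbinom(nrow(cp), spec@dropletsPerWell,
                                           p),
                 total = spec@dropletsPerWell)
    }))
    list(droplets = DropletCounts(rows,
                                  dropletVolumeNl = spec@dropletVolumeNl,
                                  reactionVolumeUl = spec@reactionVolumeUl),
         truth = cp)
  })
}

# Underlying Gaussian mean of a zero-truncated normal whose truncated mean
# is 'target' at scale 'sd'.
.truncNormMu <- function(target, sd) {
  f <- function(mu) {
    a <- -mu / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a)) - target
  }
  stats::uniroot(f, lower = target - 10 * sd, upper = target,
                 extendInt = "upX", tol = 1e-10)$root
}

#' Generate a synthetic plasma protein panel
#'
#' Concentrations are drawn per group from the spec's location-scale
#' family (zero-truncated normal by default, with the location equal to
#' the truncated mean; lognormal selectable). Subjects of the paired
#' groups receive whole-blood mRNA levels built from the pooled
#' standardized concentrations mixed with independent noise so that the
#' planted Pearson correlation holds on the raw concentration scale over
#' the pooled paired subjects. Ages are uniform over the spec's range and
#' sexes Bernoulli.
#'
#' @param spec A [plasmaSpec()].
#' @return A [PlasmaPanel-class] object.
#' @export
genPlasmaPanel <- function(spec) {
  stopifnot(is(spec, "PlasmaSpec"))
  withr::with_seed(spec@seed, {
    g <- spec@groups
    rows <- do.call(rbind, lapply(seq_len(nrow(g)), function(i) {
      n <- g$n[i]
      u <- stats::runif(n)
      conc <- if (spec@family == "truncnorm") {
        mu <- .truncNormMu(g$location[i], g$scale[i])
        pa <- stats::pnorm(-mu / g$scale[i])
        mu + g$scale[i] * stats::qnorm(pa + u * (1 - pa))
      } else {
        sdlog <- sqrt(log(1 + (g$scale[i] / g$location[i])^2))
        stats::qlnorm(u, log(g$location[i]) - sdlog^2 / 2, sdlog)
      }
      data.frame(subject = sprintf("%s_%02d", g$group[i], seq_len(n)),
                 group = g$group[i],
                 age = round(stats::runif(n, spec@ageRange[1],
                                          spec@ageRange[2])),
                 sex = ifelse(stats::runif(n) < spec@femaleProportion,
                              "F", "M"),
                 conc_ng_ml = conc, mrna_level = NA_real_)
    }))
    paired <- rows$group %in% spec@pairedGroups
    if (any(paired)) {
      z <- scale(rows$conc_ng_ml[paired])[, 1]
      rho <- spec@correlation
      rows$mrna_level[paired] <- 100 + 20 *
        (rho * z + sqrt(1 - rho^2) * stats::rnorm(sum(paired)))
    }
    PlasmaPanel(rows)
  })
}

#' Generate a synthetic ELISA plate from a plasma panel
#'
#' Maps each subject's (diluted) in-well concentration through a known
#' four-parameter logistic response and emits duplicate absorbances, plus
#' duplicate standards read off the same curve, with optional Gaussian
#' absorbance noise.
#'
#' @param panel A [PlasmaPanel-class].
#' @param params Named 4PL parameters \code{A0}, \code{D}, \code{C},
#'   \code{B} (see [StandardCurve-class]).
#' @param standards In-well standard concentrations (ng/ml); must span the
#'   diluted sample range.
#' @param dilutionFactor Plasma fold-dilution (default 20).
#' @param noiseSd Absorbance noise SD (default 0: noiseless plate).
#' @param seed Integer seed (only used when \code{noiseSd > 0}).
#' @return An [ElisaPlate-class] object.
#' @export
genElisaPlate <- function(panel,
                          params = c(A0 = 0.05, D = 3.2, C = 8, B = 1.3),
                          standards = c(0, 0.5, 1, 2, 4, 8, 16, 32),
                          dilutionFactor = 20, noiseSd = 0, seed = 1L) {
  stopifnot(is(panel, "PlasmaPanel"))
  d <- panel@data
  withr::with_seed(seed, {
    std <- expand.grid(conc_known = standards, replicate = 1:2)
    std$absorbance <- .fourPL(std$conc_known, params) +
      stats::rnorm(nrow(std), 0, noiseSd)
    sam <- expand.grid(idx = seq_len(nrow(d)), replicate = 1:2)
    sam <- data.frame(subject = d$subject[sam$idx],
                      absorbance = .fourPL(d$conc_ng_ml[sam$idx] /
                                             dilutionFactor, params) +
                        stats::rnorm(nrow(sam), 0, noiseSd),
                      replicate = sam$replicate)
    std$absorbance <- pmax(std$absorbance, 0)
    sam$absorbance <- pmax(sam$absorbance, 0)
    ElisaPlate(standards = std[, c("conc_known", "absorbance", "replicate")],
               samples = sam, dilutionFactor = dilutionFactor)
  })
}
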