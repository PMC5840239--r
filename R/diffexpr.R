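#' Signed fold change between two groups on log2 scale
#'
#' The linear-scale ratio is \code{2^(mean(case) - mean(control))}; it is
#' reported with magnitude >= 1 and a direction flag ("up" when the case
#' mean is at or above the control mean — ties break upward).
#'
#' @param caseValues,controlValues Log2 expression values (>= 1 value each).
#' @return A list with \code{direction} ("up"/"down") and
#'   \code{fc} (magnitude >= 1).
#' @examples
#' signedFoldChange(c(9, 9), c(8, 8)) # up, 2.0
#' @export
signedFoldChange <- function(caseValues, controlValues) {
  if (!length(caseValues) || !length(controlValues)) {
    stop("both groups need at least one value")
  }
  ratio <- 2^(mean(caseValues) - mean(controlValues))
  if (ratio >= 1) list(direction = "up", fc = ratio)
  else list(direction = "down", fc = 1 / ratio)
}

#' Two-group differential-expression screen
#'
#' Per gene, a one-way ANOVA across the two groups — computed as the
#' algebraically identical pooled-variance two-sided t test — plus the
#' signed fold change. A Benjamini-Hochberg column is attached for
#' information only; no filtering in this workflow uses it.
#'
#' @param x A [SummarizedExperiment::SummarizedExperiment] with a log2
#'   assay and a \code{group} column in its column data, or a genes x
#'   samples log2 matrix (then \code{groups} is required).
#' @param groups Sample group labels (one per column of \code{x}); ignored
#'   when \code{x} is a SummarizedExperiment.
#' @param case,control The two group labels (defaults "case"/"control").
#' @return A data.frame (one row per gene) with columns \code{gene},
#'   \code{p} (NA when within-group variance is zero in both groups),
#'   \code{direction}, \code{fc} and \code{bh_fdr}.
#' @export
deTest <- function(x, groups = NULL, case = "case", control = "control") {
  if (is(x, "SummarizedExperiment")) {
    groups <- as.character(SummarizedExperiment::colData(x)$group)
    x <- SummarizedExperiment::assay(x)
  }
  if (is.null(groups) || length(groups) != ncol(x)) {
    stop("'groups' must give one label per sample column")
  }
  if (!all(c(case, control) %in% groups)) {
    stop("both group labels must occur in 'groups'")
  }
  if (length(setdiff(unique(groups), c(case, control)))) {
    stop("exactly two groups expected")
  }
  if (sum(groups == case) < 2 || sum(groups == control) < 2) {
    stop("each group needs >= 2 samples")
  }
  caseIdx <- groups == case
  ctrlIdx <- groups == control
  res <- lapply(seq_len(nrow(x)), function(i) {
    a <- x[i, caseIdx]
    b <- x[i, ctrlIdx]
    p <- tryCatch(stats::t.test(a, b, var.equal = TRUE)$p.value,
                  error = function(e) NA_real_)
    sfc <- signedFoldChange(a, b)
    data.frame(p = p, direction = sfc$direction, fc = sfc$fc)
  })
  out <- do.call(rbind, res)
  out <- cbind(gene = rownames(x), out)
  out$bh_fdr <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Primary differential-expression screen
#'
#' Keeps genes with fold-change magnitude >= \code{fcThreshold} and
#' p <= \code{pThreshold}; both boundaries inclusive. Genes whose p-value
#' is undefined (zero-variance degenerate fits) are excluded.
#'
#' @param de A DE table from [deTest()] (columns \code{gene}, \code{p},
#'   \code{direction}, \code{fc}).
#' @param fcThreshold Fold-change cutoff (default 1.2).
#' @param pThreshold p-value cutoff (default 0.05).
#' @return The filtered DE table.
#' @export
primaryScreen <- function(de, fcThreshold = 1.2, pThreshold = 0.05) {
  .assertColumns(de, c("gene", "p", "fc"), "'de'")
  keep <- !is.na(de$p) & de$p <= pThreshold & de$fc >= fcThreshold
  de[keep, , drop = FALSE]
}

#' Multi-criteria candidate-panel refinement gate
#'
#' Assigns each screened gene to one of three acceptance branches (checked
#' in order; the first match wins):
#' \describe{
#'   \item{A}{p <= 0.005 and fold change >= 1.5 — statistical stringency
#'     alone.}
#'   \item{B}{supported by the correlation analysis or the literature, with
#'     0.005 < p <= 0.05 and fold change >= 1.5.}
#'   \item{C}{supported by the correlation analysis or the literature, with
#'     p <= 0.005 and fold change in [1.2, 1.5).}
#' }
#' Anything else is rejected. The fold-change interval of branch C is
#' half-open so branches A and C are disjoint, and branch B's p interval
#' is open at 0.005 so branches A and B are disjoint. Direction plays no
#' role. Whether branch C truly requires external evidence is an open
#' reading of the published criteria; the default requires it, and
#' \code{branchCRequiresEvidence = FALSE} selects the permissive reading.
#'
#' @param de A DE table (columns \code{gene}, \code{p}, \code{direction},
#'   \code{fc}).
#' @param evidence data.frame with columns \code{gene}, \code{ca}
#'   (in correlation analysis) and \code{literature}; genes without an
#'   evidence row get both flags FALSE.
#' @param branchCRequiresEvidence See above (default TRUE).
#' @return A candidate panel data.frame with columns \code{gene},
#'   \code{p}, \code{direction}, \code{fc}, \code{ca}, \code{literature},
#'   \code{branch} ("A", "B", "C" or "rejected").
#' @examples
#' refinePanel(humanCandidatePanel()[, c("gene", "p", "direction", "fc")],
#'             humanCandidatePanel()[, c("gene", "ca", "literature")])
#' @export
refinePanel <- function(de, evidence, branchCRequiresEvidence = TRUE) {
  .assertColumns(de, c("gene", "p", "direction", "fc"), "'de'")
  .assertColumns(evidence, c("gene", "ca", "literature"), "'evidence'")
  idx <- match(de$gene, evidence$gene)
  ca <- ifelse(is.na(idx), FALSE, as.logical(evidence$ca[idx]))
  lit <- ifelse(is.na(idx), FALSE, as.logical(evidence$literature[idx]))
  evid <- ca | lit
  p <- de$p
  fc <- de$fc
  branch <- rep("rejected", nrow(de))
  okC <- p <= 0.005 & fc >= 1.2 & fc < 1.5 &
    (evid | !branchCRequiresEvidence)
  branch[okC] <- "C"
  branch[evid & p > 0.005 & p <= 0.05 & fc >= 1.5] <- "B"
  branch[p <= 0.005 & fc >= 1.5] <- "A"
  branch[is.na(p)] <- "rejected"
  data.frame(gene = de$gene, p = de$p, direction = de$direction,
             fc = de$fc, ca = ca, literature = lit, branch = branch)
}
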