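#' Accessors for TransMark containers
#'
#' @param x A TransMark S4 object.
#' @return \code{geneIds}: character vector of gene ids;
#'   \code{experimentIds}: character vector of experiment ids;
#'   \code{ratioMatrix}: the genes x experiments log2-ratio matrix;
#'   \code{corValues} / \code{copresenceCounts}: the correlation and
#'   co-presence matrices; \code{tableData}: the underlying tidy
#'   data.frame of an assay container.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("experimentIds", function(x) standardGeneric("experimentIds"))
#' @rdname accessors
#' @export
setGeneric("ratioMatrix", function(x) standardGeneric("ratioMatrix"))
#' @rdname accessors
#' @export
setGeneric("corValues", function(x) standardGeneric("corValues"))
#' @rdname accessors
#' @export
setGeneric("copresenceCounts", function(x) standardGeneric("copresenceCounts"))
#' @rdname accessors
#' @export
setGeneric("tableData", function(x) standardGeneric("tableData"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionCompendium", function(x) rownames(x@ratios))
#' @rdname accessors
#' @export
setMethod("experimentIds", "ExpressionCompendium",
          function(x) colnames(x@ratios))
#' @rdname accessors
#' @export
setMethod("ratioMatrix", "ExpressionCompendium", function(x) x@ratios)
#' @rdname accessors
#' @export
setMethod("geneIds", "PairwiseCorrelation", function(x) rownames(x@r))
#' @rdname accessors
#' @export
setMethod("corValues", "PairwiseCorrelation", function(x) x@r)
#' @rdname accessors
#' @export
setMethod("copresenceCounts", "PairwiseCorrelation", function(x) x@nPairs)

#' @rdname accessors
#' @export
setMethod("tableData", "CqTable", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("tableData", "DropletCounts", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("tableData", "PlasmaPanel", function(x) x@data)

#' @rdname accessors
#' @param object Object to display.
#' @export
setMethod("show", "ExpressionCompendium", function(object) {
  m <- object@ratios
  cat("ExpressionCompendium:", nrow(m), "genes x", ncol(m), "experiments\n")
  cat(sprintf("  presence: %.1f%% of gene x experiment cells\n",
              100 * mean(!is.na(m))))
})

#' @rdname accessors
#' @export
setMethod("show", "PairwiseCorrelation", function(object) {
  cat("PairwiseCorrelation:", nrow(object@r), "genes, minPairs =",
      object@minPairs, "\n")
  off <- object@r[upper.tri(object@r)]
  cat(sprintf("  defined off-diagonal entries: %d of %d\n",
              sum(!is.na(off)), length(off)))
})

#' @rdname accessors
#' @export
setMethod("show", "CqTable", function(object) {
  d <- object@data
  cat("CqTable:", length(unique(d$gene)), "genes,",
      length(unique(d$sample)), "samples,",
      sum(d$is_reference[!duplicated(d$gene)]), "reference gene(s)\n")
})

#' @rdname accessors
#' @export
setMethod("show", "DropletCounts", function(object) {
  d <- object@data
  cat("DropletCounts:", length(unique(d$gene)), "genes,",
      length(unique(d$sample)), "samples,", nrow(d), "wells\n")
  cat(sprintf("  droplet %.2f nL, reaction %.1f uL\n",
              object@dropletVolumeNl, object@reactionVolumeUl))
})

#' @rdname accessors
#' @export
setMethod("show", "PlasmaPanel", function(object) {
  d <- object@data
  cat("PlasmaPanel:", nrow(d), "subjects in",
      length(unique(d$group)), "group(s);",
      sum(!is.na(d$mrna_level)), "with paired mRNA\n")
})

#' @rdname accessors
#' @export
setMethod("show", "ElisaPlate", function(object) {
  cat("ElisaPlate:", length(unique(object@standards$conc_known)),
      "standard levels,", length(unique(object@samples$subject)),
      "samples, dilution x", object@dilutionFactor, "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "StandardCurve", function(object) {
  p <- object@params
  cat(sprintf("StandardCurve (4PL): A0=%.4g D=%.4g C=%.4g B=%.4g\n",
              p["A0"], p["D"], p["C"], p["B"]))
  cat(sprintf("  invertible in-well range: %.4g - %.4g ng/ml\n",
              object@concRange[1], object@concRange[2]))
})
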