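#' Construct an ExpressionCompendium
#'
#' @param ratios Genes x experiments numeric matrix of log2 ratios with
#'   \code{NA} marking genes absent from an experiment's platform.
#' @return An [ExpressionCompendium-class] object.
#' @examples
#' m <- matrix(rnorm(6), 2, 3,
#'             dimnames = list(c("g1", "g2"), paste0("e", 1:3)))
#' ExpressionCompendium(m)
#' @export
ExpressionCompendium <- function(ratios) {
  new("ExpressionCompendium", ratios = as.matrix(ratios))
}

#' Construct a CqTable
#'
#' @param data data.frame with columns \code{gene}, \code{sample},
#'   \code{group}, \code{is_reference}, \code{cq}.
#' @return A [CqTable-class] object.
#' @export
CqTable <- function(data) {
  .assertColumns(data, c("gene", "sample", "group", "is_reference", "cq"),
                 "CqTable data")
  data$gene <- as.character(data$gene)
  data$sample <- as.character(data$sample)
  data$group <- as.character(data$group)
  data$is_reference <- as.logical(data$is_reference)
  new("CqTable", data = as.data.frame(data))
}

#' Construct a DropletCounts object
#'
#' @param data data.frame with columns \code{gene}, \code{sample},
#'   \code{group}, \code{well}, \code{positives}, \code{total}.
#' @param dropletVolumeNl Droplet volume in nanolitres. The default 0.85 nL
#'   is the droplet-generator convention for the instrument class this
#'   models.
#' @param reactionVolumeUl Reaction volume in microlitres (default 20).
#' @return A [DropletCounts-class] object.
#' @export
DropletCounts <- function(data, dropletVolumeNl = 0.85,
                          reactionVolumeUl = 20) {
  .assertColumns(data, c("gene", "sample", "group", "well", "positives",
                         "total"), "DropletCounts data")
  data$gene <- as.character(data$gene)
  data$sample <- as.character(data$sample)
  data$group <- as.character(data$group)
  new("DropletCounts", data = as.data.frame(data),
      dropletVolumeNl = as.numeric(dropletVolumeNl),
      reactionVolumeUl = as.numeric(reactionVolumeUl))
}

#' Construct a PlasmaPanel
#'
#' @param data data.frame with columns \code{subject}, \code{group},
#'   \code{age}, \code{sex}, \code{conc_ng_ml}, \code{mrna_level}.
#' @return A [PlasmaPanel-class] object.
#' @export
PlasmaPanel <- function(data) {
  if (!"mrna_level" %in% names(data)) data$mrna_level <- NA_real_
  .assertColumns(data, c("subject", "group", "age", "sex", "conc_ng_ml",
                         "mrna_level"), "PlasmaPanel data")
  data$subject <- as.character(data$subject)
  data$group <- as.character(data$group)
  data$sex <- as.character(data$sex)
  new("PlasmaPanel", data = as.data.frame(data))
}

#' Construct an ElisaPlate
#'
#' @param standards data.frame with columns \code{conc_known},
#'   \code{absorbance}, \code{replicate}.
#' @param samples data.frame with columns \code{subject},
#'   \code{absorbance}, \code{replicate}.
#' @param dilutionFactor Plasma fold-dilution before the assay (default 20,
#'   i.e. 10 ul diluted to 200 ul).
#' @return An [ElisaPlate-class] object.
#' @export
ElisaPlate <- function(standards, samples, dilutionFactor = 20) {
  new("ElisaPlate", standards = as.data.frame(standards),
      samples = as.data.frame(samples),
      dilutionFactor = as.numeric(dilutionFactor))
}
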