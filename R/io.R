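#' Read and write TransMark tables
#'
#' Plain-text interchange formats: the compendium as long TSV
#' (\code{experiment_id  gene_id  log2_ratio}; absent genes simply have no
#' row), the expression matrix as genes x samples TSV with a sample-group
#' map TSV (\code{sample  group}), the Cq table, droplet counts and plasma
#' panel as tidy TSV, and the ELISA plate as CSV
#' (\code{role  id  conc_known  absorbance  replicate}). Write/read
#' round-trips reproduce the objects.
#'
#' @param x Object to write.
#' @param path File path.
#' @param geneNames Optional full gene universe for [readCompendium()]
#'   (genes absent everywhere cannot be inferred from the long format).
#' @param dropletVolumeNl,reactionVolumeUl Constants attached on read
#'   (droplet TSV carries counts only).
#' @param dilutionFactor Dilution factor attached when reading a plate CSV.
#' @name transmark-io
NULL

#' @rdname transmark-io
#' @export
writeCompendium <- function(x, path) {
  stopifnot(is(x, "ExpressionCompendium"))
  m <- x@ratios
  idx <- which(!is.na(m), arr.ind = TRUE)
  long <- data.frame(experiment_id = colnames(m)[idx[, 2]],
                     gene_id = rownames(m)[idx[, 1]],
                     log2_ratio = m[idx])
  long <- long[order(long$experiment_id, long$gene_id), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname transmark-io
#' @export
readCompendium <- function(path, geneNames = NULL) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  .assertColumns(long, c("experiment_id", "gene_id", "log2_ratio"),
                 "compendium TSV")
  genes <- if (is.null(geneNames)) sort(unique(long$gene_id)) else geneNames
  exps <- sort(unique(long$experiment_id))
  m <- matrix(NA_real_, length(genes), length(exps),
              dimnames = list(genes, exps))
  m[cbind(match(long$gene_id, genes),
          match(long$experiment_id, exps))] <- long$log2_ratio
  ExpressionCompendium(m)
}

#' @rdname transmark-io
#' @export
writeCqTable <- function(x, path) {
  stopifnot(is(x, "CqTable"))
  utils::write.table(
    x@data[c("gene", "sample", "group", "is_reference", "cq")], path,
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname transmark-io
#' @export
readCqTable <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  CqTable(d)
}

#' @rdname transmark-io
#' @export
writeDropletCounts <- function(x, path) {
  stopifnot(is(x, "DropletCounts"))
  utils::write.table(
    x@data[c("gene", "sample", "group", "well", "positives", "total")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname transmark-io
#' @export
readDropletCounts <- function(path, dropletVolumeNl = 0.85,
                              reactionVolumeUl = 20) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  DropletCounts(d, dropletVolumeNl = dropletVolumeNl,
                reactionVolumeUl = reactionVolumeUl)
}

#' @rdname transmark-io
#' @export
writePlasmaPanel <- function(x, path) {
  stopifnot(is(x, "PlasmaPanel"))
  utils::write.table(
    x@data[c("subject", "group", "age", "sex", "conc_ng_ml",
             "mrna_level")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname transmark-io
#' @export
readPlasmaPanel <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  PlasmaPanel(d)
}

#' @rdname transmark-io
#' @export
writeElisaPlate <- function(x, path) {
  stopifnot(is(x, "ElisaPlate"))
  std <- data.frame(role = "standard", id = "standard",
                    conc_known = x@standards$conc_known,
                    absorbance = x@standards$absorbance,
                    replicate = x@standards$replicate)
  sam <- data.frame(role = "sample", id = x@samples$subject,
                    conc_known = NA_real_,
                    absorbance = x@samples$absorbance,
                    replicate = x@samples$replicate)
  utils::write.csv(rbind(std, sam), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname transmark-io
#' @export
readElisaPlate <- function(path, dilutionFactor = 20) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  .assertColumns(d, c("role", "id", "conc_known", "absorbance",
                      "replicate"), "ELISA plate CSV")
  std <- d[d$role == "standard",
           c("conc_known", "absorbance", "replicate")]
  sam <- d[d$role == "sample", c("id", "absorbance", "replicate")]
  names(sam)[1] <- "subject"
  ElisaPlate(standards = std, samples = sam,
             dilutionFactor = dilutionFactor)
}

#' @rdname transmark-io
#' @param se A SummarizedExperiment with a log2 assay and group column
#'   data.
#' @param matrixPath,groupsPath Paths for the expression TSV and the
#'   sample-group map TSV.
#' @export
writeExpressionMatrix <- function(se, matrixPath, groupsPath) {
  m <- SummarizedExperiment::assay(se)
  utils::write.table(
    data.frame(gene = rownames(m), m, check.names = FALSE),
    matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample = colnames(m),
               group = SummarizedExperiment::colData(se)$group),
    groupsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(matrixPath)
}

#' @rdname transmark-io
#' @export
readExpressionMatrix <- function(matrixPath, groupsPath) {
  d <- utils::read.delim(matrixPath, check.names = FALSE,
                         stringsAsFactors = FALSE)
  g <- utils::read.delim(groupsPath, stringsAsFactors = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$gene
  if (!identical(sort(colnames(m)), sort(g$sample))) {
    stop("sample ids differ between matrix and group map")
  }
  g <- g[match(colnames(m), g$sample), ]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = m),
    colData = S4Vectors::DataFrame(group = g$group,
                                   row.names = g$sample))
}
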