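#' Pairwise-complete gene-gene correlation over a compendium
#'
#' For each unordered gene pair, computes the Pearson correlation over
#' exactly the experiments where both genes were present on the platform.
#' Pairs with fewer than \code{minPairs} co-presences, or a zero-variance
#' co-present subset, are undefined (\code{NA}) — never reported as 0. The
#' co-presence count is recorded for every pair. The diagonal is 1
#' wherever a gene is present in at least two experiments.
#'
#' @param compendium An [ExpressionCompendium-class].
#' @param genes Optional subset of gene ids to correlate (default: all).
#' @param minPairs Minimum co-presence count for a defined coefficient
#'   (>= 3; default 6, so coefficients are not dominated by 2-3 point
#'   artifacts).
#' @return A [PairwiseCorrelation-class] object.
#' @examples
#' sp <- compendiumSpec(100, 5, modules = list(
#'   list(genes = c("g1", "g2"), r = 0.8)), seed = 1)
#' pairwiseCorrelation(genCompendium(sp))
#' @export
pairwiseCorrelation <- function(compendium, genes = NULL, minPairs = 6) {
  stopifnot(is(compendium, "ExpressionCompendium"))
  minPairs <- .assertCount(minPairs, "minPairs", 3L)
  m <- compendium@ratios
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(m))
    if (length(missing)) {
      stop("genes not in the compendium universe: ",
           paste(missing, collapse = ", "))
    }
    m <- m[genes, , drop = FALSE]
  }
  tm <- t(m)
  np <- crossprod(!is.na(tm))
  storage.mode(np) <- "integer"
  r <- suppressWarnings(stats::cor(tm, use = "pairwise.complete.obs"))
  r[np < minPairs] <- NA_real_
  diag(r) <- ifelse(diag(np) >= 2L, 1, NA_real_)
  new("PairwiseCorrelation", r = r, nPairs = np, minPairs = minPairs)
}

.modulesForSet <- function(r, set, threshold) {
  set <- sort(set)
  sub <- r[set, set, drop = FALSE]
  adj <- !is.na(sub) & sub >= threshold
  diag(adj) <- FALSE
  modules <- list()
  if (any(adj)) {
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    cl <- igraph::max_cliques(g, min = 2)
    members <- lapply(cl, function(v) sort(igraph::V(g)$name[v]))
    ord <- order(-lengths(members), vapply(members, `[`, "", 1L))
    members <- members[ord]
    modules <- lapply(members, function(genes) {
      rr <- sub[genes, genes]
      vals <- rr[upper.tri(rr)]
      others <- setdiff(set, genes)
      anti <- character(0)
      if (length(others)) {
        cross <- r[others, genes, drop = FALSE]
        meanR <- rowMeans(cross, na.rm = TRUE)
        meanR[rowSums(!is.na(cross)) == 0L] <- NA_real_
        anti <- sort(names(meanR)[!is.na(meanR) & meanR <= -threshold])
      }
      list(genes = genes, minR = min(vals), meanR = mean(vals),
           anticorrelated = anti)
    })
  }
  pairs <- sub[upper.tri(sub)]
  list(modules = modules,
       nPairsDefined = sum(!is.na(pairs)),
       nPairsUndefined = sum(is.na(pairs)))
}

#' Detect correlated modules among regulated gene sets
#'
#' Within the up- and (separately) down-regulated gene sets, finds all
#' maximal subsets of size >= 2 whose defined pairwise correlations are
#' all at or above the threshold (exact maximal-clique enumeration on the
#' thresholded correlation graph; undefined coefficients never support
#' membership). For each module it also lists the same-direction genes
#' whose mean defined correlation against the module is at or below
#' \code{-threshold} — the genes that are "usually negatively correlated"
#' with the module in prior experiments. Overlapping cliques are reported
#' as-is, never merged; output is invariant to gene input order.
#'
#' @param corr A [PairwiseCorrelation-class].
#' @param upSet,downSet Disjoint character vectors of gene ids.
#' @param threshold Correlation threshold in (0, 1).
#' @return A list with elements \code{up} and \code{down}, each holding
#'   \code{modules} (each with \code{genes}, \code{minR}, \code{meanR},
#'   \code{anticorrelated}) and defined/undefined pair counts, plus the
#'   \code{threshold} used.
#' @export
correlatedModules <- function(corr, upSet, downSet = character(0),
                              threshold) {
  stopifnot(is(corr, "PairwiseCorrelation"))
  .assertScalar(threshold, "threshold", 0, 1, TRUE, TRUE)
  if (length(intersect(upSet, downSet))) {
    stop("upSet and downSet must be disjoint")
  }
  known <- rownames(corr@r)
  missing <- setdiff(c(upSet, downSet), known)
  if (length(missing)) {
    stop("genes not in the correlation matrix: ",
         paste(missing, collapse = ", "))
  }
  list(up = .modulesForSet(corr@r, upSet, threshold),
       down = .modulesForSet(corr@r, downSet, threshold),
       threshold = threshold)
}

#' Heatmap gene ordering by correlation similarity
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - r;
#' undefined correlations contribute the neutral dissimilarity 1. Returns
#' the leaf order, usable to arrange a correlation heatmap.
#'
#' @param corr A [PairwiseCorrelation-class].
#' @param genes Optional subset of gene ids (default: all).
#' @return Character vector of gene ids in dendrogram leaf order.
#' @export
correlationOrdering <- function(corr, genes = NULL) {
  stopifnot(is(corr, "PairwiseCorrelation"))
  r <- corr@r
  if (!is.null(genes)) r <- r[genes, genes, drop = FALSE]
  d <- 1 - r
  d[is.na(d)] <- 1
  diag(d) <- 0
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  rownames(r)[hc$order]
}
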