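#' Collapse technical qPCR replicates
#'
#' Arithmetic mean of the replicate Cq values per gene x sample, with a QC
#' flag marking replicate sets whose max-min spread exceeds
#' \code{maxSpread} cycles.
#'
#' @param cq A [CqTable-class] possibly holding several rows per gene x
#'   sample.
#' @param maxSpread QC threshold on the replicate spread (default 0.5
#'   cycles).
#' @return A [CqTable-class] with one row per gene x sample and an extra
#'   \code{qc_wide_spread} column.
#' @export
collapseTechnicalReplicates <- function(cq, maxSpread = 0.5) {
  stopifnot(is(cq, "CqTable"))
  d <- cq@data
  key <- interaction(d$gene, d$sample, drop = TRUE)
  agg <- do.call(rbind, lapply(split(d, key), function(x) {
    data.frame(gene = x$gene[1], sample = x$sample[1], group = x$group[1],
               is_reference = x$is_reference[1], cq = mean(x$cq),
               qc_wide_spread = diff(range(x$cq)) > maxSpread)
  }))
  rownames(agg) <- NULL
  CqTable(agg[order(agg$gene, agg$sample), ])
}

#' Relative quantities from Cq values
#'
#' Mean-calibrator convention: \code{RQ(g, s) = E_g^(mean Cq_g - Cq(g, s))},
#' with the calibrator being each gene's mean Cq across all its samples. A
#' sample sitting exactly at the gene's mean Cq has RQ = 1; at E = 2 each
#' cycle below the mean doubles RQ. Fold changes and test statistics
#' downstream are invariant to the calibrator choice.
#'
#' @param cq A [CqTable-class] (one row per gene x sample; collapse
#'   replicates first if needed).
#' @param efficiency Amplification factor in (1, 2]: a single value for
#'   all genes or a named per-gene vector (default 2).
#' @return data.frame with columns \code{gene}, \code{sample},
#'   \code{group}, \code{is_reference}, \code{rq}.
#' @export
relativeQuantities <- function(cq, efficiency = 2) {
  stopifnot(is(cq, "CqTable"))
  d <- cq@data
  if (anyDuplicated(d[c("gene", "sample")])) {
    stop("multiple rows per gene x sample; ",
         "collapse with collapseTechnicalReplicates() first")
  }
  eff <- if (length(efficiency) == 1L && is.null(names(efficiency))) {
    stats::setNames(rep(efficiency, length(unique(d$gene))),
                    unique(d$gene))
  } else efficiency
  if (!all(d$gene %in% names(eff))) {
    stop("efficiency missing for gene(s): ",
         paste(setdiff(unique(d$gene), names(eff)), collapse = ", "))
  }
  if (any(eff <= 1 | eff > 2)) stop("efficiencies must be in (1, 2]")
  meanCq <- tapply(d$cq, d$gene, mean)
  d$rq <- eff[d$gene]^(meanCq[d$gene] - d$cq)
  d[c("gene", "sample", "group", "is_reference", "rq")]
}

#' geNorm reference-gene stability
#'
#' For every candidate pair (j, k), the pairwise variation \code{V_jk} is
#' the standard deviation over samples of \code{log2(RQ_j / RQ_k)}; the
#' stability of candidate j is \code{M_j}, the mean of \code{V_jk} over
#' all other candidates (lower = more stable). The coefficient of
#' variation \code{CV_j} is SD/mean of candidate j's quantities after
#' normalization by the per-sample geometric mean of all candidates.
#' Shared per-sample scale (RNA input) cancels in both statistics. All
#' statistics are computed over the samples shared by every candidate.
#' The classic iterative ranking (repeatedly recompute M on the surviving
#' set and drop the least stable candidate) is also reported.
#'
#' @param rq Relative-quantity table from [relativeQuantities()].
#' @param candidates Candidate gene ids (default: all reference-flagged
#'   genes in \code{rq}); >= 3 required.
#' @return A list: \code{stability} (data.frame \code{gene}, \code{M},
#'   \code{CV}, ascending in M), \code{topPair} (two most stable
#'   candidates), \code{exclusionOrder} (iterative drop order, least
#'   stable first) and \code{finalPair} (the iterative survivors).
#' @export
geNorm <- function(rq, candidates = NULL) {
  .assertColumns(rq, c("gene", "sample", "rq"), "'rq'")
  if (is.null(candidates)) {
    if (!"is_reference" %in% names(rq)) {
      stop("no 'candidates' given and no is_reference column present")
    }
    candidates <- sort(unique(rq$gene[rq$is_reference]))
  }
  if (length(candidates) < 3L) stop("need >= 3 candidate reference genes")
  absent <- setdiff(candidates, unique(rq$gene))
  if (length(absent)) {
    stop("candidate(s) not measured: ", paste(absent, collapse = ", "))
  }
  sub <- rq[rq$gene %in% candidates, ]
  wide <- tapply(sub$rq, list(sub$sample, sub$gene), mean)
  wide <- wide[, candidates, drop = FALSE]
  shared <- rownames(wide)[stats::complete.cases(wide)]
  if (length(shared) < 3L) {
    stop("candidates share only ", length(shared),
         " complete samples; >= 3 required")
  }
  lw <- log2(wide[shared, , drop = FALSE])
  mValues <- function(l) {
    k <- ncol(l)
    V <- matrix(0, k, k, dimnames = list(colnames(l), colnames(l)))
    for (j in seq_len(k - 1)) {
      for (h in (j + 1):k) {
        V[j, h] <- V[h, j] <- stats::sd(l[, j] - l[, h])
      }
    }
    rowSums(V) / (k - 1)
  }
  M <- mValues(lw)
  nrqLog <- lw - rowMeans(lw)
  nrq <- 2^nrqLog
  CV <- apply(nrq, 2, function(v) stats::sd(v) / mean(v))
  stability <- data.frame(gene = colnames(lw), M = M, CV = CV)
  stability <- stability[order(stability$M, stability$gene), ]
  rownames(stability) <- NULL
  # iterative geNorm ranking
  remaining <- colnames(lw)
  exclusion <- character(0)
  while (length(remaining) > 2L) {
    Mi <- mValues(lw[, remaining, drop = FALSE])
    worst <- names(which.max(Mi))
    exclusion <- c(exclusion, worst)
    remaining <- setdiff(remaining, worst)
  }
  list(stability = stability,
       topPair = stability$gene[1:2],
       exclusionOrder = exclusion,
       finalPair = sort(remaining))
}

#' Normalize relative quantities against reference genes
#'
#' \code{NRQ(g, s) = RQ(g, s) / geometric mean over references r of
#' RQ(r, s)}. After normalization the per-sample geometric mean of the
#' reference-gene NRQs is exactly 1, and multiplying every gene of one
#' sample by a common factor leaves all NRQs unchanged.
#'
#' @param rq Relative-quantity table from [relativeQuantities()].
#' @param references Reference gene ids (default: the reference-flagged
#'   genes in \code{rq}).
#' @return data.frame with columns \code{gene}, \code{sample},
#'   \code{group}, \code{is_reference}, \code{nrq}.
#' @export
normalizeRq <- function(rq, references = NULL) {
  .assertColumns(rq, c("gene", "sample", "rq"), "'rq'")
  if (is.null(references)) {
    references <- sort(unique(rq$gene[rq$is_reference]))
  }
  if (!length(references)) stop("no reference genes given")
  ref <- rq[rq$gene %in% references, ]
  bySample <- split(ref, ref$sample)
  allSamples <- unique(rq$sample)
  bad <- vapply(allSamples, function(s) {
    !s %in% names(bySample) ||
      length(unique(bySample[[s]]$gene)) < length(references)
  }, logical(1))
  if (any(bad)) {
    stop("missing reference measurement(s) in sample(s): ",
         paste(allSamples[bad], collapse = ", "))
  }
  denom <- vapply(bySample, function(x) geoMean(x$rq), numeric(1))
  out <- rq
  out$nrq <- out$rq / denom[out$sample]
  out$rq <- NULL
  out
}

#' Two-group statistics on normalized quantities
#'
#' Per gene: a two-sided unpaired t test on log2-transformed values
#' (equal-variance by default, Welch selectable) and the signed fold
#' change \code{2^(mean log2 case - mean log2 control)} with the
#' magnitude >= 1 convention. Genes with fewer than two quantifiable
#' samples in either group are reported as not analysable rather than
#' silently dropped.
#'
#' @param x Long table with columns \code{gene}, \code{sample},
#'   \code{group} and one value column (auto-detected among \code{nrq},
#'   \code{ncopies}, \code{copies}, \code{rq}, \code{value}, or named via
#'   \code{valueCol}); values must be > 0 where quantifiable.
#' @param case,control Group labels (defaults "snl"/"sham").
#' @param valueCol Optional explicit value column name.
#' @param welch Use the Welch (unequal-variance) t test (default FALSE).
#' @return data.frame with one row per gene: \code{gene},
#'   \code{direction}, \code{fc}, \code{p}, \code{n_case},
#'   \code{n_control}, \code{analysable}.
#' @export
groupStats <- function(x, case = "snl", control = "sham",
                       valueCol = NULL, welch = FALSE) {
  .assertColumns(x, c("gene", "sample", "group"), "'x'")
  if (is.null(valueCol)) {
    valueCol <- intersect(c("nrq", "ncopies", "copies", "rq", "value"),
                          names(x))[1]
    if (is.na(valueCol)) stop("no value column found")
  }
  v <- x[[valueCol]]
  res <- lapply(split(seq_len(nrow(x)), x$gene), function(idx) {
    a <- v[idx][x$group[idx] == case]
    b <- v[idx][x$group[idx] == control]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(gene = x$gene[idx][1], direction = NA_character_,
                        fc = NA_real_, p = NA_real_,
                        n_case = length(a), n_control = length(b),
                        analysable = FALSE))
    }
    la <- log2(a)
    lb <- log2(b)
    p <- tryCatch(stats::t.test(la, lb, var.equal = !welch)$p.value,
                  error = function(e) NA_real_)
    sfc <- signedFoldChange(la, lb)
    data.frame(gene = x$gene[idx][1], direction = sfc$direction,
               fc = sfc$fc, p = p, n_case = length(a),
               n_control = length(b), analysable = TRUE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Absolute copies per reaction from droplet counts
#'
#' Replicate wells are pooled per gene x sample (summing positives and
#' totals) before Poisson inversion: the mean copies per droplet is
#' \eqn{\lambda = -\ln(1 - positives/total)} and copies per reaction is
#' \eqn{\lambda \times reactionVolume / dropletVolume} (volumes in
#' consistent units; nL per droplet against uL x 1000 per reaction). All
#' droplets positive means the well set is saturated and the copy number
#' undefined (flagged); zero positives is a valid zero.
#'
#' @param droplets A [DropletCounts-class].
#' @return data.frame with columns \code{gene}, \code{sample},
#'   \code{group}, \code{positives}, \code{total}, \code{lambda},
#'   \code{copies}, \code{saturated}.
#' @export
poissonCopies <- function(droplets) {
  stopifnot(is(droplets, "DropletCounts"))
  d <- droplets@data
  scalePerReaction <- droplets@reactionVolumeUl * 1000 /
    droplets@dropletVolumeNl
  key <- interaction(d$gene, d$sample, drop = TRUE)
  out <- do.call(rbind, lapply(split(d, key), function(x) {
    P <- sum(x$positives)
    Tt <- sum(x$total)
    saturated <- P == Tt
    lambda <- if (saturated) NA_real_ else -log(1 - P / Tt)
    data.frame(gene = x$gene[1], sample = x$sample[1], group = x$group[1],
               positives = P, total = Tt, lambda = lambda,
               copies = lambda * scalePerReaction, saturated = saturated)
  }))
  rownames(out) <- NULL
  out[order(out$gene, out$sample), ]
}

#' Normalize absolute copies against reference genes
#'
#' Divides each gene's copies per reaction by the per-sample geometric
#' mean of the reference genes' copies. Scaling every gene of a sample by
#' a common factor leaves the normalized values unchanged.
#'
#' @param copies Copies table from [poissonCopies()].
#' @param references Reference gene ids (e.g. \code{c("Rpl13a", "Ubc")}).
#' @return data.frame with columns \code{gene}, \code{sample},
#'   \code{group}, \code{ncopies}.
#' @export
normalizeCopies <- function(copies, references) {
  .assertColumns(copies, c("gene", "sample", "group", "copies"),
                 "'copies'")
  if (!length(references)) stop("no reference genes given")
  ref <- copies[copies$gene %in% references, ]
  bySample <- split(ref, ref$sample)
  allSamples <- unique(copies$sample)
  bad <- vapply(allSamples, function(s) {
    x <- bySample[[s]]
    is.null(x) || length(unique(x$gene)) < length(references) ||
      any(is.na(x$copies)) || any(x$copies <= 0)
  }, logical(1))
  if (any(bad)) {
    stop("reference copies missing or zero in sample(s): ",
         paste(allSamples[bad], collapse = ", "))
  }
  denom <- vapply(bySample, function(x) geoMean(x$copies), numeric(1))
  data.frame(gene = copies$gene, sample = copies$sample,
             group = copies$group,
             ncopies = copies$copies / denom[copies$sample])
}
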