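#' Mann-Whitney comparison of two concentration groups
#'
#' Exact null distribution when the combined sample size is at most
#' \code{exactLimit} and the data are tie-free; otherwise the
#' tie-corrected normal approximation with continuity correction. The U
#' statistic reported is for the first group.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @param exactLimit Combined-n switch point for the exact distribution
#'   (default 25; the clinical group sizes this models sit inside it).
#' @return list with \code{U}, \code{p} (two-sided) and \code{exact}.
#' @examples
#' compareTwoGroups(c(1, 2, 3), c(4, 5, 6)) # U = 0, exact p = 0.1
#' @export
compareTwoGroups <- function(a, b, exactLimit = 25) {
  if (length(a) < 2 || length(b) < 2) stop("each group needs >= 2 values")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- !ties && (length(a) + length(b)) <= exactLimit
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value, exact = exact)
}

#' Kruskal-Wallis comparison of three or more groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square p-value on k - 1
#' degrees of freedom.
#'
#' @param groups Named list mapping group label to a numeric vector
#'   (>= 3 groups, each >= 2 values).
#' @return list with \code{H}, \code{df} and \code{p}.
#' @export
compareKGroups <- function(groups) {
  if (length(groups) < 3L) stop("need >= 3 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Protein/mRNA Pearson correlation over paired subjects
#'
#' Pearson correlation between plasma concentration and whole-blood mRNA
#' level over the subjects present in both tables, with the two-sided
#' p-value from the t transform. Computed on the raw (linear)
#' concentration scale.
#'
#' @param panel A [PlasmaPanel-class]; by default the paired mRNA levels
#'   stored in the panel are used.
#' @param mrna Optional named vector (subject -> mRNA level) overriding
#'   the panel's \code{mrna_level} column.
#' @return list with \code{R}, \code{p} and \code{n} (NULL-variance input
#'   gives \code{R = NA} with a message attribute rather than an error).
#' @export
proteinMrnaCorrelation <- function(panel, mrna = NULL) {
  stopifnot(is(panel, "PlasmaPanel"))
  d <- panel@data
  if (!is.null(mrna)) {
    d$mrna_level <- unname(mrna[d$subject])
  }
  ok <- !is.na(d$mrna_level) & !is.na(d$conc_ng_ml)
  if (sum(ok) < 3) stop("need >= 3 paired subjects")
  x <- d$conc_ng_ml[ok]
  y <- d$mrna_level[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(R = NA_real_, p = NA_real_, n = sum(ok),
                degenerate = TRUE))
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(R = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       degenerate = FALSE)
}

#' Age and sex covariate checks on plasma concentrations
#'
#' Sex: two-sided unpaired t test of concentration between sexes. Age:
#' one-way ANOVA across age bins (decade bins by default), or an F test
#' on continuous age via linear regression with \code{mode =
#' "continuous"}. A sex with fewer than two subjects leaves the sex
#' p-value undefined (NA).
#'
#' @param panel A [PlasmaPanel-class].
#' @param mode Age model: "bins" (default) or "continuous".
#' @param binWidth Age bin width in years (default 10).
#' @return list with \code{age_p} and \code{sex_p}.
#' @export
covariateCheck <- function(panel, mode = c("bins", "continuous"),
                           binWidth = 10) {
  stopifnot(is(panel, "PlasmaPanel"))
  mode <- match.arg(mode)
  d <- panel@data
  sexCounts <- table(d$sex)
  sexP <- if (length(sexCounts) < 2 || any(sexCounts < 2)) {
    NA_real_
  } else {
    stats::t.test(conc_ng_ml ~ sex, data = d,
                  var.equal = TRUE)$p.value
  }
  ageP <- if (mode == "bins") {
    bin <- factor(floor(d$age / binWidth))
    if (length(levels(bin)) < 2) {
      NA_real_
    } else {
      fit <- stats::aov(d$conc_ng_ml ~ bin)
      summary(fit)[[1]][["Pr(>F)"]][1]
    }
  } else {
    fit <- stats::lm(conc_ng_ml ~ age, data = d)
    stats::anova(fit)[["Pr(>F)"]][1]
  }
  list(age_p = ageP, sex_p = sexP)
}

#' Group summary of a plasma panel
#'
#' Mean, SD, range and n per group — the summary statistics a clinical
#' plasma report prints.
#'
#' @param panel A [PlasmaPanel-class].
#' @return data.frame with columns \code{group}, \code{n}, \code{mean},
#'   \code{sd}, \code{min}, \code{max}.
#' @export
plasmaGroupSummary <- function(panel) {
  stopifnot(is(panel, "PlasmaPanel"))
  d <- panel@data
  out <- do.call(rbind, lapply(split(d, d$group), function(x) {
    data.frame(group = x$group[1], n = nrow(x), mean = mean(x$conc_ng_ml),
               sd = stats::sd(x$conc_ng_ml), min = min(x$conc_ng_ml),
               max = max(x$conc_ng_ml))
  }))
  rownames(out) <- NULL
  out
}
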