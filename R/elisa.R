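# Four-parameter logistic response: A(x) = D + (A0 - D) / (1 + (x/C)^B).
# A(0) = A0, A(Inf) = D, A(C) = midpoint.
.fourPL <- function(x, params) {
  A0 <- params[["A0"]]; D <- params[["D"]]
  C <- params[["C"]]; B <- params[["B"]]
  ifelse(x <= 0, A0, D + (A0 - D) / (1 + (x / C)^B))
}

# Inverse 4PL: concentration at absorbance y, defined strictly between the
# asymptotes.
.fourPLinv <- function(y, params) {
  A0 <- params[["A0"]]; D <- params[["D"]]
  C <- params[["C"]]; B <- params[["B"]]
  lo <- min(A0, D); hi <- max(A0, D)
  out <- rep(NA_real_, length(y))
  ok <- !is.na(y) & y > lo & y < hi
  out[ok] <- C * ((A0 - D) / (y[ok] - D) - 1)^(1 / B)
  out
}

#' Fit a four-parameter logistic ELISA standard curve
#'
#' Least-squares fit of \eqn{A(x) = D + (A0 - D)/(1 + (x/C)^B)} to the
#' plate standards (Levenberg-Marquardt). The standards must describe a
#' monotone dose-response beyond noise; a non-monotone set aborts with a
#' diagnostic listing the offending mean absorbances.
#'
#' @param standards data.frame with columns \code{conc_known} (in-well
#'   ng/ml, >= 4 distinct levels), \code{absorbance} and
#'   \code{replicate}, or an [ElisaPlate-class] (its standards are used).
#' @return A [StandardCurve-class] object.
#' @export
fitStandardCurve <- function(standards) {
  if (is(standards, "ElisaPlate")) standards <- standards@standards
  .assertColumns(standards, c("conc_known", "absorbance"), "'standards'")
  if (length(unique(standards$conc_known)) < 4L) {
    stop("need >= 4 distinct standard concentrations")
  }
  means <- tapply(standards$absorbance, standards$conc_known, mean)
  concs <- as.numeric(names(means))
  ord <- order(concs)
  means <- means[ord]; concs <- concs[ord]
  steps <- diff(means)
  span <- diff(range(means))
  tolerance <- 0.05 * span
  if (any(steps < -tolerance) && any(steps > tolerance)) {
    stop("standards are not monotone beyond noise; mean absorbances: ",
         paste(sprintf("%.3g@%.3g", means, concs), collapse = ", "))
  }
  d <- standards
  start <- list(A0 = unname(means[1]),
                D = unname(means[length(means)]) + 0.05 * span,
                C = stats::median(concs[concs > 0]), B = 1)
  fit <- minpack.lm::nlsLM(
    absorbance ~ D + (A0 - D) / (1 + (conc_known / C)^B),
    data = d[d$conc_known > 0, ], start = start,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)
  params <- c(A0 = unname(p["A0"]), D = unname(p["D"]),
              C = unname(p["C"]), B = unname(p["B"]))
  resid <- standards$absorbance - .fourPL(standards$conc_known, params)
  pos <- concs[concs > 0]
  new("StandardCurve", params = params, residuals = as.numeric(resid),
      concRange = c(min(pos), max(pos)))
}

#' Convert sample absorbances to plasma concentrations
#'
#' Inverts the fitted standard curve per replicate, flags replicates whose
#' absorbance falls outside the open interval between the curve
#' asymptotes, averages replicates on the concentration scale (so curve
#' nonlinearity does not bias the mean) and multiplies by the plasma
#' dilution factor.
#'
#' @param curve A [StandardCurve-class] from [fitStandardCurve()].
#' @param plate An [ElisaPlate-class], or a data.frame of samples with
#'   columns \code{subject}, \code{absorbance}, \code{replicate} (then
#'   supply \code{dilutionFactor}).
#' @param dilutionFactor Used only when \code{plate} is a data.frame
#'   (default 20).
#' @return data.frame with one row per subject: \code{subject},
#'   \code{conc_ng_ml} (NA when no replicate was invertible),
#'   \code{n_replicates}, \code{n_out_of_range}.
#' @export
elisaConcentrations <- function(curve, plate, dilutionFactor = 20) {
  stopifnot(is(curve, "StandardCurve"))
  if (is(plate, "ElisaPlate")) {
    samples <- plate@samples
    dilutionFactor <- plate@dilutionFactor
  } else {
    samples <- plate
    .assertColumns(samples, c("subject", "absorbance"), "'plate'")
  }
  wellConc <- .fourPLinv(samples$absorbance, curve@params)
  out <- do.call(rbind, lapply(split(seq_len(nrow(samples)),
                                     samples$subject), function(idx) {
    wc <- wellConc[idx]
    data.frame(subject = samples$subject[idx][1],
               conc_ng_ml = mean(wc, na.rm = TRUE) * dilutionFactor,
               n_replicates = length(idx),
               n_out_of_range = sum(is.na(wc)))
  }))
  out$conc_ng_ml[is.nan(out$conc_ng_ml)] <- NA_real_
  rownames(out) <- NULL
  out
}
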