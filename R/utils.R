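#' Geometric mean
#'
#' Geometric mean of strictly positive values; the normalization primitive
#' used for multi-reference qPCR/ddPCR scaling.
#'
#' @param x Numeric vector, all values > 0.
#' @param na.rm Drop missing values before averaging.
#' @return A single numeric value.
#' @examples
#' geoMean(c(4, 9)) # 6
#' @export
geoMean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (length(x) == 0L) return(NA_real_)
  if (any(x <= 0)) stop("geoMean() requires strictly positive values")
  exp(mean(log(x)))
}

# Unbiasing constant for the sample SD of a normal: E[S] = c4(n) * sigma.
# Used when calibrating generator noise scales against an SD-based target.
.c4 <- function(n) {
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}

# Derive a per-task seed from a base seed, kept inside 32-bit integer range.
.subSeed <- function(seed, k) {
  as.integer((as.double(seed) + 104729 * as.double(k)) %% 2147483647)
}

.assertCount <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

.assertScalar <- function(x, name, lower = -Inf, upper = Inf,
                          open.lower = FALSE, open.upper = FALSE) {
  ok <- length(x) == 1L && is.finite(x) &&
    (if (open.lower) x > lower else x >= lower) &&
    (if (open.upper) x < upper else x <= upper)
  if (!ok) stop(sprintf("'%s' must be a single finite number in %s%s, %s%s",
                        name, if (open.lower) "(" else "[", lower, upper,
                        if (open.upper) ")" else "]"))
  as.numeric(x)
}

.assertColumns <- function(df, cols, what) {
  if (!is.data.frame(df)) stop(what, " must be a data.frame")
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing column(s): ", paste(missing, collapse = ", "))
  }
  invisible(df)
}
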