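# Independent brute-force oracles used to cross-check the package's
# statistical kernels. These deliberately avoid the code paths (and where
# possible the stats:: functions) they are checking.

# Pairwise-complete Pearson, textbook two-pass formula.
oraclePearson <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 2) return(NA_real_)
  mx <- sum(x) / n; my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2) * sum((y - my)^2))
  if (den == 0) NA_real_ else num / den
}

# Mann-Whitney U of group a by direct pair counting.
oracleU <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

# Exact two-sided Mann-Whitney p by full enumeration of all rank
# assignments (tie-free data; combined n kept small by the caller).
oracleMwExactP <- function(a, b) {
  m <- length(a); n <- length(b)
  r <- rank(c(a, b))
  uObs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  comb <- utils::combn(m + n, m)
  us <- apply(comb, 2, function(idx) sum(r[idx])) - m * (m + 1) / 2
  pLe <- mean(us <= uObs)
  pGe <- mean(us >= uObs)
  min(1, 2 * min(pLe, pGe))
}

# Null rank-sum distribution of an m-subset of ranks 1..N by dynamic
# programming (polynomial multiplication); returns counts indexed by
# sum = 0..m*N (offset 1).
oracleRankSumCounts <- function(m, N) {
  maxS <- m * N
  f <- matrix(0, nrow = m + 1, ncol = maxS + 1)
  f[1, 1] <- 1
  for (i in seq_len(N)) {
    for (k in min(i, m):1) {
      shifted <- c(rep(0, i), f[k, seq_len(maxS + 1 - i)])
      f[k + 1, ] <- f[k + 1, ] + shifted
    }
  }
  f[m + 1, ]
}

# Exact two-sided Mann-Whitney decision at level alpha from the DP null
# distribution (tie-free data).
makeOracleMwTest <- function(m, n, alpha = 0.05) {
  counts <- oracleRankSumCounts(m, m + n)
  total <- sum(counts)
  offset <- m * (m + 1) / 2
  function(a, b) {
    stopifnot(length(a) == m, length(b) == n)
    u <- oracleU(a, b)
    s <- u + offset
    pLe <- sum(counts[seq_len(s + 1)]) / total
    pGe <- sum(counts[(s + 1):length(counts)]) / total
    p <- min(1, 2 * min(pLe, pGe))
    list(p = p, reject = p <= alpha)
  }
}

# Kruskal-Wallis H with tie correction, textbook formula.
oracleKruskalH <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / tapply(r, g, length)) - 3 * (N + 1)
  tie <- table(x)
  H / (1 - sum(tie^3 - tie) / (N^3 - N))
}

# geNorm stability by direct pairwise log-ratio SDs on a samples x genes
# quantity matrix.
oracleGenormM <- function(mat) {
  k <- ncol(mat)
  vapply(seq_len(k), function(j) {
    mean(vapply(setdiff(seq_len(k), j), function(h) {
      stats::sd(log2(mat[, j] / mat[, h]))
    }, numeric(1)))
  }, numeric(1))
}

# Two-group one-way ANOVA p-value via stats::aov (independent route from
# the pooled t test used by the implementation).
oracleAnovaP <- function(a, b) {
  v <- c(a, b)
  g <- factor(rep(c("a", "b"), c(length(a), length(b))))
  summary(stats::aov(v ~ g))[[1]][["Pr(>F)"]][1]
}

# Small helper: generate a toy compendium matrix with NA holes.
toyCompendium <- function() {
  m <- matrix(
    c(0.5,  1.2, -0.3,   NA,  0.8,
      0.4,   NA, -0.1,  0.9,  0.7,
      -1.0,  0.3,   NA,  0.2, -0.5),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("gA", "gB", "gC"), paste0("e", 1:5)))
  ExpressionCompendium(m)
}
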