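makeRq <- function(mat) {
  # samples x genes quantity matrix -> tidy rq table (all candidates)
  data.frame(gene = rep(colnames(mat), each = nrow(mat)),
             sample = rep(rownames(mat), ncol(mat)),
             group = "g", is_reference = TRUE, rq = as.vector(mat))
}

test_that("relative quantities follow the mean-calibrator definition", {
  cq <- CqTable(data.frame(gene = "g", sample = paste0("s", 1:3),
                           group = "x", is_reference = FALSE,
                           cq = c(24, 25, 26)))
  rq <- relativeQuantities(cq, efficiency = 2)
  # sample at the gene's mean Cq has RQ 1; one cycle below doubles
  expect_equal(rq$rq[rq$sample == "s2"], 1, tolerance = 1e-12)
  expect_equal(rq$rq[rq$sample == "s1"], 2, tolerance = 1e-12)

  cq2 <- CqTable(data.frame(gene = "g", sample = paste0("s", 1:3),
                            group = "x", is_reference = FALSE,
                            cq = c(23, 25, 27)))
  rq2 <- relativeQuantities(cq2, efficiency = 1.9)
  # two cycles above the gene mean at E = 1.9: 1.9^-2 ~ 0.27701
  expect_equal(rq2$rq[rq2$sample == "s3"], 1.9^-2, tolerance = 1e-12)
  expect_error(relativeQuantities(cq, efficiency = 2.5), "in \\(1, 2\\]")
})

test_that("technical replicates are averaged with a spread QC flag", {
  cq <- CqTable(data.frame(gene = "g", sample = rep(c("a", "b"), each = 3),
                           group = "x", is_reference = FALSE,
                           cq = c(24, 24.2, 24.1, 30, 30.8, 30.4)))
  coll <- tableData(collapseTechnicalReplicates(cq))
  expect_equal(coll$cq, c(24.1, 30.4), tolerance = 1e-12)
  expect_identical(coll$qc_wide_spread, c(FALSE, TRUE))
})

test_that("geNorm matches the brute-force pairwise-SD oracle", {
  set.seed(91)
  mat <- matrix(2^rnorm(24, 0, 0.5), nrow = 6,
                dimnames = list(paste0("s", 1:6), paste0("g", 1:4)))
  res <- geNorm(makeRq(mat))
  oracle <- oracleGenormM(mat)
  names(oracle) <- colnames(mat)
  got <- stats::setNames(res$stability$M, res$stability$gene)
  expect_equal(got[names(oracle)], oracle, tolerance = 1e-13)

  # perfectly proportional candidates have pairwise V = 0, so their M is
  # identical and driven by the other candidates only
  mat2 <- mat
  mat2[, 2] <- 3 * mat2[, 1]
  res2 <- geNorm(makeRq(mat2))
  M <- stats::setNames(res2$stability$M, res2$stability$gene)
  expect_equal(unname(M["g1"]), unname(M["g2"]), tolerance = 1e-12)

  # M is invariant to scaling a candidate by a constant
  mat3 <- mat
  mat3[, 3] <- 10 * mat3[, 3]
  res3 <- geNorm(makeRq(mat3))
  got3 <- stats::setNames(res3$stability$M, res3$stability$gene)
  expect_equal(got3[names(oracle)], oracle, tolerance = 1e-12)

  expect_error(geNorm(makeRq(mat[, 1:2])), ">= 3 candidate")
})

test_that("multi-reference normalization has unit reference geomean and
           sample-scaling invariance", {
  qs <- timp1QpcrPreset(3)
  rq <- relativeQuantities(genCqExperiment(qs)$cq)
  nrq <- normalizeRq(rq)
  refGeo <- tapply(nrq$nrq[nrq$is_reference],
                   nrq$sample[nrq$is_reference], geoMean)
  expect_equal(as.numeric(refGeo), rep(1, length(refGeo)),
               tolerance = 1e-12)

  # multiplying every gene of one sample by 10 changes nothing
  rq10 <- rq
  rq10$rq[rq10$sample == "snl1"] <- rq10$rq[rq10$sample == "snl1"] * 10
  expect_equal(normalizeRq(rq10)$nrq, nrq$nrq, tolerance = 1e-12)

  # identity normalization when the reference is constant 1
  flat <- data.frame(gene = rep(c("t", "r"), each = 3),
                     sample = rep(paste0("s", 1:3), 2),
                     group = "x", is_reference = rep(c(FALSE, TRUE),
                                                     each = 3),
                     rq = c(2, 3, 4, 1, 1, 1))
  expect_equal(normalizeRq(flat)$nrq[1:3], c(2, 3, 4),
               tolerance = 1e-12)

  # missing reference measurement names the sample
  broken <- rq[!(rq$sample == "snl2" & rq$gene == "Ubc"), ]
  expect_error(normalizeRq(broken), "snl2")
})

test_that("group statistics: identity, exchangeability and missing data", {
  nrq <- data.frame(gene = "g", sample = paste0("s", 1:8),
                    group = rep(c("snl", "sham"), each = 4),
                    nrq = c(1, 2, 1.5, 1.8, 1, 2, 1.5, 1.8))
  gs <- groupStats(nrq)
  expect_identical(gs$direction, "up")
  expect_equal(gs$fc, 1, tolerance = 1e-12)
  expect_equal(gs$p, 1, tolerance = 1e-12)

  # permuting samples within a group changes nothing
  perm <- nrq[c(3, 1, 4, 2, 5:8), ]
  expect_equal(groupStats(perm)$p, gs$p, tolerance = 1e-12)

  # < 2 quantifiable samples per group -> not analysable, reported
  sparse <- data.frame(gene = "g", sample = paste0("s", 1:4),
                       group = c("snl", "sham", "sham", "sham"),
                       nrq = c(1, 1, 2, 3))
  gsS <- groupStats(sparse)
  expect_false(gsS$analysable)
  expect_true(is.na(gsS$p))
})

test_that("qPCR pipeline recovers the planted ratio", {
  # noiseless limit: exact recovery
  sp0 <- timp1QpcrPreset(1, targetNoiseSd = 0, referenceNoiseSd = 0,
                         sizeFactorSd = 0)
  nrq0 <- normalizeRq(relativeQuantities(genCqExperiment(sp0)$cq))
  gs0 <- groupStats(nrq0[!nrq0$is_reference, ])
  expect_equal(gs0$fc, 2.19, tolerance = 1e-10)
  expect_identical(gs0$direction, "up")

  # with noise: estimator is consistent across replicates
  fcs <- vapply(1:60, function(i) {
    nrq <- normalizeRq(relativeQuantities(
      genCqExperiment(timp1QpcrPreset(i))$cq))
    groupStats(nrq[!nrq$is_reference, ])$fc
  }, numeric(1))
  expect_lt(abs(mean(fcs) - 2.19) / 2.19, 0.05)
})

test_that("Poisson droplet inversion: closed forms and flags", {
  dc <- DropletCounts(data.frame(gene = "g", sample = "s", group = "x",
                                 well = "w1", positives = 5000,
                                 total = 15000))
  res <- poissonCopies(dc)
  expect_equal(res$lambda, -log(2 / 3), tolerance = 1e-13)
  expect_equal(res$copies, -log(2 / 3) * 20 * 1000 / 0.85,
               tolerance = 1e-13)

  # zero positives is a valid zero; saturation is flagged undefined
  dc2 <- DropletCounts(data.frame(gene = c("z", "sat"), sample = "s",
                                  group = "x", well = "w1",
                                  positives = c(0, 100),
                                  total = c(100, 100)))
  res2 <- poissonCopies(dc2)
  expect_equal(res2$copies[res2$gene == "z"], 0)
  expect_true(is.na(res2$copies[res2$gene == "sat"]))
  expect_true(res2$saturated[res2$gene == "sat"])

  # strictly increasing in positives at fixed total
  counts <- vapply(c(10, 100, 1000, 10000), function(p) {
    poissonCopies(DropletCounts(data.frame(
      gene = "g", sample = "s", group = "x", well = "w",
      positives = p, total = 15000)))$copies
  }, numeric(1))
  expect_true(all(diff(counts) > 0))

  # halving droplet volume doubles copies at fixed counts
  half <- DropletCounts(tableData(dc), dropletVolumeNl = 0.425)
  expect_equal(poissonCopies(half)$copies, 2 * res$copies,
               tolerance = 1e-12)

  # wells are pooled before inversion
  two <- DropletCounts(data.frame(gene = "g", sample = "s", group = "x",
                                  well = c("w1", "w2"),
                                  positives = c(5000, 6000),
                                  total = c(15000, 15000)))
  pooled <- poissonCopies(two)
  expect_equal(pooled$lambda, -log(1 - 11000 / 30000), tolerance = 1e-13)
})

test_that("copy normalization uses the reference geometric mean", {
  copies <- data.frame(gene = c("t", "r1", "r2"), sample = "s",
                       group = "x", copies = c(12, 4, 9))
  norm <- normalizeCopies(copies, references = c("r1", "r2"))
  expect_equal(norm$ncopies[norm$gene == "t"], 2, tolerance = 1e-12)

  # scaling all genes of a sample cancels
  scaled <- copies
  scaled$copies <- scaled$copies * 7
  expect_equal(normalizeCopies(scaled, c("r1", "r2"))$ncopies,
               norm$ncopies, tolerance = 1e-12)

  # references at 1 leave values unchanged
  ident <- data.frame(gene = c("t", "r1", "r2"), sample = "s",
                      group = "x", copies = c(5, 1, 1))
  expect_equal(normalizeCopies(ident, c("r1", "r2"))$ncopies[1], 5)

  # zero reference copies error names the sample
  zero <- copies
  zero$copies[zero$gene == "r1"] <- 0
  expect_error(normalizeCopies(zero, c("r1", "r2")), "s")
})

test_that("ddPCR generator + estimator recover planted copies", {
  est <- vapply(1:60, function(i) {
    sp <- ddpcrSpec(copies = data.frame(gene = "g", sample = "s",
                                        group = "x", copies = 9000),
                    dropletsPerWell = 15000, wellsPerSample = 1,
                    seed = i)
    poissonCopies(genDropletCounts(sp)$droplets)$copies
  }, numeric(1))
  expect_lt(abs(mean(est) - 9000) / 9000, 0.05)
})
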