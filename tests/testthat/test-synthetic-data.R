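test_that("all generators are deterministic under a fixed seed", {
  cs <- compendiumSpec(40, 8, presenceProb = 0.7, noiseSd = 1, seed = 11)
  expect_identical(ratioMatrix(genCompendium(cs)),
                   ratioMatrix(genCompendium(cs)))

  ds <- deSpec(data.frame(gene = "g1", fold_change = 1.5,
                          direction = "up"),
               nCases = 3, nControls = 3, seed = 11)
  expect_identical(SummarizedExperiment::assay(genBloodExpression(ds)$se),
                   SummarizedExperiment::assay(genBloodExpression(ds)$se))

  qs <- timp1QpcrPreset(11)
  expect_identical(tableData(genCqExperiment(qs)$cq),
                   tableData(genCqExperiment(qs)$cq))

  dd <- ratDdpcrPreset(11)
  expect_identical(tableData(genDropletCounts(dd)$droplets),
                   tableData(genDropletCounts(dd)$droplets))

  ps <- plasmaSpecPreset(11)
  expect_identical(tableData(genPlasmaPanel(ps)),
                   tableData(genPlasmaPanel(ps)))
  # a different seed changes the data
  expect_false(identical(
    tableData(genPlasmaPanel(ps)),
    tableData(genPlasmaPanel(plasmaSpecPreset(12)))))
})

test_that("compendium generator: presence mask and planted correlations", {
  # degenerate mask: presence 1 means no missing cells
  dense <- genCompendium(compendiumSpec(30, 5, presenceProb = 1,
                                        seed = 1))
  expect_false(anyNA(ratioMatrix(dense)))

  # planted 3-gene module at r = 0.9 over 500 experiments: all pairwise
  # sample correlations clear 0.6 despite partial presence
  sp <- compendiumSpec(500, 10, presenceProb = 0.8,
                       modules = list(list(genes = c("g1", "g2", "g3"),
                                           r = 0.9)),
                       seed = 2)
  corr <- corValues(pairwiseCorrelation(genCompendium(sp)))
  pairs <- corr[c("g1", "g2", "g3"), c("g1", "g2", "g3")]
  expect_true(all(pairs[upper.tri(pairs)] > 0.6))

  # opposite-sign loadings plant anti-correlation
  sp2 <- compendiumSpec(500, 6, presenceProb = 1,
                        modules = list(list(genes = c("g1", "g2"),
                                            r = 0.8,
                                            sign = c(1, -1))),
                        seed = 3)
  corr2 <- corValues(pairwiseCorrelation(genCompendium(sp2)))
  expect_lt(corr2["g1", "g2"], -0.6)

  # module correlation outside (-1, 1) is rejected at spec time
  expect_error(compendiumSpec(10, 3, modules = list(
    list(genes = c("g1", "g2"), r = 1)), seed = 1),
    "correlation")
})

test_that("expression generator recovers planted fold changes", {
  est <- vapply(1:200, function(i) {
    ds <- deSpec(data.frame(gene = "g1", fold_change = 1.5,
                            direction = "up"),
                 nCases = 10, nControls = 10, residualSd = 0.3,
                 seed = i)
    out <- genBloodExpression(ds)
    x <- SummarizedExperiment::assay(out$se)
    grp <- SummarizedExperiment::colData(out$se)$group
    sfc <- signedFoldChange(x[1, grp == "case"], x[1, grp == "control"])
    ifelse(sfc$direction == "up", sfc$fc, 1 / sfc$fc)
  }, numeric(1))
  expect_lt(abs(mean(est) - 1.5) / 1.5, 0.05)

  # null gene: expected group difference 0
  nullEst <- vapply(1:100, function(i) {
    ds <- deSpec(data.frame(gene = "g1", fold_change = 1,
                            direction = "up"),
                 nCases = 10, nControls = 10, residualSd = 0.3,
                 seed = 1000 + i)
    x <- SummarizedExperiment::assay(genBloodExpression(ds)$se)
    mean(x[1, 11:20]) - mean(x[1, 1:10])
  }, numeric(1))
  expect_lt(abs(mean(nullEst)), 0.05)

  # sign convention: planted "down" lowers the case mean
  downEst <- vapply(1:50, function(i) {
    ds <- deSpec(data.frame(gene = "g1", fold_change = 2,
                            direction = "down"),
                 nCases = 10, nControls = 10, residualSd = 0.3,
                 seed = 2000 + i)
    x <- SummarizedExperiment::assay(genBloodExpression(ds)$se)
    mean(x[1, 11:20]) - mean(x[1, 1:10])
  }, numeric(1))
  expect_lt(mean(downEst), -0.8)

  expect_error(deSpec(data.frame(gene = "g", fold_change = 1.2,
                                 direction = "up"),
                      nCases = 1, nControls = 10, seed = 1),
               "nCases")
})

test_that("Cq generator obeys the efficiency definition", {
  # doubling the true quantity at E = 2 lowers the expected Cq by one
  # cycle: noiseless specs with ratio 1 vs 2 differ by exactly 1 in the
  # case group
  mk <- function(ratio) {
    qpcrSpec(targets = data.frame(gene = "t", ratio = ratio,
                                  noise_sd = 0),
             references = data.frame(gene = "r", noise_sd = 0),
             nControl = 2, nCase = 2, sizeFactorSd = 0, seed = 5)
  }
  cq1 <- tableData(genCqExperiment(mk(1))$cq)
  cq2 <- tableData(genCqExperiment(mk(2))$cq)
  t1 <- cq1[cq1$gene == "t" & cq1$group == "snl", "cq"]
  t2 <- cq2[cq2$gene == "t" & cq2$group == "snl", "cq"]
  expect_equal(t1 - t2, rep(1, 2), tolerance = 1e-12)

  expect_error(qpcrSpec(references = data.frame(gene = "r",
                                                noise_sd = 0.1),
                        nControl = 2, nCase = 2, efficiency = 1,
                        seed = 1),
               "efficiency")
})

test_that("droplet generator: degenerate and saturating regimes", {
  mk <- function(copies) {
    ddpcrSpec(copies = data.frame(gene = "g", sample = "s1",
                                  group = "a", copies = copies),
              dropletsPerWell = 1000, wellsPerSample = 3, seed = 4)
  }
  zero <- tableData(genDropletCounts(mk(0))$droplets)
  expect_true(all(zero$positives == 0))

  # lambda >> 1: essentially every droplet positive
  sat <- tableData(genDropletCounts(mk(5e6))$droplets)
  expect_true(all(sat$positives / sat$total > 0.999))

  expect_error(ddpcrSpec(copies = data.frame(gene = "g", sample = "s",
                                             group = "a", copies = -1),
                         seed = 1),
               "copies")
})

test_that("plasma generator: positivity, families, null correlation", {
  for (fam in c("truncnorm", "lognormal")) {
    p <- genPlasmaPanel(plasmaSpecPreset(3, family = fam))
    expect_true(all(tableData(p)$conc_ng_ml > 0))
  }
  # control-group mean centred on the preset location
  mns <- vapply(1:100, function(i) {
    d <- tableData(genPlasmaPanel(plasmaSpecPreset(i)))
    mean(d$conc_ng_ml[d$group == "control"])
  }, numeric(1))
  se <- 33.2 / sqrt(100 * 10)
  expect_lt(abs(mean(mns) - 157.3), 3 * se)

  # zero planted correlation: estimated R centred on 0
  nullSpec <- plasmaSpec(
    groups = data.frame(group = "g", location = 150, scale = 30, n = 20),
    correlation = 0, pairedGroups = "g", seed = 1)
  rs <- vapply(1:100, function(i) {
    sp <- nullSpec; sp@seed <- i
    proteinMrnaCorrelation(genPlasmaPanel(sp))$R
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.07)

  expect_error(plasmaSpec(groups = data.frame(group = "g", location = 1,
                                              scale = 0, n = 5),
                          seed = 1),
               "scale")
})
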