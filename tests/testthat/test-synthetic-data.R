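test_that("every generator is deterministic under (seed, params)", {
  p <- defaultMixtureParams()
  expect_identical(simulateExpression(p, 30, seed = 4),
                   simulateExpression(p, 30, seed = 4))
  bg <- uniformBackground()
  m <- consensusMotif("M", "TF", "ACGTACGTAC")
  expect_identical(simulateSequencesWithMotifs(bg, m, 40, 60, 0.5, seed = 4),
                   simulateSequencesWithMotifs(bg, m, 40, 60, 0.5, seed = 4))
  expect_identical(simulateEpigeneticProfiles(50, seed = 4),
                   simulateEpigeneticProfiles(50, seed = 4))
  cfg <- defaultScenarioConfig(nDBGA = 4, nIDBGA = 3, nNGA = 3,
                               nDecoyDE = 2, nDecoyPeak = 2)
  expect_identical(simulateRegulatoryScenario(cfg, seed = 4),
                   simulateRegulatoryScenario(cfg, seed = 4))
})

test_that("simulated expression matches the generating moments", {
  p <- defaultMixtureParams()
  # all-null: probe effects cancel between conditions, so the SD of the
  # per-gene condition-mean difference is sqrt(2 sigma^2 / (n m))
  sim <- simulateExpression(p, 3000, seed = 6, labels = rep(0L, 3000))
  df <- exprData(sim$expr)
  mns <- tapply(df$value, list(df$gene_id, df$condition), mean)
  d <- mns[, 2] - mns[, 1]
  expect_equal(sd(d), sqrt(2 * p@sigma^2 / 9), tolerance = 0.05)

  # all-up: condition-2 means exceed condition-1 means by the centre gap
  simUp <- simulateExpression(p, 2000, seed = 7, labels = rep(1L, 2000))
  dfu <- exprData(simUp$expr)
  mu <- tapply(dfu$value, list(dfu$gene_id, dfu$condition), mean)
  expect_equal(mean(mu[, 2] - mu[, 1]), p@etaUp[2] - p@etaUp[1],
               tolerance = 0.05)
  expect_error(simulateExpression(p, 0), "I must be")
})

test_that("motif planting separates score distributions and records truth", {
  bg <- uniformBackground()
  m <- consensusMotif("M", "TF", "ACGTACGTAC")   # width 10
  sim <- simulateSequencesWithMotifs(bg, m, 400, 60, 1, seed = 8)
  expect_true(all(sim$truth$planted))
  expect_true(all(sim$truth$position >= 0 &
                    sim$truth$position <= 60 - motifWidth(m)))
  # planted instances sit where the truth says
  pickedUp <- substr(sim$sequences, sim$truth$position + 1,
                     sim$truth$position + motifWidth(m))
  expect_equal(pickedUp, sim$truth$instance, ignore_attr = TRUE)

  none <- simulateSequencesWithMotifs(bg, m, 50, 60, 0, seed = 8)
  expect_false(any(none$truth$planted))

  bgScores <- scanScores(m, none$sequences)
  plScores <- scanScores(m, sim$sequences[1:50])
  expect_gte(mean(plScores) - mean(bgScores), 4)   # >= 4 bits of separation

  expect_error(simulateSequencesWithMotifs(bg, m, 10, 5, 0.5, seed = 1),
               "length")
})

test_that("scenario bundles respect their configuration and pass validation", {
  cfg <- defaultScenarioConfig(nDBGA = 5, nIDBGA = 4, nNGA = 0,
                               nDecoyDE = 3, nDecoyPeak = 2)
  sc <- simulateRegulatoryScenario(cfg, seed = 9)
  expect_equal(nrow(sc$promoterTruth), 0)          # no NGA, no promoter plants
  expect_equal(nrow(sc$truth), 14)
  expect_true(validObject(sc$expr))
  expect_true(all(nchar(sc$peaks$sequence) == sc$peaks$end - sc$peaks$start))
  expect_true(all(sc$peaks$assigned_gene %in% sc$truth$gene_id))
  expect_equal(sum(sc$truth$mechanism == "DBGA"), 5)
  expect_error(simulateRegulatoryScenario(
    defaultScenarioConfig(nDBGA = -1), seed = 1), "counts")
})

test_that("scenario bundles serialize to files the readers accept", {
  cfg <- defaultScenarioConfig(nDBGA = 3, nIDBGA = 2, nNGA = 2,
                               nDecoyDE = 1, nDecoyPeak = 1)
  sc <- simulateRegulatoryScenario(cfg, seed = 10)
  dir <- tempfile(); writeScenario(sc, dir)
  expr <- readExpressionTable(file.path(dir, "expression.tsv"))
  expect_equal(nGenes(expr), 9)
  peaks <- readPeakTable(file.path(dir, "peaks.tsv"),
                         file.path(dir, "peaks.fa"))
  expect_equal(peaks$sequence, sc$peaks$sequence)
  prom <- readFastaSequences(file.path(dir, "promoters.fa"))
  expect_equal(as.character(prom), unname(sc$promoters), ignore_attr = TRUE)
  motifs <- readTransfacMatrices(file.path(dir, "motifs.transfac"))
  expect_length(motifs, 3)
})

test_that("epigenetic profile simulation plants exceedances where asked", {
  sim <- simulateEpigeneticProfiles(3000, seed = 11,
                                    effectConfig = list(m5 = list(n = 60,
                                                                  factor = 1000)))
  calls <- classifyMechanisms(sim$profiles)
  plantedIdx <- sim$truth$planted == "m5"
  expect_true(all(calls$m5[plantedIdx]))
  # unplanted features still flag about 20% at the 80th percentile
  expect_equal(mean(calls$m1), 0.2, tolerance = 0.02)
  expect_equal(mean(calls$m4), 0.2, tolerance = 0.02)
})
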