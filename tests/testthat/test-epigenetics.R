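annTwo <- geneAnnotation(data.frame(gene_id = c("gp", "gm"), chrom = "chr1",
                                    tss = c(5000, 5000), strand = c("+", "-")))

test_that("promoter windows are strand-aware for ChIP and symmetric for MCIp", {
  tags <- data.frame(chrom = "chr1", pos = c(4500, 5500))
  tr <- TagTrack("polII", tags)
  sig <- promoterSignal(tr, annTwo, window = "chip")
  expect_equal(unname(sig["gp"]), 1)   # upstream of TSS on +
  expect_equal(unname(sig["gm"]), 1)   # reflected downstream on -
  mc <- promoterSignal(TagTrack("mcip", tags), annTwo, window = "mcip")
  expect_equal(unname(mc), c(2, 2))    # +/- 1 kb covers both tags

  none <- promoterSignal(TagTrack("polII",
                                  data.frame(chrom = "chr1", pos = 99999)),
                         annTwo, window = "chip")
  expect_equal(unname(none), c(0, 0))
})

test_that("promoter signals are library-size normalized and order invariant", {
  r1 <- data.frame(chrom = "chr1", pos = c(4100, 4200))
  r2 <- data.frame(chrom = "chr1", pos = c(4300, 4400, 4500, 4600))
  tr <- TagTrack("h3k4me2", list(r1, r2))   # library sizes 2 and 4
  sig <- promoterSignal(tr, annTwo, window = "chip")
  # mean library = 3: rep1 contributes 2*(3/2)=3, rep2 4*(3/4)=3; mean 3
  expect_equal(unname(sig["gp"]), 3)

  shuf <- TagTrack("h3k4me2", list(r2[c(3, 1, 4, 2), ], r1[2:1, ]))
  expect_equal(promoterSignal(shuf, annTwo, window = "chip"), sig)
})

test_that("mechanism classification thresholds at the reference percentile", {
  n <- 200
  prof <- geneEpigeneticProfiles(paste0("g", 1:n),
                                 basalExpr = seq_len(n),
                                 methParental = rep(10, n),
                                 methResistant = rep(10, n),
                                 h3k4me2 = rep(10, n), h3k27me3 = rep(10, n))
  calls <- classifyMechanisms(prof, percentile = 80)
  expect_equal(sum(calls$m1), sum(seq_len(n) > quantile(seq_len(n), 0.8)))
  expect_false(any(calls$m2 | calls$m3 | calls$m4 | calls$m5))
  expect_equal(calls$unknown, !calls$m1)

  expect_error(classifyMechanisms(prof[0, ]), "empty")
  expect_error(classifyMechanisms(prof, targetIds = "nope"), "nope")

  # invariance to a monotone rescaling of a single feature
  prof2 <- prof; prof2$basal_expr_resistant <- exp(prof2$basal_expr_resistant / 50)
  expect_equal(classifyMechanisms(prof2)$m1, calls$m1)
})

test_that("mechanism fractions and overlaps summarize call sets", {
  calls <- data.frame(gene_id = paste0("g", 1:4),
                      m1 = FALSE, m2 = c(TRUE, TRUE, FALSE, FALSE),
                      m3 = FALSE, m4 = c(TRUE, TRUE, TRUE, TRUE),
                      m5 = c(FALSE, FALSE, TRUE, FALSE))
  calls$unknown <- !(calls$m2 | calls$m4 | calls$m5)
  fr <- mechanismFractions(calls)
  expect_equal(unname(fr$fractions), c(0, 50, 0, 100, 25))
  expect_equal(fr$unknown, 0)
  expect_equal(fr$overlap["m2", "m4"], 50)       # {1,2} vs {1,2,3,4}
  expect_equal(fr$overlap["m4", "m4"], 100)
  expect_equal(fr$overlap["m2", "m5"], 0)
  expect_true(is.nan(fr$overlap["m1", "m3"]))
})

test_that("direction concordance compares fold-change signs with the unit rule", {
  a <- c(g1 = 2, g2 = -3, g3 = 1.5)
  expect_equal(directionConcordance(a, a), 100)
  expect_equal(directionConcordance(a, -a), 0)
  # a fold-change of exactly 1 only agrees with another exact 1
  expect_equal(directionConcordance(c(g1 = 1, g2 = 1),
                                    c(g1 = 1, g2 = 2)), 50)
  expect_error(directionConcordance(a, a[1:2]), "unpaired")

  set.seed(3)
  n <- 10000
  s1 <- sample(c(-2, 2), n, TRUE); s2 <- sample(c(-2, 2), n, TRUE)
  names(s1) <- names(s2) <- paste0("g", 1:n)
  expect_equal(directionConcordance(s1, s2), 50, tolerance = 4)
})

test_that("the H3K4me2 median threshold is strict", {
  sig <- setNames(as.numeric(1:100), paste0("g", 1:100))
  out <- h3k4AboveMedian(sig)
  expect_true(out$flag[["g75"]]); expect_false(out$flag[["g25"]])
  expect_equal(out$percentAbove, 50)
  allEq <- h3k4AboveMedian(setNames(rep(5, 10), paste0("g", 1:10)))
  expect_equal(allEq$percentAbove, 0)
})
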