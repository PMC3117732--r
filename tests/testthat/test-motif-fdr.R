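test_that("background training reproduces hand-counted transitions", {
  bg1 <- trainBackground("AAAAAAAAAA", order = 1)
  # 9 A->A transitions, pseudocount 1: (9+1)/(9+4)
  expect_equal(unname(bg1@transition[1, 1]), 10 / 13, tolerance = 1e-12)

  bg0 <- trainBackground("ACGT", order = 0)
  expect_equal(unname(bg0@transition[1, ]), rep(0.25, 4), tolerance = 1e-12)

  bg2 <- trainBackground(c("ACGTACGTGGAA", "TTGCACCA"), order = 2)
  expect_true(all(abs(rowSums(bg2@transition) - 1) < 1e-9))
  expect_equal(sum(bg2@startProb), 1, tolerance = 1e-12)

  expect_warning(expect_warning(trainBackground(c("ACGTACGT", "AC"), order = 3),
                                "skipped"),
                 "training length")
  expect_error(suppressWarnings(trainBackground("AC", order = 3)), "training")
})

test_that("background sampling is reproducible and matches the model", {
  bg <- trainBackground(strrep("A", 200), order = 1)
  s1 <- sampleSequences(bg, 50, 30, seed = 9)
  s2 <- sampleSequences(bg, 50, 30, seed = 9)
  expect_identical(s1, s2)
  expect_gt(mean(strsplit(paste(s1, collapse = ""), "")[[1]] == "A"), 0.95)

  expect_error(sampleSequences(bg, 5, 1, seed = 1), "length")

  # empirical mononucleotide frequencies track the stationary distribution
  bgU <- uniformBackground(order = 0, probs = c(0.4, 0.1, 0.1, 0.4))
  s <- sampleSequences(bgU, 2000, 500, seed = 10)
  tab <- table(factor(strsplit(paste(s, collapse = ""), "")[[1]],
                      c("A", "C", "G", "T")))
  expect_equal(unname(as.numeric(tab / sum(tab))), c(0.4, 0.1, 0.1, 0.4),
               tolerance = 0.01)
  expect_equal(unname(baseFrequencies(bgU)), c(0.4, 0.1, 0.1, 0.4),
               tolerance = 1e-12)
})

test_that("scan scores are max log2 odds over offsets and strands", {
  # motif identical to the background: every window scores 0
  flat <- MotifMatrix("MF", "TFF", matrix(0.25, 4, 5))
  expect_equal(scanScore(flat, "ACGTGGTACTGA"), 0, tolerance = 1e-12)

  # sharply peaked columns: perfect-match score is the summed log odds
  m <- consensusMotif("MC", "TFC", "AAAA", consensusProb = 0.997)
  expect_equal(scanScore(m, "AAAA"), 4 * log2(0.997 / 0.25), tolerance = 1e-9)
  # N bases contribute zero
  expect_equal(scanScore(m, "ANAA"), 3 * log2(0.997 / 0.25), tolerance = 1e-9)

  expect_error(scanScore(m, "AC"), "shorter")

  # strand symmetry on random sequences
  bg <- uniformBackground()
  s <- sampleSequences(bg, 20, 40, seed = 8)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
  m2 <- consensusMotif("M2", "TF2", "ACGGTTCA")
  expect_equal(scanScores(m2, s), scanScores(m2, rc), tolerance = 1e-9)
})

test_that("FDR curves conserve counts, force the left tail, and zero clean tops", {
  set.seed(17)
  obs <- c(rnorm(400, 0), rnorm(30, 8, 0.2))   # clean high cluster
  nul <- rnorm(3000, 0)
  cv <- buildFdrCurve(obs, nul, k = 200, minBin = 20)
  expect_equal(sum(cv@mObs), length(obs))
  expect_equal(sum(cv@nNull), length(nul))
  # bins at or below the midpoint are forced to 1
  expect_true(all(cv@fdrBin[cv@binEdges[-1] <= cv@midpoint] == 1))
  # a top bin with observed mass and no null mass has fdr 0
  top <- length(cv@fdrBin)
  expect_equal(cv@nNull[top], 0)
  expect_equal(cv@fdrBin[top], 0)
  expect_lt(siteFdr(cv, 8), 0.05)

  expect_error(buildFdrCurve(rep(1, 50), rep(1, 50)), "degenerate")
})

test_that("siteFdr is clamped to [0,1] and returns 1 in the forced region", {
  set.seed(23)
  obs <- rnorm(2000); nul <- rnorm(2000)
  cv <- buildFdrCurve(obs, nul)
  sc <- seq(-10, 10, length.out = 101)
  f <- siteFdr(cv, sc)
  expect_true(all(f >= 0 & f <= 1))
  expect_true(all(f[sc <= cv@midpoint] == 1))
  # beyond the fitted range the boundary value is used
  expect_equal(siteFdr(cv, 1e6), siteFdr(cv, max(obs, nul)))
})

test_that("spline tracks the analytic local FDR on a monotone fixture", {
  set.seed(29)
  # observed = half null, half shifted: the true local FDR at score s is
  # phi(s) / (0.5 phi(s) + 0.5 phi(s - 3)) since I = R
  obs <- c(rnorm(20000, 0, 1), rnorm(20000, 3, 1))
  nul <- rnorm(40000, 0, 1)
  cv <- buildFdrCurve(obs, nul)
  truth <- function(s) dnorm(s) / (0.5 * dnorm(s) + 0.5 * dnorm(s - 3))
  x <- cv@spline$x
  keep <- x > cv@midpoint & truth(x) > 0.05 & truth(x) < 0.95
  expect_gt(sum(keep), 10)
  expect_lt(max(abs(siteFdr(cv, x[keep]) - truth(x[keep]))), 0.1)
  expect_lt(max(abs(siteFdr(cv, x[keep]) - cv@fdrBin[keep])), 0.1)
})

test_that("planted strong motifs are detected at low site FDR", {
  bg <- uniformBackground()
  m <- consensusMotif("MP", "TFP", "ACGTACGTAC")
  sim <- simulateSequencesWithMotifs(bg, m, 1000, 45, 0.5, seed = 15)
  obs <- scanScores(m, sim$sequences)
  nul <- scanScores(m, sampleSequences(bg, 5000, 45, seed = 16))
  cv <- buildFdrCurve(obs, nul)
  fdr <- siteFdr(cv, obs)
  expect_gte(mean(fdr[sim$truth$planted] < 0.05), 0.8)
  # non-planted sequences are rarely called
  expect_lt(mean(fdr[!sim$truth$planted] < 0.05), 0.1)
})
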