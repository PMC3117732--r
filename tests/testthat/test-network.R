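deUp <- data.frame(call = "up", local_fdr = 0.05)
deNone <- data.frame(call = "unchanged", local_fdr = 0.9)
noPeaks <- data.frame(peak_id = character(), peak_fdr = numeric())
noSites <- data.frame(peak_id = character(), tf = character(), fdr = numeric())
noProm <- data.frame(tf = character(), fdr = numeric())

test_that("the mechanism decision table follows the flow chart", {
  pk <- data.frame(peak_id = "p1", peak_fdr = 0.01)

  dbga <- classifyTarget("g1", deUp, pk,
                         data.frame(peak_id = "p1", tf = "ERalpha", fdr = 0.01),
                         noProm)
  expect_equal(dbga$mechanism, "DBGA")
  expect_equal(dbga$direction, "up")
  expect_true("ERalpha" %in% names(dbga$supporting_tfs[[1]]))

  idbga <- classifyTarget("g1", deUp, pk,
                          data.frame(peak_id = c("p1", "p1"),
                                     tf = c("ERalpha", "Sp1"),
                                     fdr = c(0.4, 0.02)),
                          noProm)
  expect_equal(idbga$mechanism, "I-DBGA")
  expect_equal(names(idbga$supporting_tfs[[1]]), "Sp1")

  nga <- classifyTarget("g1", deUp, noPeaks, noSites,
                        data.frame(tf = "E2F1", fdr = 0.03))
  expect_equal(nga$mechanism, "NGA")

  none <- classifyTarget("g1", deNone, pk,
                         data.frame(peak_id = "p1", tf = "ERalpha", fdr = 0.001),
                         noProm)
  expect_equal(none$mechanism, "none")

  unassigned <- classifyTarget("g1", deUp, pk,
                               data.frame(peak_id = "p1", tf = "Sp1", fdr = 0.5),
                               noProm)
  expect_equal(unassigned$mechanism, "genomic-unassigned")

  unexpl <- classifyTarget("g1", deUp, noPeaks, noSites,
                           data.frame(tf = "E2F1", fdr = 0.5))
  expect_equal(unexpl$mechanism, "unexplained")

  # ERalpha passing takes precedence over other TFs in the same peak
  both <- classifyTarget("g1", deUp, pk,
                         data.frame(peak_id = c("p1", "p1"),
                                    tf = c("ERalpha", "Sp1"),
                                    fdr = c(0.01, 0.02)),
                         noProm)
  expect_equal(both$mechanism, "DBGA")
  expect_setequal(names(both$supporting_tfs[[1]]), c("ERalpha", "Sp1"))
})

test_that("relaxing the site threshold never creates unassigned or unexplained calls", {
  set.seed(7)
  pk <- data.frame(peak_id = "p1", peak_fdr = 0.01)
  for (i in 1:50) {
    hasPeak <- runif(1) < 0.5
    sf <- data.frame(peak_id = "p1", tf = c("ERalpha", "Sp1"),
                     fdr = runif(2))
    pf <- data.frame(tf = c("E2F1", "Myc"), fdr = runif(2))
    strict <- classifyTarget("g", deUp, if (hasPeak) pk else noPeaks,
                             sf, pf, alphaSite = 0.02)
    loose <- classifyTarget("g", deUp, if (hasPeak) pk else noPeaks,
                            sf, pf, alphaSite = 0.50)
    if (!strict$mechanism %in% c("genomic-unassigned", "unexplained"))
      expect_false(loose$mechanism %in% c("genomic-unassigned", "unexplained"))
  }
})

test_that("genomic and non-genomic labels are mutually exclusive", {
  # a gene with a passing peak can never be NGA, whatever its promoter holds
  pk <- data.frame(peak_id = "p1", peak_fdr = 0.01)
  got <- classifyTarget("g1", deUp, pk,
                        data.frame(peak_id = "p1", tf = "Sp1", fdr = 0.9),
                        data.frame(tf = "E2F1", fdr = 0.001))
  expect_false(got$mechanism == "NGA")
})

test_that("network assembly yields one lexicographically ordered edge per supporting TF", {
  calls <- rbind(
    classifyTarget("g2", deUp, data.frame(peak_id = "p1", peak_fdr = 0.01),
                   data.frame(peak_id = "p1", tf = "ERalpha", fdr = 0.01),
                   noProm),
    classifyTarget("g1", deUp, noPeaks, noSites,
                   data.frame(tf = c("Sp1", "E2F1"), fdr = c(0.01, 0.02))))
  net <- assembleNetwork(calls)
  e <- networkEdges(net)
  expect_equal(nrow(e), 3)
  expect_equal(e$tf, sort(e$tf))
  expect_equal(e$gene[e$mechanism == "DBGA"], "g2")
  expect_setequal(e$tf[e$gene == "g1"], c("Sp1", "E2F1"))

  empty <- assembleNetwork(calls[0, ])
  expect_equal(nrow(networkEdges(empty)), 0)
})

test_that("network overlap is intersection over union per mechanism", {
  mk <- function(genes, mech) {
    calls <- do.call(rbind, lapply(genes, function(g)
      if (mech == "NGA")
        classifyTarget(g, deUp, noPeaks, noSites,
                       data.frame(tf = "Sp1", fdr = 0.01))
      else
        classifyTarget(g, deUp, data.frame(peak_id = "p", peak_fdr = 0.01),
                       data.frame(peak_id = "p", tf = "ERalpha", fdr = 0.01),
                       noProm)))
    assembleNetwork(calls)
  }
  a <- mk(c("g1", "g2"), "DBGA"); b <- mk(c("g2", "g3"), "DBGA")
  expect_equal(unname(compareNetworks(a, b)$overlap["DBGA"]), 1 / 3)
  expect_equal(unname(compareNetworks(a, a)$overlap["DBGA"]), 1)
  c1 <- mk(c("g1"), "NGA"); c2 <- mk(c("g9"), "NGA")
  expect_equal(unname(compareNetworks(c1, c2)$overlap["NGA"]), 0)
})

test_that("classifyTargets requires annotated genes", {
  de <- data.frame(gene_id = "ghost", p_up = 0.9, p_null = 0.05,
                   p_down = 0.05, fc = 2, call = "up", local_fdr = 0.1)
  ann <- geneAnnotation(data.frame(gene_id = "g1", chrom = "chr1",
                                   tss = 5000, strand = "+"))
  peaks <- data.frame(peak_id = character(), peak_fdr = numeric(),
                      assigned_gene = character())
  expect_error(classifyTargets(de, peaks, noSites,
                               data.frame(gene_id = character(),
                                          tf = character(), fdr = numeric()),
                               annot = ann),
               "ghost")
})
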