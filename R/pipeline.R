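## End-to-end driver: from a scenario bundle (simulated or assembled from
## files) to a mechanism-labelled, hub-annotated regulatory network.

#' Run the full network-construction pipeline on an input bundle
#'
#' Fits the expression mixture by EM and calls differential genes; trains a
#' Markov background on the promoter sequences; calibrates per-motif local
#' FDR curves separately for the 45-bp peak class and the promoter class
#' (matched-length nulls sampled from the background); classifies every
#' called gene as DBGA / I-DBGA / NGA / genomic-unassigned / unexplained;
#' and assembles the hub-annotated network.
#'
#' @param bundle list with components `expr` ([ProbeExpression-class]),
#'   `annot` ([GeneAnnotation-class]), `peaks` (data.frame with `sequence`
#'   and `assigned_gene`), `promoters` (named character vector), `motifs`
#'   (list of [MotifMatrix-class]) and `config$nKnownTfs` — the shape
#'   returned by [simulateRegulatoryScenario()].
#' @param R null sequences per motif/class, default 10000.
#' @param order Markov order of the background model, default 6.
#' @param k,minBin binning parameters of [buildFdrCurve()]. The default
#'   `minBin = NULL` scales the occupancy limit with the observed-set size,
#'   `min(20, max(2, I %/% 100))`: the limit of 20 presumes genome-scale
#'   score sets, and holding it fixed at desk scale collapses the histogram
#'   into a handful of bins and smears well-separated score clusters.
#' @param alphaPeak,alphaSite peak / motif-site FDR thresholds (0.05).
#' @param c,fcMin differential-expression thresholds (0.80, 1.20).
#' @param nRestarts EM restarts, default 1.
#' @param seed seed for the EM jitter and null-sequence sampling.
#' @return list with `fit` ([EBFit-class]), `deCalls`, `calls`, `network`
#'   ([RegulatoryNetwork-class]), `peakSiteFdrs`, `promoterSiteFdrs` and
#'   `curves`.
#' @export
runRegulatoryPipeline <- function(bundle, R = 10000, order = 6, k = 200,
                                  minBin = NULL, alphaPeak = 0.05,
                                  alphaSite = 0.05, c = 0.80, fcMin = 1.20,
                                  nRestarts = 1, seed = 1) {
  fit <- fitEM(bundle$expr, nRestarts = nRestarts, seed = seed)
  post <- posteriorProbs(bundle$expr, fittedParams(fit))
  de <- classifyGenes(post, c = c, fcMin = fcMin)

  bg <- trainBackground(bundle$promoters, order = order)
  bg0 <- baseFrequencies(bg)
  peakLen <- unique(nchar(bundle$peaks$sequence))[1]
  promLen <- max(nchar(bundle$promoters))
  nullPeak <- sampleSequences(bg, R, peakLen, seed = .subSeed(seed, "null-peak"))
  nullProm <- sampleSequences(bg, R, promLen, seed = .subSeed(seed, "null-prom"))

  autoBin <- function(I) if (is.null(minBin)) min(20, max(2, I %/% 100)) else minBin
  binPk <- autoBin(nrow(bundle$peaks))
  binPr <- autoBin(length(bundle$promoters))

  peakSiteFdrs <- promoterSiteFdrs <- NULL
  curves <- list()
  for (m in bundle$motifs) {
    tf <- m@tfName
    obsPk <- scanScores(m, bundle$peaks$sequence, bg0)
    cvPk <- buildFdrCurve(obsPk, scanScores(m, nullPeak, bg0), k = k,
                          minBin = binPk, motifId = paste0(m@motifId, ":peak"))
    peakSiteFdrs <- rbind(peakSiteFdrs, data.frame(
      peak_id = bundle$peaks$peak_id, tf = tf, score = obsPk,
      fdr = siteFdr(cvPk, obsPk), stringsAsFactors = FALSE))

    obsPr <- scanScores(m, bundle$promoters, bg0)
    cvPr <- buildFdrCurve(obsPr, scanScores(m, nullProm, bg0), k = k,
                          minBin = binPr,
                          motifId = paste0(m@motifId, ":promoter"))
    promoterSiteFdrs <- rbind(promoterSiteFdrs, data.frame(
      gene_id = names(bundle$promoters), tf = tf, score = obsPr,
      fdr = siteFdr(cvPr, obsPr), stringsAsFactors = FALSE))
    curves[[paste0(m@motifId, ":peak")]] <- cvPk
    curves[[paste0(m@motifId, ":promoter")]] <- cvPr
  }

  calls <- classifyTargets(de, bundle$peaks, peakSiteFdrs, promoterSiteFdrs,
                           annot = bundle$annot, alphaPeak = alphaPeak,
                           alphaSite = alphaSite)
  net <- assembleNetwork(calls, label = "scenario")
  nTfs <- if (!is.null(bundle$config$nKnownTfs)) bundle$config$nKnownTfs
          else max(50, length(bundle$motifs))
  net <- annotateHubs(net, nTfs)
  list(fit = fit, deCalls = de, calls = calls, network = net,
       peakSiteFdrs = peakSiteFdrs, promoterSiteFdrs = promoterSiteFdrs,
       curves = curves)
}

#' Mechanism-label accuracy against a known truth
#'
#' @param calls data.frame from [classifyTargets()].
#' @param truth data.frame with `gene_id` and true `mechanism`.
#' @return fraction of genes whose assigned mechanism equals the truth.
#' @export
mechanismAccuracy <- function(calls, truth) {
  m <- merge(calls[, c("gene_id", "mechanism")],
             truth[, c("gene_id", "mechanism")], by = "gene_id",
             suffixes = c("", "_true"))
  mean(m$mechanism == m$mechanism_true)
}
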