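#' @import methods
#' @importFrom stats dnorm quantile median rnorm runif rbinom sd var
#' @importFrom utils read.table write.table head
NULL

## ---------------------------------------------------------------------------
## ProbeExpression: probe-level two-condition expression measurements
## ---------------------------------------------------------------------------

#' Probe-level two-condition expression data
#'
#' Long-format container for probe-level log2 expression values measured under
#' two conditions with replication. Each row is one measurement of one probe of
#' one gene under one condition. Genes may have different probe and replicate
#' counts; within a gene and condition all probes must share the same replicate
#' count.
#'
#' @slot data a `data.frame` with columns `gene_id` (character), `probe_id`
#'   (character), `condition` (integer, 1 or 2; 1 is the reference),
#'   `replicate` (integer, >= 1) and `value` (finite numeric, log2 scale).
#'
#' @seealso [readExpressionTable()], [simulateExpression()], [fitEM()]
#' @export
setClass("ProbeExpression", representation(data = "data.frame"))

setValidity("ProbeExpression", function(object) {
  df <- object@data
  need <- c("gene_id", "probe_id", "condition", "replicate", "value")
  if (!all(need %in% names(df)))
    return(paste("missing column(s):", paste(setdiff(need, names(df)), collapse = ", ")))
  if (!is.numeric(df$value) || any(!is.finite(df$value)))
    return("all expression values must be finite numbers")
  if (!all(df$condition %in% c(1L, 2L)))
    return("condition must be 1 or 2")
  if (any(df$replicate < 1))
    return("replicate indices must be >= 1")
  both <- tapply(df$condition, df$gene_id, function(l) all(c(1L, 2L) %in% l))
  if (!all(both))
    return(paste("gene(s) lacking measurements in both conditions:",
                 paste(names(both)[!both][seq_len(min(3, sum(!both)))], collapse = ", ")))
  TRUE
})

#' Construct a ProbeExpression object
#'
#' @param data a data.frame with columns `gene_id`, `probe_id`, `condition`,
#'   `replicate`, `value`.
#' @return a [ProbeExpression-class] object.
#' @export
ProbeExpression <- function(data) {
  data$gene_id <- as.character(data$gene_id)
  data$probe_id <- as.character(data$probe_id)
  data$condition <- as.integer(data$condition)
  data$replicate <- as.integer(data$replicate)
  data$value <- as.numeric(data$value)
  new("ProbeExpression", data = data[, c("gene_id", "probe_id", "condition",
                                         "replicate", "value")])
}

#' @describeIn ProbeExpression-class the underlying long-format data.frame
#' @param x a `ProbeExpression` object
#' @export
exprData <- function(x) x@data

#' @describeIn ProbeExpression-class gene identifiers (unique, in order of
#'   first appearance)
#' @export
geneIds <- function(x) unique(x@data$gene_id)

#' @describeIn ProbeExpression-class number of genes
#' @export
nGenes <- function(x) length(geneIds(x))

setMethod("show", "ProbeExpression", function(object) {
  df <- object@data
  np <- tapply(df$probe_id, df$gene_id, function(p) length(unique(p)))
  cat("ProbeExpression:", length(np), "genes,", nrow(df), "measurements\n")
  cat("  probes per gene:", paste(range(np), collapse = "-"),
      " conditions: 1 (reference), 2\n")
})

## ---------------------------------------------------------------------------
## MixtureParams: parameters of the three-population mixture
## ---------------------------------------------------------------------------

#' Parameters of the three-population expression mixture
#'
#' The model places each gene's pair of condition means on the (mu1, mu2)
#' plane: up-regulated genes come from a bivariate normal centred above the
#' y = x line, unchanged genes sit on the line (mu1 = mu2 = mu ~ N(lambda,
#' phi^2)), and down-regulated genes come from a bivariate normal centred
#' below it. Probe effects b ~ N(0, delta^2) and measurement errors
#' eps ~ N(0, sigma^2) are shared across genes.
#'
#' @slot rho mixture weights, named `c(up=, null=, down=)`, summing to 1.
#' @slot etaUp,etaDown 2-vectors: population centres for up / down genes
#'   (condition-1 mean, condition-2 mean); `etaUp[2] > etaUp[1]` and
#'   `etaDown[2] < etaDown[1]`.
#' @slot SigmaUp,SigmaDown 2x2 positive-definite covariance matrices.
#' @slot lambda,phi mean and SD of the null-population expression level.
#' @slot sigma error SD; @slot delta probe-effect SD.
#' @export
setClass("MixtureParams", representation(
  rho = "numeric", etaUp = "numeric", SigmaUp = "matrix",
  etaDown = "numeric", SigmaDown = "matrix",
  lambda = "numeric", phi = "numeric", sigma = "numeric", delta = "numeric"))

.isPD <- function(S) {
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) return(FALSE)
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  all(ev > 0)
}

setValidity("MixtureParams", function(object) {
  if (length(object@rho) != 3 || abs(sum(object@rho) - 1) > 1e-8 || any(object@rho < 0))
    return("rho must be 3 non-negative weights summing to 1")
  if (length(object@etaUp) != 2 || length(object@etaDown) != 2)
    return("etaUp and etaDown must have length 2")
  if (!(object@etaUp[2] > object@etaUp[1]))
    return("up-population centre must lie above the y = x line (etaUp[2] > etaUp[1])")
  if (!(object@etaDown[2] < object@etaDown[1]))
    return("down-population centre must lie below the y = x line (etaDown[2] < etaDown[1])")
  if (!.isPD(object@SigmaUp) || !.isPD(object@SigmaDown))
    return("SigmaUp and SigmaDown must be symmetric positive definite")
  if (object@phi <= 0 || object@sigma <= 0 || object@delta <= 0)
    return("phi, sigma and delta must be > 0")
  TRUE
})

#' Construct mixture parameters
#'
#' @param rho 3-vector of population weights (up, null, down).
#' @param etaUp,etaDown population centres (length-2).
#' @param SigmaUp,SigmaDown 2x2 covariances.
#' @param lambda,phi null-population mean and SD.
#' @param sigma error SD.
#' @param delta probe-effect SD.
#' @return a [MixtureParams-class] object.
#' @export
MixtureParams <- function(rho, etaUp, SigmaUp, etaDown, SigmaDown,
                          lambda, phi, sigma, delta) {
  rho <- as.numeric(rho); names(rho) <- c("up", "null", "down")
  new("MixtureParams", rho = rho, etaUp = as.numeric(etaUp),
      SigmaUp = as.matrix(SigmaUp), etaDown = as.numeric(etaDown),
      SigmaDown = as.matrix(SigmaDown), lambda = as.numeric(lambda),
      phi = as.numeric(phi), sigma = as.numeric(sigma), delta = as.numeric(delta))
}

#' Default mixture parameters for a two-fold effect on a log2 microarray scale
#'
#' Centres the null population at lambda = 8 (log2 units, a mid-range
#' microarray intensity) with between-gene SD phi = 1; up and down
#' populations are mirror images one log2 unit (two-fold) off the diagonal;
#' probe and error SDs are typical probe-level values.
#'
#' @param rho population weights, default `c(0.15, 0.70, 0.15)`.
#' @return a [MixtureParams-class] object.
#' @export
defaultMixtureParams <- function(rho = c(0.15, 0.70, 0.15)) {
  S <- matrix(c(0.50, 0.30, 0.30, 0.50), 2, 2)
  MixtureParams(rho = rho,
                etaUp = c(8, 9), SigmaUp = S,
                etaDown = c(8, 7), SigmaDown = S,
                lambda = 8, phi = 1, sigma = 0.30, delta = 0.30)
}

setMethod("show", "MixtureParams", function(object) {
  cat("MixtureParams (three-population expression mixture)\n")
  cat(sprintf("  rho: up=%.3f null=%.3f down=%.3f\n",
              object@rho[1], object@rho[2], object@rho[3]))
  cat(sprintf("  etaUp=(%.3f, %.3f)  etaDown=(%.3f, %.3f)\n",
              object@etaUp[1], object@etaUp[2], object@etaDown[1], object@etaDown[2]))
  cat(sprintf("  lambda=%.3f phi=%.3f sigma=%.3f delta=%.3f\n",
              object@lambda, object@phi, object@sigma, object@delta))
})

## ---------------------------------------------------------------------------
## EBFit: result of fitting the mixture by EM
## ---------------------------------------------------------------------------

#' EM fit of the expression mixture
#'
#' @slot params fitted [MixtureParams-class].
#' @slot logLikTrace observed-data log-likelihood at each EM iteration
#'   (non-decreasing).
#' @slot converged logical; @slot iterations number of iterations run.
#' @export
setClass("EBFit", representation(params = "MixtureParams",
                                 logLikTrace = "numeric",
                                 converged = "logical",
                                 iterations = "integer"))

#' @describeIn EBFit-class the fitted [MixtureParams-class]
#' @param object an `EBFit`
#' @export
fittedParams <- function(object) object@params

#' @describeIn EBFit-class per-iteration observed-data log-likelihoods
#' @export
logLikTrace <- function(object) object@logLikTrace

setMethod("show", "EBFit", function(object) {
  cat(sprintf("EBFit: %d EM iterations, %sconverged, final logLik %.4f\n",
              object@iterations, if (object@converged) "" else "NOT ",
              object@logLikTrace[length(object@logLikTrace)]))
  show(object@params)
})

## ---------------------------------------------------------------------------
## MotifMatrix: a PWM
## ---------------------------------------------------------------------------

#' Position weight matrix for a transcription-factor motif
#'
#' @slot motifId motif accession; @slot tfName factor name.
#' @slot probs 4 x width base-probability matrix with rownames A, C, G, T;
#'   each column sums to 1.
#' @export
setClass("MotifMatrix", representation(motifId = "character",
                                       tfName = "character",
                                       probs = "matrix"))

setValidity("MotifMatrix", function(object) {
  p <- object@probs
  if (nrow(p) != 4 || !identical(rownames(p), c("A", "C", "G", "T")))
    return("probs must be a 4 x width matrix with rownames A, C, G, T")
  if (ncol(p) < 4) return("motif width must be >= 4")
  if (any(p < 0)) return("probabilities must be non-negative")
  if (any(abs(colSums(p) - 1) > 1e-9)) return("each column must sum to 1")
  TRUE
})

#' Construct a MotifMatrix
#' @param motifId,tfName identifiers.
#' @param probs 4 x width probability matrix (rows A, C, G, T).
#' @return a [MotifMatrix-class].
#' @export
MotifMatrix <- function(motifId, tfName, probs) {
  probs <- unname(as.matrix(probs))
  rownames(probs) <- c("A", "C", "G", "T")
  new("MotifMatrix", motifId = motifId, tfName = tfName, probs = probs)
}

#' @describeIn MotifMatrix-class motif width (number of columns)
#' @param x a `MotifMatrix`
#' @export
motifWidth <- function(x) ncol(x@probs)

#' @describeIn MotifMatrix-class base-probability matrix
#' @export
motifProbs <- function(x) x@probs

setMethod("show", "MotifMatrix", function(object) {
  cons <- paste(c("A", "C", "G", "T")[apply(object@probs, 2, which.max)],
                collapse = "")
  cat(sprintf("MotifMatrix %s (%s), width %d, consensus %s\n",
              object@motifId, object@tfName, ncol(object@probs), cons))
})

## ---------------------------------------------------------------------------
## MarkovBackground
## ---------------------------------------------------------------------------

#' Markov-chain background sequence model
#'
#' Order-k Markov model of genomic background: the probability of each base
#' depends on the k immediately preceding bases. Contexts are encoded as
#' integers 0..4^k-1 (base-4, A=0, C=1, G=2, T=3, most significant digit the
#' oldest base).
#'
#' @slot order the Markov order k (0 = i.i.d. bases).
#' @slot transition 4^k x 4 row-stochastic matrix.
#' @slot startProb length-4^k start-context distribution (empirical context
#'   frequencies of the training sequences).
#' @export
setClass("MarkovBackground", representation(order = "integer",
                                            transition = "matrix",
                                            startProb = "numeric"))

setValidity("MarkovBackground", function(object) {
  k <- object@order
  if (k < 0) return("order must be >= 0")
  if (nrow(object@transition) != 4^k || ncol(object@transition) != 4)
    return("transition must be 4^order x 4")
  if (any(abs(rowSums(object@transition) - 1) > 1e-9))
    return("each transition row must sum to 1")
  if (length(object@startProb) != 4^k || abs(sum(object@startProb) - 1) > 1e-9)
    return("startProb must be a distribution over 4^order contexts")
  TRUE
})

setMethod("show", "MarkovBackground", function(object) {
  cat(sprintf("MarkovBackground: order %d (%d contexts)\n",
              object@order, nrow(object@transition)))
  cat("  stationary base frequencies:",
      paste(sprintf("%s=%.3f", c("A", "C", "G", "T"),
                    baseFrequencies(object)), collapse = " "), "\n")
})

## ---------------------------------------------------------------------------
## ScoreFdrCurve
## ---------------------------------------------------------------------------

#' Binned local-FDR calibration of motif binding scores
#'
#' Observed and null binding scores are binned over their common range; per
#' bin, the local FDR is `min(1, (I * n_b / R) / m_b)` where `m_b`, `n_b`
#' count observed and null scores, `I` and `R` are the observed and null
#' totals. Bins whose upper edge is at or below the midpoint of the score
#' range are forced to FDR 1, and a cubic smoothing spline over bin midpoints
#' gives the local FDR at an arbitrary score.
#'
#' @slot motifId motif the curve calibrates.
#' @slot binEdges bin boundaries after collapsing (length nbins + 1).
#' @slot mObs,nNull per-bin observed / null score counts.
#' @slot nObsTotal,nNullTotal totals I and R.
#' @slot fdrBin per-bin local FDR (midpoint rule applied).
#' @slot midpoint midpoint of the score range (scores at or below map to 1).
#' @slot spline fitted `smooth.spline` object (or NULL-like list for the
#'   piecewise-linear fallback on very few bins).
#' @export
setClass("ScoreFdrCurve", representation(motifId = "character",
                                         binEdges = "numeric",
                                         mObs = "numeric", nNull = "numeric",
                                         nObsTotal = "integer",
                                         nNullTotal = "integer",
                                         fdrBin = "numeric",
                                         midpoint = "numeric",
                                         spline = "list"))

setValidity("ScoreFdrCurve", function(object) {
  nb <- length(object@binEdges) - 1
  if (length(object@mObs) != nb || length(object@nNull) != nb ||
      length(object@fdrBin) != nb)
    return("per-bin vectors must match the number of bins")
  if (sum(object@mObs) != object@nObsTotal)
    return("observed counts must sum to I")
  if (sum(object@nNull) != object@nNullTotal)
    return("null counts must sum to R")
  if (any(object@fdrBin < 0 | object@fdrBin > 1))
    return("fdrBin must lie in [0, 1]")
  TRUE
})

setMethod("show", "ScoreFdrCurve", function(object) {
  cat(sprintf("ScoreFdrCurve for %s: %d bins over [%.3f, %.3f], I=%d, R=%d\n",
              object@motifId, length(object@mObs), min(object@binEdges),
              max(object@binEdges), object@nObsTotal, object@nNullTotal))
})

## ---------------------------------------------------------------------------
## GeneAnnotation
## ---------------------------------------------------------------------------

#' Gene TSS/strand annotation with labelled regions
#'
#' Holds, per gene, the chromosome, 0-based TSS, strand, and a set of
#' labelled half-open regions (promoter, intron, downstream) used to assign
#' ChIP peaks to genes.
#'
#' @slot genes data.frame with columns `gene_id`, `chrom`, `tss`, `strand`.
#' @slot regions a [GenomicRanges::GRanges] with metadata columns `gene_id`
#'   and `region_type` in `{promoter, intron, downstream}` (0-based half-open
#'   intervals stored as 1-based closed GRanges internally).
#' @export
setClass("GeneAnnotation", representation(genes = "data.frame",
                                          regions = "ANY"))

setValidity("GeneAnnotation", function(object) {
  g <- object@genes
  need <- c("gene_id", "chrom", "tss", "strand")
  if (!all(need %in% names(g)))
    return(paste("genes must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(g$gene_id)) return("gene_id must be unique")
  if (any(g$tss < 0)) return("tss must be non-negative")
  if (!all(g$strand %in% c("+", "-"))) return("strand must be + or -")
  TRUE
})

setMethod("show", "GeneAnnotation", function(object) {
  cat(sprintf("GeneAnnotation: %d genes, %d labelled regions\n",
              nrow(object@genes), length(object@regions)))
})

#' @describeIn GeneAnnotation-class the per-gene table
#' @param x a `GeneAnnotation`
#' @export
annotGenes <- function(x) x@genes

#' @describeIn GeneAnnotation-class the labelled region GRanges
#' @export
annotRegions <- function(x) x@regions

## ---------------------------------------------------------------------------
## TagTrack
## ---------------------------------------------------------------------------

#' Sequencing-tag track for one assay
#'
#' Replicated single-base tag positions from a ChIP-seq (PolII, H3K4me2,
#' H3K27me3) or MCIp-seq library.
#'
#' @slot assay one of `polII`, `h3k4me2`, `h3k27me3`, `mcip`.
#' @slot replicates list of data.frames with columns `chrom`, `pos`
#'   (0-based tag positions).
#' @slot librarySizes total tag count per replicate (defaults to the number
#'   of positions supplied).
#' @export
setClass("TagTrack", representation(assay = "character",
                                    replicates = "list",
                                    librarySizes = "numeric"))

setValidity("TagTrack", function(object) {
  if (!object@assay %in% c("polII", "h3k4me2", "h3k27me3", "mcip"))
    return("assay must be one of polII, h3k4me2, h3k27me3, mcip")
  if (length(object@replicates) < 1) return("at least one replicate required")
  for (r in object@replicates) {
    if (!all(c("chrom", "pos") %in% names(r))) return("replicates need chrom, pos")
    if (any(r$pos < 0)) return("tag positions must be non-negative")
  }
  if (length(object@librarySizes) != length(object@replicates))
    return("one library size per replicate")
  TRUE
})

#' Construct a TagTrack
#' @param assay assay name (`polII`, `h3k4me2`, `h3k27me3`, `mcip`).
#' @param replicates list of data.frames with columns `chrom`, `pos`.
#' @param librarySizes optional per-replicate totals; default the tag counts.
#' @return a [TagTrack-class].
#' @export
TagTrack <- function(assay, replicates, librarySizes = NULL) {
  if (is.data.frame(replicates)) replicates <- list(replicates)
  if (is.null(librarySizes)) librarySizes <- vapply(replicates, nrow, 0L)
  new("TagTrack", assay = assay, replicates = replicates,
      librarySizes = as.numeric(librarySizes))
}

setMethod("show", "TagTrack", function(object) {
  cat(sprintf("TagTrack (%s): %d replicate(s), library sizes %s\n",
              object@assay, length(object@replicates),
              paste(object@librarySizes, collapse = ", ")))
})

## ---------------------------------------------------------------------------
## RegulatoryNetwork
## ---------------------------------------------------------------------------

#' TF -> gene regulatory network with mechanism labels
#'
#' @slot edges data.frame with columns `tf`, `gene`, `mechanism`
#'   (`DBGA`, `I-DBGA`, `NGA`), `direction` (`up`/`down`) and `site_fdr`.
#' @slot hubs data.frame with columns `tf`, `target_count`, `p_value`
#'   (empty until [annotateHubs()] is applied).
#' @slot label free-text label (e.g. time point).
#' @export
setClass("RegulatoryNetwork", representation(edges = "data.frame",
                                             hubs = "data.frame",
                                             label = "character"))

setValidity("RegulatoryNetwork", function(object) {
  need <- c("tf", "gene", "mechanism", "direction", "site_fdr")
  if (!all(need %in% names(object@edges)))
    return(paste("edges must have columns", paste(need, collapse = ", ")))
  if (nrow(object@hubs)) {
    cnt <- table(object@edges$tf)
    bad <- object@hubs$target_count != as.integer(cnt[object@hubs$tf])
    if (any(bad)) return("hub target_count inconsistent with edge list")
  }
  TRUE
})

#' @describeIn RegulatoryNetwork-class the edge list
#' @param x a `RegulatoryNetwork`
#' @export
networkEdges <- function(x) x@edges

#' @describeIn RegulatoryNetwork-class the hub table
#' @export
networkHubs <- function(x) x@hubs

setMethod("show", "RegulatoryNetwork", function(object) {
  m <- table(factor(object@edges$mechanism, c("DBGA", "I-DBGA", "NGA")))
  cat(sprintf("RegulatoryNetwork%s: %d edges (%d DBGA, %d I-DBGA, %d NGA), %d TFs, %d genes\n",
              if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
              nrow(object@edges), m[1], m[2], m[3],
              length(unique(object@edges$tf)), length(unique(object@edges$gene))))
  if (nrow(object@hubs)) cat("  hubs annotated:", nrow(object@hubs), "TFs\n")
})
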