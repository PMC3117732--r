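## Promoter signal quantification from sequencing-tag tracks and
## classification of non-responsive targets into five epigenetic mechanisms.

#' Normalized promoter tag signal per gene
#'
#' For ChIP-seq assays the promoter window is the 1000 bp upstream of the
#' TSS (strand-aware: reflected downstream of the TSS on the minus strand);
#' for MCIp-seq the window is the unstranded 1000 bp either side of the TSS.
#' Per-replicate counts are scaled to the mean library size and averaged
#' across replicates. Windows extending below coordinate 0 are truncated.
#'
#' @param track a [TagTrack-class].
#' @param annot a [GeneAnnotation-class].
#' @param window `"chip"` (strand-aware upstream) or `"mcip"` (+/- 1000 bp).
#' @param width window width, default 1000.
#' @return named numeric vector of normalized promoter counts per gene.
#' @export
promoterSignal <- function(track, annot, window = c("chip", "mcip"),
                           width = 1000) {
  window <- match.arg(window)
  g <- annotGenes(annot)
  if (window == "chip") {
    up <- g$strand == "+"
    lo <- ifelse(up, g$tss - width, g$tss + 1)
    hi <- ifelse(up, g$tss - 1, g$tss + width)
  } else {
    lo <- g$tss - width
    hi <- g$tss + width
  }
  lo <- pmax(lo, 0)
  win <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(lo + 1, hi + 1))
  meanLib <- mean(track@librarySizes)
  counts <- matrix(0, nrow(g), length(track@replicates))
  for (r in seq_along(track@replicates)) {
    rep <- track@replicates[[r]]
    tags <- GenomicRanges::GRanges(rep$chrom,
                                   IRanges::IRanges(rep$pos + 1, rep$pos + 1))
    counts[, r] <- GenomicRanges::countOverlaps(win, tags) *
      (meanLib / track@librarySizes[r])
  }
  setNames(rowMeans(counts), g$gene_id)
}

#' Assemble per-gene epigenetic profiles
#'
#' Combines basal expression with promoter methylation and histone-mark
#' signals into the feature table the mechanism classifier consumes. The
#' derived ratios use a pseudocount so zero-count promoters stay finite:
#' `hyper_fc = (meth_resistant + pc) / (meth_parental + pc)`, `hypo_fc` its
#' inverse, and `k27_k4_ratio = (h3k27me3 + pc) / (h3k4me2 + pc)`.
#'
#' @param geneIds gene identifiers.
#' @param basalExpr basal expression in the resistant line.
#' @param methParental,methResistant normalized promoter methylation signals.
#' @param h3k4me2,h3k27me3 normalized promoter histone-mark signals.
#' @param pseudocount default 1.
#' @return data.frame of profiles with derived ratio columns.
#' @export
geneEpigeneticProfiles <- function(geneIds, basalExpr, methParental,
                                   methResistant, h3k4me2, h3k27me3,
                                   pseudocount = 1) {
  stopifnot(all(basalExpr >= 0), all(methParental >= 0),
            all(methResistant >= 0), all(h3k4me2 >= 0), all(h3k27me3 >= 0))
  data.frame(gene_id = as.character(geneIds),
             basal_expr_resistant = basalExpr,
             meth_parental = methParental, meth_resistant = methResistant,
             h3k4me2 = h3k4me2, h3k27me3 = h3k27me3,
             hyper_fc = (methResistant + pseudocount) / (methParental + pseudocount),
             hypo_fc = (methParental + pseudocount) / (methResistant + pseudocount),
             k27_k4_ratio = (h3k27me3 + pseudocount) / (h3k4me2 + pseudocount),
             stringsAsFactors = FALSE)
}

.MECH_FEATURES <- c(m1 = "basal_expr_resistant", m2 = "hyper_fc",
                    m3 = "hypo_fc", m4 = "meth_resistant", m5 = "k27_k4_ratio")

#' Classify non-responsive targets into epigenetic mechanisms
#'
#' Five non-exclusive mechanisms, each defined by one feature exceeding
#' (strictly) that feature's percentile threshold computed over the whole
#' reference universe of profiles: (1) high basal expression in the
#' resistant line, (2) hyper-methylation (resistant over parental), (3)
#' hypo-methylation, (4) high methylation level in the resistant line, (5)
#' high H3K27me3/H3K4me2 ratio. A target exceeding none is `unknown`.
#'
#' @param profiles reference universe of profiles from
#'   [geneEpigeneticProfiles()].
#' @param targetIds genes to classify (must be in `profiles`); default all.
#' @param percentile threshold percentile, default 80.
#' @return data.frame with `gene_id`, logical columns `m1`..`m5`, and
#'   `unknown`; attribute `thresholds` holds the cutoffs used.
#' @export
classifyMechanisms <- function(profiles, targetIds = profiles$gene_id,
                               percentile = 80) {
  if (!nrow(profiles)) .stopf("empty reference universe")
  miss <- setdiff(targetIds, profiles$gene_id)
  if (length(miss)) .stopf("target gene '%s' not in the reference universe", miss[1])
  thr <- vapply(.MECH_FEATURES, function(f)
    as.numeric(quantile(profiles[[f]], percentile / 100)), 0)
  tp <- profiles[match(targetIds, profiles$gene_id), , drop = FALSE]
  out <- data.frame(gene_id = tp$gene_id, stringsAsFactors = FALSE)
  for (m in names(.MECH_FEATURES))
    out[[m]] <- tp[[.MECH_FEATURES[m]]] > thr[m]
  out$unknown <- !Reduce(`|`, out[names(.MECH_FEATURES)])
  attr(out, "thresholds") <- thr
  out
}

#' Per-mechanism fractions and pairwise overlap
#'
#' @param calls data.frame from [classifyMechanisms()].
#' @return list with `fractions` (percentage of targets per mechanism),
#'   `unknown` (percentage unexplained) and `overlap` (5x5 matrix of
#'   pairwise intersection-over-union between mechanism gene sets; NaN when
#'   both sets are empty).
#' @export
mechanismFractions <- function(calls) {
  ms <- names(.MECH_FEATURES)
  frac <- vapply(ms, function(m) 100 * mean(calls[[m]]), 0)
  ov <- matrix(NaN, 5, 5, dimnames = list(ms, ms))
  for (a in 1:5) for (b in 1:5) {
    A <- calls$gene_id[calls[[ms[a]]]]; B <- calls$gene_id[calls[[ms[b]]]]
    u <- union(A, B)
    ov[a, b] <- if (length(u)) 100 * length(intersect(A, B)) / length(u) else NaN
  }
  list(fractions = frac, unknown = 100 * mean(calls$unknown), overlap = ov)
}

#' Direction concordance between expression and signal fold-changes
#'
#' Percentage of genes whose signed fold-changes agree in sign. A
#' fold-change of exactly 1 (absent in both groups) is concordant only with
#' another exact 1.
#'
#' @param fcExpr,fcSignal named numeric vectors of signed fold-changes,
#'   paired by name.
#' @return percentage concordant (0-100).
#' @export
directionConcordance <- function(fcExpr, fcSignal) {
  if (is.null(names(fcExpr)) || is.null(names(fcSignal)))
    .stopf("fold-change vectors must be named by gene")
  if (!setequal(names(fcExpr), names(fcSignal)))
    .stopf("unpaired gene(s): %s",
           paste(head(c(setdiff(names(fcExpr), names(fcSignal)),
                        setdiff(names(fcSignal), names(fcExpr))), 3),
                 collapse = ", "))
  fcSignal <- fcSignal[names(fcExpr)]
  one <- fcExpr == 1 | fcSignal == 1
  conc <- ifelse(fcExpr == 1 & fcSignal == 1, TRUE,
                 ifelse(one, FALSE, sign(fcExpr) == sign(fcSignal)))
  100 * mean(conc)
}

#' Flag genes above the median of an H3K4me2 signal distribution
#'
#' @param signals named numeric vector of promoter H3K4me2 signals.
#' @return list with `flag` (named logical, strictly above the median) and
#'   `percentAbove`.
#' @export
h3k4AboveMedian <- function(signals) {
  stopifnot(length(signals) > 0)
  thr <- median(signals)
  flag <- signals > thr
  list(flag = flag, percentAbove = 100 * mean(flag), threshold = thr)
}
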