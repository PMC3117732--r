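## Mechanism decision logic: combine differential-expression calls, ChIP peak
## FDRs and motif-site FDRs into DBGA / I-DBGA / NGA labels and an edge list.
##
## A differentially expressed gene with at least one significant peak in its
## promoter/intron/downstream regions is a genomic target: DBGA when the ERa
## motif is significant in a passing peak, I-DBGA when only other TF motifs
## are, genomic-unassigned when none is. A differentially expressed gene with
## no passing peak anywhere in its regions is a non-genomic (NGA) target when
## at least one TF motif is significant in its 1-kb upstream promoter, and
## unexplained otherwise.

.MECHS <- c("DBGA", "I-DBGA", "NGA", "genomic-unassigned", "unexplained", "none")

#' Classify one gene's regulatory mechanism
#'
#' @param geneId gene identifier.
#' @param deCall the gene's row from [classifyGenes()] (needs `call` and
#'   `local_fdr`).
#' @param peaks data.frame of peaks assigned to this gene (`peak_id`,
#'   `peak_fdr`); zero rows when the gene's regions hold no peak.
#' @param peakSiteFdrs data.frame (`peak_id`, `tf`, `fdr`) of motif-site
#'   local FDRs inside those peaks.
#' @param promoterSiteFdrs data.frame (`tf`, `fdr`) of motif-site local FDRs
#'   in the gene's upstream-1-kb promoter sequence.
#' @param alphaPeak peak-level FDR threshold, default 0.05.
#' @param alphaSite motif-site FDR threshold, default 0.05.
#' @param eraName name under which the ERalpha motif appears, default
#'   `"ERalpha"`.
#' @return one-row data.frame with `gene_id`, `mechanism`, `direction`,
#'   `de_local_fdr` and list-columns `supporting_tfs` (named vector of site
#'   FDRs) and `peak_ids`.
#' @export
classifyTarget <- function(geneId, deCall, peaks, peakSiteFdrs,
                           promoterSiteFdrs, alphaPeak = 0.05,
                           alphaSite = 0.05, eraName = "ERalpha") {
  res <- function(mech, tfs = numeric(0), pk = character(0)) {
    out <- data.frame(gene_id = geneId, mechanism = mech,
                      direction = if (deCall$call == "unchanged") NA_character_
                                  else deCall$call,
                      de_local_fdr = deCall$local_fdr,
                      stringsAsFactors = FALSE)
    out$supporting_tfs <- list(tfs)
    out$peak_ids <- list(pk)
    out
  }
  if (deCall$call == "unchanged") return(res("none"))

  passPk <- if (nrow(peaks)) peaks$peak_id[peaks$peak_fdr <= alphaPeak]
            else character(0)
  if (length(passPk)) {
    sf <- peakSiteFdrs[peakSiteFdrs$peak_id %in% passPk &
                         peakSiteFdrs$fdr <= alphaSite, , drop = FALSE]
    if (nrow(sf)) {
      tfs <- tapply(sf$fdr, sf$tf, min)
      tfs <- setNames(as.numeric(tfs), names(tfs))
      if (eraName %in% names(tfs)) return(res("DBGA", tfs, passPk))
      return(res("I-DBGA", tfs, passPk))
    }
    return(res("genomic-unassigned", pk = passPk))
  }
  sf <- promoterSiteFdrs[promoterSiteFdrs$fdr <= alphaSite, , drop = FALSE]
  if (nrow(sf)) {
    tfs <- tapply(sf$fdr, sf$tf, min)
    return(res("NGA", setNames(as.numeric(tfs), names(tfs))))
  }
  res("unexplained")
}

#' Classify every gene in a dataset
#'
#' Batch driver over [classifyTarget()]. Peaks must carry `assigned_gene`
#' (see [assignPeaksToGenes()]).
#'
#' @param deCalls data.frame from [classifyGenes()].
#' @param peaks peak data.frame (`peak_id`, `peak_fdr`, `assigned_gene`).
#' @param peakSiteFdrs data.frame (`peak_id`, `tf`, `fdr`).
#' @param promoterSiteFdrs data.frame (`gene_id`, `tf`, `fdr`).
#' @param annot optional [GeneAnnotation-class]; when supplied, every called
#'   gene must be annotated (error naming the gene otherwise).
#' @inheritParams classifyTarget
#' @return data.frame of regulatory calls, one row per gene in `deCalls`.
#' @export
classifyTargets <- function(deCalls, peaks, peakSiteFdrs, promoterSiteFdrs,
                            annot = NULL, alphaPeak = 0.05, alphaSite = 0.05,
                            eraName = "ERalpha") {
  if (!is.null(annot)) {
    miss <- setdiff(deCalls$gene_id, annotGenes(annot)$gene_id)
    if (length(miss))
      .stopf("gene '%s' absent from annotation", miss[1])
  }
  rows <- lapply(seq_len(nrow(deCalls)), function(i) {
    g <- deCalls$gene_id[i]
    classifyTarget(g, deCalls[i, ],
                   peaks[peaks$assigned_gene == g, , drop = FALSE],
                   peakSiteFdrs,
                   promoterSiteFdrs[promoterSiteFdrs$gene_id == g, ,
                                    drop = FALSE],
                   alphaPeak, alphaSite, eraName)
  })
  do.call(rbind, rows)
}

#' Assemble a network from regulatory calls
#'
#' One edge per (supporting TF, gene) for genes labelled DBGA, I-DBGA or
#' NGA; the defining DBGA edge is attributed to ERalpha, with co-occurring
#' passing TFs also edged. Edges are ordered lexicographically by (tf,
#' gene).
#'
#' @param calls data.frame from [classifyTargets()].
#' @param label free-text network label (e.g. "4h").
#' @return a [RegulatoryNetwork-class] (hub table empty until
#'   [annotateHubs()]).
#' @export
assembleNetwork <- function(calls, label = "") {
  edges <- data.frame(tf = character(), gene = character(),
                      mechanism = character(), direction = character(),
                      site_fdr = numeric(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(calls))) {
    mech <- calls$mechanism[i]
    if (!mech %in% c("DBGA", "I-DBGA", "NGA")) next
    tfs <- calls$supporting_tfs[[i]]
    if (!length(tfs)) next
    edges <- rbind(edges, data.frame(
      tf = names(tfs), gene = calls$gene_id[i], mechanism = mech,
      direction = calls$direction[i], site_fdr = as.numeric(tfs),
      stringsAsFactors = FALSE))
  }
  edges <- edges[order(edges$tf, edges$gene), , drop = FALSE]
  rownames(edges) <- NULL
  new("RegulatoryNetwork", edges = edges, hubs = .emptyHubs(), label = label)
}

#' Overlap statistics between two networks
#'
#' Per-mechanism target overlap as intersection over union of the target
#' gene sets, plus the list of TFs present in both networks.
#'
#' @param netA,netB [RegulatoryNetwork-class] objects over the same gene
#'   universe.
#' @return list with `overlap` (named numeric, fraction per mechanism; NaN
#'   when both target sets are empty), `sharedTfs`, and `sharedHubs` (TFs
#'   significant in both hub tables, when annotated).
#' @export
compareNetworks <- function(netA, netB) {
  mech <- c("DBGA", "I-DBGA", "NGA")
  ov <- vapply(mech, function(m) {
    a <- unique(networkEdges(netA)$gene[networkEdges(netA)$mechanism == m])
    b <- unique(networkEdges(netB)$gene[networkEdges(netB)$mechanism == m])
    u <- union(a, b)
    if (!length(u)) NaN else length(intersect(a, b)) / length(u)
  }, 0)
  shared <- intersect(unique(networkEdges(netA)$tf),
                      unique(networkEdges(netB)$tf))
  hubsA <- networkHubs(netA); hubsB <- networkHubs(netB)
  sharedHubs <- if (nrow(hubsA) && nrow(hubsB))
    intersect(hubsA$tf[hubsA$p_value < 0.01], hubsB$tf[hubsB$p_value < 0.01])
  else character(0)
  list(overlap = ov, sharedTfs = shared, sharedHubs = sharedHubs)
}
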