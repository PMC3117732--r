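## Exact significance of TF hubs. Null: the n_i distinct TFs implicated for
## each of M differential genes are drawn uniformly without replacement from
## a pool of n known TFs. For a fixed TF the draws are independent across
## genes with inclusion probability n_i / n, so the number of connected genes
## T is Poisson-binomial; its pmf is computed by exact dynamic-programming
## convolution (algebraically identical to the subset-sum form of the null).

#' Exact null distribution of a TF's target count
#'
#' @param drawSizes integer vector `n_1..n_M`: unique TFs implicated per
#'   differential gene.
#' @param n size of the known-TF pool (`all(drawSizes <= n)`).
#' @return numeric vector of length `M + 1`: `Pr(T = 0..M)`, summing to 1
#'   within 1e-12.
#' @export
hubPmf <- function(drawSizes, n) {
  drawSizes <- as.numeric(drawSizes)
  if (any(drawSizes < 1)) .stopf("draw sizes must be >= 1")
  if (any(drawSizes > n)) .stopf("draw size exceeds the known-TF pool (n = %g)", n)
  p <- drawSizes / n
  pmf <- 1
  for (pi in p)
    pmf <- c(pmf * (1 - pi), 0) + c(0, pmf * pi)
  pmf
}

#' Exact upper-tail p-value for a TF hub
#'
#' `Pr(T >= tObs)` under the random-draw null.
#'
#' @inheritParams hubPmf
#' @param tObs observed number of genes connected to the TF
#'   (`0 <= tObs <= M`).
#' @return p-value in `[0, 1]`.
#' @export
hubPvalue <- function(drawSizes, n, tObs) {
  M <- length(drawSizes)
  if (tObs > M) .stopf("tObs (%d) exceeds the number of differential genes (%d)", tObs, M)
  if (tObs < 0) .stopf("tObs must be >= 0")
  if (tObs == 0) return(1)
  pmf <- hubPmf(drawSizes, n)
  tail <- rev(cumsum(rev(pmf)))      # tail[t+1] = Pr(T >= t)
  min(1, tail[tObs + 1])
}

#' Annotate network hubs with exact p-values
#'
#' Each TF in the network gets `tObs` = its target count; the per-gene draw
#' sizes are the numbers of distinct TFs edging each gene.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param nKnownTfs size of the known-TF pool.
#' @param alpha significance level for the `significant` flag, default 0.01.
#' @return the network with its hub table filled (sorted by p-value).
#' @export
annotateHubs <- function(net, nKnownTfs, alpha = 0.01) {
  e <- networkEdges(net)
  if (!nrow(e)) { net@hubs <- .emptyHubs(); return(net) }
  uniq <- unique(e[, c("tf", "gene")])
  drawSizes <- as.integer(table(uniq$gene))
  if (nKnownTfs < max(drawSizes))
    .stopf("known-TF pool (n = %d) smaller than the largest per-gene draw (%d)",
           nKnownTfs, max(drawSizes))
  cnt <- table(uniq$tf)
  hubs <- data.frame(tf = names(cnt), target_count = as.integer(cnt),
                     stringsAsFactors = FALSE)
  hubs$p_value <- vapply(hubs$target_count, function(t)
    hubPvalue(drawSizes, nKnownTfs, t), 0)
  hubs$significant <- hubs$p_value < alpha
  hubs <- hubs[order(hubs$p_value, -hubs$target_count, hubs$tf), ]
  rownames(hubs) <- NULL
  net@hubs <- hubs
  net
}
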