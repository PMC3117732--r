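## PWM scanning and local-FDR calibration of binding scores against a
## high-order Markov background null.

#' @useDynLib ebTFnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## ---- Markov background -----------------------------------------------------

#' Train a Markov-chain background model on genomic sequences
#'
#' Transition probabilities are pseudocounted context->base counts; the start
#' distribution is the empirical frequency of contexts in the training
#' sequences. Sequences shorter than `order + 1` bases are skipped with a
#' warning; windows containing non-ACGT characters are ignored.
#'
#' @param sequences character vector or [Biostrings::DNAStringSet] of
#'   training sequences.
#' @param order Markov order (each base depends on this many preceding
#'   bases), default 6.
#' @param pseudocount added to every context->base count, default 1.
#' @return a [MarkovBackground-class].
#' @export
trainBackground <- function(sequences, order = 6, pseudocount = 1) {
  if (methods::is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  order <- as.integer(order)
  stopifnot(order >= 0)
  keep <- nchar(sequences) >= order + 1
  if (!all(keep))
    .warnf("%d sequence(s) shorter than order+1 skipped", sum(!keep))
  sequences <- sequences[keep]
  if (!length(sequences)) .stopf("no training sequence of length > order")
  nCtx <- 4L^order
  if (sum(nchar(sequences)) < nCtx)
    .warnf("total training length below 4^order; transition estimates will lean on the pseudocount")

  transCnt <- matrix(0, nCtx, 4)
  ctxCnt <- numeric(nCtx)
  pow <- 4^((order - 1):0)   # most significant digit = oldest base
  for (s in .encodeSeq(sequences)) {
    L <- length(s)
    if (order == 0L) {
      b <- s[!is.na(s)]
      transCnt[1, ] <- transCnt[1, ] + tabulate(b + 1L, 4L)
      ctxCnt[1] <- ctxCnt[1] + length(b)
      next
    }
    if (L < order + 1) next
    E <- embed(s, order + 1L)          # rows: (s_t, s_{t-1}, ..., s_{t-order})
    ok <- rowSums(is.na(E)) == 0
    if (!any(ok)) next
    E <- E[ok, , drop = FALSE]
    ctx <- as.vector(E[, (order + 1):2, drop = FALSE] %*% pow)
    base <- E[, 1]
    transCnt <- transCnt + matrix(tabulate(ctx * 4L + base + 1L, nCtx * 4L),
                                  nCtx, 4, byrow = TRUE)
    ctxCnt[ctx + 1L] <- ctxCnt[ctx + 1L] + 1
  }
  if (sum(ctxCnt) == 0) .stopf("no valid training windows (all skipped)")
  trans <- (transCnt + pseudocount) /
    (rowSums(transCnt) + 4 * pseudocount)
  start <- ctxCnt / sum(ctxCnt)
  new("MarkovBackground", order = order, transition = trans, startProb = start)
}

#' Stationary mononucleotide frequencies of a background model
#'
#' The order-0 base distribution implied by the model: the start-context
#' distribution pushed through one transition step.
#'
#' @param bg a [MarkovBackground-class].
#' @return named numeric length-4 vector (A, C, G, T).
#' @export
baseFrequencies <- function(bg) {
  f <- as.vector(bg@startProb %*% bg@transition)
  setNames(f / sum(f), .BASES)
}

#' Sample sequences from a Markov background
#'
#' Each sequence starts from a context drawn from the start distribution and
#' is extended by chaining transitions. Reproducible given a seed.
#'
#' @param bg a [MarkovBackground-class].
#' @param R number of sequences, default 10000.
#' @param length sequence length (> `bg` order).
#' @param seed optional integer seed.
#' @return character vector of `R` sequences.
#' @export
sampleSequences <- function(bg, R = 10000, length, seed = NULL) {
  k <- bg@order
  if (length <= k) .stopf("sequence length must exceed the Markov order (%d)", k)
  .withSeed(seed, "markov-sample", {
    nCtx <- 4L^k
    out <- matrix(0L, length, R)
    if (k > 0) {
      ctx <- sample.int(nCtx, R, replace = TRUE, prob = bg@startProb) - 1L
      # emit the start context's bases (oldest first)
      c0 <- ctx
      for (p in k:1) {
        out[p, ] <- c0 %% 4L
        c0 <- c0 %/% 4L
      }
      first <- k + 1L
      mod <- 4L^(k - 1L)
    } else {
      ctx <- rep(0L, R); first <- 1L; mod <- 1L
    }
    cum <- t(apply(bg@transition, 1, cumsum))
    for (p in first:length) {
      u <- runif(R)
      b <- rowSums(cum[ctx + 1L, , drop = FALSE] < u)   # 0..3
      out[p, ] <- b
      ctx <- if (k > 0) (ctx %% mod) * 4L + b else ctx
    }
    apply(out, 2, function(col) paste(.BASES[col + 1L], collapse = ""))
  })
}

## ---- scanning --------------------------------------------------------------

.logOdds <- function(motif, bg0) {
  p <- motifProbs(motif)
  log2(p / bg0)
}

.bg0 <- function(bg0) {
  if (methods::is(bg0, "MarkovBackground")) bg0 <- baseFrequencies(bg0)
  stopifnot(length(bg0) == 4, all(bg0 > 0))
  bg0 / sum(bg0)
}

#' Scan sequences with a motif
#'
#' The binding score of a sequence is the maximum, over all offsets and both
#' strands, of the summed log2 odds of the motif base probabilities against
#' an order-0 background. `N` bases contribute 0 at their position.
#'
#' @param motif a [MotifMatrix-class].
#' @param sequences character vector / [Biostrings::DNAStringSet] of
#'   sequences, each at least as long as the motif.
#' @param bg0 order-0 background: a length-4 probability vector (A, C, G, T)
#'   or a [MarkovBackground-class] (its stationary base frequencies are
#'   used).
#' @return numeric vector of one score per sequence.
#' @export
scanScores <- function(motif, sequences, bg0 = rep(0.25, 4)) {
  if (methods::is(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  if (any(nchar(sequences) < motifWidth(motif)))
    .stopf("sequence shorter than motif width (%d)", motifWidth(motif))
  .scanMaxCpp(toupper(sequences), .logOdds(motif, .bg0(bg0)))
}

#' @rdname scanScores
#' @param sequence a single sequence.
#' @return `scanScore`: a single score.
#' @export
scanScore <- function(motif, sequence, bg0 = rep(0.25, 4))
  scanScores(motif, sequence, bg0)[1]

## ---- local FDR curve -------------------------------------------------------

#' Calibrate binding scores to a local FDR against a null score sample
#'
#' The common range of observed and null scores is split into `k` equal-width
#' bins; bins holding fewer than `minBin` observed scores are collapsed with
#' their right neighbour (leftward at the right edge). Per bin,
#' `fdr_b = min(1, (I * n_b / R) / m_b)`; every bin whose upper edge is at or
#' below the midpoint of the score range is forced to 1, because low scores
#' are implausible binding events. A cubic smoothing spline through the bin
#' midpoints (number of knots = number of unique per-bin FDR values) gives
#' the local FDR at an arbitrary score.
#'
#' @param observedScores scores of the scanned real sequences (length I).
#' @param nullScores scores of background-sampled sequences (length R).
#' @param k initial number of equal-width bins, default 200.
#' @param minBin minimum observed-score occupancy per bin, default 20.
#' @param motifId label stored on the curve.
#' @return a [ScoreFdrCurve-class].
#' @export
buildFdrCurve <- function(observedScores, nullScores, k = 200, minBin = 20,
                          motifId = "motif") {
  stopifnot(length(observedScores) > 0, length(nullScores) > 0)
  I <- length(observedScores); R <- length(nullScores)
  rng <- range(c(observedScores, nullScores))
  if (diff(rng) <= 0) .stopf("degenerate score distribution")
  edges <- seq(rng[1], rng[2], length.out = k + 1)
  binOf <- function(x, e) pmin(pmax(findInterval(x, e, rightmost.closed = TRUE), 1),
                               length(e) - 1L)
  m <- tabulate(binOf(observedScores, edges), k)

  # Empty bins hold no binding evidence; before collapsing, each run of
  # empty bins is split at its middle so its null mass joins the nearer
  # occupied bin. Without this, a sparse bin merging rightward across an
  # empty score region drags that region's null counts into the next
  # occupied (often high-scoring) bin.
  occ <- which(m > 0)
  if (!length(occ)) .stopf("degenerate score distribution")
  cutIdx <- vapply(seq_len(length(occ) - 1), function(t)
    (occ[t] + occ[t + 1]) %/% 2L, 0L)
  edges <- c(edges[1], edges[cutIdx + 1L], edges[k + 1])
  m <- tabulate(binOf(observedScores, edges), length(edges) - 1L)
  n <- tabulate(binOf(nullScores, edges), length(edges) - 1L)

  # Collapse under-occupied bins with a neighbouring bin until every bin
  # holds at least minBin observed scores. The neighbour is the one whose
  # observed scores lie nearer (so an isolated low straggler rejoins the
  # bulk below it rather than dragging its null mass into a high-scoring
  # cluster); at the array ends the only neighbour is used.
  idx <- binOf(observedScores, edges)
  s <- as.numeric(tapply(observedScores, factor(idx, seq_along(m)), sum))
  s[is.na(s)] <- 0
  while (length(m) > 1 && any(m < minBin)) {
    b <- which(m < minBin)[1]
    mu <- s / pmax(m, 1)
    j <- if (b == 1L) 1L
         else if (b == length(m)) b - 1L
         else if ((mu[b] - mu[b - 1]) <= (mu[b + 1] - mu[b])) b - 1L
         else b
    m[j] <- m[j] + m[j + 1L]; m <- m[-(j + 1L)]
    n[j] <- n[j] + n[j + 1L]; n <- n[-(j + 1L)]
    s[j] <- s[j] + s[j + 1L]; s <- s[-(j + 1L)]
    edges <- edges[-(j + 1L)]
  }
  if (length(m) < 2) .stopf("degenerate score distribution")

  ratio <- (I * n / R) / pmax(m, 1)
  fdr <- pmin(1, ratio)
  mid <- mean(rng)
  forced <- edges[-1] <= mid
  fdr[forced] <- 1
  # the spline is fitted to the uncapped ratio (capping before smoothing
  # biases sparse tail bins downward under the null); the forced left tail
  # enters as exactly 1 and the evaluated curve is capped to [0, 1]
  ratio[forced] <- 1

  # representative score of a bin: mean observed score inside it (falls back
  # to the geometric midpoint for a forced left-tail bin); for dense score
  # sets this equals the midpoint, for atomic ones it sits on the atoms
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  idx <- pmin(pmax(findInterval(observedScores, edges, rightmost.closed = TRUE),
                   1), length(m))
  x <- as.numeric(tapply(observedScores, factor(idx, seq_along(m)), mean))
  x[is.na(x)] <- mids[is.na(x)]
  ord <- order(x)
  x <- x[ord]; fdrX <- ratio[ord]; mX <- m[ord]
  uniq <- length(unique(fdrX))
  spl <- if (length(x) >= 4 && uniq >= 4) {
    # weight bins by observed occupancy: the precision of fdr_b scales with m_b
    fit <- stats::smooth.spline(x, fdrX, w = mX / sum(mX),
                                nknots = min(uniq, length(x)))
    list(type = "spline", fit = fit, x = x)
  } else {
    list(type = "linear", x = x, y = fdrX)
  }
  new("ScoreFdrCurve", motifId = motifId, binEdges = edges,
      mObs = as.numeric(m), nNull = as.numeric(n),
      nObsTotal = as.integer(I), nNullTotal = as.integer(R),
      fdrBin = fdr, midpoint = mid, spline = spl)
}

#' Local FDR of a binding score
#'
#' Evaluates the smoothed curve, clamped to `[0, 1]`; scores at or below the
#' midpoint of the calibrated score range return 1 (forced region), and
#' scores beyond the fitted range take the boundary value.
#'
#' @param curve a [ScoreFdrCurve-class].
#' @param score numeric vector of scores.
#' @return numeric vector of local FDR values in `[0, 1]`.
#' @export
siteFdr <- function(curve, score) {
  x <- curve@spline$x
  s <- pmin(pmax(score, min(x)), max(x))
  y <- if (curve@spline$type == "spline")
    stats::predict(curve@spline$fit, s)$y
  else
    stats::approx(curve@spline$x, curve@spline$y, xout = s, rule = 2)$y
  y <- pmin(pmax(y, 0), 1)
  y[score <= curve@midpoint] <- 1
  y
}
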