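## Three-population empirical Bayes random-effects mixture for two-condition
## probe-level expression, fitted by EM.
##
## Model: G_ijkl = mu_il + b_ij + eps_ijkl, eps ~ N(0, sigma^2),
## b_ij ~ N(0, delta^2) (dropped for single-probe genes). Given the latent
## population Y_i, (mu_i1, mu_i2) is bivariate normal (up/down) or degenerate
## on the diagonal with mu ~ N(lambda, phi^2) (null). Integrating the latents
## out analytically makes each gene's observation vector multivariate normal,
## so both the marginal likelihood and the E-step are closed form.

## ---- internal: design preparation -----------------------------------------

# Genes sharing a probe/replicate layout share every covariance matrix, so we
# group genes by design signature and do all heavy linear algebra once per
# (group, population).
.ebPrep <- function(x) {
  df <- exprData(x)
  df <- df[order(df$gene_id, df$condition, df$probe_id, df$replicate), ]
  ids <- unique(df$gene_id)
  split_rows <- split(seq_len(nrow(df)), df$gene_id)[ids]

  sig <- character(length(ids))
  for (g in seq_along(ids)) {
    r <- split_rows[[g]]
    sig[g] <- paste(table(df$probe_id[r], df$condition[r]), collapse = ",")
  }

  groups <- list()
  for (s in unique(sig)) {
    gidx <- which(sig == s)
    r1 <- split_rows[[gidx[1]]]
    cond <- df$condition[r1]
    probe <- match(df$probe_id[r1], unique(df$probe_id[r1]))
    N <- length(r1); n <- max(probe)
    X <- cbind(as.numeric(cond == 1L), as.numeric(cond == 2L))
    Zb <- if (n > 1) outer(probe, seq_len(n), "==") * 1 else NULL
    Y <- matrix(0, N, length(gidx))
    for (k in seq_along(gidx)) Y[, k] <- df$value[split_rows[[gidx[k]]]]
    groups[[length(groups) + 1L]] <- list(
      geneIdx = gidx, Y = Y, X = X, Zb = Zb, N = N, n = n,
      ones = matrix(1, N, 1))
  }
  list(ids = ids, groups = groups, I = length(ids),
       totalObs = nrow(df))
}

## ---- internal: per-group, per-population linear algebra --------------------

# Marginal covariance of a gene's observation vector given its population.
.ebCov <- function(grp, params, pop) {
  V <- diag(params@sigma^2, grp$N)
  if (!is.null(grp$Zb)) V <- V + params@delta^2 * tcrossprod(grp$Zb)
  if (pop == "null") {
    V + params@phi^2 * tcrossprod(grp$ones)
  } else {
    S <- if (pop == "up") params@SigmaUp else params@SigmaDown
    V + grp$X %*% S %*% t(grp$X)
  }
}

.ebMean <- function(grp, params, pop) {
  switch(pop,
         up = as.vector(grp$X %*% params@etaUp),
         down = as.vector(grp$X %*% params@etaDown),
         null = rep(params@lambda, grp$N))
}

# Per-gene log density under one population, for all genes in a group.
.ebLogDens <- function(grp, params, pop) {
  V <- .ebCov(grp, params, pop)
  U <- tryCatch(chol(V), error = function(e)
    .stopf("covariance not positive definite for genes %s under the %s population",
           paste(head(grp$geneIdx, 3), collapse = ","), pop))
  logdet <- 2 * sum(log(diag(U)))
  R <- grp$Y - .ebMean(grp, params, pop)
  Z <- backsolve(U, R, transpose = TRUE)
  q <- colSums(Z^2)
  -0.5 * (grp$N * log(2 * pi) + logdet + q)
}

# Closed-form conditional (posterior) of the latent vector u = (mu, b) given
# the data and the population. Returns the shared posterior covariance C and
# the per-gene posterior means (d x nGenes).
.ebLatent <- function(grp, params, pop) {
  n <- grp$n
  hasB <- !is.null(grp$Zb)
  if (pop == "null") {
    W <- if (hasB) cbind(grp$ones, grp$Zb) else grp$ones
    Tdiag <- c(params@phi^2, if (hasB) rep(params@delta^2, n))
    Tinv <- diag(1 / Tdiag, length(Tdiag))
    m0 <- c(params@lambda, if (hasB) rep(0, n))
    dMu <- 1L
  } else {
    S <- if (pop == "up") params@SigmaUp else params@SigmaDown
    eta <- if (pop == "up") params@etaUp else params@etaDown
    W <- if (hasB) cbind(grp$X, grp$Zb) else grp$X
    d <- 2L + if (hasB) n else 0L
    Tinv <- matrix(0, d, d)
    Tinv[1:2, 1:2] <- solve(S)
    if (hasB) diag(Tinv)[3:d] <- 1 / params@delta^2
    m0 <- c(eta, if (hasB) rep(0, n))
    dMu <- 2L
  }
  WtW <- crossprod(W)
  A <- Tinv + WtW / params@sigma^2
  C <- solve(A)
  Wty <- crossprod(W, grp$Y)
  Emu <- C %*% (as.vector(Tinv %*% m0) + Wty / params@sigma^2)
  list(W = W, WtW = WtW, C = C, Emu = Emu, Wty = Wty, dMu = dMu, hasB = hasB)
}

.POPS <- c("up", "null", "down")

# E-step quantities for the whole dataset: log mixture densities, posterior
# weights, and (optionally) latent posteriors per group/population.
.ebEStep <- function(prep, params, latents = FALSE) {
  I <- prep$I
  logd <- matrix(NA_real_, I, 3, dimnames = list(NULL, .POPS))
  lat <- if (latents) vector("list", length(prep$groups))
  for (gi in seq_along(prep$groups)) {
    grp <- prep$groups[[gi]]
    for (p in .POPS)
      logd[grp$geneIdx, p] <- .ebLogDens(grp, params, p)
    if (latents)
      lat[[gi]] <- lapply(setNames(.POPS, .POPS), function(p)
        .ebLatent(grp, params, p))
  }
  logrho <- log(pmax(params@rho, 1e-300))
  lw <- sweep(logd, 2, logrho, "+")
  ll <- .logSumExpRows(lw)
  w <- exp(lw - ll)
  list(logLik = sum(ll), weights = w, latents = lat, logDens = logd)
}

## ---- exported operations ---------------------------------------------------

#' Marginal log-likelihood of the mixture model
#'
#' Sum over genes of the log of the rho-weighted mixture of multivariate
#' normal densities obtained by integrating the latent condition means and
#' probe effects out of the random-effects model.
#'
#' @param x a [ProbeExpression-class] dataset.
#' @param params a [MixtureParams-class].
#' @return the observed-data log-likelihood (a single number).
#' @export
marginalLogLik <- function(x, params) {
  validObject(params)
  prep <- .ebPrep(x)
  .ebEStep(prep, params)$logLik
}

#' Per-gene posterior population probabilities and fold-change
#'
#' Posterior probabilities of the three latent populations for each gene,
#' `p_Y = rho_Y L_Y / sum(rho L)`, together with the signed linear-scale
#' fold-change computed from the model-based posterior means of the two
#' condition means.
#'
#' @param x a [ProbeExpression-class] dataset.
#' @param params a [MixtureParams-class] (fitted or supplied).
#' @return data.frame with columns `gene_id`, `p_up`, `p_null`, `p_down`,
#'   `fc` (linear scale, magnitude >= 1, sign = direction).
#' @export
posteriorProbs <- function(x, params) {
  validObject(params)
  prep <- .ebPrep(x)
  es <- .ebEStep(prep, params, latents = TRUE)
  mu <- matrix(0, prep$I, 2)
  for (gi in seq_along(prep$groups)) {
    grp <- prep$groups[[gi]]
    lat <- es$latents[[gi]]
    w <- es$weights[grp$geneIdx, , drop = FALSE]
    muUp <- t(lat$up$Emu[1:2, , drop = FALSE])
    muDn <- t(lat$down$Emu[1:2, , drop = FALSE])
    mu0 <- lat$null$Emu[1, ]
    mu[grp$geneIdx, ] <- w[, "up"] * muUp + w[, "down"] * muDn +
      w[, "null"] * cbind(mu0, mu0)
  }
  ratio <- 2^(mu[, 2] - mu[, 1])
  fc <- ifelse(ratio >= 1, ratio, -1 / ratio)
  data.frame(gene_id = prep$ids, p_up = es$weights[, "up"],
             p_null = es$weights[, "null"], p_down = es$weights[, "down"],
             fc = fc, stringsAsFactors = FALSE)
}

#' Call differentially expressed genes
#'
#' A gene is called up-regulated when its posterior probability of the up
#' population is at least `c` and its linear fold-change is at least
#' `fcMin`; down-regulated symmetrically; otherwise unchanged. The local FDR
#' of a gene is 1 minus the posterior probability of its assigned class;
#' the set-level FDR of the call list (attribute `set_fdr`) averages the
#' local FDR over called (up/down) genes.
#'
#' @param posteriors data.frame from [posteriorProbs()].
#' @param c posterior threshold, default 0.80.
#' @param fcMin fold-change threshold on the linear scale, default 1.20
#'   (a 20% change).
#' @return the input with columns `call` (`up`/`down`/`unchanged`) and
#'   `local_fdr` added; attribute `set_fdr` holds the mean local FDR of the
#'   called genes (NA when nothing is called).
#' @export
classifyGenes <- function(posteriors, c = 0.80, fcMin = 1.20) {
  stopifnot(c > 0, c < 1, fcMin >= 1)
  if (!nrow(posteriors)) {
    posteriors$call <- character(0); posteriors$local_fdr <- numeric(0)
    attr(posteriors, "set_fdr") <- NA_real_
    return(posteriors)
  }
  up <- posteriors$p_up >= c & posteriors$fc >= fcMin
  down <- posteriors$p_down >= c & posteriors$fc <= -fcMin
  call <- ifelse(up, "up", ifelse(down, "down", "unchanged"))
  lfdr <- ifelse(up, 1 - posteriors$p_up,
                 ifelse(down, 1 - posteriors$p_down, 1 - posteriors$p_null))
  posteriors$call <- call
  posteriors$local_fdr <- lfdr
  called <- call != "unchanged"
  attr(posteriors, "set_fdr") <- if (any(called)) mean(lfdr[called]) else NA_real_
  posteriors
}

## ---- EM --------------------------------------------------------------------

.floorVar <- 1e-6

.ebMStep <- function(prep, es, params) {
  I <- prep$I
  w <- es$weights
  sw <- colSums(w)

  swmUp <- c(0, 0); swmmUp <- matrix(0, 2, 2); swCUp <- matrix(0, 2, 2)
  swmDn <- c(0, 0); swmmDn <- matrix(0, 2, 2); swCDn <- matrix(0, 2, 2)
  swm0 <- 0; swmm0 <- 0; swC0 <- 0
  deltaNum <- 0; deltaDen <- 0
  sigmaNum <- 0

  for (gi in seq_along(prep$groups)) {
    grp <- prep$groups[[gi]]
    lat <- es$latents[[gi]]
    wg <- w[grp$geneIdx, , drop = FALSE]
    yss <- colSums(grp$Y^2)
    for (p in .POPS) {
      L <- lat[[p]]
      wv <- wg[, p]
      muM <- L$Emu[seq_len(L$dMu), , drop = FALSE]     # dMu x G
      if (p == "up") {
        swmUp <- swmUp + as.vector(muM %*% wv)
        swmmUp <- swmmUp + muM %*% (wv * t(muM))
        swCUp <- swCUp + sum(wv) * L$C[1:2, 1:2]
      } else if (p == "down") {
        swmDn <- swmDn + as.vector(muM %*% wv)
        swmmDn <- swmmDn + muM %*% (wv * t(muM))
        swCDn <- swCDn + sum(wv) * L$C[1:2, 1:2]
      } else {
        swm0 <- swm0 + sum(wv * muM[1, ])
        swmm0 <- swmm0 + sum(wv * muM[1, ]^2)
        swC0 <- swC0 + sum(wv) * L$C[1, 1]
      }
      if (L$hasB) {
        bIdx <- (L$dMu + 1):nrow(L$Emu)
        Eb2 <- colSums(L$Emu[bIdx, , drop = FALSE]^2) +
          sum(diag(L$C)[bIdx])
        deltaNum <- deltaNum + sum(wv * Eb2)
      }
      # E||y - W u||^2 = ||y||^2 - 2 Emu.Wty + Emu' WtW Emu + tr(WtW C)
      cross <- colSums(L$Emu * L$Wty)
      quad <- colSums(L$Emu * (L$WtW %*% L$Emu))
      trc <- sum(L$WtW * L$C)
      sigmaNum <- sigmaNum + sum(wv * (yss - 2 * cross + quad + trc))
    }
    if (!is.null(grp$Zb)) deltaDen <- deltaDen + grp$n * length(grp$geneIdx)
  }

  rho <- sw / I
  if (any(rho < 1e-6)) {
    .warnf("mixture weight floored at 1e-6 during EM")
    rho <- pmax(rho, 1e-6); rho <- rho / sum(rho)
  }

  symm <- function(S) (S + t(S)) / 2
  fixPD <- function(S) {
    S <- symm(S)
    ev <- eigen(S, symmetric = TRUE)
    ev$values <- pmax(ev$values, .floorVar)
    ev$vectors %*% (ev$values * t(ev$vectors))
  }
  etaUp <- swmUp / sw["up"]
  SigmaUp <- fixPD((swmmUp + swCUp) / sw["up"] - tcrossprod(etaUp))
  etaDn <- swmDn / sw["down"]
  SigmaDn <- fixPD((swmmDn + swCDn) / sw["down"] - tcrossprod(etaDn))
  lambda <- unname(swm0 / sw["null"])
  phi2 <- max((swmm0 + swC0) / sw["null"] - lambda^2, .floorVar)
  delta2 <- if (deltaDen > 0) max(deltaNum / deltaDen, .floorVar) else params@delta^2
  sigma2 <- max(sigmaNum / prep$totalObs, .floorVar)

  # slot updates only: orientation validity is enforced on the final fit,
  # not per iteration (a vestigial component may wander across the diagonal
  # while the likelihood still ascends)
  p <- params
  p@rho <- setNames(rho, c("up", "null", "down"))
  p@etaUp <- unname(etaUp); p@SigmaUp <- unname(SigmaUp)
  p@etaDown <- unname(etaDn); p@SigmaDown <- unname(SigmaDn)
  p@lambda <- lambda; p@phi <- sqrt(phi2)
  p@sigma <- sqrt(sigma2); p@delta <- sqrt(delta2)
  p
}

# Per-gene condition means and a pooled residual-SD estimate, shared by the
# initialisation strategies.
.ebMoments <- function(prep) {
  m <- matrix(0, prep$I, 2)
  resvar <- 0; nres <- 0
  for (grp in prep$groups) {
    cs1 <- colSums(grp$Y * grp$X[, 1]) / sum(grp$X[, 1])
    cs2 <- colSums(grp$Y * grp$X[, 2]) / sum(grp$X[, 2])
    m[grp$geneIdx, ] <- cbind(cs1, cs2)
    fit <- grp$Y - grp$X %*% rbind(cs1, cs2)
    resvar <- resvar + sum(fit^2); nres <- nres + length(fit)
  }
  list(m = m, sigma = max(sqrt(resvar / max(nres, 1)) * 0.8, 0.05))
}

# Moment-based initialisation: partition genes by the sign of the difference
# of their condition means beyond +/- 1 pooled SD, then method of moments.
.ebAutoInit <- function(prep) {
  mom <- .ebMoments(prep)
  m <- mom$m
  d <- m[, 2] - m[, 1]
  sdd <- max(sd(d), 0.05)
  up <- d > sdd; down <- d < -sdd; nul <- !up & !down
  prop <- pmax(c(sum(up), sum(nul), sum(down)) / prep$I, 0.02)
  rho <- prop / sum(prop)
  mkEta <- function(sel, fallback) {
    if (sum(sel) >= 2) colMeans(m[sel, , drop = FALSE]) else fallback
  }
  mid <- mean(m)
  etaUp <- mkEta(up, c(mid, mid + 1))
  etaDn <- mkEta(down, c(mid, mid - 1))
  if (etaUp[2] <= etaUp[1]) etaUp <- c(mean(etaUp), mean(etaUp)) + c(-0.5, 0.5)
  if (etaDn[2] >= etaDn[1]) etaDn <- c(mean(etaDn), mean(etaDn)) + c(0.5, -0.5)
  mkSigma <- function(sel) {
    S <- if (sum(sel) >= 5) cov(m[sel, , drop = FALSE]) else diag(0.5, 2)
    S + diag(0.05, 2)
  }
  lambda <- mean(rowMeans(m[nul, , drop = FALSE]))
  phi <- max(sd(rowMeans(m[nul, , drop = FALSE])), 0.1)
  sigma <- mom$sigma
  delta <- max(sigma * 0.8, 0.05)
  MixtureParams(rho, etaUp, mkSigma(up), etaDn, mkSigma(down),
                lambda, phi, sigma, delta)
}

# Null-dominant initialisation: starts from an almost-pure null population
# with vestigial up/down components one unit off the diagonal. On data with
# no real differential signal the likelihood surface is flat in the mixture
# weights, so EM stays near whichever basin it starts in; offering this
# candidate lets the restart selection collapse to the parsimonious fit
# when the data support it.
.ebNullInit <- function(prep) {
  mom <- .ebMoments(prep)
  mid <- rowMeans(mom$m)
  MixtureParams(c(0.01, 0.98, 0.01),
                c(mean(mid), mean(mid) + 1), diag(0.5, 2),
                c(mean(mid), mean(mid) - 1), diag(0.5, 2),
                mean(mid), max(sd(mid), 0.1), mom$sigma,
                max(mom$sigma * 0.8, 0.05))
}

.jitterInit <- function(p) {
  MixtureParams(p@rho,
                p@etaUp + rnorm(2, 0, 0.2), p@SigmaUp * exp(rnorm(1, 0, 0.2)),
                p@etaDown + rnorm(2, 0, 0.2) * c(1, -1) * 0 + rnorm(2, 0, 0.2),
                p@SigmaDown * exp(rnorm(1, 0, 0.2)),
                p@lambda + rnorm(1, 0, 0.2), p@phi * exp(rnorm(1, 0, 0.2)),
                p@sigma * exp(rnorm(1, 0, 0.2)), p@delta * exp(rnorm(1, 0, 0.2)))
}

# Relabel populations after fitting so "up" is the component whose centre
# lies furthest above the diagonal.
.relabel <- function(p) {
  dUp <- p@etaUp[2] - p@etaUp[1]
  dDn <- p@etaDown[2] - p@etaDown[1]
  if (dUp < dDn) {
    q <- p
    q@rho <- setNames(p@rho[c(3, 2, 1)], c("up", "null", "down"))
    q@etaUp <- p@etaDown; q@SigmaUp <- p@SigmaDown
    q@etaDown <- p@etaUp; q@SigmaDown <- p@SigmaUp
    p <- q
  }
  # a component that collapsed onto the diagonal (possible when its weight
  # is vestigial) is nudged minimally to its own side
  fixSide <- function(eta, sign) {
    if (sign * (eta[2] - eta[1]) > 0) return(eta)
    mean(eta) + sign * c(-5e-7, 5e-7)
  }
  p@etaUp <- fixSide(p@etaUp, 1)
  p@etaDown <- fixSide(p@etaDown, -1)
  p
}

#' Fit the three-population mixture by EM
#'
#' Expectation-Maximisation on the latent populations, condition means and
#' probe effects. Both steps are closed form (conditional Gaussians), so the
#' observed-data log-likelihood is non-decreasing at every iteration. With
#' `nRestarts > 1`, the initial parameters are jittered and the restart with
#' the best final log-likelihood wins.
#'
#' @param x a [ProbeExpression-class] dataset (>= 50 genes recommended).
#' @param init a [MixtureParams-class], or `"auto"` for a moment-based
#'   initialisation from a 3-way partition of the per-gene condition-mean
#'   differences at +/- 1 pooled SD.
#' @param tol relative log-likelihood change for convergence, default 1e-8.
#' @param maxIter maximum EM iterations, default 1000.
#' @param nRestarts number of restarts (first uses `init` untouched).
#' @param seed optional seed controlling restart jitter.
#' @return an [EBFit-class] with the winning parameters and the
#'   log-likelihood trace of the winning run.
#' @export
fitEM <- function(x, init = "auto", tol = 1e-8, maxIter = 1000,
                  nRestarts = 1, seed = NULL) {
  stopifnot(tol > 0, maxIter >= 1, nRestarts >= 1)
  prep <- .ebPrep(x)
  if (prep$I < 50)
    .warnf("EM on %d genes; >= 50 recommended for stable estimates", prep$I)
  base <- if (identical(init, "auto")) .ebAutoInit(prep) else init
  validObject(base)

  runOnce <- function(p0) {
    trace <- numeric(0)
    p <- p0
    for (it in seq_len(maxIter)) {
      es <- .ebEStep(prep, p, latents = TRUE)
      trace[it] <- es$logLik
      if (it > 1) {
        rel <- abs(trace[it] - trace[it - 1]) /
          max(1, abs(trace[it - 1]))
        if (rel < tol) break
      }
      p <- suppressWarnings(.ebMStep(prep, es, p))
    }
    list(params = p, trace = trace, converged = it < maxIter, iter = it)
  }

  starts <- list(base)
  if (identical(init, "auto")) starts <- c(starts, list(.ebNullInit(prep)))
  for (r in seq_len(nRestarts - 1))
    starts <- c(starts, list(
      .withSeed(if (is.null(seed)) r else seed, paste0("em-restart-", r),
                .jitterInit(base))))

  best <- NULL
  for (p0 in starts) {
    res <- tryCatch(runOnce(p0), error = function(e) NULL)
    if (!is.null(res) &&
        (is.null(best) || max(res$trace) > max(best$trace)))
      best <- res
  }
  if (is.null(best)) .stopf("EM failed for every restart")
  params <- .relabel(best$params)
  validObject(params)
  new("EBFit", params = params, logLikTrace = best$trace,
      converged = best$converged, iterations = as.integer(best$iter))
}
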