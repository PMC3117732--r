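# Shared fixtures and independent oracles used across test files.

# A minimal well-formed expression table: one gene, one probe, two
# conditions x two replicates.
tinyExprFile <- function(path = tempfile(fileext = ".tsv")) {
  writeLines(c("gene_id\tprobe_id\tcondition\treplicate\tvalue",
               "g1\tp1\t1\t1\t8.0",
               "g1\tp1\t1\t2\t8.2",
               "g1\tp1\t2\t1\t9.1",
               "g1\tp1\t2\t2\t8.9"), path)
  path
}

# Build a ProbeExpression directly from per-gene condition value lists.
exprFromValues <- function(valuesByGene) {
  rows <- do.call(rbind, lapply(names(valuesByGene), function(g) {
    v <- valuesByGene[[g]]
    do.call(rbind, lapply(1:2, function(l)
      data.frame(gene_id = g, probe_id = "p1", condition = l,
                 replicate = seq_along(v[[l]]), value = v[[l]],
                 stringsAsFactors = FALSE)))
  }))
  ProbeExpression(rows)
}

# Independent quadrature oracle for the marginal likelihood and posteriors
# of a single-probe gene (probe effect absent): integrates the latent
# condition means numerically instead of using the analytic Gaussian
# marginalisation.
oracleGeneLik <- function(y1, y2, params) {
  s <- params@sigma
  lik2d <- function(eta, Sigma) {
    Sinv <- solve(Sigma); dS <- det(Sigma)
    f2 <- function(m1, m2) {
      d1 <- m1 - eta[1]; d2 <- m2 - eta[2]
      prior <- exp(-0.5 * (Sinv[1, 1] * d1^2 + 2 * Sinv[1, 2] * d1 * d2 +
                             Sinv[2, 2] * d2^2)) / (2 * pi * sqrt(dS))
      ll <- 0 * m1
      for (v in y1) ll <- ll + dnorm(v, m1, s, log = TRUE)
      for (v in y2) ll <- ll + dnorm(v, m2, s, log = TRUE)
      prior * exp(ll)
    }
    # nested adaptive quadrature, inner integral over m2
    w <- 10 * sqrt(max(diag(Sigma)) + s^2)
    inner <- function(m1) vapply(m1, function(a)
      integrate(function(b) f2(a, b), eta[2] - w, eta[2] + w,
                rel.tol = 1e-12, abs.tol = 0)$value, 0)
    integrate(inner, eta[1] - w, eta[1] + w, rel.tol = 1e-11,
              abs.tol = 0)$value
  }
  lik0 <- function() {
    f <- function(m) {
      out <- dnorm(m, params@lambda, params@phi)
      for (v in c(y1, y2)) out <- out * dnorm(v, m, s)
      out
    }
    w <- 8 * (params@phi + s)
    integrate(f, params@lambda - w, params@lambda + w,
              rel.tol = 1e-11)$value
  }
  c(up = lik2d(params@etaUp, params@SigmaUp),
    null = lik0(),
    down = lik2d(params@etaDown, params@SigmaDown))
}

oraclePosterior <- function(y1, y2, params) {
  L <- oracleGeneLik(y1, y2, params)
  w <- params@rho * L
  w / sum(w)
}

# Exact subset-enumeration oracle for the hub null distribution: sums the
# probability of every subset of genes connecting the TF.
oracleHubPmf <- function(drawSizes, n) {
  M <- length(drawSizes)
  p <- drawSizes / n
  pmf <- numeric(M + 1)
  for (mask in 0:(2^M - 1)) {
    inc <- as.logical(bitwAnd(mask, 2^(0:(M - 1))))
    pmf[sum(inc) + 1] <- pmf[sum(inc) + 1] +
      prod(ifelse(inc, p, 1 - p))
  }
  pmf
}

# Direct transcription of the printed SERM inequalities.
oracleSermClass <- function(e2, serm, combo) {
  e2 <- abs(e2); serm <- abs(serm); combo <- abs(combo)
  ifelse(serm > 1 + 0.70 * (e2 - 1), "agonist",
         ifelse(serm < 1 + 0.35 * (e2 - 1) & combo < 1 + 0.50 * (e2 - 1),
                "antagonist", "partial"))
}
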