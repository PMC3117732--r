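params0 <- defaultMixtureParams()

test_that("marginal log-likelihood matches the closed form for a pure-null model", {
  p <- MixtureParams(rho = c(0, 1, 0),
                     etaUp = c(8, 9), SigmaUp = diag(0.5, 2),
                     etaDown = c(8, 7), SigmaDown = diag(0.5, 2),
                     lambda = 8, phi = 0.7, sigma = 0.3, delta = 0.2)
  x <- exprFromValues(list(g1 = list(8, 8)))   # one value per condition, at lambda
  # y ~ N(lambda * 1, sigma^2 I + phi^2 J), evaluated at y = (lambda, lambda)
  V <- diag(p@sigma^2, 2) + p@phi^2
  manual <- -log(2 * pi) - 0.5 * log(det(V))
  expect_equal(marginalLogLik(x, p), manual, tolerance = 1e-10)
})

test_that("single-probe marginals and posteriors match a quadrature oracle", {
  p <- params0
  cases <- list(list(y1 = c(7.9, 8.1), y2 = c(9.0, 9.2)),
                list(y1 = c(8.0, 8.1), y2 = c(8.05, 8.15)),
                list(y1 = c(8.5, 8.4), y2 = c(7.0, 7.2)))
  x <- exprFromValues(setNames(lapply(cases, function(cs)
    list(cs$y1, cs$y2)), paste0("g", seq_along(cases))))
  post <- posteriorProbs(x, p)
  ll <- marginalLogLik(x, p)
  llOracle <- 0
  for (i in seq_along(cases)) {
    o <- oraclePosterior(cases[[i]]$y1, cases[[i]]$y2, p)
    expect_equal(unname(unlist(post[i, c("p_up", "p_null", "p_down")])),
                 unname(o), tolerance = 1e-5)
    llOracle <- llOracle + log(sum(p@rho * oracleGeneLik(cases[[i]]$y1,
                                                         cases[[i]]$y2, p)))
  }
  expect_equal(ll, llOracle, tolerance = 1e-6)
})

test_that("log-likelihood is additive over genes", {
  sim <- simulateExpression(params0, I = 20, seed = 3)
  ll1 <- marginalLogLik(sim$expr, params0)
  df <- exprData(sim$expr)
  df2 <- df; df2$gene_id <- paste0(df2$gene_id, "_copy")
  both <- ProbeExpression(rbind(df, df2))
  expect_equal(marginalLogLik(both, params0), 2 * ll1, tolerance = 1e-9)
})

test_that("EM ascends the likelihood and recovers a zero-effect dataset", {
  sim <- simulateExpression(params0, I = 300, seed = 11)
  fit <- fitEM(sim$expr, seed = 1)
  tr <- logLikTrace(fit)
  expect_true(all(diff(tr) >= -1e-10 * pmax(1, abs(tr[-length(tr)]))))
  expect_true(fit@converged)

  # identical condition means for every gene: whatever weight the fitted
  # differential components keep, their centres collapse onto the diagonal
  # (they become null-equivalent), and no gene is called differential
  null <- simulateExpression(MixtureParams(c(0, 1, 0), c(8, 9), diag(0.3, 2),
                                           c(8, 7), diag(0.3, 2),
                                           8, 1, 0.3, 0.3),
                             I = 400, seed = 5, labels = rep(0L, 400))
  fit0 <- fitEM(null$expr, seed = 2)
  p0 <- fittedParams(fit0)
  offDiagMass <- p0@rho[["up"]] * abs(p0@etaUp[2] - p0@etaUp[1]) +
    p0@rho[["down"]] * abs(p0@etaDown[2] - p0@etaDown[1])
  expect_lt(offDiagMass, 0.1)
  de0 <- classifyGenes(posteriorProbs(null$expr, p0))
  expect_lte(mean(de0$call != "unchanged"), 0.01)
})

test_that("posteriors are normalized, symmetric, and decisive far off-diagonal", {
  sim <- simulateExpression(params0, I = 100, seed = 21)
  post <- posteriorProbs(sim$expr, params0)
  expect_true(all(abs(rowSums(post[, c("p_up", "p_null", "p_down")]) - 1) < 1e-9))

  # mirror symmetry: a gene with equal condition means under mirror-image
  # parameters has p_up == p_down
  pSym <- MixtureParams(c(0.2, 0.6, 0.2), c(8, 9), diag(0.4, 2),
                        c(9, 8), diag(0.4, 2), 8.5, 1, 0.3, 0.3)
  xe <- exprFromValues(list(g1 = list(c(8.5, 8.6), c(8.5, 8.6))))
  pe <- posteriorProbs(xe, pSym)
  expect_equal(pe$p_up, pe$p_down, tolerance = 1e-9)

  # swapping conditions with mirrored parameters swaps p_up and p_down
  df <- exprData(sim$expr); df$condition <- 3L - df$condition
  swapped <- ProbeExpression(df)
  pMir <- MixtureParams(params0@rho[c(3, 2, 1)],
                        rev(params0@etaDown), params0@SigmaDown[2:1, 2:1],
                        rev(params0@etaUp), params0@SigmaUp[2:1, 2:1],
                        params0@lambda, params0@phi, params0@sigma,
                        params0@delta)
  postSwap <- posteriorProbs(swapped, pMir)
  expect_equal(postSwap$p_up, post$p_down, tolerance = 1e-9)
  expect_equal(postSwap$p_down, post$p_up, tolerance = 1e-9)

  # a gene far above the diagonal is called up with near certainty
  far <- exprFromValues(list(g1 = list(c(8, 8), c(12, 12))))
  pf <- posteriorProbs(far, params0)
  expect_gt(pf$p_up, 0.999)
})

test_that("gene calls follow the posterior and fold-change thresholds", {
  post <- data.frame(gene_id = c("a", "b", "c"),
                     p_up = c(0.90, 0.95, 0.45),
                     p_null = c(0.05, 0.03, 0.10),
                     p_down = c(0.05, 0.02, 0.45),
                     fc = c(1.5, 1.10, 1.05))
  got <- classifyGenes(post)
  expect_equal(got$call, c("up", "unchanged", "unchanged"))
  expect_equal(got$local_fdr[1], 0.10, tolerance = 1e-12)
  expect_equal(attr(got, "set_fdr"), 0.10, tolerance = 1e-12)

  down <- data.frame(gene_id = "d", p_up = 0.05, p_null = 0.05,
                     p_down = 0.90, fc = -1.5)
  expect_equal(classifyGenes(down)$call, "down")

  empty <- classifyGenes(post[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("local FDR is calibrated against realized false calls", {
  sim <- simulateExpression(params0, I = 2000, seed = 31)
  post <- posteriorProbs(sim$expr, params0)
  de <- classifyGenes(post)
  called <- de$call != "unchanged"
  trueY <- sim$truth$Y[match(de$gene_id, sim$truth$gene_id)]
  falseCall <- (de$call == "up" & trueY != 1L) |
    (de$call == "down" & trueY != -1L)
  realized <- mean(falseCall[called])
  expect_equal(attr(de, "set_fdr"), realized, tolerance = 0.05)
})

test_that("parameter recovery holds at moderate size", {
  sim <- simulateExpression(params0, I = 600, seed = 41)
  fit <- fitEM(sim$expr, seed = 3)
  realized <- as.numeric(table(factor(sim$truth$Y, c(1, 0, -1)))) / 600
  expect_lt(max(abs(unname(fittedParams(fit)@rho) - realized)), 0.05)
  expect_lt(abs(fittedParams(fit)@lambda - 8), 0.15)
})
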