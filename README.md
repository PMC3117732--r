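# ebTFnet

Empirical Bayes inference of topological transcription-factor regulatory
networks — genomic versus non-genomic target classification for a
ligand-activated TF (the motivating system is ERα in hormone-responsive
breast cancer cells), for computational biologists integrating
two-condition expression data, ChIP peaks and motif scans.

## What it computes

Three calibrated evidence layers feed one decision rule:

1. **Differential expression.** Probe-level log2 expression follows the
   random-effects model `G_ijkl = mu_il + b_ij + eps_ijkl` with
   `b ~ N(0, delta^2)`, `eps ~ N(0, sigma^2)`, and the pair of condition
   means `(mu_i1, mu_i2)` drawn from one of three latent populations on
   the plane: a bivariate normal above the `y = x` diagonal (up-regulated),
   the diagonal itself with `mu ~ N(lambda, phi^2)` (unchanged), or a
   bivariate normal below (down-regulated), with weights `rho`. The
   parameter vector `theta = (rho, eta_1, Sigma_1, eta_-1, Sigma_-1,
   lambda, phi, sigma, delta)` is fitted by a closed-form EM; a gene is
   called when its directional posterior reaches `c = 0.80` **and** its
   linear fold-change reaches 1.20. The local FDR of a call is one minus
   the posterior of the assigned class.
2. **Motif-site local FDR.** Sequences are scanned with TRANSFAC-style
   PWMs (max log2-odds over offsets and both strands); scores are
   calibrated against `R = 10000` matched-length sequences sampled from an
   order-6 Markov background via binned local FDR,
   `fdr_b = min(1, (I n_b / R) / m_b)`, with the below-midpoint bins
   forced to 1 and a weighted cubic smoothing spline giving the FDR at any
   score.
3. **Mechanism classification.** A differentially expressed gene with a
   passing ChIP peak (peak FDR ≤ 0.05) is DBGA when the ERα motif passes
   (site FDR ≤ 0.05) inside a passing peak, I-DBGA when only other TF
   motifs pass; with no passing peak it is NGA when a TF motif passes in
   its upstream-1-kb promoter. Hub TFs get exact Poisson-binomial
   p-values `Pr(T >= t_obs)` under random draws of `n_i` TFs per gene from
   a pool of `n` known TFs.

Additional modules classify SERM (4-OH-tamoxifen / endoxifen) responses as
agonist / antagonist / partial from printed fold-change inequalities, and
non-responsive targets into five promoter-epigenetic mechanisms (basal
expression, hyper-/hypo-methylation, absolute methylation,
H3K27me3/H3K4me2 ratio) thresholded at the 80th percentile of a reference
gene universe. Synthetic-data generators for every input class make the
whole pipeline testable end to end.

## Worked example

Simulate a 200-gene scenario with a planted network (60 DBGA, 30 I-DBGA,
30 NGA targets plus 80 decoys) and run the full pipeline:

```r
library(ebTFnet)
sc  <- simulateRegulatoryScenario(defaultScenarioConfig(), seed = 1)
res <- runRegulatoryPipeline(sc, order = 2, seed = 1)
res$network
#> RegulatoryNetwork [scenario]: 112 edges (59 DBGA, 28 I-DBGA, 25 NGA), 3 TFs, 112 genes
#>   hubs annotated: 3 TFs
head(networkHubs(res$network), 3)
#>        tf target_count      p_value significant
#> 1 ERalpha           59 6.701283e-69        TRUE
#> 2     Sp1           28 1.021294e-22        TRUE
#> 3    E2F1           25 3.749892e-19        TRUE
mechanismAccuracy(res$calls, sc$truth)
#> [1] 0.955
```

59 of the 60 planted direct-binding targets are recovered as DBGA edges of
the ERα hub, whose connectivity is far beyond the random-draw null
(`p ≈ 7e-69` with a 50-TF pool); the tethering TFs (Sp1-like, E2F1-like)
recover their I-DBGA and NGA targets, and 95.5% of all 200 genes get their
true mechanism label. The fitted mixture tracks the generating parameters
(`lambda = 8.08`, `sigma = 0.21` against true values 8 and 0.2; `rho` here
reflects the forced scenario labels, not draws from `rho`).

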