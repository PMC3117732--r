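## Generators for every input class the pipeline consumes, with the
## statistical structure the models assume: three expression populations with
## probe/replicate noise, Markov background sequences with planted motifs,
## peaks with planted binding sites, and log-normal promoter epigenetic
## signals. All randomness flows from a single seed through named
## sub-streams, so regeneration from (seed, config) is byte-identical and
## adding a generator never perturbs existing fixtures.

#' Uniform Markov background
#'
#' A [MarkovBackground-class] whose every transition row equals `probs`
#' (default uniform) and whose start distribution is the corresponding
#' i.i.d. context distribution. Useful as a neutral sequence model for
#' simulations.
#'
#' @param order Markov order, default 0.
#' @param probs base probabilities (A, C, G, T).
#' @return a [MarkovBackground-class].
#' @export
uniformBackground <- function(order = 0, probs = rep(0.25, 4)) {
  probs <- probs / sum(probs)
  nCtx <- 4L^as.integer(order)
  trans <- matrix(probs, nCtx, 4, byrow = TRUE)
  start <- rep(1, nCtx)
  if (order > 0) {
    # start prob of a context = product of its digits' base probabilities
    for (i in seq_len(nCtx)) {
      c0 <- i - 1L
      for (d in seq_len(order)) {
        start[i] <- start[i] * probs[c0 %% 4L + 1L]
        c0 <- c0 %/% 4L
      }
    }
  }
  new("MarkovBackground", order = as.integer(order), transition = trans,
      startProb = start / sum(start))
}

#' Build a sharply peaked motif from a consensus string
#'
#' @param motifId,tfName identifiers.
#' @param consensus consensus sequence (A/C/G/T).
#' @param consensusProb probability of the consensus base per position;
#'   the rest is spread evenly over the other three bases.
#' @return a [MotifMatrix-class].
#' @export
consensusMotif <- function(motifId, tfName, consensus, consensusProb = 0.97) {
  b <- match(strsplit(toupper(consensus), "")[[1]], .BASES)
  if (any(is.na(b))) .stopf("consensus must be A/C/G/T only")
  p <- matrix((1 - consensusProb) / 3, 4, length(b))
  p[cbind(b, seq_along(b))] <- consensusProb
  MotifMatrix(motifId, tfName, p)
}

#' Simulate probe-level expression from the three-population mixture
#'
#' Draws each gene's population from `rho` (or takes it from `labels`), the
#' condition means from the population model, probe effects from
#' `N(0, delta^2)` (omitted for single-probe genes) and errors from
#' `N(0, sigma^2)`.
#'
#' @param params a [MixtureParams-class].
#' @param I number of genes.
#' @param probesPerGene probes per gene, default 3.
#' @param repsPerCondition replicates per condition (scalar or length-2),
#'   default 3.
#' @param seed optional seed.
#' @param labels optional integer vector of forced populations
#'   (1 = up, 0 = null, -1 = down).
#' @return list with `expr` (a [ProbeExpression-class]) and `truth`
#'   (data.frame `gene_id`, `Y`, `mu1`, `mu2`).
#' @export
simulateExpression <- function(params, I, probesPerGene = 3,
                               repsPerCondition = 3, seed = NULL,
                               labels = NULL) {
  if (I < 1) .stopf("I must be >= 1")
  validObject(params)
  m <- rep_len(repsPerCondition, 2)
  n <- probesPerGene
  .withSeed(seed, "expression", {
    Y <- if (is.null(labels))
      sample(c(1L, 0L, -1L), I, replace = TRUE, prob = params@rho)
    else rep_len(as.integer(labels), I)
    mu <- matrix(0, I, 2)
    for (s in c(1L, -1L)) {
      idx <- which(Y == s)
      if (!length(idx)) next
      eta <- if (s == 1L) params@etaUp else params@etaDown
      Sig <- if (s == 1L) params@SigmaUp else params@SigmaDown
      Z <- matrix(rnorm(2 * length(idx)), ncol = 2) %*% chol(Sig)
      mu[idx, ] <- sweep(Z, 2, eta, "+")
    }
    idx0 <- which(Y == 0L)
    if (length(idx0)) {
      m0 <- rnorm(length(idx0), params@lambda, params@phi)
      mu[idx0, ] <- cbind(m0, m0)
    }
    ids <- sprintf("gene%04d", seq_len(I))
    b <- if (n > 1) matrix(rnorm(I * n, 0, params@delta), I, n) else
      matrix(0, I, max(n, 1))
    rowsPerGene <- n * sum(m)
    gene <- rep(ids, each = rowsPerGene)
    cond <- rep(rep(c(1L, 2L), m), times = I * n)
    probe <- rep(rep(seq_len(n), each = sum(m)), times = I)
    repl <- rep(c(seq_len(m[1]), seq_len(m[2])), times = I * n)
    gi <- rep(seq_len(I), each = rowsPerGene)
    value <- mu[cbind(gi, cond)] + b[cbind(gi, probe)] +
      rnorm(I * rowsPerGene / 1, 0, params@sigma)
    expr <- ProbeExpression(data.frame(
      gene_id = gene, probe_id = sprintf("p%02d", probe),
      condition = cond, replicate = repl, value = value,
      stringsAsFactors = FALSE))
    list(expr = expr,
         truth = data.frame(gene_id = ids, Y = Y, mu1 = mu[, 1], mu2 = mu[, 2],
                            stringsAsFactors = FALSE))
  })
}

# Sample one motif instance per requested draw, base by base from the PWM
# columns (consensus-sampled, not consensus-fixed).
.sampleMotifInstances <- function(motif, nInst) {
  p <- motifProbs(motif)
  W <- ncol(p)
  out <- matrix("", nInst, W)
  for (w in seq_len(W))
    out[, w] <- sample(.BASES, nInst, replace = TRUE, prob = p[, w])
  apply(out, 1, paste, collapse = "")
}

#' Simulate background sequences with planted motif instances
#'
#' Background sequences are drawn from `bg`; a fraction `plantRate` of them
#' receives one motif instance (sampled from the PWM columns) substituted at
#' a uniformly random offset.
#'
#' @param bg a [MarkovBackground-class].
#' @param motif a [MotifMatrix-class].
#' @param nSeqs number of sequences.
#' @param length sequence length (>= motif width).
#' @param plantRate fraction of sequences carrying a planted instance.
#' @param seed optional seed.
#' @return list with `sequences` (named character vector) and `truth`
#'   (data.frame `seq_id`, `planted`, `position` (0-based, NA when not
#'   planted), `instance`).
#' @export
simulateSequencesWithMotifs <- function(bg, motif, nSeqs, length,
                                        plantRate, seed = NULL) {
  if (length < motifWidth(motif)) .stopf("length must be >= motif width")
  stopifnot(plantRate >= 0, plantRate <= 1)
  seqs <- sampleSequences(bg, nSeqs, length, seed = seed)
  W <- motifWidth(motif)
  .withSeed(seed, "motif-plant", {
    planted <- runif(nSeqs) < plantRate
    pos <- rep(NA_integer_, nSeqs)
    inst <- rep(NA_character_, nSeqs)
    idx <- which(planted)
    if (length(idx)) {
      pos[idx] <- sample.int(length - W + 1L, length(idx), replace = TRUE) - 1L
      inst[idx] <- .sampleMotifInstances(motif, length(idx))
      substr(seqs[idx], pos[idx] + 1L, pos[idx] + W) <- inst[idx]
    }
    names(seqs) <- sprintf("seq%05d", seq_len(nSeqs))
    list(sequences = seqs,
         truth = data.frame(seq_id = names(seqs), planted = planted,
                            position = pos, instance = inst,
                            stringsAsFactors = FALSE))
  })
}

#' Default configuration for a regulatory scenario
#'
#' The default mix plants the ERalpha hub with the most targets (60 DBGA
#' genes), two tethering/non-genomic TFs (Sp1-like and E2F1-like) sharing
#' the I-DBGA and NGA genes, and two decoy classes: differentially
#' expressed genes with no binding evidence, and bound genes with no
#' expression change.
#'
#' @param nDBGA,nIDBGA,nNGA,nDecoyDE,nDecoyPeak class sizes (default
#'   60/30/30/40/40).
#' @param nKnownTfs known-TF pool size for the hub test, default 50.
#' @param promoterLength promoter sequence length in bp, default 1000.
#' @param peakLength peak sequence length in bp, default 45.
#' @param peakFdr peak-level FDR given to planted peaks, default 0.001.
#' @param bgOrder Markov order of the generating background, default 0
#'   (uniform bases).
#' @return a config list consumed by [simulateRegulatoryScenario()].
#' @export
defaultScenarioConfig <- function(nDBGA = 60, nIDBGA = 30, nNGA = 30,
                                  nDecoyDE = 40, nDecoyPeak = 40,
                                  nKnownTfs = 50, promoterLength = 1000,
                                  peakLength = 45, peakFdr = 0.001,
                                  bgOrder = 0) {
  list(nDBGA = nDBGA, nIDBGA = nIDBGA, nNGA = nNGA, nDecoyDE = nDecoyDE,
       nDecoyPeak = nDecoyPeak, nKnownTfs = nKnownTfs,
       promoterLength = promoterLength, peakLength = peakLength,
       peakFdr = peakFdr, bgOrder = bgOrder,
       # low-noise expression regime: ~2.8-fold planted effects, tight
       # population spread, so differential calls are nearly deterministic
       params = MixtureParams(rho = c(0.15, 0.70, 0.15),
                              etaUp = c(8, 9.5),
                              SigmaUp = matrix(c(0.2, 0.05, 0.05, 0.2), 2),
                              etaDown = c(8, 6.5),
                              SigmaDown = matrix(c(0.2, 0.05, 0.05, 0.2), 2),
                              lambda = 8, phi = 1, sigma = 0.2, delta = 0.2),
       # 16-bp motifs: wide enough that sampled instances with 1-2
       # mismatches still score clear of the 1-kb background null
       motifs = list(
         consensusMotif("M_ERE", "ERalpha", "AGGTCACAGTGACCTG"),
         consensusMotif("M_SP1", "Sp1", "GGGGCGGGGCCTGGGC"),
         consensusMotif("M_E2F", "E2F1", "TTTCGCGCCAAAGTTT")))
}

#' Simulate a full regulatory scenario
#'
#' Generates every input of the network pipeline with known ground truth:
#' expression (DBGA/I-DBGA/NGA/DE-decoy genes differentially expressed,
#' peak-decoy genes unchanged), 45-bp ChIP peaks in the promoters of
#' genomic and peak-decoy genes (ERalpha instances planted in DBGA and
#' peak-decoy peaks, other-TF instances in I-DBGA peaks), 1-kb promoter
#' sequences (other-TF instances planted for NGA genes), gene annotation,
#' and the motif set.
#'
#' @param config list from [defaultScenarioConfig()].
#' @param seed integer seed; the bundle is a deterministic function of
#'   (seed, config).
#' @return list with `expr`, `exprTruth`, `annot`, `peaks` (data.frame with
#'   `sequence`), `promoters` (named character), `motifs`, `truth`
#'   (data.frame `gene_id`, `mechanism`, `direction`), `config`, `seed`.
#' @export
simulateRegulatoryScenario <- function(config = defaultScenarioConfig(),
                                       seed = 1) {
  nm <- c("nDBGA", "nIDBGA", "nNGA", "nDecoyDE", "nDecoyPeak")
  cnt <- unlist(config[nm])
  if (any(cnt < 0) || sum(cnt) < 1) .stopf("inconsistent class counts")
  I <- sum(cnt)
  mech <- rep(c("DBGA", "I-DBGA", "NGA", "unexplained", "none"), cnt)
  de <- mech != "none"

  labels <- integer(I)
  labels[de] <- .withSeed(seed, "scenario-directions",
                          sample(c(1L, -1L), sum(de), replace = TRUE))
  sim <- simulateExpression(config$params, I, seed = .subSeed(seed, "scenario-expr"),
                            labels = labels)
  ids <- sim$truth$gene_id

  # gene annotation: evenly spaced TSS on one chromosome, alternating strand
  genes <- data.frame(gene_id = ids, chrom = "chr1",
                      tss = 5000 + (seq_len(I) - 1) * 10000,
                      strand = rep(c("+", "-"), length.out = I),
                      stringsAsFactors = FALSE)
  annot <- geneAnnotation(genes, promoterWidth = config$promoterLength)

  bg <- uniformBackground(config$bgOrder)
  motifs <- config$motifs
  tfNames <- vapply(motifs, function(m) m@tfName, "")
  era <- which(tfNames == "ERalpha")
  others <- setdiff(seq_along(motifs), era)

  # promoters: background everywhere, other-TF instances planted in NGA genes
  prom <- sampleSequences(bg, I, config$promoterLength,
                          seed = .subSeed(seed, "scenario-promoters"))
  names(prom) <- ids
  ngaIdx <- which(mech == "NGA")
  promTruth <- data.frame(gene_id = character(), tf = character(),
                          position = integer(), stringsAsFactors = FALSE)
  .withSeed(seed, "scenario-nga-plant", {
    for (k in seq_along(ngaIdx)) {
      i <- ngaIdx[k]
      m <- motifs[[others[(k - 1) %% length(others) + 1]]]
      W <- motifWidth(m)
      pos <- sample.int(config$promoterLength - W + 1L, 1L) - 1L
      substr(prom[i], pos + 1L, pos + W) <- .sampleMotifInstances(m, 1)
      promTruth[nrow(promTruth) + 1L, ] <- list(ids[i], m@tfName, pos)
    }
  })

  # peaks: one 45-bp peak in the promoter of every genomic / peak-decoy gene
  pkIdx <- which(mech %in% c("DBGA", "I-DBGA", "none"))
  pkSeq <- sampleSequences(bg, length(pkIdx), config$peakLength,
                           seed = .subSeed(seed, "scenario-peaks"))
  .withSeed(seed, "scenario-peak-plant", {
    for (k in seq_along(pkIdx)) {
      i <- pkIdx[k]
      m <- if (mech[i] == "I-DBGA")
        motifs[[others[(k - 1) %% length(others) + 1]]]
      else motifs[[era]]                       # DBGA and peak decoys get ERE
      W <- motifWidth(m)
      pos <- sample.int(config$peakLength - W + 1L, 1L) - 1L
      substr(pkSeq[k], pos + 1L, pos + W) <- .sampleMotifInstances(m, 1)
    }
  })
  promStart <- ifelse(genes$strand[pkIdx] == "+",
                      genes$tss[pkIdx] - config$promoterLength,
                      genes$tss[pkIdx] + 1)
  pkStart <- promStart + (config$promoterLength - config$peakLength) %/% 2
  peaks <- data.frame(peak_id = sprintf("peak%04d", seq_along(pkIdx)),
                      chrom = "chr1", start = pkStart,
                      end = pkStart + config$peakLength,
                      peak_fdr = config$peakFdr,
                      assigned_gene = ids[pkIdx],
                      sequence = unname(pkSeq), stringsAsFactors = FALSE)

  truth <- data.frame(gene_id = ids, mechanism = mech,
                      direction = ifelse(labels == 1L, "up",
                                         ifelse(labels == -1L, "down", NA)),
                      stringsAsFactors = FALSE)
  list(expr = sim$expr, exprTruth = sim$truth, annot = annot, peaks = peaks,
       promoters = prom, motifs = motifs, truth = truth,
       promoterTruth = promTruth, config = config, seed = seed)
}

#' Simulate per-gene epigenetic profiles
#'
#' Draws i.i.d. log-normal raw signals (basal expression, parental and
#' resistant promoter methylation, H3K4me2, H3K27me3) and derives the ratio
#' features via [geneEpigeneticProfiles()]. `effectConfig` plants mechanism
#' carriers by multiplying the relevant raw signal for blocks of genes.
#'
#' @param N number of genes.
#' @param seed optional seed.
#' @param effectConfig optional named list (`m1`..`m5`), each entry
#'   `list(n = , factor = )`: the next `n` unplanted genes get the
#'   mechanism's driving signal multiplied by `factor`.
#' @param meanlog,sdlog log-normal parameters of the raw signals.
#' @return list with `profiles` (from [geneEpigeneticProfiles()]) and
#'   `truth` (data.frame `gene_id`, `planted` mechanism or "").
#' @export
simulateEpigeneticProfiles <- function(N, seed = NULL, effectConfig = NULL,
                                       meanlog = 3, sdlog = 1) {
  stopifnot(N >= 1)
  .withSeed(seed, "epigenetic-profiles", {
    raw <- matrix(stats::rlnorm(N * 5, meanlog, sdlog), N, 5)
    colnames(raw) <- c("basal", "methPar", "methRes", "k4", "k27")
    planted <- rep("", N)
    nextFree <- 1L
    for (m in names(effectConfig)) {
      cfg <- effectConfig[[m]]
      idx <- seq(nextFree, length.out = cfg$n)
      nextFree <- nextFree + cfg$n
      col <- switch(m, m1 = "basal", m2 = "methRes", m3 = "methPar",
                    m4 = "methRes", m5 = "k27")
      raw[idx, col] <- raw[idx, col] * cfg$factor
      planted[idx] <- m
    }
    ids <- sprintf("gene%05d", seq_len(N))
    list(profiles = geneEpigeneticProfiles(ids, raw[, "basal"],
                                           raw[, "methPar"], raw[, "methRes"],
                                           raw[, "k4"], raw[, "k27"]),
         truth = data.frame(gene_id = ids, planted = planted,
                            stringsAsFactors = FALSE))
  })
}

#' Write a simulated scenario bundle to disk
#'
#' Serialises every component in the plain-text formats the readers consume
#' (expression TSV, peak TSV + FASTA, promoter FASTA, TRANSFAC motifs, TSS
#' BED) plus the ground truth and generator parameters as JSON.
#'
#' @param bundle list from [simulateRegulatoryScenario()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeScenario <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  writeExpressionTable(bundle$expr, fp("expression.tsv"))
  pk <- bundle$peaks
  write.table(pk[, c("peak_id", "chrom", "start", "end", "peak_fdr",
                     "assigned_gene")],
              fp("peaks.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0(">", pk$peak_id, "\n", pk$sequence), fp("peaks.fa"))
  writeLines(paste0(">", names(bundle$promoters), "\n", bundle$promoters),
             fp("promoters.fa"))
  writeTransfacMatrices(bundle$motifs, fp("motifs.transfac"))
  g <- annotGenes(bundle$annot)
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", g$chrom, g$tss, g$tss + 1,
                     g$gene_id, g$strand), fp("tss.bed"))
  jsonlite::write_json(list(seed = bundle$seed,
                            truth = bundle$truth,
                            config = bundle$config[c("nDBGA", "nIDBGA", "nNGA",
                                                     "nDecoyDE", "nDecoyPeak",
                                                     "nKnownTfs")]),
                       fp("truth.json"), auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(dir)
}
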