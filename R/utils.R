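## Internal helpers shared across modules.

# Derive an independent sub-stream seed from a master seed and a stream name,
# so each generator draws from its own reproducible stream and adding a new
# generator never perturbs existing fixtures. Kept below 2^31.
.subSeed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

.withSeed <- function(seed, name, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(.subSeed(seed, name))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Row-wise logsumexp of a matrix (genes x populations).
.logSumExpRows <- function(X) {
  m <- apply(X, 1, max)
  m + log(rowSums(exp(X - m)))
}

.BASES <- c("A", "C", "G", "T")

# Encode a character vector of sequences to a list of integer vectors:
# A=0 C=1 G=2 T=3, anything else NA.
.encodeSeq <- function(s) {
  lapply(strsplit(toupper(s), ""), function(ch) {
    i <- match(ch, .BASES)
    i - 1L
  })
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
.warnf <- function(...) warning(sprintf(...), call. = FALSE)
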