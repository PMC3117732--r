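## Readers and writers for the external formats the pipeline touches.
## Coordinates are 0-based half-open everywhere in this package (BED
## convention); GRanges objects are built with the usual 1-based shift.

#' Read a probe-level expression table
#'
#' Reads a TSV with header columns `gene_id`, `probe_id`, `condition`,
#' `replicate`, `value` (log2 expression). Malformed rows are rejected with
#' the offending line number rather than coerced.
#'
#' @param path path to the TSV file.
#' @return a [ProbeExpression-class] object.
#' @export
readExpressionTable <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", colClasses = "character",
                   quote = "", comment.char = "")
  need <- c("gene_id", "probe_id", "condition", "replicate", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("expression table %s: missing column(s) %s", path,
           paste(miss, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L   # header is line 1
  val <- suppressWarnings(as.numeric(df$value))
  bad <- which(!is.finite(val))
  if (length(bad))
    .stopf("expression table %s: non-numeric or non-finite value on line %d",
           path, line[bad[1]])
  cond <- suppressWarnings(as.integer(df$condition))
  bad <- which(is.na(cond) | !(cond %in% c(1L, 2L)))
  if (length(bad))
    .stopf("expression table %s: condition outside {1,2} on line %d",
           path, line[bad[1]])
  rep <- suppressWarnings(as.integer(df$replicate))
  bad <- which(is.na(rep) | rep < 1L)
  if (length(bad))
    .stopf("expression table %s: bad replicate index on line %d", path, line[bad[1]])
  ProbeExpression(data.frame(gene_id = df$gene_id, probe_id = df$probe_id,
                             condition = cond, replicate = rep, value = val,
                             stringsAsFactors = FALSE))
}

#' Write a probe-level expression table
#'
#' Inverse of [readExpressionTable()]: the written file reproduces the
#' records up to row order.
#'
#' @param x a [ProbeExpression-class] object.
#' @param path output TSV path.
#' @export
writeExpressionTable <- function(x, path) {
  write.table(exprData(x), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read TRANSFAC-format motif matrices
#'
#' Parses TRANSFAC flat-file matrix blocks (`ID`, optional `BF`, `P0` header,
#' numbered count rows, terminated by `//`). Counts are converted to column
#' probabilities after adding a pseudocount of 0.01 per cell, so log-odds
#' scores stay finite.
#'
#' @param path path to the TRANSFAC flat file.
#' @param pseudocount per-cell pseudocount added before normalisation.
#' @return a list of [MotifMatrix-class] objects (empty list for an empty file).
#' @export
readTransfacMatrices <- function(path, pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- trimws(lines)
  motifs <- list()
  id <- NULL; tf <- NULL; ord <- NULL; counts <- NULL; open <- FALSE
  flush <- function() {
    if (is.null(id)) .stopf("TRANSFAC file %s: matrix block without ID", path)
    if (is.null(counts) || !nrow(counts))
      .stopf("TRANSFAC file %s: block %s has no count rows", path, id)
    zero <- which(rowSums(counts) == 0)
    if (length(zero))
      .stopf("TRANSFAC file %s: block %s has an all-zero column (position %d)",
             path, id, zero[1])
    m <- t(counts) + pseudocount                      # 4 x width
    m <- sweep(m, 2, colSums(m), "/")
    MotifMatrix(id, if (is.null(tf)) id else tf, m)
  }
  for (ln in lines) {
    if (ln == "" || startsWith(ln, "XX")) next
    tag <- substr(ln, 1, 2)
    if (tag == "//") {
      if (open) { motifs[[length(motifs) + 1L]] <- flush() }
      id <- NULL; tf <- NULL; ord <- NULL; counts <- NULL; open <- FALSE
    } else if (tag == "ID") {
      id <- trimws(substring(ln, 3)); open <- TRUE
    } else if (tag == "BF") {
      f <- strsplit(trimws(substring(ln, 3)), "\\s+")[[1]]
      tf <- f[length(f)]
    } else if (tag == "P0" || tag == "PO") {
      ord <- strsplit(trimws(substring(ln, 3)), "\\s+")[[1]]
      if (!setequal(ord, c("A", "C", "G", "T")))
        .stopf("TRANSFAC file %s: bad P0 header in block %s", path, id)
    } else if (grepl("^[0-9]+", tag)) {
      f <- strsplit(ln, "\\s+")[[1]]
      v <- suppressWarnings(as.numeric(f[2:5]))
      if (any(is.na(v)))
        .stopf("TRANSFAC file %s: malformed count row '%s' in block %s",
               path, ln, id)
      if (!is.null(ord)) v <- v[match(c("A", "C", "G", "T"), ord)]
      counts <- rbind(counts, v)
    }
  }
  if (open)
    .stopf("TRANSFAC file %s: truncated block %s (missing '//' terminator)",
           path, if (is.null(id)) "?" else id)
  motifs
}

#' Write motifs in TRANSFAC count format
#'
#' Writes integer-scaled counts (probabilities x `scale`) in TRANSFAC layout;
#' mainly used to serialise simulated motif sets.
#'
#' @param motifs list of [MotifMatrix-class] objects.
#' @param path output path.
#' @param scale count total per position.
#' @export
writeTransfacMatrices <- function(motifs, path, scale = 100) {
  con <- file(path, "w"); on.exit(close(con))
  for (m in motifs) {
    writeLines(c(paste("ID", m@motifId), paste("BF", m@tfName),
                 "P0      A      C      G      T"), con)
    p <- motifProbs(m)
    for (w in seq_len(ncol(p))) {
      cnt <- round(p[, w] * scale)
      cons <- c("A", "C", "G", "T")[which.max(p[, w])]
      writeLines(sprintf("%02d %6d %6d %6d %6d %s", w,
                         cnt[1], cnt[2], cnt[3], cnt[4], cons), con)
    }
    writeLines(c("XX", "//"), con)
  }
  invisible(path)
}

#' Read BED intervals as a GRanges
#'
#' BED is 0-based half-open; the returned GRanges uses the usual 1-based
#' closed convention. Negative coordinates or start >= end are rejected.
#'
#' @param path BED(-like) file with at least 3 columns; columns 4-6 are
#'   taken as name, score, strand when present.
#' @return a [GenomicRanges::GRanges].
#' @export
readBedIntervals <- function(path) {
  df <- read.table(path, header = FALSE, sep = "", quote = "",
                   comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(df) < 3) .stopf("BED file %s: fewer than 3 columns", path)
  start <- as.numeric(df[[2]]); end <- as.numeric(df[[3]])
  if (any(is.na(start) | is.na(end))) .stopf("BED file %s: non-numeric coordinates", path)
  if (any(start < 0)) .stopf("BED file %s: negative coordinates", path)
  if (any(start >= end)) .stopf("BED file %s: start must be < end", path)
  gr <- GenomicRanges::GRanges(
    seqnames = df[[1]],
    ranges = IRanges::IRanges(start = start + 1, end = end),
    strand = if (ncol(df) >= 6) df[[6]] else "*")
  if (ncol(df) >= 4) S4Vectors::mcols(gr)$name <- as.character(df[[4]])
  if (ncol(df) >= 5) S4Vectors::mcols(gr)$score <- as.numeric(df[[5]])
  gr
}

#' Read a FASTA file
#'
#' @param path FASTA path; sequence ids must be unique.
#' @return a [Biostrings::DNAStringSet].
#' @export
readFastaSequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*", "", names(ss))
  if (anyDuplicated(names(ss)))
    .stopf("FASTA file %s: duplicate sequence id '%s'", path,
           names(ss)[anyDuplicated(names(ss))])
  ss
}

#' Read a ChIP peak table
#'
#' Reads a TSV of peaks (`peak_id`, `chrom`, `start`, `end`, `peak_fdr`,
#' optional `assigned_gene`) with 0-based half-open coordinates, and
#' optionally attaches peak sequences from a FASTA keyed by `peak_id`.
#'
#' @param path peak TSV path.
#' @param fastaPath optional FASTA of peak sequences.
#' @return a data.frame of peak records (column `sequence` present when a
#'   FASTA was supplied; `assigned_gene` is `""` when unknown).
#' @export
readPeakTable <- function(path, fastaPath = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  need <- c("peak_id", "chrom", "start", "end", "peak_fdr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    .stopf("peak table %s: missing column(s) %s", path, paste(miss, collapse = ", "))
  if (any(df$start < 0) || any(df$start >= df$end))
    .stopf("peak table %s: invalid interval coordinates", path)
  if (any(df$peak_fdr < 0 | df$peak_fdr > 1))
    .stopf("peak table %s: peak_fdr outside [0,1]", path)
  if (is.null(df$assigned_gene)) df$assigned_gene <- ""
  if (!is.null(fastaPath)) {
    ss <- readFastaSequences(fastaPath)
    idx <- match(df$peak_id, names(ss))
    if (any(is.na(idx)))
      .stopf("peak table %s: no sequence for peak '%s'", path,
             df$peak_id[which(is.na(idx))[1]])
    df$sequence <- as.character(ss[idx])
    bad <- nchar(df$sequence) != (df$end - df$start)
    if (any(bad))
      .stopf("peak table %s: sequence length != interval length for peak '%s'",
             path, df$peak_id[which(bad)[1]])
  }
  df
}

#' Construct a GeneAnnotation
#'
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss` (0-based),
#'   `strand` (`+`/`-`).
#' @param regions optional data.frame with columns `gene_id`, `region_type`
#'   (`promoter`, `intron`, `downstream`), `start`, `end` (0-based
#'   half-open). When absent, a strand-aware 1-kb upstream promoter and 1-kb
#'   downstream region are derived from the TSS.
#' @param promoterWidth width of the derived promoter/downstream regions.
#' @return a [GeneAnnotation-class].
#' @export
geneAnnotation <- function(genes, regions = NULL, promoterWidth = 1000) {
  genes$gene_id <- as.character(genes$gene_id)
  if (is.null(regions)) {
    up <- genes$strand == "+"
    promStart <- ifelse(up, pmax(0, genes$tss - promoterWidth), genes$tss + 1)
    promEnd <- ifelse(up, genes$tss, genes$tss + 1 + promoterWidth)
    downStart <- ifelse(up, genes$tss, pmax(0, genes$tss + 1 - promoterWidth))
    downEnd <- ifelse(up, genes$tss + promoterWidth, genes$tss + 1)
    regions <- rbind(
      data.frame(gene_id = genes$gene_id, region_type = "promoter",
                 start = promStart, end = promEnd, stringsAsFactors = FALSE),
      data.frame(gene_id = genes$gene_id, region_type = "downstream",
                 start = downStart, end = downEnd, stringsAsFactors = FALSE))
    regions$chrom <- genes$chrom[match(regions$gene_id, genes$gene_id)]
  }
  if (is.null(regions$chrom))
    regions$chrom <- genes$chrom[match(regions$gene_id, genes$gene_id)]
  if (any(regions$start >= regions$end))
    .stopf("gene regions must satisfy start < end")
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1, end = regions$end),
    gene_id = regions$gene_id, region_type = regions$region_type)
  new("GeneAnnotation", genes = genes, regions = gr)
}

#' Assign peaks to genes by region overlap
#'
#' Peaks already carrying an `assigned_gene` keep it; the rest are assigned
#' to the gene whose labelled region (promoter, intron or downstream)
#' overlaps them most (first in annotation order on ties), or `""` when no
#' region overlaps.
#'
#' @param peaks peak data.frame as from [readPeakTable()].
#' @param annot a [GeneAnnotation-class].
#' @return the peak data.frame with `assigned_gene` filled in.
#' @export
assignPeaksToGenes <- function(peaks, annot) {
  todo <- which(is.na(peaks$assigned_gene) | peaks$assigned_gene == "")
  if (!length(todo)) return(peaks)
  pk <- GenomicRanges::GRanges(peaks$chrom[todo],
                               IRanges::IRanges(peaks$start[todo] + 1,
                                                peaks$end[todo]))
  reg <- annotRegions(annot)
  hits <- GenomicRanges::findOverlaps(pk, reg)
  if (length(hits)) {
    ov <- GenomicRanges::pintersect(pk[S4Vectors::queryHits(hits)],
                                    reg[S4Vectors::subjectHits(hits)])
    w <- GenomicRanges::width(ov)
    best <- tapply(seq_along(hits), S4Vectors::queryHits(hits), function(i)
      i[which.max(w[i])])
    q <- as.integer(names(best))
    g <- S4Vectors::mcols(reg)$gene_id[S4Vectors::subjectHits(hits)[unlist(best)]]
    peaks$assigned_gene[todo[q]] <- g
  }
  peaks
}

#' Write a regulatory network
#'
#' Writes the edge list as a TSV (`tf`, `gene`, `mechanism`, `direction`,
#' `fdr`) and, optionally, a JSON summary of the hub table. An empty network
#' yields a header-only TSV and an empty hub list.
#'
#' @param net a [RegulatoryNetwork-class].
#' @param path output TSV path.
#' @param jsonPath optional JSON summary path.
#' @export
writeNetwork <- function(net, path, jsonPath = NULL) {
  e <- networkEdges(net)
  out <- data.frame(tf = e$tf, gene = e$gene, mechanism = e$mechanism,
                    direction = e$direction, fdr = e$site_fdr)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(jsonPath)) {
    h <- networkHubs(net)
    hubs <- if (nrow(h)) lapply(seq_len(nrow(h)), function(i)
      list(tf = h$tf[i], target_count = h$target_count[i],
           p_value = h$p_value[i])) else list()
    jsonlite::write_json(list(label = net@label, n_edges = nrow(e),
                              hubs = hubs),
                         jsonPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a TSV network edge list back into a RegulatoryNetwork
#'
#' @param path TSV written by [writeNetwork()].
#' @param label optional label.
#' @return a [RegulatoryNetwork-class] (hub table empty).
#' @export
readNetwork <- function(path, label = "") {
  df <- read.table(path, header = TRUE, sep = "\t", quote = "",
                   stringsAsFactors = FALSE)
  if (!nrow(df))
    df <- data.frame(tf = character(), gene = character(),
                     mechanism = character(), direction = character(),
                     fdr = numeric())
  new("RegulatoryNetwork",
      edges = data.frame(tf = df$tf, gene = df$gene, mechanism = df$mechanism,
                         direction = df$direction, site_fdr = df$fdr,
                         stringsAsFactors = FALSE),
      hubs = .emptyHubs(), label = label)
}

.emptyHubs <- function()
  data.frame(tf = character(), target_count = integer(), p_value = numeric(),
             stringsAsFactors = FALSE)

#' Read sequencing-tag BED files as a TagTrack
#'
#' Each BED file is one replicate; the interval start is taken as the
#' (0-based) tag position.
#'
#' @param paths character vector of BED paths (one per replicate).
#' @param assay assay name (`polII`, `h3k4me2`, `h3k27me3`, `mcip`).
#' @param librarySizes optional per-replicate library sizes.
#' @return a [TagTrack-class].
#' @export
readTagTrack <- function(paths, assay, librarySizes = NULL) {
  reps <- lapply(paths, function(p) {
    gr <- readBedIntervals(p)
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               pos = GenomicRanges::start(gr) - 1, stringsAsFactors = FALSE)
  })
  TagTrack(assay, reps, librarySizes)
}
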