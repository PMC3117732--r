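## SERM (selective estrogen receptor modulator) effect classification from
## fold-change triples (E2 alone, SERM alone, E2 + SERM).

#' Signed fold-change with presence flags
#'
#' Treatment over control for up-regulation, minus the inverse ratio
#' otherwise; a gene absent in both groups gets fold-change 1. All arguments
#' recycle to a common length.
#'
#' @param exprTreat,exprCtrl expression values (> 0 where present).
#' @param presentTreat,presentCtrl detection flags, default `TRUE`.
#' @return signed fold-changes with magnitude >= 1 (exactly 1 allowed).
#' @export
signedFoldChange <- function(exprTreat, exprCtrl,
                             presentTreat = TRUE, presentCtrl = TRUE) {
  k <- max(length(exprTreat), length(exprCtrl))
  exprTreat <- rep_len(exprTreat, k); exprCtrl <- rep_len(exprCtrl, k)
  presentTreat <- rep_len(presentTreat, k); presentCtrl <- rep_len(presentCtrl, k)
  bothAbsent <- !presentTreat & !presentCtrl
  bad <- !bothAbsent & (!is.finite(exprTreat) | !is.finite(exprCtrl) |
                          exprTreat <= 0 | exprCtrl <= 0)
  if (any(bad)) .stopf("non-positive expression for a present gene")
  fc <- ifelse(exprTreat >= exprCtrl, exprTreat / exprCtrl,
               -exprCtrl / exprTreat)
  fc[bothAbsent] <- 1
  fc
}

#' Classify a SERM's effect on each gene
#'
#' A SERM is agonistic on a gene when `|FC_SERM| > 1 + 0.70 (|FC_E2| - 1)`,
#' antagonistic when `|FC_SERM| < 1 + 0.35 (|FC_E2| - 1)` and
#' `|FC_E2+SERM| < 1 + 0.50 (|FC_E2| - 1)`, and partial otherwise
#' (inequalities strict, so ties fall to partial). Only magnitudes enter the
#' rules; a `sign_discordant` flag records SERM fold-changes opposite in
#' sign to the E2 fold-change without altering the class.
#'
#' @param fcs data.frame with columns `gene_id`, `fc_e2`, `fc_serm`,
#'   `fc_combo` (signed fold-changes, magnitude >= 1).
#' @return the input with columns `effect` (`agonist`/`antagonist`/
#'   `partial`) and `sign_discordant` added.
#' @export
classifySerm <- function(fcs) {
  stopifnot(all(c("fc_e2", "fc_serm", "fc_combo") %in% names(fcs)))
  if (any(abs(fcs$fc_e2) < 1 | abs(fcs$fc_serm) < 1 | abs(fcs$fc_combo) < 1))
    .stopf("signed fold-changes must have magnitude >= 1")
  e2 <- abs(fcs$fc_e2); se <- abs(fcs$fc_serm); co <- abs(fcs$fc_combo)
  ag <- se > 1 + 0.70 * (e2 - 1)
  an <- !ag & se < 1 + 0.35 * (e2 - 1) & co < 1 + 0.50 * (e2 - 1)
  fcs$effect <- ifelse(ag, "agonist", ifelse(an, "antagonist", "partial"))
  fcs$sign_discordant <- sign(fcs$fc_serm) != sign(fcs$fc_e2) &
    fcs$fc_e2 != 1 & fcs$fc_serm != 1
  fcs
}

#' Cross-tabulate SERM effects against network mechanism and direction
#'
#' Builds the effect x {genomic, non-genomic} x {up, down} count table for
#' genes present in both inputs, plus an exact two-sided test of association
#' between agonism and genomic mechanism (agonist-vs-rest by
#' genomic-vs-non-genomic; hypergeometric, two-sided by summing table
#' probabilities not exceeding the observed one).
#'
#' @param sermCalls data.frame from [classifySerm()].
#' @param mechanisms data.frame with `gene_id`, `mechanism` (DBGA / I-DBGA
#'   counted genomic, NGA non-genomic) and `direction` (`up`/`down`).
#' @return list with `table` (3-way array), `contingency` (the tested 2x2)
#'   and `p_value` (1 for a degenerate table with an empty margin).
#' @export
sermSummary <- function(sermCalls, mechanisms) {
  mech <- mechanisms[mechanisms$mechanism %in% c("DBGA", "I-DBGA", "NGA"), ]
  df <- merge(sermCalls, mech, by = "gene_id")
  if (!nrow(df))
    return(list(table = table(effect = character(), class = character(),
                              direction = character()),
                contingency = matrix(0, 2, 2), p_value = NA_real_))
  df$class <- ifelse(df$mechanism == "NGA", "non-genomic", "genomic")
  tab3 <- table(effect = factor(df$effect, c("agonist", "antagonist", "partial")),
                class = factor(df$class, c("genomic", "non-genomic")),
                direction = factor(df$direction, c("up", "down")))
  ct <- table(agonist = factor(df$effect == "agonist", c(TRUE, FALSE)),
              genomic = factor(df$class == "genomic", c(TRUE, FALSE)))
  p <- if (any(rowSums(ct) == 0) || any(colSums(ct) == 0)) 1
       else stats::fisher.test(ct)$p.value
  list(table = tab3, contingency = ct, p_value = p)
}
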