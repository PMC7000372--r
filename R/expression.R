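#' Reads per kilobase of CDS per million mapped reads
#'
#' RPKM = count / (cds_length_bp / 1000) / (total_mapped_reads / 1e6):
#' linear in the raw count, inversely proportional to coding-sequence
#' length and library size.
#'
#' @param count Raw mapped read count(s), >= 0.
#' @param cds_length_bp Coding-sequence length(s) in bp, > 0.
#' @param total_mapped_reads Library size (total mapped reads), > 0.
#' @return RPKM value(s).
#' @examples
#' rpkm(1000, 1000, 1e6)  # 1000
#' @export
rpkm <- function(count, cds_length_bp, total_mapped_reads) {
  if (any(cds_length_bp <= 0)) stop("cds_length_bp must be positive")
  if (any(total_mapped_reads <= 0)) {
    stop("total_mapped_reads must be positive")
  }
  if (any(count < 0)) stop("counts must be non-negative")
  count / (cds_length_bp / 1000) / (total_mapped_reads / 1e6)
}

#' RPKM table from a counts table
#'
#' @param counts Data frame with columns `gene_id`, `count`,
#'   `cds_length_bp`.
#' @param total_mapped_reads Library size; defaults to `sum(count)`.
#' @return The input with an `rpkm` column appended.
#' @export
rpkm_table <- function(counts, total_mapped_reads = sum(counts$count)) {
  need <- c("gene_id", "count", "cds_length_bp")
  if (!all(need %in% names(counts))) {
    stop("counts table needs columns: ", paste(need, collapse = ", "))
  }
  counts$rpkm <- rpkm(counts$count, counts$cds_length_bp,
                      total_mapped_reads)
  counts
}

#' Fold ratio between two gene panels
#'
#' Summarises each panel's RPKM values (mean or median) and returns
#' summary(a) / summary(b). Used to compare transcript levels of the
#' galacturonate (adapted Entner-Doudoroff) pathway panel against the
#' Wood-Ljungdahl pathway panel.
#'
#' @param panel_a,panel_b Non-negative RPKM values.
#' @param summary `"mean"` or `"median"`.
#' @return Fold ratio a/b.
#' @export
panel_fold <- function(panel_a, panel_b, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  if (!length(panel_a) || !length(panel_b)) stop("panels must be non-empty")
  if (any(panel_a < 0) || any(panel_b < 0)) {
    stop("RPKM values must be non-negative")
  }
  s <- switch(summary, mean = mean, median = stats::median)
  denom <- s(panel_b)
  if (denom <= 0) stop("denominator panel summary is zero")
  s(panel_a) / denom
}

#' Reference gene panels of the enrichment culture transcriptome
#'
#' Panels of the measured RPKM table shipped with the package: the adapted
#' Entner-Doudoroff galacturonate pathway and the Wood-Ljungdahl pathway.
#' The WLP panel optionally drops the near-zero formate dehydrogenase
#' entry (its transcript level is an outlier two orders of magnitude below
#' the rest of the pathway, and the methyl branch is fed by formate
#' without it), which is the variant used for pathway-level fold
#' comparisons.
#'
#' @param include_fdh Keep formate dehydrogenase in the WLP panel.
#' @return Named list of gene-identifier character vectors.
#' @export
default_panels <- function(include_fdh = FALSE) {
  ed <- c("F7O84_RS17360", "F7O84_RS17370", "F7O84_RS17375",
          "F7O84_RS17390", "F7O84_RS17395")
  wlp <- c("F7O84_RS05385", "F7O84_RS05380", "F7O84_RS08335",
           "F7O84_RS02745")
  if (include_fdh) wlp <- c("F7O84_RS07405", wlp)
  list(entner_doudoroff = ed, wood_ljungdahl = wlp)
}
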