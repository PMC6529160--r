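# Per-gene relative coverage and two-accession duplication classification.
#
# The statistic is median-based throughout: per-gene median depth, divided by
# the genome-wide per-position median of the accession, divided again by the
# median of the resulting per-gene values. The second normalization absorbs
# accession-specific mapability differences; after it, the median relative
# coverage of genes with non-zero depth is exactly 1.

#' Per-gene relative coverage for one accession
#'
#' Step 1: median depth over all positions in each gene span (introns
#' included; zero-depth positions included). Step 2: divide by the accession
#' average, computed as the genome-wide per-position median. Step 3: divide by
#' the median over genes of the step-2 values (taken over genes with non-zero
#' step-2 value).
#'
#' @param track depth track (list with `accession_id`, `depth`).
#' @param genes gene model data.frame.
#' @return data.frame with gene_id, raw_median_depth, relative_coverage.
#' @export
gene_relative_coverage <- function(track, genes) {
  if (nrow(genes) == 0L) stopf("empty gene list")
  missing_seq <- setdiff(unique(genes$seq_id), names(track$depth))
  if (length(missing_seq)) stopf("gene on sequence absent from track: %s",
                                 missing_seq[1L])
  acc_median <- stats::median(as.numeric(unlist(track$depth, use.names = FALSE)))
  if (acc_median <= 0) stopf("accession median depth is zero")
  raw <- vapply(seq_len(nrow(genes)), function(i) {
    v <- track$depth[[genes$seq_id[i]]]
    if (genes$end[i] > length(v)) stopf("gene %s exceeds sequence length",
                                        genes$gene_id[i])
    stats::median(as.numeric(v[(genes$start[i] + 1L):genes$end[i]]))
  }, numeric(1))
  step2 <- raw / acc_median
  nz <- step2[step2 > 0]
  if (length(nz) == 0L) stopf("all genes have zero coverage")
  rel <- step2 / stats::median(nz)
  data.frame(gene_id = genes$gene_id, raw_median_depth = raw,
             relative_coverage = rel, stringsAsFactors = FALSE)
}

#' Classify per-gene duplication state between two accessions
#'
#' R is the accession whose assembly served as the mapping reference. With
#' v_R and v_Q the relative coverages, a gene is `duplicated_in_Q` when
#' v_R < low * v_Q, `duplicated_in_R` when v_R > high * v_Q (this includes
#' v_Q = 0 with v_R > 0: a deletion in Q is coverage-indistinguishable from
#' extra copies in R), `uncallable` when both are 0, and `balanced` otherwise.
#' Inequalities are strict, so a gene exactly at a cutoff stays balanced.
#'
#' @param values_r,values_q outputs of [gene_relative_coverage()] for the
#'   reference accession R and the other accession Q (same gene universe).
#' @param low,high calling cutoffs (defaults 0.5 and 1.5).
#' @return data.frame with gene_id, v_r, v_q, ratio (v_R / v_Q) and class.
#' @export
classify_duplications <- function(values_r, values_q, low = 0.5, high = 1.5) {
  if (nrow(values_r) != nrow(values_q) ||
      !setequal(values_r$gene_id, values_q$gene_id)) {
    stopf("gene universes differ between accessions")
  }
  vq <- values_q$relative_coverage[match(values_r$gene_id, values_q$gene_id)]
  vr <- values_r$relative_coverage
  cls <- rep("balanced", length(vr))
  cls[vr == 0 & vq == 0] <- "uncallable"
  cls[vq == 0 & vr > 0] <- "duplicated_in_R"
  reg <- vq > 0
  cls[reg & vr < low * vq] <- "duplicated_in_Q"
  cls[reg & vr > high * vq] <- "duplicated_in_R"
  ratio <- ifelse(vq > 0, vr / vq, ifelse(vr > 0, Inf, NA_real_))
  data.frame(gene_id = values_r$gene_id, v_r = vr, v_q = vq, ratio = ratio,
             class = cls, stringsAsFactors = FALSE)
}

#' Remove TE-flagged genes from the duplicated call sets
#'
#' Calls whose gene is flagged as a putative TE gene are dropped from the
#' duplicated classes; balanced and uncallable calls are untouched.
#'
#' @param calls output of [classify_duplications()].
#' @param te_flags output of [flag_te_genes()] (or any data.frame with
#'   gene_id and flagged columns).
#' @return filtered call data.frame.
#' @export
filter_te_calls <- function(calls, te_flags) {
  if (is.null(te_flags) || nrow(te_flags) == 0L) return(calls)
  flagged <- te_flags$gene_id[te_flags$flagged]
  drop <- calls$class %in% c("duplicated_in_Q", "duplicated_in_R") &
    calls$gene_id %in% flagged
  out <- calls[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
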