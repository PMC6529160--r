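# Pan-genome gene classification from a relative-coverage matrix.

#' Exclude low-coverage accessions from a panel
#'
#' Accessions with average depth strictly below `min_avg_depth` are removed;
#' an accession at exactly the threshold is retained. The gene universe is
#' unchanged.
#'
#' @param panel list with `matrix` (genes x accessions) and `avg_depth`
#'   (named per-accession average depth).
#' @param min_avg_depth inclusion threshold in depth units (default 10).
#' @return filtered panel (same structure).
#' @export
filter_accessions <- function(panel, min_avg_depth = 10) {
  acc <- colnames(panel$matrix)
  if (is.null(acc) || anyDuplicated(acc)) stopf("accession ids missing or duplicated")
  depth <- panel$avg_depth[acc]
  if (anyNA(depth)) stopf("avg_depth missing for some accessions")
  keep <- depth >= min_avg_depth
  if (!any(keep)) stopf("all accessions fall below the coverage threshold")
  list(matrix = panel$matrix[, keep, drop = FALSE],
       avg_depth = panel$avg_depth[acc[keep]])
}

#' Classify genes as core, dispensable or TE
#'
#' A gene is dispensable when its relative coverage is below `low` in more
#' than `min_accessions` accessions (both strict, matching the calling rule's
#' "below" / "more than"). Remaining genes are TE when flagged, else core.
#' Dispensable takes precedence over TE.
#'
#' @param matrix genes x accessions relative-coverage matrix, already
#'   accession-filtered.
#' @param te_flags optional output of [flag_te_genes()].
#' @param low relative-coverage absence cutoff (default 0.1).
#' @param min_accessions absolute count of absent accessions a dispensable
#'   gene must exceed (default 100).
#' @param min_fraction optional fraction of the panel overriding
#'   `min_accessions` (useful for small synthetic panels); the threshold is
#'   then `min_fraction * ncol(matrix)`.
#' @return data.frame with gene_id, class, n_absent.
#' @export
classify_genes <- function(matrix, te_flags = NULL, low = 0.1,
                           min_accessions = 100, min_fraction = NULL) {
  genes <- rownames(matrix)
  if (is.null(genes)) stopf("matrix must carry gene ids as rownames")
  thr <- if (!is.null(min_fraction)) min_fraction * ncol(matrix) else min_accessions
  n_absent <- rowSums(matrix < low)
  cls <- ifelse(n_absent > thr, "dispensable", "core")
  if (!is.null(te_flags) && nrow(te_flags) > 0L) {
    unknown <- setdiff(te_flags$gene_id, genes)
    if (length(unknown)) stopf("TE flag for unknown gene %s", unknown[1L])
    flagged <- te_flags$gene_id[te_flags$flagged]
    cls[cls == "core" & genes %in% flagged] <- "te"
  }
  data.frame(gene_id = genes, class = cls, n_absent = as.integer(n_absent),
             stringsAsFactors = FALSE, row.names = NULL)
}
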