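# Non-redundant TE annotation from library hit tables and TE-gene flagging.

#' Select non-overlapping TE placements from library hits
#'
#' Hits are first filtered to those scoring at least `min_frac` of the TE
#' family's top score from the self-reference mapping (inclusive at the
#' threshold). Overlaps are then resolved greedily by descending bitscore
#' (ties: longer alignment, then lexicographically smaller te_id); a hit
#' overlapping an already-accepted placement by one or more bases is
#' discarded.
#'
#' @param hits TE-library hit table (query = TE id, subject = assembly
#'   sequence); minus-strand hits have subject_start > subject_end.
#' @param top_scores data.frame with te_id and top_score.
#' @param min_frac minimum fraction of the top score (default 0.9).
#' @return data.frame of placements: te_id, seq_id, start, end (0-based
#'   half-open), score.
#' @export
select_te_placements <- function(hits, top_scores, min_frac = 0.9) {
  if (nrow(hits) == 0L) {
    return(data.frame(te_id = character(), seq_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  top <- stats::setNames(top_scores$top_score, top_scores$te_id)
  unknown <- setdiff(unique(hits$query_id), names(top))
  if (length(unknown)) stopf("no top score for TE %s", unknown[1L])
  keep <- hits$bitscore >= min_frac * top[hits$query_id]
  h <- hits[keep, , drop = FALSE]
  if (nrow(h) == 0L) {
    return(data.frame(te_id = character(), seq_id = character(),
                      start = integer(), end = integer(), score = numeric(),
                      stringsAsFactors = FALSE))
  }
  start0 <- pmin(h$subject_start, h$subject_end) - 1L
  end0 <- pmax(h$subject_start, h$subject_end)
  o <- order(-h$bitscore, -h$align_len, h$query_id)
  accepted <- integer(0)
  for (i in o) {
    same <- accepted[h$subject_id[accepted] == h$subject_id[i]]
    if (length(same) == 0L ||
        all(end0[i] <= start0[same] | start0[i] >= end0[same])) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- accepted[order(h$subject_id[accepted], start0[accepted])]
  data.frame(te_id = h$query_id[accepted], seq_id = h$subject_id[accepted],
             start = as.integer(start0[accepted]),
             end = as.integer(end0[accepted]),
             score = h$bitscore[accepted], stringsAsFactors = FALSE)
}

#' Flag genes mostly covered by TE placements
#'
#' `te_fraction` is the fraction of the gene span (or, with
#' `exons_only = TRUE`, of the summed exon length) covered by the union of TE
#' placements. A gene is flagged when the fraction strictly exceeds
#' `min_frac`.
#'
#' @param genes gene model data.frame.
#' @param placements non-overlapping TE placements from
#'   [select_te_placements()] (or any intervals with seq_id/start/end).
#' @param min_frac flagging threshold (default 0.8, strict).
#' @param exons_only restrict the overlap to exons instead of the full span.
#' @return data.frame with gene_id, te_fraction, flagged.
#' @export
flag_te_genes <- function(genes, placements, min_frac = 0.8, exons_only = FALSE) {
  frac <- vapply(seq_len(nrow(genes)), function(i) {
    p <- placements[placements$seq_id == genes$seq_id[i], , drop = FALSE]
    if (exons_only) {
      ex <- genes$exons[[i]]
      if (nrow(ex) == 0L) ex <- cbind(start = genes$start[i], end = genes$end[i])
      cov <- sum(vapply(seq_len(nrow(ex)), function(j) {
        union_cover(p$start, p$end, ex[j, 1L], ex[j, 2L])
      }, integer(1)))
      cov / sum(ex[, 2L] - ex[, 1L])
    } else {
      union_cover(p$start, p$end, genes$start[i], genes$end[i]) /
        (genes$end[i] - genes$start[i])
    }
  }, numeric(1))
  data.frame(gene_id = genes$gene_id, te_fraction = frac,
             flagged = frac > min_frac, stringsAsFactors = FALSE)
}
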