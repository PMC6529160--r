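# Reciprocal best hits, rank-based synteny outliers, and SV block calling.
#
# Positions are compared as genome-wide gene ranks (chromosomes concatenated
# in a fixed order), matching the sorted-gene scatter construction used for
# visual synteny comparison of two annotations.

#' Best subject per query from a hit table
#'
#' Maximal bitscore wins; ties are broken by lower evalue, then by
#' lexicographically smallest subject id. Queries with several co-optimal
#' subjects after the bitscore comparison are marked `tied`.
#'
#' @param hits hit table data.frame.
#' @return data.frame with query_id, subject_id, bitscore, tied.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      bitscore = numeric(), tied = logical(),
                      stringsAsFactors = FALSE))
  }
  o <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  first <- !duplicated(h$query_id)
  top <- h[first, , drop = FALSE]
  maxsc <- stats::setNames(top$bitscore, top$query_id)
  n_at_max <- tapply(h$bitscore == maxsc[h$query_id], h$query_id, sum)
  data.frame(query_id = top$query_id, subject_id = top$subject_id,
             bitscore = top$bitscore,
             tied = as.vector(n_at_max[top$query_id]) > 1L,
             stringsAsFactors = FALSE, row.names = NULL)
}

gene_ranks <- function(genes, chrom_order = NULL) {
  chroms <- chrom_order %||% sort(unique(genes$seq_id))
  unknown <- setdiff(genes$seq_id, chroms)
  if (length(unknown)) stopf("gene on chromosome outside the given order: %s",
                             unknown[1L])
  o <- order(match(genes$seq_id, chroms), genes$start)
  rank <- integer(nrow(genes))
  rank[o] <- seq_len(nrow(genes))
  data.frame(gene_id = genes$gene_id, chrom = genes$seq_id, rank = rank,
             stringsAsFactors = FALSE)
}

#' Reciprocal best hits with genome-wide ranks
#'
#' A pair (a, b) is reciprocal iff a's best subject is b and b's best subject
#' is a. Ranks are assigned per genome by sorting genes by (chromosome order,
#' start).
#'
#' @param map_ab,map_ba outputs of [best_hits()] for the two directions.
#' @param genes_a,genes_b gene model data.frames carrying positions.
#' @param chrom_order_a,chrom_order_b optional fixed chromosome orders.
#' @return data.frame of pairs sorted by rank_A: gene_a, gene_b, chrom_a,
#'   chrom_b, rank_a, rank_b, tied.
#' @export
reciprocal_best_hits <- function(map_ab, map_ba, genes_a, genes_b,
                                 chrom_order_a = NULL, chrom_order_b = NULL) {
  ra <- gene_ranks(genes_a, chrom_order_a)
  rb <- gene_ranks(genes_b, chrom_order_b)
  nopos <- setdiff(c(map_ab$query_id, map_ba$subject_id), ra$gene_id)
  if (length(nopos)) stopf("gene without position: %s", nopos[1L])
  nopos_b <- setdiff(c(map_ab$subject_id, map_ba$query_id), rb$gene_id)
  if (length(nopos_b)) stopf("gene without position: %s", nopos_b[1L])
  back <- stats::setNames(map_ba$subject_id, map_ba$query_id)
  mutual <- map_ab[!is.na(back[map_ab$subject_id]) &
                     back[map_ab$subject_id] == map_ab$query_id, , drop = FALSE]
  ia <- match(mutual$query_id, ra$gene_id)
  ib <- match(mutual$subject_id, rb$gene_id)
  tied_b <- stats::setNames(map_ba$tied, map_ba$query_id)
  out <- data.frame(gene_a = mutual$query_id, gene_b = mutual$subject_id,
                    chrom_a = ra$chrom[ia], chrom_b = rb$chrom[ib],
                    rank_a = ra$rank[ia], rank_b = rb$rank[ib],
                    tied = mutual$tied | unname(tied_b[mutual$subject_id]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$rank_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Indices of members of the longest strictly increasing subsequence of v
# (patience algorithm with predecessor backtrace; deterministic: among equal
# lengths the chain ending in the smallest tail values is kept).
lis_members <- function(v) {
  n <- length(v)
  inlis <- logical(n)
  if (n == 0L) return(inlis)
  tails <- integer(0)
  prev <- integer(n)
  for (i in seq_len(n)) {
    pos <- findInterval(v[i] - 0.5, v[tails]) + 1L
    prev[i] <- if (pos > 1L) tails[pos - 1L] else 0L
    tails[pos] <- i
    if (pos > length(tails)) tails <- tails[seq_len(pos)]
  }
  at <- tails[length(tails)]
  while (at > 0L) {
    inlis[at] <- TRUE
    at <- prev[at]
  }
  inlis
}

#' Flag synteny outliers among RBH pairs
#'
#' A pair is an outlier when any of three conditions holds: (1) its rank_b
#' deviates from the median rank_b of up to `window` flanking pairs on each
#' side by more than `tolerance`; (2) its chrom_b differs from the majority
#' chromosome of those flanking pairs; (3) it is not part of the longest
#' strictly increasing subsequence of rank_b over pairs sorted by rank_a (the
#' collinearity backbone). The third rule is what detects short inversions,
#' whose members deviate little from their flanking median because the flanks
#' are fellow inversion members.
#'
#' @param pairs output of [reciprocal_best_hits()].
#' @param window flanking pairs considered on each side (default 5).
#' @param tolerance maximal tolerated rank deviation (default 20).
#' @return `pairs` with added columns outlier and outlier_reason.
#' @export
detect_synteny_outliers <- function(pairs, window = 5, tolerance = 20) {
  n <- nrow(pairs)
  pairs <- pairs[order(pairs$rank_a), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs$outlier <- FALSE
  pairs$outlier_reason <- ""
  if (n < 3L) return(pairs)
  dev_flag <- logical(n); chrom_flag <- logical(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - window); hi <- min(n, i + window)
    fl <- setdiff(lo:hi, i)
    m <- stats::median(pairs$rank_b[fl])
    dev_flag[i] <- abs(pairs$rank_b[i] - m) > tolerance
    tab <- table(pairs$chrom_b[fl])
    maj <- names(tab)[which.max(tab)]
    chrom_flag[i] <- pairs$chrom_b[i] != maj
  }
  lis_flag <- !lis_members(pairs$rank_b)
  pairs$outlier <- dev_flag | chrom_flag | lis_flag
  reason <- character(n)
  reason[lis_flag] <- "noncollinear"
  reason[dev_flag] <- "rank_deviation"
  reason[chrom_flag] <- "chromosome"
  pairs$outlier_reason <- reason
  pairs
}

#' Call structural-variant blocks from consecutive synteny outliers
#'
#' Maximal runs of at least `min_run` consecutive outlier pairs (consecutive
#' in rank_a order) whose rank_b values are monotone become blocks; a block
#' with decreasing rank_b while rank_a increases is an inversion, otherwise a
#' translocation.
#'
#' @param pairs output of [detect_synteny_outliers()].
#' @param min_run minimum number of genes in a row (default 3).
#' @return data.frame of blocks with type, size, member gene ranges and spans.
#' @export
call_sv_blocks <- function(pairs, min_run = 3) {
  empty <- data.frame(type = character(), n_genes = integer(),
                      chrom_a = character(), chrom_b = character(),
                      first_gene_a = character(), last_gene_a = character(),
                      rank_a_start = integer(), rank_a_end = integer(),
                      rank_b_min = integer(), rank_b_max = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(pairs) == 0L || !any(pairs$outlier)) return(empty)
  pairs <- pairs[order(pairs$rank_a), , drop = FALSE]
  runs <- rle(pairs$outlier)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  blocks <- list()
  for (k in which(runs$values)) {
    idx <- starts[k]:ends[k]
    # split the run into maximal monotone segments of rank_b
    while (length(idx) > 0L) {
      if (length(idx) == 1L) { seg <- idx; idx <- integer(0) }
      else {
        dirs <- sign(diff(pairs$rank_b[idx]))
        d0 <- dirs[1L]
        stopi <- which(dirs != d0)
        seg_len <- if (length(stopi)) stopi[1L] else length(idx) - 1L
        seg <- idx[seq_len(seg_len + 1L)]
        idx <- idx[-seq_len(seg_len)]  # next segment reuses the boundary pair
        if (length(idx) == 1L) idx <- integer(0)
      }
      if (length(seg) >= min_run) {
        rb <- pairs$rank_b[seg]
        type <- if (length(seg) > 1L && all(diff(rb) < 0)) "inversion"
                else "translocation"
        blocks[[length(blocks) + 1L]] <- data.frame(
          type = type, n_genes = length(seg),
          chrom_a = pairs$chrom_a[seg[1L]], chrom_b = pairs$chrom_b[seg[1L]],
          first_gene_a = pairs$gene_a[seg[1L]],
          last_gene_a = pairs$gene_a[seg[length(seg)]],
          rank_a_start = pairs$rank_a[seg[1L]],
          rank_a_end = pairs$rank_a[seg[length(seg)]],
          rank_b_min = min(rb), rank_b_max = max(rb),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(blocks) == 0L) return(empty)
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
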