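# Genome-distribution statistics: SV clustering around centromeres,
# assembly-gap homologs, homotetramer enrichment.

#' Count structural variants in fixed windows with centromere distances
#'
#' SVs with length >= `min_len` are assigned to the non-overlapping
#' `window`-sized tile containing their start; each window is annotated with
#' the distance of its midpoint to the centromere midpoint of its sequence.
#'
#' @param svs data.frame with seq_id, start, end (0-based half-open).
#' @param seq_lengths named vector of sequence lengths.
#' @param centromeres named vector of centromere midpoints.
#' @param window tile width in bp (default 1 Mbp).
#' @param min_len minimum SV length in bp (default 1 kbp).
#' @return data.frame with seq_id, window_start, count, cen_distance.
#' @export
window_sv_counts <- function(svs, seq_lengths, centromeres, window = 1e6,
                             min_len = 1000) {
  unknown <- setdiff(unique(svs$seq_id), names(seq_lengths))
  if (length(unknown)) stopf("SV on unknown sequence %s", unknown[1L])
  svs <- svs[(svs$end - svs$start) >= min_len, , drop = FALSE]
  out <- lapply(names(seq_lengths), function(s) {
    starts <- seq(0, max(seq_lengths[[s]] - 1, 0), by = window)
    cnt <- integer(length(starts))
    sel <- svs$seq_id == s
    if (any(sel)) {
      w <- floor(svs$start[sel] / window) + 1L
      tab <- table(w)
      cnt[as.integer(names(tab))] <- as.integer(tab)
    }
    data.frame(seq_id = s, window_start = starts, count = cnt,
               cen_distance = abs(starts + window / 2 - centromeres[[s]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Spearman rank correlation with t-approximation p value
#'
#' Average ranks are used for ties. The p value comes from the
#' t-approximation with n - 2 degrees of freedom; a perfect correlation gives
#' p = 0.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return list with rho, p, n and `constant` flag (TRUE when either vector
#'   is constant, in which case rho is NA).
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stopf("need at least 3 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    return(list(rho = NA_real_, p = NA_real_, n = n, constant = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, constant = FALSE)
}

#' Find assembly gaps (N runs) in a sequence
#'
#' @param sequence character scalar or `DNAString`.
#' @param min_run minimal run length to report (default 10).
#' @return data.frame with start, end (0-based half-open).
#' @export
find_assembly_gaps <- function(sequence, min_run = 10) {
  s <- toupper(as.character(sequence))
  m <- gregexpr("N+", s)[[1L]]
  if (m[1L] == -1L) {
    return(data.frame(start = integer(), end = integer()))
  }
  len <- attr(m, "match.length")
  keep <- len >= min_run
  data.frame(start = as.integer(m[keep] - 1L),
             end = as.integer(m[keep] - 1L + len[keep]))
}

best_hit_rows <- function(hits) {
  o <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  h <- hits[o, , drop = FALSE]
  h[!duplicated(h$query_id), , drop = FALSE]
}

#' Locate target sequence homologous to reference assembly gaps
#'
#' Queries named `<gap_id>_L` and `<gap_id>_R` are the left and right gap
#' flanks. For each gap the best hit of each flank is taken; the gap is
#' accepted iff both hits land on the same target sequence, on the same
#' strand, in consistent order, and the enclosed span does not exceed
#' `max_span`. The enclosed interval runs between the inner hit boundaries
#' (0-based half-open).
#'
#' @param flank_hits hit table of gap flanks against the target assembly.
#' @param max_span maximal accepted enclosed span in bp (default 200 kbp).
#' @param assembly optional `DNAStringSet`; when given, the enclosed
#'   sequences are attached.
#' @return list with `accepted` (gap_id, seq_id, start, end, strand,
#'   optionally sequence) and `rejected` (gap_id, reason).
#' @export
extract_gap_homologs <- function(flank_hits, max_span = 200000,
                                 assembly = NULL) {
  side <- ifelse(grepl("_L$", flank_hits$query_id), "L",
                 ifelse(grepl("_R$", flank_hits$query_id), "R", NA))
  if (anyNA(side)) stopf("flank query ids must end in _L or _R")
  gap_id <- sub("_[LR]$", "", flank_hits$query_id)
  best <- best_hit_rows(flank_hits)
  best$side <- ifelse(grepl("_L$", best$query_id), "L", "R")
  best$gap_id <- sub("_[LR]$", "", best$query_id)
  acc <- list(); rej <- list()
  for (g in unique(gap_id)) {
    L <- best[best$gap_id == g & best$side == "L", , drop = FALSE]
    R <- best[best$gap_id == g & best$side == "R", , drop = FALSE]
    reject <- function(reason) {
      rej[[length(rej) + 1L]] <<- data.frame(gap_id = g, reason = reason,
                                             stringsAsFactors = FALSE)
    }
    if (nrow(L) == 0L || nrow(R) == 0L) { reject("missing_flank"); next }
    if (L$subject_id != R$subject_id) { reject("different_sequences"); next }
    minus_L <- L$subject_start > L$subject_end
    minus_R <- R$subject_start > R$subject_end
    if (minus_L != minus_R) { reject("strand_mismatch"); next }
    lo_L <- min(L$subject_start, L$subject_end); hi_L <- max(L$subject_start, L$subject_end)
    lo_R <- min(R$subject_start, R$subject_end); hi_R <- max(R$subject_start, R$subject_end)
    if (!minus_L) { start0 <- hi_L; end0 <- lo_R - 1L }
    else { start0 <- hi_R; end0 <- lo_L - 1L }
    if (start0 >= end0) { reject("inconsistent_order"); next }
    if (end0 - start0 > max_span) { reject("span_too_large"); next }
    row <- data.frame(gap_id = g, seq_id = L$subject_id,
                      start = as.integer(start0), end = as.integer(end0),
                      strand = if (minus_L) "-" else "+",
                      stringsAsFactors = FALSE)
    if (!is.null(assembly)) {
      row$sequence <- as.character(Biostrings::subseq(assembly[[row$seq_id]],
                                                      row$start + 1L, row$end))
    }
    acc[[length(acc) + 1L]] <- row
  }
  empty_acc <- data.frame(gap_id = character(), seq_id = character(),
                          start = integer(), end = integer(),
                          strand = character(), stringsAsFactors = FALSE)
  list(accepted = if (length(acc)) do.call(rbind, acc) else empty_acc,
       rejected = if (length(rej)) do.call(rbind, rej) else
         data.frame(gap_id = character(), reason = character(),
                    stringsAsFactors = FALSE))
}

#' Count homotetramers in a sequence
#'
#' In the default overlapping convention, every position starting four
#' identical consecutive bases counts, so a run of length L >= 4 contributes
#' L - 3. With `mode = "runs"` each maximal run of length >= 4 counts once.
#' Case-insensitive; N runs never count.
#'
#' @param sequence character scalar or `DNAString`.
#' @param mode counting convention.
#' @return integer count.
#' @export
homotetramer_count <- function(sequence, mode = c("overlapping", "runs")) {
  mode <- match.arg(mode)
  s <- toupper(as.character(sequence))
  if (nchar(s) == 0L) stopf("empty sequence")
  r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
  sel <- r$lengths >= 4L & r$values %in% c("A", "C", "G", "T")
  if (!any(sel)) return(0L)
  if (mode == "overlapping") sum(r$lengths[sel] - 3L) else sum(sel)
}

#' Homotetramer frequency per kbp
#' @inheritParams homotetramer_count
#' @return count / length * 1000.
#' @export
homotetramer_frequency <- function(sequence, mode = c("overlapping", "runs")) {
  s <- as.character(sequence)
  homotetramer_count(s, mode) / nchar(s) * 1000
}

#' Mann-Whitney U test
#'
#' U for the first sample with midrank tie handling. The p value is exact
#' (enumeration of the rank-sum distribution) when the pooled size is at most
#' 12 and there are no ties, otherwise a normal approximation with tie and
#' continuity correction is used.
#'
#' @param a,b numeric samples.
#' @return list with U, p (two-sided), and `exact` flag.
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stopf("both samples must be non-empty")
  r <- rank(c(a, b))
  u_a <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 12L && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(u_a), p = wt$p.value, exact = exact)
}

#' Sample length-matched control sequences from an assembly
#'
#' Sequences are drawn uniformly from the assembly by rejection sampling,
#' avoiding N gaps and any excluded intervals; deterministic under the seed.
#'
#' @param assembly `DNAStringSet`.
#' @param lengths integer vector of sequence lengths to draw.
#' @param seed RNG seed.
#' @param exclude optional data.frame of intervals (seq_id, start, end,
#'   0-based half-open) that picks must not overlap.
#' @param max_tries rejection-sampling cap per length.
#' @return list with `picks` (seq_id, start, end) and `sequences` (character
#'   vector).
#' @export
sample_control_sequences <- function(assembly, lengths, seed = 1L,
                                     exclude = NULL, max_tries = 1000L) {
  if (length(lengths) == 0L) {
    return(list(picks = data.frame(seq_id = character(), start = integer(),
                                   end = integer(), stringsAsFactors = FALSE),
                sequences = character(0)))
  }
  seq_chars <- stats::setNames(as.character(assembly), names(assembly))
  lens <- nchar(seq_chars)
  with_seed(seed, {
    picks <- list(); out <- character(length(lengths))
    for (i in seq_along(lengths)) {
      L <- lengths[i]
      ok <- FALSE
      for (t in seq_len(max_tries)) {
        cand <- lens[lens >= L]
        if (length(cand) == 0L) break
        s <- sample(names(cand), 1L, prob = cand)
        start <- sample.int(lens[[s]] - L + 1L, 1L) - 1L
        end <- start + L
        if (!is.null(exclude)) {
          ex <- exclude[exclude$seq_id == s, , drop = FALSE]
          if (nrow(ex) > 0L && any(start < ex$end & end > ex$start)) next
        }
        frag <- substr(seq_chars[[s]], start + 1L, end)
        if (grepl("N", frag, ignore.case = TRUE)) next
        picks[[length(picks) + 1L]] <- data.frame(seq_id = s, start = start,
                                                  end = end,
                                                  stringsAsFactors = FALSE)
        out[i] <- frag
        ok <- TRUE
        break
      }
      if (!ok) stopf("no valid placement found for length %d", L)
    }
    list(picks = do.call(rbind, picks), sequences = out)
  })
}
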