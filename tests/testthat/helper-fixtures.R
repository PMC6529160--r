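# Small in-code fixtures shared across test files.

toy_genes <- function(spans, seq_id = "c1", strand = "+") {
  n <- length(spans)
  if (n == 0) {
    df <- data.frame(gene_id = character(), seq_id = character(),
                     start = integer(), end = integer(), strand = character(),
                     stringsAsFactors = FALSE)
    df$exons <- I(list())
    return(df)
  }
  df <- data.frame(gene_id = sprintf("g%d", seq_len(n)), seq_id = seq_id,
                   start = vapply(spans, `[`, numeric(1), 1),
                   end = vapply(spans, `[`, numeric(1), 2),
                   strand = strand, stringsAsFactors = FALSE)
  df$exons <- I(lapply(spans, function(sp) {
    cbind(start = as.integer(sp[1]), end = as.integer(sp[2]))
  }))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df
}

toy_track <- function(depths, seq_id = "c1", accession_id = "acc") {
  out <- list()
  out[[seq_id]] <- as.integer(depths)
  list(accession_id = accession_id, depth = out)
}

toy_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(query_id = r$q, subject_id = r$s,
               percent_identity = r$pid %||% 98,
               align_len = as.integer(r$len %||% 500),
               mismatches = 0L, gap_opens = 0L,
               query_start = 1L, query_end = as.integer(r$len %||% 500),
               subject_start = as.integer(r$ss %||% 1),
               subject_end = as.integer(r$se %||% (r$len %||% 500)),
               evalue = r$e %||% 1e-50, bitscore = r$b,
               stringsAsFactors = FALSE)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic relative-coverage tables keyed by gene id.
toy_values <- function(ids, v) {
  data.frame(gene_id = ids, raw_median_depth = v * 30, relative_coverage = v,
             stringsAsFactors = FALSE)
}

# F2 genotype columns from compact strings, e.g. "AABHB-" (- = missing).
geno_col <- function(s) {
  ch <- strsplit(s, "")[[1]]
  ifelse(ch == "-", NA_character_, ch)
}

precision_recall <- function(called, truth) {
  tp <- length(intersect(called, truth))
  c(precision = if (length(called)) tp / length(called) else NA_real_,
    recall = if (length(truth)) tp / length(truth) else NA_real_)
}
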