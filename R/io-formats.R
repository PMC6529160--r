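# Readers and writers for the standard formats the pipeline touches.
#
# Coordinate conventions: everything on disk (GFF3, AGP, depth TSV, BLAST
# tabular) is 1-based inclusive; everything in memory is 0-based half-open.
# Conversion happens only here.

empty_gene_models <- function() {
  data.frame(gene_id = character(), seq_id = character(),
             start = integer(), end = integer(), strand = character(),
             exons = I(list()), stringsAsFactors = FALSE)
}

gff3_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0("(?:^|;)\\s*", key, "=([^;]+)"), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[2L] else NA_character_, character(1))
}

#' Read gene models from GFF3
#'
#' Parses `gene` and `exon` features (attributes `ID` and `Parent`). External
#' 1-based inclusive coordinates are converted to internal 0-based half-open.
#' Genes are returned sorted by (seq_id, start); exons are sorted and checked
#' to be non-overlapping and contained in their gene.
#'
#' @param path path to a GFF3 file.
#' @return data.frame with columns gene_id, seq_id, start, end, strand and a
#'   list column `exons` (integer matrices with columns start, end).
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(empty_gene_models())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L)) {
    bad <- which(nf != 9L)[1L]
    stopf("malformed GFF3 at line %d: expected 9 tab-separated fields, found %d",
          idx[bad], nf[bad])
  }
  m <- matrix(unlist(fields), ncol = 9L, byrow = TRUE)
  start1 <- suppressWarnings(as.integer(m[, 4L]))
  end1 <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(start1) || anyNA(end1)) {
    bad <- which(is.na(start1) | is.na(end1))[1L]
    stopf("malformed GFF3 at line %d: non-numeric coordinates", idx[bad])
  }
  type <- m[, 3L]
  gi <- which(type == "gene")
  ei <- which(type == "exon")
  gene_id <- gff3_attr(m[gi, 9L], "ID")
  if (anyNA(gene_id)) stopf("gene feature without ID attribute (line %d)",
                            idx[gi[which(is.na(gene_id))[1L]]])
  genes <- data.frame(gene_id = gene_id, seq_id = m[gi, 1L],
                      start = start1[gi] - 1L, end = end1[gi],
                      strand = m[gi, 7L], stringsAsFactors = FALSE)
  if (any(genes$start < 0L | genes$start >= genes$end)) {
    stopf("invalid gene coordinates for %s",
          genes$gene_id[which(genes$start < 0L | genes$start >= genes$end)[1L]])
  }
  if (anyDuplicated(genes$gene_id)) {
    stopf("duplicate gene id: %s", genes$gene_id[duplicated(genes$gene_id)][1L])
  }
  exon_parent <- gff3_attr(m[ei, 9L], "Parent")
  exons <- lapply(genes$gene_id, function(g) {
    sel <- ei[which(exon_parent == g)]
    if (length(sel) == 0L) {
      return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
    }
    ex <- cbind(start = start1[sel] - 1L, end = end1[sel])
    ex <- ex[order(ex[, 1L], ex[, 2L]), , drop = FALSE]
    ex
  })
  names(exons) <- NULL
  for (i in seq_along(exons)) {
    ex <- exons[[i]]
    if (nrow(ex) == 0L) next
    if (any(ex[, 1L] < genes$start[i]) || any(ex[, 2L] > genes$end[i])) {
      stopf("exon outside gene span for %s", genes$gene_id[i])
    }
    if (nrow(ex) > 1L && any(ex[-1L, 1L] < ex[-nrow(ex), 2L])) {
      stopf("overlapping exons in gene %s", genes$gene_id[i])
    }
  }
  orphan <- setdiff(unique(exon_parent[!is.na(exon_parent)]), genes$gene_id)
  if (length(orphan)) stopf("exon with unknown Parent: %s", orphan[1L])
  genes$exons <- I(exons)
  o <- order(genes$seq_id, genes$start)
  genes <- genes[o, , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models()]: internal 0-based half-open coordinates are
#' written 1-based inclusive.
#'
#' @param genes gene model data.frame.
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    writeLines(paste(genes$seq_id[i], "pananchor", "gene",
                     genes$start[i] + 1L, genes$end[i], ".", genes$strand[i], ".",
                     paste0("ID=", genes$gene_id[i]), sep = "\t"), con)
    ex <- genes$exons[[i]]
    for (j in seq_len(nrow(ex))) {
      writeLines(paste(genes$seq_id[i], "pananchor", "exon",
                       ex[j, 1L] + 1L, ex[j, 2L], ".", genes$strand[i], ".",
                       paste0("Parent=", genes$gene_id[i]), sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a per-base depth track
#'
#' Rows are `(seq_id, position, depth)` with 1-based positions, as emitted by
#' standard depth tools. Positions may be sparse; absent positions get depth 0.
#'
#' @param path path to the depth TSV.
#' @param seq_lengths named integer vector of sequence lengths.
#' @param accession_id label stored on the track.
#' @return list with `accession_id` and `depth`, a named list of integer
#'   vectors (one per sequence, one entry per base).
#' @export
read_depth_track <- function(path, seq_lengths, accession_id = "sample") {
  if (is.null(names(seq_lengths)) || any(!nzchar(names(seq_lengths)))) {
    stopf("seq_lengths must be a named vector")
  }
  depth <- lapply(seq_lengths, function(L) integer(L))
  info <- file.info(path)
  if (!is.na(info$size) && info$size > 0) {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = c("character", "integer", "integer"),
                             col.names = c("seq_id", "pos", "d"))
    unknown <- setdiff(unique(tab$seq_id), names(seq_lengths))
    if (length(unknown)) stopf("depth row for unknown sequence %s", unknown[1L])
    if (any(tab$d < 0L)) stopf("negative depth value")
    for (s in unique(tab$seq_id)) {
      sel <- tab$seq_id == s
      pos <- tab$pos[sel]
      if (any(pos < 1L) || any(pos > seq_lengths[[s]])) {
        stopf("depth position outside sequence %s (length %d)", s, seq_lengths[[s]])
      }
      v <- depth[[s]]
      v[pos] <- tab$d[sel]
      depth[[s]] <- v
    }
  }
  list(accession_id = accession_id, depth = depth)
}

#' Write a depth track as sparse TSV (non-zero positions only)
#' @param track depth track as returned by [read_depth_track()].
#' @param path output path.
#' @export
write_depth_track <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in names(track$depth)) {
    v <- track$depth[[s]]
    nz <- which(v != 0L)
    if (length(nz)) {
      utils::write.table(data.frame(s, nz, v[nz]), con, sep = "\t",
                         quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

hit_columns <- c("query_id", "subject_id", "percent_identity", "align_len",
                 "mismatches", "gap_opens", "query_start", "query_end",
                 "subject_start", "subject_end", "evalue", "bitscore")

empty_hit_table <- function() {
  df <- data.frame(query_id = character(), subject_id = character(),
                   percent_identity = numeric(), align_len = integer(),
                   mismatches = integer(), gap_opens = integer(),
                   query_start = integer(), query_end = integer(),
                   subject_start = integer(), subject_end = integer(),
                   evalue = numeric(), bitscore = numeric(),
                   stringsAsFactors = FALSE)
  df
}

#' Read a 12-column BLAST tabular hit table (-outfmt 6)
#'
#' Subject coordinates with `subject_start > subject_end` are kept as given and
#' interpreted downstream as minus-strand placements.
#'
#' @param path path to the tab-separated hit table.
#' @return data.frame of hits.
#' @export
read_hit_table <- function(path) {
  info <- file.info(path)
  if (is.na(info$size) || info$size == 0) return(empty_hit_table())
  cf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (any(cf != 12L)) {
    stopf("hit table row %d has %d columns, expected 12", which(cf != 12L)[1L],
          cf[cf != 12L][1L])
  }
  tab <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer", "integer", "integer",
                                          "integer", "integer", "integer",
                                          "integer", "numeric", "numeric"))
  names(tab) <- hit_columns
  if (any(tab$align_len <= 0L)) stopf("non-positive alignment length")
  if (any(tab$bitscore < 0) || any(tab$evalue < 0)) {
    stopf("negative bitscore or evalue")
  }
  tab
}

#' Write a hit table in 12-column BLAST tabular format
#' @param hits hit data.frame (columns as [read_hit_table()]).
#' @param path output path.
#' @export
write_hit_table <- function(hits, path) {
  utils::write.table(hits[, hit_columns], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Lay out contig placements as AGP v2.1 records
#'
#' W lines for contigs and U gap lines of `gap_length` between consecutive
#' contigs of one object; object coordinates are contiguous and 1-based
#' inclusive. Unknown orientations are written as `?`.
#'
#' @param placements data.frame with object_id, component_id, orientation and
#'   order_index columns (sorted by order_index within object).
#' @param contig_lengths named vector of component lengths.
#' @param gap_length spacer length between consecutive components.
#' @return data.frame of AGP records.
#' @export
make_agp <- function(placements, contig_lengths, gap_length = 100L) {
  if (gap_length < 1L) stopf("gap_length must be >= 1")
  recs <- list()
  for (obj in unique(placements$object_id)) {
    p <- placements[placements$object_id == obj, , drop = FALSE]
    p <- p[order(p$order_index), , drop = FALSE]
    if (anyDuplicated(p$component_id)) {
      stopf("duplicate component %s in object %s",
            p$component_id[duplicated(p$component_id)][1L], obj)
    }
    at <- 1L
    part <- 1L
    for (i in seq_len(nrow(p))) {
      cid <- p$component_id[i]
      len <- contig_lengths[[cid]]
      if (is.null(len)) stopf("no length for component %s", cid)
      if (i > 1L) {
        recs[[length(recs) + 1L]] <- data.frame(
          object_id = obj, object_beg = at, object_end = at + gap_length - 1L,
          part_number = part, component_type = "U",
          component_id = NA_character_, component_beg = NA_integer_,
          component_end = NA_integer_, orientation = NA_character_,
          gap_length = as.integer(gap_length), gap_type = "scaffold",
          linkage = "yes", linkage_evidence = "map", stringsAsFactors = FALSE)
        at <- at + gap_length
        part <- part + 1L
      }
      recs[[length(recs) + 1L]] <- data.frame(
        object_id = obj, object_beg = at, object_end = at + len - 1L,
        part_number = part, component_type = "W",
        component_id = cid, component_beg = 1L, component_end = as.integer(len),
        orientation = as.character(p$orientation[i]),
        gap_length = NA_integer_, gap_type = NA_character_,
        linkage = NA_character_, linkage_evidence = NA_character_,
        stringsAsFactors = FALSE)
      at <- at + as.integer(len)
      part <- part + 1L
    }
  }
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

agp_orient_out <- function(x) ifelse(is.na(x) | x == "unknown", "?", x)

#' Write AGP v2.1 records to file
#' @param agp AGP record data.frame from [make_agp()].
#' @param path output path.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  for (i in seq_len(nrow(agp))) {
    if (agp$component_type[i] == "W") {
      writeLines(paste(agp$object_id[i], agp$object_beg[i], agp$object_end[i],
                       agp$part_number[i], "W", agp$component_id[i],
                       agp$component_beg[i], agp$component_end[i],
                       agp_orient_out(agp$orientation[i]), sep = "\t"), con)
    } else {
      writeLines(paste(agp$object_id[i], agp$object_beg[i], agp$object_end[i],
                       agp$part_number[i], "U", agp$gap_length[i],
                       agp$gap_type[i], agp$linkage[i],
                       agp$linkage_evidence[i], sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read an AGP v2.1 file written by [write_agp()]
#' @param path AGP file path.
#' @return data.frame of AGP records.
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 9L)) stopf("AGP line with wrong field count")
  recs <- lapply(fields, function(f) {
    if (f[5L] == "W") {
      data.frame(object_id = f[1L], object_beg = as.integer(f[2L]),
                 object_end = as.integer(f[3L]), part_number = as.integer(f[4L]),
                 component_type = "W", component_id = f[6L],
                 component_beg = as.integer(f[7L]), component_end = as.integer(f[8L]),
                 orientation = f[9L], gap_length = NA_integer_,
                 gap_type = NA_character_, linkage = NA_character_,
                 linkage_evidence = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(object_id = f[1L], object_beg = as.integer(f[2L]),
                 object_end = as.integer(f[3L]), part_number = as.integer(f[4L]),
                 component_type = f[5L], component_id = NA_character_,
                 component_beg = NA_integer_, component_end = NA_integer_,
                 orientation = NA_character_, gap_length = as.integer(f[6L]),
                 gap_type = f[7L], linkage = f[8L], linkage_evidence = f[9L],
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, recs)
  # tiling check: object coordinates must be contiguous without overlap
  for (obj in unique(out$object_id)) {
    p <- out[out$object_id == obj, ]
    p <- p[order(p$object_beg), ]
    if (p$object_beg[1L] != 1L ||
        (nrow(p) > 1L && any(p$object_beg[-1L] != p$object_end[-nrow(p)] + 1L))) {
      stopf("AGP object %s does not tile contiguously", obj)
    }
  }
  out
}

#' Reconstruct object sequences from AGP records and component sequences
#'
#' @param agp AGP record data.frame.
#' @param contigs `DNAStringSet` of component sequences.
#' @return `DNAStringSet` of assembled objects.
#' @export
assemble_from_agp <- function(agp, contigs) {
  objs <- unique(agp$object_id)
  seqs <- vapply(objs, function(obj) {
    p <- agp[agp$object_id == obj, , drop = FALSE]
    p <- p[order(p$object_beg), , drop = FALSE]
    parts <- vapply(seq_len(nrow(p)), function(i) {
      if (p$component_type[i] == "U") {
        strrep("N", p$gap_length[i])
      } else {
        cid <- p$component_id[i]
        if (!cid %in% names(contigs)) stopf("missing contig sequence %s", cid)
        s <- Biostrings::subseq(contigs[[cid]], p$component_beg[i], p$component_end[i])
        if (identical(p$orientation[i], "-")) s <- Biostrings::reverseComplement(s)
        as.character(s)
      }
    }, character(1))
    paste(parts, collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- objs
  out
}

#' Read sequences from FASTA
#' @param path FASTA file path.
#' @return `DNAStringSet`.
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Write sequences to FASTA
#' @param seqs `DNAStringSet` (or named character vector).
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  invisible(path)
}
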