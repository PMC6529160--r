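# F2 recombination-fraction estimation and genetic anchoring of contigs.
#
# The estimator is a maximum-likelihood EM for the F2 intercross: the joint
# genotype of a marker pair follows a 9-class multinomial whose class
# probabilities are products of two independent gamete transmissions with
# recombination fraction r; the double-heterozygote class mixes parental and
# recombinant phase. EM iterates the expected recombinant-gamete count.

f2_class_counts <- function(calls1, calls2) {
  ok <- !is.na(calls1) & !is.na(calls2)
  table(factor(calls1[ok], levels = c("A", "H", "B")),
        factor(calls2[ok], levels = c("A", "H", "B")))
}

f2_class_probs <- function(r) {
  p <- r * (1 - r) / 2
  matrix(c((1 - r)^2 / 4, p, r^2 / 4,
           p, ((1 - r)^2 + r^2) / 2, p,
           r^2 / 4, p, (1 - r)^2 / 4),
         nrow = 3, byrow = TRUE)
}

f2_loglik <- function(tab, r) {
  p <- f2_class_probs(r)
  sel <- tab > 0
  if (any(sel & p <= 0)) return(-Inf)
  sum(tab[sel] * log(p[sel]))
}

#' Estimate the recombination fraction between two F2 markers
#'
#' Plants with a missing call at either marker are excluded pairwise. The EM
#' update is r' = E[recombinant gametes | r] / (2n); classes other than the
#' double heterozygote contribute fixed recombinant-gamete counts, the
#' double-heterozygote class contributes 2 r^2 / ((1-r)^2 + r^2) expected
#' recombinant gametes. The iteration runs unconstrained in (0, 1) from both
#' phase basins (the likelihood maps to itself under r -> 1-r combined with an
#' allele relabeling, so it can carry one mode on each side of 0.5); the
#' better mode is kept and the estimate folded to [0, 0.5] (min(r, 1-r)).
#' Folding makes the estimate invariant under an allele swap at either
#' marker; `loglik` is the value at the achieved maximum.
#'
#' @param calls1,calls2 character vectors of calls in {A, H, B, NA}.
#' @param tol convergence tolerance on |delta r| (default 1e-6).
#' @param max_iter EM iteration cap (default 200).
#' @return list with r_hat, n_informative, loglik, degenerate.
#' @export
estimate_rf <- function(calls1, calls2, tol = 1e-6, max_iter = 200L) {
  tab <- f2_class_counts(calls1, calls2)
  n <- sum(tab)
  mono <- sum(rowSums(tab) > 0) < 2L || sum(colSums(tab) > 0) < 2L
  if (n == 0L || mono) {
    return(list(r_hat = 0, n_informative = as.integer(n),
                loglik = if (n > 0) f2_loglik(tab, 0) else NA_real_,
                degenerate = TRUE))
  }
  # fixed recombinant-gamete counts per class (double het handled separately)
  konst <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), nrow = 3, byrow = TRUE)
  base <- sum(tab * konst)  # HH cell has konst 0
  n_hh <- tab[2L, 2L]
  run_em <- function(r) {
    for (it in seq_len(max_iter)) {
      e_hh <- if (n_hh > 0) n_hh * 2 * r^2 / ((1 - r)^2 + r^2) else 0
      r_new <- (base + e_hh) / (2 * n)
      done <- abs(r_new - r) < tol
      r <- r_new
      if (done) break
    }
    r
  }
  # the likelihood can have one mode on each side of 0.5 (the two phase
  # labelings); start EM in both basins and keep the better mode
  cand <- vapply(c(0.25, 0.75), run_em, numeric(1))
  ll <- vapply(cand, function(r) f2_loglik(tab, r), numeric(1))
  r_star <- cand[which.max(ll)]
  list(r_hat = min(r_star, 1 - r_star), n_informative = as.integer(n),
       loglik = max(ll), degenerate = FALSE)
}

#' Pairwise recombination-fraction matrix
#'
#' @param geno plants x markers character genotype matrix.
#' @return symmetric marker x marker matrix of r estimates, zero diagonal.
#' @export
rf_matrix <- function(geno) {
  mk <- colnames(geno)
  if (is.null(mk) || length(mk) < 2L) stopf("need >= 2 named markers")
  k <- length(mk)
  m <- matrix(0, k, k, dimnames = list(mk, mk))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      m[i, j] <- m[j, i] <- estimate_rf(geno[, i], geno[, j])$r_hat
    }
  }
  m
}

#' Group contigs into linkage groups by single linkage
#'
#' The distance between two contigs is the minimum estimated r over their
#' marker pairs; contigs are joined iff that distance is strictly below
#' `r_max` (single linkage, implemented as union-find so the boundary is
#' exact). Contigs without markers are reported unplaced.
#'
#' @param rfm marker x marker r matrix from [rf_matrix()].
#' @param marker_contigs data.frame with marker_id and contig_id.
#' @param r_max joining threshold (default 0.25).
#' @return list with `groups` (data.frame contig_id, linkage_group) and
#'   `unplaced` (contig ids without markers, if any were named).
#' @export
cluster_linkage_groups <- function(rfm, marker_contigs, r_max = 0.25,
                                   all_contigs = NULL) {
  mk <- rownames(rfm)
  mc <- marker_contigs[match(mk, marker_contigs$marker_id), , drop = FALSE]
  if (anyNA(mc$contig_id)) stopf("marker without contig assignment")
  contigs <- sort(unique(mc$contig_id))
  parent <- stats::setNames(seq_along(contigs), contigs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (a in seq_along(contigs)) {
    for (b in seq_along(contigs)) {
      if (b <= a) next
      d <- min(rfm[mc$contig_id == contigs[a], mc$contig_id == contigs[b]])
      if (d < r_max) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
    }
  }
  root <- vapply(seq_along(contigs), find, numeric(1))
  gid <- match(root, sort(unique(root)))
  groups <- data.frame(contig_id = contigs, linkage_group = gid,
                       stringsAsFactors = FALSE)
  unplaced <- if (is.null(all_contigs)) character(0) else
    sort(setdiff(all_contigs, contigs))
  list(groups = groups, unplaced = unplaced)
}

all_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in all_permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], p)
  }
  out
}

contig_min_rf <- function(rfm, mc, c1, c2) {
  min(rfm[mc$contig_id == c1, mc$contig_id == c2])
}

#' Order and orient the contigs of one linkage group
#'
#' The order minimizes the sum of adjacent inter-contig minimum r
#' (exhaustive search up to 8 contigs, greedy nearest-neighbour beyond). Of
#' the two mirror-image orders the one with the lexicographically smaller
#' first contig id is kept. Each contig with at least two markers is oriented
#' so that the physical order of its markers agrees with the genetic
#' direction implied by the flanking contigs (mean r to markers of earlier
#' contigs minus mean r to markers of later contigs, increasing along the
#' group); contigs with fewer than two markers get orientation `unknown`.
#'
#' @param group_contigs contig ids forming one linkage group.
#' @param rfm marker x marker r matrix.
#' @param marker_map data.frame with marker_id, contig_id, phys_pos.
#' @param linkage_group group label stored on the placements.
#' @return data.frame of placements: contig_id, linkage_group, order_index,
#'   orientation, n_markers.
#' @export
order_and_orient <- function(group_contigs, rfm, marker_map,
                             linkage_group = 1L) {
  mk <- rownames(rfm)
  mc <- marker_map[match(mk, marker_map$marker_id), , drop = FALSE]
  cs <- sort(unique(group_contigs))
  if (length(cs) == 1L) {
    ord <- cs
  } else {
    D <- matrix(0, length(cs), length(cs), dimnames = list(cs, cs))
    for (a in seq_along(cs)) for (b in seq_along(cs)) {
      if (a < b) D[a, b] <- D[b, a] <- contig_min_rf(rfm, mc, cs[a], cs[b])
    }
    path_cost <- function(p) sum(D[cbind(p[-length(p)], p[-1L])])
    if (length(cs) <= 8L) {
      perms <- all_permutations(cs)
      costs <- vapply(perms, path_cost, numeric(1))
      ord <- perms[[which.min(costs)]]
    } else {
      best <- NULL; best_cost <- Inf
      for (s in seq_along(cs)) {
        p <- cs[s]; rest <- setdiff(cs, p)
        while (length(rest)) {
          nxt <- rest[which.min(D[p[length(p)], rest])]
          p <- c(p, nxt); rest <- setdiff(rest, nxt)
        }
        cost <- path_cost(p)
        if (cost < best_cost) { best <- p; best_cost <- cost }
      }
      ord <- best
    }
    if (ord[1L] > ord[length(ord)]) ord <- rev(ord)  # deterministic mirror
  }
  # orientation from flanking-contig anchors
  orientation <- character(length(ord))
  for (i in seq_along(ord)) {
    cmk <- mc$marker_id[mc$contig_id == ord[i]]
    if (length(cmk) < 2L) { orientation[i] <- "unknown"; next }
    left_mk <- mc$marker_id[mc$contig_id %in% ord[seq_len(i - 1L)]]
    right_mk <- if (i < length(ord)) {
      mc$marker_id[mc$contig_id %in% ord[(i + 1L):length(ord)]]
    } else character(0)
    u <- vapply(cmk, function(m) {
      l <- if (length(left_mk)) mean(rfm[m, left_mk]) else NA_real_
      r <- if (length(right_mk)) mean(rfm[m, right_mk]) else NA_real_
      if (is.na(l) && is.na(r)) NA_real_
      else if (is.na(l)) -r
      else if (is.na(r)) l
      else l - r
    }, numeric(1))
    if (anyNA(u)) { orientation[i] <- "+"; next }  # singleton group
    phys <- marker_map$phys_pos[match(cmk, marker_map$marker_id)]
    slope <- sum((phys - mean(phys)) * (u - mean(u)))
    orientation[i] <- if (slope >= 0) "+" else "-"
  }
  n_markers <- vapply(ord, function(cc) sum(mc$contig_id == cc), integer(1))
  data.frame(contig_id = ord, linkage_group = linkage_group,
             order_index = seq_along(ord) - 1L, orientation = orientation,
             n_markers = n_markers, stringsAsFactors = FALSE, row.names = NULL)
}

#' Group, order and orient all contigs of a genotype matrix
#'
#' Convenience wrapper running [rf_matrix()], [cluster_linkage_groups()] and
#' [order_and_orient()] per group.
#'
#' @param geno plants x markers genotype matrix.
#' @param marker_map data.frame with marker_id, contig_id, phys_pos.
#' @param r_max linkage-group joining threshold.
#' @return list with `placements` (all groups combined), `rf` (the marker
#'   matrix) and `unplaced`.
#' @export
anchor_contigs <- function(geno, marker_map, r_max = 0.25) {
  rfm <- rf_matrix(geno)
  cl <- cluster_linkage_groups(rfm, marker_map, r_max = r_max)
  placements <- do.call(rbind, lapply(sort(unique(cl$groups$linkage_group)),
    function(g) {
      order_and_orient(cl$groups$contig_id[cl$groups$linkage_group == g],
                       rfm, marker_map, linkage_group = g)
    }))
  list(placements = placements, rf = rfm, unplaced = cl$unplaced)
}

#' Join placed contigs into pseudochromosome sequences with AGP
#'
#' Contigs are concatenated in placement order with N spacers of
#' `gap_length`; minus-orientation contigs are reverse-complemented, unknown
#' orientations are treated as forward. `reference_polarity` optionally flips
#' whole groups (reversing order and inverting orientations) to match an
#' external north-south convention.
#'
#' @param placements data.frame from [order_and_orient()] /
#'   [anchor_contigs()].
#' @param contig_seqs `DNAStringSet` of contig sequences.
#' @param gap_length N spacer length (default 100).
#' @param reference_polarity optional named vector of "+"/"-" per linkage
#'   group.
#' @return list with `seqs` (`DNAStringSet`, one per group, named LG<k>) and
#'   `agp` (AGP records).
#' @export
build_pseudochromosomes <- function(placements, contig_seqs, gap_length = 100L,
                                    reference_polarity = NULL) {
  missing <- setdiff(placements$contig_id, names(contig_seqs))
  if (length(missing)) stopf("missing contig sequence %s", missing[1L])
  plc <- placements
  plc$object_id <- sprintf("LG%d", plc$linkage_group)
  rows <- list()
  for (obj in unique(plc$object_id)) {
    p <- plc[plc$object_id == obj, , drop = FALSE]
    p <- p[order(p$order_index), , drop = FALSE]
    pol <- reference_polarity[[sub("^LG", "", obj)]] %||%
      reference_polarity[[obj]] %||% "+"
    if (identical(pol, "-")) {
      p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
      p$orientation <- c("+" = "-", "-" = "+", unknown = "unknown")[p$orientation]
      p$order_index <- seq_len(nrow(p)) - 1L
    }
    rows[[length(rows) + 1L]] <- p
  }
  plc <- do.call(rbind, rows)
  agp <- make_agp(data.frame(object_id = plc$object_id,
                             component_id = plc$contig_id,
                             orientation = ifelse(plc$orientation == "unknown",
                                                  "?", plc$orientation),
                             order_index = plc$order_index,
                             stringsAsFactors = FALSE),
                  stats::setNames(Biostrings::width(contig_seqs),
                                  names(contig_seqs)),
                  gap_length = gap_length)
  seqs <- assemble_from_agp(agp, contig_seqs)
  list(seqs = seqs, agp = agp)
}

#' Two-sample proportion test for recombination-rate contrasts
#'
#' Pearson chi-square on the 2x2 table with Yates continuity correction (the
#' default of the standard two-sample proportion test), p from the chi-square
#' distribution with 1 df.
#'
#' @param x1,n1 recombinants and total in region 1.
#' @param x2,n2 recombinants and total in region 2.
#' @param correct apply the continuity correction (default TRUE).
#' @return list with chi2 and p.
#' @export
compare_recombination_rates <- function(x1, n1, x2, n2, correct = TRUE) {
  if (n1 <= 0 || n2 <= 0) stopf("sample sizes must be positive")
  if (x1 > n1 || x2 > n2 || x1 < 0 || x2 < 0) stopf("counts must satisfy 0 <= x <= n")
  if (x1 / n1 == x2 / n2) return(list(chi2 = 0, p = 1))
  res <- suppressWarnings(stats::prop.test(c(x1, x2), c(n1, n2),
                                           correct = correct))
  list(chi2 = unname(res$statistic), p = res$p.value)
}
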