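# Synthetic-data generators.
#
# These generators define the study conditions under which the analysis
# stages are exercised: a two-genotype assembly pair with planted copy-number
# truth, Poisson depth tracks with per-gene mapability bias, an accession
# panel with planted dispensable genes, F2 genotype matrices under a Haldane
# (no-interference) crossover model, and hit tables consistent with planted
# orthology. Everything is deterministic under a fixed seed.

#' Simulation configuration for a two-genotype genome pair
#'
#' Defaults describe a compact diploid-plant-like test genome: 1,000 genes on
#' a 2 Mbp chromosome, 30 genes amplified in each genotype, a small deleted
#' set and one inverted block of 10 consecutive genes. Planted amplifications
#' carry `dup_copies = 3` total copies; a single extra copy would put the
#' expected coverage ratio exactly on the 50% calling boundary (see the
#' methods vignette).
#'
#' @param genome_size chromosome length in bp.
#' @param n_genes number of protein-coding gene models.
#' @param n_tes number of transposable-element intervals.
#' @param n_te_genes number of genes fully covered by a TE (planted TE genes).
#' @param gene_len min/max gene span in bp.
#' @param n_dup_q,n_dup_r genes amplified in genotype Q / in genotype R.
#' @param n_del_q genes deleted from genotype Q.
#' @param dup_copies total copy number of an amplified gene.
#' @param inversion_genes length (in genes) of the planted inverted block;
#'   0 disables it.
#' @return validated config list.
#' @export
sim_config <- function(genome_size = 2e6, n_genes = 1000, n_tes = 50,
                       n_te_genes = 20, gene_len = c(600, 1600),
                       n_dup_q = 30, n_dup_r = 30, n_del_q = 10,
                       dup_copies = 3, inversion_genes = 10) {
  cfg <- list(genome_size = as.integer(genome_size), n_genes = as.integer(n_genes),
              n_tes = as.integer(n_tes), n_te_genes = as.integer(n_te_genes),
              gene_len = as.integer(gene_len), n_dup_q = as.integer(n_dup_q),
              n_dup_r = as.integer(n_dup_r), n_del_q = as.integer(n_del_q),
              dup_copies = as.integer(dup_copies),
              inversion_genes = as.integer(inversion_genes))
  if (any(unlist(cfg[c("n_tes", "n_te_genes", "n_dup_q", "n_dup_r", "n_del_q",
                       "inversion_genes")]) < 0L)) {
    stopf("all feature counts must be >= 0")
  }
  if (cfg$n_genes < 1L) stopf("n_genes must be >= 1")
  if (cfg$dup_copies < 2L) stopf("dup_copies must be >= 2")
  slot <- cfg$genome_size %/% cfg$n_genes
  if (slot < cfg$gene_len[2L] + 20L) {
    stopf("requested genes exceed genome capacity: %d genes of up to %d bp on %d bp",
          cfg$n_genes, cfg$gene_len[2L], cfg$genome_size)
  }
  planted <- cfg$n_dup_q + cfg$n_dup_r + cfg$n_del_q + cfg$inversion_genes
  if (planted > cfg$n_genes) stopf("planted variants exceed gene count")
  if (cfg$inversion_genes > 0L && cfg$inversion_genes < 2L) {
    stopf("inversion must span at least 2 genes")
  }
  cfg
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a two-genotype assembly with planted variant truth
#'
#' Generates the reference genotype R assembly (one chromosome), gene models
#' with exon structure, TE intervals, and a truth record listing genes
#' amplified in R, amplified in the second genotype Q, deleted in Q, and an
#' inverted block of consecutive genes (reversed in Q's gene order).
#'
#' @param config from [sim_config()].
#' @param seed RNG seed.
#' @return list with `assembly` (`DNAStringSet`), `genes`, `tes`, `truth`,
#'   `config`.
#' @export
simulate_genome_pair <- function(config = sim_config(), seed = 1L) {
  with_seed(seed, {
    n <- config$n_genes
    slot <- config$genome_size %/% n
    len <- sample(seq(config$gene_len[1L], config$gene_len[2L]), n, replace = TRUE)
    jitter <- vapply(slot - len - 10L, function(m) sample.int(m, 1L), integer(1))
    start <- as.integer((seq_len(n) - 1L) * slot + jitter)
    end <- start + len
    gene_id <- sprintf("g%04d", seq_len(n))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    exons <- lapply(seq_len(n), function(i) {
      if (len[i] < 500L || stats::runif(1) < 0.3) {
        return(cbind(start = start[i], end = end[i]))
      }
      k <- sample(2:3, 1L)
      cuts <- sort(sample(seq(start[i] + 100L, end[i] - 100L, by = 10L),
                          2L * (k - 1L)))
      bs <- c(start[i], cuts[seq(2, length(cuts), by = 2)])
      be <- c(cuts[seq(1, length(cuts), by = 2)], end[i])
      cbind(start = as.integer(bs), end = as.integer(be))
    })
    genes <- data.frame(gene_id = gene_id, seq_id = "chr1", start = start,
                        end = end, strand = strand, stringsAsFactors = FALSE)
    genes$exons <- I(exons)

    # planted truth: disjoint gene sets
    inv_genes <- character(0)
    inv_start_index <- NA_integer_
    if (config$inversion_genes > 0L) {
      inv_start_index <- sample(seq(n %/% 4, 3L * n %/% 4), 1L)
      inv_genes <- gene_id[inv_start_index:(inv_start_index + config$inversion_genes - 1L)]
    }
    pool <- setdiff(gene_id, inv_genes)
    pick <- sample(pool, config$n_dup_q + config$n_dup_r + config$n_del_q)
    dup_q <- pick[seq_len(config$n_dup_q)]
    dup_r <- pick[config$n_dup_q + seq_len(config$n_dup_r)]
    del_q <- pick[config$n_dup_q + config$n_dup_r + seq_len(config$n_del_q)]

    # TE intervals: some fully covering genes (planted TE genes), rest random
    te_gene_ids <- sample(setdiff(pool, c(dup_q, dup_r, del_q)),
                          min(config$n_te_genes, length(pool)))
    tes <- list()
    for (g in te_gene_ids) {
      i <- match(g, gene_id)
      tes[[length(tes) + 1L]] <- data.frame(
        te_id = sprintf("te%03d", length(tes) + 1L), seq_id = "chr1",
        start = max(0L, start[i] - 50L),
        end = min(config$genome_size, end[i] + 50L), stringsAsFactors = FALSE)
    }
    n_free <- max(0L, config$n_tes - length(tes))
    if (n_free > 0L) {
      tl <- sample(500:3000, n_free, replace = TRUE)
      ts <- vapply(tl, function(L) sample.int(config$genome_size - L, 1L) - 1L,
                   integer(1))
      for (i in seq_len(n_free)) {
        tes[[length(tes) + 1L]] <- data.frame(
          te_id = sprintf("te%03d", length(tes) + 1L), seq_id = "chr1",
          start = ts[i], end = ts[i] + tl[i], stringsAsFactors = FALSE)
      }
    }
    tes <- if (length(tes)) do.call(rbind, tes) else
      data.frame(te_id = character(), seq_id = character(),
                 start = integer(), end = integer(), stringsAsFactors = FALSE)

    # Q gene order: R order with the inverted block reversed
    q_order <- seq_len(n)
    if (length(inv_genes)) {
      blk <- inv_start_index:(inv_start_index + config$inversion_genes - 1L)
      q_order[blk] <- rev(blk)
    }

    truth <- list(
      dup_in_q = data.frame(gene_id = dup_q,
                            copies = rep(config$dup_copies, length(dup_q)),
                            stringsAsFactors = FALSE),
      dup_in_r = data.frame(gene_id = dup_r,
                            copies = rep(config$dup_copies, length(dup_r)),
                            stringsAsFactors = FALSE),
      del_in_q = data.frame(gene_id = del_q, stringsAsFactors = FALSE),
      inversion = list(genes = inv_genes, start_index = inv_start_index),
      te_genes = te_gene_ids,
      q_order = gene_id[q_order])

    assembly <- Biostrings::DNAStringSet(c(chr1 = random_dna(config$genome_size)))
    list(assembly = assembly, genes = genes, tes = tes, truth = truth,
         config = config)
  })
}

#' Per-gene copy map for one genotype of a simulated pair
#'
#' `k` is the copy number in the sampled genotype's genome, `m` the copy
#' number represented in the reference assembly (the assembly is genotype R's
#' own, so R's amplified genes have k = m and normal relative depth, while
#' Q's reads pile all copies onto a single assembled locus).
#'
#' @param sim output of [simulate_genome_pair()].
#' @param genotype `"R"` (assembly genotype) or `"Q"`.
#' @return data.frame with gene_id, k, m.
#' @export
truth_copy_map <- function(sim, genotype = c("R", "Q")) {
  genotype <- match.arg(genotype)
  cm <- data.frame(gene_id = sim$genes$gene_id, k = 1L, m = 1L,
                   stringsAsFactors = FALSE)
  tr <- sim$truth
  i_dr <- match(tr$dup_in_r$gene_id, cm$gene_id)
  cm$m[i_dr] <- tr$dup_in_r$copies
  if (genotype == "R") {
    cm$k[i_dr] <- tr$dup_in_r$copies
  } else {
    i_dq <- match(tr$dup_in_q$gene_id, cm$gene_id)
    cm$k[i_dq] <- tr$dup_in_q$copies
    cm$k[match(tr$del_in_q$gene_id, cm$gene_id)] <- 0L
  }
  cm
}

#' Simulate a per-base depth track over a simulated assembly
#'
#' Depth is Poisson(mean_depth * k/m * b_g) inside gene g and
#' Poisson(mean_depth) elsewhere, where b_g is a per-gene multiplicative
#' mapability bias drawn once per accession as lognormal with median 1 and
#' log-sd `bias_spread`.
#'
#' @param assembly `DNAStringSet` (lengths only are used).
#' @param genes gene model data.frame.
#' @param copy_map data.frame gene_id/k/m (genes absent from it get k = m = 1).
#' @param mean_depth mean background read depth.
#' @param bias_spread log-sd of the per-gene mapability bias; 0 disables it.
#'   The default 0.05 models a few percent per-gene coverage bias between
#'   accessions of one species; see the methods vignette for the power
#'   arithmetic behind the choice.
#' @param seed RNG seed.
#' @param accession_id label stored on the track.
#' @return depth track (list with `accession_id`, `depth`).
#' @export
simulate_depth_track <- function(assembly, genes, copy_map = NULL,
                                 mean_depth = 30, bias_spread = 0.05,
                                 seed = 1L, accession_id = "sim") {
  if (mean_depth < 0) stopf("mean_depth must be >= 0")
  if (bias_spread < 0) stopf("bias_spread must be >= 0")
  with_seed(seed, {
    lens <- stats::setNames(Biostrings::width(assembly), names(assembly))
    depth <- lapply(lens, function(L) stats::rpois(L, mean_depth))
    k <- rep(1, nrow(genes)); m <- rep(1, nrow(genes))
    if (!is.null(copy_map)) {
      idx <- match(genes$gene_id, copy_map$gene_id)
      k[!is.na(idx)] <- copy_map$k[idx[!is.na(idx)]]
      m[!is.na(idx)] <- copy_map$m[idx[!is.na(idx)]]
      if (any(m < 1)) stopf("assembly copy number m must be >= 1")
    }
    b <- if (bias_spread > 0) exp(stats::rnorm(nrow(genes), 0, bias_spread))
         else rep(1, nrow(genes))
    for (i in seq_len(nrow(genes))) {
      rate <- mean_depth * (k[i] / m[i]) * b[i]
      s <- genes$seq_id[i]
      span <- (genes$start[i] + 1L):genes$end[i]
      depth[[s]][span] <- stats::rpois(length(span), rate)
    }
    list(accession_id = accession_id, depth = lapply(depth, as.integer))
  })
}

haldane_r <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

haldane_d <- function(r) -50 * log(1 - 2 * r)

#' Simulate a genetic marker map over contigs
#'
#' Places `markers_per_contig` markers on each of
#' `n_groups * contigs_per_group` contigs, assigns contigs to linkage groups
#' in a random order with random true orientations, and draws inter-marker
#' genetic spacings uniformly from `spacing_cm`. Physical marker positions
#' within a contig run opposite to the genetic direction for `-` contigs.
#'
#' Columns `linkage_group`, `cm` and the returned `truth` table are the
#' simulation truth; estimation consumes only marker_id, contig_id and
#' phys_pos together with a genotype matrix.
#'
#' @param n_groups number of linkage groups (chromosomes).
#' @param contigs_per_group contigs per linkage group.
#' @param markers_per_contig markers per contig.
#' @param spacing_cm min/max genetic spacing between consecutive markers.
#' @param contig_len physical contig length in bp.
#' @param seed RNG seed.
#' @return list with `marker_map` and `truth` (contig order/orientation).
#' @export
simulate_marker_map <- function(n_groups = 3, contigs_per_group = 3,
                                markers_per_contig = 3, spacing_cm = c(4, 12),
                                contig_len = 2e6, seed = 1L) {
  with_seed(seed, {
    n_contigs <- n_groups * contigs_per_group
    ids <- sample(sprintf("c%02d", seq_len(n_contigs)))  # shuffled assignment
    rows <- list(); truth <- list()
    ci <- 0L
    for (g in seq_len(n_groups)) {
      cm_at <- 0
      for (j in seq_len(contigs_per_group)) {
        ci <- ci + 1L
        cid <- ids[ci]
        ori <- sample(c("+", "-"), 1L)
        cms <- numeric(markers_per_contig)
        for (mk in seq_len(markers_per_contig)) {
          cm_at <- cm_at + stats::runif(1, spacing_cm[1L], spacing_cm[2L])
          cms[mk] <- cm_at
        }
        phys <- sort(sample.int(contig_len, markers_per_contig))
        if (ori == "-") phys <- rev(phys)
        rows[[length(rows) + 1L]] <- data.frame(
          marker_id = sprintf("%s_m%d", cid, seq_len(markers_per_contig)),
          linkage_group = g, contig_id = cid, phys_pos = phys, cm = cms,
          stringsAsFactors = FALSE)
        truth[[length(truth) + 1L]] <- data.frame(
          contig_id = cid, linkage_group = g, order_index = j - 1L,
          orientation = ori, stringsAsFactors = FALSE)
      }
    }
    list(marker_map = do.call(rbind, rows), truth = do.call(rbind, truth))
  })
}

#' Simulate F2 intercross genotype calls
#'
#' Each plant receives two independent gametes; each gamete recombines
#' between adjacent markers at genetic distance d cM with probability
#' (1 - exp(-2d/100))/2 (Haldane, no interference). Genotypes are the gamete
#' sum coded A/H/B; calls are masked to NA independently at `missing_rate`.
#' Markers on different linkage groups segregate independently.
#'
#' @param marker_map data.frame with marker_id, linkage_group, cm.
#' @param n_plants F2 population size.
#' @param missing_rate per-call missing probability.
#' @param seed RNG seed.
#' @return list with `geno` (plants x markers character matrix) and `truth`
#'   (per adjacent-marker-pair true r, recombinant-gamete counts, and counts
#'   of plants with at least one recombinant gamete).
#' @export
simulate_f2_population <- function(marker_map, n_plants = 1000,
                                   missing_rate = 0.05, seed = 1L) {
  if (n_plants < 0) stopf("n_plants must be >= 0")
  if (missing_rate < 0 || missing_rate > 1) stopf("missing_rate must be in [0,1]")
  with_seed(seed, {
    nm <- nrow(marker_map)
    geno <- matrix(NA_character_, nrow = n_plants, ncol = nm,
                   dimnames = list(if (n_plants > 0) sprintf("P%04d", seq_len(n_plants)),
                                   marker_map$marker_id))
    truth_rows <- list()
    for (g in unique(marker_map$linkage_group)) {
      sel <- which(marker_map$linkage_group == g)
      sel <- sel[order(marker_map$cm[sel])]
      k <- length(sel)
      d <- diff(marker_map$cm[sel])
      if (any(d < 0)) stopf("negative genetic distances")
      r <- haldane_r(d)
      if (n_plants > 0) {
        ng <- 2L * n_plants
        al <- matrix(0L, nrow = ng, ncol = k)
        al[, 1L] <- stats::rbinom(ng, 1L, 0.5)
        rec <- matrix(0L, nrow = ng, ncol = max(k - 1L, 0L))
        for (j in seq_len(k - 1L)) {
          rec[, j] <- stats::rbinom(ng, 1L, r[j])
          al[, j + 1L] <- bitwXor(al[, j], rec[, j])
        }
        gsum <- al[seq_len(n_plants), , drop = FALSE] +
          al[n_plants + seq_len(n_plants), , drop = FALSE]
        geno[, sel] <- c("A", "H", "B")[gsum + 1L]
        for (j in seq_len(k - 1L)) {
          plant_rec <- rec[seq_len(n_plants), j] | rec[n_plants + seq_len(n_plants), j]
          truth_rows[[length(truth_rows) + 1L]] <- data.frame(
            marker_1 = marker_map$marker_id[sel[j]],
            marker_2 = marker_map$marker_id[sel[j + 1L]],
            r_true = r[j], rec_gametes = sum(rec[, j]), n_gametes = ng,
            rec_plants = sum(plant_rec), n_plants = n_plants,
            stringsAsFactors = FALSE)
        }
      }
    }
    if (n_plants > 0 && missing_rate > 0) {
      mask <- matrix(stats::runif(length(geno)) < missing_rate, nrow = n_plants)
      geno[mask] <- NA_character_
    }
    truth <- if (length(truth_rows)) do.call(rbind, truth_rows) else
      data.frame(marker_1 = character(), marker_2 = character(),
                 r_true = numeric(), rec_gametes = integer(),
                 n_gametes = integer(), rec_plants = integer(),
                 n_plants = integer(), stringsAsFactors = FALSE)
    list(geno = geno, truth = truth)
  })
}

#' Simulate a relative-coverage accession panel with planted dispensable genes
#'
#' Present genes are centered at 1 with Poisson-derived noise at `noise_depth`
#' (set `noise_depth = NULL` for a noise-free panel of exact ones); absent
#' genes get a uniform noise floor below 0.05. A fraction of accessions is
#' generated with overall average depth below 10x so the downstream inclusion
#' filter has something to exclude.
#'
#' @param genes character vector of gene ids.
#' @param n_accessions panel size.
#' @param n_dispensable number of planted dispensable genes.
#' @param absent_frac min/max fraction of accessions lacking a dispensable gene.
#' @param noise_depth read depth controlling the coverage noise, or NULL.
#' @param low_cov_frac fraction of accessions planted with low average depth.
#' @param low_cov_depth average depth assigned to those accessions.
#' @param seed RNG seed.
#' @return list with `matrix` (genes x accessions), `avg_depth` (named vector)
#'   and `truth` (dispensable gene table and absent-accession sets).
#' @export
simulate_accession_panel <- function(genes, n_accessions = 300,
                                     n_dispensable = 40,
                                     absent_frac = c(0.4, 0.9),
                                     noise_depth = 15, low_cov_frac = 0.05,
                                     low_cov_depth = 5, seed = 1L) {
  if (n_dispensable > length(genes)) stopf("more dispensable genes than genes")
  with_seed(seed, {
    acc <- sprintf("acc%04d", seq_len(n_accessions))
    ng <- length(genes)
    if (is.null(noise_depth)) {
      m <- matrix(1, nrow = ng, ncol = n_accessions, dimnames = list(genes, acc))
    } else {
      m <- matrix(stats::rpois(ng * n_accessions, noise_depth) / noise_depth,
                  nrow = ng, ncol = n_accessions, dimnames = list(genes, acc))
    }
    disp <- sample(genes, n_dispensable)
    absent <- stats::setNames(vector("list", n_dispensable), disp)
    for (g in disp) {
      frac <- stats::runif(1, absent_frac[1L], absent_frac[2L])
      who <- sample(acc, max(1L, round(frac * n_accessions)))
      absent[[g]] <- sort(who)
      m[g, who] <- if (is.null(noise_depth)) 0 else stats::runif(length(who), 0, 0.045)
    }
    n_low <- floor(low_cov_frac * n_accessions)
    low <- if (n_low > 0) sample(acc, n_low) else character(0)
    avg_depth <- stats::setNames(rep(noise_depth %||% 30, n_accessions), acc)
    avg_depth[low] <- low_cov_depth
    truth <- list(dispensable = data.frame(
      gene_id = disp, n_absent = lengths(absent), stringsAsFactors = FALSE),
      absent = absent, low_coverage = sort(low))
    list(matrix = m, avg_depth = avg_depth, truth = truth)
  })
}

hit_row <- function(q, s, bitscore, pident = 98, len = 900, qs = 1L, qe = NULL,
                    ss = 1L, se = NULL, evalue = 1e-50) {
  qe <- qe %||% (qs + len - 1L)
  se <- se %||% (ss + len - 1L)
  data.frame(query_id = q, subject_id = s, percent_identity = pident,
             align_len = as.integer(len), mismatches = 0L, gap_opens = 0L,
             query_start = as.integer(qs), query_end = as.integer(qe),
             subject_start = as.integer(ss), subject_end = as.integer(se),
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

#' Build hit tables consistent with a simulated genome pair
#'
#' Produces bidirectional gene-level best-hit tables (genotype Q annotation
#' versus genotype R annotation) consistent with the planted orthology:
#' the inverted block's partners appear in reversed order, genes amplified in
#' Q contribute extra lower-scoring Q-side copies hitting the same R gene, and
#' genes deleted in Q are absent from the Q annotation. Also returns a
#' TE-library hit table with per-family top scores, and gap-flank hits placing
#' synthetic reference gap flanks at known target locations.
#'
#' @param sim output of [simulate_genome_pair()].
#' @param seed RNG seed.
#' @param n_flank_pairs number of synthetic gap-flank pairs.
#' @return list with hits_qr, hits_rq, genes_q, te_top_scores, te_hits,
#'   flank_hits, flank_truth.
#' @export
make_hit_tables <- function(sim, seed = 1L, n_flank_pairs = 5L) {
  with_seed(seed, {
    genes <- sim$genes
    tr <- sim$truth
    n <- nrow(genes)
    # Q annotation: orthologs in q_order, minus deletions, plus duplicate copies
    q_units <- list()
    for (g in tr$q_order) {
      if (g %in% tr$del_in_q$gene_id) next
      qid <- sub("^g", "q", g)
      q_units[[length(q_units) + 1L]] <- c(qid = qid, ortholog = g, rank = "1")
      if (g %in% tr$dup_in_q$gene_id) {
        copies <- tr$dup_in_q$copies[match(g, tr$dup_in_q$gene_id)]
        for (cc in seq_len(copies - 1L)) {
          q_units[[length(q_units) + 1L]] <- c(qid = sprintf("%s_d%d", qid, cc + 1L),
                                               ortholog = g, rank = as.character(cc + 1L))
        }
      }
    }
    qm <- do.call(rbind, q_units)
    slot <- 2000L
    genes_q <- data.frame(gene_id = qm[, "qid"], seq_id = "chr1",
                          start = as.integer((seq_len(nrow(qm)) - 1L) * slot + 100L),
                          end = as.integer((seq_len(nrow(qm)) - 1L) * slot + 1100L),
                          strand = "+", ortholog = qm[, "ortholog"],
                          stringsAsFactors = FALSE)
    base_score <- stats::setNames(500 + stats::runif(n, 0, 20), genes$gene_id)
    rows_qr <- vector("list", nrow(genes_q))
    for (i in seq_len(nrow(genes_q))) {
      og <- genes_q$ortholog[i]
      rk <- as.integer(qm[i, "rank"])
      sc <- base_score[[og]] - (rk - 1L) * 15 - stats::runif(1, 0, 3) * (rk > 1L)
      rows_qr[[i]] <- hit_row(genes_q$gene_id[i], og, bitscore = round(sc, 1))
    }
    hits_qr <- do.call(rbind, rows_qr)
    primary_q <- stats::setNames(genes_q$gene_id[qm[, "rank"] == "1"],
                                 genes_q$ortholog[qm[, "rank"] == "1"])
    keep_r <- genes$gene_id[!genes$gene_id %in% tr$del_in_q$gene_id]
    rows_rq <- lapply(keep_r, function(g) {
      hit_row(g, primary_q[[g]], bitscore = round(base_score[[g]], 1))
    })
    hits_rq <- do.call(rbind, rows_rq)

    # TE library hits: one family per ~5 placements, top score per family
    te_hits <- empty_hit_table(); te_top <- NULL
    if (nrow(sim$tes) > 0L) {
      fam <- sprintf("TEF%02d", ((seq_len(nrow(sim$tes)) - 1L) %% 10L) + 1L)
      top <- stats::setNames(800 + stats::runif(10, 0, 200), sprintf("TEF%02d", 1:10))
      rows <- lapply(seq_len(nrow(sim$tes)), function(i) {
        L <- sim$tes$end[i] - sim$tes$start[i]
        hit_row(fam[i], sim$tes$seq_id[i],
                bitscore = round(top[[fam[i]]] * stats::runif(1, 0.92, 1.0), 1),
                len = L, ss = sim$tes$start[i] + 1L, se = sim$tes$end[i])
      })
      # sub-threshold decoys
      decoys <- lapply(seq_len(10L), function(i) {
        p <- sample.int(sim$config$genome_size - 1000L, 1L)
        f <- sample(names(top), 1L)
        hit_row(f, "chr1", bitscore = round(top[[f]] * 0.5, 1), len = 800L,
                ss = p, se = p + 799L)
      })
      te_hits <- do.call(rbind, c(rows, decoys))
      te_top <- data.frame(te_id = names(top), top_score = unname(top),
                           stringsAsFactors = FALSE)
    }

    # gap-flank hits: planted enclosed intervals on the assembly
    flank_rows <- list(); flank_truth <- list()
    gsize <- sim$config$genome_size
    for (i in seq_len(n_flank_pairs)) {
      span <- sample(2000:20000, 1L)
      a <- sample(seq(30000L, gsize - span - 30000L), 1L)  # enclosed [a, a+span)
      b <- a + span
      gid <- sprintf("gap%02d", i)
      flank_rows[[length(flank_rows) + 1L]] <-
        hit_row(paste0(gid, "_L"), "chr1", bitscore = 2000, len = 1000L,
                ss = a - 999L, se = a)
      flank_rows[[length(flank_rows) + 1L]] <-
        hit_row(paste0(gid, "_R"), "chr1", bitscore = 2000, len = 1000L,
                ss = b + 1L, se = b + 1000L)
      flank_truth[[length(flank_truth) + 1L]] <- data.frame(
        gap_id = gid, seq_id = "chr1", start = a, end = b,
        stringsAsFactors = FALSE)
    }
    list(hits_qr = hits_qr, hits_rq = hits_rq, genes_q = genes_q,
         te_top_scores = te_top, te_hits = te_hits,
         flank_hits = do.call(rbind, flank_rows),
         flank_truth = do.call(rbind, flank_truth))
  })
}

#' Simulate a homotetramer-enriched DNA sequence
#'
#' Starts from a uniform-composition random sequence and overwrites random
#' positions with 4-base runs until the overlapping homotetramer count reaches
#' `factor` times the count of the unmodified sequence.
#'
#' @param length sequence length in bp.
#' @param factor target enrichment relative to the random baseline.
#' @param seed RNG seed.
#' @return a character scalar DNA sequence.
#' @export
simulate_enriched_sequence <- function(length, factor = 3, seed = 1L) {
  if (length < 100L) stopf("sequence too short")
  if (factor < 1) stopf("factor must be >= 1")
  with_seed(seed, {
    chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
    target <- ceiling(factor * homotetramer_count(paste(chars, collapse = "")))
    for (iter in seq_len(50L)) {
      current <- homotetramer_count(paste(chars, collapse = ""))
      need <- target - current
      if (need <= 0) break
      pos <- sample.int(length - 3L, need, replace = TRUE)
      bases <- sample(c("A", "C", "G", "T"), need, replace = TRUE)
      for (j in seq_len(need)) chars[pos[j]:(pos[j] + 3L)] <- bases[j]
    }
    paste(chars, collapse = "")
  })
}

#' Simulate structural variants clustered around a centromere
#'
#' SV midpoints are drawn with density proportional to exp(-|x - cen| / tau),
#' emulating the pericentromeric clustering of large variants.
#'
#' @param seq_len chromosome length in bp.
#' @param centromere centromere midpoint position.
#' @param n_sv number of variants.
#' @param tau exponential decay scale in bp.
#' @param len_range min/max SV length in bp.
#' @param seed RNG seed.
#' @return data.frame with seq_id, start, end (0-based half-open).
#' @export
simulate_sv_set <- function(seq_len = 30e6, centromere = 15e6, n_sv = 300,
                            tau = 3e6, len_range = c(1000, 10000), seed = 1L) {
  with_seed(seed, {
    mids <- numeric(0)
    while (length(mids) < n_sv) {
      x <- stats::runif(4L * n_sv, 0, seq_len)
      acc <- stats::runif(length(x)) < exp(-abs(x - centromere) / tau)
      mids <- c(mids, x[acc])
    }
    mids <- mids[seq_len(n_sv)]
    len <- sample(seq(len_range[1L], len_range[2L]), n_sv, replace = TRUE)
    start <- pmax(0, pmin(round(mids - len / 2), seq_len - len))
    data.frame(seq_id = "chr1", start = as.integer(start),
               end = as.integer(start + len), stringsAsFactors = FALSE)
  })
}
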