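test_that("cosegregating markers estimate r = 0 and unlinked markers r ~ 0.5", {
  g1 <- geno_col("AABBHHABHA")
  expect_equal(estimate_rf(g1, g1)$r_hat, 0, tolerance = 1e-9)

  mm <- data.frame(marker_id = c("m1", "m2"), linkage_group = 1:2,
                   contig_id = c("c1", "c2"), phys_pos = 1, cm = 0)
  f2 <- simulate_f2_population(mm, n_plants = 3000, missing_rate = 0, seed = 61)
  est <- estimate_rf(f2$geno[, 1], f2$geno[, 2])
  se <- sqrt(0.25 / (2 * 3000))  # binomial se on 2n gametes at r = 0.5
  expect_lt(abs(est$r_hat - 0.5), 4 * se)
})

test_that("EM matches the grid-search maximum likelihood on toy tables", {
  g1 <- geno_col("AAHHBBAHBH")
  g2 <- geno_col("AHHHBBAABH")
  est <- estimate_rf(g1, g2)
  expect_lt(abs(est$r_hat - oracle_grid_rf(g1, g2)), 1e-3)
  expect_equal(est$n_informative, 10L)
})

test_that("EM matches grid search on random tables and stays in [0, 0.5]", {
  set.seed(62)
  for (rep in 1:25) {
    n <- sample(20:60, 1)
    g1 <- sample(c("A", "H", "B", NA), n, replace = TRUE,
                 prob = c(0.25, 0.45, 0.25, 0.05))
    g2 <- sample(c("A", "H", "B", NA), n, replace = TRUE,
                 prob = c(0.25, 0.45, 0.25, 0.05))
    est <- estimate_rf(g1, g2)
    expect_gte(est$r_hat, 0)
    expect_lte(est$r_hat, 0.5)
    if (!est$degenerate) {
      expect_lt(abs(est$r_hat - oracle_grid_rf_folded(g1, g2)), 1e-3)
    }
  }
})

test_that("the estimate is invariant under allele swap at either marker", {
  mm <- data.frame(marker_id = c("m1", "m2"), linkage_group = 1,
                   contig_id = "c1", phys_pos = 1:2, cm = c(0, 15))
  f2 <- simulate_f2_population(mm, n_plants = 400, missing_rate = 0, seed = 63)
  g1 <- f2$geno[, 1]; g2 <- f2$geno[, 2]
  swap <- function(g) c(A = "B", H = "H", B = "A")[g]
  r0 <- estimate_rf(g1, g2)$r_hat
  expect_equal(estimate_rf(swap(g1), g2)$r_hat, r0, tolerance = 1e-6)
  expect_equal(estimate_rf(g1, swap(g2))$r_hat, r0, tolerance = 1e-6)
  expect_equal(estimate_rf(swap(g1), swap(g2))$r_hat, r0, tolerance = 1e-6)
})

test_that("monomorphic markers are reported degenerate with r = 0", {
  est <- estimate_rf(rep("A", 10), geno_col("AHBAHBAHBA"))
  expect_true(est$degenerate)
  expect_equal(est$r_hat, 0)
  expect_equal(est$n_informative, 10L)
})

test_that("the rf matrix is symmetric, zero-diagonal, and per-pair consistent", {
  mm <- simulate_marker_map(n_groups = 1, contigs_per_group = 2,
                            markers_per_contig = 2, seed = 64)
  f2 <- simulate_f2_population(mm$marker_map, n_plants = 300,
                               missing_rate = 0.05, seed = 65)
  rfm <- rf_matrix(f2$geno)
  expect_equal(rfm, t(rfm))
  expect_true(all(diag(rfm) == 0))
  for (j in 2:4) {
    expect_equal(rfm[1, j], estimate_rf(f2$geno[, colnames(rfm)[1]],
                                        f2$geno[, colnames(rfm)[j]])$r_hat)
  }
})

test_that("single linkage joins contig chains strictly below r_max", {
  rfm <- matrix(0.5, 6, 6, dimnames = list(paste0("m", 1:6), paste0("m", 1:6)))
  diag(rfm) <- 0
  mc <- data.frame(marker_id = paste0("m", 1:6),
                   contig_id = rep(c("c1", "c2", "c3"), each = 2))
  # all distances 0.5: every contig is its own group
  cl <- cluster_linkage_groups(rfm, mc, r_max = 0.25)
  expect_equal(length(unique(cl$groups$linkage_group)), 3L)
  # chain c1-c2-c3 with r 0.05 links: one group through single linkage
  rfm2 <- rfm
  rfm2["m2", "m3"] <- rfm2["m3", "m2"] <- 0.05
  rfm2["m4", "m5"] <- rfm2["m5", "m4"] <- 0.05
  cl2 <- cluster_linkage_groups(rfm2, mc, r_max = 0.25)
  expect_equal(length(unique(cl2$groups$linkage_group)), 1L)
  # boundary is strict: distance exactly r_max does not join
  rfm3 <- rfm
  rfm3["m2", "m3"] <- rfm3["m3", "m2"] <- 0.25
  cl3 <- cluster_linkage_groups(rfm3, mc, r_max = 0.25)
  expect_equal(length(unique(cl3$groups$linkage_group)), 3L)
  # contigs without markers are reported unplaced
  cl4 <- cluster_linkage_groups(rfm, mc, all_contigs = c("c1", "c2", "c3", "c9"))
  expect_equal(cl4$unplaced, "c9")
})

test_that("three contigs order along the minimal adjacent-r path", {
  rfm <- matrix(0.5, 6, 6, dimnames = list(paste0("m", 1:6), paste0("m", 1:6)))
  diag(rfm) <- 0
  rfm["m1", "m2"] <- rfm["m2", "m1"] <- 0.01   # within c1
  rfm["m3", "m4"] <- rfm["m4", "m3"] <- 0.01   # within c2
  rfm["m5", "m6"] <- rfm["m6", "m5"] <- 0.01   # within c3
  set_pair <- function(m, a, b, v) { m[a, b] <- v; m[b, a] <- v; m }
  for (p in list(c("m2", "m3"), c("m1", "m3"), c("m1", "m4"), c("m2", "m4"))) {
    rfm <- set_pair(rfm, p[1], p[2], 0.05)
  }
  for (p in list(c("m4", "m5"), c("m3", "m5"), c("m3", "m6"), c("m4", "m6"))) {
    rfm <- set_pair(rfm, p[1], p[2], 0.05)
  }
  for (p in list(c("m1", "m5"), c("m1", "m6"), c("m2", "m5"), c("m2", "m6"))) {
    rfm <- set_pair(rfm, p[1], p[2], 0.15)
  }
  mm <- data.frame(marker_id = paste0("m", 1:6),
                   contig_id = rep(c("c1", "c2", "c3"), each = 2),
                   phys_pos = rep(c(100, 900), 3))
  pl <- order_and_orient(c("c1", "c2", "c3"), rfm, mm)
  expect_equal(pl$contig_id, c("c1", "c2", "c3"))  # c2 must sit in the middle
  expect_equal(pl$order_index, 0:2)

  single <- order_and_orient("c1", rfm, mm)
  expect_equal(nrow(single), 1L)
  expect_equal(single$order_index, 0L)
})

test_that("a simulated nine-contig map is recovered up to whole-group mirror", {
  mm <- simulate_marker_map(n_groups = 3, contigs_per_group = 3,
                            markers_per_contig = 3, seed = 66)
  f2 <- simulate_f2_population(mm$marker_map, n_plants = 1000,
                               missing_rate = 0.05, seed = 67)
  anc <- anchor_contigs(f2$geno, mm$marker_map, r_max = 0.25)

  # grouping: recovered groups equal the true chromosome partitions
  true_split <- unname(split(mm$truth$contig_id, mm$truth$linkage_group))
  got_split <- unname(split(anc$placements$contig_id, anc$placements$linkage_group))
  expect_setequal(lapply(true_split, sort), lapply(got_split, sort))

  # order and orientation: exact up to whole-group mirror
  for (g in unique(anc$placements$linkage_group)) {
    got <- anc$placements[anc$placements$linkage_group == g, ]
    got <- got[order(got$order_index), ]
    tg <- mm$truth[mm$truth$contig_id %in% got$contig_id, ]
    tg <- tg[order(tg$order_index), ]
    same <- identical(got$contig_id, tg$contig_id) &&
      identical(got$orientation, tg$orientation)
    flip <- c("+" = "-", "-" = "+", unknown = "unknown")
    mirrored <- identical(got$contig_id, rev(tg$contig_id)) &&
      identical(got$orientation, unname(flip[rev(tg$orientation)]))
    expect_true(same || mirrored)
  }
})

test_that("pseudochromosome construction concatenates, gaps and flips", {
  contigs <- Biostrings::DNAStringSet(c(c1 = strrep("ACGT", 250),
                                        c2 = strrep("GGCA", 250)))
  p1 <- data.frame(contig_id = "c1", linkage_group = 1L, order_index = 0L,
                   orientation = "+", n_markers = 2L, stringsAsFactors = FALSE)
  out1 <- build_pseudochromosomes(p1, contigs)
  expect_equal(as.character(out1$seqs[["LG1"]]), strrep("ACGT", 250))

  p1m <- p1; p1m$orientation <- "-"
  out1m <- build_pseudochromosomes(p1m, contigs)
  expect_equal(as.character(out1m$seqs[["LG1"]]),
               as.character(Biostrings::reverseComplement(
                 Biostrings::DNAString(strrep("ACGT", 250)))))

  p2 <- data.frame(contig_id = c("c1", "c2"), linkage_group = 1L,
                   order_index = 0:1, orientation = "+", n_markers = 2L,
                   stringsAsFactors = FALSE)
  out2 <- build_pseudochromosomes(p2, contigs, gap_length = 100)
  expect_equal(nchar(as.character(out2$seqs[["LG1"]])), 2100L)

  # polarity flip reverses order and inverts orientations
  pol <- build_pseudochromosomes(p2, contigs, gap_length = 100,
                                 reference_polarity = c("1" = "-"))
  expect_equal(pol$agp$component_id[pol$agp$component_type == "W"],
               c("c2", "c1"))
  expect_true(all(pol$agp$orientation[pol$agp$component_type == "W"] == "-"))

  expect_error(build_pseudochromosomes(
    data.frame(contig_id = "cX", linkage_group = 1L, order_index = 0L,
               orientation = "+", n_markers = 0L), contigs), "missing contig")
})

test_that("AGP written from placements reconstructs the FASTA byte-for-byte", {
  contigs <- with_seed(68, Biostrings::DNAStringSet(
    c(c1 = paste(sample(c("A", "C", "G", "T"), 500, TRUE), collapse = ""),
      c2 = paste(sample(c("A", "C", "G", "T"), 700, TRUE), collapse = ""),
      c3 = paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""))))
  pl <- data.frame(contig_id = c("c2", "c3", "c1"), linkage_group = 1L,
                   order_index = 0:2, orientation = c("-", "+", "unknown"),
                   n_markers = c(2L, 2L, 1L), stringsAsFactors = FALSE)
  built <- build_pseudochromosomes(pl, contigs, gap_length = 42)
  agp_path <- withr::local_tempfile()
  fa_path <- withr::local_tempfile()
  write_agp(built$agp, agp_path)
  write_fasta(built$seqs, fa_path)
  rebuilt <- assemble_from_agp(read_agp(agp_path), contigs)
  expect_identical(as.character(rebuilt), as.character(read_fasta(fa_path)))
})

test_that("the proportion test matches prop.test semantics", {
  eq <- compare_recombination_rates(5, 100, 5, 100)
  expect_equal(eq$chi2, 0)
  expect_equal(eq$p, 1)
  eq2 <- compare_recombination_rates(10, 50, 20, 100, correct = FALSE)
  expect_equal(eq2$chi2, 0)
  expect_equal(eq2$p, 1)
  res <- compare_recombination_rates(1, 60, 16, 108)
  oracle <- oracle_yates_chi2(1, 60, 16, 108)
  expect_equal(res$chi2, oracle$chi2, tolerance = 1e-12)
  expect_equal(res$p, oracle$p, tolerance = 1e-12)
  expect_error(compare_recombination_rates(1, 0, 1, 10), "positive")
})
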