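small_cfg <- function(...) {
  args <- utils::modifyList(list(genome_size = 1e5, n_genes = 40, n_tes = 6,
                                 n_te_genes = 2, n_dup_q = 3, n_dup_r = 3,
                                 n_del_q = 1, inversion_genes = 5), list(...))
  do.call(sim_config, args)
}

test_that("genome-pair simulation is deterministic and conserves truth counts", {
  s1 <- simulate_genome_pair(small_cfg(), seed = 42)
  s2 <- simulate_genome_pair(small_cfg(), seed = 42)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(s1$assembly, f1); write_fasta(s2$assembly, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(s1$truth, s2$truth)

  expect_equal(nrow(s1$truth$dup_in_q), 3L)
  expect_equal(nrow(s1$truth$dup_in_r), 3L)
  expect_equal(nrow(s1$truth$del_in_q), 1L)
  expect_length(s1$truth$inversion$genes, 5L)
  # truth references existing genes, and planted sets are disjoint
  planted <- c(s1$truth$dup_in_q$gene_id, s1$truth$dup_in_r$gene_id,
               s1$truth$del_in_q$gene_id, s1$truth$inversion$genes)
  expect_true(all(planted %in% s1$genes$gene_id))
  expect_equal(anyDuplicated(planted), 0L)
})

test_that("a variant-free config yields identical copy numbers in both genotypes", {
  s <- simulate_genome_pair(small_cfg(n_dup_q = 0, n_dup_r = 0, n_del_q = 0,
                                      inversion_genes = 0), seed = 1)
  expect_equal(nrow(s$truth$dup_in_q), 0L)
  cm_r <- truth_copy_map(s, "R"); cm_q <- truth_copy_map(s, "Q")
  expect_identical(cm_r, cm_q)
  expect_true(all(cm_r$k == 1L & cm_r$m == 1L))
})

test_that("capacity and count validation reject impossible configs", {
  expect_error(sim_config(genome_size = 1e4, n_genes = 100), "capacity")
  expect_error(sim_config(n_dup_q = -1), ">= 0")
  expect_error(sim_config(n_genes = 10, n_dup_q = 20,
                          genome_size = 1e5), "exceed gene count")
})

test_that("depth tracks follow the planted copy-number Poisson model", {
  genes <- toy_genes(list(c(1000, 11000)), seq_id = "chr1")
  assembly <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 20000)))

  # deleted gene: all-zero depth inside the gene
  tr0 <- simulate_depth_track(assembly, genes,
                              data.frame(gene_id = "g1", k = 0, m = 1),
                              mean_depth = 30, bias_spread = 0, seed = 5)
  expect_true(all(tr0$depth$chr1[1001:11000] == 0L))
  expect_true(mean(tr0$depth$chr1[1:1000]) > 20)

  # neutral gene at 30x: sample mean within 3 Poisson standard errors
  tr1 <- simulate_depth_track(assembly, genes,
                              data.frame(gene_id = "g1", k = 1, m = 1),
                              mean_depth = 30, bias_spread = 0, seed = 6)
  gm <- mean(tr1$depth$chr1[1001:11000])
  expect_lt(abs(gm - 30), 3 * sqrt(30 / 10000))

  # doubled gene: gene mean ~ 2x flank mean
  tr2 <- simulate_depth_track(assembly, genes,
                              data.frame(gene_id = "g1", k = 2, m = 1),
                              mean_depth = 30, bias_spread = 0, seed = 7)
  ratio <- mean(tr2$depth$chr1[1001:11000]) / mean(tr2$depth$chr1[11001:20000])
  expect_lt(abs(ratio - 2), 0.1)

  expect_error(simulate_depth_track(assembly, genes, mean_depth = -1), ">= 0")
})

test_that("F2 gametes recombine at the Haldane rate and matrix contract holds", {
  mm <- data.frame(marker_id = c("m1", "m2"), linkage_group = 1,
                   contig_id = "c1", phys_pos = c(1, 2), cm = c(0, 10))
  f2 <- simulate_f2_population(mm, n_plants = 2000, missing_rate = 0,
                               seed = 11)
  r_true <- (1 - exp(-0.2)) / 2
  obs <- f2$truth$rec_gametes / f2$truth$n_gametes
  se <- sqrt(r_true * (1 - r_true) / f2$truth$n_gametes)
  expect_lt(abs(obs - r_true), 3 * se)
  expect_true(all(f2$geno %in% c("A", "H", "B")))

  # coincident markers give identical genotype columns before masking
  mm0 <- data.frame(marker_id = c("m1", "m2"), linkage_group = 1,
                    contig_id = "c1", phys_pos = c(1, 2), cm = c(5, 5))
  f20 <- simulate_f2_population(mm0, n_plants = 200, missing_rate = 0, seed = 2)
  expect_identical(f20$geno[, 1], f20$geno[, 2])

  empty <- simulate_f2_population(mm, n_plants = 0, seed = 1)
  expect_equal(nrow(empty$geno), 0L)

  masked <- simulate_f2_population(mm, n_plants = 1000, missing_rate = 0.1,
                                   seed = 3)
  expect_gt(mean(is.na(masked$geno)), 0.06)
  expect_lt(mean(is.na(masked$geno)), 0.14)

  mm_bad <- data.frame(marker_id = c("m1", "m2"), linkage_group = 1,
                       contig_id = "c1", phys_pos = c(1, 2), cm = c(10, 5))
  # distances are computed on cm-sorted markers, so reversal is not negative;
  # a truly negative spacing cannot be expressed, and n_plants < 0 errors
  expect_error(simulate_f2_population(mm, n_plants = -1), ">= 0")
})

test_that("accession panels plant dispensable genes and low-coverage accessions", {
  genes <- sprintf("g%03d", 1:50)
  p <- simulate_accession_panel(genes, n_accessions = 60, n_dispensable = 5,
                                noise_depth = 15, low_cov_frac = 0.1,
                                seed = 21)
  expect_equal(dim(p$matrix), c(50L, 60L))
  for (g in p$truth$dispensable$gene_id) {
    expect_true(all(p$matrix[g, p$truth$absent[[g]]] < 0.05))
  }
  expect_length(p$truth$low_coverage, 6L)
  expect_true(all(p$avg_depth[p$truth$low_coverage] < 10))

  clean <- simulate_accession_panel(genes, n_accessions = 10,
                                    n_dispensable = 0, noise_depth = NULL,
                                    low_cov_frac = 0, seed = 1)
  expect_true(all(clean$matrix == 1))
})

test_that("hit tables are deterministic and consistent with planted orthology", {
  sim <- simulate_genome_pair(small_cfg(), seed = 9)
  t1 <- make_hit_tables(sim, seed = 4)
  t2 <- make_hit_tables(sim, seed = 4)
  expect_identical(t1, t2)

  # a gene amplified in Q yields several Q->R hits to one R gene,
  # with distinct scores
  g <- sim$truth$dup_in_q$gene_id[1]
  hits_g <- t1$hits_qr[t1$hits_qr$subject_id == g, ]
  expect_equal(nrow(hits_g), sim$truth$dup_in_q$copies[1])
  expect_equal(anyDuplicated(hits_g$bitscore), 0L)

  # deleted genes are absent from the Q annotation
  expect_false(any(t1$genes_q$ortholog %in% sim$truth$del_in_q$gene_id))

  # pure 1:1 config: the downstream RBH stage recovers every pair
  s0 <- simulate_genome_pair(small_cfg(n_dup_q = 0, n_dup_r = 0, n_del_q = 0,
                                       inversion_genes = 0), seed = 2)
  t0 <- make_hit_tables(s0, seed = 2)
  pairs <- reciprocal_best_hits(best_hits(t0$hits_rq), best_hits(t0$hits_qr),
                                s0$genes, t0$genes_q)
  expect_equal(nrow(pairs), nrow(s0$genes))
})

test_that("enriched sequences reach the requested homotetramer density", {
  s <- simulate_enriched_sequence(20000, factor = 3, seed = 13)
  base <- with_seed(13, paste(sample(c("A", "C", "G", "T"), 20000,
                                     replace = TRUE), collapse = ""))
  expect_gte(homotetramer_count(s), 2.5 * homotetramer_count(base))
  expect_identical(s, simulate_enriched_sequence(20000, factor = 3, seed = 13))
})

test_that("simulated SVs cluster around the centromere", {
  svs <- simulate_sv_set(seq_len = 10e6, centromere = 5e6, n_sv = 400,
                         tau = 1e6, seed = 3)
  mids <- (svs$start + svs$end) / 2
  near <- mean(abs(mids - 5e6) < 1e6)
  far <- mean(abs(mids - 5e6) > 3e6)
  expect_gt(near, far)
})
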