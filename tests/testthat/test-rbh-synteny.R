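linear_genes <- function(ids, seq_id = "chr1") {
  g <- toy_genes(lapply(seq_along(ids), function(i) {
    c((i - 1) * 1000, i * 1000 - 500)
  }), seq_id = seq_id)
  g$gene_id <- ids
  g
}

# bidirectional hit tables realizing a given A-order -> B-order permutation
perm_hits <- function(ids_a, ids_b, perm) {
  ab <- do.call(toy_hits, lapply(seq_along(ids_a), function(i) {
    list(q = ids_a[i], s = ids_b[perm[i]], b = 500)
  }))
  ba <- do.call(toy_hits, lapply(seq_along(ids_a), function(i) {
    list(q = ids_b[perm[i]], s = ids_a[i], b = 500)
  }))
  list(ab = ab, ba = ba)
}

test_that("best hit selection maximizes bitscore with deterministic ties", {
  h <- toy_hits(list(q = "q1", s = "s1", b = 100),
                list(q = "q1", s = "s2", b = 90),
                list(q = "q2", s = "s3", b = 50, e = 1e-20),
                list(q = "q2", s = "s4", b = 50, e = 1e-30),
                list(q = "q3", s = "sB", b = 70),
                list(q = "q3", s = "sA", b = 70))
  bh <- best_hits(h)
  expect_equal(bh$subject_id[bh$query_id == "q1"], "s1")
  expect_equal(bh$subject_id[bh$query_id == "q2"], "s4")  # lower evalue wins
  expect_equal(bh$subject_id[bh$query_id == "q3"], "sA")  # lexicographic
  expect_true(bh$tied[bh$query_id == "q3"])
  expect_false(bh$tied[bh$query_id == "q1"])
})

test_that("best hits equal the exhaustive per-query scan on random tables", {
  set.seed(44)
  for (rep in 1:5) {
    n <- 200
    h <- do.call(toy_hits, lapply(seq_len(3 * n), function(i) {
      list(q = sprintf("q%03d", sample.int(n, 1)),
           s = sprintf("s%03d", sample.int(n, 1)),
           b = round(runif(1, 50, 500), 1), e = 10^-sample.int(100, 1))
    }))
    bh <- best_hits(h)
    oracle <- oracle_best_hits(h)
    expect_equal(stats::setNames(bh$subject_id, bh$query_id)[names(oracle)],
                 unlist(oracle))
  }
})

test_that("reciprocal pairing equals the brute-force all-pairs oracle", {
  set.seed(45)
  ids_a <- sprintf("a%03d", 1:60)
  ids_b <- sprintf("b%03d", 1:60)
  ga <- linear_genes(ids_a); gb <- linear_genes(ids_b)
  for (rep in 1:10) {
    ab <- do.call(toy_hits, lapply(ids_a, function(q) {
      list(q = q, s = sample(ids_b, 1), b = round(runif(1, 100, 500), 1))
    }))
    ba <- do.call(toy_hits, lapply(ids_b, function(q) {
      list(q = q, s = sample(ids_a, 1), b = round(runif(1, 100, 500), 1))
    }))
    pairs <- reciprocal_best_hits(best_hits(ab), best_hits(ba), ga, gb)
    map_ab <- as.list(stats::setNames(best_hits(ab)$subject_id,
                                      best_hits(ab)$query_id))
    map_ba <- as.list(stats::setNames(best_hits(ba)$subject_id,
                                      best_hits(ba)$query_id))
    oracle <- oracle_rbh_pairs(map_ab, map_ba)
    expect_equal(sort(pairs$gene_a), sort(oracle$a))
    expect_equal(stats::setNames(pairs$gene_b, pairs$gene_a)[oracle$a],
                 stats::setNames(oracle$b, oracle$a))
    # symmetry: swapping the genomes yields the same pair set
    rev_pairs <- reciprocal_best_hits(best_hits(ba), best_hits(ab), gb, ga)
    expect_setequal(paste(pairs$gene_a, pairs$gene_b),
                    paste(rev_pairs$gene_b, rev_pairs$gene_a))
    expect_lte(nrow(pairs), min(length(ids_a), length(ids_b)))
  }
})

test_that("asymmetric best hits produce no pair", {
  ga <- linear_genes(c("a1", "a2")); gb <- linear_genes(c("b1", "b2"))
  ab <- toy_hits(list(q = "a1", s = "b1", b = 100),
                 list(q = "a2", s = "b2", b = 100))
  ba <- toy_hits(list(q = "b1", s = "a2", b = 100),  # b1 points back to a2
                 list(q = "b2", s = "a2", b = 100))
  pairs <- reciprocal_best_hits(best_hits(ab), best_hits(ba), ga, gb)
  expect_equal(pairs$gene_a, "a2")
})

test_that("collinear genomes yield zero outliers and zero blocks", {
  ids_a <- sprintf("a%03d", 1:80)
  ids_b <- sprintf("b%03d", 1:80)
  h <- perm_hits(ids_a, ids_b, seq_along(ids_a))
  pairs <- reciprocal_best_hits(best_hits(h$ab), best_hits(h$ba),
                                linear_genes(ids_a), linear_genes(ids_b))
  out <- detect_synteny_outliers(pairs)
  expect_equal(sum(out$outlier), 0L)
  expect_equal(nrow(call_sv_blocks(out)), 0L)
})

test_that("a single displaced gene is flagged as the only outlier", {
  n <- 100
  ids_a <- sprintf("a%03d", 1:n)
  ids_b <- sprintf("b%03d", 1:n)
  perm <- seq_len(n)
  perm[10] <- 80; perm[80] <- 10  # swap two genes 70 ranks apart
  h <- perm_hits(ids_a, ids_b, perm)
  pairs <- reciprocal_best_hits(best_hits(h$ab), best_hits(h$ba),
                                linear_genes(ids_a), linear_genes(ids_b))
  out <- detect_synteny_outliers(pairs)
  expect_setequal(out$gene_a[out$outlier], c("a010", "a080"))
  expect_equal(nrow(call_sv_blocks(out)), 0L)  # isolated outliers, no block
})

test_that("outlier detection is invariant under gene id relabeling", {
  n <- 60
  perm <- seq_len(n); perm[20:25] <- rev(20:25)
  ids_a <- sprintf("a%03d", 1:n); ids_b <- sprintf("b%03d", 1:n)
  h <- perm_hits(ids_a, ids_b, perm)
  p1 <- detect_synteny_outliers(
    reciprocal_best_hits(best_hits(h$ab), best_hits(h$ba),
                         linear_genes(ids_a), linear_genes(ids_b)))
  ids_a2 <- sprintf("zz%03d", sample(1000:1999, n))
  h2 <- perm_hits(ids_a2, ids_b, perm)
  p2 <- detect_synteny_outliers(
    reciprocal_best_hits(best_hits(h2$ab), best_hits(h2$ba),
                         linear_genes(ids_a2), linear_genes(ids_b)))
  expect_equal(p1$outlier, p2$outlier)
})

test_that("a planted inversion becomes one inversion block within one gene", {
  sim <- simulate_genome_pair(sim_config(genome_size = 4e5, n_genes = 200,
                                         n_dup_q = 0, n_dup_r = 0, n_del_q = 0,
                                         inversion_genes = 10, n_tes = 0,
                                         n_te_genes = 0), seed = 55)
  tabs <- make_hit_tables(sim, seed = 56)
  pairs <- reciprocal_best_hits(best_hits(tabs$hits_rq), best_hits(tabs$hits_qr),
                                sim$genes, tabs$genes_q)
  out <- detect_synteny_outliers(pairs)
  flagged <- out$gene_a[out$outlier]
  expect_gte(length(intersect(flagged, sim$truth$inversion$genes)), 9L)
  expect_length(setdiff(flagged, sim$truth$inversion$genes), 0L)
  blocks <- call_sv_blocks(out)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$type, "inversion")
  i0 <- sim$truth$inversion$start_index
  expect_lte(abs(blocks$rank_a_start - i0), 1L)
  expect_lte(abs(blocks$rank_a_end - (i0 + 9L)), 1L)
})

test_that("monotone outlier runs are typed by rank direction", {
  pairs <- data.frame(
    gene_a = sprintf("a%d", 1:10), gene_b = sprintf("b%d", 1:10),
    chrom_a = "chr1", chrom_b = "chr1",
    rank_a = 1:10, rank_b = c(1, 2, 50, 49, 48, 47, 46, 8, 9, 10),
    tied = FALSE, stringsAsFactors = FALSE)
  pairs$outlier <- c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE,
                     FALSE, FALSE, FALSE)
  pairs$outlier_reason <- ""
  blocks <- call_sv_blocks(pairs)
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$type, "inversion")
  expect_equal(blocks$n_genes, 5L)

  pairs$rank_b <- c(1, 2, 46, 47, 48, 49, 50, 8, 9, 10)
  blocks2 <- call_sv_blocks(pairs)
  expect_equal(blocks2$type, "translocation")
})
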