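# Independent oracles: brute-force / closed-form / enumeration
# implementations kept deliberately separate from the package's code paths.

# Relative coverage by direct median arithmetic on a flat depth vector.
oracle_relative_coverage <- function(depths, gene_spans) {
  gene_medians <- vapply(gene_spans, function(sp) {
    median(depths[(sp[1] + 1):sp[2]])
  }, numeric(1))
  step2 <- gene_medians / median(depths)
  step2 / median(step2[step2 > 0])
}

# Best subject per query by exhaustive scan.
oracle_best_hits <- function(hits) {
  out <- list()
  for (q in sort(unique(hits$query_id))) {
    h <- hits[hits$query_id == q, , drop = FALSE]
    h <- h[order(-h$bitscore, h$evalue, h$subject_id), , drop = FALSE]
    out[[q]] <- h$subject_id[1]
  }
  out
}

# Reciprocal pairs by O(n^2) scan over two query->subject maps.
oracle_rbh_pairs <- function(map_ab, map_ba) {
  pairs <- list()
  for (a in names(map_ab)) {
    b <- map_ab[[a]]
    if (!is.null(map_ba[[b]]) && map_ba[[b]] == a) {
      pairs[[length(pairs) + 1]] <- c(a = a, b = b)
    }
  }
  if (length(pairs) == 0) return(data.frame(a = character(), b = character()))
  df <- as.data.frame(do.call(rbind, pairs), stringsAsFactors = FALSE)
  df[order(df$a), , drop = FALSE]
}

# 9-class F2 log-likelihood from the joint genotype counts, written out
# independently of the package (explicit class probabilities, 0*log0 = 0).
oracle_f2_loglik <- function(g1, g2, r) {
  ok <- !is.na(g1) & !is.na(g2)
  key <- paste0(g1[ok], g2[ok])
  cnt <- function(...) sum(key %in% c(...))
  n_par <- cnt("AA", "BB")           # 0 recombinant gametes
  n_one <- cnt("AH", "HA", "HB", "BH")  # 1 recombinant gamete
  n_two <- cnt("AB", "BA")           # 2 recombinant gametes
  n_hh <- cnt("HH")                  # phase-ambiguous double het
  term <- function(n, p) if (n == 0) 0 else n * log(p)
  term(n_par, (1 - r)^2 / 4) + term(n_one, r * (1 - r) / 2) +
    term(n_two, r^2 / 4) + term(n_hh, ((1 - r)^2 + r^2) / 2)
}

# Grid-search maximum-likelihood recombination fraction over [0, 0.5].
oracle_grid_rf <- function(g1, g2, grid = seq(0, 0.5, by = 0.001)) {
  ll <- vapply(grid, function(r) oracle_f2_loglik(g1, g2, r), numeric(1))
  grid[which.max(ll)]
}

# Phase-folded grid search over the full [0, 1] range: the global maximum is
# located on either phase side and reported as min(r, 1-r). This is the
# oracle matching an estimator that treats allele labeling as arbitrary.
oracle_grid_rf_folded <- function(g1, g2, grid = seq(0, 1, by = 0.001)) {
  ll <- vapply(grid, function(r) oracle_f2_loglik(g1, g2, r), numeric(1))
  r <- grid[which.max(ll)]
  min(r, 1 - r)
}

# Closed-form 2x2 chi-square with Yates continuity correction.
oracle_yates_chi2 <- function(x1, n1, x2, n2, correct = TRUE) {
  a <- x1; b <- n1 - x1; c <- x2; d <- n2 - x2
  N <- a + b + c + d
  num <- abs(a * d - b * c) - if (correct) N / 2 else 0
  num <- max(num, 0)
  chi2 <- N * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(chi2 = chi2, p = pchisq(chi2, df = 1, lower.tail = FALSE))
}

# Spearman rho via explicit midranks and the Pearson formula on ranks.
oracle_spearman <- function(x, y) {
  midrank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    i <- 1
    sv <- v[o]
    while (i <= length(v)) {
      j <- i
      while (j < length(v) && sv[j + 1] == sv[i]) j <- j + 1
      r[o[i:j]] <- mean(i:j)
      i <- j + 1
    }
    r
  }
  rx <- midrank(x); ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact two-sided Mann-Whitney p by enumeration of all group labelings.
oracle_mwu_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combos <- utils::combn(n, na)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
}

# Homotetramer count by a per-position scan.
oracle_ht_count <- function(s) {
  ch <- strsplit(toupper(s), "")[[1]]
  count <- 0
  for (i in seq_len(max(length(ch) - 3, 0))) {
    w <- ch[i:(i + 3)]
    if (w[1] %in% c("A", "C", "G", "T") && all(w == w[1])) count <- count + 1
  }
  count
}

# Covered fraction of a gene interval by a per-base bitmap.
oracle_cover_fraction <- function(gene_start, gene_end, starts, ends) {
  bit <- logical(gene_end - gene_start)
  for (k in seq_along(starts)) {
    lo <- max(starts[k], gene_start); hi <- min(ends[k], gene_end)
    if (lo < hi) bit[(lo - gene_start + 1):(hi - gene_start)] <- TRUE
  }
  mean(bit)
}
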