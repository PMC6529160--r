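# End-to-end pipeline driver: runs the analysis stages in dependency order on
# a structured config, with a single root seed and provenance-stamped output
# files (version, config hash, seed in every header).

#' Default pipeline configuration
#'
#' Thresholds default to the calling rules used throughout the package
#' (duplication cutoffs 0.5/1.5, pan-genome absence cutoff 0.1 in more than
#' `min_accessions` accessions, accession inclusion at 10x, TE score fraction
#' 0.9 and overlap fraction 0.8, SV blocks of at least 3 genes, outlier
#' window 5 and tolerance 20, linkage-group joining at r 0.25, AGP gap 100
#' bp, SV minimum length 1 kbp). The demo simulation scale is kept small so a
#' full run finishes in seconds.
#'
#' @param seed root seed; all stage seeds derive from it.
#' @param stages stages to run, in dependency order.
#' @return config list.
#' @export
default_config <- function(seed = 1L,
                           stages = c("simulate", "te", "cnv", "pangenome",
                                      "rbh", "anchor", "stats")) {
  list(
    seed = as.integer(seed),
    stages = stages,
    inputs = list(),
    genome = list(genome_size = 4e5, n_genes = 200, n_tes = 30, n_te_genes = 10,
                  n_dup_q = 8, n_dup_r = 8, n_del_q = 3, dup_copies = 3,
                  inversion_genes = 10),
    depth = list(mean_depth = 30, bias_spread = 0.05),
    panel = list(n_accessions = 150, n_dispensable = 15, noise_depth = 15,
                 low_cov_frac = 0.05),
    f2 = list(n_groups = 2, contigs_per_group = 2, markers_per_contig = 3,
              n_plants = 200, missing_rate = 0.05),
    thresholds = list(low = 0.5, high = 1.5, pan_low = 0.1,
                      min_accessions = 100, min_fraction = NULL,
                      min_avg_depth = 10, te_score_frac = 0.9,
                      te_overlap_frac = 0.8, min_run = 3, window = 5,
                      tolerance = 20, r_max = 0.25, gap_length = 100,
                      sv_min_len = 1000, min_contig_len = 0))
}

pipeline_header <- function(config) {
  ver <- tryCatch(as.character(utils::packageVersion("pananchor")),
                  error = function(e) "dev")
  c(sprintf("# pananchor %s", ver),
    sprintf("# config_hash=%s seed=%d", config_hash(config), config$seed))
}

write_stamped_tsv <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the pipeline end-to-end
#'
#' Executes the enabled stages in dependency order (TE annotation before the
#' coverage and pan-genome stages; RBH pairing before block calling). With
#' the `simulate` stage enabled every input is generated; without it the
#' coverage stage reads external files named in `config$inputs` (`fasta`,
#' `genes`, `depth_r`, `depth_q`) and the other analysis stages are
#' unavailable. Missing dependencies are reported before any work is done.
#' Every output file carries a header with package version, config hash and
#' seed; a fixed seed gives byte-identical outputs.
#'
#' @param config from [default_config()], or a path to a YAML file with the
#'   same structure.
#' @param out_dir output directory (created).
#' @return invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config = default_config(), out_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- utils::modifyList(default_config(), yaml::read_yaml(config))
  }
  stages <- config$stages
  th <- config$thresholds
  simulate_on <- "simulate" %in% stages
  if (!simulate_on) {
    if ("cnv" %in% stages) {
      for (need in c("fasta", "genes", "depth_r", "depth_q")) {
        if (is.null(config$inputs[[need]])) {
          stopf("cnv stage enabled without the '%s' input", need)
        }
        if (!file.exists(config$inputs[[need]])) {
          stopf("cnv input '%s' not found: %s", need, config$inputs[[need]])
        }
      }
    }
    unavailable <- intersect(stages, c("te", "pangenome", "rbh", "anchor"))
    if (length(unavailable)) {
      stopf("stage '%s' requires the simulate stage", unavailable[1L])
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  header <- pipeline_header(config)
  seed <- config$seed
  res <- list()

  sim <- NULL; tabs <- NULL
  if (simulate_on) {
    sim <- simulate_genome_pair(do.call(sim_config, config$genome),
                                seed = derive_seed(seed, 1L))
    tabs <- make_hit_tables(sim, seed = derive_seed(seed, 2L))
    write_fasta(sim$assembly, file.path(out_dir, "assembly.fasta"))
    write_gene_models(sim$genes, file.path(out_dir, "genes.gff3"))
    res$sim <- sim
  }

  te_flags <- NULL
  if ("te" %in% stages) {
    placements <- select_te_placements(tabs$te_hits, tabs$te_top_scores,
                                       min_frac = th$te_score_frac)
    te_flags <- flag_te_genes(sim$genes, placements,
                              min_frac = th$te_overlap_frac)
    write_stamped_tsv(placements, file.path(out_dir, "te_placements.tsv"), header)
    write_stamped_tsv(te_flags, file.path(out_dir, "te_flags.tsv"), header)
    res$te <- list(placements = placements, flags = te_flags)
  }

  if ("cnv" %in% stages) {
    if (simulate_on) {
      genes <- sim$genes
      track_r <- simulate_depth_track(sim$assembly, genes,
                                      truth_copy_map(sim, "R"),
                                      mean_depth = config$depth$mean_depth,
                                      bias_spread = config$depth$bias_spread,
                                      seed = derive_seed(seed, 3L),
                                      accession_id = "R")
      track_q <- simulate_depth_track(sim$assembly, genes,
                                      truth_copy_map(sim, "Q"),
                                      mean_depth = config$depth$mean_depth,
                                      bias_spread = config$depth$bias_spread,
                                      seed = derive_seed(seed, 4L),
                                      accession_id = "Q")
    } else {
      fa <- read_fasta(config$inputs$fasta)
      lens <- stats::setNames(Biostrings::width(fa), names(fa))
      genes <- read_gene_models(config$inputs$genes)
      track_r <- read_depth_track(config$inputs$depth_r, lens, "R")
      track_q <- read_depth_track(config$inputs$depth_q, lens, "Q")
    }
    vals_r <- gene_relative_coverage(track_r, genes)
    vals_q <- gene_relative_coverage(track_q, genes)
    calls <- classify_duplications(vals_r, vals_q, low = th$low, high = th$high)
    filtered <- filter_te_calls(calls, te_flags)
    write_stamped_tsv(filtered, file.path(out_dir, "duplication_calls.tsv"),
                      header)
    res$cnv <- list(calls = calls, filtered = filtered)
  }

  if ("pangenome" %in% stages) {
    panel <- simulate_accession_panel(sim$genes$gene_id,
                                      n_accessions = config$panel$n_accessions,
                                      n_dispensable = config$panel$n_dispensable,
                                      noise_depth = config$panel$noise_depth,
                                      low_cov_frac = config$panel$low_cov_frac,
                                      seed = derive_seed(seed, 5L))
    kept <- filter_accessions(panel, min_avg_depth = th$min_avg_depth)
    classes <- classify_genes(kept$matrix, te_flags, low = th$pan_low,
                              min_accessions = th$min_accessions,
                              min_fraction = th$min_fraction)
    write_stamped_tsv(classes, file.path(out_dir, "gene_classes.tsv"), header)
    res$pangenome <- list(panel = panel, classes = classes)
  }

  if ("rbh" %in% stages) {
    pairs <- reciprocal_best_hits(best_hits(tabs$hits_rq),
                                  best_hits(tabs$hits_qr),
                                  sim$genes, tabs$genes_q)
    pairs <- detect_synteny_outliers(pairs, window = th$window,
                                     tolerance = th$tolerance)
    blocks <- call_sv_blocks(pairs, min_run = th$min_run)
    write_stamped_tsv(pairs, file.path(out_dir, "rbh_pairs.tsv"), header)
    write_stamped_tsv(blocks, file.path(out_dir, "sv_blocks.tsv"), header)
    res$rbh <- list(pairs = pairs, blocks = blocks)
  }

  if ("anchor" %in% stages) {
    mm <- simulate_marker_map(n_groups = config$f2$n_groups,
                              contigs_per_group = config$f2$contigs_per_group,
                              markers_per_contig = config$f2$markers_per_contig,
                              contig_len = 2e4,
                              seed = derive_seed(seed, 6L))
    f2 <- simulate_f2_population(mm$marker_map,
                                 n_plants = config$f2$n_plants,
                                 missing_rate = config$f2$missing_rate,
                                 seed = derive_seed(seed, 7L))
    anc <- anchor_contigs(f2$geno, mm$marker_map, r_max = th$r_max)
    contigs <- with_seed(derive_seed(seed, 8L), {
      ids <- sort(unique(mm$marker_map$contig_id))
      Biostrings::DNAStringSet(stats::setNames(
        vapply(ids, function(i) random_dna(2e4), character(1)), ids))
    })
    ps <- build_pseudochromosomes(anc$placements, contigs,
                                  gap_length = th$gap_length)
    write_stamped_tsv(anc$placements, file.path(out_dir, "placements.tsv"),
                      header)
    write_fasta(ps$seqs, file.path(out_dir, "pseudochromosomes.fasta"))
    write_agp(ps$agp, file.path(out_dir, "pseudochromosomes.agp"))
    res$anchor <- list(map = mm, placements = anc$placements, agp = ps$agp)
  }

  if ("stats" %in% stages) {
    svs <- simulate_sv_set(seq_len = 10e6, centromere = 5e6, n_sv = 150,
                           tau = 1.5e6, seed = derive_seed(seed, 9L))
    wc <- window_sv_counts(svs, c(chr1 = 10e6), c(chr1 = 5e6),
                           window = 1e6, min_len = th$sv_min_len)
    sp <- spearman_cor(wc$cen_distance, wc$count)
    enriched <- vapply(1:8, function(i) {
      simulate_enriched_sequence(10000, factor = 3,
                                 seed = derive_seed(seed, 100L + i))
    }, character(1))
    controls <- with_seed(derive_seed(seed, 10L),
                          vapply(1:8, function(i) random_dna(10000), character(1)))
    mwu <- mann_whitney_u(vapply(enriched, homotetramer_frequency, numeric(1)),
                          vapply(controls, homotetramer_frequency, numeric(1)))
    summary <- data.frame(
      statistic = c("sv_centromere_rho", "sv_centromere_p",
                    "homotetramer_U", "homotetramer_p"),
      value = c(sp$rho, sp$p, mwu$U, mwu$p), stringsAsFactors = FALSE)
    write_stamped_tsv(wc, file.path(out_dir, "sv_windows.tsv"), header)
    write_stamped_tsv(summary, file.path(out_dir, "distribution_stats.tsv"),
                      header)
    res$stats <- list(windows = wc, spearman = sp, mwu = mwu)
  }

  invisible(res)
}
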