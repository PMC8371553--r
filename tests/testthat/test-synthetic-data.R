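test_that("generate_genome is deterministic and rejects impossible sizing", {
  cfg <- tiny_config(seed = 3L)
  w1 <- generate_genome(cfg)
  w2 <- generate_genome(cfg)
  expect_identical(w1$genome, w2$genome)
  expect_identical(w1$genes, w1$genes)
  expect_false(identical(w1$genome, generate_genome(tiny_config(seed = 4L))$genome))

  expect_error(sim_config(genome_length = 5000L, n_chromosomes = 1L,
                          n_genes = 10L, gene_length = 1000L),
               "sizing")
  expect_error(sim_config(gc_content = 1.2), "gc_content")
  expect_error(sim_config(group_sizes = c(YC = 4L)), "group_sizes")
})

cg_density <- function(seq) {
  n_cg <- length(gregexpr("CG", seq, fixed = TRUE)[[1]])
  if (regexpr("CG", seq, fixed = TRUE) == -1L) n_cg <- 0L
  n_cg / (nchar(seq) - 1L)
}

test_that("island CpG boosting raises island CG density (and boost=1 does not)", {
  cfg <- sim_config(genome_length = 10000L, n_chromosomes = 1L,
                    n_genes = 2L, gene_length = 1000L,
                    n_islands = 2L, island_length = 1000L,
                    island_cpg_boost = 5, seed = 5L)
  w <- generate_genome(cfg)
  seqs <- w$genome[[1]]
  island_seq <- paste(substring(seqs, w$islands$start + 1L, w$islands$end),
                      collapse = "")
  mask <- rep(TRUE, nchar(seqs))
  for (k in seq_len(nrow(w$islands)))
    mask[(w$islands$start[k] + 1L):w$islands$end[k]] <- FALSE
  bg_seq <- paste(strsplit(seqs, "")[[1]][mask], collapse = "")
  expect_gte(cg_density(island_seq) / cg_density(bg_seq), 2)

  cfg1 <- sim_config(genome_length = 20000L, n_chromosomes = 1L,
                     n_genes = 2L, gene_length = 1000L,
                     n_islands = 2L, island_length = 2000L,
                     island_cpg_boost = 1, seed = 6L)
  w1 <- generate_genome(cfg1)
  s1 <- w1$genome[[1]]
  island_seq1 <- paste(substring(s1, w1$islands$start + 1L, w1$islands$end),
                       collapse = "")
  mask1 <- rep(TRUE, nchar(s1))
  for (k in seq_len(nrow(w1$islands)))
    mask1[(w1$islands$start[k] + 1L):w1$islands$end[k]] <- FALSE
  bg1 <- paste(strsplit(s1, "")[[1]][mask1], collapse = "")
  # two-proportion z: difference within sampling error of the i.i.d. model
  p_isl <- cg_density(island_seq1); p_bg <- cg_density(bg1)
  se <- sqrt(p_bg * (1 - p_bg) * (1 / nchar(island_seq1) + 1 / nchar(bg1)))
  expect_lt(abs(p_isl - p_bg), 4 * se)
})

test_that("cpg_oe depletes background CG density proportionally", {
  mk <- function(oe) sim_config(genome_length = 30000L, n_chromosomes = 1L,
                                n_genes = 2L, gene_length = 1000L,
                                n_islands = 1L, island_length = 200L,
                                cpg_oe = oe, seed = 9L)
  d_full <- cg_density(generate_genome(mk(1))$genome[[1]])
  d_depl <- cg_density(generate_genome(mk(0.2))$genome[[1]])
  expect_lt(d_depl / d_full, 0.35)
  expect_gt(d_depl / d_full, 0.1)
})

test_that("simulate_methylomes: null world recovers baselines exactly in truth", {
  w <- tiny_world(seed = 21L, kit_effect_logit = 0)
  sm <- simulate_methylomes(w$genome, w$genes, w$islands, w$config)
  sites <- sm$counts$sites
  # truth fractions are the per-context baselines, exactly
  for (ctx in c("CpG", "CHG", "CHH"))
    expect_true(all(abs(sm$truth$fractions[sites$context == ctx, ] -
                          w$config$baseline_methylation[[ctx]]) < 1e-12))
  # pooled empirical CpG methylation close to 0.75
  cpg <- sites$context == "CpG"
  emp <- sum(sm$counts$meth[cpg, ]) / sum(sm$counts$total[cpg, ])
  expect_lt(abs(emp - 0.75), 0.01)
})

test_that("planted promoter effect shifts truth by the closed-form logit arithmetic", {
  w <- tiny_world(seed = 22L)
  cfg <- w$config
  cfg$planted_effects <- list(planted_effect(w$genes$gene_id[1],
                                             region = "promoter",
                                             context = "CpG",
                                             direction = "hypo",
                                             delta_logit = -1.5,
                                             active_in = "Y"))
  sm <- simulate_methylomes(w$genome, w$genes, w$islands, cfg)
  samples <- sm$counts$samples
  eff <- sm$truth$effect_sites[[1]]
  expect_gt(length(eff), 0)
  kit_of <- samples$kit == "kitB"
  grp <- paste0(samples$age, samples$treatment)
  base <- qlogis(0.75) + cfg$kit_effect_logit * kit_of
  for (j in which(grp == "YT"))
    expect_equal(sm$truth$fractions[eff, j], rep(plogis(base[j] - 1.5),
                                                 length(eff)),
                 tolerance = 1e-12)
  for (j in which(grp == "YC"))
    expect_equal(sm$truth$fractions[eff, j], rep(plogis(base[j]),
                                                 length(eff)),
                 tolerance = 1e-12)
  # aged treated samples are untouched (effect active in Y only)
  for (j in which(grp == "AT"))
    expect_equal(sm$truth$fractions[eff, j], rep(plogis(base[j]),
                                                 length(eff)),
                 tolerance = 1e-12)
  # observed counts difference has the right sign and size
  ymt <- rowMeans(sm$counts$meth[eff, grp == "YT", drop = FALSE] /
                    pmax(sm$counts$total[eff, grp == "YT", drop = FALSE], 1))
  ymc <- rowMeans(sm$counts$meth[eff, grp == "YC", drop = FALSE] /
                    pmax(sm$counts$total[eff, grp == "YC", drop = FALSE], 1))
  expect_lt(mean(ymt) - mean(ymc), -0.2)
})

test_that("simulate_methylomes is deterministic and conserves counts/truth", {
  w <- tiny_world(seed = 23L)
  sm1 <- simulate_methylomes(w$genome, w$genes, w$islands, w$config)
  sm2 <- simulate_methylomes(w$genome, w$genes, w$islands, w$config)
  expect_identical(sm1$counts$meth, sm2$counts$meth)
  expect_identical(sm1$counts$total, sm2$counts$total)
  expect_true(all(sm1$counts$meth <= sm1$counts$total))
  expect_identical(nrow(sm1$truth$fractions), nrow(sm1$counts$sites))
  labs <- sm1$truth$gene_labels
  expect_identical(nrow(labs), nrow(w$genes) * 3L)
  expect_identical(anyDuplicated(labs[, .(gene_id, context)]), 0L)
})

test_that("empirical fractions converge to truth at high coverage", {
  w <- tiny_world(seed = 24L, coverage_mean = 200, genome_length = 6000L,
                  n_chromosomes = 1L, n_genes = 2L, n_islands = 1L)
  sm <- simulate_methylomes(w$genome, w$genes, w$islands, w$config)
  emp <- sm$counts$meth / pmax(sm$counts$total, 1)
  dev <- abs(emp - sm$truth$fractions)
  expect_gt(mean(dev <= 0.05), 0.95)
  expect_lt(mean(dev), 0.02)
})

test_that("simulate_reads honours the conversion model at its edges", {
  w <- tiny_world(seed = 31L, read_length = 60L)
  sites <- cytosine_sites(w$genome)
  truth0 <- data.table::data.table(sites[, .(chrom, pos, strand)], fraction = 0)

  cfg_all <- w$config; cfg_all$conversion_rate_converted <- 1
  cfg_all$failed_read_fraction <- 0
  reads <- simulate_reads(w$genome, truth0, cfg_all, n_reads = 200L)
  # unmethylated + full conversion: no cytosine survives in any read
  expect_false(any(grepl("C", reads$seq, fixed = TRUE)))

  cfg_none <- w$config; cfg_none$conversion_rate_converted <- 0
  cfg_none$failed_read_fraction <- 0
  reads0 <- simulate_reads(w$genome, truth0, cfg_none, n_reads = 200L)
  ref <- unname(substring(w$genome[reads0$chrom], reads0$pos + 1L,
                          reads0$pos + 60L))
  neg <- reads0$strand == "-"
  ref[neg] <- revcomp(ref[neg])
  expect_identical(reads0$seq, ref)
})

test_that("failed-read labelling matches the binomial rate", {
  w <- tiny_world(seed = 32L, failed_read_fraction = 0.05)
  sites <- cytosine_sites(w$genome)
  truth <- data.table::data.table(sites[, .(chrom, pos, strand)],
                                  fraction = 0.5)
  n <- 10000L
  reads <- simulate_reads(w$genome, truth, w$config, n_reads = n)
  expect_identical(nrow(reads), n)
  expect_lt(abs(mean(reads$failed) - 0.05), 3 * sqrt(0.05 * 0.95 / n))
  # strand alternation guarantees both strands
  expect_identical(as.integer(table(reads$strand)[c("+", "-")]),
                   c(n %/% 2L, n %/% 2L))
})

test_that("simulate_reads rejects read_length beyond the chromosome", {
  w <- tiny_world(seed = 33L, read_length = 5000L)
  sites <- cytosine_sites(w$genome)
  truth <- data.table::data.table(sites[, .(chrom, pos, strand)],
                                  fraction = 0.5)
  expect_error(simulate_reads(w$genome, truth, w$config, n_reads = 10L),
               "read_length")
})

test_that("SAM subset round-trips through write_sam/read_sam", {
  w <- tiny_world(seed = 34L, read_length = 50L)
  sites <- cytosine_sites(w$genome)
  truth <- data.table::data.table(sites[, .(chrom, pos, strand)],
                                  fraction = 0.8)
  reads <- simulate_reads(w$genome, truth, w$config, n_reads = 50L)
  f <- withr::local_tempfile(fileext = ".sam")
  write_sam(reads, w$genome, f)
  back <- read_sam(f)
  expect_identical(back$n_malformed, 0L)
  expect_identical(back$reads$seq, reads$seq)
  expect_identical(back$reads$pos, reads$pos)
  expect_identical(back$reads$strand, reads$strand)

  # malformed records are skipped with a warning, not fatal
  writeLines(c(readLines(f), "broken\trecord"), f)
  expect_warning(back2 <- read_sam(f), "malformed")
  expect_identical(nrow(back2$reads), nrow(reads))
})

test_that("FASTA / BED12 / BED3 / sample sheet round-trips", {
  w <- tiny_world(seed = 35L)
  d <- withr::local_tempdir()
  p <- file.path(d, "g.fa")
  write_genome_fasta(w$genome, p)
  expect_identical(read_genome_fasta(p), w$genome)

  pb <- file.path(d, "g.bed12")
  write_genes_bed12(w$genes, pb)
  back <- read_genes_bed12(pb)
  expect_identical(back$gene_id, w$genes$gene_id)
  expect_identical(back$start, w$genes$start)
  expect_identical(back$exon_starts, w$genes$exon_starts)
  expect_identical(back$exon_ends, w$genes$exon_ends)

  pi <- file.path(d, "i.bed")
  write_islands_bed(w$islands, pi)
  expect_identical(read_islands_bed(pi), w$islands[, .(chrom, start, end)])

  ps <- file.path(d, "s.tsv")
  samples <- sim_samples(w$config)
  write_sample_sheet(samples, ps)
  expect_identical(read_sample_sheet(ps), samples)
})
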