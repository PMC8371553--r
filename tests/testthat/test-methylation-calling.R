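test_that("classify_context follows the strand-relative definition", {
  g <- c(chr1 = "ACGT")
  expect_identical(classify_context(g, "chr1", 1L, "+"), "CpG")
  g2 <- c(chr1 = "CAG", chr2 = "CTT")
  expect_identical(classify_context(g2, "chr1", 0L, "+"), "CHG")
  expect_identical(classify_context(g2, "chr2", 0L, "+"), "CHH")
  # minus strand: CCG, the G at index 2 is a minus-strand C followed (5'->3'
  # on the minus strand) by the complement of index 1 (C -> G): CpG
  g3 <- c(chr1 = "CCG")
  expect_identical(classify_context(g3, "chr1", 2L, "-"), "CpG")
  # truncated windows default to CHH
  expect_identical(classify_context(c(chr1 = "TAC"), "chr1", 2L, "+"), "CHH")
  # caller misuse: not a strand-relative cytosine
  expect_error(classify_context(g, "chr1", 0L, "+"), "cytosine")
  expect_error(classify_context(g, "chr1", 1L, "-"), "cytosine")
})

test_that("cytosine_sites partitions both strands and agrees with classify_context", {
  w <- tiny_world(seed = 41L)
  sites <- cytosine_sites(w$genome)
  for (ch in names(w$genome)) {
    chars <- strsplit(w$genome[[ch]], "")[[1]]
    expect_identical(sum(sites$chrom == ch & sites$strand == "+"),
                     sum(chars == "C"))
    expect_identical(sum(sites$chrom == ch & sites$strand == "-"),
                     sum(chars == "G"))
  }
  expect_true(all(sites$context %in% c("CpG", "CHG", "CHH")))
  expect_identical(anyDuplicated(sites[, .(chrom, pos, strand)]), 0L)
  # CG is its own reverse complement: equal CpG counts per strand
  expect_identical(sites[context == "CpG" & strand == "+", .N],
                   sites[context == "CpG" & strand == "-", .N])
  # spot-check agreement with the scalar classifier
  idx <- seq(1, nrow(sites), length.out = 25)
  for (i in idx) {
    s <- sites[i]
    expect_identical(classify_context(w$genome, s$chrom, s$pos, s$strand),
                     s$context)
  }
})

test_that("lone_cytosine_fraction matches the hand-counted definition", {
  expect_equal(lone_cytosine_fraction("ACGACTC"), 2 / 3)
  expect_equal(lone_cytosine_fraction("ATTGA"), 0)
  expect_equal(lone_cytosine_fraction(""), 0)
  expect_equal(lone_cytosine_fraction("GC"), 0)     # GC: preceded by G
  expect_equal(lone_cytosine_fraction("CG"), 0)     # CG: followed by G
  expect_equal(lone_cytosine_fraction("C"), 1)
  # constructed 150 bp window: 20 cytosines, 4 in CG/GC, 16 lone -> 0.8
  win <- paste0(paste(rep("ACGA", 2), collapse = ""),
                paste(rep("AGCA", 2), collapse = ""),
                paste(rep("ACA", 16), collapse = ""))
  win <- paste0(win, paste(rep("T", 150 - nchar(win)), collapse = ""))
  expect_identical(nchar(win), 150L)
  expect_identical(lone_cytosine_count(win), 16L)
  expect_equal(lone_cytosine_fraction(win), 16 / 20)
})

test_that("filter_reads applies the threshold per read, order-preserving", {
  # per-cytosine mode reproduces the definitional example:
  # fractions {0, 0.03, 0.40} at threshold 0.05 -> one removal
  mk_read <- function(seq, q) data.table::data.table(
    qname = q, chrom = "chr1", pos = 0L, strand = "+", seq = seq)
  reads <- rbind(
    mk_read(paste(rep("CG", 10), collapse = ""), "r0.00"),
    mk_read(paste(c(rep("CG", 32), "ACA", rep("T", 4)), collapse = ""), "r0.03"),
    mk_read(paste(c(rep("CG", 3), rep("ACA", 2)), collapse = ""), "r0.40"))
  expect_equal(lone_cytosine_fraction(reads$seq), c(0, 1 / 33, 2 / 5),
               tolerance = 1e-12)
  out <- filter_reads(reads, read_filter_config(0.05,
                                                denominator = "cytosines"))
  expect_identical(out$n_removed, 1L)
  expect_identical(out$reads$qname, c("r0.00", "r0.03"))
  # threshold 1.0 retains everything
  out_all <- filter_reads(reads, read_filter_config(1,
                                                    denominator = "cytosines"))
  expect_identical(out_all$n_removed, 0L)
  # absolute cap
  out_cap <- filter_reads(reads, read_filter_config(1, max_lone_count = 1L,
                                                    denominator = "cytosines"))
  expect_identical(out_cap$reads$qname, c("r0.00", "r0.03"))
})

test_that("filter retention is monotone in the threshold", {
  w <- tiny_world(seed = 42L, failed_read_fraction = 0.3,
                  conversion_rate_failed = 0.3)
  sites <- cytosine_sites(w$genome)
  truth <- data.table::data.table(sites[, .(chrom, pos, strand)],
                                  fraction = 0.3)
  reads <- simulate_reads(w$genome, truth, w$config, n_reads = 400L)
  for (den in c("read_length", "cytosines")) {
    kept <- vapply(seq(0, 1, by = 0.05), function(th)
      nrow(filter_reads(reads, read_filter_config(th, denominator = den))$reads),
      numeric(1))
    expect_true(all(diff(kept) >= 0))
  }
})

test_that("call_methylation tallies single observations and is additive", {
  g <- c(chr1 = "ACGT")
  one <- data.table::data.table(qname = "r1", chrom = "chr1", pos = 0L,
                                strand = "+", seq = "ACGT")
  calls <- call_methylation(one, g)
  site <- calls[pos == 1L & strand == "+"]
  expect_identical(site$n_methylated, 1L)
  expect_identical(site$n_total, 1L)
  expect_identical(site$context, "CpG")

  two <- rbind(one, data.table::data.table(qname = "r2", chrom = "chr1",
                                           pos = 0L, strand = "+",
                                           seq = "ATGT"))
  calls2 <- call_methylation(two, g)
  site2 <- calls2[pos == 1L & strand == "+"]
  expect_identical(site2$n_methylated, 1L)
  expect_identical(site2$n_total, 2L)
})

test_that("calling conserves observations and recovers simulated fractions", {
  w <- tiny_world(seed = 43L, coverage_mean = 10, failed_read_fraction = 0)
  sites <- cytosine_sites(w$genome)
  truth <- data.table::data.table(sites[, .(chrom, pos, strand)],
                                  fraction = 0.75)
  reads <- simulate_reads(w$genome, truth, w$config)
  calls <- call_methylation(reads, w$genome, sites = sites)
  # conservation: every C/T read-base at a reference cytosine is counted once
  ref <- substring(w$genome[reads$chrom], reads$pos + 1L,
                   reads$pos + nchar(reads$seq))
  neg <- reads$strand == "-"
  ref[neg] <- revcomp(ref[neg])
  n_obs <- 0L
  for (i in seq_len(nrow(reads))) {
    cpos <- gregexpr("C", ref[i], fixed = TRUE)[[1]]
    if (cpos[1] == -1L) next
    bases <- substring(reads$seq[i], cpos, cpos)
    n_obs <- n_obs + sum(bases %in% c("C", "T"))
  }
  expect_identical(sum(calls$n_total), n_obs)
  # pooled fraction near truth (conversion failures pull it up slightly)
  expect_lt(abs(sum(calls$n_methylated) / sum(calls$n_total) - 0.75), 0.03)
})

test_that("high-coverage calling pins the per-site fraction near truth", {
  w <- tiny_world(seed = 44L, coverage_mean = 200, genome_length = 2000L,
                  n_chromosomes = 1L, n_genes = 1L, gene_length = 500L,
                  n_islands = 1L, island_length = 200L,
                  failed_read_fraction = 0)
  sites <- cytosine_sites(w$genome)
  truth <- data.table::data.table(sites[, .(chrom, pos, strand)],
                                  fraction = 0.75)
  reads <- simulate_reads(w$genome, truth, w$config)
  calls <- call_methylation(reads, w$genome, sites = sites)
  well <- calls[n_total >= 100]
  expect_gt(nrow(well), 50)
  expect_true(all(abs(well$n_methylated / well$n_total - 0.75) < 0.15))
  expect_lt(mean(abs(well$n_methylated / well$n_total - 0.75)), 0.05)
})

test_that("reads past the chromosome end are rejected records", {
  g <- c(chr1 = "ACGTACGT")
  reads <- data.table::data.table(qname = c("ok", "long"), chrom = "chr1",
                                  pos = c(0L, 5L), strand = "+",
                                  seq = c("ACGT", "CGTACG"))
  expect_warning(calls <- call_methylation(reads, g), "rejected")
  expect_identical(sum(calls$n_total), 1L)  # only the valid read's C
})

test_that("cytosine report round-trips with 1-based positions on disk", {
  w <- tiny_world(seed = 45L, coverage_mean = 5)
  sites <- cytosine_sites(w$genome)
  truth <- data.table::data.table(sites[, .(chrom, pos, strand)],
                                  fraction = 0.5)
  reads <- simulate_reads(w$genome, truth, w$config, n_reads = 300L)
  calls <- call_methylation(reads, w$genome, sites = sites)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_cytosine_report(calls, f)
  on_disk <- data.table::fread(f, header = FALSE)
  expect_identical(on_disk$V2, calls$pos + 1L)
  back <- read_cytosine_report(f)
  expect_identical(back$pos, calls$pos)
  expect_identical(back$n_methylated, calls$n_methylated)
  expect_identical(back$context, calls$context)
})
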