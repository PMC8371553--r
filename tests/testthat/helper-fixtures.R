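# Shared fixtures, built in code. Small worlds keep the suite fast; the
# acceptance file uses its own, larger, stated-world configurations.

tiny_config <- function(seed = 11L, ...) {
  args <- list(genome_length = 8000L, n_chromosomes = 2L, gc_content = 0.42,
               n_genes = 4L, gene_length = 1200L, n_islands = 2L,
               island_length = 400L, island_cpg_boost = 4, seed = seed)
  do.call(sim_config, utils::modifyList(args, list(...)))
}

tiny_world <- function(seed = 11L, ...) {
  cfg <- tiny_config(seed = seed, ...)
  c(generate_genome(cfg), list(config = cfg))
}

# hand-built gene model table (0-based half-open, two exons)
toy_genes <- function() {
  data.table::data.table(
    gene_id = c("gA", "gB"), chrom = c("chr1", "chr1"),
    start = c(5000L, 20000L), end = c(9000L, 24000L),
    strand = c("+", "-"),
    exon_starts = list(c(5000L, 8000L), c(20000L, 23000L)),
    exon_ends = list(c(6000L, 9000L), c(21000L, 24000L)))
}

# counts container built directly from matrices (bypasses the simulator)
manual_counts <- function(meth, total, context = "CpG",
                          ages = NULL, treatments = NULL, kits = NULL) {
  n_site <- nrow(meth); n_samp <- ncol(meth)
  ids <- sprintf("S%02d", seq_len(n_samp))
  samples <- data.table::data.table(
    sample_id = ids,
    age = ages %||% rep("Y", n_samp),
    treatment = treatments %||% rep(c("C", "T"), length.out = n_samp),
    kit = kits %||% rep(c("kitA", "kitB"), length.out = n_samp))
  colnames(meth) <- colnames(total) <- ids
  sites <- data.table::data.table(
    chrom = "chr1", pos = seq_len(n_site) * 10L, strand = "+",
    context = rep_len(context, n_site))
  meth_counts(sites, meth, total, samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# The recovery world of the critical-window experiments: one gene per small
# chromosome (no cross-gene promoter bleed), mammalian-like background CpG
# depletion, promoter CpG hypomethylation of -1.5 logits planted on 10
# critical-window and 10 always-responsive genes. Group sizes mirror the
# emulated study; coverage is Poisson(30).
recovery_config <- function(seed) {
  cfg <- sim_config(genome_length = 32000L, n_chromosomes = 20L,
                    gc_content = 0.42, cpg_oe = 0.2,
                    n_genes = 20L, gene_length = 800L,
                    n_islands = 1L, island_length = 200L,
                    island_cpg_boost = 1,
                    coverage_mean = 30, seed = seed)
  world <- generate_genome(cfg)
  cfg$planted_effects <- default_planted_effects(world$genes,
                                                 n_critical = 10L,
                                                 n_always = 10L,
                                                 context = "CpG",
                                                 delta_logit = -1.5)
  list(config = cfg, world = world)
}

run_recovery_once <- function(seed) {
  rw <- recovery_config(seed)
  sm <- simulate_methylomes(rw$world$genome, rw$world$genes, rw$world$islands,
                            rw$config)
  cts <- study_contrasts(sim_samples(rw$config))
  ann <- annotate_sites(sm$counts$sites, rw$world$genes, rw$world$islands)
  calls <- lapply(cts[c("YT-YC", "MT-MC", "AT-AC")], function(ct)
    gene_calls(run_contrast(sm$counts, ct, contexts = "CpG"), ann,
               contexts = "CpG"))
  w <- critical_window_genes(calls[["YT-YC"]], calls[["MT-MC"]],
                             calls[["AT-AC"]], context = "CpG")
  labels <- sm$truth$gene_labels[context == "CpG"]
  list(window = w,
       cw_genes = labels[label == "critical_window", gene_id],
       ar_genes = labels[label == "always_responsive", gene_id])
}
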