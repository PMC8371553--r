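#' Planted differential-methylation effect
#'
#' Describes one ground-truth treatment effect placed on a gene's promoter or
#' body, in one cytosine context, active in a subset of age groups. Effects are
#' additive on the logit scale of the per-site methylation fraction and apply
#' to treated samples of the active ages only. A critical-window gene is one
#' whose effect is active in young and middle-age but not aged animals
#' (`active_in = c("Y", "M")`).
#'
#' @param gene_id gene identifier; must exist in the generated gene models.
#' @param region `"promoter"` (a +/- 1 kb window around the TSS by default) or
#'   `"body"` (the annotated gene span).
#' @param context cytosine context the effect applies to: `"CpG"`, `"CHG"` or
#'   `"CHH"`.
#' @param direction `"hypo"` or `"hyper"`; must agree with the sign of
#'   `delta_logit`.
#' @param delta_logit signed logit-scale shift (negative for hypomethylation).
#' @param active_in character subset of `c("Y", "M", "A")`: age groups in which
#'   treated samples receive the shift.
#' @param promoter_upstream,promoter_downstream extent of the promoter window
#'   used to materialize `region = "promoter"`, in bases around the TSS.
#' @return an object of class `planted_effect`.
#' @export
planted_effect <- function(gene_id, region = c("promoter", "body"),
                           context = c("CpG", "CHG", "CHH"),
                           direction = c("hypo", "hyper"),
                           delta_logit = if (match.arg(direction) == "hypo") -1.5 else 1.5,
                           active_in = c("Y", "M"),
                           promoter_upstream = 1000L,
                           promoter_downstream = 1000L) {
  region <- match.arg(region)
  context <- match.arg(context)
  direction <- match.arg(direction)
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  if (!is.numeric(delta_logit) || !is.finite(delta_logit))
    stop("'delta_logit' must be finite")
  if (direction == "hypo" && delta_logit > 0 ||
      direction == "hyper" && delta_logit < 0)
    stop("sign of 'delta_logit' contradicts 'direction'")
  active_in <- unique(match.arg(active_in, c("Y", "M", "A"), several.ok = TRUE))
  structure(list(gene_id = gene_id, region = region, context = context,
                 direction = direction, delta_logit = delta_logit,
                 active_in = active_in,
                 promoter_upstream = as.integer(promoter_upstream),
                 promoter_downstream = as.integer(promoter_downstream)),
            class = "planted_effect")
}

#' Simulation configuration for the synthetic WGBS world
#'
#' Collects every knob of the synthetic-data generator: a toy genome with
#' CpG-dense islands, a cohort of three age groups (Y/M/A) crossed with
#' control/estradiol treatment (C/T) and two library-preparation kits, per-
#' context baseline methylation, additive logit-scale kit/age/treatment
#' effects, binomial read sampling at Poisson coverage, and an incomplete
#' bisulfite-conversion model for simulated reads.
#'
#' Default cohort sizes mirror the study design the generator emulates:
#' treated n = 6/6/7 and control n = 4/4/4 for young/middle-age/aged.
#'
#' @param genome_length total genome length in bases (split over chromosomes).
#' @param n_chromosomes number of chromosomes.
#' @param gc_content fraction of G+C bases, in (0,1).
#' @param n_genes,gene_length number and length of non-overlapping gene models.
#' @param n_islands,island_length number and length of CpG islands.
#' @param island_cpg_boost multiplier (>= 1) on CpG dinucleotide density inside
#'   islands relative to the background.
#' @param cpg_oe background CpG observed/expected ratio in (0,1]; 1 keeps the
#'   i.i.d. base model, lower values deplete background CpG dinucleotides
#'   (CpG -> TpG) toward the mammalian genome-wide ratio of ~0.2.
#' @param group_sizes named integer vector over the six groups YC/YT/MC/MT/AC/AT.
#' @param kit_assignment optional named character vector sample_id -> kitA/kitB;
#'   by default kits alternate within each group (balanced batch).
#' @param baseline_methylation named fractions per context
#'   (CpG 0.75, CHG 0.02, CHH 0.02 by default).
#' @param kit_effect_logit logit-scale shift added for kitB samples.
#' @param age_effect_logit named numeric shifts per age (Y/M/A), default zero.
#' @param planted_effects list of [planted_effect()] objects.
#' @param coverage_mean mean per-site read coverage (Poisson).
#' @param read_length simulated read length in bases.
#' @param conversion_rate_converted probability that an unmethylated cytosine is
#'   converted (read as T) in a normally converted read.
#' @param conversion_rate_failed same probability in a conversion-failed read.
#' @param failed_read_fraction fraction of reads with failed conversion.
#' @param seed integer seed making every generator operation deterministic.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(genome_length = 50000L,
                       n_chromosomes = 2L,
                       gc_content = 0.42,
                       n_genes = 10L,
                       gene_length = 2000L,
                       n_islands = 6L,
                       island_length = 600L,
                       island_cpg_boost = 5,
                       cpg_oe = 1,
                       group_sizes = c(YC = 4L, YT = 6L, MC = 4L, MT = 6L,
                                       AC = 4L, AT = 7L),
                       kit_assignment = NULL,
                       baseline_methylation = c(CpG = 0.75, CHG = 0.02, CHH = 0.02),
                       kit_effect_logit = 0.3,
                       age_effect_logit = c(Y = 0, M = 0, A = 0),
                       planted_effects = list(),
                       coverage_mean = 30,
                       read_length = 150L,
                       conversion_rate_converted = 0.995,
                       conversion_rate_failed = 0.2,
                       failed_read_fraction = 0.02,
                       seed = 1L) {
  genome_length <- assert_count(genome_length, "genome_length")
  n_chromosomes <- assert_count(n_chromosomes, "n_chromosomes")
  assert_fraction(gc_content, "gc_content", allow_zero = FALSE, allow_one = FALSE)
  n_genes <- assert_count(n_genes, "n_genes")
  gene_length <- assert_count(gene_length, "gene_length")
  n_islands <- assert_count(n_islands, "n_islands", min = 0L)
  island_length <- assert_count(island_length, "island_length")
  if (!is.numeric(island_cpg_boost) || island_cpg_boost < 1)
    stop("'island_cpg_boost' must be >= 1")
  assert_fraction(cpg_oe, "cpg_oe", allow_zero = FALSE)

  needed <- c("YC", "YT", "MC", "MT", "AC", "AT")
  if (!all(needed %in% names(group_sizes)))
    stop("'group_sizes' must name all of: ", paste(needed, collapse = ", "))
  group_sizes <- vapply(group_sizes[needed], assert_count, integer(1),
                        name = "group_sizes")

  for (ctx in c("CpG", "CHG", "CHH"))
    assert_fraction(baseline_methylation[[ctx]],
                    paste0("baseline_methylation[", ctx, "]"),
                    allow_zero = FALSE, allow_one = FALSE)
  if (!all(c("Y", "M", "A") %in% names(age_effect_logit)))
    stop("'age_effect_logit' must name Y, M and A")
  stopifnot(is.numeric(kit_effect_logit), is.finite(kit_effect_logit))
  if (!is.list(planted_effects) ||
      !all(vapply(planted_effects, inherits, logical(1), "planted_effect")))
    stop("'planted_effects' must be a list of planted_effect objects")
  if (!is.numeric(coverage_mean) || coverage_mean <= 0)
    stop("'coverage_mean' must be > 0")
  read_length <- assert_count(read_length, "read_length")
  assert_fraction(conversion_rate_converted, "conversion_rate_converted")
  assert_fraction(conversion_rate_failed, "conversion_rate_failed")
  assert_fraction(failed_read_fraction, "failed_read_fraction")
  seed <- assert_count(seed, "seed", min = 0L)

  # sizing: genes must fit their per-chromosome territories; islands must fit
  chrom_len <- genome_length %/% n_chromosomes
  genes_per_chrom <- ceiling(n_genes / n_chromosomes)
  if (genes_per_chrom * gene_length > chrom_len)
    stop("sizing error: ", n_genes, " genes of ", gene_length,
         " bases do not fit a genome of ", genome_length, " bases over ",
         n_chromosomes, " chromosomes")
  if (n_islands > 0 &&
      ceiling(n_islands / n_chromosomes) * island_length > chrom_len)
    stop("sizing error: islands of ", island_length,
         " bases do not fit the chromosomes")

  cfg <- list(genome_length = genome_length, n_chromosomes = n_chromosomes,
              gc_content = gc_content, n_genes = n_genes,
              gene_length = gene_length, n_islands = n_islands,
              island_length = island_length,
              island_cpg_boost = island_cpg_boost, cpg_oe = cpg_oe,
              group_sizes = group_sizes, kit_assignment = kit_assignment,
              baseline_methylation = baseline_methylation,
              kit_effect_logit = kit_effect_logit,
              age_effect_logit = age_effect_logit,
              planted_effects = planted_effects,
              coverage_mean = coverage_mean, read_length = read_length,
              conversion_rate_converted = conversion_rate_converted,
              conversion_rate_failed = conversion_rate_failed,
              failed_read_fraction = failed_read_fraction, seed = seed)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic WGBS world configuration\n")
  cat(sprintf("  genome: %d bp over %d chromosome(s), GC %.2f, CpG o/e %.2f\n",
              x$genome_length, x$n_chromosomes, x$gc_content, x$cpg_oe))
  cat(sprintf("  genes: %d x %d bp; islands: %d x %d bp (CpG boost %.1f)\n",
              x$n_genes, x$gene_length, x$n_islands, x$island_length,
              x$island_cpg_boost))
  cat(sprintf("  cohort: %s\n",
              paste(names(x$group_sizes), x$group_sizes, sep = "=",
                    collapse = " ")))
  cat(sprintf("  coverage ~ Poisson(%g); %d planted effect(s); seed %d\n",
              x$coverage_mean, length(x$planted_effects), x$seed))
  invisible(x)
}

#' Build the sample sheet implied by a simulation configuration
#'
#' Samples are named `<group><index>` (for example `YT3`). Unless
#' `kit_assignment` overrides it, library kits alternate within each group so
#' the batch is balanced across groups.
#'
#' @param config a [sim_config()] object.
#' @return `data.table` with columns `sample_id`, `age`, `treatment`, `kit`.
#' @export
sim_samples <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  rows <- lapply(names(config$group_sizes), function(g) {
    n <- config$group_sizes[[g]]
    data.table(sample_id = paste0(g, seq_len(n)),
               age = substr(g, 1, 1), treatment = substr(g, 2, 2),
               kit = rep(c("kitA", "kitB"), length.out = n))
  })
  samples <- rbindlist(rows)
  if (!is.null(config$kit_assignment)) {
    ka <- config$kit_assignment
    bad <- setdiff(names(ka), samples$sample_id)
    if (length(bad))
      stop("kit_assignment names unknown samples: ", paste(bad, collapse = ", "))
    if (!all(ka %in% c("kitA", "kitB")))
      stop("kit_assignment values must be 'kitA' or 'kitB'")
    samples[names(ka), kit := unname(ka), on = "sample_id"]
  }
  samples[]
}

#' Default planted effects: critical-window and always-responsive genes
#'
#' Convenience builder of the canonical ground-truth layout: the first
#' `n_critical` genes carry a treatment hypomethylation effect active in young
#' and middle-age only (critical-window genes), the next `n_always` carry the
#' same effect active at every age (always-responsive genes).
#'
#' @param genes gene-model `data.table` from [generate_genome()].
#' @param n_critical,n_always numbers of genes of each class.
#' @param context cytosine context of the effects.
#' @param delta_logit signed logit shift (negative = hypomethylation).
#' @param region `"promoter"` or `"body"`.
#' @return list of [planted_effect()] objects.
#' @export
default_planted_effects <- function(genes, n_critical = 10L, n_always = 10L,
                                    context = "CpG", delta_logit = -1.5,
                                    region = "promoter") {
  if (n_critical + n_always > nrow(genes))
    stop("not enough genes for the requested planted effects")
  direction <- if (delta_logit < 0) "hypo" else "hyper"
  ids <- genes$gene_id
  c(
    lapply(ids[seq_len(n_critical)], planted_effect, region = region,
           context = context, direction = direction,
           delta_logit = delta_logit, active_in = c("Y", "M")),
    lapply(ids[n_critical + seq_len(n_always)], planted_effect, region = region,
           context = context, direction = direction,
           delta_logit = delta_logit, active_in = c("Y", "M", "A"))
  )
}
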