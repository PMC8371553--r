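#' Pipeline run configuration
#'
#' Bundles the stage configurations, input paths (when not simulating) and
#' output directory for [run_pipeline()]. Every numeric threshold is echoed
#' into the run report for provenance.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed for the run.
#' @param simulate generate the synthetic world (default) instead of loading
#'   inputs from files.
#' @param use_reads when simulating, go through the read-level path (simulate
#'   reads, filter, call) instead of drawing counts directly; much slower and
#'   intended for reduced coverage.
#' @param genome_fasta,genes_bed,islands_bed,sample_sheet,reports_dir input
#'   paths for `simulate = FALSE`: reference FASTA, BED12 gene models, BED3
#'   islands, sample-sheet TSV, and a directory of per-sample cytosine
#'   reports named `<sample_id>.tsv`.
#' @param gmt optional GMT gene-set collection for the enrichment stage; when
#'   simulating and omitted, a synthetic collection is built from the planted
#'   ground-truth labels.
#' @param sim a [sim_config()] (used when `simulate = TRUE`).
#' @param filter a [read_filter_config()] (read-level path only).
#' @param unite an [unite_config()].
#' @param annotation an [annotation_config()].
#' @param fdr_threshold,directed_p_threshold enrichment thresholds echoed in
#'   the report.
#' @param min_sites_per_call per-gene site minimum for [gene_calls()].
#' @param contexts cytosine contexts analysed.
#' @param write_reports write per-sample cytosine-report TSVs (default TRUE).
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, simulate = TRUE, use_reads = FALSE,
                       genome_fasta = NULL, genes_bed = NULL,
                       islands_bed = NULL, sample_sheet = NULL,
                       reports_dir = NULL, gmt = NULL,
                       sim = sim_config(seed = seed),
                       filter = read_filter_config(),
                       unite = unite_config(),
                       annotation = annotation_config(),
                       fdr_threshold = 0.05, directed_p_threshold = 0.05,
                       min_sites_per_call = 1L,
                       contexts = c("CpG", "CHG", "CHH"),
                       write_reports = TRUE) {
  if (!simulate) {
    for (p in c(genome_fasta, genes_bed, islands_bed, sample_sheet))
      if (is.null(p) || !file.exists(p))
        stop("with simulate = FALSE, genome_fasta, genes_bed, islands_bed ",
             "and sample_sheet must exist")
    if (is.null(reports_dir) || !dir.exists(reports_dir))
      stop("with simulate = FALSE, 'reports_dir' must be a directory of ",
           "per-sample cytosine reports")
  }
  if (!is.null(gmt) && !file.exists(gmt)) stop("GMT file not found: ", gmt)
  assert_fraction(fdr_threshold, "fdr_threshold", allow_zero = FALSE,
                  allow_one = FALSE)
  assert_fraction(directed_p_threshold, "directed_p_threshold",
                  allow_zero = FALSE, allow_one = FALSE)
  structure(list(out_dir = out_dir, seed = assert_count(seed, "seed", 0L),
                 simulate = isTRUE(simulate), use_reads = isTRUE(use_reads),
                 genome_fasta = genome_fasta, genes_bed = genes_bed,
                 islands_bed = islands_bed, sample_sheet = sample_sheet,
                 reports_dir = reports_dir, gmt = gmt, sim = sim,
                 filter = filter, unite = unite, annotation = annotation,
                 fdr_threshold = fdr_threshold,
                 directed_p_threshold = directed_p_threshold,
                 min_sites_per_call = assert_count(min_sites_per_call,
                                                   "min_sites_per_call"),
                 contexts = contexts, write_reports = isTRUE(write_reports)),
            class = "run_config")
}

#' Default synthetic run configuration
#'
#' A desk-scale world with 20 genes on a 60 kb genome and the canonical
#' planted-effect layout (10 critical-window genes, 10 always-responsive
#' genes, promoter CpG hypomethylation of -1.5 logits), study-sized groups,
#' a balanced library-kit batch effect of +0.3 logits, and Poisson(30)
#' coverage.
#'
#' @param out_dir output directory.
#' @param seed master seed.
#' @param ... overrides forwarded to [run_config()].
#' @return a [run_config()].
#' @export
default_run_config <- function(out_dir, seed = 1L, ...) {
  sim <- sim_config(genome_length = 60000L, n_chromosomes = 2L,
                    n_genes = 20L, gene_length = 2000L,
                    n_islands = 8L, island_length = 600L, cpg_oe = 0.2,
                    seed = seed)
  world <- generate_genome(sim)
  sim$planted_effects <- default_planted_effects(world$genes)
  run_config(out_dir = out_dir, seed = seed, sim = sim, ...)
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> \[read filter + methylation calling\] ->
#' the six study contrasts -> annotation -> critical-window classification ->
#' enrichment, writing every stage output plus a machine-readable
#' `report.json` into the output directory. The run is a pure function of the
#' configuration (including its seed): rerunning with the same config yields a
#' byte-identical report.
#'
#' @param config a [run_config()].
#' @return the report (a nested list), invisibly; it is also written to
#'   `file.path(config$out_dir, "report.json")`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  if (config$simulate) {
    world <- stage("simulate", generate_genome(config$sim))
    samples <- sim_samples(config$sim)
    sim_out <- stage("simulate",
                     simulate_methylomes(world$genome, world$genes,
                                         world$islands, config$sim))
    truth <- sim_out$truth
    counts <- if (config$use_reads)
      stage("call", counts_via_reads(world, sim_out, config))
    else sim_out$counts
    write_genome_fasta(world$genome, file.path(out, "genome.fa"))
    write_genes_bed12(world$genes, file.path(out, "genes.bed12"))
    write_islands_bed(world$islands, file.path(out, "islands.bed"))
    write_sample_sheet(samples, file.path(out, "samples.tsv"))
    fwrite(truth$gene_labels, file.path(out, "truth_gene_labels.tsv"),
           sep = "\t")
    if (config$write_reports) {
      dir.create(file.path(out, "counts"), showWarnings = FALSE)
      for (sid in samples$sample_id) {
        rep_i <- cbind(counts$sites,
                       data.table(n_methylated = counts$meth[, sid],
                                  n_unmethylated = counts$total[, sid] -
                                    counts$meth[, sid]))
        if (!"tri" %in% names(rep_i)) rep_i[, tri := "NNN"]
        write_cytosine_report(
          rep_i[, .(chrom, pos, strand, n_methylated, n_unmethylated,
                    context, tri)],
          file.path(out, "counts", paste0(sid, ".tsv")))
      }
    }
  } else {
    world <- stage("load", list(
      genome = read_genome_fasta(config$genome_fasta),
      genes = read_genes_bed12(config$genes_bed),
      islands = read_islands_bed(config$islands_bed)))
    samples <- read_sample_sheet(config$sample_sheet)
    counts <- stage("load", {
      sites <- cytosine_sites(world$genome)
      calls <- lapply(samples$sample_id, function(sid) {
        f <- file.path(config$reports_dir, paste0(sid, ".tsv"))
        if (!file.exists(f)) stop("missing cytosine report: ", f)
        r <- read_cytosine_report(f)
        r[, n_total := n_methylated + n_unmethylated]
        r
      })
      names(calls) <- samples$sample_id
      counts_from_calls(calls, samples)
    })
    truth <- NULL
  }

  contrasts <- stage("diff", study_contrasts(samples))
  contrast_results <- stage("diff", lapply(contrasts, function(ct)
    run_contrast(counts, ct, config$unite, contexts = config$contexts)))

  annotated <- stage("annotate",
                     annotate_sites(counts$sites, world$genes, world$islands,
                                    config$annotation))
  dir.create(file.path(out, "contrasts"), showWarnings = FALSE)
  ann_key <- annotated[, .(chrom, pos, strand, feature, gene_id, island_zone)]
  summaries <- list()
  calls_by_contrast <- list()
  for (nm in names(contrast_results)) {
    cr <- contrast_results[[nm]]
    res_out <- ann_key[cr$results, on = c("chrom", "pos", "strand")]
    fwrite(res_out, file.path(out, "contrasts", paste0(nm, ".tsv")),
           sep = "\t")
    summaries[[nm]] <- c(cr$summary[c("n_tested", "n_hyper", "n_hypo",
                                      "n_significant")],
                         stage("annotate", summarize_contrast(cr, ann_key)))
    calls_by_contrast[[nm]] <- lapply(
      setNames(config$contexts, config$contexts), function(ctx)
        gene_calls(cr, ann_key, config$min_sites_per_call, contexts = ctx))
  }

  windows <- stage("window", {
    need <- c("YT-YC", "MT-MC", "AT-AC")
    if (!all(need %in% names(calls_by_contrast)))
      stop("missing treatment contrast(s): ",
           paste(setdiff(need, names(calls_by_contrast)), collapse = ", "))
    lapply(setNames(config$contexts, config$contexts), function(ctx)
      critical_window_genes(calls_by_contrast[["YT-YC"]][[ctx]],
                            calls_by_contrast[["MT-MC"]][[ctx]],
                            calls_by_contrast[["AT-AC"]][[ctx]],
                            context = ctx))
  })
  dir.create(file.path(out, "window"), showWarnings = FALSE)
  for (ctx in names(windows))
    fwrite(window_membership(windows[[ctx]]),
           file.path(out, "window", paste0(ctx, ".tsv")), sep = "\t")

  enrich <- stage("enrich", {
    collection <- NULL
    if (!is.null(config$gmt)) {
      gm <- read_gmt(config$gmt)
      collection <- gene_set_collection(gm$sets, world$genes$gene_id)
    } else if (config$simulate && !is.null(truth)) {
      labs <- truth$gene_labels[context == config$contexts[1]]
      sets <- list(
        truth_critical_window = labs[label == "critical_window", gene_id],
        truth_always_responsive = labs[label == "always_responsive", gene_id])
      sets <- sets[vapply(sets, length, integer(1)) > 0]
      if (length(sets))
        collection <- gene_set_collection(sets, world$genes$gene_id)
    }
    if (is.null(collection)) NULL else {
      lapply(setNames(names(windows), names(windows)), function(ctx) {
        q <- windows[[ctx]]$nonresponsive_in_aged
        if (!length(q)) return(NULL)
        tab <- hypergeom_enrichment(q, collection)
        fwrite(tab, file.path(out, paste0("enrichment_", ctx, ".tsv")),
               sep = "\t")
        tab
      })
    }
  })

  report <- list(
    config = list(seed = config$seed, simulate = config$simulate,
                  use_reads = config$use_reads,
                  alpha_site = contrasts[[1]]$alpha_site,
                  min_coverage = config$unite$min_coverage,
                  max_lone_fraction = config$filter$max_lone_fraction,
                  lone_denominator = config$filter$denominator,
                  promoter_upstream = config$annotation$promoter_upstream,
                  promoter_downstream = config$annotation$promoter_downstream,
                  shore_width = config$annotation$shore_width,
                  shelf_width = config$annotation$shelf_width,
                  fdr_threshold = config$fdr_threshold,
                  directed_p_threshold = config$directed_p_threshold,
                  min_sites_per_call = config$min_sites_per_call,
                  contexts = config$contexts),
    n_sites = nrow(counts$sites),
    n_samples = nrow(counts$samples),
    contrasts = summaries,
    window = lapply(windows, function(w)
      list(shared = unname(w$sizes[["shared"]]),
           nonresponsive_in_aged = unname(w$sizes[["nonresponsive_in_aged"]]),
           responsive_in_all = unname(w$sizes[["responsive_in_all"]]),
           nonresponsive_genes = w$nonresponsive_in_aged)),
    enrichment = if (is.null(enrich)) NULL else
      lapply(enrich, function(tab) if (is.null(tab)) NULL else
        tab[q < config$fdr_threshold | p < config$directed_p_threshold])
  )
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}

# read-level path: simulate reads per sample, filter, call, assemble counts
counts_via_reads <- function(world, sim_out, config) {
  samples <- sim_samples(config$sim)
  sites <- sim_out$counts$sites
  calls <- list()
  for (j in seq_len(nrow(samples))) {
    sid <- samples$sample_id[j]
    truth_j <- cbind(sites[, .(chrom, pos, strand)],
                     data.table(fraction = sim_out$truth$fractions[, sid]))
    reads <- simulate_reads(world$genome, truth_j, config$sim,
                            sample_id = sid,
                            seed = child_seed(config$sim$seed, 100L + j))
    kept <- filter_reads(reads, config$filter)$reads
    calls[[sid]] <- call_methylation(kept, world$genome, sid, sites = sites)
  }
  counts_from_calls(calls, samples)
}
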