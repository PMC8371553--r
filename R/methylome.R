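#' Per-site methylation count container
#'
#' The central data container of the pipeline: one row of `sites` per
#' strand-relative reference cytosine, with parallel matrices of methylated and
#' total read counts (sites x samples) and the sample sheet.
#'
#' @param sites `data.table` with `chrom`, `pos`, `strand`, `context`.
#' @param meth,total integer matrices, `nrow(sites)` x `nrow(samples)`, with
#'   column names equal to `samples$sample_id`; `0 <= meth <= total` cellwise.
#' @param samples sample sheet `data.table`.
#' @return an object of class `mw_counts`.
#' @export
meth_counts <- function(sites, meth, total, samples) {
  sites <- as.data.table(sites)
  stopifnot(nrow(meth) == nrow(sites), nrow(total) == nrow(sites),
            ncol(meth) == nrow(samples), ncol(total) == nrow(samples),
            identical(colnames(meth), samples$sample_id),
            identical(colnames(total), samples$sample_id))
  if (any(meth > total) || any(meth < 0))
    stop("need 0 <= methylated <= total in every cell")
  structure(list(sites = sites, meth = meth, total = total,
                 samples = as.data.table(samples)),
            class = "mw_counts")
}

#' @export
print.mw_counts <- function(x, ...) {
  cat(sprintf("mw_counts: %d sites x %d samples\n", nrow(x$sites),
              nrow(x$samples)))
  ctx <- table(x$sites$context)
  cat("  contexts:", paste(names(ctx), ctx, sep = "=", collapse = " "), "\n")
  cat("  samples:", paste(head(x$samples$sample_id, 8), collapse = " "),
      if (nrow(x$samples) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.mw_counts <- function(x) c(nrow(x$sites), nrow(x$samples))

# subset an mw_counts by site rows and/or sample ids
subset_counts <- function(counts, rows = NULL, sample_ids = NULL) {
  rows <- rows %||% seq_len(nrow(counts$sites))
  cols <- if (is.null(sample_ids)) seq_len(nrow(counts$samples))
          else match(sample_ids, counts$samples$sample_id)
  if (anyNA(cols)) stop("unknown sample id(s): ",
                        paste(sample_ids[is.na(cols)], collapse = ", "))
  meth_counts(counts$sites[rows],
              counts$meth[rows, cols, drop = FALSE],
              counts$total[rows, cols, drop = FALSE],
              counts$samples[cols])
}

# Resolve the genomic interval (0-based half-open) of a planted effect.
effect_interval <- function(effect, genes) {
  g <- genes[genes$gene_id == effect$gene_id]
  if (nrow(g) != 1L)
    stop("planted effect names unknown gene '", effect$gene_id, "'")
  if (effect$region == "body")
    return(list(chrom = g$chrom, lo = g$start, hi = g$end))
  tss <- if (g$strand == "+") g$start else g$end - 1L
  up <- effect$promoter_upstream; down <- effect$promoter_downstream
  if (g$strand == "+")
    list(chrom = g$chrom, lo = tss - up, hi = tss + down + 1L)
  else
    list(chrom = g$chrom, lo = tss - down, hi = tss + up + 1L)
}

#' Simulate methylomes and per-site counts for the whole cohort
#'
#' For every sample and every reference cytosine, the true methylation
#' fraction is `plogis(qlogis(baseline[context]) + age_effect + kit_effect +
#' planted deltas)`, where a planted delta applies when the site lies in the
#' effect's region and context and the sample is treated and of an active age.
#' Total counts are Poisson(`coverage_mean`) per site and sample, methylated
#' counts Binomial(total, fraction). Deterministic given the config seed.
#'
#' @param genome,genes,islands output of [generate_genome()].
#' @param config the same [sim_config()].
#' @return list with
#'   \describe{
#'     \item{counts}{an [meth_counts()] object.}
#'     \item{truth}{list: `fractions` (sites x samples matrix of true
#'       methylation fractions), `group_fractions` (sites x 6 group means),
#'       `gene_labels` (`data.table` of per-gene, per-context ground-truth
#'       labels: critical_window / always_responsive / never_responsive),
#'       `effect_sites` (logical site index per planted effect).}
#'   }
#' @export
simulate_methylomes <- function(genome, genes, islands, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$coverage_mean <= 0) stop("'coverage_mean' must be positive")
  samples <- sim_samples(config)
  sites <- cytosine_sites(genome)
  n_sites <- nrow(sites)
  n_samp <- nrow(samples)

  base_logit <- qlogis(config$baseline_methylation[sites$context])

  effects <- config$planted_effects
  effect_rows <- lapply(effects, function(ef) {
    iv <- effect_interval(ef, genes)
    which(sites$chrom == iv$chrom & sites$pos >= iv$lo & sites$pos < iv$hi &
            sites$context == ef$context)
  })

  fractions <- matrix(0, n_sites, n_samp,
                      dimnames = list(NULL, samples$sample_id))
  for (j in seq_len(n_samp)) {
    lg <- base_logit +
      config$age_effect_logit[[samples$age[j]]] +
      config$kit_effect_logit * (samples$kit[j] == "kitB")
    if (samples$treatment[j] == "T" && length(effects)) {
      for (k in seq_along(effects)) {
        if (samples$age[j] %in% effects[[k]]$active_in && length(effect_rows[[k]]))
          lg[effect_rows[[k]]] <- lg[effect_rows[[k]]] + effects[[k]]$delta_logit
      }
    }
    fractions[, j] <- plogis(lg)
  }

  counts <- with_seed(child_seed(config$seed, 2L), {
    total <- matrix(rpois(n_sites * n_samp, config$coverage_mean),
                    n_sites, n_samp, dimnames = list(NULL, samples$sample_id))
    meth <- matrix(rbinom(n_sites * n_samp, as.vector(total),
                          as.vector(fractions)),
                   n_sites, n_samp, dimnames = list(NULL, samples$sample_id))
    meth_counts(sites, meth, total, samples)
  })

  group <- paste0(samples$age, samples$treatment)
  group_fractions <- vapply(unique(group), function(g)
    rowMeans(fractions[, group == g, drop = FALSE]), numeric(n_sites))

  gene_labels <- rbindlist(lapply(c("CpG", "CHG", "CHH"), function(ctx) {
    lab <- setNames(rep("never_responsive", nrow(genes)), genes$gene_id)
    for (ef in effects) {
      if (ef$context != ctx) next
      lab[ef$gene_id] <- if (setequal(ef$active_in, c("Y", "M")))
        "critical_window"
      else if (setequal(ef$active_in, c("Y", "M", "A")))
        "always_responsive"
      else "other"
    }
    data.table(gene_id = names(lab), context = ctx, label = unname(lab))
  }))

  list(counts = counts,
       truth = list(fractions = fractions, group_fractions = group_fractions,
                    gene_labels = gene_labels, effect_sites = effect_rows))
}
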