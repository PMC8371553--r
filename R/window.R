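#' Per-gene directional responsiveness calls from a contrast
#'
#' A gene is called hypomethylated under a contrast when at least
#' `min_sites_per_call` of its annotated significant hypo sites exist (any
#' feature, including intergenic sites assigned by nearest TSS); analogously
#' for hyper. A gene may appear in both sets when different sites move in
#' different directions.
#'
#' @param contrast_result an `mw_contrast_result` from [run_contrast()].
#' @param annotated annotated sites from [annotate_sites()] covering the
#'   tested sites.
#' @param min_sites_per_call minimum significant sites per gene and direction
#'   (default 1).
#' @param contexts optional character vector restricting contexts.
#' @return list with `hypo_genes`, `hyper_genes` (character vectors) and
#'   `site_counts` (`data.table` gene x direction x context site tallies).
#' @export
gene_calls <- function(contrast_result, annotated, min_sites_per_call = 1L,
                       contexts = NULL) {
  stopifnot(inherits(contrast_result, "mw_contrast_result"))
  min_sites_per_call <- assert_count(min_sites_per_call, "min_sites_per_call")
  res <- contrast_result$results[annotated,
                                 on = c("chrom", "pos", "strand"),
                                 nomatch = NULL]
  if (!is.null(contexts)) res <- res[context %in% contexts]
  sig <- res[direction != "ns" & nzchar(gene_id)]
  counts <- sig[, .(n_sites = .N), by = .(gene_id, direction, context)]
  per_dir <- sig[, .(n_sites = .N), by = .(gene_id, direction)]
  list(hypo_genes = sort(per_dir[direction == "hypo" &
                                   n_sites >= min_sites_per_call, gene_id]),
       hyper_genes = sort(per_dir[direction == "hyper" &
                                    n_sites >= min_sites_per_call, gene_id]),
       site_counts = counts[])
}

#' Critical-window classification across the three treatment contrasts
#'
#' Genes responsive (hypomethylated by treatment) in both young and middle-age
#' form the shared set; those of the shared set that are not responsive in the
#' aged contrast are the candidate critical-window (non-responsive-in-aged)
#' genes, the remainder are responsive at every age. Pure set algebra, order
#' independent; the two output parts are disjoint and their union is the
#' shared set. Set `direction = "hyper"` for the mirror analysis.
#'
#' @param young_calls,middle_calls,aged_calls [gene_calls()] results for the
#'   young, middle-age and aged treatment contrasts (same context).
#' @param context label recorded in the result (informational).
#' @param direction `"hypo"` (default) or `"hyper"`.
#' @return an object of class `mw_window_result`: list with `context`,
#'   `direction`, `shared_young_middle`, `nonresponsive_in_aged`,
#'   `responsive_in_all` (sorted character vectors) and `sizes`.
#' @export
critical_window_genes <- function(young_calls, middle_calls, aged_calls,
                                  context = NA_character_,
                                  direction = c("hypo", "hyper")) {
  direction <- match.arg(direction)
  for (nm in c("young_calls", "middle_calls", "aged_calls")) {
    v <- get(nm)
    if (is.null(v) || !is.list(v) || is.null(v[[paste0(direction, "_genes")]]))
      stop("missing contrast gene calls: ", nm)
  }
  pick <- function(calls) calls[[paste0(direction, "_genes")]]
  shared <- sort(intersect(pick(young_calls), pick(middle_calls)))
  nonresp <- sort(setdiff(shared, pick(aged_calls)))
  resp_all <- sort(intersect(shared, pick(aged_calls)))
  structure(list(context = context, direction = direction,
                 shared_young_middle = shared,
                 nonresponsive_in_aged = nonresp,
                 responsive_in_all = resp_all,
                 sizes = c(shared = length(shared),
                           nonresponsive_in_aged = length(nonresp),
                           responsive_in_all = length(resp_all))),
            class = "mw_window_result")
}

#' @export
print.mw_window_result <- function(x, ...) {
  cat(sprintf("Critical-window result (%s, %smethylation):\n",
              x$context, x$direction))
  cat(sprintf("  shared young+middle: %d; non-responsive in aged: %d; responsive in all: %d\n",
              x$sizes[["shared"]], x$sizes[["nonresponsive_in_aged"]],
              x$sizes[["responsive_in_all"]]))
  invisible(x)
}

#' Tabulate a critical-window result as a membership table
#'
#' @param window an `mw_window_result`.
#' @return `data.table` with `gene_id`, `shared`, `nonresponsive_in_aged`,
#'   `responsive_in_all` logical columns.
#' @export
window_membership <- function(window) {
  stopifnot(inherits(window, "mw_window_result"))
  genes <- window$shared_young_middle
  data.table(gene_id = genes,
             shared = TRUE,
             nonresponsive_in_aged = genes %in% window$nonresponsive_in_aged,
             responsive_in_all = genes %in% window$responsive_in_all)
}
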