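#' Benjamini-Hochberg step-up adjustment
#'
#' Hand-rolled BH step-up: q(i) = cummin over decreasing p of p(i) * m / rank.
#' Permutation invariant, tie preserving, bounded by 1.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @return q-values of the same length and order.
#' @export
bh_adjust <- function(p_values) {
  m <- length(p_values)
  if (!m) return(numeric())
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
}

#' Gene-set collection for over-representation testing
#'
#' @param sets named list of character vectors (annotation gene sets).
#' @param universe character vector of all eligible gene ids; each set is
#'   intersected with the universe before testing.
#' @return an object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), length(sets) >= 1L, !is.null(names(sets)),
            all(nzchar(names(sets))))
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  sets <- lapply(sets, function(s) intersect(unique(as.character(s)),
                                             universe))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation of a query gene set
#'
#' For each annotation set, p is the upper-tail hypergeometric probability of
#' drawing at least the observed overlap when `|query|` genes are sampled
#' without replacement from a universe containing `|set|` annotated genes.
#' q-values are Benjamini-Hochberg adjusted across the collection. Query genes
#' outside the universe are dropped with a message.
#'
#' @param query character vector of gene ids.
#' @param collection a [gene_set_collection()].
#' @return `data.table` with `set_id`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`, ordered by `p`.
#' @export
hypergeom_enrichment <- function(query, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  query <- unique(as.character(query))
  if (!length(query)) stop("empty query gene set")
  outside <- setdiff(query, collection$universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe dropped")
    query <- setdiff(query, outside)
  }
  if (!length(query)) stop("no query gene lies in the universe")
  N <- length(collection$universe)
  k <- length(query)
  res <- rbindlist(lapply(names(collection$sets), function(id) {
    s <- collection$sets[[id]]
    ov <- length(intersect(query, s))
    data.table(set_id = id, overlap = ov, set_size = length(s),
               query_size = k, universe_size = N,
               p = phyper(ov - 1L, length(s), N - length(s), k,
                          lower.tail = FALSE))
  }))
  res[, q := bh_adjust(p)]
  setorder(res, p, set_id)
  res[]
}
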