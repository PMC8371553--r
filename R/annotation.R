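#' Annotation configuration: promoter window and island flank widths
#'
#' The promoter is a window around the TSS (default -1,000 to +1,000 bp,
#' strand-oriented). CpG-island flanks follow the field-standard convention:
#' shores are the 0-2 kb flanks of an island, shelves the 2-4 kb flanks, and
#' everything further is open sea.
#'
#' @param promoter_upstream,promoter_downstream promoter extent around the
#'   TSS, in bases.
#' @param shore_width,shelf_width island flank widths in bases.
#' @return an object of class `annotation_config`.
#' @export
annotation_config <- function(promoter_upstream = 1000L,
                              promoter_downstream = 1000L,
                              shore_width = 2000L, shelf_width = 2000L) {
  for (v in c(promoter_upstream, promoter_downstream, shore_width,
              shelf_width))
    if (!is.numeric(v) || v < 0) stop("annotation widths must be >= 0")
  structure(list(promoter_upstream = as.integer(promoter_upstream),
                 promoter_downstream = as.integer(promoter_downstream),
                 shore_width = as.integer(shore_width),
                 shelf_width = as.integer(shelf_width)),
            class = "annotation_config")
}

gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1L)
}

promoter_intervals <- function(genes, config) {
  tss <- gene_tss(genes)
  up <- config$promoter_upstream; down <- config$promoter_downstream
  lo <- ifelse(genes$strand == "+", tss - up, tss - down)
  hi <- ifelse(genes$strand == "+", tss + down, tss + up)
  data.table(gene_id = genes$gene_id, chrom = genes$chrom,
             lo = pmax(as.integer(lo), 0L), hi = as.integer(hi), tss = tss)
}

# Nearest TSS per site within one chromosome; ties broken by the smaller
# genomic TSS coordinate.
nearest_tss_gene <- function(pos, tss, gene_id) {
  o <- order(tss, gene_id)
  tss_s <- tss[o]; id_s <- gene_id[o]
  i <- findInterval(pos, tss_s)
  left <- pmax(i, 1L); right <- pmin(i + 1L, length(tss_s))
  d_left <- abs(pos - tss_s[left]); d_left[i == 0L] <- Inf
  d_right <- abs(pos - tss_s[right]); d_right[i >= length(tss_s)] <- Inf
  # tie (equidistant): prefer the smaller coordinate, i.e. the left TSS
  ifelse(d_left <= d_right, id_s[left], id_s[right])
}

#' Annotate sites with genic feature, assigned gene, and island zone
#'
#' Feature precedence is promoter > exon > intron > intergenic (promoters win
#' over the gene body, mirroring the HOMER hierarchy). Promoter and genic
#' sites take the matching gene (nearest TSS when promoters overlap);
#' intergenic sites take the gene with the nearest TSS, ties broken by the
#' smaller TSS coordinate. Island zoning is by distance from the nearest
#' island edge: inside an island, shore within `shore_width`, shelf within
#' `shore_width + shelf_width`, open sea beyond; overlapping flanks resolve to
#' the nearer island automatically. Sites on chromosomes without gene models
#' are annotated intergenic with an empty `gene_id` and a warning.
#'
#' @param sites `data.table` with `chrom`, `pos` (0-based), `strand`.
#' @param genes gene models (as from [generate_genome()] or
#'   [read_genes_bed12()]).
#' @param islands island `data.table` (`chrom`, `start`, `end`, 0-based
#'   half-open).
#' @param config an [annotation_config()].
#' @return copy of `sites` with `feature`, `gene_id`, `island_zone` columns.
#' @export
annotate_sites <- function(sites, genes, islands,
                           config = annotation_config()) {
  stopifnot(inherits(config, "annotation_config"))
  sites <- copy(as.data.table(sites))
  genes <- as.data.table(genes)
  n <- nrow(sites)
  sites[, feature := "intergenic"]
  sites[, gene_id := ""]
  sites[, island_zone := "open_sea"]
  if (!n) return(sites[])

  gr_sites <- GenomicRanges::GRanges(
    sites$chrom, IRanges::IRanges(sites$pos + 1L, sites$pos + 1L))

  if (nrow(genes)) {
    unknown <- !sites$chrom %in% unique(genes$chrom)
    if (any(unknown))
      warning(sum(unknown), " site(s) on chromosome(s) without gene models; ",
              "annotated intergenic with empty gene_id")

    # nearest TSS per chromosome (default assignment, also the intergenic one)
    tss_tab <- data.table(chrom = genes$chrom, tss = gene_tss(genes),
                          gene_id = genes$gene_id)
    for (ch in unique(tss_tab$chrom)) {
      rows <- which(sites$chrom == ch)
      if (!length(rows)) next
      tt <- tss_tab[chrom == ch]
      sites[rows, gene_id := nearest_tss_gene(sites$pos[rows], tt$tss,
                                              tt$gene_id)]
    }

    prom <- promoter_intervals(genes, config)
    gr_prom <- GenomicRanges::GRanges(
      prom$chrom, IRanges::IRanges(prom$lo + 1L, prom$hi + 1L))
    exons <- genes[, .(start = unlist(exon_starts), end = unlist(exon_ends)),
                   by = .(gene_id, chrom)]
    gr_exon <- GenomicRanges::GRanges(
      exons$chrom, IRanges::IRanges(exons$start + 1L, exons$end))
    gr_gene <- GenomicRanges::GRanges(
      genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end))

    hit_gene <- GenomicRanges::findOverlaps(gr_sites, gr_gene,
                                            select = "first")
    in_gene <- !is.na(hit_gene)
    sites[in_gene, `:=`(feature = "intron",
                        gene_id = genes$gene_id[hit_gene[in_gene]])]
    hit_exon <- GenomicRanges::findOverlaps(gr_sites, gr_exon,
                                            select = "first")
    in_exon <- !is.na(hit_exon)
    sites[in_exon, `:=`(feature = "exon",
                        gene_id = exons$gene_id[hit_exon[in_exon]])]

    hit_prom <- GenomicRanges::findOverlaps(gr_sites, gr_prom)
    if (length(hit_prom)) {
      hp <- data.table(site = S4Vectors::queryHits(hit_prom),
                       gene = S4Vectors::subjectHits(hit_prom))
      hp[, d := abs(sites$pos[site] - prom$tss[gene])]
      hp[, tss := prom$tss[gene]]
      setorder(hp, site, d, tss)
      hp <- hp[!duplicated(site)]
      sites[hp$site, `:=`(feature = "promoter", gene_id = prom$gene_id[hp$gene])]
    }
    sites[unknown, `:=`(feature = "intergenic", gene_id = "")]
  }

  if (nrow(islands)) {
    gr_isl <- GenomicRanges::GRanges(
      islands$chrom, IRanges::IRanges(islands$start + 1L, islands$end))
    dtn <- GenomicRanges::distanceToNearest(gr_sites, gr_isl)
    q <- S4Vectors::queryHits(dtn)
    d <- S4Vectors::mcols(dtn)$distance
    inside <- rep(FALSE, n)
    ov <- GenomicRanges::findOverlaps(gr_sites, gr_isl, select = "first")
    inside[!is.na(ov)] <- TRUE
    zone <- rep("open_sea", n)
    zone[q[d <= config$shore_width + config$shelf_width]] <- "shelf"
    zone[q[d <= config$shore_width]] <- "shore"
    zone[inside] <- "island"
    sites[, island_zone := zone]
  }
  sites[]
}

#' Classify one or more positions into island/shore/shelf/open-sea
#'
#' Convenience scalar/vector wrapper around the zoning rule of
#' [annotate_sites()].
#'
#' @param chrom,pos site coordinates (0-based).
#' @param islands island `data.table`.
#' @param config an [annotation_config()].
#' @return character vector of zones.
#' @export
annotate_island_zone <- function(chrom, pos, islands,
                                 config = annotation_config()) {
  sites <- data.table(chrom = chrom, pos = as.integer(pos), strand = "+")
  annotate_sites(sites, genes = data.table(), islands = islands,
                 config = config)$island_zone
}

#' Annotate the genic feature of one or more positions
#'
#' Convenience wrapper around [annotate_sites()] returning the feature and the
#' assigned gene.
#'
#' @param chrom,pos site coordinates (0-based).
#' @param genes gene models.
#' @param config an [annotation_config()].
#' @return `data.table` with `feature` and `gene_id`.
#' @export
annotate_feature <- function(chrom, pos, genes,
                             config = annotation_config()) {
  sites <- data.table(chrom = chrom, pos = as.integer(pos), strand = "+")
  annotate_sites(sites, genes = genes, islands = data.table(),
                 config = config)[, .(feature, gene_id)]
}

#' Cross-tabulate a contrast's significant sites by annotation
#'
#' Produces the hyper/hypo decomposition tables by chromosome, by genic
#' feature (promoter, gene body = exon + intron, intergenic) and by island
#' zone. Row sums of every table equal the contrast's hyper and hypo totals.
#'
#' @param contrast_result an `mw_contrast_result` from [run_contrast()].
#' @param annotated annotated sites from [annotate_sites()] covering the
#'   tested sites.
#' @return list of `data.table`s: `by_chromosome`, `by_feature`,
#'   `by_island_zone`, plus scalars `n_hyper`, `n_hypo`.
#' @export
summarize_contrast <- function(contrast_result, annotated) {
  stopifnot(inherits(contrast_result, "mw_contrast_result"))
  res <- contrast_result$results[annotated,
                                 on = c("chrom", "pos", "strand"),
                                 nomatch = NULL]
  if (nrow(res) < nrow(contrast_result$results))
    stop("annotation does not cover every tested site")
  res[, feature_group := ifelse(feature %in% c("exon", "intron"),
                                "gene_body", feature)]
  tab <- function(key, levels) {
    t0 <- res[, .(n_hyper = sum(direction == "hyper"),
                  n_hypo = sum(direction == "hypo")), by = key]
    setnames(t0, key, "level")
    all_lv <- data.table(level = levels)
    t0 <- t0[all_lv, on = "level"]
    t0[is.na(n_hyper), n_hyper := 0L]
    t0[is.na(n_hypo), n_hypo := 0L]
    t0[]
  }
  list(by_chromosome = tab("chrom", sort(unique(res$chrom))),
       by_feature = tab("feature_group",
                        c("promoter", "gene_body", "intergenic")),
       by_island_zone = tab("island_zone",
                            c("island", "shore", "shelf", "open_sea")),
       n_hyper = sum(res$direction == "hyper"),
       n_hypo = sum(res$direction == "hypo"))
}
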