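#' Read and write the package's plain-text interchange formats
#'
#' Genomes travel as FASTA (via Biostrings), gene models as BED12 (0-based
#' half-open; blocks are exons; thickStart/thickEnd unused), islands as BED3,
#' sample sheets as TSV with header `sample_id age treatment kit`, aligned
#' reads as a minimal SAM subset (`@SQ` header lines; records with MAPQ 60,
#' CIGAR `<len>M`, FLAG 0/16), per-site counts as cytosine-report TSV, and
#' gene-set collections as GMT.
#'
#' @param genome named character vector of chromosome sequences.
#' @param path file path.
#' @name io
NULL

#' @rdname io
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' @rdname io
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' @rdname io
#' @param genes gene-model `data.table` as produced by [generate_genome()].
#' @export
write_genes_bed12 <- function(genes, path) {
  lines <- vapply(seq_len(nrow(genes)), function(i) {
    es <- genes$exon_starts[[i]]; ee <- genes$exon_ends[[i]]
    paste(genes$chrom[i], genes$start[i], genes$end[i], genes$gene_id[i], 0,
          genes$strand[i], genes$start[i], genes$start[i], "0",
          length(es), paste0(paste(ee - es, collapse = ","), ","),
          paste0(paste(es - genes$start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname io
#' @export
read_genes_bed12 <- function(path) {
  bed <- fread(path, header = FALSE, sep = "\t")
  if (ncol(bed) < 12L) stop("expected BED12, got ", ncol(bed), " columns")
  setnames(bed, 1:12, c("chrom", "start", "end", "gene_id", "score", "strand",
                        "thickStart", "thickEnd", "rgb", "n_blocks",
                        "block_sizes", "block_starts"))
  parse_ints <- function(s) as.integer(strsplit(sub(",$", "", s), ",")[[1]])
  bed[, exon_starts := mapply(function(st, bs) st + parse_ints(bs),
                              start, block_starts, SIMPLIFY = FALSE)]
  bed[, exon_ends := mapply(function(es, sz) es + parse_ints(sz),
                            exon_starts, block_sizes, SIMPLIFY = FALSE)]
  bed[, .(gene_id, chrom, start, end, strand, exon_starts, exon_ends)]
}

#' @rdname io
#' @param islands BED3-shaped `data.table` (`chrom`, `start`, `end`).
#' @export
write_islands_bed <- function(islands, path) {
  fwrite(islands[, c("chrom", "start", "end")], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_islands_bed <- function(path) {
  bed <- fread(path, header = FALSE, sep = "\t", select = 1:3,
               col.names = c("chrom", "start", "end"))
  bed[]
}

#' @rdname io
#' @param samples sample-sheet `data.table`.
#' @export
write_sample_sheet <- function(samples, path) {
  fwrite(samples, path, sep = "\t")
  invisible(path)
}

#' @rdname io
#' @export
read_sample_sheet <- function(path) {
  samples <- fread(path, sep = "\t", colClasses = "character")
  need <- c("sample_id", "age", "treatment", "kit")
  if (!all(need %in% names(samples)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  samples[]
}

#' @rdname io
#' @param reads read set `data.table` from [simulate_reads()] or [read_sam()]:
#'   columns `qname`, `chrom`, `pos` (0-based leftmost), `strand`, `seq`
#'   (bisulfite-space sequence, 5'->3' of the sequenced molecule).
#' @export
write_sam <- function(reads, genome, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(genome), nchar(genome)))
  flag <- ifelse(reads$strand == "+", 0L, 16L)
  seq_out <- reads$seq
  neg <- reads$strand == "-"
  if (any(neg)) seq_out[neg] <- revcomp(seq_out[neg])  # SAM stores ref orientation
  rec <- paste(reads$qname, flag, reads$chrom, reads$pos + 1L, 60L,
               paste0(nchar(reads$seq), "M"), "*", 0L, 0L, seq_out, "*",
               sep = "\t")
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' @rdname io
#' @return `read_sam()` returns a list with `reads` (bisulfite-space, as for
#'   [write_sam()]) and `n_malformed`, the count of skipped records.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, function(f) {
    length(f) >= 10L && !is.na(suppressWarnings(as.integer(f[2]))) &&
      !is.na(suppressWarnings(as.integer(f[4]))) && grepl("^[0-9]+M$", f[6])
  }, logical(1))
  n_malformed <- sum(!ok)
  if (n_malformed)
    warning(n_malformed, " malformed SAM record(s) skipped")
  fields <- fields[ok]
  if (!length(fields))
    return(list(reads = data.table(qname = character(), chrom = character(),
                                   pos = integer(), strand = character(),
                                   seq = character()),
                n_malformed = n_malformed))
  flag <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  seqs <- vapply(fields, `[`, character(1), 10L)
  neg <- bitwAnd(flag, 16L) == 16L
  if (any(neg)) seqs[neg] <- revcomp(seqs[neg])
  reads <- data.table(
    qname = vapply(fields, `[`, character(1), 1L),
    chrom = vapply(fields, `[`, character(1), 3L),
    pos = vapply(fields, function(f) as.integer(f[4]), integer(1)) - 1L,
    strand = ifelse(neg, "-", "+"),
    seq = seqs)
  list(reads = reads, n_malformed = n_malformed)
}

#' @rdname io
#' @param counts per-site count `data.table` for one sample with columns
#'   `chrom`, `pos` (0-based), `strand`, `n_methylated`, `n_unmethylated`,
#'   `context`, `tri`.
#' @export
write_cytosine_report <- function(counts, path) {
  out <- counts[, .(chrom, pos = pos + 1L, strand, n_methylated,
                    n_unmethylated, context, tri)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname io
#' @export
read_cytosine_report <- function(path) {
  counts <- fread(path, header = FALSE, sep = "\t",
                  col.names = c("chrom", "pos", "strand", "n_methylated",
                                "n_unmethylated", "context", "tri"))
  counts[, pos := pos - 1L]
  counts[]
}

#' @rdname io
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(fields, length, integer(1)) < 3L
  if (any(bad)) stop("GMT lines need at least 3 tab-separated fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1L)
  descriptions <- vapply(fields, `[`, character(1), 2L)
  list(sets = sets, descriptions = setNames(descriptions, names(sets)))
}

#' @rdname io
#' @param sets named list of character vectors (gene sets).
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
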