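#' Lone-cytosine statistics of bisulfite read sequences
#'
#' A "lone" cytosine is a read C that is part of neither a CG nor a GC
#' dinucleotide (no G immediately before or after it). After bisulfite
#' conversion, read cytosines should be almost exclusively methylated CpGs, so
#' an excess of lone cytosines marks an incompletely converted read. Both
#' statistics are evaluated on the read sequence itself (bisulfite space), not
#' on the reference.
#'
#' `lone_cytosine_fraction()` returns lone C / total C (0 for reads with no C);
#' `lone_cytosine_count()` returns the absolute lone-C count.
#'
#' @param read_sequence character vector of read sequences over A/C/G/T/N.
#' @return numeric (fraction) or integer (count) vector, one value per read.
#' @export
lone_cytosine_fraction <- function(read_sequence) {
  n_lone <- lone_cytosine_count(read_sequence)
  n_c <- count_matches("C", read_sequence)
  ifelse(n_c == 0L, 0, n_lone / n_c)
}

#' @rdname lone_cytosine_fraction
#' @export
lone_cytosine_count <- function(read_sequence) {
  count_matches("(?<!G)C(?!G)", read_sequence, perl = TRUE)
}

count_matches <- function(pattern, x, perl = FALSE) {
  if (!length(x)) return(integer())
  m <- gregexpr(pattern, x, perl = perl, fixed = !perl)
  vapply(m, function(mi) if (mi[1] == -1L) 0L else length(mi), integer(1))
}

#' Read-filter configuration for bisulfite conversion QC
#'
#' @param max_lone_fraction remove a read when its lone-cytosine load exceeds
#'   this fraction (default 0.05).
#' @param max_lone_count optional absolute cap on lone cytosines per read;
#'   `NULL` (default) disables it.
#' @param denominator what the lone-cytosine count is divided by:
#'   `"read_length"` (default; stable per-read statistic) or `"cytosines"`
#'   (the ratio returned by [lone_cytosine_fraction()], which for converted
#'   reads has a denominator of only a handful of retained cytosines and makes
#'   single methylated non-CpG cytosines fatal — see the methods vignette).
#' @return an object of class `read_filter_config`.
#' @export
read_filter_config <- function(max_lone_fraction = 0.05,
                               max_lone_count = NULL,
                               denominator = c("read_length", "cytosines")) {
  assert_fraction(max_lone_fraction, "max_lone_fraction")
  if (!is.null(max_lone_count))
    max_lone_count <- assert_count(max_lone_count, "max_lone_count", min = 0L)
  structure(list(max_lone_fraction = max_lone_fraction,
                 max_lone_count = max_lone_count,
                 denominator = match.arg(denominator)),
            class = "read_filter_config")
}

#' Remove incompletely converted reads
#'
#' A read is removed iff its lone-cytosine fraction exceeds
#' `max_lone_fraction`, or (when `max_lone_count` is enabled) its lone count
#' exceeds that cap. Removal is per read and order-preserving.
#'
#' @param reads read `data.table` (from [simulate_reads()] or [read_sam()])
#'   with a `seq` column in bisulfite space.
#' @param filter_config a [read_filter_config()].
#' @return list with `reads` (retained, original order), `removed` (the
#'   dropped rows) and `n_removed`.
#' @export
filter_reads <- function(reads, filter_config = read_filter_config()) {
  stopifnot(inherits(filter_config, "read_filter_config"))
  reads <- as.data.table(reads)
  n_lone <- lone_cytosine_count(reads$seq)
  frac <- switch(filter_config$denominator,
                 read_length = n_lone / pmax(nchar(reads$seq), 1L),
                 cytosines = lone_cytosine_fraction(reads$seq))
  drop <- frac > filter_config$max_lone_fraction
  if (!is.null(filter_config$max_lone_count))
    drop <- drop | n_lone > filter_config$max_lone_count
  list(reads = reads[!drop], removed = reads[drop], n_removed = sum(drop))
}

#' Call per-site methylation from retained reads
#'
#' For every strand-relative reference cytosine covered by a read, the read
#' base at that position contributes one observation: C is methylated, T is
#' unmethylated, anything else is ignored. Sites with zero observations are
#' omitted. Reads extending past their chromosome end are rejected (dropped
#' with a warning).
#'
#' @param reads retained reads (bisulfite-space `seq`).
#' @param genome named character vector of chromosome sequences.
#' @param sample_id sample label attached to the output.
#' @param sites optional precomputed [cytosine_sites()] table (an
#'   optimization when calling many samples on one genome).
#' @return `data.table` with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `tri`, `n_methylated`, `n_unmethylated`, `n_total`,
#'   `sample_id`.
#' @export
call_methylation <- function(reads, genome, sample_id = "S1", sites = NULL) {
  reads <- as.data.table(reads)
  bad_chrom <- !reads$chrom %in% names(genome)
  too_long <- !bad_chrom &
    reads$pos + nchar(reads$seq) > nchar(genome)[reads$chrom]
  if (any(bad_chrom | too_long)) {
    warning(sum(bad_chrom | too_long),
            " read(s) rejected (unknown chromosome or past chromosome end)")
    reads <- reads[!(bad_chrom | too_long)]
  }
  sites <- sites %||% cytosine_sites(genome)
  empty <- data.table(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      tri = character(), n_methylated = integer(),
                      n_unmethylated = integer(), n_total = integer(),
                      sample_id = character())
  if (!nrow(reads)) return(empty)

  rl <- nchar(reads$seq)
  ref <- substring(genome[reads$chrom], reads$pos + 1L, reads$pos + rl)
  templ_ref <- ref
  neg <- reads$strand == "-"
  if (any(neg)) templ_ref[neg] <- revcomp(templ_ref[neg])

  cpos <- gregexpr("C", templ_ref, fixed = TRUE)
  n_c <- vapply(cpos, function(m) if (m[1] == -1L) 0L else length(m),
                integer(1))
  if (!sum(n_c)) return(empty)
  read_id <- rep.int(seq_len(nrow(reads)), n_c)
  off <- unlist(lapply(cpos, function(m) if (m[1] == -1L) integer() else m),
                use.names = FALSE)
  gpos <- ifelse(reads$strand[read_id] == "+",
                 reads$pos[read_id] + off - 1L,
                 reads$pos[read_id] + rl[read_id] - off)
  base <- substring(reads$seq[read_id], off, off)

  obs <- data.table(chrom = reads$chrom[read_id], pos = as.integer(gpos),
                    strand = reads$strand[read_id], base = base)
  obs <- obs[base %in% c("C", "T")]
  tallies <- obs[, .(n_methylated = sum(base == "C"),
                     n_unmethylated = sum(base == "T")),
                 by = .(chrom, pos, strand)]
  out <- sites[tallies, on = c("chrom", "pos", "strand")]
  out[, n_total := n_methylated + n_unmethylated]
  out[, sample_id := sample_id]
  setorder(out, chrom, pos, strand)
  out[]
}

#' Assemble an [meth_counts()] object from per-sample calls
#'
#' Aligns a list of per-sample call tables (as returned by
#' [call_methylation()]) on the union of covered sites; uncovered cells get
#' zero totals.
#'
#' @param calls named list of per-sample call tables; names are sample ids.
#' @param samples sample sheet covering those ids.
#' @return an [meth_counts()] object.
#' @export
counts_from_calls <- function(calls, samples) {
  samples <- as.data.table(samples)
  stopifnot(all(names(calls) %in% samples$sample_id))
  samples <- samples[samples$sample_id %in% names(calls)]
  sites <- unique(rbindlist(lapply(calls, function(x)
    x[, .(chrom, pos, strand, context)])))
  setorder(sites, chrom, pos, strand)
  n <- nrow(sites)
  meth <- total <- matrix(0L, n, nrow(samples),
                          dimnames = list(NULL, samples$sample_id))
  for (sid in samples$sample_id) {
    idx <- sites[calls[[sid]], on = c("chrom", "pos", "strand"), which = TRUE]
    meth[idx, sid] <- calls[[sid]]$n_methylated
    total[idx, sid] <- calls[[sid]]$n_total
  }
  meth_counts(sites, meth, total, samples)
}
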