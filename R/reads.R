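#' Simulate aligned bisulfite reads for one sample
#'
#' Reads of `config$read_length` are drawn with uniformly random start
#' positions; the strand alternates deterministically (odd reads plus, even
#' reads minus) so both strands are always covered. For every cytosine of the
#' read's strand, the molecule is methylated with the site's true methylation
#' fraction; a methylated cytosine is emitted as C, an unmethylated one is
#' converted to T with the read's bisulfite conversion rate
#' (`conversion_rate_converted` for normal reads, `conversion_rate_failed` for
#' the `failed_read_fraction` of conversion-failed reads) and left as C
#' otherwise. All other bases are copied from the reference. Sequences are
#' stored in bisulfite space (5'->3' of the sequenced molecule); [write_sam()]
#' flips minus-strand reads into reference orientation.
#'
#' @param genome named character vector of chromosome sequences.
#' @param truth per-site true methylation fractions for this sample:
#'   a `data.table` with `chrom`, `pos`, `strand`, `fraction` covering every
#'   reference cytosine (e.g. one column of `simulate_methylomes()$truth`
#'   joined to its sites).
#' @param config a [sim_config()].
#' @param n_reads number of reads; default achieves `coverage_mean` on
#'   average over the genome.
#' @param sample_id label used in read names.
#' @param seed RNG seed; defaults to a child of `config$seed`.
#' @return `data.table` with columns `qname`, `chrom`, `pos` (0-based leftmost
#'   reference position), `strand`, `seq`, and the ground-truth flag `failed`.
#' @export
simulate_reads <- function(genome, truth, config, n_reads = NULL,
                           sample_id = "S1", seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  rl <- config$read_length
  lens <- nchar(genome)
  if (any(rl > lens))
    stop("read_length ", rl, " exceeds a chromosome length")
  truth <- as.data.table(truth)
  stopifnot(all(c("chrom", "pos", "strand", "fraction") %in% names(truth)))
  setkey(truth, chrom, pos, strand)
  n_reads <- n_reads %||%
    as.integer(ceiling(config$coverage_mean * sum(lens) / rl))
  seed <- seed %||% child_seed(config$seed, 3L)

  with_seed(seed, {
    chrom <- sample(names(genome), n_reads, replace = TRUE,
                    prob = lens / sum(lens))
    start <- floor(runif(n_reads) * (lens[chrom] - rl + 1L))
    strand <- ifelse(seq_len(n_reads) %% 2L == 1L, "+", "-")
    failed <- runif(n_reads) < config$failed_read_fraction
    conv <- ifelse(failed, config$conversion_rate_failed,
                   config$conversion_rate_converted)

    ref <- substring(genome[chrom], start + 1L, start + rl)
    templ <- ref
    neg <- strand == "-"
    if (any(neg)) templ[neg] <- revcomp(templ[neg])

    # explode to (read, offset) pairs at template cytosines
    cpos <- gregexpr("C", templ, fixed = TRUE)
    n_c <- vapply(cpos, function(m) if (m[1] == -1L) 0L else length(m),
                  integer(1))
    read_id <- rep.int(seq_len(n_reads), n_c)
    off <- unlist(lapply(cpos, function(m) if (m[1] == -1L) integer() else m),
                  use.names = FALSE)
    if (length(off)) {
      gpos <- ifelse(strand[read_id] == "+",
                     start[read_id] + off - 1L,
                     start[read_id] + rl - off)
      key <- data.table(chrom = chrom[read_id], pos = as.integer(gpos),
                        strand = strand[read_id])
      frac <- truth[key, x.fraction, on = c("chrom", "pos", "strand")]
      if (anyNA(frac))
        stop("methylome truth missing for ", sum(is.na(frac)),
             " covered cytosine(s)")
      methylated <- runif(length(frac)) < frac
      converted <- !methylated & (runif(length(frac)) < conv[read_id])
      if (any(converted)) {
        ch_list <- strsplit(templ, "", fixed = TRUE)
        ri <- read_id[converted]; oi <- off[converted]
        conv_by_read <- split(oi, ri)
        for (nm in names(conv_by_read)) {
          i <- as.integer(nm)
          ch_list[[i]][conv_by_read[[nm]]] <- "T"
        }
        templ <- vapply(ch_list, paste, character(1), collapse = "")
      }
    }
    data.table(qname = sprintf("%s_read%06d", sample_id, seq_len(n_reads)),
               chrom = chrom, pos = as.integer(start), strand = strand,
               seq = templ, failed = failed)
  })
}
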