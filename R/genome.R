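#' Generate a toy genome with gene models and CpG islands
#'
#' Chromosome sequences are i.i.d. bases at the configured GC content. With
#' `cpg_oe < 1`, background CpG dinucleotides are depleted by in-place
#' CpG -> TpG replacement (the deamination mechanism that shaped real mammalian
#' genomes), sparing the islands. Islands are then CpG-enriched by planting
#' additional CG dinucleotides until their expected density is
#' `island_cpg_boost` times the i.i.d. expectation. Genes are laid out
#' non-overlapping, one equal territory per gene, with strand alternating and
#' two exons flanking a central intron; islands are evenly spaced along each
#' chromosome. Everything is a pure function of `config` (including its seed).
#'
#' @param config a [sim_config()] object.
#' @return list with elements
#'   \describe{
#'     \item{genome}{named character vector of chromosome sequences.}
#'     \item{genes}{`data.table`: `gene_id`, `chrom`, `start`, `end` (0-based
#'       half-open), `strand`, and list-columns `exon_starts`, `exon_ends`.}
#'     \item{islands}{`data.table`: `chrom`, `start`, `end` (0-based half-open).}
#'   }
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(child_seed(config$seed, 1L), {
    n_chrom <- config$n_chromosomes
    chrom_len <- config$genome_length %/% n_chrom
    chroms <- paste0("chr", seq_len(n_chrom))
    p <- c(A = (1 - config$gc_content) / 2, C = config$gc_content / 2,
           G = config$gc_content / 2, T = (1 - config$gc_content) / 2)

    islands <- place_islands(config, chroms, chrom_len)
    genes <- place_genes(config, chroms, chrom_len)

    genome <- setNames(vector("character", n_chrom), chroms)
    for (ch in chroms) {
      bases <- sample(names(p), chrom_len, replace = TRUE, prob = p)
      isl <- islands[islands$chrom == ch]
      in_island <- rep(FALSE, chrom_len)
      if (nrow(isl))
        for (k in seq_len(nrow(isl)))
          in_island[(isl$start[k] + 1L):isl$end[k]] <- TRUE

      if (config$cpg_oe < 1) {
        cg <- which(bases[-chrom_len] == "C" & bases[-1L] == "G")
        cg <- cg[!in_island[cg] & !in_island[cg + 1L]]
        kill <- cg[runif(length(cg)) > config$cpg_oe]
        if (length(kill)) bases[kill] <- "T"
      }

      if (nrow(isl) && config$island_cpg_boost > 1) {
        d0 <- (config$gc_content / 2)^2  # i.i.d. CG density per dinucleotide
        for (k in seq_len(nrow(isl))) {
          len <- isl$end[k] - isl$start[k]
          n_add <- round((config$island_cpg_boost - 1) * d0 * len)
          if (n_add > 0) {
            # plant CG at even offsets so planted dinucleotides cannot overlap
            slots <- seq(isl$start[k] + 1L, isl$end[k] - 1L, by = 2L)
            pos <- sample(slots, min(n_add, length(slots)))
            bases[pos] <- "C"; bases[pos + 1L] <- "G"
          }
        }
      }
      genome[[ch]] <- paste(bases, collapse = "")
    }
    list(genome = genome, genes = genes, islands = islands)
  })
}

place_genes <- function(config, chroms, chrom_len) {
  n_chrom <- length(chroms)
  idx <- seq_len(config$n_genes) - 1L
  chrom_of <- idx %% n_chrom + 1L
  rank_on <- integer(config$n_genes)
  for (c_i in seq_len(n_chrom))
    rank_on[chrom_of == c_i] <- seq_len(sum(chrom_of == c_i)) - 1L
  per_chrom <- tabulate(chrom_of, n_chrom)
  territory <- ifelse(per_chrom > 0, chrom_len %/% pmax(per_chrom, 1L), chrom_len)
  gl <- config$gene_length
  start <- rank_on * territory[chrom_of] +
    pmax((territory[chrom_of] - gl) %/% 2L, 0L)
  end <- start + gl
  strand <- ifelse(idx %% 2L == 0L, "+", "-")
  # two exons (30% each end) around one central intron
  e_len <- pmax(gl %/% 10L * 3L, 1L)
  genes <- data.table(
    gene_id = sprintf("gene%03d", idx + 1L),
    chrom = chroms[chrom_of], start = as.integer(start), end = as.integer(end),
    strand = strand)
  genes[, `:=`(exon_starts = mapply(function(s, e) c(s, e - e_len),
                                    start, end, SIMPLIFY = FALSE),
               exon_ends = mapply(function(s, e) c(s + e_len, e),
                                  start, end, SIMPLIFY = FALSE))]
  genes[]
}

place_islands <- function(config, chroms, chrom_len) {
  if (config$n_islands == 0L)
    return(data.table(chrom = character(), start = integer(), end = integer()))
  n_chrom <- length(chroms)
  idx <- seq_len(config$n_islands) - 1L
  chrom_of <- idx %% n_chrom + 1L
  rank_on <- integer(config$n_islands)
  for (c_i in seq_len(n_chrom))
    rank_on[chrom_of == c_i] <- seq_len(sum(chrom_of == c_i))
  per_chrom <- tabulate(chrom_of, n_chrom)
  centre <- (rank_on * chrom_len) %/% (per_chrom[chrom_of] + 1L)
  start <- pmax(centre - config$island_length %/% 2L, 0L)
  end <- pmin(start + config$island_length, chrom_len)
  data.table(chrom = chroms[chrom_of], start = as.integer(start),
             end = as.integer(end))
}

#' Enumerate every strand-relative reference cytosine with its context
#'
#' Walks both strands of each chromosome and returns one row per reference
#' cytosine (a C on the plus strand, a G on the minus strand), classified as
#' CpG, CHG or CHH from the strand-relative downstream bases. Windows truncated
#' by a chromosome end default to CHH.
#'
#' @param genome named character vector of chromosome sequences.
#' @return `data.table` with columns `chrom`, `pos` (0-based position of the
#'   strand-relative C on the reference), `strand`, `context`, `tri`
#'   (strand-relative trinucleotide, padded with N at chromosome ends).
#' @export
cytosine_sites <- function(genome) {
  out <- lapply(names(genome), function(ch) {
    chars <- strsplit(genome[[ch]], "", fixed = TRUE)[[1]]
    n <- length(chars)
    res <- list()
    plus <- which(chars == "C")
    if (length(plus)) {
      n1 <- ifelse(plus + 1L <= n, chars[pmin(plus + 1L, n)], "N")
      n2 <- ifelse(plus + 2L <= n, chars[pmin(plus + 2L, n)], "N")
      res$p <- data.table(chrom = ch, pos = plus - 1L, strand = "+",
                          context = context_from_next(n1, n2),
                          tri = paste0("C", n1, n2))
    }
    minus <- which(chars == "G")
    if (length(minus)) {
      n1 <- ifelse(minus - 1L >= 1L,
                   COMPLEMENT[chars[pmax(minus - 1L, 1L)]], "N")
      n2 <- ifelse(minus - 2L >= 1L,
                   COMPLEMENT[chars[pmax(minus - 2L, 1L)]], "N")
      res$m <- data.table(chrom = ch, pos = minus - 1L, strand = "-",
                          context = context_from_next(unname(n1), unname(n2)),
                          tri = paste0("C", n1, n2))
    }
    rbindlist(res)
  })
  sites <- rbindlist(out)
  setorder(sites, chrom, pos, strand)
  sites[]
}

context_from_next <- function(n1, n2) {
  ifelse(n1 == "G", "CpG", ifelse(n2 == "G", "CHG", "CHH"))
}

#' Classify the sequence context of a reference cytosine
#'
#' @param genome named character vector of chromosome sequences.
#' @param chrom chromosome name.
#' @param pos 0-based position(s) of the cytosine on the reference.
#' @param strand `"+"` or `"-"` (recycled); on the minus strand the reference
#'   base must be G and the context is read from the reverse complement.
#' @return character vector of contexts (`"CpG"`, `"CHG"`, `"CHH"`).
#' @export
classify_context <- function(genome, chrom, pos, strand = "+") {
  stopifnot(chrom %in% names(genome))
  chars <- strsplit(genome[[chrom]], "", fixed = TRUE)[[1]]
  n <- length(chars)
  pos <- as.integer(pos)
  strand <- rep_len(strand, length(pos))
  if (any(pos < 0L | pos >= n)) stop("position out of chromosome bounds")
  base <- chars[pos + 1L]
  bad <- (strand == "+" & base != "C") | (strand == "-" & base != "G")
  if (any(bad))
    stop("reference base at position ", pos[which(bad)[1]],
         " is not a strand-relative cytosine")
  n1 <- ifelse(strand == "+",
               ifelse(pos + 2L <= n, chars[pmin(pos + 2L, n)], "N"),
               ifelse(pos >= 1L, COMPLEMENT[chars[pmax(pos, 1L)]], "N"))
  n2 <- ifelse(strand == "+",
               ifelse(pos + 3L <= n, chars[pmin(pos + 3L, n)], "N"),
               ifelse(pos >= 2L, COMPLEMENT[chars[pmax(pos - 1L, 1L)]], "N"))
  unname(context_from_next(n1, n2))
}
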