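#' Parse a flat TOML-style run configuration file
#'
#' The file format is a minimal typed key-value subset of TOML: `[section]`
#' headers, `key = value` lines, `#` comments, with bare numbers, `true` /
#' `false`, quoted strings and flat arrays (`["a", "b"]` / `[1, 2]`).
#' Recognized sections map onto the stage configurations: `[pipeline]`
#' (out_dir, seed, use_reads, contexts, min_sites_per_call, gmt, input
#' paths...), `[simulation]` (arguments of [sim_config()]), `[filter]`
#' ([read_filter_config()]), `[unite]` ([unite_config()]), `[annotation]`
#' ([annotation_config()]) and `[enrichment]` (fdr_threshold,
#' directed_p_threshold).
#'
#' @param path config file path.
#' @param overrides named list overriding `[pipeline]` keys (CLI flags).
#' @return a [run_config()].
#' @export
parse_run_config <- function(path, overrides = list()) {
  raw <- parse_toml_lite(path)
  pl <- utils::modifyList(raw$pipeline %||% list(), overrides)
  if (is.null(pl$out_dir)) stop("[pipeline] out_dir is required")
  seed <- as.integer(pl$seed %||% 1L)

  sim_args <- raw$simulation %||% list()
  if (!is.null(sim_args$group_sizes))
    stop("group_sizes cannot be set from the config file; use the API")
  sim_args$seed <- sim_args$seed %||% seed
  sim <- do.call(sim_config, sim_args)
  if (isTRUE(pl$default_planted_effects)) {
    world <- generate_genome(sim)
    sim$planted_effects <- default_planted_effects(
      world$genes,
      n_critical = as.integer(pl$n_critical %||% 10L),
      n_always = as.integer(pl$n_always %||% 10L))
  }

  run_config(
    out_dir = pl$out_dir, seed = seed,
    simulate = pl$simulate %||% TRUE,
    use_reads = pl$use_reads %||% FALSE,
    genome_fasta = pl$genome_fasta, genes_bed = pl$genes_bed,
    islands_bed = pl$islands_bed, sample_sheet = pl$sample_sheet,
    reports_dir = pl$reports_dir, gmt = pl$gmt,
    sim = sim,
    filter = do.call(read_filter_config, raw$filter %||% list()),
    unite = do.call(unite_config, raw$unite %||% list()),
    annotation = do.call(annotation_config, raw$annotation %||% list()),
    fdr_threshold = (raw$enrichment %||% list())$fdr_threshold %||% 0.05,
    directed_p_threshold =
      (raw$enrichment %||% list())$directed_p_threshold %||% 0.05,
    min_sites_per_call = as.integer(pl$min_sites_per_call %||% 1L),
    contexts = pl$contexts %||% c("CpG", "CHG", "CHH"),
    write_reports = pl$write_reports %||% TRUE)
}

parse_toml_lite <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- "pipeline"
  for (ln in lines) {
    if (grepl("^\\[[^]]+\\]$", ln)) {
      section <- sub("^\\[([^]]+)\\]$", "\\1", ln)
      next
    }
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) != 3L)
      stop("cannot parse config line: ", ln)
    out[[section]][[m[2]]] <- parse_toml_value(trimws(m[3]))
  }
  out
}

parse_toml_value <- function(v) {
  if (grepl("^\\[.*\\]$", v)) {
    inner <- trimws(sub("^\\[(.*)\\]$", "\\1", v))
    if (!nzchar(inner)) return(character())
    parts <- trimws(strsplit(inner, ",", fixed = TRUE)[[1]])
    vals <- lapply(parts, parse_toml_value)
    return(unlist(vals))
  }
  if (grepl('^".*"$', v)) return(sub('^"(.*)"$', "\\1", v))
  if (grepl("^'.*'$", v)) return(sub("^'(.*)'$", "\\1", v))
  if (v %in% c("true", "false")) return(v == "true")
  num <- suppressWarnings(as.numeric(v))
  if (!is.na(num)) return(if (num == as.integer(num)) as.integer(num) else num)
  v
}
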