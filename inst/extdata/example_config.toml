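# Example methwindow run configuration (TOML-lite: [section], key = value,
# numbers, true/false, quoted strings, flat arrays).

[pipeline]
out_dir = "mw_out"
seed = 1
contexts = ["CpG", "CHG", "CHH"]
min_sites_per_call = 1
# plant the canonical ground truth: 10 critical-window genes (treatment
# hypomethylation in young+middle-age only) and 10 always-responsive genes
default_planted_effects = true
n_critical = 10
n_always = 10

[simulation]
genome_length = 60000
n_chromosomes = 2
gc_content = 0.42
cpg_oe = 0.2
n_genes = 20
gene_length = 2000
n_islands = 8
island_length = 600
island_cpg_boost = 5
coverage_mean = 30
read_length = 150
conversion_rate_converted = 0.995
conversion_rate_failed = 0.2
failed_read_fraction = 0.02
kit_effect_logit = 0.3

[filter]
max_lone_fraction = 0.05
denominator = "read_length"

[unite]
min_coverage = 10

[annotation]
promoter_upstream = 1000
promoter_downstream = 1000
shore_width = 2000
shelf_width = 2000

[enrichment]
fdr_threshold = 0.05
directed_p_threshold = 0.05
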