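---
title: "Models and methods behind methwindow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind methwindow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methwindow)
```

# The scientific problem

Estrogen replacement is only effective inside a *critical window*: estradiol
(E2) enhances hippocampal function when treatment starts near the loss of
ovarian hormones, and loses efficacy when it is delayed into old age. One
candidate mechanism for the closing of this window is DNA methylation: genes
that E2 normally hypomethylates (and thereby licenses for transcription) in
young and middle-aged animals may become unresponsive in aged animals.

`methwindow` implements a desk-scale, fully testable version of the analysis
that operationalizes this idea with whole-genome bisulfite sequencing (WGBS)
of three age groups (young Y, middle-age M, aged A) crossed with vehicle
control (C) and E2 treatment (T), with two library-preparation kits as a
batch covariate: per-site differential methylation between group pairs,
genomic and CpG-island annotation of the significant sites, per-gene
directional responsiveness calls, and the critical-window set algebra. A
synthetic-data generator with planted ground truth makes every stage
verifiable without any sequencing data.

# The synthetic world

`sim_config()` fixes a small diploid-agnostic genome and the cohort:

* **Genome.** Chromosome sequences are i.i.d. bases at `gc_content`
  (default 0.42, mammalian-like). `cpg_oe` (default 1) optionally depletes
  background CpG dinucleotides by CpG→TpG replacement — the deamination
  mechanism that gave real mammalian genomes their observed/expected CpG
  ratio of ~0.2. CpG islands are enriched by planting CG dinucleotides until
  their expected density is `island_cpg_boost` times the i.i.d. expectation.
  Genes are non-overlapping, one territory each, strand alternating, with
  two exons around a central intron.
* **Cohort.** Group sizes default to the emulated study design: treated
  n = 6 (YT), 6 (MT), 7 (AT); controls n = 4 each (YC, MC, AC). Library
  kits alternate within groups, so the batch is balanced unless the user
  confounds it deliberately.
* **Methylomes.** Every strand-relative reference cytosine carries a true
  methylation fraction `plogis(qlogis(baseline[context]) + age_effect +
  kit_effect + planted deltas)`. Baselines are CpG 0.75, CHG 0.02, CHH 0.02
  — high symmetric CpG methylation and low non-CpG methylation, as in
  mammalian somatic tissue. Effects are additive on the logit scale so
  planted differences stay well defined near 0 and 1. The default kit
  effect is +0.3 logits — a visible but not overwhelming batch artifact.
* **Counts.** Per site and sample, total reads are Poisson(`coverage_mean`,
  default 30 — realistic WGBS depth) and methylated reads are binomial in
  the true fraction.
* **Reads.** `simulate_reads()` emits aligned single-end reads (default
  150 bp, the common Illumina read length) alternating deterministically
  between strands, converts unmethylated cytosines to thymine with
  probability 0.995 (normal reads) or 0.2 (a configurable fraction of
  conversion-failed reads), and serializes to a minimal SAM subset.
* **Planted truth.** `planted_effect()` places a logit shift on a gene's
  promoter or body, per context, active in treated samples of selected age
  groups. `active_in = c("Y", "M")` defines a critical-window gene;
  `c("Y", "M", "A")` an always-responsive gene. The canonical layout
  (`default_planted_effects()`) plants 10 of each with promoter CpG
  hypomethylation of −1.5 logits, which moves CpG methylation from 0.75 to
  ≈ 0.40 — a strong, biologically plausible treatment effect.

What the generator deliberately does *not* emulate: sequencing errors,
indels, PCR duplicates, paired-end mechanics, quality strings, local
methylation correlation along the chromosome, and biological overdispersion
beyond the binomial. A green recovery test therefore establishes that the
pipeline's logic and statistics are correct under binomial sampling — not
that the real study's effect sizes were detectable at its coverage.

# Methylation calling and the lone-cytosine filter

Context classification is strand-relative: a site is CpG when the next base
(5′→3′ on its own strand) is G, CHG when the base after next is G, CHH
otherwise; windows truncated by a chromosome end default to CHH. Symmetric
CpG sites are *not* collapsed across strands; each strand's cytosine is its
own site.

A **lone cytosine** is a read C in neither a CG nor a GC dinucleotide.
After complete bisulfite conversion, read cytosines are almost exclusively
methylated CpGs, so lone cytosines mark conversion failures.
`lone_cytosine_fraction()` returns lone C / total C on the read sequence.

**Filter normalization (a deliberate design decision).** `filter_reads()`
removes a read when its lone-cytosine count exceeds 5% *of the read length*
(default), not 5% of its retained cytosines. The per-cytosine ratio is
unusable as a filter on converted reads: a 150 bp read at 40% GC retains
only ≈ 5 cytosines after conversion, so one methylated non-CpG cytosine
(expected ≈ 0.5 per read at the 2% CHH/CHG baseline) or a single 0.5%
conversion failure pushes the ratio over 5%. Closed-form Poisson arithmetic
gives ≥ 9% loss of perfectly normal reads even with zero non-CpG
methylation, ~37% at the default baselines — and the discarded reads are
exactly those carrying genuine non-CpG methylation, which the CHG/CHH
analyses need. Normalizing by read length yields a stable per-read statistic
(normal reads ≈ 0.3%, conversion-failed reads ≈ 10%) that separates the two
populations cleanly. The per-cytosine variant remains available via
`read_filter_config(denominator = "cytosines")`, as does an absolute
per-read cap (`max_lone_count`, default disabled).

Calling is plain base counting: at every strand-relative reference cytosine
covered by a retained read, read C is a methylated observation, read T an
unmethylated one, other bases are ignored; uncovered sites are omitted.
Reports use the 1-based cytosine-report TSV convention; all internal
coordinates are 0-based half-open.

# Differential methylation

For a contrast (test vs reference group), sites are retained when total
coverage reaches `min_coverage` (default 10 — a common WGBS site filter;
the emulated pipeline does not state its own) in all samples of both groups.
Each retained site is tested with a binomial logistic regression of
per-sample (methylated, unmethylated) counts on group plus covariates
(default: library kit), and the group term is assessed with a 1-df
likelihood-ratio χ². Numerical choices:

* Degenerate sites (all per-sample fractions identical) return p = 1.
* Perfect separation (the fitted group effect runs to the boundary,
  |β| > 12) falls back to the Rao score test evaluated at the reduced-model
  fit, which stays finite under separation.
* Non-convergence returns p = 1 with a diagnostic flag.
* The methylation difference is the *unweighted* mean of per-sample
  fractions (test − reference), so unequal coverage or batch composition
  cannot masquerade as direction.
* Significance is the raw per-site p < 0.01 with **no multiple-testing
  correction**, reproducing the emulated pipeline's operating point; a BH
  q-value column is emitted for reference but unused downstream.
* No overdispersion correction is applied (the generator is exactly
  binomial; real data would need one, which is out of scope).

Direction is `hyper` when p < α and the difference is positive, `hypo` when
negative, `ns` otherwise — so hyper + hypo = significant by construction,
per contrast, per chromosome, per context.

`fisher_exact_oracle()` is an independent check for the covariate-free
case: a two-sided Fisher exact p by full enumeration of the hypergeometric
support. Note that the asymptotic LRT p and the discrete exact p agree
closely only in the decision region: simulation shows absolute differences
up to ~0.1 at mid-range p even with all cells ≥ 20, shrinking to < 0.01 for
p < 0.05 with cells ≥ 100. The test suite asserts exactly that.

# Annotation

Features follow the HOMER-style hierarchy promoter > exon > intron >
intergenic, with the promoter a −1,000/+1,000 bp strand-oriented window
around the TSS. Intergenic sites are assigned the gene with the nearest TSS
(no distance cap; ties break to the smaller coordinate). Gene body = exon ∪
intron excluding the promoter window, giving the two-way promoter/gene-body
reporting plus intergenic. CpG-island zoning uses the field-standard
convention the source analysis never spells out: shores are the 0–2 kb
island flanks, shelves 2–4 kb, open sea beyond; overlapping flanks resolve
to the nearer island.

# Critical-window classification

A gene is called hypomethylated under a contrast when at least
`min_sites_per_call` (default 1 — gene lists in the emulated workflow derive
directly from annotated significant sites with no stated minimum) of its
annotated significant hypo sites exist, counting intergenic nearest-gene
assignments; hyper analogously, and a gene can carry both calls. Across the
three treatment contrasts, per context:

* shared = hypo(YT-YC) ∩ hypo(MT-MC)
* non-responsive in aged = shared \\ hypo(AT-AC) — the critical-window
  candidates
* responsive in all = shared ∩ hypo(AT-AC)

The last two partition the shared set for any input. (The source analysis
labels the middle-age treatment contrast inconsistently — "MT-YC" twice in
the text, MT-MC in methods and figures; the age-matched control version,
MT-MC, is implemented.)

# Enrichment

DAVID-style annotation clustering is replaced by plain per-set
over-representation: upper-tail hypergeometric p of the overlap between a
query gene set and each annotation set within a universe, BH-adjusted across
the collection (default report thresholds: BH FDR 0.05, directed p 0.05).
The kappa-statistic functional clustering of the original web service is a
presentation layer over the same signal and is deliberately out of scope.
The universe defaults to all genes of the annotation; the original
database's implicit universe is unrecoverable, so enrichment on real gene
lists is not a validation surface.

# Design of the validation experiments

**Type-I calibration.** A null world (kit batch effect +0.3 logits present
and adjusted for, no group effect) with ~2,000 CpG sites, 4 vs 4 samples,
coverage 30, over 10 seeds. The binomial LRT with ~240 Bernoulli trials per
site is expected to be near-nominal; the acceptance band is rejection rate
in [0.005, 0.02] at α = 0.01. Measured in this build: ≈ 0.010.

**Recovery power analysis (done before any measurement).** With the
uncorrected per-site α = 0.01 and per-gene aggregation at
`min_sites_per_call = 1`, a critical-window gene is lost whenever *any* of
its sites is falsely called hypo in the aged contrast:
P(loss) = 1 − (1 − α/2)^n for n null sites per gene. Keeping mean recovery
≥ 8/10 therefore requires n ≲ 30, i.e. a genome with few, CpG-sparse sites
per gene. The recovery world places one 800 bp gene per 1,600 bp chromosome
(20 chromosomes — no cross-gene promoter bleed), with background CpG
depleted to the mammalian observed/expected ratio 0.2, giving ≈ 28 CpG
sites per gene: expected retention (1 − 0.005)^28 ≈ 0.87, expected recovery
≈ 8.7/10, while per-gene power in young/middle (and aged, for
always-responsive genes) is ≈ 1 with ~24 affected sites of effect size
0.75 → 0.40 at coverage 30. Measured in this build: 9.0/10 recovered, 0/10
always-responsive genes misclassified (test-suite seeds).

**Conversion-filter discrimination.** 40% GC genome, default baselines,
conversion 0.995 vs 0.2 with 5% failed reads: ≥ 90% of failed reads removed
(measured ≈ 99%), ≤ 5% of normal reads removed (measured 0%).

These worlds, their parameters and the seeds were fixed from the closed-form
analysis above and are not tuned against test outcomes.

# Pipeline and reproducibility

`run_pipeline()` executes simulate (or load) → call → all six study
contrasts → annotate → critical window → enrich, writing every stage output
and a `report.json` whose numeric thresholds all trace back to the
configuration. Every stochastic operation derives its RNG stream from the
configuration seed, so a rerun is byte-identical. The read-level path
(`use_reads = TRUE`) is O(total bases) in plain R and intended for reduced
coverage; the default counts path draws per-site counts directly from the
truth model. The CLI (`mw_cli()`, or the `inst/cli/methwindow` launcher)
exposes the stages as `simulate`, `call`, `diff`, `annotate`, `window`,
`enrich` and `run` subcommands driven by a flat TOML-style config file.

# Known limitations

* Binomial likelihood without overdispersion: real replicate variability
  would inflate the type-I error; a beta-binomial variant is out of scope.
* One TSS per gene model; no isoforms, no enhancer annotation.
* No DMR segmentation or smoothing — strictly per-site, as in the emulated
  analysis.
* The simulator's independence across sites understates the correlation of
  real methylomes; power estimates transfer only qualitatively.
* Headline counts of the emulated study (tens of thousands of significant
  sites from ~2.5 million testable CpGs) are functions of its raw data and
  are not reproduction targets at desk scale.
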