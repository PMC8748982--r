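---
title: "astroreact: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{astroreact: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astroreact)
```

This vignette is the package's own account of its statistical
machinery: what each stage assumes, which tunable parameters matter and
why their defaults are what they are, what the synthetic-data
generators do and do not emulate, and where the genuinely open design
choices were resolved.

## The scientific setting

Astrocytes react to chronic neurodegenerative pathology (amyloid
plaques, tau tangles) with broad changes in their actively translated
mRNA pool. TRAP-seq isolates that translatome cell-type-specifically,
yielding gene-by-sample count matrices for disease and wild-type
animals. Three analyses are layered on top: (i) characterising the
disease response (differential expression, threshold selection,
enrichment in externally derived reactive-astrocyte sets and in GWAS
risk genes), (ii) distilling signatures shared across models, species
and regions, and (iii) quantifying how far an intervention genotype
(astrocyte-specific Nrf2 overexpression crossed into the disease
background) rescues the disease signature.

## Expression core

**FPKM.** `compute_fpkm()` uses the textbook definition
`count · 10⁹ / (length_bp · library_size)` with the library size taken
as the raw column sum. FPKM is zero exactly where the count is zero; a
zero library size is an error naming the offending sample.

**Differential expression.** `differential_expression()` is a
deliberately simple two-group negative-binomial Wald test, documented
as such rather than a reimplementation of a shrinkage-based tool:

- size factors by median-of-ratios over the contrast samples only
  (contrasts in this design are run pairwise), using genes with no
  zero count as the reference;
- per-gene dispersion by method of moments on normalised counts,
  `α = max((s² − μ)/μ², 10⁻⁸)`, with the pooled within-group variance —
  no shrinkage, no trend fitting (both are out of scope by design);
- log2 fold change of pseudocount-guarded normalised group means
  (pseudocount 0.5 counts);
- a Wald statistic with the delta-method standard error
  `SE² = Σ_g v_g/(n_g μ_g²) / ln²2`, `v_g = μ_g + α μ_g²`, referred to
  a **t distribution on n₁+n₂−2 degrees of freedom**;
- Benjamini–Hochberg adjustment across tested genes; all-zero genes
  are flagged `low_count` and excluded from testing and adjustment.

The t reference is the one deliberate departure from the plain
`z ~ N(0,1)` Wald convention. With four replicates per group the
plug-in variance has few effective degrees of freedom, and simulation
at exactly those conditions shows the normal reference is
anti-conservative (raw type-I ≈ 0.075 at the nominal 0.05), while the
t(n₁+n₂−2) reference is mildly conservative (≈ 0.035) and inside the
0.05 ± 0.02 calibration band that the test suite enforces. A
small-sample correction of the reference distribution is not a
dispersion-shrinkage method, so the no-shrinkage scope is respected.
Gene-level p values will differ from DESeq2-class tools; what the
package calibrates, by simulation, is set-level behaviour.

**Selection.** `select_genes()` applies three thresholds whose
defaults mirror the analysis conventions: fold ≥ 1.5 on the point
estimate (fold = 2^log2fc, no shrinkage), padj < 0.05, and an
expression cut-off of 1 FPKM. The expression rule is read
permissively as *maximum group-mean FPKM ≥ threshold* — the gene must
be expressed in at least one condition; per-sample minima and overall
means were the alternatives, and the group-mean-max reading keeps
genes switched on by disease. Up- and down-selections are disjoint by
construction.

## Reactive gene-set derivation

The classifier input is a probe-level table of fold changes under two
acute stimuli (inflammatory LPS-like and ischaemic MCAO-like).
`collapse_probes()` drops unannotated probes and collapses multi-probe
genes by the arithmetic mean per stimulus; the mean is applied
uniformly to all multi-probe genes, which coincides with the published
"average the probes that compete for the top ranks" convention
everywhere it can affect the outcome. `rank_genes()` ranks each
stimulus separately, rank 1 = highest fold change; ties are broken
lexicographically by gene symbol so that the ranking is a
deterministic total order (the source procedure is silent on ties).

`classify_reactive()` then applies, with defaults 100/250/50:

- *stimulus-specific*: rank ≤ 100 for one stimulus **and** at least 50
  ranking places lower for the other (`rank_other − rank_this ≥ 50`,
  inclusive);
- *pan-reactive*: both ranks ≤ 250 and no more than 50 places apart
  (inclusive), **and** not already assigned to a specific set.

At a rank difference of exactly 50 with one rank ≤ 100 a gene
satisfies both rules; specific sets take precedence. This precedence
keeps the three sets pairwise disjoint on every input and matches the
treatment of the classic borderline example (a gene 55 places apart
going specific, not pan). Both inclusive readings of "at least" and
"no more than" are plain-language choices and are exposed as the
`separation` parameter.

When externally derived sets interrogate a new dataset,
`filter_expressed()` removes set genes not expressed above 1 FPKM in
*every* condition group of that dataset — stricter than the selection
filter, because a set gene must be measurable everywhere for its fold
change to be interpretable.

## Enrichment statistics

`fisher_enrichment()` reports the sample odds ratio `(ad)/(bc)` as the
fold enrichment, because the companion error bars are defined as 95%
confidence intervals *of the odds ratio*; the alternative reading
(observed/expected overlap) is easily derived from the exposed cells.
The CI is the Woolf log-OR normal interval. Zero cells receive the
Haldane–Anscombe +0.5 correction **only** for the OR and CI; the
two-sided exact p (minimum-likelihood rule, as in standard
implementations) is never corrected. `compare_enrichments()` uses the
normal approximation to the difference in log odds ratios with
`SE² = Σ 1/cell` per table, on the corrected cells whenever the
correction was applied.

`risk_enrichment_sweep()` defines its universe as the genes expressed
above 1 FPKM for which a gene-level GWAS p value is available, and its
`"auto"` cutoff grid as `0.05/|universe|` (the study-wide Bonferroni
rule) followed by `5·10⁻⁵, 5·10⁻⁴, 5·10⁻³, 5·10⁻²`. The four relaxed
points are a convention of this package (the published analyses print
five p values without stating the grid); any explicit cutoff vector
can be supplied. Cutoffs are processed in ascending order, so the
reference set and the overlap grow monotonically along the sweep.

`overrepresentation()` is the flat-set hypergeometric test (one-sided,
unlike the two-sided 2×2 enrichment, mirroring the two distinct
conventions): terms are clipped to the universe, name patterns (e.g.
`"disease"`) can be excluded, terms with query overlap below
`min_genes = 5` are dropped *before* testing, and BH runs across
tested terms only. `top_terms()` implements the conventional display
rule — top ten by adjusted p unless fewer reach 0.05.

## Signatures across models, species and regions

`core_overlap()` intersects the per-model significant sets over the
jointly tested universe and scores the overlap with the same 2×2
machinery; it is symmetric in its inputs. `cross_species_compare()`
maps a human-derived set through **1:1 orthologs only** (any
one-to-many pair is dropped), filters at 10 FPKM in either model, and
reports both the raw-p and adjusted-p significance tallies, because
scatter displays conventionally use raw p < 0.05 while set
construction uses adjusted p — both are emitted rather than choosing.

`precocity_test()` implements the ratio paired t-test as a one-sample
t on per-gene log2 ratios of group-mean FPKM, with `df = n_genes − 1`.
Published df values for tests of this shape vary by one or two
depending on pairing convention; the per-gene convention here is
documented rather than asserted as anyone else's. The pseudocount
(0.1 FPKM, added to both means) guards zero means; because it is an
absolute-scale term, exact invariance to uniform FPKM rescaling is
traded for zero-safety — the tests check invariance holds to high
accuracy whenever expression is well above the pseudocount.

`regional_concordance()` is a Pearson correlation plus OLS slope with
normal-theory CI on the shared universe of genes at ≥ 1 FPKM in both
regions, consistent with the global expression filter.

## Rescue quantification

`rescue_fold_change_test()` pairs, per signature gene, the log2 fold
change under the primary contrast (TG vs WT) with the log2 fold change
under the intervention contrast (TG×NRF2 vs NRF2), both from
pseudocount-guarded group-mean FPKM, and runs a paired t on the
per-gene differences. The attenuation estimate
`1 − mean(log2FC_int)/mean(log2FC_primary)` is 1 for complete rescue
and 0 for none. The test is gene-paired on group means — the per-gene
scatter presentation — not a per-animal mixed model, which is out of
scope. Two caveats are documented and quantified by simulation:
FPKM's total-count normalisation introduces a composition bias when a
sizeable fraction of the library is perturbed (with 35% of genes
induced two-fold the planted attenuation 0.7 is recovered around
0.67), and the pseudocount compresses ratios of weakly expressed
genes. Both effects sit well inside the ±0.1 recovery tolerance the
test suite asserts. `baseline_shift_check()` is the companion control:
the intervention alone should leave signature-gene baselines flat, so
its one-sample t is *intended* to be non-significant.

`allele_fraction()` scores reads by exact forward-strand substring
match against the wild-type and mutant motifs spanning a two-allele
locus (e.g. the APP Swedish KM→NL codons, whose exact window is a
required user input); reads containing neither or both motifs are
reported as unscored, and the Wilson 95% CI accompanies the mutant
percentage. Reverse-complement handling belongs to the caller's
read-preparation step, since alignment is out of scope.

`bar_score()` converts horizontal-bar trial times into the 0–10 scale
(fall fast → 0 … reach fast → 10; either outcome at the 60 s cut-off
→ 5). Times are truncated to whole seconds before band lookup because
the scoring table is specified in whole seconds; the session score is
the mean of three trials. The longitudinal mixed-effects analysis of
those session scores is out of scope.

## Synthetic data: what is emulated, and what is not

All generators derive their randomness from a single integer seed
(per-generator offsets keep the streams independent) and are
bit-reproducible.

**Translatome and rescue counts** are negative-binomial with
`Var = μ + αμ²`, matching the DE stage's assumed model. Defaults are
the study conditions: 4 replicates per genotype, planted |log2FC| = 1
for 5% induced + 5% repressed genes, dispersion α = 0.05, baseline
means log-uniform over ~3 decades (`10^[0.5, 3]` counts at the
reference depth), gene lengths log-uniform in 0.5–10 kb, library sizes
log-normal around 10⁷ with σ = 0.15 — together giving a realistic FPKM
dynamic range without any external reference. The rescue design adds
the two intervention genotypes: TG×NRF2 carries the signature at
`(1 − rescue_factor)` of the effect, NRF2 alone is null for signature
genes. Not emulated: batch effects, per-read error profiles,
multi-region correlation structure, outlier samples.

**Two-stimulus probe tables** are built *backwards* from a rank
layout. This is forced by geometry, not convenience: every gene ranked
in the top 100 of either stimulus is necessarily classified by the
rules above, so "plant these classes and nothing else" is only
satisfiable when the planted classes tile both top-100s (the *banded*
layout, padding the 101–250 bands with null genes whose other rank
lies beyond 250) or when the table is small and null-free (the
*compact* layout). `stimulus_config()` validates feasibility and
refuses impossible class sizes with an explanation. Fold changes are
then drawn strictly decreasing along the layout, multi-probe genes get
probe values whose arithmetic mean is exactly the gene value, a
fraction of unannotated probes is mixed in, and the generator verifies
its own output by running the classifier before emitting. Defaults
(70/70/42 with 400 nulls) mirror the published set sizes.

**GWAS tables** give risk genes p values below the smallest sweep
cutoff and non-risk genes uniform p values; `induced_bias` multiplies
the odds that an induced gene is a risk gene, with bias 1 producing an
exactly null table. **Locus reads** embed exactly one motif in 40 nt
i.i.d. uniform flanks per side, rejection-sampled so neither motif
occurs by chance; the mutant count is Binomial(n, fraction).

Because the generators share the DE stage's noise model, passing tests
demonstrate internal consistency and correct implementation of the
procedures — not robustness to real-data pathologies (overdispersion
heterogeneity, probe cross-hybridisation, mapping artefacts).

## Numerical choices and degenerate inputs

- Dispersion floor 10⁻⁸; means floored at 10⁻⁸ inside the SE only.
- Fold-change pseudocounts: 0.5 normalised counts (DE), 0.1 FPKM
  (paired signature/rescue statistics); both recorded in provenance.
- Ties in ranking: lexicographic by symbol. Ties in exact-test
  probabilities: the standard `≤ p_obs·(1+10⁻⁷)` tolerance.
- Zero-variance log-ratio vectors (all ratios identical), fewer than
  three genes, zero scored reads, empty universes and contrast levels
  missing from metadata are all refused with informative errors
  rather than returning NaN statistics.
- `run_pipeline()` skips stages whose inputs are not configured
  (logged), aborts on stage errors naming the stage, and writes a
  provenance JSON (inputs, thresholds, seed, version) that contains no
  timestamps, so reruns are byte-identical.

## Problem sizes in the shipped checks

The test suite and acceptance script run entirely on synthetic data at
deliberately desk-sized conditions, chosen to make each assertion
statistically meaningful at interactive runtimes: exhaustive Fisher
enumeration for universes ≤ 25 plus 500 random tables up to 200; 2000
null tables for Woolf CI coverage; ten 2000-gene null simulations for
type-I calibration; one hundred random feasible stimulus
configurations for exact classifier recovery; ten 1500-gene rescue
simulations for attenuation recovery; 10⁴ reads for the allele
fraction. Larger runs only narrow Monte-Carlo error; none of the
qualitative conclusions depend on these sizes.

## Known limitations

- The NB test is intentionally minimal: no dispersion shrinkage,
  independent filtering, surrogate variables or multi-factor designs;
  gene-level results differ from DESeq2-class tools.
- Fold enrichment as the sample OR diverges from the
  observed/expected-overlap reading when margins are extreme; both
  views are computable from the exposed cells.
- The rescue statistic inherits FPKM composition bias (quantified
  above) and is a per-gene, not per-animal, inference.
- Microarray preprocessing, read alignment and counting, species read
  separation, live annotation services and GO graph topology are all
  outside the package; inputs arrive as plain TSV/GMT/FASTA.
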