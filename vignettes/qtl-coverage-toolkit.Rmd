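---
title: "Methods: genotype-stratified QTL coverage, credible-set filtering and signal colocalisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genotype-stratified QTL coverage, credible-set filtering and signal colocalisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlcanvas)
```

This vignette documents the models and procedures implemented in `qtlcanvas`,
the assumptions behind them, the parameters a user may want to change, and
the design decisions taken where more than one reasonable choice existed.

## The problem

Molecular QTL studies quantify transcription at several levels — gene
expression, exon expression, transcript usage, transcriptional-event usage,
splice-junction usage. The transcript-level quantifications are ratios
(each trait divided by the total of its gene or splice cluster) followed by a
rank-based inverse normal transform, so a mapped effect size carries little
information about what physically changes in the transcript pool, where in
the gene it happens, or how large the change is in absolute terms. A
genotype-stratified read-coverage figure answers those questions directly:
if a variant shifts the inclusion of one exon, the per-genotype mean coverage
shows it at that exon, at true scale.

## Intron-compressed coordinates

Genes are mostly intron. To make exonic coverage visible, the display axis is
a piecewise-linear transform of the genome built on the union of the
displayed transcripts' exons: exon segments map with slope 1 (length is
preserved exactly), and each gap between consecutive union exons maps
linearly onto a fixed `intron_display_length` of 50 bp. The total display
length is therefore `sum(exon widths) + 50 * n_introns`, an identity the test
suite checks exactly on randomised structures (200 structures of up to 20
exons). Choices worth noting:

- Coordinates are 0-based half-open internally; GFF3's 1-based inclusive
  convention is converted at the parser (`read_exons_gff3`) and nowhere else.
- Maps are built in genomic orientation regardless of strand. A renderer may
  flip the axis for minus-strand genes, but keeping the map orientation fixed
  means the coverage, effect and annotation panels can never disagree.
- When several transcripts are drawn, one map is built on the union of all
  their exons so every panel shares an axis; a shared exon lands at identical
  display coordinates in every row.
- Adjacent exons (zero-length gap) are treated as contiguous sequence, not as
  an intron of width 0 — compressing nothing is the only behaviour that keeps
  exon lengths exact.
- Positions inside compressed introns map by linear interpolation and are not
  exactly invertible (by design, ~50/gap-length resolution); exonic positions
  round-trip exactly.

## Coverage extraction and stratification

Per-sample coverage enters as bigWig or bedGraph (bedGraph is accepted
everywhere bigWig is, so plain-text pipelines work end to end). Processing is:

1. **Binning** (`bin_coverage`, default 5 bp, the resolution coverage files
   are typically generated at): each bin is the mean of its constituent
   bases, so total signal (depth × width) is conserved; a final partial bin
   is averaged over its true width rather than padded.
2. **Normalisation** (`normalize_track`): reads-per-million scaling,
   `values * 1e6 / library_size`. The library size is the sample's total
   mapped reads when available. Without it, the sum of the track is a usable
   proxy, with a caveat: for a gene with a strong local genotype effect the
   track sum itself depends on genotype, which folds a small opposite-signed
   artefact into every other exon. The synthetic pipeline therefore uses one
   common scale factor (the mean track sum) across samples, which is exact
   there because simulated samples share a sequencing depth.
3. **Stratification** (`assign_genotype_groups`): imputed dosages in [0, 2]
   are rounded to the nearest hard class, half away from zero (0.5 → 1,
   1.5 → 2). No imputation-certainty filter is applied by default;
   `max_dosage_distance` (default 0.5, i.e. keep everything) can exclude
   ambiguous dosages. Missing dosages are excluded and counted.
4. **Averaging** (`group_mean_coverage`): per class, the arithmetic mean of
   member tracks per bin. Classes with no members are omitted with a notice.
   An optional rescale by the global maximum puts all classes on a 0–1 axis;
   it is off by default and enabled by the figure renderer only, since
   downstream numeric use of the means should see real units. Whether
   published coverage plots scale per sample, per class or per panel is not
   something the figures themselves document; scaling the whole panel by one
   maximum preserves between-class depth differences, which is the point of
   the figure.

## Exon-level effects

`exon_effects` fits, per exon, ordinary least squares of the exon signal on
allele dosage with an intercept and optional covariates, reporting the
dosage coefficient β (effect per alternative-allele copy), its standard
error, a Student-t 95% CI on `n − k − 2` degrees of freedom, the nominal
p-value, and a Benjamini–Hochberg flag at FDR ≤ 1% computed across the exons
of the displayed gene (the plotting context; genome-wide FDR control belongs
to the full mapping pipeline, not the figure). The inverse normal transform
is available inside the fit (`int = TRUE`, used by the figure pipeline) but
is not forced, so exact algebraic cases — a noise-free linear signal must
return its slope with zero standard error — behave as expected.

Surrounding conventions follow standard QTL-mapping practice: usage ratios
divide each trait by its group total, with a zero group total producing
missing values (a zero would assert absence of usage that was never
measured); the inverse normal transform is `qnorm((rank − 0.5)/n)` with
average ranks for ties — the offset that avoids infinite quantiles and is
symmetric, making the output invariant to any strictly monotone transform of
the input; covariates (typically the first six genotype and six trait
principal components) are removed by OLS residualisation; traits with fewer
than five variants in the ±1 Mb cis window around the gene start can be
excluded with `filter_traits_by_cis_variants`, since such regions usually
reflect poor genotyping coverage. The regression engine is QR least squares,
cross-checked against `stats::lm` in the tests; BH adjustment delegates to
`stats::p.adjust` and is cross-checked against a literal step-up enumeration.

## Credible-set filtering

Exon- and transcript-level analyses test many strongly correlated traits per
gene, so their summary statistics are large and redundant. The filtering
implemented in `credfilter_pipeline` keeps one molecular trait per
independent genetic signal:

1. **QC**: a credible set is dropped when its maximum absolute univariate
   z-score is lower than 3 (no convincing marginal association) or its size
   is bigger than 200 variants (uninformative). Both rules are strict
   inequalities, so max |z| = 3.0 and size = 200 survive; the z criterion
   uses the maximum over the set's variants.
2. **Connected components**: within one group (gene, or splice-junction
   cluster for junction traits) and one quantification method, credible sets
   sharing at least one variant are linked, and components are the
   transitive closure — each component is treated as one independent signal.
   The implementation builds an edge list per shared variant and takes
   `igraph::components`; its behaviour is pinned by a brute-force
   pairwise-overlap + transitive-closure oracle over hundreds of randomised
   instances rather than by the choice of algorithm.
3. **Selection**: per component, the trait with the highest PIP survives.
   "Highest PIP" defaults to the single best variant PIP over the trait's
   member sets (`pip_rule = "max"`); a summed-PIP rule is available since
   either reading is defensible. Exact ties break to the lexicographically
   smallest trait ID, which keeps reruns reproducible.
4. **Filtering**: only selected traits keep their summary statistics; the
   report records input rows, output rows and the reduction fraction. The
   operation is idempotent, and the partition and argmax invariants are
   asserted on every run.

## Colocalisation from log Bayes factors

For two fine-mapped signals with per-variant natural-log Bayes factors,
`coloc_pair` evaluates the five standard hypotheses (H0 no association, H1/H2
one trait only, H3 two distinct causal variants, H4 one shared causal
variant) on the intersection of the variant grids. All sums are log-sum-exp;
the H3 score subtracts the same-variant mass from the full cross product in
log space, guarded to −∞ when the subtraction is non-positive within 1e-12
(the degenerate one-shared-variant case). The engine is checked against a
brute-force enumeration of all Q² causal-variant configurations to 1e-10.
Default priors are the coloc-family convention p₁ = p₂ = 1e-4, p₁₂ = 5e-6,
exposed as arguments since published analyses rarely print them. Variants
match by exact `chr_pos_ref_alt` string; no allele flipping is attempted
because Bayes factors are invariant to allele order, and mismatched IDs
simply drop out of the intersection. `coloc_all_pairs` crosses up to 10
signals per side (more are dropped with a notice) and flags PP4 strictly
greater than 0.9 — a pair at exactly the threshold does not pass.

## What the synthetic generators emulate

The generators in `synthfix` produce every input the toolkit consumes, with
ground truth, under a fixed seed (byte-identical reruns):

- `sim_genotypes`: hard genotypes from Binomial(2, MAF) — Hardy–Weinberg
  proportions, no LD, no imputation uncertainty.
- `sim_coverage_dataset`: per-base counts around an expected-depth profile;
  the sQTL archetype shifts the affected exon's inclusion through a logistic
  model `plogis(qlogis(base_inclusion) + β · dosage)`, the eQTL archetype
  multiplies all exons by `2^(β/2 · dosage)`, and the null applies no effect.
  Noise is Poisson, or negative-binomial (dispersion 0.1 by default) since
  real RNA-seq coverage is overdispersed. Intronic depth is a flat 0.1.
- `sim_credible_sets`: groups with 1–3 planted signals, each signal's
  credible sets (2–4 traits) sharing that signal's causal variant on
  otherwise disjoint variant pools, winner PIPs in 0.85–0.95 against
  everything else below 0.8, plus a configurable fraction of QC-violating
  sets (low z or oversized) on their own variant pools.
- `sim_lbf_pair`: one-hot LBF peaks (default 20 nats) arranged per scenario
  H0–H4.

Defaults are the conditions the package is exercised under throughout:
200 samples, MAF 0.3, effect 0.8, 50× depth, a five-exon gene (exon widths
300/200/150/180/250 bp, introns 1.2–2 kb, modelled loosely on a mid-sized
protein-coding gene), effect at exon 4; credible-set fixtures use 1,000
groups × 20 traits. These sizes keep the full test suite and the
reproduction script in the minutes range while leaving sampling error well
below the effects being detected.

What the generators deliberately do **not** emulate: linkage disequilibrium
(every variant is independent, so fine-mapping ambiguity between correlated
variants never arises), reference-mapping bias, GC-content effects,
positionally correlated coverage noise within a read length, and
multi-variant signals within one credible set. Passing tests therefore
demonstrate that the machinery is correct on data with the assumed
statistical structure, not that the upstream fine mapping or quantification
would be well behaved on difficult real loci.

## Numerical and rendering choices

- Least squares via QR; covariate collinearity is an error naming the
  offending columns rather than a silent drop.
- A zero-variance dosage ("monomorphic variant") is an error, not a NaN.
- `se = 0` (perfect fit) yields p = 0 for a nonzero slope, p = 1 otherwise.
- Log-sum-exp everywhere Bayes factors are summed; LBF vectors up to ~700
  nats per variant are safe.
- Figures use a fixed canvas, fixed styling (`covplot_style`) and no
  randomness, so the SVG output for a given bundle is byte-stable; genotype
  class labels derive REF/ALT allele strings from the variant ID and carry
  the class sample counts.
- The geometry of a figure can be dumped to TSV (`write_panel_geometry`)
  for assertions without a graphics device.

## Limitations

- Coverage stratification assumes the supplied tracks are comparable after
  a scalar normalisation; fragment-length and positional biases are not
  modelled.
- The exon-effect model is a per-exon linear fit; it does not borrow
  strength across exons or model count noise explicitly.
- Component-based filtering keeps a single trait per signal; biologically, a
  signal can affect several traits, and the discarded ones are recoverable
  only from the unfiltered files.
- Colocalisation consumes fine-mapping Bayes factors as given; errors in the
  upstream fine mapping propagate untouched.
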