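---
title: "Methods: post-annotation metatranscriptome analysis with samsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: post-annotation metatranscriptome analysis with samsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(samsa)
```

## Scope and model of the data

`samsa` starts where read annotation ends.  Its input is the
tab-delimited, per-read best-hit export of an annotation service such as
MG-RAST: one line per matched read, carrying a read id, a match id, the
usual similarity statistics, and an annotation string (an organism name,
a transcript function, or an ontology category, depending on which
reference database the file was matched against).  Four source databases
are distinguished: RefSeq organism, RefSeq function, SEED Subsystems,
and SILVA SSU; the last is ribosomal by construction.

Two facts about this format drive the design:

* **Tied best hits.**  When several reference entries tie for best match
  score, the service reports all of them, so one read can yield several
  records sharing a read id.  `aggregate_counts()` therefore supports
  two counting policies: `count_all` (each reported match contributes a
  full count, mirroring the service's own convention) and `fractional`
  (each of a read's *k* tied records contributes 1/*k*, so every read
  has unit weight).  `count_all` is the default because it reproduces
  what the annotation service itself publishes; it double-counts tied
  reads, which is why the alternative is offered and the policy is
  recorded on the table.
* **Unspecified column order.**  The exact export schema varies by route
  and era, so parsing goes through an `annotation_dialect()` that names
  the columns in file order; the default is the BLAST-tabular-like
  layout (read id, match id, percent identity, alignment length,
  e-value, annotation text).  Malformed lines are counted and dropped by
  default, or fatal under `strict = TRUE`.

rRNA reads that survive ribosomal depletion carry a biased taxonomic
signal (see below) and should be discarded before functional analysis.
`filter_rrna()` partitions records by database of origin first (SILVA
SSU is ribosomal by definition) with a case-insensitive keyword fallback
("ribosomal RNA", "16S", ...) for ribosomal annotations that appear in
mRNA-oriented databases.  The keyword list is user-extensible because no
fixed vocabulary covers every annotation dialect.

## Aggregation and rollup

Aggregation is deliberately elementary: a dictionary of unique
annotation strings and their counts, sorted by decreasing count with a
lexicographic (byte-order) tie-break so output is identical across runs
and platforms.  Taxonomic rollup (`rollup_rank()`) sums organism-level
counts by a rank taken from a user-supplied taxonomy map; organisms
missing from the map pool into `"unclassified"` so totals are always
conserved exactly.  Without a map only the genus rollup is available,
via the documented fallback of taking the first whitespace-delimited
token of the organism name (the binomial convention); coarser ranks
genuinely require lineage data the annotation text does not carry.

The display convention for long-tailed communities keeps the top 30
categories and pools the remainder into an `"Other"` catch-all (the
count-conserving mode) or drops it (not conserving).  An input category
literally named "Other" is escaped rather than silently absorbed.

## Sequencing-depth sufficiency

How many annotated reads are enough for stable abundance estimates?
The package answers by subsampling: random subsets of an annotated
dataset at fractions 1, 5, 10, 20, ..., 90 % (the default grid), many
replicates per fraction, comparing each subset's relative abundances to
the full data's.  Per feature,

accuracy = 100 × (1 − |rel_subset − rel_full| / rel_full),

clamped to [0, 100] because the relative deviation of a rare feature
can exceed 100 % (the clamp is our choice; unclamped means would let a
single outlier dominate a class mean).  Accuracies are averaged,
unweighted, over features and replicates within three abundance classes
taken on the full data's sorted list: *high* = the 5 most abundant
features, *medium* = the top half of the sorted list minus the high
class, *low* = the bottom tenth.  `min_depth()` then reports the
smallest subset size whose class-mean accuracy reaches a threshold
(default: the low class at 90 %), converted to absolute reads.

Two design points deserve note:

* **Subsampling operates on count tables, not read files.**  Drawing
  *n* reads without replacement from the read population implied by a
  count vector is exactly a multivariate hypergeometric draw, which is
  distributionally identical to subsampling the reads themselves and
  orders of magnitude cheaper.  The sampler is validated two independent
  ways in the tests: against the exact hypergeometric mean absolute
  deviation computed from the pmf, and against brute-force enumeration
  of all subsets of an 8-read parent.
* **Replicates default to 100 per fraction**, the operational choice
  for the procedure; the replicate count, fraction grid, and class
  boundaries are all exposed (`subsample_spec()`, `class_spec()`)
  because reasonable analyses vary them.

The test suite and the acceptance script exercise this on a synthetic
parent of 2 million annotations over 300 lognormal-abundance taxa (20-30
replicates per fraction) — big enough that the three classes separate
cleanly, small enough to run in seconds.  On such parents the curves
reproduce the qualitative result the procedure exists to show: accuracy
rises monotonically with depth for every class, is exact at full depth,
and the low-abundance class crosses any fixed accuracy threshold at a
strictly greater depth than the high class (e.g. 40 % vs 1 % of a
2-million-read parent for 90 % accuracy).

## Ribodepletion bias

Hybridization-based rRNA depletion does not remove ribosomes uniformly
across taxa, so the rRNA that survives is a biased sample of the
community.  `depletion_percent()` quantifies this per taxon from paired
control/depleted libraries as

d_i(t) = 100 × (1 − rel_depleted,i(t) / rel_control,i(t)),

averaged over pairs, where `rel` are within-library relative abundances
— making the metric invariant to library size.  Negative values mean
apparent enrichment, which is expected: renormalizing a fixed
sequencing budget necessarily inflates whatever was not depleted.  Taxa
absent from the control cannot be normalized and are excluded (and
reported); taxa absent from the depleted library score 100.  This is
the package's own transparent definition: published "% depleted" tables
rarely state their normalization, so we define one and label it rather
than guess at any particular table's arithmetic.

The generator plants per-phylum retention probabilities and emits the
analytically expected depletion (100 × (1 − r_p/R), with R the
retention-weighted rRNA share), so recovery is asserted against ground
truth rather than against any published value.

## mRNA-vs-rRNA concordance and paired/single-end comparison

If mRNA abundance tracks organism activity, organism profiles estimated
from mRNA annotations and from rRNA annotations of the same library
should agree after rollup to a common rank.  `rank_correlation()`
computes the Pearson correlation of relative abundances over the union
of rank-level taxa (absent taxa enter as zero, penalizing dropout; an
intersection mode exists), with an option to drop non-bacterial
lineages — rRNA false annotations concentrate in eukaryotes, and the
comparison is about the bacterial community.  Fewer than three taxa
shared by both profiles is an error, not a number: a correlation on two
points is meaningless.

`compare_pe_sr()` summarizes what is lost when a paired-end library is
processed as truncated single reads: total and unique annotation
yields, shared features, and the Pearson correlation of
log10(count + 1) over the feature union.  The log transform is our
choice (raw counts would let a handful of dominant transcripts set the
correlation); the digital truncation itself (`simulate_single_end()`)
discards reverse reads and keeps the first 100 bases (configurable) of
each forward read, sequence and quality in lockstep, leaving shorter
reads unchanged — which makes it idempotent and read-count-preserving.

## The differential stage

The differential-abundance stage is a deliberately transparent
negative-binomial pipeline, of the same family as the established
count-based differential-expression methods but not a port of any of
them: Cox–Reid adjusted likelihoods, independent filtering, and fold
change shrinkage are omitted so that every number is reproducible by
hand from the formulas below.

* **Normalization** — median-of-ratios size factors: sample *j*'s
  factor is the median over features (expressed in all samples) of
  count_fj / geometric-mean_f.
* **Dispersion** — method of moments under Var = μ + αμ²: per feature,
  α̂ = max(0, (s² − μ̄)/μ̄²) on normalized counts within each group,
  pooled across groups by degrees of freedom; a trend α(μ) = a0 + a1/μ
  is fit to the raw estimates by robust regression; the final value is
  a log-scale weighted combination of raw and trend (weight 0.5 by
  default), floored at 1e-8.  A raw estimate of exactly zero carries no
  per-feature signal (the truncated moment estimator), so such features
  take the trend value outright instead of dragging the geometric
  combination toward the floor — without this the Wald test is visibly
  anticonservative for low-count features.
* **Testing** — group means on the normalized scale (the mean of
  count/size-factor within each group, which makes fold changes exactly
  invariant to rescaling any one sample), log2 fold change with a
  0.5-normalized-count pseudo-mean added to both groups when either
  mean is zero (flagged in the output), standard errors from the NB
  Fisher information I_g = Σ_j μ_gj/(1 + α μ_gj), two-sided normal
  p-values, Benjamini–Hochberg adjustment over all tested features, and
  sorting by adjusted p (ties by raw p, then feature name).  All-zero
  features are reported with fold change 0 and p = 1 rather than
  dropped, so output rows always match input features.

Calibration is checked by simulation in the test suite: on null
matrices (2,000 features, 8 vs 8, dispersion 0.05) the raw p < 0.05
fraction sits at 0.05 ± 0.02 and BH discoveries are essentially absent;
planted 4-fold changes are recovered within ±0.3 log2 units; a planted
dispersion of 0.2 is recovered within [0.1, 0.35] at 10 samples per
group.  Only two-group designs are supported — the comparisons this
pipeline exists for are all two-group — and exact numeric agreement
with any specific external implementation is a non-goal (sign and
significant-set agreement on well-expressed features is the realistic
expectation).

## The synthetic-data generator

Every analysis above is testable offline because the generator emits
data *and* machine-readable truth:

* `sim_community()` — taxon proportions from a lognormal (σ = 1.5 by
  default; a power law is the alternative) over a built-in mock
  taxonomy of 6 bacterial phyla / 30 genera plus a few non-bacterial
  entries for domain-filter tests.  Real lineages are unnecessary for
  correctness testing.  The community's rRNA fraction defaults to 0.9,
  reflecting non-ribodepleted total-RNA libraries in which ribosomal
  reads dominate; analyses that want mRNA-rich input set it lower.
* `sim_annotations()` / `sim_abundance_table()` — multinomial read
  assignment, tied second-best hits at a configurable rate, SILVA-source
  rRNA records at the profile's rRNA fraction.
* `sim_depleted_pair()` — per-phylum Bernoulli retention of rRNA reads
  followed by resampling back to the original depth, mimicking fixed
  sequencing throughput; the resampling realistically inflates whatever
  was not depleted, and the emitted truth accounts for it.
* `sim_count_matrix()` — NB (or Poisson) counts with lognormal baseline
  means, lognormal per-sample depth factors, and planted log2 fold
  changes.
* `sim_fastq()` — random-base paired reads with constant quality.

Every generator is a pure function of its seed (the global RNG stream
is saved and restored), and `profile_taxonomy()` returns the lineage
map covering exactly the simulated taxa.

What the generator does **not** emulate bounds what green tests mean:
there is no annotation error (every read is labeled with its true
organism), no sequence-level realism (error models, GC bias), no
compositional coupling between taxa, and no overdispersion between
biological replicates of the same community beyond the NB model.
Passing tests demonstrate that the *computations* are correct and
calibrated under their stated models — not that any particular real
dataset satisfies those models.

## Numerical conventions

Ties in every sort are broken lexicographically in byte order
(locale-independent), so identical inputs give byte-identical outputs;
the CLI writes no timestamps into data files for the same reason.
Proportions are validated to sum to 1 within 1e-9.  Dispersions are
floored at 1e-8.  Accuracy is clamped to [0, 100].  Degenerate inputs
error early with typed conditions (`samsa_validation_error`,
`samsa_parse_error`, ...) rather than propagating NaNs: empty tables
cannot be normalized, abundance classes need more than five features,
correlations need three shared taxa, dispersion estimation needs two
samples per group.

## Command-line layer

`run_cli()` (wrapped by `inst/scripts/samsa`) exposes the pipeline as
subcommands — `aggregate`, `matrix`, `diff`, `depth-curve`,
`depletion`, `correlate`, `single-end`, `simulate` — each a thin shim
over the functions above, configured by a YAML file, with the seed and
parameters recorded in every output header.  Plots (stacked
composition bars with the top-30 + "Other" convention; sample
dendrograms on Bray–Curtis dissimilarity with average linkage, both
configurable since conventions vary) always write their underlying
numbers as TSV alongside the image, so checks assert on data rather
than pixels.

## Worked example

```{r example}
prof <- sim_community(n_taxa = 20, rrna_fraction = 0.3, seed = 42)
recs <- sim_annotations(prof, 20000, tie_rate = 0.05, seed = 43)
parts <- filter_rrna(recs)
tab <- aggregate_counts(parts$mrna, sample_id = "demo")
head(sort_abundance(tab))

curve <- accuracy_curve(tab, subsample_spec(replicates = 20, seed = 44))
min_depth(curve, class = "low", threshold = 90)
```

## Known limitations

Only two-group differential designs; no taxonomy database is bundled
(rollup above genus needs a user map); the depletion metric is the
package's own definition and is not numerically comparable to published
tables computed with unstated normalizations; the MG-RAST client builds
request URLs but performs no network calls; and the generator's
simplifications listed above.
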