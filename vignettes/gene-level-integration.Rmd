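---
title: "Gene-level integration of methylation and expression with rule-based models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level integration of methylation and expression with rule-based models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ruleOmics)
```

# The model

`ruleOmics` classifies tissue samples as tumoral or normal from two
molecular views of the same genes and extracts *many* alternative
rule-based models rather than a single black box. This vignette records
the methodological decisions and their rationale.

## Gene methylation quantity

Array- or sequencing-based methylation data arrive as per-CpG-site
*beta values*, the fraction of methylated signal at a site
(methylated / total intensity, in $[0, 1]$). The gene-level measure
used throughout the package is the **sum** of the beta values of all
sites annotated to the gene in one sample:

$$ b_{ij} = \sum_{h \in \mathrm{sites}(j)} a_{ijh} $$

A sum (rather than a mean) keeps the measure sensitive to both the
methylation level and the number of covered sites. The consequences
are testable invariants: gene-level quantities conserve the total
annotated beta mass of a sample, are invariant to the record order of
the input file, and grow monotonically when sites are added. Sites
with a missing beta value or an empty gene annotation are excluded
before summation; composite annotations (`"A;B"`) contribute the site
to every listed gene.

## The combined matrix

The per-experiment matrices are joined with a **full outer join** on
truncated aliquot barcodes (`project-TSS-participant-sample`, the
granularity at which tissue class is defined). Two choices matter:

* **Suffixed disjoint union of features.** Every methylation feature
  gets `_dnaMeth`, every expression feature `_rnaSeq`. A gene measured
  in both experiments contributes two columns; there is deliberately
  no symbol-level deduplication, so the combined width is always the
  exact sum of the input widths and a rule's threshold is always
  interpretable in the units of one data type.
* **Missingness is explicit, conflicts are errors.** Samples present
  in one experiment keep the other block as `NA` (`?` on disk), so
  downstream rules simply never fire on absent values (a conjunction
  with a missing operand is unsatisfied). Two aliquots of the same
  truncated sample within one experiment, or class labels that
  disagree between experiments, abort with an error: both indicate an
  upstream bookkeeping problem no join should paper over.

## Rule induction

The learner is a RIPPER-style sequential covering algorithm:

1. The minority class is the positive class (ties break to the
   lexicographically first); the majority class is the default.
2. The data are split 2:1 into grow/prune sets (`pruneFolds = 3`).
3. A rule is grown greedily by adding the condition maximizing FOIL
   information gain $p(\log_2 \frac{p}{p+n} - \log_2 \mathrm{base})$,
   with candidate thresholds at the midpoints of consecutive distinct
   values of each feature among the currently covered grow rows.
4. The rule is pruned back to the prefix maximizing $(p-n)/(p+n)$ on
   the prune set, and accepted while pruned precision stays at least
   $0.5$; covered positives are removed and the loop repeats.
5. The whole procedure runs `optimizationRuns = 2` times with derived
   seeds and keeps the model with the best training macro F-measure.

Determinism is a design requirement: ties between candidate conditions
prefer `<=` over `>=` and then the smaller midpoint, so the same input
and seed always yield the same model, byte for byte.

**Small-data path.** Reduced-error pruning needs a prune set large
enough to estimate precision; with very few samples a 2:1 split leaves
a 2-4 row prune set whose precision estimate is mostly noise and can
reject every rule. When fewer than 15 samples (or fewer than 5 of
either class) remain, the learner therefore grows on all remaining
rows and skips pruning, accepting rules at training precision
$\ge 0.5$. The cutoff was chosen (and then verified on 420 freshly
generated tiny datasets) so that the trained model's training accuracy
always dominates an exhaustive search over all single-condition
rules — an oracle bound any sensible rule learner should clear.

## Iterative multi-model extraction

`runCamur` archives every model whose mean macro F-measure over
stratified k-fold cross-validation reaches `fThreshold` (default 0.8),
then continues training with features eliminated:

* **standard** mode removes the rule features of each archived model
  permanently and stops as soon as quality drops below the threshold —
  fast, and yields pairwise-disjoint gene sets.
* **loose** mode enumerates elimination subsets of the pool of
  previously used rule features, by increasing size and
  lexicographically within a size, one subset per iteration. A subset
  that fails to intersect the rule-feature set of *every* archived
  model is skipped without training: the learner is deterministic
  given a feature set, so training without such a subset provably
  reproduces an already-archived model. This hitting-set filter is
  what makes loose mode practical — without it, reaching the $k$-th
  alternative gene requires enumerating $O(2^k)$ subsets that cannot
  produce anything new. Enumeration is capped at 200000 examined
  candidates per iteration.

A model is archived only if its rule-feature set differs from every
archived model's (novelty), preventing duplicate models from temporary
eliminations that the learner routes around. Runs stop on
`below_threshold`, `max_iterations`, `time_limit` or `exhausted`, and
each iteration draws its learner and fold seeds from the master seed,
so a run is exactly reproducible.

## Evaluation and permutation validation

Per-class precision, recall and F-measure use the standard definitions
with degenerate denominators mapped to 0; both the macro (equal class
weight) and frequency-weighted averages are reported. Cross-validation
folds are stratified by class and seeded. Permutation validation
reruns the full cross-validated pipeline on label-shuffled copies of
the data: each replicate is a pure permutation (class frequencies
preserved) under a derived seed. On a balanced two-class problem the
expected macro F-measure under shuffled labels is near 0.5; values far
above indicate leakage, values far below a broken scoring path.

# The synthetic cohort

Genuine cohorts are multi-gigabyte downloads, so the package generates
TCGA-like cohorts on disk with known ground truth.

* **Site-level betas** are drawn from Beta(2, 5) — right-skewed with
  mean $2/7 \approx 0.29$ and SD $\approx 0.16$, resembling the bulk of
  CpG sites, which are lowly methylated with a long upper tail. Each
  gene gets 3-8 sites, so gene-level aggregation is genuinely
  exercised.
* **Expression values** are LogNormal(2, 1): positive, heavy-tailed
  abundances like RSEM estimates.
* **Planted genes**: in tumoral samples, every site of a planted
  methylation gene is shifted by `effectSize` background SDs (then
  truncated to $[0,1]$), and planted expression genes are shifted by
  `effectSize` SDs on the log scale. The default effect of 3 SDs makes
  recovery expected rather than lucky, which is the right regime for
  acceptance testing: failures then indicate bugs, not noise.
* **Availability** mimics real cohorts: by default 80% of samples have
  both experiments, 10% only methylation, 10% only expression, so the
  outer join and missing-block handling are always exercised.
* Values are rounded to 4 decimals before writing, making generated
  files byte-identical across runs.

The default study size — 200 samples, 500 genes, 10 planted — was
chosen so that the full pipeline (matrix assembly, 10-fold CV, a loose
extraction run and 25 permutation replicates) completes in minutes on
one CPU while leaving 490 decoy genes to make false recovery
detectable.

# Limitations

* Gene-level sums discard within-gene spatial structure (promoter vs
  body methylation act differently in reality).
* The learner handles exactly two classes and numeric features.
* Loose-mode enumeration, even with the hitting-set filter, grows with
  the pool size; very large archives should use standard mode or an
  iteration cap.
* The synthetic generator plants mean-shift effects only; it does not
  simulate batch effects, copy-number confounding or correlated gene
  modules.
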