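---
title: "Methods: tissue-of-origin classification, actionability tiering, and outcome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue-of-origin classification, actionability tiering, and outcome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`seqdirect` re-implements, as tested and seedable code, the analysis layer
of an integrative (DNA + RNA) precision-oncology program: classifying the
tissue of origin of carcinomas of unknown primary (CUP) from bulk RNA
expression, assigning genomic alterations to clinical-actionability tiers,
categorising pathogenic germline variants (PGVs) and calling somatic second
hits, and computing duration-based clinical-benefit statistics. Real
patient-level sequencing from such programs sits under controlled access,
so the package ships a synthetic-cohort generator with planted ground truth
that exercises every stage end to end.

## Tissue-of-origin ensemble

A metastatic biopsy is never pure tumor: it carries transcripts from the
normal tissue at the biopsy site. A classifier trained on clean primary
tumor profiles degrades on such mixtures. The estimator here confronts the
classifier with contamination *during training*. Each training profile may
be admixed with normal-tissue expression, and the admixture is a physical
mixture of transcripts, so it is computed in linear space:

$$x_{\text{mix}} = \log\!\big(1 + (1-\alpha)\,e^{x_\text{tumor}} - (1-\alpha) + \alpha\, (e^{x_\text{normal}} - 1)\big),$$

i.e. de-log (expm1), mix with fraction $\alpha \in [0,1]$ of normal signal,
re-log (log1p). Profiles are first library-size normalised to a fixed total
of $10^4$ and log1p-transformed, which makes them invariant to global
scaling of the raw abundances.

Three contamination schemes build three training sets:

* **NONE** — profiles unmodified;
* **BIOPSY_SITE** — each sample mixed with the normal expression vector of
  its own biopsy site;
* **MEAN_ALL_SITES** — each sample mixed with the unweighted linear-space
  mean of all sites' normal vectors.

Two learner families are fitted on each: a nu-support-vector machine
(linear kernel, `e1071`; margin scores mapped to probabilities by Platt
scaling fitted on internal cross-validation folds, since the ensemble needs
members on a common probability scale) and an L1-penalised multinomial
logistic regression (`glmnet`; penalty chosen by internal cross-validation).
That yields the 6-member bag: {nu-SVM, multinomial lasso} x {NONE,
BIOPSY_SITE, MEAN_ALL_SITES}. Prediction aggregates with equal weights: the
ensemble probability vector is the element-wise arithmetic mean of the six
members' vectors. The label is the arg-max class, ties broken by
lexicographic class name; when the top mean probability falls below the
confidence threshold the case is reported `UNCLASSIFIED`. A CUP case counts
as *reclassified* when the prediction is definitive.

Decisions taken where the design was genuinely open:

* **Contamination fraction.** No canonical distribution for $\alpha$
  exists; the default sampler is uniform on $[0, 0.5]$, one draw per
  training sample, spanning plausible biopsy impurity without letting
  normal signal dominate. It is an argument (`alpha_sampler`), not a
  constant.
* **Bag membership.** "Bagging" here means equal-weight aggregation of the
  six fixed (learner x scheme) models; members are not additionally trained
  on bootstrap resamples. The six models already differ systematically in
  training data and inductive bias, which is the diversity the ensemble
  needs; resampling would add variance without adding a new axis.
* **Probabilities, not votes.** Averaging probabilities preserves
  calibrated uncertainty and makes the `UNCLASSIFIED` gate meaningful;
  majority voting would discard the margin information the gate relies on.
* **Confidence threshold.** Default 0.6: above it one class must hold a
  clear majority of the averaged probability mass, which in practice leaves
  near-uniform mixtures unclassified while passing clean profiles. It is a
  config knob (`threshold`), because any fixed value is a clinical policy
  choice, not a statistical constant.
* **Gene-space alignment.** Prediction requires the exact training gene
  order; a mismatch is a hard error. Silent reindexing or imputation hides
  format bugs that in a clinical pipeline would be catastrophic.
* **nu = 0.25, lasso lambda by cross-validation** — defaults override-able
  through `hyperparams`.
* **Determinism.** Every stochastic step (alpha draws, Platt-scaling folds,
  lasso folds) draws from a substream derived from one master seed; the
  learner substream depends on the learner but not the scheme, so
  degenerate contamination (alpha identically 0) reproduces the NONE
  members bit for bit.

## Actionability tiering

Alterations are placed in one of three tiers by a deterministic rule
engine against a *frozen local knowledge base* (a TSV snapshot of
gene-alteration-context evidence, playing the role live resources such as
OncoKB or CIViC play in practice; live queries would make runs
irreproducible as those databases drift):

* **Tier 1** — established clinical utility in that patient's cancer type:
  pathogenic/likely-pathogenic germline variants with a cancer-risk entry
  (subcategory G, flagged `G1*` when the gene has direct therapeutic
  implications), transcriptome-driven changes of diagnosis (D), and somatic
  events matching FDA-approved benefit (S) or resistance (R) evidence in
  the matching indication.
* **Tier 2** — rationale for investigational or off-label therapy (S), or
  resistance postulated from strong preclinical evidence (R). A somatic
  event whose FDA-approved evidence is for a *different* indication lands
  here: the approval justifies off-label use, not established utility.
* **Tier 3** — biological relevance without therapeutic implication;
  unmatched alterations default here with an empty rationale.

Context matching is exact-string or `ANY` — no ontology traversal, so every
match is auditable. When several entries match, the strongest wins: tier
ascending, then subcategory order G < D < S < R, then entry id. Under this
resolution, upgrading any entry's evidence level can never worsen (increase)
the assigned tier — a property the test suite checks over randomized
fixtures. A patient is *potentially actionable* when they harbor at least
one tier-1 or tier-2 assignment; patient-level counts are deduplicated, so
duplicate records never inflate them.

## Germline analysis

PGVs are categorised by gene against an editable panel TSV into four
groups: highly penetrant cancer-predisposition syndromes, moderately
penetrant syndromes, autosomal-recessive conditions with increased cancer
risk, and autosomal-recessive conditions without known cancer risk. Genes
in the double-strand-break repair set (BRCA1, BRCA2, ATM, PALB2, BRIP1 —
PARP-inhibitor rationale) or the mismatch-repair set (MLH1, MSH2, PMS2 —
immune-checkpoint rationale) carry the therapeutic-target flag. Two genes
appear in published example lists under more than one group (APC, FH); the
shipped panel assigns each gene its first-listed (more severe) category,
and users supply their own panel where a fuller table is available.

A somatic **second hit** for a PGV is called when the same patient's tumor
harbors at least one somatic event in the same gene of class mutation,
homozygous deletion, or loss of heterozygosity. LOH enters as an explicit
event class in the input table rather than being computed from allele
fractions — tumor/normal allele-level analysis is upstream of this package.
Amplifications do not inactivate the remaining allele and do not count.
The call is order-invariant and unaffected by events in other genes.

## Outcome statistics

Therapy courses carry ISO dates; duration is exact day count divided by
30.4375 (the mean Gregorian month), with ongoing courses measured to a
censor date. For sequencing-directed therapy (SDT): **clinical benefit** =
duration >= 6 months, **exceptional response** = >= 12 months. Both bounds
are inclusive ("6 months or longer"), so the exceptional set is a subset of
the benefit set by construction, and thresholds are applied to exact
day-count arithmetic, not rounded months. Benefit rates are computed per
patient (patients with >= 1 benefit course over patients with >= 1 SDT
course) or per instance (courses over courses) — the CUP stratum uses
instances because one patient can receive several serial SDTs. All
percentages are `round_half_up(100 * num / den, 1)`; base R's
round-half-even would drop some boundary cases by 0.1.

## Synthetic cohort: what it emulates, and what it does not

`generate_expression_corpus()` draws log-expression from
$\mathcal{N}(\mu_{\text{tissue}}, \sigma)$ and exponentiates (log-normal
abundances, hence nonnegative and right-skewed). Each tissue up-regulates a
disjoint 10-gene marker block by +2.0 log units over a shared baseline
drawn uniformly on $[0.5, 3]$; block size shrinks automatically when the
gene space is too small for disjoint blocks. Sites get their own marker
blocks and baseline shifts; each site's normal vector is the linear-space
mean of 25 dedicated normal draws — mirroring the use of separate
normal-tissue compendia rather than deriving "normal" from tumors. With
`noise_sd = 0` all samples of a tissue are identical and downstream
classification must recover planted labels perfectly.

`generate_clinical_table()` plants, per patient, Bernoulli-sampled
actionability (a tier-1 or tier-2 alteration whose gene/class/context the
bundled knowledge base resolves back to that tier), PGVs from the panel
genes, somatic second hits at the requested fraction (observable as
same-gene events), and therapy courses with durations from a two-component
mixture — exponential non-responders (mean 2.5 months) and uniform
responders on [6, 30] months — so both benefit classes occur on either
side of the 6- and 12-month thresholds. Planted truths are stored in
`true_*` columns, separate from the observable fields.

The generator makes no attempt to mimic real expression compendia: no
batch effects, no realistic gene-gene correlation, no heavy-tailed
library-size variation, no real gene identifiers, and class separations
are far cleaner than real tumor heterogeneity. Passing the recovery tests
therefore demonstrates that the machinery is correct — contamination
handled in the right space, members aggregated as specified, rules applied
as written — not that the classifier would reach any particular accuracy
on real cohorts.

## Problem sizes and numerical choices

The reference corpus used by the contamination-robustness checks is 5
tissues x 3 sites x 200 genes x 40 samples/tissue at `noise_sd = 0.5`,
split 30/10 per tissue into train/test; property tests run 10 000
randomized tiering fixtures and 1 000 aggregation fixtures. These sizes
give sharp, fast checks at desk scale. Probability vectors are validated
to sum to 1 within 1e-9 (member outputs are renormalised to absorb solver
drift); aggregation equality is checked to 1e-12; ensemble ties break
lexicographically. Dates must satisfy stop >= start; a zero denominator in
a rate reports 0 rather than erroring, except where a rate is undefined by
definition (benefit rate of an empty course set).

## Limitations

* Pathogenicity calls, tier evidence, and panel membership are *inputs*;
  the package adjudicates none of them from primary evidence.
* The knowledge base is a snapshot; keeping it current is the user's
  responsibility, which is the price of reproducibility.
* The tissue-of-origin estimator is trained and evaluated here only on
  synthetic corpora; applying it to real RNA-seq requires retraining on a
  real reference compendium with consistent normalisation.
* No survival modelling: benefit is a duration dichotomy, which is the
  operational definition used in the source analyses, not a
  time-to-event model.
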