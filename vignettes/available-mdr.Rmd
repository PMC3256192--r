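---
title: "Case-control association and Available-case MDR: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case-control association and Available-case MDR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(availmdr)
```

`availmdr` analyses case-control studies in which the risk factors are
categorical: biallelic SNP genotypes coded 0 (homozygous wild type),
1 (heterozygous), 2 (homozygous variant), plus categorical exposures such as
tobacco habit (0 = no habit, 1 = tobacco only, 2 = tobacco + alcohol).  It
was built around cohorts of tobacco-related multiple primary neoplasms -- a
design in which one patient has developed two or more distinct primary
cancers, enriching the cohort for genetic susceptibility -- but nothing in
the machinery is specific to that disease.  This vignette explains the
statistical models, the tunable parameters and their defaults, the numerical
conventions, and what the simulation-based tests do and do not demonstrate.

## Univariate association

For each SNP the three-genotype table against status is collapsed to a 2x2
table under three models:

* **heterozygous**: genotype 1 vs genotype 0 (variant homozygotes dropped);
* **extreme**: genotype 2 vs genotype 0 (heterozygotes dropped);
* **dominant**: genotypes 1+2 (carriers) vs genotype 0.

The crude odds ratio is the cross product $(ad)/(bc)$, with the Woolf
(log-scale) interval $\exp(\ln\mathrm{OR} \pm z_{0.975}\sqrt{1/a + 1/b +
1/c + 1/d})$ and a two-sided exact p-value from the hypergeometric
point-probability rule (all tables with the observed margins whose
probability does not exceed the observed table's; a mid-P variant is
available).  Published tables of this kind mix interval methods -- some
printed intervals are clearly not Woolf -- so the package treats the OR
point estimate as the reproducible quantity and tags every interval with
its method.

Zero cells: by default the OR is reported as 0 or $\infty$ with the finite
interval bound computed from Haldane-Anscombe 0.5-corrected cells; full
correction of all cells is available on request and is always flagged in the
result.  Tables with two zeros on a diagonal (or a 0/0 cross product) have
no defined OR and raise an error.  No multiple-testing correction gates any
output; a Bonferroni column is emitted in the scan purely for transparency.

Covariate-adjusted ORs come from a maximum-likelihood binary logistic model
of status on the collapsed exposure indicator plus covariates, with Wald
intervals.  With no covariates this is algebraically identical to the crude
OR; separation or non-convergence is flagged and no estimate is reported.

## Hardy-Weinberg equilibrium and linkage disequilibrium

HWE is tested in controls: with variant allele frequency
$q = (n_1 + 2n_2)/(2n)$ the expected counts are $(p^2 n,\, 2pqn,\, q^2 n)$
and the statistic is the usual $\chi^2$ on 1 df.  Monomorphic counts return
$\chi^2 = 0$, $p = 1$ by convention.  The statistic is exactly zero iff the
observed counts sit on the HW manifold, and scales linearly when all counts
are multiplied by a constant -- both properties are tested.

Pairwise LD is estimated from unphased genotypes by EM over the four
two-locus haplotype frequencies.  Every genotype pair resolves its two
haplotypes unambiguously except the double heterozygote, whose mass is split
between coupling and repulsion in proportion to the current haplotype
frequencies.  Initialisation is at linkage equilibrium (allele-frequency
products), making the procedure deterministic; iteration stops when the
largest frequency change falls below `1e-8` or after 1000 iterations.
Reported are $D = p_{11} - p_A p_B$ (variant alleles), $D' = |D|/D_{max}$,
$r^2 = D^2 / (p_A p_a p_B p_b)$, and a genotype-association $\chi^2$ on the
3x3 table.  Monomorphic inputs yield an undefined-LD flag rather than a
number.

## The Available-case MDR engine

Multifactor dimensionality reduction pools the cells of a k-way genotype
(or genotype-by-exposure) table into high- and low-risk classes and scores
the resulting one-dimensional classifier by cross-validation.  The package
implements the *Available* variant: for every candidate combination, all
subjects with complete data on exactly those factors are used, so different
combinations may analyse different subject subsets.  Before any interaction
analysis, subjects with more than `max_missing = 5` missing factor values
are excluded outright.

Conventions, in the order they matter:

* **Threshold**: a training cell is high-risk iff its case:control ratio is
  at least $T$, with $T$ the training data's overall case:control ratio.
  This generalises the classic balanced-data $T = 1$ to unbalanced cohorts.
  Comparisons use integer cross-multiplication, so exact ties are exact; a
  tie is labelled high.  Cells with cases and no controls are high, controls
  and no cases low, and empty cells are a third state.
* **Folds**: 10 status-stratified folds derived deterministically from the
  current subject order as consecutive blocks (case remainders fill the
  earliest folds, control remainders the latest, so no fold is left empty
  when the subject count allows).  "Shuffling the order of individuals"
  therefore re-randomises the folds and nothing else.
* **Accuracy**: (correctly labelled cases + correctly labelled controls)/n.
  Test subjects falling into cells empty during training are classified
  low-risk and stay in the denominator -- a conservative convention.
* **Search**: every k-subset of the factors for k in `k_min..k_max`
  (default 1..5); the habit exposure enters on equal footing with the SNPs.
  Within each fold the winner maximises training accuracy, ties broken by
  test accuracy, then by enumeration order.  CVC (cross-validation
  consistency) of a model is the number of folds it won; the per-k winner
  maximises CVC with ties broken by mean test accuracy.
* **Repeats**: the whole search is repeated (default 10 times) after
  shuffling the subject order, with per-repeat seed = master seed + repeat
  index; per k the modal winner across repeats is reported with its CVC and
  accuracies averaged over *all* repeats (its CVC is defined in every
  repeat's search, so the average does not depend on where it won), plus the
  number of repeats in which it was selected.  The overall best model
  maximises mean CVC, ties broken by mean test accuracy.

Two test-accuracy summaries are reported because they answer different
questions.  The winning model's fold-mean test accuracy is the number a
summary table of models quotes.  The *prediction accuracy* -- each fold's
winner scored on its own held-out fold -- is the classic cross-validated
estimate in which selection touches only training data; it is the quantity
that must sit at 0.5 under a null permutation, and the one the calibration
tests assert on.  The winning-model summary can drift above 0.5 on null
data through the CVC tie-break on test accuracy (hundreds of models tie at
trivial CVC), which is a property of the selection rule, not leakage.

### OR-MDR

For the final model, each non-empty cell $j$ with $(a_j, b_j)$ cases and
controls gets an effect size $\mathrm{OR}_j = (a_j/b_j)/(a_0/b_0)$ against
a reference $(a_0, b_0)$ that pools all low-risk cells (default; a
single-lowest-ratio-cell reference is available, since the literature's
convention is not unambiguous).  Intervals use
$\exp(\ln\mathrm{OR}_j \pm z\sqrt{1/a_j + 1/b_j + 1/a_0 + 1/b_0})$; zero
cells are 0.5-corrected and flagged; a cell is significant when its interval
excludes 1.  With no low-risk cell the reference is undefined and the
operation errors rather than guessing.

## The synthetic-data generator

Because the motivating cohort's individual-level genotypes are not publicly
deposited, every stage is exercised on synthetic data and on fixtures
rebuilt from published genotype-by-status *count panels* (shipped as a plain
TSV; reconstruction fills each SNP column independently against its own
subjects, so per-SNP marginals are exact while the joint distribution across
SNPs is deliberately synthetic).

The generator draws SNPs in HWE at configured MAFs and habit from level
probabilities, assigns disease from a penetrance table (a map from
factor-level combinations to disease probability), and ascertains by
rejection sampling until the case and control targets are met -- mirroring
clinic accrual.  Missingness is MCAR only, applied per genotype cell;
status and covariates are never masked.  What this emulates well: marginal
genotype structure, arbitrary k-way penetrance interactions, case-control
ascertainment, available-case missingness.  What it does not: linkage
between the 21 real loci beyond explicit two-locus haplotype draws,
population stratification, genotyping error, or informative missingness --
so passing tests demonstrate algorithmic correctness under the stated
model, not robustness to those real-data features.

The headline recovery experiment plants an XOR-style two-locus interaction:
disease probability 0.45 when exactly one locus carries a variant allele
and 0.05 otherwise, both MAFs 0.5, 200 cases + 200 controls, with 10 noise
SNPs.  Under the default 10-fold / 10-repeat protocol the causal pair is
recovered as the overall best model with mean CVC 10 and mean test accuracy
around 0.8:

```{r xor, eval = FALSE}
snps <- setNames(rep(0.5, 12), c("SNP1", "SNP2", paste0("N", 1:10)))
cfg <- simulation_config(200, 200, snps = snps, penetrance = xor_penetrance())
ds <- simulate_case_control(cfg, seed = 42)
repeat_with_shuffles(ds, k_min = 1, k_max = 5, folds = 10, repeats = 10,
                     seed = 42)
```

Problem sizes used by the test-suite experiments are deliberately modest --
the full search over 12 factors at k up to 5 (1585 models, 10 folds, 10
repeats) runs in a few seconds thanks to a vectorised cell-indexing engine,
and the brute-force equivalence checks use 6 factors and 80 subjects where
a naive per-subject reimplementation is still tractable.

## Design choices that were genuinely open

* **Habit coding**: ingested as a 3-level factor (no habit / tobacco only /
  tobacco + alcohol) with an optional binarisation (any tobacco vs none,
  `habit_factor(binary = TRUE)`), off by default: the 3-level coding loses
  no information and the MDR engine handles multi-level factors natively.
* **Tie at the threshold ratio labelled high**: a cell exactly at the
  cohort ratio carries no evidence either way; labelling it high follows
  the common MDR convention and is applied identically in the engine and
  the enumeration oracle it is tested against.
* **Genotype codes 0/1/2** with a label map per factor, so tables print in
  amino-acid notation while all arithmetic is ordinal.
* **Accuracy, not balanced accuracy**: the method's original formulation
  and the motivating tables report plain accuracy; the threshold-$T$ rule
  already absorbs the cohort imbalance.
* **Reports**: JSON is canonical (full precision, timestamp isolated on one
  field so identical config + seed reproduce byte-identical content
  otherwise); TSVs mirror the published table layouts at 3 significant
  figures by default.

## Known limitations

* Confidence intervals for published tables cannot all be reproduced:
  the sources mix exact, adjusted and asymptotic intervals without saying
  which; only OR point estimates are treated as ground truth.
* Covariate-adjusted ORs require individual-level covariates, which count
  panels cannot provide; the adjusted operation is validated on simulated
  data only.
* The EM LD estimator assumes HWE within loci for the double-heterozygote
  split, as all unphased two-locus EM estimators do.
* MDR results carry no permutation p-value; CVC and held-out accuracy are
  descriptive model-selection statistics, and the null-calibration tests
  quantify their behaviour under no association.
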