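---
title: "Estimating recessive-disease genotype frequencies from population allele counts"
author: "carrierfreq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating recessive-disease genotype frequencies from population allele counts}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrierfreq)
```

## The problem

APRT deficiency is an autosomal-recessive disorder of purine metabolism:
loss of adenine phosphoribosyltransferase activity leads to
2,8-dihydroxyadenine kidney stones and chronic kidney disease.  Like many
rare recessive disorders it is plausibly underdiagnosed, and the reported
case count is a poor prevalence estimate.  A better route is genetic: if
the set of pathogenic alleles of the gene is known, their frequency in
large population sequencing databases predicts how many biallelic
(affected) individuals a population should contain, regardless of whether
those individuals were ever diagnosed.

`carrierfreq` implements that pipeline: a registry of pathogenic variants
in HGVS nomenclature, allele counts per (database, population) cohort,
pooling into a cumulative minor allele frequency, and Hardy-Weinberg
genotype-frequency estimation with the field's reporting conventions.

## The model

Let $p_1, \dots, p_k$ be the population frequencies of the $k$ pathogenic
alleles of the gene in one cohort.  Two assumptions carry the whole
analysis:

1. **Alleles never share a haplotype.**  Each pathogenic allele is
   individually rare and no chromosome carries two of them, so the
   frequency of "a pathogenic allele" is the *cumulative* minor allele
   frequency $p = \sum_i p_i$ (cMAF).
2. **Random mating (Hardy-Weinberg equilibrium).**  Genotype classes then
   have frequencies $p^2 + 2pq + q^2 = 1$ with $q = 1 - p$.

Under assumption 1 the $p^2$ class contains *all* biallelic genotypes —
true homozygotes *and* compound heterozygotes — which is exactly the
clinically affected class of a recessive disease.  $2pq$ is the carrier
frequency; carriers of one allele retain partial enzyme function and are
unaffected.

The estimator ([`hw_fit()`]) therefore needs nothing but pooled integer
allele counts per cohort:

```{r}
fit <- hw_fit(read_counts(cf_fixture("table3_cohorts.tsv")))
fit
```

## Reporting conventions

Published cohort tables report three derived quantities, and matching them
digit-for-digit fixes the numeric conventions:

* **Percent frequency** — `percent(p, decimals)` multiplies by 100 and
  rounds *half away from zero* (so $368/576 = 63.888\%$ displays as 63.9,
  not 63.8).  Base R's `round()` rounds half to even and does not
  reproduce published cells.
* **"1 in N"** — the reciprocal of $p^2$ (or $2pq$), computed from the
  exact integer ratio `alt/an` and rounded half away from zero.  Computing
  from a pre-rounded percent gives visibly different integers: the
  fixture's founder cohort (1304/107,928) yields 1 in 6850 from the exact
  ratio, while its source table prints 6840 (consistent with a pre-rounded
  1.2%).  The package standardises on exact ratios and carries such
  divergences as `note` strings rather than reproducing them.
* **"Not observed"** — a cohort with a pooled alt count of 0 has no finite
  reciprocal; the package returns `NA` and writes an empty string in
  machine output, never 0 or `Inf`.
* **Mixed denominators** — when a cohort's variants were genotyped on
  call sets with different allele numbers, $p$ is the sum of per-variant
  frequencies and the largest allele number is shown as the display
  denominator (with a `mixed_an` flag and a logged message).  The 1-in-N
  figures are then derived from $p$ itself, not from the display ratio.
* **Expected cases** — `expected_cases(p, N)` returns the unrounded
  $N p^2$; headline projections in the literature apply an unstated
  significant-figure convention, so presentation rounding is left to the
  caller.

## HGVS parsing scope

`parse_cdna()` / `parse_protein()` cover the constructs that occur in
curated registries of small variants: substitutions (including intronic
offsets such as `c.81-3C>G`), duplications, deletions, insertions and
delins on the cDNA side; missense, nonsense, frameshift (`fs*3`, `fs*?`),
in-frame deletion, start loss (`p.(Met1?)`) and stop loss
(`p.(*181Argext*?)`) on the protein side.  Formatting a parsed value
reproduces the input byte-for-byte (after whitespace normalisation:
`c.400 + 2dup` and `c.400+2dup` are the same allele).  This is
deliberately *not* a full HGVS implementation — no reference-sequence
validation, no transcript-to-genome projection (the gene sits on the
reverse strand; genomic coordinates are stored as opaque `16:<pos>`
strings), no multi-allele or repeat syntax.

`classify_variant()` computes a systematic consequence class with fixed
rules: an offset of absolute value 1 or 2 is `splice_region` (the
canonical dinucleotide); `c.81-3C>G`, three bases into the intron, is
`other`.  Source tables sometimes print looser labels ("Indel" for a
splice-donor duplication, "Nonsense" for a start loss); those labels are
preserved verbatim in the registry's `paper_label` column so that
golden-table comparisons can use them while analysis logic uses the
systematic class.  Registry rows that print both `c.521_523del` and
`c.521_524del` are kept as distinct raw strings — possibly distinct
alleles are never silently merged.

## The synthetic-data generator

`simulate_cohort()` draws each diploid individual's two chromosomes
independently from the categorical distribution
$\{\text{ref}: 1 - \sum p_i;\ \text{variant}_i: p_i\}$, which encodes both
model assumptions (one pathogenic allele per chromosome at most; random
mating).  Its output is the standard counts TSV, so simulated cohorts flow
through `cmaf()` and `hw_fit()` unchanged.  All randomness comes from R's
default Mersenne-Twister stream seeded once per scenario, so a
(scenario, seed) pair is exactly reproducible.

Three presets mirror the analysis's headline cohorts:

* `iceland_founder` — 50,000 diploids with one allele at frequency 0.012,
  plus a mainland population carrying the same allele 100-fold rarer; a
  classic founder-effect configuration.
* `ireland` — 1365 diploids with three pathogenic variants at 5, 1 and 1
  copies per 2730 chromosomes (following the narrative decomposition of
  the pooled count of 7; the sequenced-cohort table splits the same total
  as 5 + 2).
* `null` — no pathogenic alleles.

What the generator emulates is the *sampling* process of a database
cohort under the model; what it does not emulate is everything the model
itself ignores: consanguinity and inbreeding (which inflate homozygote
frequency beyond $p^2$), relatedness within databases, linkage,
genotyping error, and population structure within a cohort label.  Tests
passing on simulated data therefore validate the estimator's mathematics
and implementation, not the model's adequacy for any real population —
the analysis itself notes that consanguineous populations violate
Hardy-Weinberg.

## Parameter recovery and its calibration

`recovery_check()` simulates replicate cohorts and verifies two things per
population:

1. the mean realized biallelic fraction lies within 3 Monte-Carlo standard
   errors of $p^2$, with
   $\mathrm{SE} = \sqrt{p^2(1-p^2)/(nR)}$ over $R$ replicates of $n$
   individuals;
2. the per-replicate realized cMAF lies within 3 binomial standard errors
   ($\sqrt{p(1-p)/2n}$) of the truth.

Check 2 needs calibration: a *correct* simulator leaves each replicate
outside a 3-SE band with probability $2\Phi(-3) \approx 0.27\%$, so over
200 replicates demanding zero outliers would reject a faithful simulator
about 42% of the time.  The allowed number of outliers is therefore the
upper 99.9% Poisson quantile of $R \cdot 2\Phi(-3)$ (4 outliers at
$R = 200$), which keeps the false-alarm rate near $10^{-3}$ while still
detecting any real miscalibration of the frequency scale.  Replicate
seeds are fixed in advance (consecutive integers), never chosen by
outcome.

The shipped validation uses 200 replicates of 50,000 diploids at
$p = 0.012$ — the founder-cohort configuration, where $p^2 = 1.44\times
10^{-4}$ is large enough that each replicate realises several biallelic
individuals.  For very rare alleles (e.g. $p = 5\times10^{-4}$ in 10,000
individuals, where $np^2 = 0.0025$ per replicate) per-replicate checks
are uninformative and the harness instead compares the *pooled* biallelic
count across replicates with its Poisson expectation.

## Degenerate inputs and tie-breaks

* `alt = 0`: "not observed" sentinel, never a number.
* `alt = an` ($p = 1$): homozygote figure is 1 in 1; the carrier class is
  empty and its reciprocal a domain error.
* $p > 0.5$: mathematically valid, flagged with a "not a minor allele"
  warning.
* Empty count list: $p = 0$, $q = 1$.
* Variants absent from a database contribute `alt = 0` rows rather than
  being dropped, so observed-in-$k$-databases statistics stay computable.
* Rounding ties (`x.5`): always away from zero, at every precision.

## Fixture design

The packaged tables transcribe the printed per-variant and per-cohort
counts of the source study of APRT deficiency (registry of 17 named
variants; the 14-row sequenced-cohort count table; 16 pooled cohort
rows).  Cells whose printed derived values are internally inconsistent
with their own counts (a founder homozygote cell computed from a
pre-rounded percent; one cohort whose frequency corresponds to a subset
of its pooled count; one allele number printed 10-fold too large; one
count/frequency mismatch) carry their discrepancy as a `note` string and
are excluded from golden comparisons.

The per-variant case-allele table
(`case_alleles_synthetic.tsv`) is a *synthetic stand-in*: the full
62-variant case list lives in supplementary material that is not
redistributed here, so the file is constructed to satisfy every published
aggregate (62 variants; 29 observed in databases, 33 absent; 576 case
alleles of which the three most common variants carry 368) with plausible
per-variant counts for the named minor variants.  Only those aggregates
are ever asserted.

## Limitations

* No confidence intervals on allele or genotype frequencies (the source
  analysis reports none); counts are treated as exact.
* No inbreeding-coefficient ($F$) adjustment, no X-linked model.
* Database allele numbers are stored verbatim, including ones flagged as
  implausible; no attempt is made to correct them.
* HGVS support is limited to the constructs above.
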