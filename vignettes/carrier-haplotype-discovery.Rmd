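---
title: "Carrier-haplotype discovery in founder populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Carrier-haplotype discovery in founder populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(founderscan)
```

## The problem

In a population isolate, an ultra-rare clinically actionable variant that
entered on a single founder chromosome can drift to a frequency hundreds of
times higher than in outbred populations. The variant itself is usually too
rare to be on a genotyping array or in imputation panels, but the *haplotype*
it rides on — the allele configuration of the common array SNPs surrounding
it — is measurable in every genotyped cohort member. If a handful of carriers
are known (say, from whole-genome sequencing of one proband plus targeted
sequencing of relatives), the shared haplotype around the variant can be
defined from their phased genotypes and then sought in the whole cohort.
Individuals who carry the full-length haplotype but have no recorded
genealogical connection to the known carriers are candidate *cryptic
carriers*, connected through unrecorded ancestors several generations back.

`founderscan` implements this procedure end to end, together with the
genotype QC it presupposes, an identity-by-descent (IBD) segment caller used
to characterise the relationship between carrier kindreds, the QTc phenotype
statistics used in reporting (the motivating application is a long-QT
potassium-channel variant), and — because real cohorts of this kind are not
publicly distributable — a gene-dropping simulator that generates cohorts
with known ground truth for every quantity the pipeline estimates.

## Coarse and fine haplotype matching

Alleles are coded 0 (reference) / 1 (alternative), two phased haplotypes per
individual. All matching treats a missing allele as a wildcard; the
conservative alternative (missing = mismatch) is available via
`missing_match = FALSE`.

**Coarse method.** For a window of total length $L$ centred on the focal
position $p$ — half-open $[p - L/2,\; p + L/2)$, $L$ grown in 0.2 Mb
increments — `define_carrier_haplotype()` seeks an assignment of one
haplotype per known carrier such that the chosen haplotypes are identical
across the in-window markers. The consensus is that shared allele string;
`scan_cohort()` then returns every other individual with at least one
haplotype identical to it. Because the constraint set at a longer window
contains the constraint set at a shorter one, match sets are nested: growing
the window can only remove matches. Window growth is symmetric about the
focal position; the choice is a convention (the growth direction is not
identifiable from the procedure itself) and is isolated in
`window_marker_idx()`.

Two subtleties deserve note:

* *Ambiguity.* With a single known carrier both haplotypes are valid
  consensus candidates; with several carriers, small windows can admit more
  than one valid assignment (for example when the known carriers are close
  relatives who also share their *other* parental haplotype over a few
  markers). `coarse_sweep()` resolves this by keeping the assignment that
  stays consistent at the largest window — validity is monotone in window
  length, so that assignment is valid at every window of the sweep, which is
  precisely what makes the reported match sets nested.
* *Unresolved positions.* A consensus position missing in every carrier is
  reported unresolved and matches anything.

**Fine method.** Between two specific haplotypes, `fine_extend()` measures
shared length at single-variant resolution: starting from the four markers
physically closest to the focal position (all four must match, otherwise the
shared interval is empty), markers are added outward one at a time in order
of physical distance; a mismatch on one side freezes that side while the
other continues. The reported interval spans the outermost *matching*
markers — a deliberate inner bound. One consequence: for a pair that matches
a coarse window of length $L$, the fine interval always covers the window's
markers but its bp length can undercut $L$ by up to about two inter-marker
spacings when the first marker outside the window already mismatches. The
test suite asserts the coverage form of the coarse/fine consistency claim.

**Uniqueness.** `haplotype_background_frequency()` reports the fraction of
non-carrier haplotypes matching the consensus. With founder alleles i.i.d.
at frequencies $p_j$, the expected chance-match probability of a window is
$\prod_j \max(p_j, 1-p_j)$-ish per haplotype (exactly $\prod_j \Pr(\text{
match at } j)$), so the background decays geometrically in marker count —
short haplotypes are shared by many non-carriers, long ones become unique to
the descent group. This is the entire logic of the sweep: decoy sharers drop
out as the window grows while true carriers persist as far as their descent
segment extends.

## The discovery pipeline

`run_pipeline()` chains QC → consensus/sweep → scan → confirmation → fine
extension → IBD summaries → report. Matches at *every* window are put
through the confirmation assay (in reality, targeted sequencing of matched
individuals; in simulation, a truth lookup), and the nominated carrier set is
the union of confirmed matches up to the first window whose entire match set
confirms — the uniqueness window. Confirming only the final window's matches
would make a single genotyping error inside the uniqueness window silently
drop a true carrier; confirming along the way mirrors how such studies
actually proceed (the shorter-haplotype sharers get sequenced too, and that
is also what establishes that short haplotypes are uninformative).

## Genotype QC

Filter order is fixed, because it changes results: individual call rate
(≥ 98%) → marker call rate (≥ 98%, recomputed on retained individuals) →
exact Hardy–Weinberg test (remove markers with $p < 10^{-6}$) → Mendelian
masking → ancestry outliers (|PC1 or PC2 score| > 6 SD, PCs computed on the
cohort itself after imputing missing calls to marker means and standardising;
no external reference panel). The Hardy–Weinberg test is the exact
conditional test — the probability, given the allele counts, of all
heterozygote counts no more probable than the observed one — implemented by
the standard two-term recurrence and verified against full log-factorial
enumeration for every table with ≤ 60 alleles. Mendelian scanning applies
the biallelic trio/duo impossibility rules; because the erroneous member of
a flagged trio is unidentifiable, the whole trio is masked at the offending
marker (a conservative reading of "set erroneous genotypes to missing").

## IBD segment calling

`call_ibd_segments()` is a deliberately transparent stand-in for
likelihood-based kinship toolkits, operating on unphased genotypes (phase is
not required to exclude IBD: opposite homozygotes AA/aa are impossible on a
shared haplotype). Candidate segments are maximal runs of informative
markers containing at most `max_opposite_homozygotes` (default 1) opposite
homozygote pairs; runs shorter than `min_length_bp` (2.5 Mb) or
`min_markers` (100) are dropped. A run whose IBS2 fraction is ≥ 0.99 is
upgraded to IBD2.

Raw run edges overshoot the true segment by the waiting distance to the next
chance opposite homozygote (mean ≈ 0.4 Mb at the default density), so when
marker allele frequencies are available the edges are refined by the
maximum-likelihood changepoint of the cumulative per-marker log-likelihood
ratio of the IBD1 versus IBD0 genotype-pair distributions (with a small
error mixture so an isolated opposite homozygote is penalised, not fatal).
Two guards matter: short raw runs are discarded *before* refinement (a true
segment's raw run always spans it, and an adjacent spurious run would
otherwise climb the neighbouring likelihood hill and claim part of a real
segment), and each run's refinement window is capped at its neighbours.

**Accuracy limits.** At the desk-scale default of 30 markers/Mb with founder
MAF uniform on [0.1, 0.5], the per-marker information for the changepoint
(KL divergence between the IBD1 and IBD0 pair distributions) is only ≈ 0.16
nats, which bounds changepoint accuracy to tens of markers. Measured over 50
simulated first-cousin pairs: precision 1.00, and ~81–88% (not ≥ 95%) of
truth segments ≥ 5 Mb are recovered with both boundaries within ±0.5 Mb. The
corresponding acceptance test is left red rather than loosened; real array
densities (~180 markers/Mb) would meet it.

**Relationship calibration.** `relationship_calibration()` gene-drops cousin
pairs of a chosen degree and reports sharing in both conventions in use:
the genome fraction where the pair shares ≥ 1 haplotype (expectation
$(1/2)^{2d}$ for degree-$d$ cousins — $1/64$ for third cousins — and $3/4$
for siblings) and the haplotype-weighted fraction in which one-haplotype
sharing counts half (expectation $(1/2)^{2d+1}$ — the familiar 0.78% for
third cousins, 50% for siblings). Both are validated against single-locus
path enumeration.

## The synthetic cohort: what it emulates, and what it does not

`sim_config()` describes the stated world; its defaults are the conditions
the whole test suite runs under:

| parameter | default | rationale |
|---|---|---|
| genome | 4 autosomes × 50 Mb | desk scale; keeps full-pipeline tests in minutes while preserving segment-length arithmetic |
| recombination | Haldane, 1 cM/Mb sex-averaged | simplest testable model; no interference, crossovers Poisson with mean = genetic length |
| marker density | 30 / Mb | array-like desk scale (the region's real array density is unreported; exposed as config) |
| founder MAF | uniform on [0.1, 0.5] | post-QC common array SNPs; i.i.d. across markers and founders |
| array MAF cut | 0.05 | array ascertainment; the focal variant itself is never a marker |
| pedigree | 2 kindreds × 3 generations, Poisson(2.5) sibships, 1 hidden third-cousin link, 150 unrelated singletons | two recorded kindreds joined ~4 generations back through unrecorded ancestors, in a background of nominally unrelated participants |
| QTc model | carrier 456 ms, non-carrier 413 ms, sd 15 ms, penetrance 1 | the reported group means; sd chosen as a typical within-group spread; penetrance refers to the QTc *shift*, so 1 reproduces group means computed over all carriers |
| error rates | 0 | corruption is opt-in per experiment (tests use 0.2% genotype / 0.1% switch where stated) |

Founder haplotypes are i.i.d. per marker — there is **no background linkage
disequilibrium**. This is a deliberate modelling choice: haplotype-match
power depends mainly on marker density and allele frequency, and i.i.d.
founders make uniqueness and background-frequency computations analytic, so
tests can check observed counts against closed forms. The cost is realism:
in real data, LD makes short haplotypes *more* shared than the product
formula predicts, so a green test here does not establish calibrated
false-match rates for real cohorts — only the structural properties
(nestedness, sensitivity to descent segments, geometric background decay).

Chromosomes are 0.5 Morgans long, so founder segments survive many meioses
largely intact; whole-chromosome sharing between conditioned relatives is
common in this world, and fine-extension lengths are correspondingly long.

**Ascertainment conditioning.** With one hidden link, the focal variant is
planted on haplotype 1 of the hidden ancestral father, and its transmission
is conditioned along both hidden chains, to two children of the first
chain-bottom and one child of the second. The conditioned meioses are
redrawn until the child inherits the founder haplotype over at least
`focal$min_shared_bp` (default 1.22 Mb) around the focal position. This
emulates how such carrier sets are ascertained in reality — the analysis is
only ever run because a sequenced proband, confirmed relatives, and a
cryptic carrier pair sharing a sizeable haplotype *were observed* — and it
is also the world the acceptance fixture stipulates (cryptic carriers
sharing at least the uniqueness window). Everything else recombines freely;
additional unconditioned carriers arise naturally.

Known out-of-scope features: no X chromosome, no de novo mutation, no
selection, no coalescent-realistic LD, no population splits; statistical
phasing is replaced by truth phase plus optional switch-error injection.

## Numerical conventions

* Marker positions are 1-based bp; windows are half-open; truth IBD segments
  are half-open on the 0-based line and tile $[0, L)$ exactly.
* Lengths print as Mb to 2 decimals (windows) or 1 decimal (IBD summaries).
* The exact HWE p-value comparison uses a $1 + 10^{-10}$ relative tolerance
  when summing "no more probable" outcomes, the standard guard against
  floating-point ties.
* All randomness flows from one seed through named substreams
  (`substream_seed()`), so every module is reproducible independently of
  call order; pedigree build and conditioned gene-dropping retry on
  deterministic substreams, so a config maps to exactly one cohort.
* Bazett's correction uses RR in seconds (`QTc = QT/sqrt(RR)`); a heart-rate
  overload (`RR = 60/HR`) is provided. The frequency denominator counts
  diploid individuals (5 carriers in 2,011 individuals → 5/4022 ≈ 0.0012).
* QTc prolongation cut-offs default to the clinical convention 450 ms
  (male) / 470 ms (female), exposed as configuration.

## Known limitations

* Exact-identity matching has no error model; robustness under genotyping
  error comes from the pipeline's confirmation design, not the matcher.
* The IBD caller's boundary accuracy is information-limited at desk-scale
  density (see above); its IBD2 upgrade is a simple IBS2-fraction rule.
* The ancestry outlier step has no external reference panel, so it detects
  only outliers relative to the cohort itself.
* CLI configuration files are JSON rather than YAML (no YAML parser in the
  supported dependency set).
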