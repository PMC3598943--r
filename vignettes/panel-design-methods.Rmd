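---
title: "Methods: designing an even, multi-line SNP array panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: designing an even, multi-line SNP array panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelforge)
```

panelforge packages the methodology behind the chicken 600K genotyping
array: reduce a very large multi-line variant catalog to a designable
candidate list, select a budget-constrained panel that is evenly spaced
in genetic-map distance for every target line, and qualify the panel
with post-genotyping analytics. This vignette records the model, its
assumptions, the tunable parameters, and the design decisions taken
where the methodology leaves the implementer latitude.

## The selection model

The unit of evenness is the centimorgan. Physical spacing would
under-serve micro-chromosomes, whose recombination rate (cM/Mb) is
several-fold that of the macro-chromosomes; a panel meant for
association mapping and genomic selection needs markers per unit of
*recombination*, not per megabase. All spacing decisions therefore run
through a `genetic_map`: per-chromosome anchors (bp, cM), strictly
increasing in both coordinates. Between anchors we interpolate
linearly — the simplest monotone scheme, and the standard choice when a
published map provides only marker-level anchors; no interpolation rule
is dictated by the methodology itself, so this choice is flagged for
sensitivity analysis. Beyond the terminal anchors we extrapolate at the
terminal interval's rate (floored at 0 cM) rather than clamping, so
telomeric candidates retain a strict ordering.

Selection proceeds in two phases.

**Backbones.** Candidates segregating across whole groups of lines are
placed first: segregating in all lines (count *N*), in all inbred lines
(*I*, of which *I_u* segregate in no commercial line), in all layer
lines (*L*, of which *L_u* segregate in no broiler), and in all broiler
lines (*B*). Each pass scans positions left to right and accepts a
candidate iff it lies more than *t* bases from every accepted SNP on
the chromosome. The default *t* = 2000 bases corresponds to the mean
spacing of a 600K panel on a ~1 Gb genome. Two readings were open here:
whether *t* binds in the later passes (we apply it to every backbone
pass — the spacing rationale, assayability and redundancy, does not
weaken after pass one) and whether "segregating in the inbred lines"
means every inbred line or any (we read *every*, symmetric with the
all-layers and all-broilers passes; `build_backbones` documents the
counters so the union reading can be audited from the output). "Layer
lines" means the commercial WEL and BEL groups; the unselected
experimental layer line is deliberately excluded from the group
definition since it is not a selection target. In final-panel mode,
validated coding SNPs are appended with no spacing constraint (*C*).

**Per-line gap filling.** Lines are processed in order of decreasing
LD — white egg layers, then brown, then broilers — so the lines that
need the densest coverage fill last, against the richest backbone. For
line *i*, panel SNPs segregating in that line (plus the chromosome's
map ends) bound the segments; with *F_i* the panel SNPs *not*
segregating in the line, the chromosome set splits into *X − F_i + 1*
segments. A segment of length *L* cM at target density *d_i* SNPs/cM
receives a quota

> n = 0 if L < 1/d_i, else round(L · d_i) (half up),

filled by the size-*n* subset of the line's unselected candidates
minimising the sum of squared consecutive gaps, segment bounds
included as fixed endpoints. The quota rule is a declared design
choice — the methodology states only that *n* is "a function of the
density and the length". One consequence is worth recording: a segment
of length exactly 1/d receives one SNP even though its bounding
markers already realise the target spacing, so re-processing an
already-covered line places a small number of SNPs into segments at or
just above the critical length rather than exactly zero. The package's
tests assert the resulting strong (not total) saturation; a
`quota_rule = "floor"` option gives the stricter behaviour.

The squared-gap objective is solved exactly per segment by dynamic
programming over (candidate, count) in O(m²n); an exhaustive-search
oracle over all subsets verifies optimality for m ≤ 12, n ≤ 5 in the
test suite. Ties (exactly equal cost) break to the lexicographically
smallest position tuple, then smallest SNP id — ties carry no
scientific meaning, but determinism requires a rule: identical inputs
must yield byte-identical panels.

**Budget calibration.** The methodology fixes the total budget and the
group ratio (1:1 broiler:layer for pre-screening, 3:2 for the final
panel) but not per-line densities. We set
`d_i = s · w_g(i) / (n_g · G)` with *w_g* the group weight, *n_g* the
number of filled lines in the group and *G* the total map length, and
find the scalar *s* by bisection so the realised panel lands within
`budget × (1 ± 0.02)`. Panel size is non-decreasing in *s* (placing
quotas only grow), which bisection exploits; if even saturating
densities cannot reach the budget, all reachable candidates are
selected with a warning. Because selection is per-pass greedy in
provenance, the realised broiler:layer ratio is reported from
provenance (which pass or line placed each SNP); a SNP segregating in
both groups counts toward the pass that placed it, and the
segregation-based ratio can be recomputed from the catalog
independently.

## The filter cascade

Thresholds live in `filter_policy()` and follow the published design:
quality ≥ 60 with MAF ≥ 0.05 per line or globally, prior-panel rescue,
and Chr16/ChrZ exemption (those chromosomes are poorly represented or
unusually depauperate, and retaining MHC- and sex-linked candidates was
worth the artefact risk); ≥ 10 SNP-free bases on one side and ≥ 4 on
the other; 16-mer count ≤ 100 with p-convert ≥ 0.2; coverage beyond
mean + 3 SD per line; Hardy-Weinberg P < 1e-5 after genotyping. Four
decisions were genuinely open:

* **Either-strand design rule.** Whether both probe strands or either
  must pass the design thresholds is not decidable from the published
  account ("irrespective of whether the forward or reverse probes were
  considered"); we require *at least one* strand to pass both
  thresholds, the permissive reading consistent with how Axiom probes
  are tiled. Inclusive comparisons at the printed thresholds.
* **Single-pass proximity.** The spacing screen is evaluated once on
  the original configuration, not iteratively after removals: the
  clustered region is itself the suspected artefact, and iterative
  re-evaluation would erode cluster flanks that are individually
  well-spaced. An `iterative = TRUE` flag exists for sensitivity work.
  The screen is applied to the union catalog (not per line).
* **Sample SD, strict inequality** for coverage outliers; the
  published account does not distinguish population from sample SD.
  Lines with fewer than two segregating records contribute no
  exclusions.
* **Missingness is never a pass**: absent evidence fails a threshold
  but `filter_hwe_extreme` keeps records with no p-value (untested is
  not extreme).

The k-mer masker counts forward-strand, overlap-inclusive occurrences
and ignores k-mers containing N; both choices are conventions (the
published account specifies neither), recorded here and enforced by an
independent dictionary-count oracle in the tests.

## Validation analytics

The exact Hardy-Weinberg test is the conditional test: given sample
size and minor-allele count, heterozygote counts of matching parity are
weighted by `n!/(n_AA! n_AB! n_BB!) · 2^n_AB`, and the p-value sums the
probabilities of outcomes no more probable than the observed one. This
is the concrete meaning we assign to a "Fisher's exact" HWE
probability; a mid-p variant sits behind a flag. A genuinely
independent oracle (enumeration of equally likely allele-slot
configurations) confirms the implementation for all tables with n ≤ 8,
and the null rejection rate over 2,000 simulated HWE SNPs stays below
nominal, as expected of a conservative exact test.

In the pipeline the Hardy-Weinberg exclusion is evaluated *within*
lines (any line with at least 10 genotyped samples; a SNP is removed if
extreme in any of them): validation samples pool strongly
differentiated lines, and testing the pooled genotypes would reject
most SNPs through the Wahlund effect rather than flag genotyping
errors. Related samples (trios) can be excluded via the `samples`
argument of `hwe_test_all()` when a pedigree is available.

Conversion classes use call rate ≥ 0.98 and minor-allele count ≥ 2 as
the operational meaning of "high call rate" and "monomorphic due to low
allele count"; the array vendor's internal cluster-quality rules are
proprietary, so both thresholds are exposed as arguments and declared
approximations. Mendelian checking flags a SNP if any trio shows an
offspring genotype that cannot receive one allele from each parent; any
missing genotype in the trio yields no evidence (the conservative
standard practice), and ChrZ/ChrW are excluded by default because
hemizygous inheritance needs different rules.

Genotype PCA drops SNPs fixed in the sample, imputes missing calls
with the mean dosage 2p̂ (the standard neutral choice; the methodology
is silent), normalises by the Hardy-Weinberg standard deviation
`sqrt(2p̂(1−p̂))`, and decomposes in sample space — equivalent to the
SNP-space SVD, which the tests assert — with the sign of each component
fixed so its largest-magnitude score is positive. Adjacent-pair LD is
the squared Pearson correlation of dosages over samples called at both
SNPs; pairs spanning chromosomes emit nothing, monomorphic members give
`NA`.

## Report arithmetic

Percentages round half up to two decimals and per-group means to one
decimal of a million — the printed precision of the published tables,
which makes the table arithmetic exactly reproducible from counts and
is asserted as a self-consistency invariant by the report writers. Two
distinct gap conventions coexist deliberately: the proximity filter
counts *intervening SNP-free bases* (`pos2 − pos1 − 1`), while spacing
statistics use plain position differences plus the two chromosome-end
distances, so that the gap multiset tiles each chromosome. MAF
histograms bin (0, 0.5] in steps of 0.05 with exact zeros folded into
the first bin. Venn sharing counts SNPs segregating in ≥ 1 line of each
group combination; SNPs segregating only in ungrouped lines are
excluded. The genome-coverage denominator for the cumulative spacing
curve is the supplied chromosome-length table.

## What the generator emulates — and what it does not

`sim_config()` defaults *are* the emulated study conditions: 24 lines
(4 broiler, 6 WEL, 5 BEL, 8 inbred, 1 experimental layer), pools of 10
diploid individuals whose 2×10 allele draws decide segregation,
Balding-Nichols drift with F = 0.1 between groups and 0.05 within, and
F = 0.9 for the inbred lines — chosen so inbred segregation rates fall
an order of magnitude below commercial ones, mirroring the ~1M versus
~10M per-line counts. Quality scores share a per-SNP base component
(N(75, 30), line noise SD 10) so genuinely poor sites fail everywhere;
the combined-lines analysis contributes evidence for 30% of SNPs;
coverage is Poisson(12); per-strand design scores pass with rate 0.417
so roughly two thirds of SNPs are designable on at least one strand.
The genome is scaled down to five chromosomes (2–40 Mb, 2.5–12 cM/Mb)
capturing the macro/micro contrast.

The generator deliberately omits: linkage disequilibrium between loci
(no in-scope computation depends on it; the LD sanity checks construct
correlated pairs explicitly), read-level sequencing noise (pooling
enters only through the segregation draw and coverage), selection
sweeps and demographic history, and ChrW. Passing tests therefore
demonstrate the algorithms' correctness and statistical behaviour under
a neutral drift model — not robustness to real-data pathologies such as
reference bias, batch effects in genotyping intensity, or
map-assembly disagreements.

## Numerical choices and problem sizes

Exact-tie comparisons in the DP and its oracle use a 1e-12 relative
guard; HWE outcome comparison uses `p ≤ p_obs(1 + 1e-12)` so
floating-point noise cannot drop the observed outcome itself. One
boundary case is worth noting: for genotype counts like (2, 0, 2) the
"no more probable than observed" rule yields p = 6/70, counting only
the observed outcome — outcomes with *larger* probability are never
included even when a naive one-sided accumulation might suggest
otherwise. Degenerate inputs follow documented conventions: empty
catalogs select empty panels with a warning; single-anchor chromosomes
have map length 0; chromosomes without panel SNPs contribute their
whole length as one spacing gap; monomorphic-in-sample SNPs are dropped
before PCA, and all-monomorphic input is an error.

The test suite runs at desk scale, sized for thoroughness per CPU
minute: 500 random DP instances against exhaustive enumeration; all
HWE tables to n = 8 plus 2,000 null SNPs; 100 seeded replicates of
50,000-SNP four-line catalogs for the evenness comparison (mean
per-line coefficient of variation of cM gaps, selected versus an
equal-size random subset of the same line's candidates — the mean
aggregates the per-line criterion into one decision per replicate);
3 × 30 samples × 5,000 SNPs for PCA group recovery; and a
1,200-SNP two-chromosome study for the end-to-end pipeline and its
byte-identity rerun check.

## Known limitations

* Densities are calibrated to the *total* budget; per-chromosome
  candidate scarcity (e.g. a sparse micro-chromosome catalog) shows up
  as saturation on that chromosome rather than re-allocation
  elsewhere.
* The quota rule's behaviour at exactly-critical segment lengths
  (above) slightly over-places when a line is re-processed; at realistic
  budget-to-candidate ratios the effect is marginal.
* The flat-file interface replaces the original NoSQL working store;
  no behaviour depends on the storage layer.
* Hemizygous (ChrZ/W) trio rules and sex-specific maps are out of
  scope; both are exclusion flags, not models.
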