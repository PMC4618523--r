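---
title: "Mapping higher-order epistasis by bulk segregant analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping higher-order epistasis by bulk segregant analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsacross)
```

## The genetic system

`bsacross` models a cryptic colony-morphology trait that segregates in
crosses of the *S. cerevisiae* lab strain BY and the clinical isolate 3S.
Most segregants form smooth colonies; a small fraction form rough
colonies, but only when a capacitating perturbation — the
*ira2*&Delta;2933 lesion (a truncation of the Ras-pathway inhibitor Ira2)
or deletion of the repressor gene *SFL1* — co-occurs with a specific
combination of cryptic variants at up to six genes: *END3*, *FLO8*,
*MGA1*, *MSS11*, *SFL1* and *TRR1*. Two such combinations produce the
trait in the *ira2*&Delta;2933 background:

* the **five-way interaction**:
  *END3*^BY^ *FLO8*^3S^ *ira2*&Delta;2933 *MSS11*^BY^ *TRR1*^3S^;
* the **six-way interaction**:
  *END3*^3S^ *FLO8*^3S^ *ira2*&Delta;2933 *MGA1*^BY^ *MSS11*^BY^
  *SFL1*^BY^.

A third combination is revealed by deleting *SFL1* from both parents:
*END3*^BY^ *FLO8*^3S^ *MSS11*^BY^ *TRR1*^3S^ in the *sfl1*&Delta;
background. The package encodes each combination as a penetrance rule
(`trait_rule()`), evaluates rules in order with first-match-wins
semantics, and assigns the rule's phenotype with probability equal to its
penetrance (all default rules are fully penetrant, so classification is
deterministic by default). Everything the rules do is independently
checkable by brute force: `enumerate_rough_genotypes()` scores all
2^6 = 64 allele combinations per background, and the test suite holds the
classifier to that oracle.

With the default rules, 6 of the 64 combinations are rough in the
*ira2*&Delta;2933 background — four satisfy the five-way rule (*MGA1* and
*SFL1* are free) and two satisfy the six-way rule (*TRR1* is free). Since
every cryptic gene and the lesion segregate 1:2 in a BY&times;3S
*ira2*&Delta;2933 cross, exact enumeration
(`expected_class_probabilities()`, 256 weighted states, no Monte Carlo)
gives

```{r expectations}
ex <- expected_class_probabilities(default_rule_set(),
                                   cross_scheme("BYx3S_IRA2MUT"))
ex$p_class
ex$five_to_six_ratio
ex$p_rough
```

that is, a five-way : six-way ratio of exactly 2 and a rough fraction of
3/64. The corresponding study observed a 20:1 ratio among 42 rough
segregants and attributed the skew to a selective advantage of a
BY allele linked to *END3* during random spore isolation, without
quantifying it; the package deliberately does not model that bias (see
*Limitations*), so simulated cohorts converge to 2:1, not 20:1.
Likewise, rough *sfl1*&Delta; segregants are 100% concordant with the
potentiating genotype at penetrance 1, whereas the study reported 43/44
(98%) with one unexplained exception it did not resolve; that exception
is available as an optional low-penetrance rule but ships disabled.

## Meiosis and cross simulation

Gametes are drawn under the Haldane (no crossover interference) model:
crossovers form a Poisson process on the genetic map, so the parental
strand along a chromosome is a two-state Markov chain at the markers,
switching between adjacent markers separated by *d* Morgans with the
Haldane recombination fraction *r* = (1 − e^−2d^)/2, from a fair random
strand at each chromosome start. Sampling this chain marker-by-marker is
distributionally identical to drawing a Poisson crossover count and
placing breakpoints uniformly on the genetic map, and it vectorises over
whole populations. The genetic map is linear in physical position at a
constant rate (default 0.4 cM/kb, a standard yeast genome-wide average;
the study itself states no recombination model).

The engineered sites — *ira2*&Delta;2933 and the *SFL1* deletion — are
carried as states attached to their gene's marker and transmitted with
whichever parental strand is present there, exactly like alleles. The
five cross designs of the study are available through `cross_scheme()`:
the plain BY&times;3S cross, the cross in which 3S carries
*ira2*&Delta;2933, the cross of two *sfl1*&Delta; parents, and the two
backcrosses of a recombinant founder to wild-type BY or 3S. In a
backcross, markers where the founder matches the recurrent parent are
monomorphic; `segregating_markers()` derives the resulting
informativeness mask, which the mapper consumes.

Not modelled: crossover interference, gene conversion, aneuploidy,
mating-type or canavanine selection, and the *END3*-linked viability
bias. Selection enters only through phenotype (and optional causal-allele)
filtering of simulated segregants, mirroring the study's picking of rough
colonies and restriction genotyping of *END3*.

## Pooled sequencing

Selected segregants are pooled equimolarly (exactly — the study states
equimolar mixing, and no strain-abundance noise is added by default). At
each marker the true pooled 3S frequency is the fraction of pooled
haploids with 3S origin. Sequencing draws a Poisson depth per marker
(study coverages: 73&times; and 122&times;; the experiments in this
package use 100&times;) and each read reports the true allele with
probability 1 − *e*, otherwise one of the three other bases uniformly, so
BY&harr;3S cross-contamination occurs at *e*/3 and the remainder lands in
`count_other`. The default *e* = 0.005 stands in for the "small number of
sequencing or read mapping errors" the study mentions without
quantifying. Counts always satisfy
`count_by + count_3s + count_other = depth`, and the frequency estimator
`count_3s / (count_by + count_3s)` is unbiased at *e* = 0.

## The mapping statistic

Mapping follows the study's procedure: per-SNP 3S frequencies, averaged
in running windows of 10 consecutive informative SNPs (step one SNP;
markers with informative depth below `min_depth`, or masked as
monomorphic, are skipped rather than interpolated), and loci called where
windowed means reach 95% or higher (the comparison is inclusive). BY
fixation is detected symmetrically at 1 − threshold, which in a backcross
is only meaningful at segregating markers — hence the mask. A call whose
interval covers an engineered-site marker whose mutant-allele fraction
also reaches the threshold is relabelled `MUTANT`, reproducing the
grey-bar loci of the study's frequency plots. `delimit_interval()`
reports the smallest region spanned by the qualifying windows of a call;
the threshold rule is applied at the window level throughout (the
single-SNP reading of the delimitation step would only tighten intervals
at the cost of noise sensitivity).

Two hygiene parameters guard the window machinery, both expressed in
genetic distance because the underlying physics is recombination decay —
the expected pooled frequency at distance *d* from a selected site is
1 − *r*(*d*), which falls through 0.95 at about 5 cM:

* `max_window_cm` (default 10): a window of 10 consecutive *informative*
  markers can straddle a long monomorphic founder block, averaging
  markers tens of cM apart where 1 − *r* is far below threshold; such
  windows carry no usable signal and are discarded.
* `merge_gap_cm` (default 25): qualifying windows whose spans lie within
  this distance are one locus. A selected locus's above-threshold
  shoulder extends ~5 cM, and pool-sampling noise (which is regionally
  correlated, since neighbouring windows share segregants) pushes
  detached qualifying windows 10–20 cM further out; distinct causal loci
  on one chromosome sit many tens of cM apart, so the radius separates
  the two regimes cleanly. The same radius merges reciprocal-panel calls
  in `map_backcross_pools()` — the engineered IRA2 locus legitimately
  appears in both panels, fixed for different alleles.

`map_backcross_pools()` maps the two backcross panels independently and
unions the calls by causal-site overlap and proximity, preserving
panel provenance: in a six-way founder's backcrosses, *END3*, *FLO8* and
the IRA2 lesion are only mappable against BY, while *MGA1*, *MSS11* and
*SFL1* are only mappable against 3S — the reason the study ran
reciprocal backcrosses at all.

## Scaled maps: what is preserved and why

The real design assessed 36,756 SNPs across the ~12.1 Mb, ~4,800 cM
genome (~7.7 SNPs/cM, so a 10-SNP window spans ~1.2 cM). Simulations at
that density are wasteful for routine testing, but naive scale-downs
change the physics. Shrinking only the marker count stretches windows to
~20 cM, where 1 − *r* averaged over a window cannot reach 0.95 even at a
perfectly selected locus; shrinking the genome proportionally restores
window width but collapses three *genetic* quantities that the real map
keeps large. `scaled_marker_map()` therefore preserves, in order of
priority:

1. **marker density per cM** (`markers_per_cm`, default 4, close to the
   study's 7.7): keeps 10-SNP windows a few cM wide, so windowed means at
   selected loci sit near 0.99 rather than straddling the threshold;
2. **the IRA2–SFL1 separation on chromosome XV** (`xv_sep_cm`, default
   120 cM; really ~166 cM): the two XV loci must stay quasi-unlinked.
   The failure modes of a too-small separation are concrete: the valley
   between two selected loci has expected 3S frequency
   *r*(*u*)·*r*(*D*−*u*)/(1 − *r*(*D*)) at distance *u* from one locus,
   and the exposed band just beyond the merge radius must sit at least
   ~3 pool-noise SDs below threshold (pools of ~88 give SD ≈ 0.035).
   *D* = 120 with a 25 cM merge radius satisfies that with margin, while
   also keeping the pair's recombination fraction (0.45) near the real
   0.48 so segregation ratios are not distorted;
3. **a minimum flank around each causal site** (`min_flank_cm`, default
   6 cM): proportional shrinking pushes *MGA1* (at 91% of chromosome
   VII) against the telomere, deleting the plateau on one side; on the
   real map every causal gene has ≥ 40 cM of flank. Chromosomes without
   causal sites absorb the freed genetic length — they need no mapping
   power.

The default `build_marker_map()` keeps the real chromosome sizes and is
used wherever genetics rather than mapping power is under test (e.g.
segregation-ratio convergence), since there all causal pairs except
IRA2–SFL1 lie on different chromosomes and assort independently.

## Problem sizes used by the tests and the acceptance script

The mapping experiments run on 2,000-marker scaled maps with the study's
pool sizes (63 rough segregants from the BY backcross, 88 from the 3S
backcross, both *END3*-genotyped as in the study) at 100&times; coverage;
recovery is checked across 20 seeds in the test suite and 10 in the
acceptance script, and the unselected null control uses 50 (suite) or 20
(script) pools of 100 segregants. Backcross founders are sampled from the
simulated BY&times;3S *ira2*&Delta;2933 F1 cross, which keeps both
backcross panels ~50% informative; the study's founders came from a
second-iteration backcross pedigree, a difference that affects only the
informativeness fraction, not which loci are mappable. Segregation-ratio
tests use 6,000–10,000 segregants on full-size sparse maps. These sizes
are the package's choices for routine verification; all of them are
parameters, and the full-density design (36,756 markers) is available
through `build_marker_map(36756)`.

## Numerical and degenerate-input choices

* Rule evaluation is first-match-wins; the default rules are disjoint, so
  order is irrelevant (tested). A matched rule that fails its penetrance
  draw yields the default phenotype rather than falling through.
* Threshold comparisons are inclusive (`>=` 0.95, `<=` 0.05).
* Zero-depth or sub-`min_depth` markers become missing and windows skip
  them; chromosomes with fewer informative markers than the window size
  yield no windows at all.
* Pooling an empty selection is an error (there is nothing to sequence);
  selecting zero segregants is not.
* Physical coordinates are 1-based inclusive everywhere in memory and in
  TSVs; BED export converts to 0-based half-open.
* Map construction, simulation and sequencing accept seeds and restore
  the caller's RNG state afterwards; the same seed gives byte-identical
  outputs.

## Limitations

* The *END3*-linked viability bias is not modelled, so observed cohort
  compositions that depend on it (the study's 20:1 ratio and 95.2%/4.8%
  split) are not reproduced — by design, the simulator converges to the
  exact 2:1 expectation instead.
* Penetrance defaults to 1; the study's single discordant *sfl1*&Delta;
  segregant is representable (as a low-penetrance extra rule) but not
  default.
* The `BUMPY` phenotype class is representable in rules but ships with no
  default rule, as no genotype was reported for it.
* Reads are simulated as per-marker counts, not as sequences: no
  read-mapping bias, library artifacts, or depth autocorrelation.
* The exact-enumeration module treats causal sites as unlinked. On the
  real map that is true for all pairs except IRA2–SFL1 (*r* ≈ 0.48),
  which the six-way rule does couple (it requires *SFL1*^BY^ together
  with the lesion carried on the 3S strand of *IRA2*), so simulated
  five:six ratios converge to ~2.08 rather than the enumerated 2.0 — a
  shift an order of magnitude below the sampling error of the cohort
  sizes involved.
* *TRR1* is placed on its native chromosome IV; the study itself does not
  state its chromosome, so the placement is configurable.
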