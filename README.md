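# bsacross

Bulk segregant mapping of higher-order epistatic interactions in yeast
crosses — a simulation and analysis toolkit for the BY×3S
colony-morphology system.

## The problem

In crosses of the *S. cerevisiae* lab strain BY and the clinical isolate
3S, a rough colony-morphology phenotype is *cryptic*: it appears only
when a capacitating perturbation — the *ira2*Δ2933 truncation of the
Ras-pathway inhibitor Ira2, or deletion of the repressor *SFL1* —
co-occurs with a specific combination of standing variants at up to six
genes (*END3*, *FLO8*, *MGA1*, *MSS11*, *SFL1*, *TRR1*). Two
combinations produce the trait in the *ira2*Δ2933 background:

- **five-way**: END3^BY FLO8^3S *ira2*Δ2933 MSS11^BY TRR1^3S
- **six-way**: END3^3S FLO8^3S *ira2*Δ2933 MGA1^BY MSS11^BY SFL1^BY

and one in the *sfl1*Δ background (END3^BY FLO8^3S MSS11^BY TRR1^3S).
The loci are mapped by **bulk segregant analysis (BSA)**: pool
phenotype-selected segregants, sequence the pools, and call as causal the
regions where one parental allele is *fixed* — windowed allele
frequencies of 10 consecutive SNPs at **95% or higher**.

`bsacross` implements this end to end, with no external data required:

- a seeded meiosis/backcross simulator over dense biallelic SNP maps
  (Haldane model, engineered sites transmitted like alleles);
- the genotype→phenotype penetrance-rule model, with a brute-force
  enumeration oracle over all 2⁶ allele combinations;
- phenotype/genotype pool selection, equimolar pooling, and
  pooled-sequencing count simulation (Poisson depth, symmetric miscalls);
- the sliding-window fixation caller with smallest-interval
  delimitation, segregation masks for backcross panels, MUTANT-site
  relabelling, and reciprocal-pool merging;
- exact enumeration of genotype-class expectations (no Monte Carlo);
- TSV/BED/mpileup interfaces and a small CLI
  (`inst/cli/bsacross`: `simulate-cross`, `simulate-pools`, `map-loci`,
  `classify`, `expect`).

## Worked example

Simulate the study's six-way mapping design: sample a six-way rough
founder, backcross it to BY and 3S, select rough segregants (63 and 88,
the study's pool sizes, with *END3* genotyped as in the study), sequence
the pools at 100×, and map both panels:

```r
library(bsacross)

map <- scaled_marker_map(2000, seed = 7)   # density-preserving scale-down
map
#> marker_map: 2000 markers on 16 chromosomes (490.5 cM total)
#> causal sites: FLO8=V_29191, MGA1=VII_146019, MSS11=XIII_26986,
#>   END3=XIV_22112, IRA2=XV_123258, SFL1=XV_423247, TRR1=IV_50271

expected_class_probabilities(default_rule_set(),
                             cross_scheme("BYx3S_IRA2MUT"))$five_to_six_ratio
#> [1] 2        # the five-way genotype is expected twice as often

res <- backcross_mapping_experiment(map, "SIX_WAY",
                                    pool_sizes = c(by = 63L, s3 = 88L),
                                    coverage = 100, seed = 11)
res$loci[, c("chrom", "start_bp", "end_bp", "fixed_allele",
             "mean_freq", "causal_genes", "pool")]
#>   chrom start_bp end_bp fixed_allele mean_freq causal_genes pool
#> 1     V    13927  42646           3S 0.9809086         FLO8   BY
#> 2   VII   137036 160513           BY 0.9779018         MGA1   3S
#> 3  XIII     6833  41601           BY 0.9765746        MSS11   3S
#> 4   XIV      954  36272           3S 0.9879567         END3   BY
#> 5    XV   102299 130114       MUTANT 0.9689451         IRA2   BY
#> 6    XV   406737 446492       BY     0.9761996         SFL1   3S
```

The merged report recovers the six-way architecture exactly: single loci
on chromosomes V, VII, XIII and XIV plus two on XV, each interval
containing its causal gene. The `fixed_allele` column shows which
parental allele is fixed in the pool (`MUTANT` marks the engineered
*ira2*Δ2933 site, fixed for the lesion); `pool` records which backcross
panel carries the signal — founder-BY loci are monomorphic against BY and
only mappable in the 3S panel, which is why the study ran reciprocal
backcrosses. `mean_freq` is the windowed frequency of the fixed allele
averaged over the qualifying windows (≥ 0.95 by construction).

The same machinery replays the *sfl1*Δ cross
(`sfl1_cross_experiment()`, four loci: *END3*, *FLO8*, *MSS11*, *TRR1*)
and classifies individual segregants into interaction classes
(`classify_interaction()`, `summarize_population()`).

## Documentation

The methods vignette (`vignettes/bsa-mapping.Rmd`) describes the
penetrance-rule model, the meiosis and pooled-sequencing simulators, the
window statistic and its parameters, how the scaled-down marker maps
preserve the full-density mapping regime (marker density per cM, the
IRA2–SFL1 genetic separation, causal-site flanks), and what the simulator
deliberately does not model (the *END3*-linked viability bias behind the
study's 20:1 observed ratio, partial penetrance, read-level artifacts).
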