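# ribdtools

Bidirectional introgression scanning between diverged domestic
populations, built around haplotype identity-by-descent sharing and
windowed ABBA-BABA statistics, with a forward-in-time admixture-pulse
simulator for end-to-end validation.

## The problem

When two domesticated lineages (for example East-Asian and European
domestic pigs) exchange migrants, each population ends up carrying
chromosome segments that descend from the other. Given phased SNP
genotypes for the two domestic populations, a conspecific wild
"background" relative of each, and a distant outgroup, `ribdtools`
locates those segments, infers the direction of gene flow, and tests
which structural variants (SVs) travelled with them.

## The statistics

**Relative IBD (rIBD).** For each 50 kb window (25 kb slide), pairwise
haplotype IBD sharing is summarised as `nIBD = cIBD / tIBD`, where `cIBD`
counts cross-group haplotype pairs sharing an IBD tract in the window and
`tIBD` is the total number of cross-group pairs, so `nIBD` runs from 0
(no sharing) to 1 (all pairs share). The scan statistic is

```
rIBD = nIBD(recipient, donor) - nIBD(recipient, background)
```

Windows above the top-1% empirical quantile of rIBD (and > 0) are
candidate introgression windows. IBD tracts come from a deterministic
seed-and-extend identity-run matcher (maximal allele-identity runs with a
small mismatch budget), implemented in C++.

**Patterson's D and f_d.** With per-site derived-allele frequencies
`p1` (background), `p2` (recipient), `p3` (donor) and `pO` (outgroup,
used only to polarize),

```
ABBA = (1 - p1) p2 p3 (1 - pO)      BABA = p1 (1 - p2) p3 (1 - pO)
D    = sum(ABBA - BABA) / sum(ABBA + BABA)
f_d  = sum(ABBA - BABA) / sum(ABBA_D - BABA_D),  p_D = max(p2, p3)
```

`f_d` is set to 0 wherever `D < 0`. Candidate windows are confirmed when
`f_d > 0`. Two population arrangements are scored — arrangement 1 treats
the B-side domestic as recipient, arrangement 2 the A-side — and the
arrangement with the larger f_d indicates the direction of flow (the
mismatched arrangement underestimates the admixture fraction). Confirmed
seeds are extended across their surrounding run of positive-rIBD windows
and merged into segments; segments called in the two directions are
intersected to report bidirectional regions. Genome-wide D significance
uses a weighted block jackknife (|Z| > 3), and the f4-ratio estimates the
admixture proportion.

**Population-specific and introgressed SVs.** Per SV, Weir-Cockerham
F_ST between the two domestic populations plus a label-permutation
empirical P `(1 + #{perm >= obs}) / (1 + n_perm)`. An SV is
population-specific when F_ST exceeds the top-5% quantile, empirical
P < 0.05, missingness < 0.1 and MAF > 0.01 — and is classified
introgressed when it overlaps (or flanks) an inferred segment. SVs are
also tagged by their maximum r² to SNPs within 50 kb.

**Haplotype networks.** For a locus of interest, phased haplotypes are
collapsed into classes (MAF > 0.05 sites), tabulated per population, and
connected in a minimum-spanning network over Hamming distances with
equal-weight alternative links; cutting the largest MST edge yields the
two major haplogroups.

## Worked example

```r
library(ribdtools)

# a 5 Mb world with a one-way pulse: 20% of population B's gene pool
# replaced by population A donors 30 generations ago
cfg <- sim_config(seed = 1,
                  pulse_specs = list(pulse_spec(30, "P_A", "P_B", 0.2)))
sim <- simulate_history(cfg)
panel <- bind_panels(sim$panels)

scan <- scan_bidirectional(panel, sim$popmap, cfg$chromosome_length)
scan$fraction_ab                    # genome fraction called A -> B
#> [1] 0.39
scan$fraction_ba                    # false-direction fraction
#> [1] 0.05
scan$segments_ab[c("start", "end", "mean_ribd", "mean_fd")]
#>    start     end  mean_ribd  mean_fd
#> 1 225000 2175000 0.02354257 0.190825

truth <- sim$tracts[sim$tracts$donor_pop == "P_A", ]
evaluate_recovery(scan$segments_ab, truth)[c("precision", "recall")]
#> $precision
#> [1] 1
#> $recall
#> [1] 0.39
```

The calls are essentially pure (precision ~1: called bases overlap true
donor tracts) while recall against the union of all per-haplotype tracts
is bounded by the deliberately conservative, null-safe seeding rule — on
a matched no-pulse world the same pipeline calls 0% of the genome in
either direction.

Command line, equivalently:

```sh
ribdtools simulate --seed 1 --pulse 30:P_A:P_B:0.2 --out-prefix sim
ribdtools ribd   --vcf sim.snps.vcf --popmap sim.popmap.tsv \
                 --recipient P_B --donor P_A --background W_B --out ribd.tsv
ribdtools dstats --vcf sim.snps.vcf --popmap sim.popmap.tsv \
                 --p1 W_B --p2 P_B --p3 P_A --outgroup OUT --out fd.tsv
ribdtools call   --ribd ribd.tsv --fd fd.tsv --donor P_A --recipient P_B \
                 --out segments.tsv
```

(the launcher script installs under
`system.file("scripts", "ribdtools", package = "ribdtools")`).

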