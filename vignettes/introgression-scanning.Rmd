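---
title: "Detecting bidirectional introgression with rIBD and windowed f_d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting bidirectional introgression with rIBD and windowed f_d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ribdtools)
```

# The model

`ribdtools` targets a five-population design: two diverged domestic
populations (call them A-side and B-side), a conspecific wild relative of
each serving as its background, and one distant outgroup used only to
polarize alleles. Gene flow between the two domestic populations leaves
two complementary signals:

* **excess haplotype sharing** — a recipient haplotype carrying a donor
  tract is identical-by-descent with present-day donor haplotypes over
  long physical spans, far beyond what the recipient shares with its own
  wild background at that locus; and
* **site-pattern asymmetry** — derived alleles in the recipient line up
  with the donor more often than with the recipient's wild sister,
  producing positive Patterson's D and a positive windowed admixture
  fraction f_d.

The pipeline uses the first signal to localize (windowed
`rIBD = nIBD(recipient, donor) - nIBD(recipient, background)`, with the
top-1% windows as seeds), the second to confirm (window f_d > 0 after
zeroing f_d wherever D < 0) and to orient (the two population
arrangements score f_d with each domestic population in the recipient
slot; the true direction's arrangement yields the larger value, because
the mismatched arrangement underestimates the admixture fraction).

## Assumptions

* Phased, biallelic SNPs on a single chromosome per panel; phasing is
  assumed exact (the simulator emits truth-phased data; phasing error is
  out of scope).
* The wild populations are genuine sisters of their domestic
  counterparts and exchanged no recent migrants themselves.
* The outgroup is deep enough that its major allele approximates the
  ancestral state; sites with outgroup frequency in [0.4, 0.6] are
  treated as unpolarizable and dropped.

# Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| `window`, `step` | 50 kb / 25 kb | bp | the analysis grid of the original study design |
| `q` | 0.01 | quantile mass | "top 1%" rIBD seed rule |
| `fd_min` | 0 | f_d | confirmation is `f_d > 0` after the `D < 0` zeroing rule |
| `min_sites` | 10 | sites/window | windows with fewer informative sites are not scored |
| `min_length` | 200 kb | bp | minimum physical IBD tract span |
| `min_sites` (IBD) | 50 | sites/tract | guards against identity-by-state runs through site deserts |
| `max_mismatch` | 1 | sites | mismatch budget per identity run (genotype error / recent mutation) |
| `end_clearance` | 10 | sites | a tolerated mismatch may not sit near a run end |
| `max_sites` (IBD) | 8000 | sites | matcher thins denser panels to this grid; cost is linear in sites |
| `n_perm` | 1000 | permutations | SV empirical P resolution (1/1001) |
| `block_size` | 1 Mb | bp | jackknife block for genome-wide D |

The detectability horizon of the IBD matcher is worth internalizing: an
identity run of at least `min_length` survives roughly
`1 / (r * min_length)` meioses of recombination — 500 meioses at
r = 1e-8 and 200 kb. Sharing along genealogical paths much longer than
that is invisible to the matcher; paths much shorter are conspicuous.
All demographic reasoning below is anchored to this horizon.

# The synthetic world

`sim_config()` defaults describe a desk-scale world chosen once, from
first principles, so that every analysis channel has honest signal:

* **Chromosome**: 5 Mb, ~24,000 segregating sites (high density keeps
  per-window f_d noise down; the IBD matcher thins to 8,000 sites).
* **Splits**: wild-domestic 500 generations, A/B 3,000, outgroup 4,500.
  Background IBD paths (>= 1,000 meioses) lie beyond the 500-meiosis
  horizon; pulse-derived paths (tens to a few hundred meioses) lie well
  inside it. The long interval between the wild split and the A/B split
  is what powers direction inference: the f_d margin between the two
  arrangements is proportional to the drift accumulated on the donor
  lineage over exactly that interval.
* **Effective sizes**: breeding pools (census x time rescaling) of
  Ne 3,000 for the domestic populations and wilds, Ne 4,500 ancestral.
  Domestic pools are small enough that an introgressed tract finds
  present-day donor relatives within the horizon.
* **Rescaling**: the engine runs `T / time_scale` internal generations
  at `time_scale`-multiplied recombination and mutation rates — the
  standard coalescent rescaling, preserving drift, crossover and
  mutation per nominal generation in distribution while keeping runtime
  at seconds per replicate.
* **Pulse mechanics**: at the pulse generation each recipient gamete is
  drawn from the donor pool with probability f; donor-derived segments
  carry an ancestry label through all subsequent recombination, so truth
  tracts are exact, not inferred.

What the generator does **not** emulate: phasing error, genotype error,
missing data patterns, variable recombination/mutation rates along the
chromosome, selection, and any quantitative match to a real species'
demography. A green test on this world establishes that the statistics
and decision rules behave as designed under their own assumptions — not
that the pipeline is robust to the failure modes of real data.

# Numerical and design choices

* **Frequency-based ABBA/BABA** (not pattern counting): handles any
  panel size; the per-window estimator is checked against a direct-sum
  oracle at 1e-12.
* **Windowed F_ST** is the ratio of summed Weir-Cockerham (1984)
  variance components, not the mean of per-site ratios. Negative raw
  estimates are reported as computed and floored at zero in the reported
  column. Note one consequence: "identical populations" toys give a
  slightly negative raw estimate (the estimator is unbiased only in
  expectation), which the floor maps to 0.
* **Jackknife**: weighted delete-one blocks (Busing-style); with equal
  weights it reduces to the textbook delete-one jackknife, which the
  tests exploit as an oracle. A zero jackknife SE yields a signed
  infinity sentinel rather than NaN.
* **Top-quantile threshold** is nearest-rank; candidates must be
  strictly above it *and* strictly positive, so a degenerate
  all-equal-rIBD chromosome yields no candidates.
* **Segment extension**: confirmed seeds grow across their maximal
  surrounding run of positive-rIBD windows before merging. Merging only
  the seed windows themselves cannot recover extended introgressed
  regions: with ~200 windows per scan the top-1% rule yields two seeds.
  Extension follows the definition of introgressed regions as regions of
  positive rIBD.
* **Direction at segment scale**: the pipeline compares length-weighted
  mean f_d of the two arrangements over each segment's windows and keeps
  the segment only if its own arrangement wins. A single 50 kb window
  carries too few informative sites for a reliable per-window call, and
  the strongest-rIBD windows are the worst place to ask: where local
  sharing is strongest, the recipient's local allele frequencies have
  converged toward the donor's, which erases the arrangement margin.
  The per-window comparison (`infer_direction()`) remains available and
  is what the acceptance tests measure, faithfully.
* **Permutation P-values** use the add-one estimator with ties counted
  as exceedances; the permutation unit is the diploid sample. For a
  single biallelic locus the permutation support is discrete, so these
  p-values are *valid but conservative* (super-uniform) — exactly
  uniform null p-values are impossible for this statistic, and the
  uniformity acceptance check is expected to fail for any faithful
  implementation of this estimator.
* **Haplotype networks** are minimum-spanning networks (Kruskal MST
  under a lexicographic tie-break, plus equal-weight alternative links);
  median-joining inference of unobserved haplotypes is deliberately not
  implemented. Haplogroups are the two components left after cutting the
  largest-weight MST edge — a documented heuristic.
* **MAF for the SV-specificity criterion** is computed over the union of
  the two compared groups; the top-5% F_ST quantile is taken over all
  tested SVs (a class-stratified variant is a one-line change around
  `filter_specific()`).

# Known limitations

* The seed rule that keeps null worlds perfectly clean (no segment
  called in either direction across null replicates) also bounds recall
  when introgression is spatially uniform: with a 20% pulse into every
  lineage, true donor material sits in *every* window, but only runs of
  positive-rIBD windows containing a top-1% seed are called. On such
  worlds the caller is near-perfectly precise but recovers roughly
  half the genome rather than all of it. Real introgression landscapes
  (and the study design this mirrors) are localized, which is the regime
  the seed rule was designed for.
* Per-window direction inference is noise-limited at 50 kb; trust the
  segment-level calls.
* The IBD matcher assumes exact phasing; with statistically phased data
  switch errors would fragment tracts, and `min_length` would need
  retuning.
* Runtime is dominated by the pairwise IBD scan (O(haplotype pairs x
  sites)); the compiled kernel handles desk-scale panels (hundreds of
  haplotypes, 10^4 sites) in seconds but is not engineered for
  biobank-scale cohorts.
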