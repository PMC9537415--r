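---
title: "Models and methods for detecting incipient hybrid lineages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for detecting incipient hybrid lineages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyblineage)
```

This vignette is the package's own account of the statistics it implements,
the demographic model its simulator emulates, and the design decisions taken
where the underlying methods leave choices open.

## The scientific problem

A young hybrid lineage — a population founded by hybridization between two
parental species that has begun reproducing among itself — leaves a
characteristic multi-locus signature. Its members carry intermediate
ancestry, but unlike F1s their interclass heterozygosity decays by roughly
one half per generation of within-lineage mating. Genome-wide, the lineage
shares an excess of derived alleles with *both* parental species, and allele
sharing across four-taxon quartets becomes asymmetric. `hyblineage` computes
all of these signals from a genotype matrix and, crucially, ships a
simulator of the generating process so each estimator can be validated on
data whose truth is known.

## The demographic model and the simulator

`simulate_frequencies()` runs per-locus, per-generation Wright–Fisher
binomial drift, $p' = \mathrm{Binomial}(2N_e, p)/2N_e$, along a fixed tree:
an ancestral population (size `ne_ancestral`) splits into parental species A
and B at `tau_split` generations before present; a hybrid lineage is founded
at `tau_hybrid` with initial frequency $p_0 = \varphi p_A + (1-\varphi) p_B$
and drifts with `ne_hybrid`; an outgroup diverges at `tau_outgroup`. Only
standing variation is simulated. Default parameter values describe the
crater-lake cichlid system that motivated the package: `tau_split = 2578`
and `tau_hybrid = 242` generations, $\varphi = 0.546$, parental sizes of
23,280 and 17,329, hybrid size 6,369, ancestral size 44,301, and a mutation
rate of $3.5\times10^{-9}$ per site per generation (carried as metadata;
new mutation enters only through the optional `private_mutations` spike-in).

Decisions the model description leaves open, resolved here once:

- **Ancestral frequencies** are drawn from Beta(0.8, 0.8) truncated to
  [0.05, 0.95]: segregating and U-shaped like a neutral site-frequency
  spectrum, while guaranteeing every locus starts polymorphic. The draw
  function is configurable.
- **Forward binomial drift** replaces the coalescent-with-introgression
  model under which the default parameters were originally estimated. For
  the moment-based statistics tested here (frequency variances, f-type
  pattern sums, F<sub>ST</sub>) the two give the same expectations; the
  forward form additionally yields exact pedigrees and byte-reproducible
  VCFs.
- **Outgroup divergence** is not part of the core parameter set; the
  default is `4 * tau_split`, deep enough that outgroup polarization is
  nearly always correct, and the outgroup branch drifts with the ancestral
  size (the model provides no separate outgroup size; the internal-node
  sizes of the original coalescent fit have no unambiguous branch mapping
  and are deliberately not exposed).
- **Fixation filtering**: loci fixed for the *same* allele in all four
  terminal populations are dropped (and counted) — they could never be
  observed as SNPs. Loci fixed for *opposite* alleles are retained: they
  are precisely the diagnostic fixed differences downstream stages consume.
- **Scaling**: the `scale` argument divides every $\tau$ and $N_e$ by a
  common factor, preserving all per-branch drift ratios $t/2N_e$. The test
  suite runs the default demography at scales 25–50 with $10^3$–$5\times
  10^4$ loci, which keeps each simulation in seconds while leaving the
  drift process, and therefore every expectation being tested, unchanged.
- **Continuous backcrossing** is available as `migration_rate`, a
  per-generation fraction of the hybrid population replaced by migrants
  from each parental species (default 0).

`make_pedigree()` complements the population samples with explicit crosses
(F1 = A×B, F2 = F1×F1 from independent F1s, BC1A = F1×A, BC1B = F1×B).
Meioses place crossovers as a Poisson process on a uniform genetic map
(`recomb_rate` cM/Mb, 1 cM = 1% recombination), and per-locus ancestry
labels propagate through every crossover, so each individual's realised
ancestry proportion and interclass heterozygosity are known exactly
(`pedigree_truth()`). Note that simulated chromosomes impose linkage: a
single-chromosome F2 can easily inherit two like gametes and look parental.
Tests of Mendelian expectations therefore place each locus on its own
chromosome.

What the generator does *not* emulate: genotyping error and allele dropout,
linkage disequilibrium within populations (sites are exchangeable given the
frequency trajectories), selection, and recurrent mutation. Passing tests
demonstrate estimator correctness under the model, not robustness to
artefacts of real variant calling.

## Genotype I/O and filters

`read_vcf()` parses VCF v4.2 via `vcfR`, keeps biallelic SNPs, accepts
phased and unphased genotype separators (phase is never used downstream),
and masks genotype calls with depth below `min_depth` (default 5).
`write_vcf()` emits plain-text VCF that round-trips exactly. Coordinates
are 1-based (VCF convention); F<sub>ST</sub> windows are half-open
`[start, start + size)`. Distance thinning (`thin_by_distance`) is
greedy-from-left — keep the first site per chromosome, then every site at
least `min_bp` beyond the last kept one — a deterministic, idempotent
dialect recorded in the output metadata. The missingness filter never
alters surviving genotype values, only site membership.

## Diagnostic markers

A site is a *fixed difference* when one allele has frequency exactly 1 in
one parental sample and 0 in the other; no distance thinning is applied to
fixed differences, so recombination between physically close markers
remains visible. The *relaxed panel* requires frequency ≥ `hi` (default
0.95) in one species and ≤ `lo` (0.05) in the other, followed by 50-kb
thinning to limit linkage between panel loci. Threshold comparisons carry
an epsilon of $10^{-9}$ because count ratios such as 19/20 can fall a ulp
below their decimal thresholds. *Private alleles* of a focal group must
segregate at frequency ≥ 0.5 (but < 1) in that group and have **zero**
copies among genotyped individuals of every comparison group; a
carrier-fraction variant of the frequency criterion is available
(`criterion = "carrier"`) because the two definitions differ in general,
and the choice is recorded in the result's metadata. All frequencies are
computed from genotyped individuals only.

## The (S, H) triangle likelihood

For an individual genotyped at $L$ diagnostic loci, let $S$ be the fraction
of its genome of parental-A ancestry and $H$ the fraction of loci carrying
one allele of each ancestry. The three per-locus ancestry classes have
probabilities

$$P(AA) = S - H/2,\qquad P(AB) = H,\qquad P(BB) = 1 - S - H/2,$$

which are valid on the triangle $0 \le H \le 2\min(S, 1-S)$. Given the
class, each allele is drawn from the panel's parental frequencies
(`freqA`, `freqB`), so genotype likelihoods marginalise over classes and
loci are treated as independent — the same approximation the 50-kb panel
thinning is meant to protect (linked loci would overweight shared
information; this is documented, not corrected). The likelihood is
maximised on a coarse grid of step 0.02 followed by three levels of local
grid refinement to a resolution of $2\times10^{-5}$; grid maximisation is
slower than gradient methods but immune to the boundary non-smoothness of
the triangle, and deterministic. On fully fixed panels the hybrid-index MLE
has the closed form $\hat h = \sum \text{codes}/2L$ and equals $1-\hat S$
to optimizer tolerance (asserted at $10^{-4}$ in the tests).

Generation classes are assigned by comparing the log-likelihood at six
fixed hypothesis points — parental A (1,0), parental B (0,0), F1 (0.5,1),
F2 (0.5,0.5), BC1A (0.75,0.5), BC1B (0.25,0.5) — against the free maximum.
The free model wins, and the individual is labelled
`later_generation_hybrid`, only when it leads by more than `class_margin`
log-units. The default margin is 4, i.e. an information-criterion penalty
of 2 log-units for each of the two free parameters; under a true fixed
class $2\Delta\log L$ is asymptotically $\chi^2_2$, so the margin keeps the
false "later-generation" rate near
$P(\chi^2_2 > 8) \approx 2\%$, which is what makes ≥95% confusion-matrix
recovery attainable. Ties prefer the simpler fixed hypothesis. The margin
is exposed because it trades sensitivity to genuinely old hybrids against
false flags on F2/BC1 individuals.

## The invariants-based hybridization test

Polarizing all groups on the outgroup major allele (sites at outgroup
frequency exactly 0.5 are unpolarizable and skipped), the package
accumulates frequency products

$$x_1 = \sum d_{P1} d_{H} (1-d_{P2}) (1-d_{O}),\quad
  x_2 = \sum (1-d_{P1}) d_{H} d_{P2} (1-d_{O}),\quad
  x_3 = \sum d_{P1} (1-d_{H}) d_{P2} (1-d_{O}),$$

so $x_1 - x_3$ and $x_2 - x_3$ are the excesses of derived-allele sharing
between the hybrid and each parent over the incomplete-lineage-sorting
baseline $x_3$, and

$$\hat\gamma = \frac{x_1 - x_3}{(x_1 - x_3) + (x_2 - x_3)}$$

estimates the parental-A fraction of the hybrid's ancestry. This
f-statistic (frequency-product) form is consistent ($\hat\gamma \to
\varphi$) when the two parental branches drift equally; when parental
$N_e$ differ, the excesses scale with each parent's post-founding drift
$\,1 - e^{-t/2N_e}$ and $\hat\gamma$ is biased toward the
larger-$N_e$ parent (about $-0.07$ at the default unequal sizes). The
simulation suite therefore validates recovery under equal parental sizes
and treats the unequal-size case as qualitative. Orientation is explicit
in the output (γ is the P1 share; relabeling the parents maps
$\hat\gamma \to 1 - \hat\gamma$ exactly).

Significance uses a delete-one block jackknife over 100 contiguous
equal-count site blocks (configurable), with test statistic
$f_{\min} = \min(x_1 - x_3,\, x_2 - x_3)$: a genuine hybrid must share
excess derived alleles with *both* parents, so the weaker excess carries
the test. $Z = f_{\min}/\mathrm{SE}_{\text{jack}}$, one-tailed
$p = 1 - \Phi(Z)$. When either excess is non-positive the result is
flagged `no_signal` and γ is reported clamped. Under sister-lineage
(no-admixture) simulations the test's type-I rate at $\alpha = 0.05$ is
verified to stay at or below 8% over 200 replicates.

## Quartet concordance factors

For each of `n_quartets` (default 100) sampled quartets — one individual
per species, uniform with replacement, seeded — one allele per individual
per site is sampled from its genotype. A site is informative when the four
alleles split 2-vs-2; it then supports exactly one of the three
resolutions, the per-quartet CFs are supported fractions (summing to 1
identically), and the reported CFs average over quartets. Whether real
pipelines use phased haplotypes or sampled alleles varies; the seeded
single-allele draw is the default, and a `mode = "both"` variant that uses
only homozygous individuals is provided. Under divergence without gene
flow the two minor CFs are equal in expectation; both-parent-ward
asymmetry of the minor CFs is the quartet-level signature of
hybridization. On a star phylogeny all three CFs converge to 1/3.

## F<sub>ST</sub>, PCA, inbreeding

Per-site Weir & Cockerham (1984) components $a$, $b$, $c$ are computed from
genotype counts with unequal, site-varying sample sizes, and windows report
the weighted ratio $\sum a / \sum(a+b+c)$ over non-overlapping 10-kb
windows (half-open), alongside the mean of per-site ratios. Negative
values are preserved — truncating at zero would bias window medians
upward — and the genome-wide median is taken over non-empty windows,
matching the convention of the standard VCF tooling. The implementation is
checked against an independently transcribed scalar version of the 1984
formulas to $10^{-10}$.

PCA mean-imputes missing dosages per site, centres without variance
scaling (the default of the common genotype-PCA stacks; scaling is a
flag), and fixes component signs by making each component's
largest-magnitude loading positive, so results are fully deterministic.
The inbreeding coefficient is $F = 1 - H_{\text{obs}}/H_{\text{exp}}$ with
$H_{\text{exp}} = \sum_l 2p_l(1-p_l)$ over the individual's genotyped
sites, frequencies taken from a designated reference sample; $F$ is
undefined (flagged) when the expectation is zero.

## Numerical and degenerate-input conventions

- Genotype dosages are stored as integers 0/1/2/NA; all frequency
  computations use genotyped individuals only.
- Likelihood evaluations clamp probabilities to $[10^{-12}, 1-10^{-12}]$
  before logs; $-\infty$ log-likelihoods are tolerated and compared.
- `optimize()` cannot return an interval endpoint, so the hybrid-index
  maximiser explicitly compares both bounds.
- Empty panels warn rather than error; individuals with zero genotyped
  panel loci are returned with `NA` estimates and a warning.
- A jackknife with zero variance (identical blocks) reports $Z = \infty$
  for a positive statistic rather than dividing by zero.

## Known limitations

- Independence across loci is assumed by every likelihood; thinning
  mitigates but does not remove linkage.
- $\hat\gamma$ is biased under strongly unequal parental drift (above).
- The simulator's standing-variation-only model cannot generate genuinely
  new private alleles except through the explicit spike-in option, whose
  surviving-locus count is random.
- Concordance factors are computed over sampled individual quartets, not
  all site patterns, so they inherit sampling noise of order
  $n_{\text{quartets}}^{-1/2}$.
- Real-data accuracy depends on upstream variant calling and filtering,
  which are out of scope here; the packaged validation is entirely
  simulation-based.
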