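---
title: "Models and methods behind ventpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ventpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ventpop` analyses single-marker (mtCOI) population samples of
hydrothermal-vent meiofauna and studies, by simulation, how much multi-locus
data would be needed to estimate connectivity parameters directly. This
vignette explains the models, the numerical choices, and the limits of what
the synthetic tests demonstrate.

## The data model

The unit of analysis is a codon alignment: equal-length aligned coding
sequences with a reading-frame offset and a genetic code (invertebrate
mitochondrial, NCBI table 5, where TGA encodes tryptophan and only TAA/TAG
are stops). Sequences are grouped into (species, site) populations by a
sample sheet. All statistics are computed over the population's
complete-case site mask: columns where every retained specimen has an
unambiguous A/C/G/T. Ambiguity codes are treated as missing rather than as
partial information, which matches the complete-case "sites used" semantics
of standard mtCOI diversity tables; the alternative (fractional counting)
would change denominators by well under a percent in typical data but
complicate every downstream pair count.

### The NUMT screen

Nuclear copies of mitochondrial fragments (NUMTs) evolve without functional
constraint and are the main contamination risk for mtCOI population
genetics. `screen_orf()` fails a sequence if (a) any internal gap run in
the alignment has a length that is not a multiple of three — a frame-shift
proxy — or (b) its in-frame translation contains an internal stop codon. A
terminal stop is tolerated (it may be the genuine end of the open reading
frame). Reading-frame detection is deliberately *not* automatic: the frame
offset is part of the alignment's provenance, and guessing it silently
would make runs irreproducible.

## Diversity statistics

Haplotype diversity is Nei's unbiased estimator
$H_d = \frac{n}{n-1}\left(1 - \sum_i p_i^2\right)$, zero iff the population
is monomorphic and one iff all haplotypes are distinct. Nucleotide
diversity averages pairwise per-site difference proportions; in the
Jukes–Cantor mode each pairwise $p$ is corrected as
$d = -\tfrac34\ln(1-\tfrac43 p)$ *before* averaging (the standard corrected
estimator; correcting the average instead would understate diversity by
Jensen's inequality). The correction is undefined at $p \ge 3/4$ and the
package raises an error naming the offending pair — for conspecific mtCOI
data this only happens if something upstream went badly wrong.

The synonymous/nonsynonymous partition follows Nei–Gojobori pathway
counting: per codon pair, differences are classified along all orderings of
the differing positions, pathways through stop codons are excluded (if
every pathway hits a stop, all are used and stop steps count as
nonsynonymous), and site counts use the per-position synonymous fractions
of the code table, with changes *to* stops counted as nonsynonymous
opportunity. Each pair's $p_a$ and $p_s$ are JC-corrected and averaged over
pairs. The ratio is reported as `NA` when both diversities are zero, `0`
when only $\pi_a$ is zero, and `Inf` when only $\pi_s$ is zero, so
downstream tables can render "-" or "0" faithfully.

Between-group p-distance summaries use uncorrected distances with pairwise
deletion of non-ACGT positions. The standard error of a within-group mean
is a site-resampling bootstrap (columns resampled with replacement, 500
replicates by default) — the convention of the distance software this
mirrors — not a specimen bootstrap.

## Demography statistics and their null distributions

Four statistics are computed per population:

* **Tajima's D** $= (k - S/a_1)/\sqrt{e_1 S + e_2 S(S-1)}$ with the 1989
  constants; negative under a singleton excess.
* **Fu's Fs** $= \ln\frac{S'}{1-S'}$ with
  $S' = P(K \ge K_{obs} \mid \theta = k)$ from the Ewens sampling formula,
  $P(K=j) = |s(n,j)|\,\theta^j/\theta^{(n)}$. Unsigned Stirling numbers of
  the first kind are computed by the row recurrence in log space, exact to
  machine precision for the sample sizes involved (n ≤ ~100). When $S'$
  degenerates numerically the value is clamped at $\varepsilon = 10^{-8}$
  and flagged via the `clamped` attribute rather than returned infinite.
* **R2** $= \sqrt{\tfrac1n\sum_i (U_i - k/2)^2}\,/\,S$, where $U_i$ counts
  singleton mutations carried by sequence $i$. Singletons are defined by
  minor-allele count 1 at a column — there is no outgroup in these data, so
  no polarisation is attempted.
* **Raggedness** of the mismatch distribution. The implemented convention
  sums squared steps between adjacent relative-frequency classes
  *including both boundary steps* (from zero into the first observed class
  and from the last observed class back to zero):
  $rg = \sum_{i=0}^{d+1}(x_i - x_{i-1})^2$ with $x_{-1} = x_{d+2} = 0$. A
  degenerate distribution (all pairs identical) therefore scores 2, and a
  smooth unimodal expansion curve scores below ~0.05. Harpending's original
  index omits the boundary terms; the boundary-inclusive form is used
  consistently here (observed values are compared against nulls computed
  under the same convention, so the choice cancels in the tests).

P-values come from neutral constant-size coalescent replicates (no
recombination, infinite sites) at Watterson's $\theta_W = S/a_1$ fitted
from the observed data. The published tables this mirrors used a software
default "population growth-decline model" θ whose precise definition is not
reproducible from the text; $\theta_W$ conditioning is the documented
surrogate, and the conditioning choice is exposed rather than hidden. D,
Fs and R2 are tested on the lower tail (the expansion direction); the
raggedness index on the upper-or-equal tail, as its footnoted definition
states. Both orientations are available via the `tails` argument because
the literal footnote wording ("P of observing a value larger or equal")
conflicts with the expansion-direction convention for D and Fs; the default
resolves the conflict in favour of the expansion alternative for D/Fs/R2.
Empirical P-values use $+1/(reps+1)$ smoothing so they are never exactly 0.

## F_ST

The default estimator is the Weir–Cockerham (1984) variance-components θ
adapted to haploid data: mtDNA sequences are single alleles, so the
individual-within-population component of the diploid estimator drops out,
leaving, per haplotype allele,
$MSP = \sum_i n_i(p_i-\bar p)^2/(r-1)$ and
$MSG = \sum_i n_i p_i(1-p_i)/\sum_i(n_i-1)$, combined across alleles as
$\theta = \sum(MSP-MSG)\,/\,\sum(MSP+(n_c-1)MSG)$. Negative estimates are
retained (they are informative about θ ≈ 0), and significance comes from
permuting individuals among populations with sizes preserved — the standard
AMOVA significance procedure, which is what the source tables' "bootstrap"
footnote operationally denotes in the cited software. A distance-weighted
Φ\_ST (pairwise-difference AMOVA) is available as `method = "phi"` since
the published analyses could have used either; the frequency-based form is
the default because the cited reference is the frequency-based estimator.
Populations with fewer than four sequences are excluded from estimation but
still reported with their counts.

## Haplotype networks

The connection limit follows the statistical-parsimony logic: how many
observed differences can two haplotypes show before the assumption "each
difference is a single substitution, nothing is hidden" drops below
confidence α? The package models substitutions as site-independent Poisson
events under a Jukes–Cantor chain, calibrates the per-site intensity λ so
the expected difference proportion matches $j/L$, and evaluates

$$P_j = \left(\frac{\lambda e^{-\lambda}}{p_{diff}}\right)^{j}
        \left(\frac{e^{-\lambda}}{1-p_{diff}}\right)^{L-j},$$

the probability that the $j$ differing sites were hit exactly once each and
no other site was hit at all. The limit is the largest $j$ with
$P_j \ge \alpha$, floored at one step (at α → 1 only single-step
connections survive). At $L = 657$ and α = 0.95 this gives 8 steps,
slightly more conservative than the ~11 the original TCS tables give for
comparable lengths; the original cladogram-probability machinery (and its
root-weighting of join order) is intentionally not reproduced — the
construction here is a deterministic distance-ordered agglomeration whose
tie-breaking (higher-frequency partner first, then lexicographic label) is
fully specified, because the reference implementation's internal
tie-breaking is unobservable. Multi-step connections insert $d-1$
unobserved intermediate nodes ("missing haplotypes"); alternative
equal-length connections evaluated against the component structure at the
start of each distance level are retained, so reticulations survive.
Haplotype labels order by frequency then sequence, making the whole network
invariant to specimen input order.

## The synthetic-data generator

`simulate_genealogy()` is a standard Kingman coalescent, optionally with
exponential growth implemented as a time-inhomogeneous coalescence
intensity $\binom{k}{2}e^{gt}$ (inverted in closed form), which shortens
internal branches and produces the star genealogies of expanding
populations. `drop_mutations()` overlays finite-sites Jukes–Cantor
mutations at rate θ/2 per branch-length unit: finite sites (rather than
infinite) so the JC correction in the diversity module is exercised
nontrivially. The codon constraint is acceptance sampling, not a full codon
substitution model: a candidate change that is nonsynonymous in its current
codon context is kept with probability ω, and candidates creating stops are
rejected outright when stop suppression is on (so generated data always
pass the ORF screen). With three out of four candidate changes
nonsynonymous, the effective neutral mutation supply is roughly
$(0.25 + 0.75\,\omega)\,\theta$.

The defaults — $L = 657$, θ = 150, growth = 30, ω = 0.05 — were chosen once
to land simulated samples of 15–30 sequences in the empirical mtCOI regime:
haplotype diversity ≈ 0.9–1, nucleotide diversity ≈ 0.003–0.015 per site,
clearly negative Tajima's D, and π\_a/π\_s well below 1. What the generator
does *not* emulate: transition/transversion bias and among-site rate
heterogeneity (real mtCOI third positions are far faster), selection beyond
the uniform ω filter, recombination (correctly absent for mtDNA), and
sequencing error. Tests passing on this generator therefore demonstrate
statistical correctness of the estimators, not robustness to those
real-data features.

## The isolation-with-migration study

The simulator is a structured coalescent in continuous time (generations):
two demes of $N$ diploids (2N gene copies each; a pair coalesces at rate
$1/2N$ per generation), backward migration at per-lineage rates $m_{12}$,
$m_{21}$, merging into an ancestral deme at $T_{div}$. The ancestral size
equals $N$ — the source design states sizes were constant over time and
shows no separate ancestral size. Sampled copies are 40 per deme (20
diploid individuals). Each dataset is a set of unlinked 600 bp fragments
with μ = 1e-8/bp/generation; sites within a fragment are fully linked.
A recombination rate is carried in the configuration for provenance but
intra-fragment recombination is not simulated: the joint SFS, which is the
only statistic consumed downstream, is insensitive to within-fragment
linkage, so simulating it would add cost without changing any estimate.

Two numerical choices matter:

* **Strong-migration shortcut.** When both $2Nm$ values exceed ~50, the
  event loop would spend thousands of migration events per coalescence
  while the genealogy becomes indistinguishable from that of a single pool
  of $4N$ copies; the simulator then uses the panmictic limit directly
  (tip deme labels kept). This only engages deep in the
  high-migration corner of the search space, where differentiation is
  zero anyway.
* **Common random numbers.** Every likelihood evaluation re-simulates the
  expected SFS by Monte Carlo from a seed fixed per estimation run, so the
  composite-likelihood surface is deterministic and smooth enough for
  Nelder–Mead refinement.

The expected SFS is estimated from accumulated branch lengths per
frequency configuration (mutation-free Rao–Blackwellisation: the expected
count in cell $(i,j)$ is $\mu L\,E[\ell_{ij}]$), which has far lower
variance than counting Poisson mutations. Estimation maximises a composite
likelihood over the folded spectrum: a multinomial term over polymorphic
cells plus a Poisson term on the total polymorphic-site count. The total
term is essential: proportions alone are invariant to rescaling
$(N, T_{div}, m) \to (cN, cT_{div}, m/c)$, so absolute deme size is only
identified through the expected SNP count at the known mutation rate. The
purely multinomial form remains available (`include_total = FALSE`) for
shape-only comparisons. Zero cells in the expected spectrum are floored at
a small pseudo-count before normalisation so the likelihood stays finite.
The spectrum is folded by default because real mtCOI data have no outgroup
polarisation; unfolded spectra are supported where the ancestral state is
known (simulations).

The search runs a 5-point-per-axis log10 grid over
$N \in [10^2, 10^6]$, $T_{div} \in [10^2, 10^7]$,
$m \in [10^{-6}, 10^{-2}]$ (bounds bracket all study truths), then
Nelder–Mead on log10 parameters from the best grid point, with Monte-Carlo
budgets of 200 fragments per grid evaluation and 600 per refinement
evaluation. These problem sizes — together with 5 pseudo-observed datasets
per cell in the default performance study rather than 20, and 100-fragment
datasets as the headline condition — are the package's desk-scale defaults;
each estimation completes in a few seconds, and all sizes are arguments, so
the full 20-pseudo-dataset, 10000-fragment grid of the original design is a
configuration choice, not a code change. Estimates landing within 2% (log
scale) of a search bound are flagged `at_bound`: with data simulated under
panmixia, for instance, the migration rate correctly escapes to the upper
bound and the flag says so.

Two systematic behaviours of the estimator are worth knowing. First, at
$T_{div} = 10^5$ generations the divergence-time estimate sits below the
truth: the time to the most recent common ancestor of the sample bounds the
signal, and with ongoing migration the coalescent history rarely reaches
back to the split. The migration rate and deme size remain well estimated.
Second, below ~100 fragments the per-dataset spectra are too sparse and the
inter-replicate spread of all three estimates widens sharply — the
motivating observation of the performance study.

## Geographic and abundance utilities

Inter-site distances use the haversine great circle on a sphere of radius
6371.0 km from degree–minute coordinates (the site-table values are
consistent with spherical distances at minute precision; ellipsoidal
geodesics would change them by < 0.5%). One published site coordinate
(ABE, printed 177°11'W) is consistent with its printed neighbour distances
only under 176°11'W; the parser takes coordinates as given and this
discrepancy is surfaced here rather than silently corrected. Abundance
extrapolation scales a mean count per 64 cm² sampler by 10000/64 to a per-m²
density and then by the target area.

## Known limitations

* Statistics are single-locus; no recombination anywhere (correct for
  mtDNA, wrong for nuclear data).
* The coalescent P-values condition on $\theta_W$, not on S; for very small
  S the two conditionings can differ noticeably.
* The network construction is TCS-*like*: identical connection limits, but
  deterministic join order instead of the original's probabilistic root
  weighting.
* The IM estimator assumes unlinked fragments of equal length and a known
  mutation rate; misspecifying μ biases N̂ inversely.
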