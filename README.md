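# ventpop

Population genetics of hydrothermal-vent meiofauna from a single
mitochondrial marker. `ventpop` implements the analysis chain used for
vent-endemic copepods (family Dirivultidae) sampled across mid-ocean-ridge
systems: codon-aware quality screening of mtCOI alignments, per-population
diversity and demography statistics, AMOVA-based F\_ST, statistical-parsimony
haplotype networks, and a two-deme isolation-with-migration (IM) coalescent
simulator with composite-likelihood parameter estimation on the joint site
frequency spectrum (SFS). A seeded synthetic-data generator produces
mtCOI-like samples with the statistical structure these analyses assume, so
the whole pipeline is testable without any sequence download.

## What it computes

**Sequence QC.** mtCOI is protein-coding, so nuclear mitochondrial
insertions (NUMTs) betray themselves by frame-shifting indels or internal
stop codons. `screen_orf()` applies both checks under the invertebrate
mitochondrial code; `complete_sites()` restricts each population to columns
where every specimen has an unambiguous base.

**Diversity** (`diversity_summary()` and friends). Haplotype diversity uses
Nei's unbiased estimator `Hd = n(1 − Σ p_i²)/(n − 1)`; nucleotide diversity
π averages Jukes–Cantor-corrected pairwise distances
`d = −(3/4)·ln(1 − (4/3)p)`; the synonymous/nonsynonymous partition
π\_a/π\_s uses Nei–Gojobori pathway counting, with π\_a/π\_s ≪ 1 expected
for a functional mitochondrial gene under purifying selection. Between-group
p-distances come with site-resampling bootstrap standard errors.

**Demography** (`demography_summary()`). Tajima's D, Fu's Fs (via the Ewens
sampling formula with exact Stirling-number arithmetic), Ramos-Onsins &
Rozas R2, and the mismatch-distribution raggedness index, each with an
empirical P-value from neutral constant-size coalescent replicates at
Watterson's θ. Jointly negative / small values are the signature of
population expansion.

**Divergence** (`amova_fst()`). Weir–Cockerham (1984) variance-components
θ adapted to haploid haplotype data, multi-allelic, with a permutation test
of individuals among populations; a distance-weighted Φ\_ST variant is
available.

**Networks** (`build_network()`). Haplotypes are connected by single
mutational steps up to a statistical-parsimony connection limit
(`parsimony_limit()`), with unobserved intermediates inserted on multi-step
connections and reticulations retained; export to GraphML, locality-sharing
reports, `autoplot()`.

**IM model** (`simulate_im()`, `estimate_params()`,
`run_performance_study()`). Structured coalescent for two demes of N
diploids exchanging migrants at rate m and merging T\_div generations ago;
datasets are sets of unlinked 600 bp fragments. Parameters (N, T\_div, m)
are re-estimated by maximising a composite likelihood of the folded joint
SFS (multinomial over polymorphic cells plus a Poisson term on the total
SNP count, which is what identifies absolute N at known mutation rate).
The performance study re-estimates from pseudo-observed datasets across
fragment counts, reproducing the finding that ~100 fragments suffice for
reliable recovery of m and N.

## Worked example

Three synthetic populations of one species at East Pacific Rise site labels,
generated at the package defaults (which emulate the empirical mtCOI regime:
high Hd, low π, expansion, purifying selection), then the full pipeline:

```r
library(ventpop)

cfgs <- list(
  `Bio 9`     = synth_config(n = 30, seed = 101),
  `V-Vent`    = synth_config(n = 25, seed = 102),
  `Marker 28` = synth_config(n = 15, seed = 103)
)
paths <- synthesize_dataset(cfgs, "example_in",
                            species = "Stygiopontius sp.", region = "EPR")
res <- run_pipeline(fasta = paths$fasta, sheet = paths$sheet,
                    out_dir = "example_out", seed = 7, reps = 1000)

dplyr::select(res$diversity, site, n_seq, sites_used, n_hap, hd, s, pi, pi_ratio)
#> # A tibble: 4 × 8
#>   site      n_seq sites_used n_hap    hd     s      pi pi_ratio
#>   <chr>     <int>      <int> <int> <dbl> <int>   <dbl>    <dbl>
#> 1 Bio 9        30        657    21 0.963    36 0.00853   0.126
#> 2 V-Vent       25        657    16 0.937    23 0.00442   0.0736
#> 3 Marker 28    15        657    12 0.962    22 0.00806   0.0344
#> 4 overall      70        657    49 0.984    75 0.00783   0.0877

dplyr::select(res$demography, site, tajima_d, p_d, fu_fs, p_fs, r2, rg)
#> # A tibble: 4 × 7
#>   site      tajima_d      p_d  fu_fs     p_fs     r2      rg
#>   <chr>        <dbl>    <dbl>  <dbl>    <dbl>  <dbl>   <dbl>
#> 1 Bio 9       -1.42  0.0500   -10.2  0.00300  0.0663 0.0247
#> 2 V-Vent      -1.92  0.0190   -10.2  0.000999 0.0716 0.0458
#> 3 Marker 28   -0.920 0.171     -4.55 0.0130   0.0896 0.0247
#> 4 overall     -2.27  0.000999 -18.4  0.000999 0.0301 0.00876

res$fst
#> # A tibble: 1 × 7
#>   species           method       fst  p_value n_permutations n_populations n_seq
#> 1 Stygiopontius sp. frequency 0.0466 0.000999           1000             3    70

res$networks[["Stygiopontius sp."]]
#> <haplotype_network> 49 observed + 67 inferred haplotypes, 123 edges,
#>   1 component(s); limit 8 steps
```

Reading the output: every population has high haplotype diversity but low
nucleotide diversity (many closely related haplotypes), π\_a/π\_s far below
1 (purifying selection on the protein), uniformly negative Tajima's D and
strongly negative Fu's Fs with small coalescent P-values (population
expansion), and a small but significant F\_ST (high connectivity with
detectable structure). The network is a single component dominated by
frequent central haplotypes — the classic expansion star.

The IM machinery runs the same way:

```r
cfg <- im_config(N = 10000, T_div = 1e5, m12 = 1e-4, m21 = 1e-4,
                 n_frag = 100, seed = 11)
migrants_per_generation(cfg)   # Nm12 = Nm21 = 1 migrant/generation
sim <- simulate_im(cfg)
fit <- estimate_params(sim$sfs_folded, n_frag = 100, seed = 12)
tidy(fit)
#> term  estimate  (N ~ 1e4, T_div below truth, m ~ 1e-4)
```

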