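# cryptwebs

Cryptic species delimitation and quantitative host–parasitoid food webs.

## What this package is for

Parasitoid host specificity is usually read off a quantitative food web: a
host × parasitoid matrix whose cells count reared individuals. Every number
computed from such a web — a species' host range as much as whole-network
connectance — depends on where the species boundaries are drawn. Minute
parasitoids (e.g. encyrtid wasps reared from armored scale insects) routinely
hide complexes of cryptic species inside one morphospecies, so DNA-based
delimitation can turn one apparent generalist into several strict
specialists and reshape the web it sits in.

`cryptwebs` implements the complete analysis chain for studying that effect:

* **Delimitation** — pairwise Kimura two-parameter (K2P) distances;
  barcode-gap partitioning over a log-spaced grid of prior intraspecific
  divergences (defaults p ∈ [0.001, 0.04], 50 steps, relative gap width
  X = 0.75) with initial, recursive and stable partitions; the
  single-threshold generalized mixed Yule–coalescent (GMYC) model
  `b_i = λ_div·n_div^p_div + λ_coal·Σ_k [n_k(n_k−1)]^p_coal` with a
  likelihood-ratio test against a single-process null; and consensus
  integration that refines, but never lumps, the morphospecies.
* **Web building** — quantitative interaction matrices from rearing records
  under all four crossings of morphological (MOR) and molecular (MOL)
  taxonomies, with integer largest-remainder apportioning of records whose
  morphospecies were split, plus regional subsetting.
* **Species-level indices** — resource range RR = (R−r)/(R−1), paired
  difference index, species specificity index (population-SD coefficient of
  variation / √(R−1)), Blüthgen's d and standardized d′ with exact integer
  extremes, and the interaction service index PSI.
* **Network-level metrics** — connectance, H2′ (standardized two-dimensional
  Shannon entropy), weighted generality/vulnerability/linkage density,
  compartments, NODF and a documented temperature approximation,
  specialization asymmetry, and secondary-extinction robustness.
* **Sampling completeness** — sample coverage and Simpson (Hill q = 2)
  rarefaction–extrapolation.
* **Synthetic data** — a seeded generator producing species trees, marker
  alignments with cryptic structure (intraspecific divergence ≲ 1.9%,
  interspecific ≥ 3.7%), and overdispersed rearing records, so the whole
  pipeline runs without any external data.

The package is tidyverse-shaped: functions take and return tibbles, fitted
objects have `tidy()`/`glance()` methods, result types have `autoplot()`
methods, and `run_pipeline()` drives the full analysis end to end, writing a
TSV report bundle plus a run manifest.

## Worked example

Simulate a study at the default conditions (41 molecular / 18 morphospecies
parasitoids on 37 / 28 hosts), build the four crossed webs from the same
rearing records, and compare:

```r
library(cryptwebs)
library(dplyr)

study <- simulate_study(sim_config(seed = 11), alignments = FALSE)
ws <- build_webset(study$records, study$truth$host, study$truth$parasitoid)
ws
#> <web set>
#>   MOR-MOR: 21 x 20, m = 2496
#>   MOR-MOL: 21 x 40, m = 2496
#>   MOL-MOR: 24 x 20, m = 2496
#>   MOL-MOL: 24 x 40, m = 2496
```

All four webs share the grand total m = 2496 reared individuals; only the
species boundaries differ. Per-parasitoid specialization in the fully
molecular web:

```r
species_indices(ws[["MOL-MOL"]], "parasitoid") |>
  arrange(desc(n_host)) |> head(5) |> format_species_indices() |>
  select(label, n_host, RR, PDI, SSI, d_prime, PSI)
#>   label               n_host    RR   PDI   SSI d_prime   PSI
#> 1 Encyrtidae_sp14          3  0.91  0.98  0.74    0.36  0.99
#> 2 Encyrtidae_sp02_nr1      2  0.96  0.98  0.73    0.33  0.51
#> 3 Encyrtidae_sp02_nr4      2  0.96  1.00  0.91    0.45  0.27
#> 4 Encyrtidae_sp05_nr3      2  0.96  0.96  0.69    0.32  0.76
#> 5 Encyrtidae_sp10_nr1      2  0.96  0.98  0.74    0.56  0.93
```

`RR` close to 1 marks near-specialists (2–3 of 24 hosts used); `SSI` 0.69
for an even 2-host split is the population-SD convention's fingerprint; low
`d_prime` despite high `RR` flags parasitoids whose only hosts are shared
"superhosts". Network-level contrast between the morphological and the fully
molecular web:

```r
network_metrics(ws, seed = 11, n_orders = 200) |>
  select(web, connectance, H2_prime, generality, n_compartments, robustness)
#>       web connectance H2_prime generality n_compartments robustness
#> 1 MOR-MOR      0.1000    0.786       2.38              6      0.626
#> 2 MOR-MOL      0.0548    0.948       1.21             15      0.524
#> 3 MOL-MOR      0.0896    0.828       2.39              7      0.633
#> 4 MOL-MOL      0.0490    0.953       1.21             17      0.524
```

Resolving the cryptic parasitoid complexes halves connectance and
generality, nearly triples the number of compartments, and raises
network-level specialization H2′ — the directional signature the package's
acceptance experiments verify on 100 seeded replicates.

Delimitation runs the same way from sequences:

```r
al   <- simulate_alignments(study$community)
coi  <- dplyr::filter(al$sequences, guild == "parasitoid", marker == "COI")
abgd <- abgd_partition(k2p_matrix(coi))
n_entities(abgd$stable)   # recovers the 41 simulated species
```

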