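# satellitome

Satellite DNA (satDNA) families — tandemly repeated monomers organized in
long arrays — are among the fastest-evolving components of eukaryotic
genomes, yet related species often share an ancestral collection of them
(the "library hypothesis"). `satellitome` is an R package for researchers
who characterize these repeats from unassembled paired-end short reads and
ask how they evolve across species: it discovers tandem-repeat families,
estimates each family's genomic abundance and divergence, curates a named
catalog, and compares catalogs across species through conserved-family
detection, genetic distances and consensus turnover rates.

## The quantities at the core

* **Similarity tiers.** Consensus monomers are circular and strand-less;
  similarity is the identity of the best global alignment over every
  rotation and strand (gap columns included in the denominator). Pairs
  >95 % similar are the same variant (SV), >80 % variants of one satDNA
  (V), >50 % a superfamily (SF); families ≥50 % similar across species
  (with a significant local-homology segment) are *conserved*.
* **Kimura 2-parameter distance** between consensus sequences, with `P`
  transitions and `Q` transversions per site:
  `K = −½ · ln[(1 − 2P − Q) · √(1 − 2Q)]`,
  falling back to the Jukes–Cantor correction `d = −¾ · ln(1 − 4p/3)`
  when K2P saturates.
* **Consensus turnover rate**: `CTR = K / (2T)` — the per-year rate at
  which two orthologous consensus sequences accumulate substitutions,
  given the species divergence time `T` in years.
* **Repeat landscapes**: family abundance mass per 1 % divergence bin,
  the standard summary of amplification timing.
* **Abundance**: matched read nucleotides over total nucleotides
  analyzed, with best-hit assignment so family abundances never double
  count.

A seeded generator (`build_library()`, `make_species_scenario()`) plants
tandem arrays of known monomers, abundances and divergences — including
multi-species scenarios where shared monomers drift independently at a
known substitution rate — so every stage is testable against ground
truth without downloading anything.

## Worked example

Plant two satellite families in a 0.6 Mb genome, sequence it to 10× as
2 × 150 bp pairs, and run the full pipeline (discover → quantify →
curate → name):

```r
library(satellitome)

specs <- list(
  planted_family("satA",  60, at_fraction = 0.60, target_abundance = 0.010,
                 copy_divergence_mean = 2),
  planted_family("satB", 120, at_fraction = 0.50, target_abundance = 0.005,
                 copy_divergence_mean = 2))
lib <- build_library(specs, genome_size = 6e5, coverage = 10, seed = 11)
lib
#> Paired-end read library: 20000 pairs of 2 x 150 bp
#>   origin: background=19685, satA=217, satB=98

run <- run_pipeline(lib, "Syn",
                    pipeline_config(seed = 1, discovery_pairs = 12000L,
                                    quant_pairs = 12000L))
run$catalog[, c("name", "monomer_length", "abundance", "mean_divergence")]
#> # A tibble: 2 × 4
#>   name         monomer_length abundance mean_divergence
#>   <chr>                 <int>     <dbl>           <dbl>
#> 1 SynSat01-60              60   0.0110             2.73
#> 2 SynSat02-120            120   0.00547            2.17
```

Both planted families are recovered, named in decreasing order of
abundance (`SynSat01-60` = most abundant, 60 bp monomer), with abundance
estimates close to the planted 1 % and 0.5 % and mean divergences close
to the planted 2 % per copy.

Comparative arithmetic works directly on published catalog numbers: the
most diverged conserved pair between the *Myloplus tiete* and
*Piaractus mesopotamicus* satellitomes has K2P distance 2.53 at a 40-Myr
divergence,

```r
round(ctr(2.53, 40e6) * 1e6, 4)
#> [1] 0.0316
```

i.e. 0.0316 substitutions/site/Myr. Bundled tables
(`mti_catalog()`, `serrasalmidae_conserved()`,
`serrasalmidae_k2p_summary()`) carry the published *M. tiete* catalog
statistics and the three-species conservation and distance summaries
used by the tests.

For cross-species simulation, `make_species_scenario()` builds catalogs
whose shared families drifted for known times at a known rate, and
`scenario_ctr_recovery()` + `summarize_pairs()` recover that rate from
the estimated distances.

A thin command-line wrapper (`inst/cli/satellitome-cli.R`) exposes
`simulate`, `discover`, `quantify`, `catalog`, `compare` and `run-all`
subcommands over FASTQ/FASTA/TSV files.

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline comparative
quantities — consensus turnover rates derived from the bundled published
distance tables via `ctr()` — and writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/satellitome-methods.Rmd` documents the substitution model,
the discovery floors, the alignment and distance conventions (including
why substitution counting is gapless for equal-length monomers and why
conservation calls require a homology gate), the synthetic world's
assumptions, and known limitations.
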