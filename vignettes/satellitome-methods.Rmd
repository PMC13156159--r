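---
title: "Methods: satellite DNA discovery, quantification and comparative turnover"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: satellite DNA discovery, quantification and comparative turnover}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`satellitome` characterizes the satellite DNA (satDNA) repertoire of a
genome from unassembled paired-end short reads and compares repertoires
across related species. The pipeline has five analytical stages —
discovery, quantification, curation, naming, comparison — plus a seeded
synthetic-data generator that plants known tandem arrays so that every
stage can be tested against ground truth. This vignette documents the
models, the tunable parameters, and the numerical and design choices made
where the problem left the design open.

# The synthetic world

`build_library()` constructs a genome of user-chosen size containing one
contiguous head-to-tail tandem array per planted family, embedded in
random background, and samples paired-end reads uniformly from it.

Defaults and what they emulate:

* **Reads**: 2 × 150 bp pairs from contiguous 300 bp fragments — the
  read geometry of a typical BGISEQ/Illumina satellitome survey.
* **Background composition**: A+T fraction 0.56, the mean catalog
  composition observed in fish satellitomes; configurable.
* **Copy divergence** (`copy_divergence_mean`, percent): each array copy
  is independently mutated away from the family consensus by a per-site
  Poisson substitution process with this expectation. The default 2 %
  reflects the recent-amplification regime that dominates repeat
  landscapes of abundant satellites; quantification tests also plant
  diverged (≈12 %) families.
* **Indels**: off by default — all distance estimators downstream assume
  a substitution-only process; enabling indels exercises alignment
  robustness only.
* **Array structure**: one contiguous array per family per genome, in
  head-to-tail orientation. Real satellites may occupy several loci; for
  abundance and divergence estimation from reads only the total planted
  mass matters, so a single array is the simplest faithful layout.
* **Sequencing error**: uniform per-base substitution (default 0.001), a
  constant quality string, and no indel or quality-profile realism.
* **Truth manifest**: each read pair is tagged by the region containing
  its fragment midpoint, making the manifest fraction an unbiased
  estimate of the planted genomic fraction.

`evolve_sequence()` implements the substitution process used everywhere:
each site receives Poisson(`rate × time`) substitution events; each event
is a transition with probability `ts_tv_ratio / (ts_tv_ratio + 1)`
(default ratio 2, the standard vertebrate value — the source data does
not report one) and otherwise a uniform transversion. Multiple hits apply
sequentially, so the realized p-distance saturates exactly as the Kimura
2-parameter (K2P) model assumes, and the K2P estimator is consistent for
`rate × time`.

`make_species_scenario()` emulates the satDNA "library hypothesis":
shared families descend from common ancestral monomers that drift
independently along an ultrametric species tree reconstructed from the
supplied pairwise divergence times (UPGMA merge order); private families
are drawn fresh per species. Two lineages separated by time `T`
accumulate an expected `2·rate·T` substitutions per site between their
consensus sequences, which is the identity that the consensus turnover
rate inverts.

**Shared-monomer lengths default to 1–2 kb.** This is a deliberate
choice: at Late-Eocene depths (≈40 Myr at ≈1.85e-8 substitutions/site/yr)
the true consensus identity falls to ≈35 %, while the best *chance*
alignment of two unrelated monomers — a maximum over every rotation,
strand and gap placement — sits near 50 % for monomers below a few
hundred bp. Only monomers long enough for the true rotation to outscore
chance carry usable distance signal at that depth. Short conserved
satellites in real catalogs are informative precisely because they are
*not* that diverged.

# Alignment and distances

Monomers are circular and strand-less, so `best_circular_alignment()`
aligns the first sequence globally (Needleman–Wunsch; match +1, mismatch
−1, gap column −2) against every rotation of the second and of its
reverse complement, and returns the alignment with the highest identity,
defined as matches over all aligned columns *including gaps* — the
conservative denominator appropriate for thresholding similarity.
Determinism is guaranteed by a lexicographic DP objective (maximize
score, then matches, then minimize gap columns; traceback prefers
diagonal) and explicit tie-breaks (forward strand first, then smallest
rotation offset). For monomers beyond 500 bp the exhaustive rotation scan
is replaced by a doubled-sequence local-alignment shortcut that locates
the best rotation first; the two strategies agree on the brute-force
oracle test set. Ambiguous bases (N) score as mismatches and are excluded
from substitution counts.

Distances come from the aligned substitution fractions:

* **K2P**: `K = −½·ln[(1 − 2P − Q)·√(1 − 2Q)]` with `P` transitions and
  `Q` transversions per ungapped, unambiguous column. When either log
  argument is non-positive the estimator is saturated and returns `NA`
  (a typed signal, not an error).
* **Jukes–Cantor fallback**: `d = −¾·ln(1 − 4p/3)` on the p-distance,
  applied per pair whenever K2P saturates; itself saturated at
  `p ≥ 0.75`. Pairs where both saturate carry `method_used =
  "undefined"` and are excluded from means (and counted separately).

**Gapless distance counting.** `seq_distance()` counts substitutions
over the best *gapless* circular rotation whenever the two monomers have
equal length, and only falls back to the gapped alignment for unequal
lengths. The substitution models are gap-free; at deep divergence a
gapped aligner shifts segments to manufacture chance matches, inflating
identity to ≈50 % and collapsing K2P to roughly a third of its true
value. With gapless counting the three-species drift scenario at the
published divergence times and rate returns the planted rate within a
few percent, where the gapped path underestimates it three-fold. For
low-divergence pairs the two paths coincide (the optimal gapped
alignment contains no gaps).

**Homology gate for conservation calls.** Because chance circular
gapped identity is ≈50 %, a bare "≥50 % similar" rule would call almost
any pair of equal-length monomers conserved. `find_conserved()` (and the
superfamily tier of `tier_and_dedupe()`) therefore requires a
significant local homology segment first — the role the RepeatMasker
cross-masking step plays in published pipelines — using a local
alignment score floor of `max(8, min(len_min/2, 4 + log2(len_a·len_b)))`,
a Karlin–Altschul-style log-scaled threshold capped so that short
monomers remain detectable. Chance scores between unrelated monomers
plateau near 8–19 over the relevant length range; genuine homologs at
≥60 % identity score well above it.

# Discovery

`detect_tandem_families()` reimplements graph-based tandem detection:
count k-mers (default `k = 21`) over both mates, keep k-mers above an
abundance floor, and walk the k-mer adjacency greedily to the heaviest
unvisited successor. A walk that revisits its own path closes a cycle —
the signature of a tandem monomer — which is spelled into a circular
consensus, refined by one round of read realignment with per-column
majority vote, and normalized to its canonical rotation and strand
(lexicographically smallest, so outputs are comparable across runs).

The floors are expressed relative to the **effective coverage**,
estimated as the mass-weighted median k-mer count: the plain median is
dragged to 1–2 by singleton error k-mers, while half the k-mer *mass*
sits at the background multiplicity. Seeds must exceed 3× effective
coverage (tandem k-mers occur `copies × coverage` times); cycle
extension tolerates 1.5× so a single under-sampled k-mer does not break
an otherwise supported cycle. An early design that took the floor as a
fixed fraction (10⁻⁴) of total k-mer mass could not reach the 0.1 %
abundance regime at realistic monomer lengths and was replaced.

`iterate_discovery()` repeats subsample → detect → subtract until a
round adds no new family (similarity ≤95 % to all known families) or the
round cap (default 8) is reached; termination is guaranteed because
subtraction only removes reads. Subtraction drops a pair when either
mate aligns locally to any family's doubled consensus at ≥80 % identity
over ≥50 % of the read, after an exact 12-mer prefilter that keeps the
scan linear. Desk-scale defaults subsample 2 × 50 000 pairs per round;
the full-scale protocol value (2 × 500 000) is a configuration choice.

Known limitations: monomers longer than ~1 kb fragment in the k-mer
graph at read length 150 and are recovered only partially; families
whose copies exceed ~5 % divergence lose consensus k-mer support
(`0.95²¹ ≈ 0.34`) and need proportionally more copies or coverage to
seed a walk. Discovery tests therefore plant recent (1–2 % divergence)
families, consistent with the repeat-landscape regime that discovery
tools are designed for; older families still quantify correctly once a
consensus is known.

# Quantification

`estimate_abundance()` aligns a read sample against every catalog
consensus (local alignment against the consensus tiled to read length
plus one monomer — a merely *doubled* short monomer could never span a
full read — both strands, exact 10-mer prefilter). A hit requires ≥70 %
identity over ≥50 read bases: at 70 % identity a 30-base hit scores ~12,
which is the chance level once a shared prefilter k-mer seeds the
alignment, and admitting such hits measurably inflates rare families
(+16 % on a 0.5 % family in the test world); at 50 bases the false mass
falls to ~3 % with no loss of true hits. Each read is assigned to at most
one family — best identity wins, ties to the lower catalog index — so
summed abundances can never exceed 1. Abundance is matched read
nucleotides over total nucleotides analyzed; divergence is the K2P
distance of each hit segment (JC fallback on saturation); the repeat
landscape accumulates abundance mass in 1 % divergence bins from 0 to
50 %, with more diverged hits capped into the last bin so that landscape
mass equals abundance exactly, as an accounting identity.

Per-read divergence estimates carry binomial noise: a 150 nt read from a
2 %-diverged family carries ~3 substitutions, so the landscape mode for
such a family can fall anywhere in bins 0–3, and local-alignment end
trimming shifts it slightly downward. Tests assert the mode within that
band rather than at a single bin.

# Curation and naming

`tier_and_dedupe()` applies the standard similarity tiers with strict
inequalities: >95 % — same variant (collapsed, keeping the
highest-abundance consensus); >80 % — variants of one satDNA (shared
`variant_group`); >50 % — superfamily (shared `superfamily_id`, subject
to the homology gate above). All tiers use single-linkage transitive
closure, which is order-independent and matches how superfamilies are
used in the satellitome literature. An optional contaminant screen drops
candidates >80 % similar to user-supplied sequences (multigene families,
transposable elements); no contaminant database is bundled.

`name_catalog()` names families `<Prefix>Sat<NN>-<monomer length>` in
decreasing order of abundance, ties broken by shorter monomer and then
lexicographic consensus so renaming is idempotent.

# Comparative analysis

`find_conserved()` matches families one-to-one, greedily by descending
similarity, at ≥50 % similarity plus the homology gate; a switch permits
many-to-one matching (real catalogs contain such cases), with conflicts
logged either way. `fill_distances()` computes each conserved pair's
distance and the consensus turnover rate `CTR = K/(2T)`, with `T` the
species divergence time in years supplied by configuration (divergence
times are inputs, not estimates). `summarize_pairs()` reports mean ± sd
of K2P and CTR per species pair and overall, excluding and counting
undefined pairs. `three_way_table()` lays out the focal species' shared
families against two other catalogs, with counts of families shared with
both or exactly one.

For parameter-recovery tests, `scenario_ctr_recovery()` can pair
families by the scenario's recorded orthology (`pairing = "truth"`)
instead of by similarity. At 40-Myr depths the true consensus identity
(~35 %) falls *below* the 50 % operational threshold, so similarity
matching would discard exactly the pairs whose distances are being
tested; truth pairing isolates the estimator from the matching step.
Family-level rates for three-way families are reported per pairwise
comparison, each with its own `T`.

`anova_oneway()` is the classic fixed-effects one-way ANOVA (Welch's
variant behind a flag); `anova_from_summary()` reconstructs the same F
statistic from per-group sizes, means and standard deviations, for use
when only published summaries of the underlying distance table are
available. Reconstruction from rounded summaries reproduces published F
values to about the second decimal.

# Numerical and testing notes

* All randomness is seeded through function arguments; identical seeds
  give byte-identical libraries and FASTQ output.
* The alignment DP uses exact integer/rational comparisons for identity
  ties; no floating-point tie-breaking.
* `k2p(0.5, 0.1)` and `jc(0.75)` return `NA` by design — saturation is
  data, not an error; invalid fractions (negative, `P + Q > 1`) raise
  errors.
* Desk-scale test worlds (genomes of 0.5–2 Mb at ~10× coverage) keep the
  full suite within minutes while preserving the copy-number and
  coverage ratios that the discovery floors rely on; paper-scale
  subsample sizes are exposed as configuration (`pipeline_config(scale =
  "paper")`) but not exercised in tests.
* A green suite establishes recovery of *planted* truth under the
  generator's assumptions (uniform coverage, substitution-only drift,
  single arrays); it does not establish performance on real libraries
  with coverage bias, higher-order repeat structure, or transposable
  elements.
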