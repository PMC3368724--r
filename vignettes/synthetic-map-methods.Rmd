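---
title: "Building synthetic linkage maps and comparative synteny analyses with synmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building synthetic linkage maps and comparative synteny analyses with synmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synmapr)
library(dplyr)
```

## The problem

Several research groups often publish independent genetic linkage maps for
the same species, each built from its own mapping families, marker panels
and software. A *synthetic* (consensus) map merges them into a single,
denser map. The catch is that published maps rarely ship their raw
segregation data: some provide genotypes, others only ordered loci with
inter-locus distances. `synmapr` implements a complete workflow for this
situation, modelled on consensus mapping in salmonid fish — where a recent
lineage-specific whole-genome duplication (WGD) additionally leaves a
quarter of all loci duplicated, and where comparative analysis against
model fish genomes (medaka, stickleback, zebrafish) both validates the map
and illuminates genome evolution.

The package assumes doubled-haploid (DH) mapping families: every offspring
is fully homozygous, so its genotype vector *is* a gamete and recombination
fractions are directly countable from call discordance.

## Reconstructing gametes from distance-only maps

A distance-only map is converted back into *pseudo-gamete vectors* so that
it can be merged with raw genotype data. Kosambi distances $k$ (in
Morgans) become recombination fractions through the inverse Kosambi map
function

$$r = \tfrac12\,\frac{e^{4k}-1}{e^{4k}+1} = \tfrac12\tanh(2k),$$

and each linkage group is rebuilt locus by locus: the first locus is
$\lceil N/2\rceil$ zeros followed by $\lfloor N/2\rfloor$ ones for a family
of $N$ gametes, and each next locus copies its predecessor with
$\mathrm{round}(rN)$ flips, alternating the leftmost unflipped 0 and the
leftmost unflipped 1. The Hamming distance between adjacent loci is then
exactly $\mathrm{round}(rN)$, so two-point estimation on the
reconstruction returns the encoded fractions up to rounding. Rounding is
half-away-from-zero; per-interval counts are rounded independently
(accumulating fractional recombinants across intervals would make each
vector depend on the whole path, for no measurable benefit at realistic
$N$). `rescale_profile()` supports down-weighting a large family by
reconstructing at a smaller nominal $N$; the message it emits when an
interval's count rounds to zero makes the information loss explicit.

```{r}
dm <- tibble::tibble(dataset = "ARS", linkage_group = "RT01",
                     locus = c("A", "B"), locus_index = 1:2,
                     interval = c(recomb_to_kosambi(0.04) * 100, NA),
                     distance_kind = "kosambi_cM")
g <- gametes_from_profile(as_recomb_profile(dm, family_size = 50))
table(first = g$call[g$locus == "A"], second = g$call[g$locus == "B"])
```

## Screening heterogeneous datasets

Before merging, locus names are standardized against a synonym table
(`standardize_locus_names()`, with a machine-readable rename log), and
redundant loci — two names sharing a database accession within one map —
are flagged (`detect_redundant_loci()`). Name-similarity heuristics are
deliberately not used: they are error-prone, and accession identity is the
only evidence that two names are one physical marker. Duplicated-locus
twins (`/1`, `/2` suffixes), which legitimately share accessions, are
exempt.

Cross-dataset consistency is checked at two levels:

* **linkage-group assignment** (`check_group_consistency()`): a locus
  placed on different groups in different datasets, plus wholesale
  exclusion of source groups flagged as merged/ambiguous;
* **marker order** (`check_order_consistency()`): for each dataset pair
  sharing at least three loci on a group, the longest common subsequence
  (LCS) of the shared-locus orders is computed, allowing whole-group
  reversal since a linkage group has no intrinsic orientation. Loci
  outside the LCS are order-discrepant. "Order discrepancy" has no
  standard formal definition; exclusion from the orientation-free LCS is
  the natural minimal-edit formalization. When several minimal deviant
  sets exist, the set with the smallest summed rank displacement is
  chosen, then the lexicographically first — a deterministic tie rule.

`resolve_discrepancies()` applies auditable rules: a single deviant
dataset against two or more concordant ones loses the locus; a conflict
between exactly two raw-genotype datasets is *ignored* (orders merged)
when at most two genotype-call changes would reconcile it, and otherwise
the locus is split under dataset-suffixed names; group conflicts always
split. The two-call threshold operationalizes "one or two inconsistent
genotypes": the reconciliation count is found by brute force over single
calls of the deviant locus, and calls are only counted, never altered.
Pseudo-gamete datasets carry no genotype-level evidence, so conflicts
involving them go straight to the suffix split. Every action lands in an
audit log, and re-screening the cleaned data returns nothing.

## Building the map

`merge_matrices()` takes the union of loci and concatenation of
(dataset-namespaced) individuals per linkage group. `two_point_table()`
counts concordant/discordant calls over pairwise-complete columns; since
allele coding polarity is arbitrary between datasets, the recombinant
count of a pair is `min(discordant, concordant)` with a coupling/repulsion
phase label. Because crossover interference is close to complete in
salmonids, the recombination percentage itself is used as the mapping
function: position increments are $100\,\hat r$ cM and the ordering
objective is the expected map length $\sum \hat r$ over adjacent pairs.

### The search distance

The phase-free `min()` estimate is correct for the linked pairs that
matter, but it is a poor *search* distance: under (near-)complete
interference a long chromosome arm accumulates crossover probability well
above one half, so truly distant same-group pairs show *more* than 50%
discordance, and folding that back through `min()` makes chromosome ends
look tightly linked in repulsion. An ordering search over folded distances
will happily glue the two ends of a group together. `order_markers()`
therefore searches on the *unfolded* discordance fraction after aligning
call polarity within each dataset (chaining along each dataset's own locus
order and complementing any locus in repulsion to its predecessor — only
relative polarity within a dataset affects merged counts). On adjacent
pairs of any reasonable order the two distances coincide, so the reported
map length is still $\sum \hat r$.

### Ordering engines

Four engines minimize the path objective, all O(1)-delta local search on
the distance matrix:

* `annealing` (default): simulated annealing, start temperature 1.0,
  geometric cooling 0.95, 300 moves per temperature, stop at $10^{-3}$;
  moves are segment reversals and single-locus reinsertions;
* `taboo`: steepest-descent over all segment reversals with a recency
  tabu list (tenure 15) and aspiration;
* `flips`: exhaustive permutation of every sliding window of width 5,
  swept until stable, from a greedy nearest-neighbour start (window
  permutation is a polishing move; it cannot carry a misplaced locus
  across the group);
* `exact`: Held–Karp dynamic programming over subsets, guaranteed optimal,
  accepted up to 15 loci.

Heuristics are seed-deterministic and finish with a windowed-permutation
polish; output orders are canonicalized so the first locus name sorts
before the last. Zero-information pairs (no shared typed individual) are
barred from adjacency by a large penalty; if a group cannot be ordered
without one, the junction is flagged rather than silently trusted.

### Error masking and local arbitration

Two refinements are applied by `build_synthetic_map()` by default, both
standard linkage-mapping practice:

* **Singleton-error masking** (`mask_singleton_errors()`): under complete
  interference a call that disagrees with both of its tight (≤ 20 cM)
  flanking calls in the same gamete would require a double crossover in a
  short interval — essentially impossible within an arm — so it is treated
  as a genotyping error and masked before positions are estimated. Left
  in, each such error inflates an interval by roughly twice the error
  rate; on simulated data masking cut the mean total-length error from
  about 12% to about 5%. Calls are masked, never corrected.
* **Terminal-pair arbitration** (`polish_marker_order()`): the path
  objective decides the orientation of the two outermost locus pairs from
  a single flanking estimate, its weakest decision. Every other locus of
  the group carries the same information: a reference locus on one side
  should be closer, in discordance, to the pair member nearer that side.
  References vote, weighted by the additivity attenuation $1-2m$ (with $m$
  the reference-to-pair distance), which automatically silences references
  beyond the distance at which discordance stops growing — including
  across the centromere, where the gradient reverses. Interior pairs are
  left to the objective, which measured more reliable there.

`partition_arms()` labels loci p / centromeric / q around a supplied
centromere range (an input, typically from half-tetrad analysis);
acrocentric groups use a terminal range and an empty first arm is legal.

## Duplicated loci and the Oxford grid

`arm_oxford_grid()` counts duplicate pairs (twins from the lineage WGD)
linking each unordered pair of chromosome arms; pairs with a centromeric
or arm-less member go to an explicit unassigned bucket so that cells plus
bucket always equal the number of duplicate pairs — an identity asserted
in the test suite. `classify_homeologies()` applies the support rule
(single-marker cells are unreliable orphans; default `min_support = 2`)
and annotates the rest against a prior-knowledge table as previously
known, confirmed, or new.

The enrichment question — do arms hit *homeologous* model-species
chromosome pairs more often than chance? — is answered with an exact
binomial tail, computed in log space:

```{r}
binomial_tail(12, 24, 1 / 24)
```

The chromosome count $n$ is exposed as a parameter rather than hard-coded,
since the appropriate null varies with the model species.

## Cross-species synteny

BLAST tabular output (the commented `-m 9` dialect) is parsed with strict
12-column validation. Translated-search hits are collapsed from protein to
gene identifiers before filtration, so alternative-splicing duplicates
cannot masquerade as ambiguity. Filtration keeps, per query: minimal
e-value, then maximal HSP score (percent identity × alignment length),
and drops any query that still has more than one hit — markers without a
unique location are useless for synteny. The filter is idempotent and its
drops are logged.

Species Oxford grids (trout arms × model chromosomes) are then pruned in
two logged steps (`refine_grid()`): a single-marker arm assignment
opposite a well-supported sister-arm assignment to the same model
chromosome is re-assigned (the marker is presumed misplaced around the
centromere — applied only when the sister arm has at least two markers,
since a 1–1 split gives no direction); then remaining single-marker cells
are removed as orphan noise. `reduce_to_expected_homeolog()` keeps, per
arm, only the better-supported member of each within-species homeolog
pair (exact ties keep both, flagged), yielding the parsimonious grid used
for alignment drawings and fragment counting
(`count_syntenic_fragments()`: one fragment = one retained cell).
`project_ancestor()` translates the retained model chromosomes into
ancestral proto-chromosome labels, reporting per-arm composition and the
arms traced to a single ancestor. When nucleotide and translated searches
disagree on a marker, `combine_program_hits()` prefers the location
consistent with the local synteny of the five nearest mapped neighbours,
with ties going to the gene-level (translated) evidence.

Comparative alignments are exported in MapChart text format, model-side
positions taken as subject start divided by $0.5\times10^6$ bp/cM and
markers named by gene identifier when one exists, otherwise by start
position.

## The simulator and what passing tests mean

`simulate_true_map()` plants a full ground truth: marker orders and
positions (spacings are a minimum plus a random share of the remaining
length, so each group spans its nominal length exactly), centromere
ranges, duplicate-pair structure across distinct arms, a one-chromosome-
per-arm synteny layout, within-species homeolog pairs, and an ancestor map
consistent with them. `simulate_dh_dataset()` draws gametes under complete
interference (at most one crossover per arm, interval chosen with
probability equal to its recombination fraction; an `"none"` mode with
independent intervals exists for calibration) and applies symmetric call
errors and missingness. `simulate_homology_table()` writes parseable BLAST
tabular fixtures with planted orphan and tie decoys whose fate under the
pruning rules is known; decoy counts are Poisson, and decoys never reduce
an arm below two planted markers.

Defaults follow the biology being emulated: complete interference (the
reason the recombination percentage is the mapping function), 26%
duplicated loci, DH families of around 50. The simulator does *not*
emulate segregation distortion, clustered missingness, locus-specific
error rates, paralog cross-amplification, or assembly errors in the model
genomes; passing tests demonstrate correctness of the algorithms under
the stated model, not robustness to every artefact of real data.

Simulated problem sizes in the tests and the acceptance script — groups of
5–20 markers, two-group genomes, families of 40–50, 100-seed replications
— were chosen to exercise every code path with tight Monte-Carlo error
while keeping a full run in minutes.

## Known limitations

* With ~150 meioses, 20% missing calls and 0.5% call error, adjacent
  markers 5–7 cM apart occasionally show zero or one observed recombinant;
  their relative order is then genuinely undecidable, and simulated map
  recovery plateaus around 90% of seeds, every residual failure being a
  single adjacent swap of such a pair. More meioses, not more algorithm,
  is the cure.
* The two-point objective deliberately replaces multipoint likelihood;
  positions are sums of adjacent estimates and inherit their noise.
* Homeolog and ancestor correspondence tables are inputs; the package
  ships none for real species.
* The min-flip reconciliation bound in screening is a per-locus brute
  force; simultaneous multi-locus inconsistencies are split rather than
  reconciled.
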