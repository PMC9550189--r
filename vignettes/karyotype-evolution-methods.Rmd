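---
title: "Models and methods behind karyevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind karyevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyevol)
```

`karyevol` studies chromosome evolution at synteny-block resolution: genomes
are ordered, signed sequences of blocks per chromosome, evolving by
inversion, fusion and fission along a dated phylogeny. This vignette
explains the models, the tunable parameters and their defaults, the
numerical conventions, and what the simulation-based validation does and
does not establish about real data.

## Coordinate and representation conventions

All coordinates are 0-based, half-open. Abutting intervals do not overlap;
window classification and per-window base tallies are exact integer
arithmetic under this convention, and 1-based inputs are converted at the
I/O boundary (`read_orthology_table(one_based = TRUE)`).

Block orientation is a sign carried on the block id, never a separate
field: a block `+b` runs tail→head. A junction between consecutive blocks
is an unordered pair of block extremities, written canonically (`"3h|12t"`),
so the adjacency set of a genome is invariant under whole-chromosome
reversal and a genome with B blocks and C chromosomes has exactly B − C
adjacencies. Chromosome order within a genome is display-only.

## The evolution simulator

`simulate_history()` draws a root genome of `n_blocks` blocks with
gamma-distributed lengths (mean 880 kbp, shape 2, floor 10 kbp — the mean
matches the typical size of the conserved building blocks of mammalian
genomes) split into `n_chromosomes` chromosomes. Along each branch the
event count is Poisson with mean `rate × Δt`; the event type follows the
configured mix. Defaults:

* `rate = 1.2` events/My. Under the default mix this corresponds to about
  2 breakpoints/My (each inversion contributes 2 breakpoints and each
  fission 1: 2·0.8 + 0.1 = 1.7 breakpoints per event), the long-term
  average reported for mammalian lineages.
* `mix = c(inversion = 0.8, fusion = 0.1, fission = 0.1)`, consistent with
  inversions accounting for roughly three-quarters to 85% of mammalian
  rearrangements.

Breakpoints fall only between blocks: block granularity *is* the
resolution, and sub-block breakage is modelled by choosing more, smaller
blocks. Two deliberate restrictions:

* inversion cut sites are two *distinct internal* junctions of one
  chromosome (chromosomes need ≥ 3 blocks). This makes the ground-truth
  accounting exact — every inversion breaks exactly 2 ancestral junctions,
  every fission 1, every fusion 0 — at the cost of excluding
  telomere-touching inversions, which leave no internal junction signature
  anyway at block resolution.
* translocations are not a primitive; where a parsimony solution would use
  one, it appears as fission + fusion and is flagged.

Infeasible draws (a fission on a single-block chromosome, a fusion with one
chromosome) are resampled and counted. One global RNG stream is keyed by
`config$seed`; `run_pipeline()` uses `seed` for the simulation and
`seed + 1` for annotation generation, in that order, so identical seeds
give byte-identical outputs.

The event log records, for every broken junction, the two block extremities
involved and their reference-frame coordinates. This is the ground truth
against which EBR calls are benchmarked (`ebr_truth_overlap()`), replacing
coordinate liftover: the simulator knows the exact mapping between frames.

## Reconstruction: SFs, adjacency scoring, RACFs

`detect_sfs()` cuts the reference axis at every junction where any genome
interrupts colinearity — a change of target chromosome, target order, or
orientation. Maximal uncut runs at least `resolution` long (default
300 kbp, the standard syntenic-fragment resolution for mammal-scale work,
shared with the msHSB minimum length) become SFs; shorter runs are dropped
but tracked as unplaced spans so coverage statistics remain honest.

`score_adjacencies()` scores each observed SF adjacency at a target node by
phylogeny-weighted presence with weights `1/patristic distance`. Two-sided
support (`sided`) requires at least one descendant carrier plus either an
outgroup carrier or carriers in both child subtrees. The acceptance rule is
a replaceable parameter; the default accepts `score >= 0.5 & sided`. The
threshold is deliberately *inclusive*: on balanced trees the weight
structure frequently puts genuinely well-supported adjacencies (e.g. two
descendants plus an outgroup on a six-tip tree) at exactly 0.5, and a
strict inequality would reject them all; the sidedness requirement is what
actually guards the boundary against one-sided ties.

`assemble_racfs()` accepts adjacencies greedily (score desc, sided first,
lexicographic adjacency id as the final tie-break), refusing any that
would reuse an extremity or close a circular chromosome. This determinism
is a design choice: a global optimiser could trade it for slightly better
likelihoods, but reproducibility and testability matter more at this scale.
`order_racfs()` then concatenates RACFs whose terminal SFs are adjacent in
a 2/3 majority of informative descendant genomes, in the majority
orientation; equal-vote conflicts mean no join, and every decision is
logged. This automates a step that in large published reconstructions is
manual curation; it is validated against simulation truth only.

## Rearrangement algebra

`reversal_distance()` implements the exact Hannenhalli–Pevzner count
`d = (n + 1) − c + h + f` with full hurdle detection (unoriented
interleaving-components that occupy a single contiguous arc of the position
circle) and the fortress case (an odd number of hurdles, at least three,
all of them superhurdles). The test suite sweeps *all* signed permutations
up to n = 5 against breadth-first search and 500 random cases up to n = 8
against an independent exact search pruned only by the cycle lower bound —
the oracle deliberately avoids the hurdle/fortress theory it checks.

`multichromosomal_scenario()` finds a minimal typed scenario between two
genomes over {inversion, fusion, fission} by iterative-deepening A\*. The
admissible heuristic is the double-cut-and-join distance (every allowed
move is a single DCJ) combined with the chromosome-count difference; the
returned scenario replays exactly, and equals the breadth-first-search
optimum on every random test instance. Beyond `exact_limit` blocks
(default 10) a deterministic constructive fallback is used — fissions at
junctions joining blocks of different target chromosomes, fusions in
target order, then optimal per-chromosome reversal sorting — which is
replay-exact but not guaranteed minimal.

`fraction_rearranged()` concretises the inter/intrachromosomal fractions of
an ancestral chromosome in a descendant: interchromosomal = 1 − (share of
mapped length on the majority chromosome); intrachromosomal = 1 − (share of
the majority chromosome's mapped length lying in the maximum-weight
signed-colinear subsequence, taken over both orientations). Both rules are
parameters of interpretation, not of fitting, and are exposed as such.

`classify_orthology()` labels chromosome-level orthology from fractional
segment coverages: 1:1 needs a single partner covering ≥ 95% both ways
(`tol = 0.95`, reflecting that published karyotype tables make qualitative
complete/part calls); 1:n complete needs every partner mapped entirely
back. The packaged MAM↔GGA table encodes the printed complete/partial calls
as stylised fractions — the fractions' magnitudes are synthetic, the calls
are not — and is frozen with an md5 checksum.

## EBRs, reuse, msHSBs

`detect_ebrs()` compares a root-to-tip series of SF arrangements against
the first element (the baseline ancestor). A baseline junction becomes an
EBR on the first branch where it is absent *and stays absent in every node
below*; a transient absence at one intermediate reconstruction is treated
as reconstruction noise, not a break. The EBR interval is the SF-free
reference gap flanking the broken extremity (1-bp placeholder when SFs
abut, flagged); the partner extremity is retained as a secondary
coordinate, and junctions whose extremities end up at distant reference
loci are flagged diffuse. Because the intervals are SF-free gaps, EBRs are
disjoint from msHSBs by construction.

`classify_reuse()` follows the published convention: only EBRs shorter
than 300 kbp participate (the size gate avoids spurious reuse calls caused
by EBR chaining), and reuse requires an overlapping small EBR from an
*independent* lineage — branches that share no root-to-tip path.
Centromere-overlapping EBRs can be flagged (`flag_centromeric_ebrs()`) and
are conventionally excluded from enrichment statistics.

`detect_mshsbs()` intersects the per-species colinear coverage of the
reference (strict set intersection — the package's reading of how pairwise
blocks combine into multispecies blocks) and filters at the shared 300-kbp
floor. `max_mshsb_test()` supplies the exponential order-statistics check:
expected maximum `μ·H_n`, tail probability `1 − (1 − e^{−x/μ})^n`. At the
scale of a genome-wide catalogue (n = 1215 blocks of mean 1.4 Mbp) the
expected maximum is about 10.7 Mbp, which is why individual blocks beyond
10 Mbp are flagged as larger than chance expects.

## Rates and enrichment statistics

`compute_rates()` divides per-branch counts by branch length in My.
`test_rates()` compares each branch with the remaining branches by a
leave-one-out t statistic with the single-outlier standard error,
`(x_i − mean_{−i}) / (sd_{−i}·√(1 + 1/(m−1)))`, df = m − 2, followed by
Benjamini–Hochberg FDR at 0.05. The naive form that omits the `1 + 1/(m−1)`
factor treats the tested branch as noise-free and is anticonservative by
roughly √m; the outlier form is calibrated, which the null-simulation tests
verify. The same procedure drives `gene_density_per_mam()`.

Window statistics follow the published recipe: 10- and 100-kbp windows,
the last partial window kept but flagged; windows with > 50% gap bases or
any centromere overlap removed; region class assigned only on *full*
containment, with boundary-straddling windows falling back to "other".
Gene counts use the gene-start rule (each gene counted once, in the window
containing its start; bases are split across windows) to avoid double
counting. TAD presence means ≥ 1 bp of a TAD body; the compartment label
is A, B, A/B (both compartments intersect the window) or none. Tests are
pairwise two-sided Wilcoxon rank-sum with Bonferroni correction over the
pairs, and Pearson χ² without continuity correction with cross-product
odds ratios (Haldane–Anscombe 0.5 correction, flagged, when a cell is
empty). Repeat subclasses averaging under 100 bp per 10-kbp window in every
region class are suppressed from reports; the published filter sentence
reads "per 10-bp window", which this package interprets as a typo for
10-kbp — consistent with every other use — with the floor exposed as an
argument.

## The annotation generator and what the tests mean

`generate_annotations()` plants the enrichment structure reported for
mammalian EBRs versus msHSBs around breakpoint neighbourhoods (±150 kbp by
default):

| effect | default | null value |
|---|---|---|
| gene density (per 100 kbp) | 2× inside EBRs (2 vs 1) | 1 |
| complete-gene median length | 19 vs 36 kbp (`gene_len_mult = 19/36`) | 1 |
| Alu base density | 1.6× | 1 |
| odds of a 10-kbp window lacking a TAD | 8.5× | 1 |
| odds of the A compartment | 1 (neutral) | 1 |

Genes are a Poisson process with lognormal lengths (sdlog 1); repeat
subclasses are Poisson element processes with stylised element lengths and
genome-wide coverages (Alu 10%, L1 5%, L2 3%, MIR 2%, ERV1 2%,
hAT-Charlie 1.5%, segmental duplications 0.5%). TAD occupancy is drawn
independently per 10-kbp tile and merged into domains. That choice is
deliberate: window-level TAD presence is then exactly Bernoulli, so the χ²
test is calibrated under the null and the planted odds ratio is estimable
without bias. The price is realism — real TADs impose serial correlation
between neighbouring windows, which inflates χ² statistics; on real data a
block-aware test (or domain-level resampling) would be needed where this
package can rely on its generator's independence.

More generally, the simulator omits duplications and losses, nucleotide
sequence, assembly error, and alignment artefacts. Passing the validation
suite therefore shows that the *pipeline logic* is correct under its own
model — recovery of true ancestral adjacencies, truthful EBR placement,
calibrated tests, unbiased effect recovery — not that any particular
biological conclusion transfers to a 32-genome dataset.

## Validation scales and numerical choices

The test suite fixes its problem sizes to keep the full run in a few
minutes: the 6-tip clock-like tree (total length 12 My) with 40 blocks and
2 events/My for reconstruction recovery — about 24 expected events, chosen
so that rearrangement density stays within what 39 junctions can absorb;
10-Mbp genomes × 200 replicates for null calibration; a 50-Mbp genome for
planted-effect recovery; 5,000 Monte-Carlo replicates for the exponential
maximum. Degenerate inputs are handled explicitly: zero-width EBR gaps get
flagged 1-bp placeholders, zero leave-one-out variance yields NA p-values
rather than zero, empty groups are skipped and flagged in comparison
tables, and all greedy tie-breaks are lexicographic so that reruns are
byte-identical.

## Known limitations

* The constructive scenario fallback above `exact_limit` blocks is not
  guaranteed minimal; branch event counts on large genomes are upper
  bounds on the parsimony count.
* RACF chromosome ordering is validated against simulation truth only; it
  will not reproduce manual curation decisions made in published
  reconstructions.
* Reference bias: SFs are defined on one reference genome. Rebuilding with
  another reference changes the SF universe; `compare_reconstructions()`
  quantifies the disagreement (maintained/extra/inconsistent adjacencies
  and the inconsistent length fraction) but does not remove the bias.
* The annotation generator's independence assumptions (see above) make it
  a calibration instrument, not a realistic genome model.
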