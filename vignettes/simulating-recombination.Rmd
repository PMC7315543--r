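---
title: "Simulating prokaryotic genome evolution with homologous recombination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating prokaryotic genome evolution with homologous recombination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recombsim)
```

## The model

`recombsim` evolves a root genome forward in time along a rooted phylogeny
whose branch lengths are expected substitutions per site. The root sequence
is either generated de novo — each position G or C with probability `gc`
(split evenly), A or T otherwise — or supplied as FASTA. It is treated as a
concatenate of protein-coding genes with no intergenic DNA, partitioned into
genes of fixed size (`gene_length`, default 999 bp).

The central design constraint is that **only lineages that co-exist in time
may recombine**. The depth axis of the tree is cut at every distinct node
depth, producing *time segments*: maximal intervals within which the set of
living branches is constant. Cutting at every node depth is the minimal rule
with this property; it is a package choice, since constant membership alone
does not pin down the boundaries (in particular for non-ultrametric trees).
Non-ultrametric input is accepted: a leaf shallower than the deepest leaf
simply stops appearing in later segments, and the frozen lineage neither
receives events nor serves as a recombination donor afterwards — the only
reading consistent with confining recombination to co-existing sequences.

Within a segment of width `l`, each living branch draws a mutation count
`M ~ Poisson(l · L)` and a recombination-attempt count
`R ~ Poisson(ρ · l · L)`, with `L` the lineage's current genome length
(core plus accessory, so gene-rich genomes receive proportionally more
events) and ρ the recombination rate defined *relative to the substitution
rate*: attempts arrive at ρ times the mutation rate. We note that a
per-branch-segment draw and a single per-branch draw split across segments
are distributionally identical by Poisson additivity. Events are then
introduced in random interleaved order: repeatedly pick a uniformly random
lineage with remaining budget, pick mutation vs recombination in proportion
to its remaining counts, and apply the event. All lineages of a segment
therefore evolve simultaneously, and recombination donors always reflect the
partially evolved state of the segment, not its start. At internal nodes the
parent genome is copied verbatim to each child; no events occur at nodes.

### Substitution

Because the event *count* is fixed by the Poisson draw, the substitution
models reduce to per-event conditional target distributions: given that a
substitution hits a site, the replacement base is drawn from the model's
normalized weights for the current base (never the same base; repeated hits
at a site act on the current state). JC69 is uniform over the three
alternatives; K2P gives the transition target weight κ and each transversion
weight 1, so K2P with κ = 1 is exactly JC69. Two conventions the model names
alone do not fix, chosen and documented here: **K3P** weights transitions
κ1, transversions within the same complementary pair (A↔T, C↔G) κ2 and the
remaining transversions 1; **GTR** weights origin→target by exchangeability
× equilibrium frequency of the target, with equilibrium frequencies derived
from the configured GC content `((1−gc)/2, gc/2, gc/2, (1−gc)/2)` for
(A, C, G, T) unless overridden. Under non-uniform models the realized
composition can drift toward the model's stationary distribution over deep
trees; this is not corrected.

Codon-position selection is modelled by a rate profile `(w1, w2, w3)`,
renormalized to sum to one: the profile redistributes *where* events land
(position class proportional to its weight, uniform within the class) but
never changes how many there are — the overall rate stays imposed by the
branch lengths and the rescaling coefficient.

### Recombination

A recombination attempt places a tract start uniformly on the recipient's
genome and draws the raw length from a geometric distribution parameterized
on support {1, 2, ...} with success probability 1/δ, so the mean is exactly
δ. Genomes are linear, so tracts are truncated at the right end rather than
wrapped or redrawn; truncation slightly lowers the realized mean tract
length, which the stats output reports alongside the raw mean. The donor is
drawn uniformly among the segment's other lineages (self-donation is
excluded as a no-op that would deflate η); a single-lineage segment — e.g. a
basal root branch — records the attempt as skipped.

With the divergence bias enabled, the per-site divergence π of the
*candidate tract's homologous portion* is computed first — local divergence
is what the mismatch-repair machinery senses, so the window is the tract,
not the genome — and the event succeeds with probability `10^(−πΦ)`
(Φ ≥ 0, default 18.1). Rejected attempts are **discarded**, reducing the
realized recombination rate; both attempted and accepted counts are logged
so the realized rate is visible. Resampling rejected attempts instead would
keep the attempt count at the Poisson draw; discarding was chosen because
the bias is a biased probability of recombination, not a re-weighting of
donors, and the alternative would silently decouple ρ from the attempt
process.

Transfer is non-reciprocal: the donor is never modified. Only positions
whose containing gene is shared between donor and recipient are overwritten.
Whole accessory genes move only when *both* tract breakpoints fall inside
shared genes: donor-only genes fully contained between the breakpoint genes
are inserted whole, recipient-only genes deleted whole. A breakpoint inside
a non-shared gene transfers only the shared fragments. Recombination
therefore never creates partial indels, and homologous gene copies have
equal length everywhere, asserted after every simulated run in the test
suite.

### Gene gain and loss

Gains model horizontal transfer from outside the simulated dataset: a fresh
gene id, a new random sequence at the configured GC, inserted at a uniform
random rank in gene order (nothing in the model constrains the position or
length of gained genes; both are configurable, defaulting to a uniform rank
and `gene_length`). Losses remove a uniformly chosen gene —
any gene, since "core" is a property of the final dataset, not a protection
during simulation. Counts per branch segment are Poisson with means
`gain_rate·l` and `loss_rate·l`. Flux events are applied at the start of
each branch segment, before the segment's mutation/recombination budgets are
drawn, so those budgets see the post-flux genome length.

### Statistics

η is defined as the per-site SNP density of accepted tracts (total SNPs
exchanged / total recombined bp). The phrase "average number of
polymorphisms exchanged by recombination" can also be read per event; only
the per-site reading makes `r/m = ρ·η·δ` dimensionally consistent, so the
per-event mean is reported separately as `mean_snps_per_event = η ×` mean
realized tract. `r/m` is reported twice — from the relationship ρ·η·δ and as
the direct count SNPs/mutations — and the direct count is labelled
authoritative; the two agree to within a few percent in recombination-heavy
runs and differ through truncation, skipped attempts and bias rejection.

## Tunable parameters

| parameter | meaning | units | default |
|---|---|---|---|
| `L` | root genome length | bp (multiple of 3) | 30000 |
| `gc` | GC content of root and gained genes | fraction | 0.5 |
| `model`, params | substitution model | — | JC69 |
| `codon_rates` | relative rates of codon positions | — | 1,1,1 |
| `rho` | recombination attempts per mutation | — | required |
| `delta` | mean tract length | bp | 100 |
| `bias`, `phi` | divergence bias and slope | — | off, 18.1 |
| `gain_rate`, `loss_rate` | gene flux per unit branch length | — | 0 |
| `scale` | branch-length multiplier | — | 1 |
| `gene_length` | root/gained gene size | bp (multiple of 3) | 999 |
| `seed` | RNG seed | integer | 1 |

A rescaling coefficient of 0.5 halves every branch; 0.05 is a typical choice
to thin polymorphism down to realistic intra-species levels on an
ML tree. Φ is species-specific where it has been measured; 18.1
(*S. pneumoniae*) is intermediate among known values, hence the default.

## Numerical and degenerate-input choices

Depth boundaries closer than 1e-9 are merged when cutting segments, and
per-branch segment overlaps reconstruct each branch length to the same
tolerance. Zero-length branches are legal and receive zero expected events;
a zero-depth tree returns the root genome at every leaf; a single-taxon tree
is rejected when segments are requested ("nothing to simulate"). Trees are
used as rooted, as written, with no rerooting; a basal root edge is honoured
as a single-lineage first segment. Missing branch lengths, duplicate leaf
names and malformed Newick are hard errors — no silent defaults. All
randomness flows through R's global RNG seeded once per run and consumed in
a fixed documented order (root sequence, then per segment: flux, budgets,
event interleaving), so identical configuration and seed reproduce outputs
byte-for-byte.

## What the test conditions do and do not show

The test and benchmark runs use synthetic trees (2–34 leaves), genomes of
3–100 kb, and the parameter sets exercised throughout: GC 0.45–0.5,
κ = 1.6, codon profile (0.15, 0.07, 0.78), δ = 100 bp, ρ ≤ 2. Problem sizes
were chosen so that stochastic checks have ≥ 10^5 events where a 4-standard-
error band is asserted. The generator emulates branch-proportional Poisson
substitution, segment-confined gene conversion and whole-gene flux; it does
not emulate intergenic DNA, within-gene indels, selection coefficients,
demography or population dynamics below the tree's resolution — the tree
*is* the genealogy, and selection enters only through codon-position rates.
Passing tests therefore validate the simulator's internal consistency and
parameter recovery, not any claim about a particular real species.

## Known limitations

- Realized GC drifts under non-uniform models on deep trees (documented
  above, not corrected).
- Gene order matters only for tract placement; alignments always use
  canonical order (root genes, then gained genes by age), so genome
  rearrangement is not modelled.
- Recombination donors are internal to the dataset; imports from outside
  enter only as whole gained genes.
- Detection-side analyses (e.g. inferring recombination back from the
  alignments) are out of scope; the event logs are the ground truth such
  tools can be benchmarked against.
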