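---
title: "Comparative gene maps and ancestral karyotype reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative gene maps and ancestral karyotype reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyorec)
```

## The problem

Marsupial karyotypes are remarkably conserved: cross-species chromosome
painting resolves all autosomal variation into 18 conserved segments
(C1–C18) plus the X. Two diploid numbers dominate the infraclass, 2n = 14
and 2n = 22, and the identity of the ancestral complement was debated for
decades. Settling it requires (i) gene maps dense enough to see
rearrangements that painting cannot, and (ii) an outgroup to polarize
ancestral versus derived segment arrangements.

`karyorec` implements that workflow end to end: conserved synteny-block
detection between two genomes and FISH probe-target selection; assembly and
accounting of a species gene map with discrepancy flagging; delineation of
oriented conserved segments between two maps with painting-label boundaries;
and outgroup-anchored adjacency parsimony that reconstructs ancestral
karyotypes as contiguous ancestral regions (CARs). A rearrangement simulator
generates signed genomes with known histories so every stage is validated
against planted truth rather than against data that cannot be redistributed.

## Blocks, maps and segments

**Synteny blocks** (`detect_blocks`). Orthologs are sorted along species A; a
block is a maximal run of consecutive species-A genes whose species-B
chromosome is constant. Gene order *within* species B is deliberately not
required to be conserved — inversions inside a block do not split it, they
only clear its `order_conserved` flag. This yields fewer, larger blocks than
order-conserved definitions, which is what makes two-probe FISH mapping of
block ends efficient. Blocks below `min_span_kb` (default 100 kb, the
resolution floor of the synteny source) are discarded; the filter is a
parameter because the published accounting retains a 0.03 Mb block,
indicating the cutoff was not applied uniformly at source.

**Probe targets** (`select_probe_targets`). Blocks spanning more than
`large_threshold_mb` (default 3 Mb, matching the roughly 1 Mb order
resolution of FISH on condensed metaphase chromosomes) contribute their two
end genes; smaller blocks contribute the single gene nearest the block
midpoint. A span of exactly the threshold takes the small-block rule (the
published rule is strictly "greater than"), and midpoint ties break toward
the earlier gene along species A, so selection is deterministic.

**Gene maps** (`merge_maps`, `summarize_map`, `flag_discrepancies`,
`order_confidence`). FISH band assignments are modelled as point coordinates
(a single ordering key); one location per gene is enforced, and a gene
reported at two locations is an error rather than a silent overwrite. A gene
whose observed chromosome is not homologous to its expected chromosome is
flagged: `transposition_candidate` when an expected-map neighbour is also
discordant, else `assembly_error_candidate` — both advisory, since single-gene
cases cannot be resolved from map data alone. `order_confidence` groups genes
closer than `resolution_mb` (default 1 Mb) into order-uncertain runs instead
of guessing an order below FISH resolution.

**Homology segments** (`build_segments`, `assign_painting`). Between two
maps, a segment is a maximal gene run consecutive in both species with
consistent direction; consecutiveness is defined on gene-order ranks
restricted to the shared gene universe, not on base-pair gaps, because FISH
maps are ordinally but not metrically reliable. Singleton segments are
`unoriented`. Painting labels are assigned per segment by majority;
boundaries between differently labelled segments are `definitive` unless a
flank contains interleaved minority labels or labels alternate within a
window of `window` genes (default 3 — the scale at which published boundary
calls became inconclusive); such boundaries are `ambiguous`.

## Adjacency parsimony and CAR assembly

A signed genome is encoded as the set of adjacencies between marker
extremities (head/tail), with telomeres as a special extremity. For
reconstruction at a named internal node:

1. **Candidates** are the union of internal adjacencies over all leaf
   genomes.
2. **Scoring.** Each candidate is a binary presence/absence character.
   Leaves missing either marker are treated as missing data. Unit-cost
   parsimony (Sankoff down/up pass, equivalent to two-pass Fitch for a
   binary character) yields the set of states attainable in a most
   parsimonious reconstruction at the target node: unambiguously present
   scores 1, unambiguously absent 0, ambiguous 0.5 — unless the designated
   outgroup carries the adjacency, which breaks ambiguity toward present
   (score 1). Outgroup *absence* does not force absence; the outgroup only
   arbitrates toward presence, mirroring how chicken gene order was used as
   a guide rather than a veto.
3. **CAR assembly.** Candidates with positive weight are sorted by weight
   (descending), then lexicographically, and accepted greedily iff both
   extremities are free and acceptance does not close a cycle (chromosomes
   are linear; cycle-closing adjacencies are skipped and logged on the
   result object). Sex-linked markers are pre-grouped into a single CAR and
   never joined to autosomes. Maximal paths are the CARs; the diploid number
   is twice the CAR count (the X CAR counts as a pair like any autosome, so
   6 autosomes + X encode 2n = 14).

Greedy assembly with a deterministic tie-break was chosen over search-based
optimisation deliberately: at 19–21 markers the weight-1 adjacency set is
almost always conflict-free, reproducibility matters more than optimality at
the margin, and the historical reconstruction this formalizes was itself
assembled by inspection. Exact (e.g. ILP) assembly is out of scope.

`dcj_distance` computes the double-cut-and-join distance in closed form,
`d = N − C − I/2`, from the cycle/path decomposition of the adjacency graph
(vertices: adjacencies and telomeres of both genomes; edges join vertices
sharing an extremity). `infer_events` splits the distance into fissions or
fusions implied by the net chromosome-number change, attributing the
remainder to inversions or other intrachromosomal operations — a parsimony
budget, not a unique event history.

## The packaged marsupial fixture

The fixture encodes segment arrangements for six marsupials (fat-tailed
dunnart, tammar wallaby, rufous bettong, brushtail possum, grey short-tailed
opossum, common opossum) and a chicken-derived outgroup proxy, on the
alphabet C1–C18 + X with C1 and C4 split into a/b sub-segments (treated as
ordinary distinct markers). Only part of each karyotype is stated verbatim
in the literature; every line reconstructed from qualitative statements is
flagged `reconstructed-from-literature` in the fixture file, and the chicken
entry is flagged `synthetic` — it is not a chicken karyotype but a proxy
genome carrying exactly the six outgroup-supported linkages (C10-C12-C11,
the C1–C6 chain, C8-C7-C9, C13-C14, C15-C16, C17-C18). Reconstruction at the
marsupial root yields 7 CARs (2n = 14), with the dunnart-order chromosome 1
chain recovered segment for segment.

The therian-ancestor sketch (`therian_fixture`) is deliberately coarse: the
published therian karyotype is resolved at human-chromosome-colour
granularity that the C-segment alphabet cannot express. The documented
alternative placement of human-chromosome-19 material on two rather than
three chromosomes is exposed as `split_hsa19 = c("three", "two")`, defaulting
to the published three-way split. The sketch is not used in any accounting
check.

The accounting tables (per-chromosome block counts; per-chromosome gene-map
counts by provenance) are packaged as published. `expand_block_summary` and
`expand_map_summary` expand the counts into synthetic record lists so that
the summary operations recompute the totals (208 blocks overall, 154 on the
six newly analysed autosomes; 242 newly mapped genes, 554 in total) rather
than copying them.

## The simulator and what passing tests show

`simulate_genomes` evolves a signed genome along a tree: per-branch event
counts are Poisson(rate × branch length), truncated at
`max_events_per_branch` by rejection; types are drawn from the event mix,
renormalized over what the current genome admits (no fusion with one
chromosome, no fission of single-marker chromosomes, no reciprocal
translocation without a multi-marker partner). Defaults are the study
conditions: the 19-marker, 7-chromosome ancestral configuration; a six-leaf
unit-branch tree (one outgroup, five ingroup); rate 1 truncated at 2 events
per branch; inversion:fission:fusion = 0.6:0.2:0.2 with translocation
implemented but weighted 0, since inversions dominate marsupial chromosome
evolution and translocations are not part of the inferred histories. Unit
branch lengths are a convention, not an estimate. Each branch consumes an
RNG substream derived by stable string hashing of the child node label, so
results are independent of traversal order, and replaying the logged history
reproduces every node genome exactly.

`make_ortholog_table` and `genome_to_gene_map` expand markers into evenly
spaced genes (default 5 per marker, 16.2 Mb per marker — the published mean
conserved-block size — as a realistic coordinate scale), letting the block,
map and segment stages run end to end on data with planted truth.

What the simulator does *not* emulate: unequal marker sizes, gene gain/loss,
missing orthologs, assembly errors, breakpoint reuse and centromere
repositioning. Passing recovery tests therefore demonstrate correctness of
the inference machinery under the stated regime (few events per branch,
complete marker sets), not robustness to the noise sources of real
cytogenetic data.

## Numerical and edge-case choices

- Coordinates: 1-based inclusive on disk (genome-browser convention),
  0-based half-open internally; conversion preserves interval length.
- Chromosome identifiers are always character, even when they look numeric.
- Block spans are reported to 2 decimal places in summaries.
- A single-gene block has span near zero and is removed by any positive
  span filter; an empty result writes a header-only table.
- CAR canonical orientation: the reading with more forward-oriented markers,
  ties broken lexicographically; CARs sorted by their string form.
- Degenerate parsimony inputs (a candidate adjacency with no informative
  leaf) score as ambiguous, 0.5.
- DCJ requires identical marker sets and errors otherwise; distance 0 iff
  genomes are equal up to chromosome order and whole-chromosome reversal.

## Problem sizes used in validation

The test suite checks the DCJ formula against a breadth-first-search oracle
over the full rearrangement state space exhaustively for up to 5 markers
(9,496 states at n = 5, one sweep covering every linear genome, plus random
non-identity pairs at n ≤ 4 — the distance is invariant under the extremity
relabeling that maps any source genome to the identity, so the identity
sweep is representative of all pairs). Parsimony weights are checked against
exhaustive minimum-change enumeration on 4-leaf trees over up to 6 markers;
block and segment detection against brute-force run enumeration on 200
random instances; parameter recovery over 100 seeded replicates of the
default simulation (median adjacency precision and recall are required to
reach 0.9, and the median CAR-count error 0). These sizes were chosen as the
largest at which the oracles remain exact and fast.

## Known limitations

- Adjacency parsimony treats each adjacency independently; the greedy
  assembly resolves conflicts deterministically but is not guaranteed
  globally optimal for pathological weight configurations.
- The fixture encodes segment-level arrangements; sub-segment rearrangements
  (visible in gene-level maps) are below its resolution, and per-species
  lines not stated verbatim in the literature are representative choices.
- `infer_events` classifies only the chromosome-number component of a DCJ
  scenario; it does not reconstruct an ordered event sequence.
- Circular chromosomes are rejected throughout: the package models
  karyotypes of organisms with linear chromosomes.
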