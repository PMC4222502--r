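# karyorec

Comparative gene maps and ancestral karyotype reconstruction for marsupials.

Marsupial autosomes are composed of 18 chromosome segments (C1–C18, plus the
X) conserved across the whole infraclass, and the ancestral diploid number —
2n = 14 or 2n = 22 — was debated for decades. `karyorec` implements the
comparative-mapping workflow that settles this kind of question from gene
maps and an outgroup:

- **Conserved synteny blocks** between two genomes from an ortholog position
  table: a block is a maximal run of genes along species A lying on one
  species-B chromosome, *without* requiring internal order conservation
  (inversions only clear an `order_conserved` flag). FISH probe targets are
  selected at both ends of blocks > 3 Mb and at the midpoint gene of smaller
  blocks.
- **Cytogenetic map accounting**: merging newly mapped genes with previous
  assignments under a one-location-per-gene contract, per-chromosome
  provenance counts, discrepancy flagging (observed chromosome not
  homologous to the expected one), and order-uncertainty grouping below FISH
  resolution (1 Mb).
- **Comparative maps**: oriented conserved segments between two gene maps
  (maximal runs consecutive in both species with consistent direction, on
  ordinal ranks), painting-label assignment by majority, and
  definitive/ambiguous boundary calls.
- **Ancestral karyotype reconstruction**: each candidate adjacency between
  marker extremities is scored by unit-cost parsimony on the species tree
  (most-parsimonious state set at the target node; present = 1, ambiguous =
  0.5, outgroup presence breaks ambiguity toward present), and contiguous
  ancestral regions (CARs) are assembled greedily under linearity and
  extremity-uniqueness constraints. The diploid number is twice the CAR
  count. Rearrangement distances use the double-cut-and-join (DCJ) closed
  form `d = N − C − I/2` over the adjacency-graph cycle/path decomposition.
- **A rearrangement simulator** (inversion / fission / fusion /
  translocation along a tree, Poisson per-branch event counts, replayable
  logged histories) that substitutes for wet-lab FISH data and lets every
  stage be validated against planted truth.

## Worked example

Reconstructing the ancestral marsupial karyotype from the packaged segment
arrangements (six marsupials, chicken-derived outgroup adjacencies):

```r
library(karyorec)
fx <- marsupial_fixture()
k  <- reconstruct_ancestor(fx$tree, fx$genomes, fx$node, outgroup = fx$outgroup)
print(k)
#> ancestral_karyotype at node 'Marsupialia': 7 CAR(s), 2n = 14
#>   CAR1: C10 C12 C11
#>   CAR2: C13 C14
#>   CAR3: C15 C16
#>   CAR4: C17 C18
#>   CAR5: C2 C1a C4a C3 C1b C4b C5 C6
#>   CAR6: C8 C7 C9
#>   CAR7: X
infer_events(k, fx$genomes$M_domestica)
#> Marsupialia -> M_domestica: 4 DCJ operation(s): 2 fission(s), 0 fusion(s), 2 inversion(s)/other.
```

Seven CARs — six autosomes plus the X — give 2n = 14: the low-diploid-number
ancestor. The grey short-tailed opossum (2n = 18) derives from it by two
fissions plus two intrachromosomal operations; the fat-tailed dunnart
(2n = 14) sits at DCJ distance 0 from the reconstruction.

The numbered drivers under `analysis/` run the whole pipeline on simulated
data and the packaged tables, writing their outputs under `results/`:

```sh
Rscript analysis/01_simulate.R        # signed-genome evolution + ortholog table
Rscript analysis/02_blocks.R          # block detection, probe targets, accounting
Rscript analysis/03_comparative_map.R # segments, painting boundaries, map accounting
Rscript analysis/04_reconstruct.R     # marsupial ancestor + event scenarios
Rscript analysis/05_recovery.R        # 100-replicate parameter-recovery study
```

For example, `analysis/05_recovery.R` prints:

```
Recovery over 100 replicates (19 markers, 6 leaves, <=2 events/branch):
  median precision 1.000, median recall 1.000, median F1 1.000
  median CAR-count error 0; exact CAR count in 85/100 replicates
```

i.e. under the study conditions the true ancestral adjacencies are recovered
essentially perfectly, and the chromosome count exactly in 85% of runs.

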